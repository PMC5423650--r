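# Annotated-genome data model: circular/linear sequence plus typed, stranded,
# 1-based-inclusive features, mirroring the GenBank coordinate convention.

FEATURE_TYPES <- c("CDS", "tRNA", "rRNA", "control_region")

# Canonical blattarian gene order (J/N-strand layout of the ancestral insect
# mitogenome); used for sorting partitions and for the synthetic generator.
CANONICAL_PCGS <- c("ND2", "COX1", "COX2", "ATP8", "ATP6", "COX3", "ND3",
                    "ND5", "ND4", "ND4L", "ND6", "CYTB", "ND1")
CANONICAL_RRNAS <- c("rrnL", "rrnS")

#' Construct an annotated mitogenome
#'
#' @param id genome label.
#' @param sequence upper-case nucleotide string over A/C/G/T/N.
#' @param features data frame with columns `name`, `ftype`, `strand`,
#'   `start`, `end` and optionally `wraps_origin` (logical) and `anticodon`;
#'   coordinates are 1-based inclusive. Rows are re-sorted by `start`.
#' @param topology `"circular"` (default) or `"linear"`.
#' @return object of class `annotated_genome`.
#' @export
annotated_genome <- function(id, sequence, features = empty_features(),
                             topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  stopifnot(is.character(sequence), length(sequence) == 1L, nchar(sequence) >= 1L)
  sequence <- toupper(sequence)
  bad <- setdiff(unique(seq_chars(sequence)), c(DNA_BASES, "N"))
  if (length(bad) > 0L)
    stop("sequence contains non-ACGTN characters: ", paste(bad, collapse = ", "))
  features <- normalize_features(features, nchar(sequence), topology)
  structure(list(id = id, sequence = sequence, topology = topology,
                 features = features),
            class = "annotated_genome")
}

empty_features <- function() {
  data.frame(name = character(), ftype = character(), strand = character(),
             start = integer(), end = integer(), wraps_origin = logical(),
             anticodon = character(), stringsAsFactors = FALSE)
}

# Guess the feature class from the controlled gene label.
infer_ftype <- function(name) {
  ifelse(grepl("^tRNA", name), "tRNA",
    ifelse(grepl("^rrn", name), "rRNA",
      ifelse(name %in% c("CR", "A+T-rich", "control_region", "D-loop"),
             "control_region", "CDS")))
}

normalize_features <- function(features, genome_length, topology) {
  stopifnot(is.data.frame(features))
  need <- c("name", "strand", "start", "end")
  miss <- setdiff(need, names(features))
  if (length(miss) > 0L)
    stop("feature table lacks columns: ", paste(miss, collapse = ", "))
  if (is.null(features$ftype) && nrow(features) > 0L)
    features$ftype <- infer_ftype(features$name)
  if (is.null(features$ftype)) features$ftype <- character()
  if (is.null(features$wraps_origin)) features$wraps_origin <- rep(FALSE, nrow(features))
  if (is.null(features$anticodon)) features$anticodon <- rep(NA_character_, nrow(features))
  features$anticodon[!is.na(features$anticodon) & features$anticodon == ""] <- NA_character_
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  if (nrow(features) > 0L) {
    if (anyNA(features$start) || anyNA(features$end))
      stop("malformed coordinates: start/end must be numeric")
    if (!all(features$strand %in% c("J", "N")))
      stop("strand must be 'J' or 'N'")
    bad <- features$end < features$start & !features$wraps_origin
    if (any(bad))
      stop("end < start without wraps_origin for feature(s): ",
           paste(features$name[bad], collapse = ", "))
    if (any(features$wraps_origin) && topology != "circular")
      stop("wraps_origin features require circular topology")
    if (any(features$start < 1L | features$start > genome_length |
            features$end < 1L | features$end > genome_length))
      stop("feature coordinates outside [1, genome length]")
    features <- features[order(features$start, features$end), , drop = FALSE]
    rownames(features) <- NULL
  }
  front <- c("name", "ftype", "strand", "start", "end", "wraps_origin", "anticodon")
  features[, c(front, setdiff(names(features), front)), drop = FALSE]
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("<annotated_genome> %s: %s bp, %s, %d features\n",
              x$id, format(genome_length(x), big.mark = ","), x$topology,
              nrow(x$features)))
  tab <- table(x$features$ftype)
  if (length(tab) > 0L)
    cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Genome length in base pairs
#' @param genome an `annotated_genome`.
#' @export
genome_length <- function(genome) nchar(genome$sequence)

#' Length of a feature, resolving wrap-around
#'
#' `end - start + 1`, plus the genome length when the feature wraps the
#' origin of a circular genome.
#'
#' @param feature one-row feature data frame (or list) with `start`, `end`,
#'   `wraps_origin`.
#' @param genome_length genome length in bp (needed for wrapping features).
#' @export
feature_length <- function(feature, genome_length = NULL) {
  len <- feature$end - feature$start + 1L
  wraps <- isTRUE(feature$wraps_origin) | (is.logical(feature$wraps_origin) & feature$wraps_origin)
  if (any(wraps)) {
    if (is.null(genome_length)) stop("genome_length required for wrapping features")
    len[wraps] <- len[wraps] + genome_length
  }
  as.integer(len)
}

#' Read an annotated genome
#'
#' Reads either a GenBank flat file or the package's feature-table dialect
#' (TSV with header `gene  ftype  strand  start  end  anticodon`, 1-based
#' inclusive coordinates, strand `J`/`N`). For feature tables the sequence is
#' taken from `fasta`; when only coordinate arithmetic is needed a sequence of
#' `N` of length `genome_length` (default: the maximum annotated coordinate)
#' is substituted.
#'
#' @param path path to the annotation file.
#' @param format `"auto"` (default; sniffs the file), `"genbank"` or
#'   `"feature_table"`.
#' @param fasta optional FASTA file providing the genome sequence
#'   (feature-table input only).
#' @param genome_length optional genome length when no FASTA is given.
#' @param id genome label; defaults to the file name or record locus.
#' @param topology `"circular"` or `"linear"`.
#' @return an [annotated_genome()].
#' @export
read_genome <- function(path, format = c("auto", "feature_table", "genbank"),
                        fasta = NULL, genome_length = NULL, id = NULL,
                        topology = "circular") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    head1 <- readLines(path, n = 1L)
    format <- if (grepl("^LOCUS", head1)) "genbank" else "feature_table"
  }
  if (format == "genbank") return(read_genbank(path, id = id))

  tab <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (!all(c("gene", "strand", "start", "end") %in% names(tab)))
    stop("feature table must have columns gene, strand, start, end")
  suppressWarnings({
    starts <- as.integer(tab$start)
    ends <- as.integer(tab$end)
  })
  bad <- which(is.na(starts) | is.na(ends))
  if (length(bad) > 0L)
    stop("malformed coordinates at line ", bad[1L] + 1L, " of ", path)
  n_rows <- nrow(tab)
  feats <- data.frame(name = tab$gene,
                      ftype = tab$ftype %||% infer_ftype(tab$gene),
                      strand = tab$strand, start = starts, end = ends,
                      wraps_origin = if (is.null(tab$wraps_origin))
                                       rep(FALSE, n_rows)
                                     else as.logical(tab$wraps_origin),
                      anticodon = tab$anticodon %||% rep(NA_character_, n_rows),
                      stringsAsFactors = FALSE)
  for (extra in setdiff(names(tab), c("gene", "ftype", "strand", "start",
                                      "end", "wraps_origin", "anticodon")))
    feats[[extra]] <- tab[[extra]]

  if (!is.null(fasta)) {
    seqs <- Biostrings::readDNAStringSet(fasta)
    if (length(seqs) != 1L) stop("expected a single-sequence FASTA: ", fasta)
    sequence <- toupper(as.character(seqs[[1L]]))
    if (is.null(id)) id <- names(seqs)[1L]
  } else {
    L <- genome_length %||% if (nrow(feats) > 0L) max(feats$end) else 1L
    if (nrow(feats) > 0L && L < max(feats$end))
      stop("genome_length shorter than annotated coordinates")
    sequence <- strrep("N", L)
  }
  genome <- annotated_genome(id %||% basename(path), sequence, feats,
                             topology = topology)
  if (nrow(genome$features) > 0L && max(genome$features$end) > genome_length(genome))
    stop("sequence/feature length mismatch for ", path)
  genome
}

#' Write a feature table
#'
#' Writes the package's TSV feature-table dialect; [read_genome()] round-trips
#' coordinates bit-exactly.
#'
#' @param genome an `annotated_genome`.
#' @param path output path.
#' @export
write_feature_table <- function(genome, path) {
  f <- genome$features
  out <- data.frame(gene = f$name, ftype = f$ftype, strand = f$strand,
                    start = f$start, end = f$end,
                    wraps_origin = f$wraps_origin,
                    anticodon = ifelse(is.na(f$anticodon), "", f$anticodon),
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Locate a feature by name or row index; returns a one-row data frame.
resolve_feature <- function(genome, feature) {
  if (is.character(feature)) {
    hit <- which(genome$features$name == feature)
    if (length(hit) == 0L) stop("no feature named ", feature)
    genome$features[hit[1L], , drop = FALSE]
  } else if (is.numeric(feature)) {
    genome$features[feature, , drop = FALSE]
  } else feature
}

#' Extract the sequence of a feature
#'
#' J-strand features return the stored subsequence; N-strand features return
#' its reverse complement. Features wrapping the origin of a circular genome
#' are concatenated across position 1.
#'
#' @param genome an `annotated_genome`.
#' @param feature feature name, row index, or one-row feature data frame.
#' @return nucleotide string whose length equals the declared feature length.
#' @export
extract_feature_sequence <- function(genome, feature) {
  f <- resolve_feature(genome, feature)
  L <- genome_length(genome)
  if (f$end > L || f$start > L || f$start < 1L) stop("feature out of range")
  if (isTRUE(f$wraps_origin)) {
    if (genome$topology != "circular")
      stop("feature wraps origin on a linear genome")
    s <- paste0(substr(genome$sequence, f$start, L),
                substr(genome$sequence, 1L, f$end))
  } else {
    s <- substr(genome$sequence, f$start, f$end)
  }
  if (f$strand == "N") s <- revcomp(s)
  s
}

#' Intergenic spacers and gene overlaps
#'
#' Walks adjacent feature pairs in coordinate order (closing the circle for
#' circular genomes) and reports, for each pair, whether they are separated by
#' a spacer (`next.start - prev.end - 1 > 0`), overlap
#' (`prev.end - next.start + 1 > 0`), or abut exactly.
#'
#' @param genome an `annotated_genome` (at least 2 features for a non-empty
#'   result).
#' @return data frame with columns `upstream`, `downstream`, `kind`
#'   (`spacer`/`overlap`/`abutting`) and `length` (bp, non-negative).
#' @export
compute_spacers_overlaps <- function(genome) {
  f <- genome$features
  empty <- data.frame(upstream = character(), downstream = character(),
                      kind = character(), length = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(f) < 2L) return(empty)
  n <- nrow(f)
  L <- genome_length(genome)
  prev_idx <- seq_len(n)
  next_idx <- c(seq_len(n)[-1L], 1L)
  if (genome$topology != "circular") {
    prev_idx <- prev_idx[-n]
    next_idx <- next_idx[-n]
  }
  prev_end <- f$end[prev_idx] + ifelse(f$wraps_origin[prev_idx], L, 0L)
  next_start <- f$start[next_idx]
  # Closing pair of a circular genome: measure the gap across the origin.
  closing <- next_idx < prev_idx
  gap <- next_start - prev_end - 1L
  gap[closing] <- next_start[closing] + L - prev_end[closing] - 1L
  kind <- ifelse(gap > 0L, "spacer", ifelse(gap < 0L, "overlap", "abutting"))
  data.frame(upstream = f$name[prev_idx], downstream = f$name[next_idx],
             kind = kind, length = as.integer(abs(gap)),
             stringsAsFactors = FALSE)
}

#' Per-feature length table with range summary
#'
#' @param genome an `annotated_genome`.
#' @param ftype optional feature class filter (`"CDS"`, `"tRNA"`, `"rRNA"`,
#'   `"control_region"`).
#' @return data frame `(name, ftype, length)` with attributes `min` and `max`.
#' @export
feature_length_table <- function(genome, ftype = NULL) {
  f <- genome$features
  if (!is.null(ftype)) f <- f[f$ftype %in% ftype, , drop = FALSE]
  out <- data.frame(name = f$name, ftype = f$ftype,
                    length = feature_length(f, genome_length(genome)),
                    stringsAsFactors = FALSE)
  attr(out, "min") <- if (nrow(out) > 0L) min(out$length) else NA_integer_
  attr(out, "max") <- if (nrow(out) > 0L) max(out$length) else NA_integer_
  out
}

#' Write a spacer/overlap report
#' @param spacers result of [compute_spacers_overlaps()].
#' @param path output TSV path.
#' @export
write_spacer_report <- function(spacers, path) {
  write.table(spacers, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
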