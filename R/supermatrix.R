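# Phylogenetic dataset construction: per-gene alignments, codon-position
# filtering, gap-fraction column filtering, and concatenation into the four
# standard supermatrices (ALL-123, ALL-12, PCG-123, PCG-12) with partition
# bookkeeping and PHYLIP/NEXUS/FASTA output.

SUPERMATRIX_MODES <- c("ALL-123", "ALL-12", "PCG-123", "PCG-12")

CANONICAL_TRNAS <- c(
  "tRNA-Ile", "tRNA-Gln", "tRNA-Met", "tRNA-Trp", "tRNA-Cys", "tRNA-Tyr",
  "tRNA-Leu(UUR)", "tRNA-Lys", "tRNA-Asp", "tRNA-Gly", "tRNA-Ala", "tRNA-Arg",
  "tRNA-Asn", "tRNA-Ser(AGN)", "tRNA-Glu", "tRNA-Phe", "tRNA-His", "tRNA-Thr",
  "tRNA-Pro", "tRNA-Ser(UCN)", "tRNA-Leu(CUN)", "tRNA-Val")

#' Construct a per-gene alignment
#'
#' @param gene gene name.
#' @param class `"PCG"`, `"rRNA"` or `"tRNA"`.
#' @param sequences named character vector of equal-length gapped sequences
#'   (gap `-`, missing `?`).
#' @param frame codon offset for PCGs: number of leading columns before the
#'   first complete codon (0, 1 or 2). `NA` marks an alignment whose codon
#'   structure has been consumed (e.g. after [drop_third_positions()]).
#' @return object of class `gene_alignment`.
#' @export
gene_alignment <- function(gene, class = c("PCG", "rRNA", "tRNA"),
                           sequences, frame = 0L) {
  class <- match.arg(class)
  sequences <- toupper(unlist(sequences))
  if (is.null(names(sequences))) stop("sequences must be named by taxon")
  w <- unique(nchar(sequences))
  if (length(w) != 1L) stop("ragged alignment for gene ", gene)
  if (class == "PCG" && !is.na(frame) && frame == 0L && w %% 3L != 0L)
    stop("PCG alignment width not divisible by 3 at frame 0 for gene ", gene)
  structure(list(gene = gene, class = class, sequences = sequences,
                 frame = if (class == "PCG") as.integer(frame) else NA_integer_,
                 width = w),
            class = "gene_alignment")
}

#' @export
print.gene_alignment <- function(x, ...) {
  cat(sprintf("<gene_alignment> %s (%s): %d taxa x %d columns, frame %s\n",
              x$gene, x$class, length(x$sequences), x$width,
              ifelse(is.na(x$frame), "-", x$frame)))
  invisible(x)
}

# Column indices of third codon positions for width w at the given frame.
third_position_cols <- function(w, frame) {
  cols <- seq_len(w)
  which(((cols - 1L - frame) %% 3L) == 2L)
}

#' Remove third codon positions from a PCG alignment
#'
#' Drops every third-codon-position column, respecting the frame offset.
#' The returned alignment has its frame metadata cleared (`NA`), so a second
#' application refuses: removing "thirds" of a two-position alignment is
#' meaningless.
#'
#' @param aln a PCG [gene_alignment()] with known frame.
#' @return a `gene_alignment` containing positions 1 and 2 only.
#' @export
drop_third_positions <- function(aln) {
  if (!inherits(aln, "gene_alignment") || aln$class != "PCG")
    stop("drop_third_positions requires a PCG gene_alignment")
  if (is.na(aln$frame))
    stop("codon frame unknown (already dropped?): refusing second application")
  drop <- third_position_cols(aln$width, aln$frame)
  keep <- setdiff(seq_len(aln$width), drop)
  seqs <- vapply(aln$sequences, function(x)
    paste(seq_chars(x)[keep], collapse = ""), character(1L))
  out <- aln
  out$sequences <- seqs
  out$width <- length(keep)
  out$frame <- NA_integer_
  out
}

#' Remove gap-rich alignment columns
#'
#' Drops columns whose gap fraction (`-` or `?`) exceeds `max_gap_fraction` —
#' an explicit, reproducible stand-in for the manual removal of unaligned and
#' unmatched regions. PCG alignments with a known frame are filtered
#' codon-wise: a whole codon is removed when any of its three columns fails,
#' preserving the reading frame.
#'
#' @param aln a [gene_alignment()].
#' @param max_gap_fraction maximum tolerated gap fraction per column
#'   (default 0.5).
#' @return the filtered `gene_alignment`.
#' @export
filter_gappy_columns <- function(aln, max_gap_fraction = 0.5) {
  stopifnot(inherits(aln, "gene_alignment"))
  mat <- do.call(rbind, strsplit(aln$sequences, "", fixed = TRUE))
  gap_frac <- colMeans(mat == "-" | mat == "?")
  fails <- gap_frac > max_gap_fraction
  if (aln$class == "PCG" && !is.na(aln$frame)) {
    cols <- seq_len(aln$width)
    # group columns into codons; a leading partial codon keeps its own group
    codon_id <- (cols - 1L - aln$frame) %/% 3L
    bad_codons <- unique(codon_id[fails])
    fails <- codon_id %in% bad_codons
  }
  keep <- which(!fails)
  seqs <- vapply(aln$sequences, function(x)
    paste(seq_chars(x)[keep], collapse = ""), character(1L))
  out <- aln
  out$sequences <- seqs
  out$width <- length(keep)
  if (out$class == "PCG" && !is.na(out$frame)) {
    # frame is preserved codon-wise unless the leading partial codon was cut
    lead <- sum(keep <= aln$frame)
    out$frame <- as.integer(lead)
  }
  out
}

canonical_gene_rank <- function(gene, class) {
  order_all <- c(CANONICAL_PCGS, CANONICAL_RRNAS, CANONICAL_TRNAS)
  r <- match(gene, order_all)
  class_rank <- match(class, c("PCG", "rRNA", "tRNA"))
  ifelse(is.na(r), 1000L + seq_along(gene), r) + 100L * class_rank
}

#' Concatenate gene alignments into a partitioned supermatrix
#'
#' Builds one of the four standard mitogenomic datasets: `ALL-123` (all
#' genes, all codon positions), `ALL-12` (all genes, PCG third positions
#' excluded), `PCG-123`, `PCG-12`. Partitions are ordered PCGs first, then
#' rRNAs, then tRNAs, each in the canonical blattarian gene order. Taxa
#' missing a gene receive a `?`-filled block for that partition and are
#' flagged.
#'
#' @param gene_alignments list of [gene_alignment()] objects with distinct
#'   gene names.
#' @param mode one of `"ALL-123"`, `"ALL-12"`, `"PCG-123"`, `"PCG-12"`.
#' @return object of class `supermatrix`: `sequences` (named character
#'   vector), `partitions` (data frame `gene`, `class`, `start`, `end`,
#'   `positions`), `mode`, `missing` (data frame of taxon/gene gaps).
#' @export
build_supermatrix <- function(gene_alignments, mode = SUPERMATRIX_MODES) {
  mode <- match.arg(mode)
  if (length(gene_alignments) == 0L) stop("no gene alignments supplied")
  stopifnot(all(vapply(gene_alignments, inherits, logical(1L), "gene_alignment")))
  genes <- vapply(gene_alignments, `[[`, character(1L), "gene")
  if (anyDuplicated(genes)) stop("duplicate gene names in input")
  classes <- vapply(gene_alignments, `[[`, character(1L), "class")
  if (startsWith(mode, "PCG"))
    gene_alignments <- gene_alignments[classes == "PCG"]
  if (length(gene_alignments) == 0L)
    stop("no protein-coding alignments available for mode ", mode)
  drop3 <- endsWith(mode, "-12")
  gene_alignments <- lapply(gene_alignments, function(aln) {
    if (drop3 && aln$class == "PCG") drop_third_positions(aln) else aln
  })
  genes <- vapply(gene_alignments, `[[`, character(1L), "gene")
  classes <- vapply(gene_alignments, `[[`, character(1L), "class")
  ord <- order(canonical_gene_rank(genes, classes))
  gene_alignments <- gene_alignments[ord]

  taxa <- unique(unlist(lapply(gene_alignments, function(a) names(a$sequences))))
  rows <- setNames(rep("", length(taxa)), taxa)
  partitions <- data.frame(gene = character(), class = character(),
                           start = integer(), end = integer(),
                           positions = character(), stringsAsFactors = FALSE)
  missing <- data.frame(taxon = character(), gene = character(),
                        stringsAsFactors = FALSE)
  offset <- 0L
  for (aln in gene_alignments) {
    absent <- setdiff(taxa, names(aln$sequences))
    if (length(absent) > 0L)
      missing <- rbind(missing, data.frame(taxon = absent, gene = aln$gene,
                                           stringsAsFactors = FALSE))
    block <- setNames(rep(strrep("?", aln$width), length(taxa)), taxa)
    block[names(aln$sequences)] <- aln$sequences
    rows <- paste0(rows, block[taxa])
    names(rows) <- taxa
    partitions <- rbind(partitions, data.frame(
      gene = aln$gene, class = aln$class,
      start = offset + 1L, end = offset + aln$width,
      positions = if (aln$class == "PCG") (if (drop3) "12" else "123") else "all",
      stringsAsFactors = FALSE))
    offset <- offset + aln$width
  }
  structure(list(sequences = rows, partitions = partitions, mode = mode,
                 width = offset, missing = missing),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("<supermatrix> %s: %d taxa x %d columns, %d partitions\n",
              x$mode, length(x$sequences), x$width, nrow(x$partitions)))
  if (nrow(x$missing) > 0L)
    cat("  ", nrow(x$missing), "taxon/gene blocks filled with '?'\n")
  invisible(x)
}

#' Write a supermatrix as relaxed PHYLIP
#' @param sm a `supermatrix`.
#' @param path output path.
#' @export
write_phylip <- function(sm, path) {
  lines <- c(sprintf("%d %d", length(sm$sequences), sm$width),
             sprintf("%s  %s", names(sm$sequences), sm$sequences))
  writeLines(lines, path)
  invisible(path)
}

#' Read relaxed PHYLIP written by [write_phylip()]
#' @param path input path.
#' @return named character vector of sequences.
#' @export
read_phylip <- function(path) {
  lines <- readLines(path)
  header <- as.integer(strsplit(trimws(lines[1L]), "\\s+")[[1L]])
  body <- lines[-1L][nzchar(lines[-1L])]
  parts <- strsplit(body, "\\s+")
  seqs <- setNames(vapply(parts, `[`, character(1L), 2L),
                   vapply(parts, `[`, character(1L), 1L))
  if (length(seqs) != header[1L] || any(nchar(seqs) != header[2L]))
    stop("PHYLIP dimensions disagree with header: ", path)
  seqs
}

#' Write a supermatrix as NEXUS with a charset block
#'
#' Each partition becomes a `charset`; PCG partitions retaining positions
#' 1+2 only are still contiguous ranges because third positions were removed
#' before concatenation.
#'
#' @param sm a `supermatrix`.
#' @param path output path.
#' @export
write_nexus <- function(sm, path) {
  taxa <- names(sm$sequences)
  lines <- c(
    "#NEXUS", "",
    "BEGIN DATA;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", length(taxa), sm$width),
    "  FORMAT DATATYPE=DNA GAP=- MISSING=?;",
    "  MATRIX",
    sprintf("    %s  %s", taxa, sm$sequences),
    "  ;",
    "END;", "",
    "BEGIN SETS;",
    sprintf("  charset %s = %d-%d;",
            gsub("[^A-Za-z0-9_]", "_", sm$partitions$gene),
            sm$partitions$start, sm$partitions$end),
    "END;")
  writeLines(lines, path)
  invisible(path)
}

#' Read NEXUS written by [write_nexus()]
#' @param path input path.
#' @return list with `sequences` (named character vector) and `charsets`
#'   (data frame `name`, `start`, `end`).
#' @export
read_nexus <- function(path) {
  lines <- readLines(path)
  in_matrix <- FALSE
  seqs <- character(); labels <- character()
  for (ln in lines) {
    t <- trimws(ln)
    if (toupper(t) == "MATRIX") { in_matrix <- TRUE; next }
    if (in_matrix && t == ";") { in_matrix <- FALSE; next }
    if (in_matrix && nzchar(t)) {
      parts <- strsplit(t, "\\s+")[[1L]]
      labels <- c(labels, parts[1L])
      seqs <- c(seqs, parts[2L])
    }
  }
  cs <- grep("^\\s*charset ", lines, value = TRUE, ignore.case = TRUE)
  m <- regmatches(cs, regexec("charset\\s+(\\S+)\\s*=\\s*(\\d+)-(\\d+);", cs))
  charsets <- do.call(rbind, lapply(m, function(h)
    data.frame(name = h[2L], start = as.integer(h[3L]), end = as.integer(h[4L]),
               stringsAsFactors = FALSE)))
  list(sequences = setNames(seqs, labels),
       charsets = charsets %||% data.frame(name = character(),
                                           start = integer(), end = integer()))
}

#' Write a supermatrix as FASTA
#'
#' Plain writer preserving `-` and `?` states verbatim.
#' @param sm a `supermatrix` (or named character vector).
#' @param path output path.
#' @export
write_supermatrix_fasta <- function(sm, path) {
  seqs <- if (inherits(sm, "supermatrix")) sm$sequences else sm
  writeLines(as.vector(rbind(paste0(">", names(seqs)), seqs)), path)
  invisible(path)
}

#' Write the partition table
#' @param sm a `supermatrix`.
#' @param path output TSV path.
#' @export
write_partition_table <- function(sm, path) {
  write.table(sm$partitions, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
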