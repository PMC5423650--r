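# Minimal GenBank flat-file reader for locally stored annotated mitogenomes.
# Handles the subset of the format these records use: LOCUS topology, the
# FEATURES table (CDS/tRNA/rRNA/D-loop/misc_feature) with plain, complement()
# and origin-spanning join() locations, /gene and /product qualifiers, and the
# ORIGIN sequence block.

read_genbank <- function(path, id = NULL) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus) == 0L) stop("not a GenBank flat file (no LOCUS line): ", path)
  topology <- if (grepl("circular", locus[1L], ignore.case = TRUE)) "circular" else "linear"
  locus_id <- strsplit(trimws(sub("^LOCUS", "", locus[1L])), "\\s+")[[1L]][1L]

  feat_from <- grep("^FEATURES", lines)
  orig_from <- grep("^ORIGIN", lines)
  if (length(orig_from) == 0L) stop("GenBank record has no ORIGIN block: ", path)
  seq_lines <- lines[(orig_from[1L] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))

  feats <- empty_features()
  if (length(feat_from) > 0L) {
    block <- lines[(feat_from[1L] + 1L):(orig_from[1L] - 1L)]
    starts <- grep("^ {5}\\S", block)
    for (i in seq_along(starts)) {
      from <- starts[i]
      to <- if (i < length(starts)) starts[i + 1L] - 1L else length(block)
      chunk <- block[from:to]
      key <- sub("^ {5}(\\S+).*", "\\1", chunk[1L])
      if (!key %in% c("CDS", "tRNA", "rRNA", "D-loop", "misc_feature")) next
      loc <- sub("^ {5}\\S+\\s+", "", chunk[1L])
      # location may continue onto the next line(s) until a qualifier starts
      j <- 2L
      while (j <= length(chunk) && !grepl("^\\s+/", chunk[j])) {
        loc <- paste0(loc, trimws(chunk[j]))
        j <- j + 1L
      }
      quals <- parse_qualifiers(chunk[seq_along(chunk) >= j])
      parsed <- parse_gb_location(loc, path)
      name <- quals[["gene"]] %||% quals[["product"]] %||% key
      ftype <- switch(key, "D-loop" = "control_region",
                      "misc_feature" = "control_region", key)
      feats <- rbind(feats, data.frame(
        name = name, ftype = ftype,
        strand = if (parsed$complement) "N" else "J",
        start = parsed$start, end = parsed$end,
        wraps_origin = parsed$wraps, anticodon = NA_character_,
        stringsAsFactors = FALSE))
    }
  }
  annotated_genome(id %||% locus_id, sequence, feats, topology = topology)
}

parse_qualifiers <- function(lines) {
  lines <- trimws(lines)
  hits <- regmatches(lines, regexec('^/([A-Za-z_]+)="?([^"]*)"?$', lines))
  out <- list()
  for (h in hits) if (length(h) == 3L) out[[h[2L]]] <- h[3L]
  out
}

parse_gb_location <- function(loc, path) {
  loc <- gsub("[<>]", "", gsub("\\s", "", loc))
  complement <- grepl("^complement\\(", loc)
  if (complement) loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(inner, ",", fixed = TRUE)[[1L]]
    if (length(parts) != 2L)
      stop("unsupported join() location in ", path, ": ", loc)
    p1 <- parse_span(parts[1L], path)
    p2 <- parse_span(parts[2L], path)
    # two-segment join spanning the origin: (start..L, 1..end)
    if (p2$start != 1L)
      stop("join() does not span the origin in ", path, ": ", loc)
    return(list(start = p1$start, end = p2$end, complement = complement,
                wraps = TRUE))
  }
  p <- parse_span(loc, path)
  list(start = p$start, end = p$end, complement = complement, wraps = FALSE)
}

parse_span <- function(x, path) {
  m <- regmatches(x, regexec("^(\\d+)\\.\\.(\\d+)$", x))[[1L]]
  if (length(m) != 3L) {
    m1 <- regmatches(x, regexec("^(\\d+)$", x))[[1L]]
    if (length(m1) == 2L) return(list(start = as.integer(m1[2L]),
                                      end = as.integer(m1[2L])))
    stop("malformed location '", x, "' in ", path)
  }
  list(start = as.integer(m[2L]), end = as.integer(m[3L]))
}
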