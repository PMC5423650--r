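# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement a nucleotide string
#'
#' Full IUPAC complement (W and S are self-complementary); kept as a plain
#' string operation since it sits on the extraction hot path.
#'
#' @param x single nucleotide string (A/C/G/T/N and IUPAC ambiguity codes).
#' @return the reverse complement as a character scalar.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  comp <- chartr("ACGTUNRYKMBVDHWSacgtunrykmbvdhws",
                 "TGCAANYRMKVBHDWStgcaanyrmkvbhdws", x)
  intToUtf8(rev(utf8ToInt(comp)))
}

# Split a sequence string into a character vector of single bases.
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

# Run-length positions of TRUE runs in a logical vector:
# data.frame(start, end, length), possibly empty.
true_runs <- function(flags) {
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep], length = r$lengths[keep])
}

# Longest run of a given base; returns list(length, start); length 0 when absent.
longest_base_run <- function(seq, base = "T") {
  ch <- seq_chars(seq)
  runs <- true_runs(ch == base)
  if (nrow(runs) == 0L) return(list(length = 0L, start = NA_integer_))
  i <- which.max(runs$length)
  list(length = runs$length[i], start = runs$start[i])
}

#' Longest poly-T stretch in a region
#'
#' Reports the longest run of consecutive T with at least `min_len` bases,
#' the convention used when describing T-stretches of insect control regions.
#'
#' @param seq nucleotide string.
#' @param min_len minimum run length to report (default 5).
#' @return list with `length` and `start` (both `NA`/0 when no qualifying run).
#' @export
poly_t_stretch <- function(seq, min_len = 5L) {
  run <- longest_base_run(seq, "T")
  if (run$length < min_len) return(list(length = 0L, start = NA_integer_))
  run
}

# Evaluate an expression with a temporary RNG state seeded from `seed`,
# restoring the caller's .Random.seed afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Stable content hash used for provenance stamps on generated objects.
spec_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(x), f)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
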