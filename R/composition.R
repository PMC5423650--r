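# Nucleotide composition, strand skews, codon usage / RSCU under the
# invertebrate mitochondrial code, and start/stop-codon classification.

#' Base composition and strand skews
#'
#' Counts A/C/G/T exactly and computes `AT skew = (A - T) / (A + T)` and
#' `GC skew = (G - C) / (G + C)`. Ambiguous bases (N) are counted separately
#' and excluded from all denominators: fractions and skews are over the
#' unambiguous A/C/G/T content, the primary convention here since real
#' mitogenome submissions carry no Ns.
#'
#' @param seq nucleotide string (A/C/G/T/N).
#' @return list of class `composition_report`: `counts` (named integer),
#'   `n_acgt`, `n_other`, `at_fraction`, `gc_fraction`, `at_skew`, `gc_skew`,
#'   `undefined` (TRUE when no unambiguous bases remain).
#' @export
base_composition <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, nchar(seq) >= 1L)
  ch <- seq_chars(toupper(seq))
  counts <- vapply(DNA_BASES, function(b) sum(ch == b), integer(1L))
  n_acgt <- sum(counts)
  n_other <- length(ch) - n_acgt
  undefined <- n_acgt == 0L
  at <- counts[["A"]] + counts[["T"]]
  gc <- counts[["G"]] + counts[["C"]]
  res <- list(
    counts = counts, n_acgt = n_acgt, n_other = n_other,
    at_fraction = if (undefined) NA_real_ else at / n_acgt,
    gc_fraction = if (undefined) NA_real_ else gc / n_acgt,
    at_skew = if (at > 0L) (counts[["A"]] - counts[["T"]]) / at else NA_real_,
    gc_skew = if (gc > 0L) (counts[["G"]] - counts[["C"]]) / gc else NA_real_,
    undefined = undefined)
  class(res) <- "composition_report"
  res
}

#' @export
print.composition_report <- function(x, ...) {
  cat(sprintf("<composition> %d bp ACGT (+%d other)  A=%d C=%d G=%d T=%d\n",
              x$n_acgt, x$n_other, x$counts[["A"]], x$counts[["C"]],
              x$counts[["G"]], x$counts[["T"]]))
  cat(sprintf("  AT%% %.1f  AT-skew %+0.3f  GC-skew %+0.3f\n",
              100 * x$at_fraction, x$at_skew, x$gc_skew))
  invisible(x)
}

#' Synonymous codon families of the invertebrate mitochondrial code
#'
#' Families follow NCBI translation table 5, with leucine split into
#' `L(CUN)`/`L(UUR)` and serine into `S(UCN)`/`S(AGN)` sub-families (the
#' `L/L*/S/S*` convention of mitogenome codon-usage tables). Stop codons
#' (TAA, TAG) form their own two-member family.
#'
#' @param include_stops include the stop-codon family (default TRUE).
#' @return named character vector: codon -> family label.
#' @export
mito_codon_families <- function(include_stops = TRUE) {
  code <- Biostrings::getGeneticCode("5")   # invertebrate mitochondrial
  fam <- setNames(unname(code), names(code))
  fam[c("TTA", "TTG")] <- "L(UUR)"
  fam[fam == "L"] <- "L(CUN)"
  fam[c("AGA", "AGC", "AGG", "AGT")] <- "S(AGN)"
  fam[fam == "S"] <- "S(UCN)"
  if (!include_stops) fam <- fam[fam != "*"]
  fam
}

#' Codon usage and RSCU
#'
#' Counts in-frame codons over a set of CDS sequences and computes the
#' relative synonymous codon usage, `RSCU = count * family_size /
#' family_total`, within the synonymous families of [mito_codon_families()].
#' Trailing partial codons (the 1-2 nt of incomplete stop codons) are dropped;
#' codons containing non-ACGT characters are skipped with a warning.
#'
#' @param cds_sequences character vector (or list) of in-frame CDS nucleotide
#'   strings, each starting at codon position 1.
#' @param include_stops count complete stop codons (default TRUE, the usual
#'   convention for mitogenome codon-usage tables).
#' @return data frame of class `codon_usage_table` with columns `codon`,
#'   `family`, `count`, `rscu`, `family_observed`; attribute `total_codons`.
#' @export
codon_usage_rscu <- function(cds_sequences, include_stops = TRUE) {
  fam <- mito_codon_families(include_stops = include_stops)
  counts <- setNames(integer(length(fam)), names(fam))
  skipped <- 0L
  for (cds in as.character(cds_sequences)) {
    cds <- toupper(cds)
    n_codons <- nchar(cds) %/% 3L
    if (n_codons == 0L) next
    codons <- substring(cds, 3L * seq_len(n_codons) - 2L, 3L * seq_len(n_codons))
    known <- codons %in% names(counts)
    ambiguous <- !known & grepl("[^ACGT]", codons)
    skipped <- skipped + sum(ambiguous)
    tab <- table(codons[known])
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  if (skipped > 0L)
    warning(skipped, " codon(s) containing non-ACGT characters skipped")
  fam_totals <- tapply(counts, fam, sum)
  fam_sizes <- table(fam)
  total <- fam_totals[fam]
  size <- as.integer(fam_sizes[fam])
  rscu <- ifelse(total > 0, counts * size / total, 0)
  out <- data.frame(codon = names(fam), family = unname(fam),
                    count = unname(counts), rscu = unname(rscu),
                    family_observed = unname(total > 0),
                    stringsAsFactors = FALSE)
  out <- out[order(out$family, out$codon), ]
  rownames(out) <- NULL
  attr(out, "total_codons") <- sum(counts)
  class(out) <- c("codon_usage_table", class(out))
  out
}

START_CODON_VOCAB <- c("ATG", "ATA", "ATT", "ATC", "TTG", "GTG")

#' Stop-codon class implied by CDS length
#'
#' Mitochondrial CDSs truncated by post-transcriptional polyadenylation leave
#' 1-2 terminal nucleotides of an incomplete stop codon inside the annotated
#' interval: length = 0 (mod 3) means a complete stop, = 2 means `TA-`,
#' = 1 means `T-`.
#'
#' @param length CDS length(s) in bp.
#' @return character vector over `"complete"`, `"T-"`, `"TA-"`.
#' @export
stop_class_from_length <- function(length) {
  c("complete", "T-", "TA-")[(as.integer(length) %% 3L) + 1L]
}

#' Classify start and stop codons of a CDS
#'
#' The start codon is reported verbatim (with a warning outside the vocabulary
#' observed in blattarian mitogenomes plus GTG/ATC). The stop class is derived
#' from length mod 3 and the terminal nucleotides: a complete CDS must end in
#' TAA or TAG; a 2 (mod 3) CDS must end in `TA`; a 1 (mod 3) CDS must end in
#' `T` (incomplete stops completed by polyadenylation).
#'
#' @param cds in-frame CDS nucleotide string, length >= 6.
#' @return list of class `start_stop_call`: `start_codon`, `stop_class`
#'   (one of `TAA`, `TAG`, `TA-`, `T-`).
#' @export
classify_start_stop <- function(cds) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n < 6L) stop("CDS shorter than 6 nt")
  start <- substr(cds, 1L, 3L)
  if (!start %in% START_CODON_VOCAB)
    warning("unusual start codon: ", start)
  rem <- n %% 3L
  if (rem == 0L) {
    last3 <- substr(cds, n - 2L, n)
    if (!last3 %in% c("TAA", "TAG"))
      stop("no stop: complete CDS ends in ", last3, ", not TAA/TAG")
    stop_class <- last3
  } else if (rem == 2L) {
    last2 <- substr(cds, n - 1L, n)
    if (last2 != "TA")
      stop("inconsistent incomplete stop: expected terminal TA, found ", last2)
    stop_class <- "TA-"
  } else {
    last1 <- substr(cds, n, n)
    if (last1 != "T")
      stop("inconsistent incomplete stop: expected terminal T, found ", last1)
    stop_class <- "T-"
  }
  structure(list(start_codon = start, stop_class = stop_class),
            class = "start_stop_call")
}

#' Write a codon-usage table
#' @param usage a `codon_usage_table`.
#' @param path output TSV path (`codon  aa  count  rscu`).
#' @export
write_codon_usage <- function(usage, path) {
  out <- data.frame(codon = usage$codon, aa = usage$family,
                    count = usage$count, rscu = round(usage$rscu, 4))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
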