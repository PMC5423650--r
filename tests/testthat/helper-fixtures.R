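# Shared fixtures and small independent oracles.

table3_path <- function(which = c("pa", "nr")) {
  which <- match.arg(which)
  system.file("extdata", paste0("table3_", which, "_features.tsv"),
              package = "mitocompare")
}

table2_dist_path <- function() {
  system.file("extdata", "table2_k2p_distances.tsv", package = "mitocompare")
}

table2_taxa_path <- function() {
  system.file("extdata", "table2_taxa.tsv", package = "mitocompare")
}

read_pa <- function() read_genome(table3_path("pa"))
read_nr <- function() read_genome(table3_path("nr"))

random_dna <- function(n, at = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2)),
        collapse = "")
}

# Position-by-position brute-force IUPAC scanner (independent of the
# regex-based implementation under test).
iupac_match_brute <- function(seq, pattern) {
  map <- Biostrings::IUPAC_CODE_MAP
  s <- strsplit(toupper(seq), "")[[1L]]
  p <- strsplit(toupper(pattern), "")[[1L]]
  w <- length(p); n <- length(s)
  hits <- integer()
  if (n < w) return(hits)
  allowed <- lapply(p, function(ch) strsplit(map[[ch]], "")[[1L]])
  for (i in seq_len(n - w + 1L)) {
    ok <- TRUE
    for (k in seq_len(w)) {
      if (!(s[i + k - 1L] %in% allowed[[k]])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, i)
  }
  hits
}

# Minimal GenBank record exercising plain, complement() and origin-spanning
# join() locations on a circular molecule.
genbank_fixture <- function() {
  path <- tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       synthrec                40 bp    DNA     circular INV 01-JAN-2000",
    "DEFINITION  synthetic test record.",
    "FEATURES             Location/Qualifiers",
    "     tRNA            3..12",
    "                     /gene=\"tRNA-Ile\"",
    "     CDS             complement(14..25)",
    "                     /gene=\"ND9\"",
    "     rRNA            join(35..40,1..2)",
    "                     /gene=\"rrnX\"",
    "ORIGIN",
    "        1 acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt",
    "//"), path)
  path
}

# Feature-table fixture written to a temp file.
write_feature_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  names(df)[names(df) == "name"] <- "gene"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
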