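# Control-region structure: motif scanning, tandem repeats, conserved
# blocks, hairpins.

test_that("IUPAC motif scanning finds all and only the matching windows", {
  hits <- scan_iupac_motif("GGTACTTAAGG", "WACTTAA")
  expect_equal(hits$start, 3L)
  expect_equal(hits$matched, "TACTTAA")
  expect_equal(nrow(scan_iupac_motif("CACTTAA", "WACTTAA")), 0L)  # C not in W
  hits <- scan_iupac_motif("AACTTAATACTTAA", "WACTTAA")
  expect_equal(hits$start, c(1L, 8L))
  # overlapping occurrences are all reported
  hits <- scan_iupac_motif("AAAA", "AA")
  expect_equal(hits$start, 1:3)
  expect_error(scan_iupac_motif("ACGT", "AXC"), "invalid IUPAC")
  # sequence N never matches, even against pattern N
  expect_equal(nrow(scan_iupac_motif("ANA", "ANA")), 0L)
})

test_that("both-strand scans map reverse-complement hits onto stored-strand coordinates", {
  # GATTC at 4..8 on the reverse complement of the stored strand
  s <- paste0("ACG", revcomp("TTGATTCAA"))
  hits <- scan_iupac_motif(s, "GATTC", both_strands = TRUE)
  n_hits <- hits[hits$strand == "N", ]
  expect_equal(nrow(n_hits), 1L)
  expect_equal(substr(revcomp(s), nchar(s) - n_hits$start - 5L + 2L,
                      nchar(s) - n_hits$start + 1L), "GATTC")
})

test_that("the motif scanner agrees with a brute-force oracle on random sequences", {
  set.seed(404)
  patterns <- c("WACTTAA", "RYN", "TWGS", "ACGT", "MMKK", "HDBV")
  for (i in 1:20) {
    s <- random_dna(1000, at = runif(1, 0.4, 0.8))
    p <- sample(patterns, 1)
    expect_equal(scan_iupac_motif(s, p)$start, iupac_match_brute(s, p),
                 info = paste("pattern", p, "iteration", i))
  }
})

test_that("gapped patterns with wildcard runs locate composite elements", {
  seq <- paste0("GGG", "A", "CCG", "TAATTTA", "AC", "TT", "G", "ATA", "CG",
                "ACATTT", "GGG")
  hits <- scan_gapped_pattern(seq,
    "A N{1,10} TAATTTA N{1,10} TT N{1,10} ATA N{1,10} ACATTT")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 4L)
  expect_true(endsWith(hits$matched, "ACATTT"))
  expect_equal(nrow(scan_gapped_pattern("AAACCC", "A N{1,2} TTT")), 0L)
})

test_that("tandem repeat calls report unit, fractional copies and full identity", {
  calls <- find_tandem_repeats("ACGACGACGACG")
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$unit, "ACG")
  expect_equal(calls$copies, 4.0)
  expect_equal(calls$identity, 1.0)
  expect_equal(c(calls$start, calls$end), c(1L, 12L))
  calls <- find_tandem_repeats("ATGATGAT")
  expect_equal(calls$copies, 8 / 3)         # partial final copy
  expect_equal(calls$end - calls$start + 1L, as.integer(round(calls$copies * calls$period)))
})

test_that("the minimal-period call wins over multiples of itself", {
  calls <- find_tandem_repeats("ATATATATAT", min_period = 2L)
  expect_equal(calls$period, 2L)
  expect_equal(calls$unit, "AT")
  expect_equal(calls$copies, 5.0)
  # property: no divisor of the reported period tiles the unit
  set.seed(405)
  for (i in 1:10) {
    unit <- random_dna(sample(3:12, 1))
    arr <- paste0(strrep(unit, 4), random_dna(30))
    calls <- find_tandem_repeats(arr, min_period = 2L, max_period = 30L)
    for (k in seq_len(nrow(calls))) {
      u <- calls$unit[k]
      divisors <- setdiff(which(nchar(u) %% seq_len(nchar(u)) == 0), nchar(u))
      for (q in divisors)
        expect_false(strrep(substr(u, 1, q), nchar(u) / q) == u)
    }
  }
})

test_that("repeat-free sequences return an empty call table", {
  expect_equal(nrow(find_tandem_repeats("ACGTTGCAAC", min_period = 3L)), 0L)
})

test_that("conserved-block detection scores one variable column in twenty as 95%", {
  base <- strsplit(random_dna(20), "")[[1L]]
  s1 <- paste(base, collapse = "")
  v <- base; v[10] <- setdiff(c("A", "C", "G", "T"), v[10])[1L]
  s2 <- paste(v, collapse = "")
  blocks <- find_conserved_blocks(c(a = s1, b = s2), min_width = 10L,
                                  max_interruptions = 1L)
  expect_equal(nrow(blocks), 1L)
  expect_equal(blocks$width, 20L)
  expect_equal(blocks$similarity, 95.0)
})

test_that("identical alignments yield a single fully conserved block", {
  s <- random_dna(60)
  blocks <- find_conserved_blocks(c(a = s, b = s, c = s))
  expect_equal(nrow(blocks), 1L)
  expect_equal(c(blocks$start, blocks$end), c(1L, 60L))
  expect_equal(blocks$similarity, 100.0)
})

test_that("alternating variable columns leave no block when interruptions are disallowed", {
  base <- strsplit(random_dna(40), "")[[1L]]
  v <- base
  odd <- seq(1, 40, by = 2)
  v[odd] <- vapply(base[odd], function(ch)
    setdiff(c("A", "C", "G", "T"), ch)[1L], character(1L))
  blocks <- find_conserved_blocks(
    c(a = paste(base, collapse = ""), b = paste(v, collapse = "")),
    min_width = 10L, max_interruptions = 0L)
  expect_equal(nrow(blocks), 0L)
})

test_that("gap columns never count as conserved and ragged alignments are rejected", {
  s <- random_dna(30)
  gapped <- paste0(substr(s, 1, 10), "-", substr(s, 12, 30))
  blocks <- find_conserved_blocks(c(a = s, b = gapped), min_width = 5L,
                                  max_interruptions = 0L)
  expect_true(all(blocks$start > 11 | blocks$end < 11))
  expect_error(find_conserved_blocks(c(a = "ACGT", b = "ACG")), "ragged")
})

test_that("hairpin prediction maximizes stem pairs with deterministic tie-breaking", {
  # perfect inverted repeat under Watson-Crick pairing
  s <- paste0("GGGGG", strrep("T", 11), "CCCCC")
  hp <- predict_best_hairpin(s, allow_gu = FALSE)
  expect_equal(hp$stem_pairs, 5L)
  expect_equal(hp$loop_length, 11L)
  expect_equal(hp$t_stretch, 11L)
  expect_equal(c(hp$arm5_start, hp$arm3_end), c(1L, 21L))
  # with G:T wobble allowed the same stem count is reachable with a shorter
  # loop (G pairs the loop Ts), and the shorter-loop tie-break takes it
  hp_gu <- predict_best_hairpin(s, allow_gu = TRUE)
  expect_equal(hp_gu$stem_pairs, 5L)
  expect_lte(hp_gu$loop_length, 11L)
  # no qualifying hairpin in a homopolymer
  expect_null(predict_best_hairpin(strrep("A", 60)))
})

test_that("G:T wobble pairs are counted exactly when enabled", {
  s <- paste0("GGGGG", "CAACAACAACA", "TTTTT")  # arms pair only via G:T
  expect_null(predict_best_hairpin(s, allow_gu = FALSE))
  hp <- predict_best_hairpin(s, allow_gu = TRUE)
  expect_equal(hp$stem_pairs, 5L)
  expect_true(all(paste0(hp$pairs$base5, hp$pairs$base3) %in%
                  c("GT", "TG")))
})

test_that("reported pairs re-validate and dropping wobble never gains stem pairs", {
  set.seed(406)
  pair_ok <- function(x, y, gu) {
    wc <- paste0(x, y) %in% c("AT", "TA", "GC", "CG")
    if (gu) wc | paste0(x, y) %in% c("GT", "TG") else wc
  }
  for (i in 1:25) {
    s <- random_dna(60, at = 0.7)
    hp <- predict_best_hairpin(s, min_stem = 4L)
    hp_wc <- predict_best_hairpin(s, min_stem = 4L, allow_gu = FALSE)
    if (!is.null(hp)) {
      expect_true(all(pair_ok(hp$pairs$base5, hp$pairs$base3, TRUE)))
      expect_true(all(hp$pairs$pos3 > hp$loop_end & hp$pairs$pos5 < hp$loop_start))
      expect_gt(hp$loop_start, hp$arm5_end)      # arms do not overlap the loop
    }
    if (!is.null(hp_wc)) {
      expect_true(all(pair_ok(hp_wc$pairs$base5, hp_wc$pairs$base3, FALSE)))
      expect_lte(hp_wc$stem_pairs, if (is.null(hp)) 3L else hp$stem_pairs)
    }
  }
})

test_that("poly-T stretches report the longest qualifying run", {
  r <- poly_t_stretch("ACGTTTTTTAG")
  expect_equal(r$length, 6L)
  expect_equal(r$start, 4L)
  expect_equal(poly_t_stretch("ACGTTTTAG")$length, 0L)   # below the 5-T floor
  expect_equal(poly_t_stretch("ACGTTTTAG", min_len = 3L)$length, 4L)
})
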