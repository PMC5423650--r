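# Annotated-genome model: parsing, coordinate arithmetic, strand-aware
# extraction, spacer/overlap accounting.

test_that("feature tables of the two annotated blattid genomes parse with exact coordinates", {
  pa <- read_pa()
  expect_s3_class(pa, "annotated_genome")
  expect_equal(nrow(pa$features), 38L)   # 37 genes + control region
  expect_equal(sum(pa$features$ftype == "CDS"), 13L)
  expect_equal(sum(pa$features$ftype == "tRNA"), 22L)
  expect_equal(sum(pa$features$ftype == "rRNA"), 2L)
  expect_equal(sum(pa$features$ftype == "control_region"), 1L)
  nd2 <- pa$features[pa$features$name == "ND2", ]
  expect_equal(c(nd2$start, nd2$end), c(208L, 1236L))
  expect_equal(nd2$strand, "J")
  expect_true(all(diff(pa$features$start) >= 0))   # sorted by start
  nr <- read_nr()
  expect_equal(genome_length(nr), 15711L)
  expect_equal(genome_length(pa), 15605L)
})

test_that("empty feature table yields a featureless genome", {
  path <- write_feature_fixture(
    data.frame(name = character(), ftype = character(), strand = character(),
               start = integer(), end = integer()))
  g <- read_genome(path, genome_length = 10L)
  expect_equal(nrow(g$features), 0L)
  expect_equal(genome_length(g), 10L)
  expect_equal(nrow(compute_spacers_overlaps(g)), 0L)
})

test_that("origin-wrapping features resolve length and extraction across position 1", {
  seq100 <- random_dna(100)
  feats <- data.frame(name = "CR", ftype = "control_region", strand = "J",
                      start = 95L, end = 5L, wraps_origin = TRUE)
  g <- annotated_genome("wrap", seq100, feats)
  expect_equal(feature_length(g$features[1L, ], 100L), 11L)   # 100-95+1+5
  ext <- extract_feature_sequence(g, 1L)
  expect_equal(nchar(ext), 11L)
  expect_equal(ext, paste0(substr(seq100, 95, 100), substr(seq100, 1, 5)))
})

test_that("extraction is strand-aware and length-faithful for every annotated feature", {
  sim <- synth_mitogenome(genome_spec(seed = 11L))
  g <- sim$genome
  for (i in seq_len(nrow(g$features))) {
    s <- extract_feature_sequence(g, i)
    expect_equal(nchar(s), feature_length(g$features[i, ], genome_length(g)))
  }
  # N-strand extraction returns the reverse complement of the stored slice
  nd1 <- g$features[g$features$name == "ND1", ]
  stored <- substr(g$sequence, nd1$start, nd1$end)
  expect_equal(extract_feature_sequence(g, "ND1"), revcomp(stored))
  expect_equal(revcomp(revcomp(stored)), stored)
})

test_that("spacer and overlap accounting reproduces the annotated gene junctions", {
  pa <- read_pa()
  sp <- compute_spacers_overlaps(pa)
  pick <- function(up, dn) sp[sp$upstream == up & sp$downstream == dn, ]
  r <- pick("tRNA-Ser(UCN)", "ND1")
  expect_equal(r$kind, "spacer"); expect_equal(r$length, 25L)
  r <- pick("tRNA-Leu(UUR)", "COX2")
  expect_equal(r$kind, "spacer"); expect_equal(r$length, 16L)
  r <- pick("ATP8", "ATP6")
  expect_equal(r$kind, "overlap"); expect_equal(r$length, 7L)
  # circular closure: CR (ends at genome length) back to tRNA-Ile (starts at 1)
  r <- pick("CR", "tRNA-Ile")
  expect_equal(r$kind, "abutting"); expect_equal(r$length, 0L)
  nr <- read_nr()
  spn <- compute_spacers_overlaps(nr)
  expect_equal(spn[spn$upstream == "tRNA-Cys" & spn$downstream == "tRNA-Tyr",
                   "length"], 18L)
})

test_that("features ending and starting on consecutive positions abut with length 0", {
  feats <- data.frame(name = c("g1", "g2"), ftype = "CDS", strand = "J",
                      start = c(1L, 101L), end = c(100L, 150L))
  g <- annotated_genome("toy", random_dna(200), feats, topology = "linear")
  sp <- compute_spacers_overlaps(g)
  expect_equal(sp$kind[1L], "abutting")
  expect_equal(sp$length[1L], 0L)
})

test_that("feature lengths, spacers and overlaps partition the circular genome", {
  # toy circular genome with one overlap and one terminal spacer
  feats <- data.frame(name = c("a", "b"), ftype = "CDS", strand = "J",
                      start = c(1L, 8L), end = c(10L, 20L))
  g <- annotated_genome("toy", random_dna(25), feats)
  sp <- compute_spacers_overlaps(g)
  total <- sum(feature_length(g$features, 25L)) +
    sum(sp$length[sp$kind == "spacer"]) - sum(sp$length[sp$kind == "overlap"])
  expect_equal(total, 25L)
  # and for a full synthetic genome (no overlaps by construction)
  sim <- synth_mitogenome(genome_spec(seed = 5L))
  sp <- compute_spacers_overlaps(sim$genome)
  total <- sum(feature_length(sim$genome$features, genome_length(sim$genome))) +
    sum(sp$length[sp$kind == "spacer"]) - sum(sp$length[sp$kind == "overlap"])
  expect_equal(total, genome_length(sim$genome))
})

test_that("tRNA length tables summarize the annotated ranges", {
  pa_trna <- feature_length_table(read_pa(), "tRNA")
  expect_equal(nrow(pa_trna), 22L)
  expect_equal(attr(pa_trna, "min"), 64L)
  expect_equal(attr(pa_trna, "max"), 71L)
  expect_equal(pa_trna$length[pa_trna$name == "tRNA-Thr"], 64L)
  nr_trna <- feature_length_table(read_nr(), "tRNA")
  expect_equal(attr(nr_trna, "max"), 72L)
  expect_equal(nr_trna$length[nr_trna$name == "tRNA-Val"], 72L)
  # degenerate single-feature genome
  g <- annotated_genome("one", "ACGT",
                        data.frame(name = "x", ftype = "CDS", strand = "J",
                                   start = 2L, end = 2L))
  tab <- feature_length_table(g)
  expect_equal(tab$length, 1L)
})

test_that("feature tables round-trip bit-exactly through write and read", {
  pa <- read_pa()
  tmp <- tempfile(fileext = ".tsv")
  write_feature_table(pa, tmp)
  back <- read_genome(tmp, genome_length = genome_length(pa))
  cols <- c("name", "ftype", "strand", "start", "end", "wraps_origin")
  expect_identical(back$features[, cols], pa$features[, cols])
})

test_that("GenBank flat files parse locations, strands and origin-spanning joins", {
  g <- read_genome(genbank_fixture())
  expect_equal(g$topology, "circular")
  expect_equal(genome_length(g), 40L)
  expect_equal(nrow(g$features), 3L)
  ile <- g$features[g$features$name == "tRNA-Ile", ]
  expect_equal(c(ile$start, ile$end), c(3L, 12L))
  expect_equal(ile$strand, "J")
  nd9 <- g$features[g$features$name == "ND9", ]
  expect_equal(nd9$strand, "N")   # complement(...) maps to the minority strand
  expect_equal(extract_feature_sequence(g, "ND9"),
               revcomp(substr(g$sequence, 14, 25)))
  wrap <- g$features[g$features$name == "rrnX", ]
  expect_true(wrap$wraps_origin)
  expect_equal(feature_length(wrap, 40L), 8L)
})

test_that("malformed annotations are rejected with informative errors", {
  bad <- write_feature_fixture(
    data.frame(name = "x", ftype = "CDS", strand = "J",
               start = "ten", end = "20"))
  expect_error(read_genome(bad, genome_length = 100L), "malformed")
  expect_error(annotated_genome("g", random_dna(100),
    data.frame(name = "x", ftype = "CDS", strand = "J",
               start = 50L, end = 10L)), "wraps_origin")
  expect_error(annotated_genome("g", random_dna(20),
    data.frame(name = "x", ftype = "CDS", strand = "J",
               start = 5L, end = 30L)), "outside")
  path <- write_feature_fixture(
    data.frame(name = "x", ftype = "CDS", strand = "J",
               start = 5L, end = 300L))
  expect_error(read_genome(path, genome_length = 100L), "length")
})
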