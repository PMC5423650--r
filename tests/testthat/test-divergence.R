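# K2P distances, barcoding-gap summaries, saturation profiles, NJ trees.

test_that("substitution counts use pairwise deletion and the purine/pyrimidine split", {
  cnt <- pairwise_substitution_counts("AAAA", "GGGG")
  expect_equal(cnt$n, 4L); expect_equal(cnt$P, 1.0); expect_equal(cnt$Q, 0.0)
  cnt <- pairwise_substitution_counts("ACGT", "ACGT")
  expect_equal(cnt$P, 0.0); expect_equal(cnt$Q, 0.0)
  cnt <- pairwise_substitution_counts("A-CT", "AGCA")
  expect_equal(cnt$n, 3L)
  expect_equal(cnt$transitions, 0L)
  expect_equal(cnt$transversions, 1L)   # T<->A
  expect_error(pairwise_substitution_counts("---", "AAA"), "undefined")
  expect_error(pairwise_substitution_counts("AC", "ACG"), "length")
})

test_that("the K2P closed form and analytic standard error evaluate exactly", {
  r <- k2p(0, 0, n = 100)
  expect_equal(r$d, 0); expect_equal(r$se, 0)
  r <- k2p(0.1, 0.05)
  expect_equal(r$d, -0.5 * log(1 - 0.25) - 0.25 * log(0.9))
  expect_equal(round(r$d, 5), 0.17018)
  r <- k2p(0.1, 0, n = 100)
  expect_equal(r$se, 0.0375)
  # saturation outside the log domain
  r <- k2p(0.5, 0.3)
  expect_true(r$saturated); expect_true(is.na(r$d))
})

test_that("K2P reduces to the transition-only form at Q=0 and dominates the p-distance", {
  set.seed(407)
  for (i in 1:200) {
    P <- runif(1, 0, 0.35); Q <- runif(1, 0, min(0.25, 1 - 2 * P - 0.01))
    if (1 - 2 * P - Q <= 0) next
    r <- k2p(P, Q)
    expect_gte(r$d, P + Q - 1e-12)
    expect_equal(k2p(P, 0)$d, -0.5 * log(1 - 2 * P))
  }
})

test_that("distance and variance agree with an independent K80 implementation", {
  set.seed(408)
  seqs <- c(a = random_dna(600), b = random_dna(600))
  # make b a perturbed copy of a so distances are moderate
  bb <- strsplit(seqs[["a"]], "")[[1L]]
  idx <- sample(600, 60)
  bb[idx] <- vapply(bb[idx], function(ch)
    sample(setdiff(c("A", "C", "G", "T"), ch), 1), character(1L))
  bb[sample(600, 10)] <- "-"   # exercise pairwise deletion
  seqs[["b"]] <- paste(bb, collapse = "")
  dm <- build_distance_matrix(seqs)
  bin <- ape::as.DNAbin(lapply(strsplit(tolower(seqs), ""), identity))
  ref <- ape::dist.dna(bin, model = "K80", variance = TRUE,
                       pairwise.deletion = TRUE)
  expect_equal(dm$d["a", "b"], as.numeric(ref)[1L], tolerance = 1e-12)
  expect_equal(dm$se["a", "b"]^2, attr(ref, "variance")[1L], tolerance = 1e-12)
})

test_that("distance matrices are symmetric with zero diagonal and flag undecidable pairs", {
  seqs <- c(x = "ACGTACGTAC", y = "ACGTACGTAC", z = "NNNNNNNNNN")
  dm <- build_distance_matrix(seqs)
  expect_equal(dm$d["x", "y"], 0)
  expect_equal(diag(dm$d), c(x = 0, y = 0, z = 0))
  expect_equal(dm$d, t(dm$d))
  expect_true(is.na(dm$d["x", "z"]))   # no comparable sites
})

test_that("simulated pairs are estimated within three standard errors", {
  p <- evolve_pair_k2p(10000, 0.15, kappa = 2, seed = 99L)
  cnt <- pairwise_substitution_counts(p$a, p$b)
  est <- k2p(cnt)
  expect_lt(abs(est$d - 0.15), 3 * est$se)
})

test_that("the printed divergence table round-trips through the triangular layout", {
  dm <- read_distance_table(table2_dist_path())
  expect_equal(length(dm$labels), 21L)
  expect_equal(dm$d["P_japonica_AM114929", "P_americana_JX402724"], 0.170)
  expect_equal(dm$d["P_australasiae_KX640825", "P_fuliginosa_AB126004"], 0.076)
  expect_equal(dm$se["P_americana_JX402724", "P_japonica_AM114929"], 0.018)
  expect_equal(dm$d, t(dm$d))
  tmp <- tempfile(fileext = ".tsv")
  write_distance_table(dm, tmp)
  back <- read_distance_table(tmp)
  expect_equal(back$d, dm$d, tolerance = 1e-9)
  expect_equal(back$se, dm$se, tolerance = 1e-9)
})

test_that("barcoding categories partition all pairs and the gap test is exact", {
  dm <- read_distance_table(table2_dist_path())
  taxa <- utils::read.delim(table2_taxa_path(), stringsAsFactors = FALSE)
  gap <- barcoding_gap_summary(dm, taxa)
  n <- length(dm$labels)
  expect_equal(gap$intraspecific$count + gap$interspecific_within_genus$count +
                 gap$intergeneric$count, n * (n - 1L) / 2L)
  # constructed matrix with a real gap
  labs <- c("a1", "a2", "b1")
  d <- matrix(0.5, 3, 3, dimnames = list(labs, labs)); diag(d) <- 0
  d[1, 2] <- d[2, 1] <- 0.05
  dm2 <- structure(list(labels = labs, d = d, se = d * 0, n_sites = d * 0),
                   class = "dist_matrix")
  map2 <- data.frame(label = labs, species = c("sp1", "sp2", "sp3"),
                     genus = c("G1", "G1", "G2"))
  expect_true(barcoding_gap_summary(dm2, map2)$gap_present)
  # single-species matrix: interspecific category empty, gap undefined
  map3 <- data.frame(label = labs, species = "sp1", genus = "G1")
  g3 <- barcoding_gap_summary(dm2, map3)
  expect_equal(g3$interspecific_within_genus$count, 0L)
  expect_true(is.na(g3$gap_present))
  expect_error(barcoding_gap_summary(dm2, map2[-1L, ]), "unmapped")
})

test_that("identical sequences give an all-zero saturation profile", {
  s <- random_dna(300)
  prof <- saturation_profile(c(a = s, b = s, c = s))
  for (pos in 1:3) {
    expect_true(all(prof$positions[[pos]]$pairs$s == 0))
    expect_true(all(prof$positions[[pos]]$pairs$v == 0))
    expect_true(all(prof$positions[[pos]]$pairs$d == 0))
  }
})

test_that("transitions are concave and transversions near-linear against divergence", {
  aln <- synth_codon_alignment(n_taxa = 8L, n_codons = 500L,
                               branch_d = seq(0.01, 0.35, length.out = 8L),
                               rate_multipliers = c(1, 1, 1), kappa = 4,
                               seed = 31L)
  prof <- saturation_profile(aln)
  tab <- do.call(rbind, lapply(prof$positions, `[[`, "pairs"))
  tab <- tab[order(tab$d), ]
  # transitions flatten: s/d falls from the lowest- to highest-divergence third
  n <- nrow(tab)
  lo <- tab[seq_len(n %/% 3), ]; hi <- tab[(n - n %/% 3):n, ]
  expect_gt(mean(lo$s / lo$d, na.rm = TRUE), mean(hi$s / hi$d, na.rm = TRUE))
  # transversions stay near-proportional to d at these divergences
  expect_gt(stats::cor(tab$v, tab$d), 0.9)
})

test_that("a fast third position is flagged saturated while slower positions are not", {
  aln <- synth_codon_alignment(n_taxa = 8L, n_codons = 400L,
                               branch_d = seq(0.02, 0.5, length.out = 8L),
                               rate_multipliers = c(1, 0.5, 10), seed = 3L)
  prof <- saturation_profile(aln)
  expect_false(isTRUE(prof$positions[[1L]]$saturated))
  expect_false(isTRUE(prof$positions[[2L]]$saturated))
  expect_true(prof$positions[[3L]]$saturated)
})

test_that("NJ solves the three-point equations and recovers additive four-taxon trees", {
  labs <- c("a", "b", "c")
  d <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3, dimnames = list(labs, labs))
  dm <- structure(list(labels = labs, d = d, se = d * 0, n_sites = d * 0),
                  class = "dist_matrix")
  tree <- nj_tree(dm)
  bl <- setNames(tree$edge.length, tree$tip.label[tree$edge[, 2L]])
  expect_equal(bl[["a"]], 0.5); expect_equal(bl[["b"]], 1.5)
  expect_equal(bl[["c"]], 2.5)
  # additive matrix from ((a,b),(c,d)) with known branch lengths
  labs <- c("a", "b", "c", "d")
  d <- matrix(0, 4, 4, dimnames = list(labs, labs))
  d["a", "b"] <- d["b", "a"] <- 0.2 + 0.3
  d["c", "d"] <- d["d", "c"] <- 0.25 + 0.15
  d["a", "c"] <- d["c", "a"] <- 0.2 + 0.1 + 0.25
  d["a", "d"] <- d["d", "a"] <- 0.2 + 0.1 + 0.15
  d["b", "c"] <- d["c", "b"] <- 0.3 + 0.1 + 0.25
  d["b", "d"] <- d["d", "b"] <- 0.3 + 0.1 + 0.15
  tree <- nj_tree(structure(list(labels = labs, d = d), class = "dist_matrix"))
  truth <- ape::read.tree(text = "((a:0.2,b:0.3):0.1,c:0.25,d:0.15);")
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tree), truth)), 0)
  expect_equal(sort(tree$edge.length), sort(truth$edge.length))
})

test_that("NJ matches UPGMA topology on ultrametric distances and validates input", {
  set.seed(409)
  tr <- ape::rcoal(5)                      # ultrametric by construction
  d <- ape::cophenetic.phylo(tr)
  dm <- structure(list(labels = rownames(d), d = d), class = "dist_matrix")
  njt <- nj_tree(dm)
  upg <- ape::as.phylo(stats::hclust(stats::as.dist(d), method = "average"))
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(njt), ape::unroot(upg))), 0)
  d_bad <- d; d_bad[1, 2] <- d_bad[2, 1] <- NA
  expect_error(nj_tree(structure(list(labels = rownames(d), d = d_bad),
                                 class = "dist_matrix")), "missing")
  expect_match(nj_newick(dm), "^\\(.*\\);$")
})
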