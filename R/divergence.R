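# Kimura two-parameter divergence with analytic standard errors, distance
# matrices in the d-below / SE-above triangular layout, barcoding-gap
# summaries, codon-position saturation profiles, and NJ trees.

#' Transition/transversion counts between two aligned sequences
#'
#' Pairwise deletion: sites where either sequence has a gap or non-ACGT
#' character are excluded from `n`. A<->G and C<->T differences are
#' transitions; every other difference is a transversion.
#'
#' @param a,b aligned nucleotide strings of equal length.
#' @return list of class `subst_counts`: `n`, `transitions`, `transversions`,
#'   `P`, `Q`.
#' @export
pairwise_substitution_counts <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("sequences differ in aligned length")
  x <- seq_chars(toupper(a))
  y <- seq_chars(toupper(b))
  use <- x %in% DNA_BASES & y %in% DNA_BASES
  x <- x[use]; y <- y[use]
  n <- length(x)
  if (n == 0L) stop("undefined comparison: no shared unambiguous sites")
  diff <- x != y
  purine_x <- x %in% c("A", "G")
  purine_y <- y %in% c("A", "G")
  ts <- diff & (purine_x == purine_y)   # A<->G or C<->T
  tv <- diff & !ts
  structure(list(n = n, transitions = sum(ts), transversions = sum(tv),
                 P = sum(ts) / n, Q = sum(tv) / n),
            class = "subst_counts")
}

#' Kimura two-parameter distance and standard error
#'
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)` with the analytic (delta
#' method) standard error
#' `SE = sqrt((c1^2 P + c3^2 Q - (c1 P + c3 Q)^2) / n)` where
#' `c1 = 1/(1 - 2P - Q)`, `c2 = 1/(1 - 2Q)`, `c3 = (c1 + c2)/2`.
#' Outside the log domain (`1 - 2P - Q <= 0` or `1 - 2Q <= 0`) the distance
#' is saturated: both values are `NA` and `saturated` is TRUE.
#'
#' @param counts a `subst_counts` object, or a transition proportion `P`.
#' @param Q,n transversion proportion and number of sites when `counts` is
#'   given as `P`.
#' @return list `d`, `se`, `saturated`.
#' @export
k2p <- function(counts, Q = NULL, n = NULL) {
  if (inherits(counts, "subst_counts")) {
    P <- counts$P; Q <- counts$Q; n <- counts$n
  } else {
    P <- counts
    if (is.null(Q)) stop("Q required when P is given directly")
  }
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    return(list(d = NA_real_, se = NA_real_, saturated = TRUE))
  d <- -0.5 * log(w1) - 0.25 * log(w2)
  se <- if (is.null(n)) NA_real_ else {
    c1 <- 1 / w1; c2 <- 1 / w2; c3 <- (c1 + c2) / 2
    sqrt((c1^2 * P + c3^2 * Q - (c1 * P + c3 * Q)^2) / n)
  }
  list(d = d, se = se, saturated = FALSE)
}

#' Pairwise K2P distance matrix
#'
#' Applies [pairwise_substitution_counts()] and [k2p()] to every pair of a
#' labelled alignment, with pairwise deletion of gapped/ambiguous sites.
#'
#' @param alignment named character vector of equal-length aligned sequences
#'   (or a `Biostrings::DNAStringSet`).
#' @return object of class `dist_matrix`: list with `labels` and symmetric
#'   matrices `d`, `se`, `n_sites` (saturated or undefined pairs are `NA`).
#' @export
build_distance_matrix <- function(alignment) {
  if (inherits(alignment, "XStringSet"))
    alignment <- setNames(as.character(alignment), names(alignment))
  labels <- names(alignment) %||% paste0("seq", seq_along(alignment))
  m <- length(alignment)
  if (m < 2L) stop("need at least 2 sequences")
  d <- se <- ns <- matrix(NA_real_, m, m, dimnames = list(labels, labels))
  diag(d) <- 0; diag(se) <- 0
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      res <- tryCatch({
        cnt <- pairwise_substitution_counts(alignment[[i]], alignment[[j]])
        c(k2p(cnt), list(n = cnt$n))
      }, error = function(e) NULL)
      if (!is.null(res)) {
        d[i, j] <- d[j, i] <- res$d
        se[i, j] <- se[j, i] <- res$se
        ns[i, j] <- ns[j, i] <- res$n
      }
    }
  }
  structure(list(labels = labels, d = d, se = se, n_sites = ns),
            class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("<dist_matrix> %d taxa, K2P distances (NA pairs: %d)\n",
              length(x$labels), sum(is.na(x$d[upper.tri(x$d)]))))
  invisible(x)
}

#' Read a triangular distance table
#'
#' Parses the conventional report layout of pairwise-divergence tables:
#' a TSV with one labelled row per taxon, distances below the diagonal and
#' standard errors above it, empty diagonal.
#'
#' @param path TSV path.
#' @return a `dist_matrix`.
#' @export
read_distance_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  labels <- tab[[1L]]
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  m <- length(labels)
  if (ncol(vals) != m) stop("triangular table is not square: ", path)
  vals <- matrix(suppressWarnings(as.numeric(vals)), m, m)
  d <- se <- matrix(NA_real_, m, m, dimnames = list(labels, labels))
  low <- lower.tri(d)
  d[low] <- vals[low]
  d[upper.tri(d)] <- t(d)[upper.tri(d)]
  up <- upper.tri(se)
  se[up] <- vals[up]
  se[lower.tri(se)] <- t(se)[lower.tri(se)]
  diag(d) <- 0; diag(se) <- 0
  structure(list(labels = labels, d = d, se = se,
                 n_sites = matrix(NA_real_, m, m, dimnames = list(labels, labels))),
            class = "dist_matrix")
}

#' Write a distance matrix in the triangular layout
#'
#' Distances below the diagonal, standard errors above, values rounded to 3
#' decimals at report time only.
#'
#' @param dm a `dist_matrix`.
#' @param path output TSV path.
#' @param digits decimals for the report (default 3).
#' @export
write_distance_table <- function(dm, path, digits = 3L) {
  m <- length(dm$labels)
  out <- matrix("", m, m)
  low <- lower.tri(out); up <- upper.tri(out)
  out[low] <- ifelse(is.na(dm$d[low]), "NA", sprintf("%.*f", digits, dm$d[low]))
  out[up] <- ifelse(is.na(dm$se[up]), "NA", sprintf("%.*f", digits, dm$se[up]))
  df <- data.frame(label = dm$labels, out, stringsAsFactors = FALSE)
  colnames(df) <- c("label", dm$labels)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Barcoding-gap summary of a distance matrix
#'
#' Partitions all taxon pairs into three categories — intraspecific (same
#' species), interspecific within a genus (same genus, different species;
#' intraspecific pairs are excluded), and intergeneric — and summarizes each.
#' A barcoding gap is present when the smallest intergeneric distance exceeds
#' the largest interspecific-within-genus distance.
#'
#' @param dm a `dist_matrix`.
#' @param taxon_map data frame with columns `label`, `species`, `genus`
#'   covering every matrix label.
#' @param focal_genus optionally restrict the within-genus category to one
#'   genus (e.g. the genus under revision).
#' @param outside_taxon optionally restrict the intergeneric category to
#'   pairs involving this species or genus.
#' @return list of class `barcoding_gap_summary`: per-category `count`,
#'   `mean`, `min`, `max`; `gap_present` (NA when a category is empty).
#' @export
barcoding_gap_summary <- function(dm, taxon_map, focal_genus = NULL,
                                  outside_taxon = NULL) {
  need <- setdiff(dm$labels, taxon_map$label)
  if (length(need) > 0L)
    stop("unmapped label(s): ", paste(need, collapse = ", "))
  idx <- match(dm$labels, taxon_map$label)
  species <- taxon_map$species[idx]
  genus <- taxon_map$genus[idx]
  m <- length(dm$labels)
  pairs <- which(upper.tri(dm$d), arr.ind = TRUE)
  d <- dm$d[pairs]
  same_sp <- species[pairs[, 1L]] == species[pairs[, 2L]]
  same_gen <- genus[pairs[, 1L]] == genus[pairs[, 2L]]
  cat3 <- ifelse(same_sp, "intraspecific",
                 ifelse(same_gen, "interspecific_within_genus", "intergeneric"))
  keep_within <- cat3 == "interspecific_within_genus"
  if (!is.null(focal_genus))
    keep_within <- keep_within & genus[pairs[, 1L]] == focal_genus &
      genus[pairs[, 2L]] == focal_genus
  keep_between <- cat3 == "intergeneric"
  if (!is.null(outside_taxon)) {
    is_out <- species %in% outside_taxon | genus %in% outside_taxon
    keep_between <- keep_between &
      (is_out[pairs[, 1L]] | is_out[pairs[, 2L]])
  }
  summarize <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L)
      return(list(count = 0L, mean = NA_real_, min = NA_real_, max = NA_real_))
    list(count = length(v), mean = mean(v), min = min(v), max = max(v))
  }
  res <- list(
    intraspecific = summarize(d[cat3 == "intraspecific"]),
    interspecific_within_genus = summarize(d[keep_within]),
    intergeneric = summarize(d[keep_between]),
    category_counts = table(cat3))
  res$gap_present <-
    if (res$intergeneric$count == 0L ||
        res$interspecific_within_genus$count == 0L) NA
    else res$intergeneric$min > res$interspecific_within_genus$max
  class(res) <- "barcoding_gap_summary"
  res
}

#' @export
print.barcoding_gap_summary <- function(x, ...) {
  for (cat in c("intraspecific", "interspecific_within_genus", "intergeneric")) {
    s <- x[[cat]]
    cat(sprintf("  %-28s n=%3d  mean %.3f  range %.3f-%.3f\n", cat, s$count,
                s$mean, s$min, s$max))
  }
  cat(sprintf("  barcoding gap present: %s\n", x$gap_present))
  invisible(x)
}

#' Substitution-saturation profile by codon position
#'
#' For each codon position, computes per-pair transition (`s`) and
#' transversion (`v`) proportions and the K2P distance on that position's
#' sites, then summarizes the flattening of transitions against divergence:
#' the least-squares slope of `s ~ d` among the most divergent quartile of
#' pairs divided by the slope among the least divergent quartile. A position
#' is flagged saturated when this ratio drops below `ratio_threshold` (a
#' heuristic: transitions plateau once multiple hits accumulate).
#'
#' @param codon_alignment named character vector of equal-length in-frame CDS
#'   alignments (length divisible by 3 after the frame offset), or a
#'   [gene_alignment()] of class PCG.
#' @param frame codon offset (columns before the first complete codon).
#' @param ratio_threshold saturation flag threshold (default 0.5).
#' @return list of class `saturation_profile`: per position a data frame
#'   `pairs` (`pair`, `s`, `v`, `d`) plus `slope_ratio` and `saturated`
#'   (both NA with fewer than 4 pairs).
#' @export
saturation_profile <- function(codon_alignment, frame = 0L,
                               ratio_threshold = 0.5) {
  if (inherits(codon_alignment, "gene_alignment")) {
    frame <- codon_alignment$frame
    codon_alignment <- codon_alignment$sequences
  }
  seqs <- unlist(codon_alignment)
  w <- unique(nchar(seqs))
  if (length(w) != 1L) stop("ragged alignment")
  if ((w - frame) %% 3L != 0L) stop("alignment length not divisible by 3")
  labels <- names(seqs) %||% paste0("seq", seq_along(seqs))
  cols <- (frame + 1L):w
  codon_pos <- ((cols - frame - 1L) %% 3L) + 1L
  out <- list(positions = list())
  for (pos in 1:3) {
    keep <- cols[codon_pos == pos]
    sub <- vapply(seqs, function(x)
      paste(seq_chars(x)[keep], collapse = ""), character(1L))
    m <- length(sub)
    rows <- list()
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      cnt <- tryCatch(pairwise_substitution_counts(sub[[i]], sub[[j]]),
                      error = function(e) NULL)
      if (is.null(cnt)) next
      kk <- k2p(cnt)
      rows[[length(rows) + 1L]] <- data.frame(
        pair = paste(labels[i], labels[j], sep = "|"),
        s = cnt$P, v = cnt$Q, d = kk$d, stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, rows)
    ratio <- saturation_slope_ratio(tab)
    out$positions[[pos]] <- list(
      pairs = tab, slope_ratio = ratio,
      saturated = if (is.na(ratio)) NA else ratio < ratio_threshold)
  }
  class(out) <- "saturation_profile"
  out
}

# Slope of s ~ d in the top distance quartile over that in the bottom
# quartile; NA with < 4 usable pairs or degenerate spread.
saturation_slope_ratio <- function(tab) {
  tab <- tab[!is.na(tab$d), , drop = FALSE]
  if (is.null(tab) || nrow(tab) < 4L) return(NA_real_)
  qs <- quantile(tab$d, c(0.25, 0.75))
  lo <- tab[tab$d <= qs[1L], , drop = FALSE]
  hi <- tab[tab$d >= qs[2L], , drop = FALSE]
  if (nrow(lo) < 2L || nrow(hi) < 2L) return(NA_real_)
  if (diff(range(lo$d)) == 0 || diff(range(hi$d)) == 0) return(NA_real_)
  slope <- function(df) unname(coef(lm(s ~ d, data = df))[2L])
  s_lo <- slope(lo)
  if (!is.finite(s_lo) || s_lo == 0) return(NA_real_)
  slope(hi) / s_lo
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via \pkg{ape}) on the K2P distances; negative
#' branch lengths are clamped to zero with a warning.
#'
#' @param dm a `dist_matrix` with at least 3 taxa and no missing entries.
#' @return an \pkg{ape} `phylo` tree.
#' @export
nj_tree <- function(dm) {
  d <- if (inherits(dm, "dist_matrix")) dm$d else as.matrix(dm)
  if (nrow(d) < 3L) stop("need at least 3 taxa")
  if (anyNA(d)) stop("distance matrix has missing entries")
  tree <- ape::nj(d)
  if (any(tree$edge.length < 0)) {
    warning("negative branch length(s) clamped to 0")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

#' Newick serialization of an NJ tree
#' @param tree a `phylo` object (or a `dist_matrix`, which is first passed to
#'   [nj_tree()]).
#' @return Newick string with branch lengths.
#' @export
nj_newick <- function(tree) {
  if (inherits(tree, "dist_matrix")) tree <- nj_tree(tree)
  ape::write.tree(tree)
}
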