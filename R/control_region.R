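# Structural analysis of non-coding mitochondrial sequence: degenerate motif
# scanning, tandem-repeat calling, conserved-block detection across aligned
# control regions, and stem-loop (hairpin) prediction with T-stretch
# annotation.

# IUPAC nucleotide classes (DNA). An N in the *sequence* never matches any
# pattern position; pattern classes therefore expand to ACGT subsets only.
iupac_regex_class <- function(ch) {
  map <- Biostrings::IUPAC_CODE_MAP
  if (!ch %in% names(map)) stop("invalid IUPAC character: ", ch)
  cls <- map[[ch]]
  if (nchar(cls) == 1L) cls else paste0("[", cls, "]")
}

iupac_to_regex <- function(pattern) {
  paste(vapply(seq_chars(toupper(pattern)), iupac_regex_class, character(1L)),
        collapse = "")
}

#' Scan a sequence for a degenerate IUPAC motif
#'
#' Finds all (possibly overlapping) occurrences of an IUPAC pattern such as
#' `WACTTAA`, the conserved spacer motif of blattarian mitogenomes.
#' Sequence Ns never match.
#'
#' @param seq nucleotide string.
#' @param pattern IUPAC pattern.
#' @param both_strands also scan the reverse complement and report hits with
#'   strand `N` at their position on the stored strand (default FALSE).
#' @return data frame with columns `start`, `strand`, `matched`, sorted by
#'   position.
#' @export
scan_iupac_motif <- function(seq, pattern, both_strands = FALSE) {
  seq <- toupper(seq)
  w <- nchar(pattern)
  rx <- paste0("(?=(", iupac_to_regex(pattern), "))")
  hit_starts <- function(s) {
    m <- gregexpr(rx, s, perl = TRUE)[[1L]]
    if (m[1L] == -1L) integer() else as.integer(m)
  }
  substr_all <- function(s, pos)
    if (length(pos) == 0L) character() else substring(s, pos, pos + w - 1L)
  pos_j <- hit_starts(seq)
  out <- data.frame(start = pos_j,
                    strand = rep("J", length(pos_j)),
                    matched = substr_all(seq, pos_j),
                    stringsAsFactors = FALSE)
  if (both_strands) {
    rc <- revcomp(seq)
    pos_rc <- hit_starts(rc)
    L <- nchar(seq)
    out <- rbind(out, data.frame(
      start = L - (pos_rc + w - 1L) + 1L,
      strand = rep("N", length(pos_rc)),
      matched = substr_all(rc, pos_rc),
      stringsAsFactors = FALSE))
  }
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "pattern") <- toupper(pattern)
  out
}

#' Scan for a gapped IUPAC pattern
#'
#' A mini-language for composite control-region elements such as the
#' `5'-A...TAATTTA...TT...ATA...ACATTT-3'` core: whitespace-separated tokens,
#' each either an IUPAC word or `N{n,m}`, a wildcard run of n to m unambiguous
#' bases. Example: `"A N{1,30} TAATTTA N{1,30} TT N{1,30} ATA N{1,30} ACATTT"`.
#'
#' @param seq nucleotide string.
#' @param pattern gapped pattern string.
#' @return data frame with columns `start`, `end`, `matched` (leftmost,
#'   non-overlapping matches).
#' @export
scan_gapped_pattern <- function(seq, pattern) {
  seq <- toupper(seq)
  tokens <- strsplit(trimws(pattern), "\\s+")[[1L]]
  rx <- vapply(tokens, function(tok) {
    m <- regexec("^N\\{(\\d+),(\\d+)\\}$", tok)[[1L]]
    if (m[1L] != -1L) {
      parts <- regmatches(tok, regexec("^N\\{(\\d+),(\\d+)\\}$", tok))[[1L]]
      sprintf("[ACGT]{%s,%s}", parts[2L], parts[3L])
    } else iupac_to_regex(tok)
  }, character(1L))
  rx <- paste(rx, collapse = "")
  m <- gregexpr(rx, seq, perl = TRUE)[[1L]]
  if (m[1L] == -1L)
    return(data.frame(start = integer(), end = integer(),
                      matched = character(), stringsAsFactors = FALSE))
  starts <- as.integer(m)
  ends <- starts + attr(m, "match.length") - 1L
  data.frame(start = starts, end = ends,
             matched = substring(seq, starts, ends), stringsAsFactors = FALSE)
}

#' Detect tandem repeats
#'
#' A deliberately simple, deterministic tandem-repeat detector (not a
#' re-implementation of Tandem Repeat Finder's probabilistic alignment
#' scoring): for each candidate period it seeds on exact self-matches at lag
#' `period`, extends greedily in both directions while the extension keeps the
#' running identity at or above `min_identity`, and reports
#' maximal, non-redundant calls. For any repeated region the minimal-period
#' call wins; a partial final copy is allowed (fractional `copies`).
#'
#' @param seq nucleotide string (length >= 2 * `min_period`).
#' @param min_period,max_period candidate unit lengths in bp.
#' @param min_copies minimum copy number, fractional copies allowed
#'   (default 2.0).
#' @param min_identity minimum fraction of positions matching the rotated
#'   consensus (default 0.85).
#' @return data frame with columns `unit`, `period`, `copies`, `start`, `end`,
#'   `identity`, ordered by position; zero rows when nothing qualifies.
#' @export
find_tandem_repeats <- function(seq, min_period = 3L, max_period = 200L,
                                min_copies = 2.0, min_identity = 0.85) {
  seq <- toupper(seq)
  s <- seq_chars(seq)
  n <- length(s)
  if (n < 2L * min_period) stop("sequence shorter than 2 * min_period")
  valid <- s %in% DNA_BASES
  calls <- list()
  covered <- logical(n)

  for (p in min_period:min(max_period, n %/% 2L)) {
    lag_match <- s[(p + 1L):n] == s[1L:(n - p)] & valid[(p + 1L):n] & valid[1L:(n - p)]
    runs <- true_runs(lag_match)   # index i <=> positions (i) and (i + p) match
    min_run <- max(p, ceiling(p * (min_copies - 1)))
    runs <- runs[runs$length >= min_run, , drop = FALSE]
    for (k in seq_len(nrow(runs))) {
      a <- runs$start[k]              # genome pos a matches a + p
      b <- runs$end[k] + p            # span of the exact repeat
      # greedy mismatch-tolerant extension; trim back to the last match
      ext <- extend_repeat(s, valid, a, b, p, min_identity, n)
      a <- ext$start; b <- ext$end
      span <- b - a + 1L
      copies <- span / p
      if (copies < min_copies) next
      if (sum(covered[a:b]) > 0.5 * span) next   # shadowed by an earlier call
      unit <- repeat_consensus(s, a, b, p)
      if (minimal_period(unit) < p) next         # reported at its true period
      idx <- a:b
      identity <- mean(s[idx] == seq_chars(unit)[((idx - a) %% p) + 1L])
      if (identity < min_identity) next
      covered[a:b] <- TRUE
      calls[[length(calls) + 1L]] <- data.frame(
        unit = unit, period = p, copies = copies, start = a, end = b,
        identity = identity, stringsAsFactors = FALSE)
    }
  }
  if (length(calls) == 0L)
    return(data.frame(unit = character(), period = integer(),
                      copies = numeric(), start = integer(), end = integer(),
                      identity = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, calls)
  out <- out[order(out$start, out$period), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Extend a seeded repeat span while the running identity of the extension
# stays >= min_identity; the extension must end on a matching position.
extend_repeat <- function(s, valid, a, b, p, min_identity, n) {
  # rightwards: compare position j against j - p
  j <- b + 1L; match_cnt <- 0L; tried <- 0L; last_good <- b
  while (j <= n && valid[j]) {
    tried <- tried + 1L
    if (s[j] == s[j - p]) match_cnt <- match_cnt + 1L
    if (match_cnt / tried < min_identity) break
    if (s[j] == s[j - p]) last_good <- j
    j <- j + 1L
  }
  b <- last_good
  # leftwards: compare position j against j + p
  j <- a - 1L; match_cnt <- 0L; tried <- 0L; last_good <- a
  while (j >= 1L && valid[j]) {
    tried <- tried + 1L
    if (s[j] == s[j + p]) match_cnt <- match_cnt + 1L
    if (match_cnt / tried < min_identity) break
    if (s[j] == s[j + p]) last_good <- j
    j <- j - 1L
  }
  list(start = last_good, end = b)
}

# Majority-vote consensus unit over the phases of a repeat span.
repeat_consensus <- function(s, a, b, p) {
  idx <- a:b
  phase <- ((idx - a) %% p) + 1L
  unit <- vapply(seq_len(p), function(k) {
    tab <- sort(table(s[idx[phase == k]]), decreasing = TRUE)
    names(tab)[1L]
  }, character(1L))
  paste(unit, collapse = "")
}

# Smallest period q (divisor of nchar(unit)) that tiles the unit exactly.
minimal_period <- function(unit) {
  L <- nchar(unit)
  for (q in seq_len(L - 1L)) {
    if (L %% q != 0L) next
    if (strrep(substr(unit, 1L, q), L %/% q) == unit) return(q)
  }
  L
}

#' Detect conserved blocks in an alignment
#'
#' A column is conserved when it has no gaps and all sequences agree (with
#' `column_threshold < 1`, when the modal state reaches that fraction). Runs
#' of conserved columns separated by at most `max_interruptions` non-conserved
#' columns are merged; blocks narrower than `min_width` are dropped.
#' Similarity is `100 * conserved columns / block width`, so a 20-column
#' block with exactly one variable column scores 95%.
#'
#' @param alignment named character vector of equal-length gapped sequences
#'   (gap character `-`), at least 2 sequences.
#' @param min_width minimum block width in columns (default 10).
#' @param column_threshold fraction of sequences that must share the modal
#'   state for a column to count as conserved (default 1.0 = invariant).
#' @param max_interruptions non-conserved columns tolerated inside a block
#'   (default 1).
#' @return data frame with columns `start`, `end`, `width`, `similarity`;
#'   attribute `taxon_coords` holds per-taxon ungapped start/end matrices.
#' @export
find_conserved_blocks <- function(alignment, min_width = 10L,
                                  column_threshold = 1.0,
                                  max_interruptions = 1L) {
  alignment <- toupper(unlist(alignment))
  if (length(alignment) < 2L) stop("need at least 2 sequences")
  widths <- nchar(alignment)
  if (length(unique(widths)) != 1L) stop("ragged alignment: unequal lengths")
  mat <- do.call(rbind, strsplit(alignment, "", fixed = TRUE))
  w <- ncol(mat)
  conserved <- vapply(seq_len(w), function(j) {
    col <- mat[, j]
    if (any(col == "-")) return(FALSE)
    tab <- table(col)
    max(tab) / length(col) >= column_threshold
  }, logical(1L))

  runs <- true_runs(conserved)
  if (nrow(runs) == 0L)
    return(empty_blocks())
  # merge runs across short interruptions
  merged <- runs[1L, , drop = FALSE]
  if (nrow(runs) > 1L) {
    for (k in 2L:nrow(runs)) {
      gap <- runs$start[k] - merged$end[nrow(merged)] - 1L
      if (gap <= max_interruptions) {
        merged$end[nrow(merged)] <- runs$end[k]
      } else {
        merged <- rbind(merged, runs[k, , drop = FALSE])
      }
    }
  }
  merged$width <- merged$end - merged$start + 1L
  merged <- merged[merged$width >= min_width, , drop = FALSE]
  if (nrow(merged) == 0L) return(empty_blocks())
  merged$similarity <- vapply(seq_len(nrow(merged)), function(k) {
    100 * sum(conserved[merged$start[k]:merged$end[k]]) / merged$width[k]
  }, numeric(1L))
  out <- data.frame(start = merged$start, end = merged$end,
                    width = merged$width, similarity = merged$similarity)
  rownames(out) <- NULL
  # per-taxon ungapped coordinates of each block
  ungapped <- apply(mat != "-", 1L, cumsum)   # w x ntaxa
  attr(out, "taxon_coords") <- lapply(seq_len(nrow(out)), function(k) {
    st <- out$start[k]; en <- out$end[k]
    data.frame(taxon = names(alignment) %||% paste0("seq", seq_along(alignment)),
               start = ungapped[st, ] - (mat[, st] != "-") + 1L,
               end = ungapped[en, ], stringsAsFactors = FALSE)
  })
  out
}

empty_blocks <- function() {
  out <- data.frame(start = integer(), end = integer(), width = integer(),
                    similarity = numeric())
  attr(out, "taxon_coords") <- list()
  out
}

# Watson-Crick (+ optional G:T wobble) pairing test for two base characters.
bases_pair <- function(x, y, allow_gu = TRUE) {
  wc <- (x == "A" & y == "T") | (x == "T" & y == "A") |
        (x == "G" & y == "C") | (x == "C" & y == "G")
  if (allow_gu) wc | (x == "G" & y == "T") | (x == "T" & y == "G") else wc
}

#' Predict the best stem-loop (hairpin) in a sequence
#'
#' Exhaustive search over all loop placements within `[loop_min, loop_max]`,
#' extending the stem outwards from the loop and counting paired bases
#' (A:T, G:C, and G:T wobble when `allow_gu`). Up to `max_stem_mismatch`
#' unpaired rungs may interrupt the stem (they do not count as pairs, and the
#' stem is trimmed back to its outermost pair). The call maximizing
#' `stem_pairs` wins; ties break to the shorter loop, then leftmost. This is
#' base-pair maximization, not thermodynamic folding.
#'
#' @param seq nucleotide string of length >= `2 * min_stem + loop_min`.
#' @param min_stem minimum paired bases to report a hairpin (default 5).
#' @param loop_min,loop_max loop length bounds in nt (defaults 3, 20).
#' @param allow_gu allow G:T wobble pairs (default TRUE).
#' @param max_stem_mismatch unpaired rungs tolerated inside the stem
#'   (default 0).
#' @return `NULL` when nothing qualifies, otherwise a list of class
#'   `hairpin_call`: `stem_pairs`, `loop_start`, `loop_end`, `loop_length`,
#'   `loop_seq`, `t_stretch` (longest T run in the loop), arm coordinates
#'   (`arm5_start/arm5_end/arm3_start/arm3_end`) and a `pairs` data frame.
#' @export
predict_best_hairpin <- function(seq, min_stem = 5L, loop_min = 3L,
                                 loop_max = 20L, allow_gu = TRUE,
                                 max_stem_mismatch = 0L) {
  seq <- toupper(seq)
  s <- seq_chars(seq)
  n <- length(s)
  if (n < 2L * min_stem + loop_min) stop("sequence too short for a hairpin")
  best <- NULL
  for (i in seq(2L, n - loop_min)) {            # loop start
    for (L in loop_min:loop_max) {
      j <- i + L                                 # first base after the loop
      if (j > n) break
      a <- i - 1L; b <- j
      pairs5 <- integer(); pairs3 <- integer()
      mism <- 0L
      while (a >= 1L && b <= n) {
        ok <- s[a] %in% DNA_BASES && s[b] %in% DNA_BASES &&
          bases_pair(s[a], s[b], allow_gu)
        if (ok) {
          pairs5 <- c(pairs5, a); pairs3 <- c(pairs3, b)
        } else {
          mism <- mism + 1L
          if (mism > max_stem_mismatch) break
        }
        a <- a - 1L; b <- b + 1L
      }
      np <- length(pairs5)
      if (np < min_stem) next
      cand <- list(stem_pairs = np, loop_start = i, loop_end = i + L - 1L,
                   loop_length = L)
      if (is.null(best) ||
          np > best$stem_pairs ||
          (np == best$stem_pairs && L < best$loop_length) ||
          (np == best$stem_pairs && L == best$loop_length &&
           min(pairs5) < best$arm5_start)) {
        cand$arm5_start <- min(pairs5); cand$arm5_end <- max(pairs5)
        cand$arm3_start <- min(pairs3); cand$arm3_end <- max(pairs3)
        cand$pairs <- data.frame(pos5 = rev(pairs5), pos3 = rev(pairs3),
                                 base5 = s[rev(pairs5)], base3 = s[rev(pairs3)],
                                 stringsAsFactors = FALSE)
        best <- cand
      }
    }
  }
  if (is.null(best)) return(NULL)
  best$loop_seq <- substr(seq, best$loop_start, best$loop_end)
  best$t_stretch <- longest_base_run(best$loop_seq, "T")$length
  class(best) <- "hairpin_call"
  best
}

#' @export
print.hairpin_call <- function(x, ...) {
  cat(sprintf("<hairpin> stem %d bp, loop %d nt (%d-%d), T-stretch %d\n",
              x$stem_pairs, x$loop_length, x$loop_start, x$loop_end,
              x$t_stretch))
  invisible(x)
}
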