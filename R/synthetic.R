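# Synthetic annotated mitogenomes with a ground-truth ledger, plus K2P
# sequence-pair and codon-alignment simulators. The generator emulates the
# blattid study system: a circular ~15.6 kb A+T-rich (~75%) genome with 13
# CDS / 22 tRNA / 2 rRNA features in the ancestral insect arrangement,
# incomplete stop codons, short intergenic spacers carrying a degenerate
# 7-mer motif, and a control region containing tandem arrays, a planted
# stem-loop with a loop T-stretch, and conserved blocks.

# Base sampling probabilities for a target A+T fraction (A/T and G/C split
# evenly, the neutral default).
at_base_probs <- function(at_target) {
  c(A = at_target / 2, C = (1 - at_target) / 2,
    G = (1 - at_target) / 2, T = at_target / 2)
}

random_bases <- function(n, probs) {
  if (n <= 0L) return("")
  paste(sample(DNA_BASES, n, replace = TRUE, prob = probs[DNA_BASES]),
        collapse = "")
}

# Default start codons observed in blattid mitogenomes.
DEFAULT_START_CODONS <- c(
  ND2 = "ATG", COX1 = "TTG", COX2 = "ATG", ATP8 = "ATT", ATP6 = "ATG",
  COX3 = "ATG", ND3 = "ATT", ND5 = "ATG", ND4 = "ATG", ND4L = "ATG",
  ND6 = "ATT", CYTB = "ATG", ND1 = "ATG")

#' Default synthetic-genome layout
#'
#' Canonical blattid gene order with realistic lengths; `spacer_after` gives
#' the intergenic gap following each feature (0 = abutting). The 25 bp
#' spacer after tRNA-Ser(UCN) carries the conserved WACTTAA-type motif; a
#' 16 bp spacer follows tRNA-Leu(UUR).
#'
#' @param cr_length control-region length in bp (default 900).
#' @return data frame `name`, `ftype`, `strand`, `length`, `spacer_after`.
#' @export
default_genome_layout <- function(cr_length = 900L) {
  rows <- list(
    c("tRNA-Ile",      "tRNA", "J",  67, 0), c("tRNA-Gln", "tRNA", "N", 69, 7),
    c("tRNA-Met",      "tRNA", "J",  67, 0), c("ND2",      "CDS",  "J", 1029, 0),
    c("tRNA-Trp",      "tRNA", "J",  71, 0), c("tRNA-Cys", "tRNA", "N", 68, 9),
    c("tRNA-Tyr",      "tRNA", "N",  69, 4), c("COX1",     "CDS",  "J", 1536, 5),
    c("tRNA-Leu(UUR)", "tRNA", "J",  66, 16), c("COX2",    "CDS",  "J", 685, 0),
    c("tRNA-Lys",      "tRNA", "J",  71, 0), c("tRNA-Asp", "tRNA", "J", 65, 0),
    c("ATP8",          "CDS",  "J", 159, 0), c("ATP6",     "CDS",  "J", 680, 0),
    c("COX3",          "CDS",  "J", 789, 4), c("tRNA-Gly", "tRNA", "J", 65, 0),
    c("ND3",           "CDS",  "J", 352, 0), c("tRNA-Ala", "tRNA", "J", 66, 0),
    c("tRNA-Arg",      "tRNA", "J",  67, 0), c("tRNA-Asn", "tRNA", "J", 66, 0),
    c("tRNA-Ser(AGN)", "tRNA", "J",  67, 1), c("tRNA-Glu", "tRNA", "J", 70, 1),
    c("tRNA-Phe",      "tRNA", "N",  67, 0), c("ND5",      "CDS",  "N", 1731, 0),
    c("tRNA-His",      "tRNA", "N",  66, 2), c("ND4",      "CDS",  "N", 1338, 0),
    c("ND4L",          "CDS",  "N", 285, 2), c("tRNA-Thr", "tRNA", "J", 64, 0),
    c("tRNA-Pro",      "tRNA", "N",  67, 2), c("ND6",      "CDS",  "J", 500, 0),
    c("CYTB",          "CDS",  "J", 1132, 5), c("tRNA-Ser(UCN)", "tRNA", "J", 71, 25),
    c("ND1",           "CDS",  "N", 948, 3), c("tRNA-Leu(CUN)", "tRNA", "N", 64, 0),
    c("rrnL",          "rRNA", "N", 1308, 0), c("tRNA-Val", "tRNA", "N", 71, 0),
    c("rrnS",          "rRNA", "N", 812, 0),
    c("CR", "control_region", "J", cr_length, 0))
  out <- do.call(rbind, lapply(rows, function(r)
    data.frame(name = r[1L], ftype = r[2L], strand = r[3L],
               length = as.integer(r[4L]), spacer_after = as.integer(r[5L]),
               stringsAsFactors = FALSE)))
  out
}

#' Specification for a synthetic mitogenome
#'
#' Defines the study conditions the generator emulates. Defaults: target AT
#' fraction 0.749, the canonical blattid 37-gene + control-region layout of
#' [default_genome_layout()] (~15.6 kb total), the degenerate spacer motif
#' `WACTTAA` realized as `TACTTAA` planted in the 25 bp spacer following
#' tRNA-Ser(UCN), and a control region carrying three tandem arrays (two full
#' A-type units, two full B-type units, two-and-a-half C-type units), a
#' 30-pair stem-loop with an 8 nt loop T-stretch, and three conserved block
#' seeds.
#'
#' @param seed integer controlling all randomness of the genome draw.
#' @param at_target background A+T fraction in expectation.
#' @param layout feature layout data frame (`name`, `ftype`, `strand`,
#'   `length`, `spacer_after`).
#' @param motif motif string planted in a spacer (must fit).
#' @param motif_spacer_after name of the feature whose following spacer
#'   receives the motif.
#' @param start_codons named vector of CDS start codons.
#' @param cr_tandem data frame `period`, `copies` of arrays to plant.
#' @param cr_hairpin list `stem`, `loop`, `t_stretch`.
#' @param cr_blocks character vector of conserved block seed sequences
#'   (NULL = draw three 20-mers).
#' @return list of class `genome_spec`.
#' @export
genome_spec <- function(seed = 1L, at_target = 0.749,
                        layout = default_genome_layout(),
                        motif = "TACTTAA",
                        motif_spacer_after = "tRNA-Ser(UCN)",
                        start_codons = DEFAULT_START_CODONS,
                        cr_tandem = data.frame(period = c(12L, 20L, 28L),
                                               copies = c(2, 2, 2.5)),
                        cr_hairpin = list(stem = 30L, loop = 15L,
                                          t_stretch = 8L),
                        cr_blocks = NULL) {
  spec <- list(seed = as.integer(seed), at_target = at_target, layout = layout,
               motif = toupper(motif), motif_spacer_after = motif_spacer_after,
               start_codons = start_codons, cr_tandem = cr_tandem,
               cr_hairpin = cr_hairpin, cr_blocks = cr_blocks)
  validate_genome_spec(spec)
  class(spec) <- "genome_spec"
  spec
}

validate_genome_spec <- function(spec) {
  lay <- spec$layout
  stopifnot(all(c("name", "ftype", "strand", "length", "spacer_after")
                %in% names(lay)))
  if (any(lay$length < 1L) || any(lay$spacer_after < 0L))
    stop("spec error: feature lengths must be >= 1 and spacers >= 0")
  if (!is.null(spec$motif)) {
    i <- match(spec$motif_spacer_after, lay$name)
    if (is.na(i)) stop("spec error: motif_spacer_after names no feature")
    if (lay$spacer_after[i] < nchar(spec$motif))
      stop("spec error: motif does not fit in its spacer")
  }
  cds_len <- lay$length[lay$ftype == "CDS"]
  if (any(cds_len < 7L)) stop("spec error: CDS too short")
  cr_rows <- which(lay$ftype == "control_region")
  if (length(cr_rows) != 1L) stop("spec error: exactly one control region required")
  h <- spec$cr_hairpin
  arrays_len <- sum(round(spec$cr_tandem$copies * spec$cr_tandem$period))
  need <- arrays_len + 2L * h$stem + h$loop +
    sum(nchar(spec$cr_blocks %||% character())) + 40L
  if (lay$length[cr_rows] < need)
    stop("spec error: control region too short for planted items (needs >= ",
         need, " bp)")
  invisible(spec)
}

sense_codon_set <- function() {
  codons <- as.vector(outer(outer(DNA_BASES, DNA_BASES, paste0), DNA_BASES,
                            paste0))
  setdiff(codons, c("TAA", "TAG"))
}

sense_codon_weights <- function(probs) {
  vapply(strsplit(sense_codon_set(), ""), function(b) prod(probs[b]),
         numeric(1L))
}

# Excluding the AT-rich stop codons from the sense-codon draw depresses the
# realized A+T fraction of coding sequence below the base-probability target;
# solve for the base AT level whose sense-codon expectation hits the target.
calibrate_cds_at <- function(at_target) {
  at_count <- vapply(strsplit(sense_codon_set(), ""), function(b)
    sum(b %in% c("A", "T")), numeric(1L))
  expected <- function(tp) {
    w <- sense_codon_weights(at_base_probs(tp))
    sum(w * at_count) / sum(w) / 3 - at_target
  }
  stats::uniroot(expected, c(at_target, min(0.999, at_target + 0.1)),
                 tol = 1e-6)$root
}

# Sense (non-stop) codons weighted by AT-biased base composition.
sample_sense_codons <- function(n, probs) {
  if (n <= 0L) return("")
  paste(sample(sense_codon_set(), n, replace = TRUE,
               prob = sense_codon_weights(probs)), collapse = "")
}

# A CDS of exactly `len` bp: start codon + sense body + (possibly incomplete)
# stop implied by len mod 3.
synth_cds <- function(len, start_codon, probs) {
  stop_seq <- switch(as.character(len %% 3L),
                     "0" = sample(c("TAA", "TAG"), 1L, prob = c(0.8, 0.2)),
                     "1" = "T", "2" = "TA")
  body <- len - 3L - nchar(stop_seq)
  paste0(start_codon, sample_sense_codons(body %/% 3L, probs), stop_seq)
}

# Random tandem-repeat unit of the given period whose minimal period is the
# period itself and which carries no internal lag-q self-similarity long
# enough to seed a smaller-period call, so the planted array is irreducible
# and its recovery well-defined.
synth_repeat_unit <- function(period, probs) {
  repeat {
    u <- random_bases(period, probs)
    if (minimal_period(u) != period || length(unique(seq_chars(u))) < 2L) next
    dd <- seq_chars(paste0(u, u))
    n <- length(dd)
    selfish <- FALSE
    # a lag-q self-match run of length >= q anywhere in the tiled array
    # would seed a competing period-q call; the doubled unit captures the
    # circular lag structure of the array
    for (q in 3:max(3L, period - 1L)) {
      if (q >= period) break
      m <- dd[(q + 1L):n] == dd[1L:(n - q)]
      runs <- true_runs(m)
      if (nrow(runs) > 0L && max(runs$length) >= q) { selfish <- TRUE; break }
    }
    if (!selfish) return(u)
  }
}

# Pick a base different from `avoid` (a character vector), preferring the
# AT-biased draw.
base_not <- function(avoid, probs) {
  ok <- setdiff(DNA_BASES, avoid)
  sample(ok, 1L, prob = probs[ok] / sum(probs[ok]))
}

# A base that pairs (incl. G:T) with none of `partners`.
base_not_pairing <- function(partners, probs) {
  ok <- DNA_BASES[vapply(DNA_BASES, function(b)
    !any(bases_pair(b, partners, allow_gu = TRUE)), logical(1L))]
  if (length(ok) == 0L) ok <- "A"
  sample(ok, 1L, prob = probs[ok] / sum(probs[ok]))
}

# Assemble the control region; returns list(seq, truth) with coordinates
# relative to the CR start.
synth_control_region <- function(cr_len, spec, probs) {
  h <- spec$cr_hairpin
  blocks <- spec$cr_blocks %||%
    vapply(1:3, function(i) random_bases(20L, probs), character(1L))
  arrays <- spec$cr_tandem
  pieces <- character()
  truth_arrays <- list(); truth_blocks <- list()
  pos <- 0L
  gap_each <- 4L   # guard filler between planted items

  push <- function(x) { pieces[[length(pieces) + 1L]] <<- x; pos <<- pos + nchar(x) }

  push(random_bases(gap_each, probs))
  truth_blocks[[1L]] <- data.frame(seq = blocks[1L], start = pos + 1L,
                                   end = pos + nchar(blocks[1L]))
  push(blocks[1L])
  push(random_bases(gap_each, probs))

  for (k in seq_len(nrow(arrays))) {
    p <- arrays$period[k]; cp <- arrays$copies[k]
    unit <- synth_repeat_unit(p, probs)
    span <- as.integer(round(cp * p))
    cp <- span / p                        # realized copy number
    arr <- substr(strrep(unit, ceiling(cp)), 1L, span)
    # left guard: last filler base must not continue the periodicity
    guard_l <- base_not(substr(arr, p, p), probs)
    push(paste0(random_bases(gap_each - 1L, probs), guard_l))
    a <- pos + 1L
    push(arr)
    truth_arrays[[k]] <- data.frame(unit = unit, period = p, copies = cp,
                                    start = a, end = pos,
                                    stringsAsFactors = FALSE)
    # right guard: next base must break the periodicity
    guard_r <- base_not(substr(arr, span - p + 1L, span - p + 1L), probs)
    push(paste0(guard_r, random_bases(gap_each - 1L, probs)))
  }

  truth_blocks[[2L]] <- data.frame(seq = blocks[2L], start = pos + 1L,
                                   end = pos + nchar(blocks[2L]))
  push(blocks[2L])

  # hairpin: arm5 + loop (with planted T-stretch) + revcomp(arm5), flanked by
  # non-pairing guard bases so the detected stem is exactly `stem` pairs.
  arm5 <- random_bases(h$stem, probs)
  loop_fill <- h$loop - h$t_stretch - 2L
  if (loop_fill < 0L) stop("spec error: t_stretch too long for loop")
  mid <- if (loop_fill > 0L)
    paste(sample(c("A", "C", "G"), loop_fill, replace = TRUE), collapse = "")
  else ""
  first_loop <- base_not_pairing("A", probs)      # must not pair loop end 'A'
  if (first_loop == "T") first_loop <- "C"
  loop <- paste0(first_loop, strrep("T", h$t_stretch), mid, "A")
  stopifnot(nchar(loop) == h$loop)
  # the rung just outside the stem compares the two flanking guard bases
  guard_l <- sample(DNA_BASES, 1L, prob = probs[DNA_BASES])
  guard_r <- base_not_pairing(guard_l, probs)
  push(paste0(random_bases(gap_each - 1L, probs), guard_l))
  hp_start <- pos + 1L
  push(arm5)
  loop_start <- pos + 1L
  push(loop)
  push(revcomp(arm5))
  hp_end <- pos
  push(paste0(guard_r, random_bases(gap_each - 1L, probs)))

  truth_blocks[[3L]] <- data.frame(seq = blocks[3L], start = pos + 1L,
                                   end = pos + nchar(blocks[3L]))
  push(blocks[3L])

  if (pos > cr_len) stop("spec error: planted control-region items exceed CR length")
  push(random_bases(cr_len - pos, probs))
  list(seq = paste(pieces, collapse = ""),
       truth = list(
         arrays = do.call(rbind, truth_arrays),
         blocks = do.call(rbind, truth_blocks),
         hairpin = list(stem_pairs = h$stem, start = hp_start, end = hp_end,
                        loop_start = loop_start,
                        loop_end = loop_start + h$loop - 1L,
                        loop_length = h$loop, t_stretch = h$t_stretch)))
}

#' Generate a synthetic annotated mitogenome with ground truth
#'
#' Deterministic for a fixed spec seed. Background bases are drawn to hit the
#' target AT fraction in expectation; every planted item (spacer motif,
#' tandem arrays, stem-loop, conserved block seeds, start/stop codons) is
#' present verbatim at the recorded coordinates.
#'
#' @param spec a [genome_spec()].
#' @return list with elements `genome` (an [annotated_genome()]) and `truth`
#'   (the ground-truth ledger: features with start/stop classes, spacers,
#'   motif location, control-region structure, the spec hash and seed).
#' @export
synth_mitogenome <- function(spec = genome_spec()) {
  validate_genome_spec(spec)
  probs <- at_base_probs(spec$at_target)
  cds_probs <- at_base_probs(calibrate_cds_at(spec$at_target))
  with_seed(spec$seed, {
    lay <- spec$layout
    segs <- character(nrow(lay))
    gene_seqs <- character(nrow(lay))
    cr_truth <- NULL
    cr_offset <- NA_integer_
    pos <- 0L
    starts <- ends <- integer(nrow(lay))
    spacer_seqs <- character(nrow(lay))
    for (i in seq_len(nrow(lay))) {
      len <- lay$length[i]
      g <- switch(lay$ftype[i],
        CDS = synth_cds(len, spec$start_codons[[lay$name[i]]] %||% "ATG",
                        cds_probs),
        control_region = {
          cr <- synth_control_region(len, spec, probs)
          cr_truth <- cr$truth
          cr$seq
        },
        random_bases(len, probs))
      gene_seqs[i] <- g
      segs[i] <- if (lay$strand[i] == "N") revcomp(g) else g
      starts[i] <- pos + 1L
      ends[i] <- pos + len
      if (lay$ftype[i] == "control_region") cr_offset <- pos
      pos <- pos + len
      sp <- lay$spacer_after[i]
      spacer <- random_bases(sp, probs)
      if (!is.null(spec$motif) && lay$name[i] == spec$motif_spacer_after) {
        off <- max(0L, (sp - nchar(spec$motif)) %/% 2L)
        substr(spacer, off + 1L, off + nchar(spec$motif)) <- spec$motif
        motif_truth <- list(pattern = spec$motif,
                            start = pos + off + 1L,
                            upstream = lay$name[i])
      }
      spacer_seqs[i] <- spacer
      pos <- pos + sp
    }
    sequence <- paste(rbind(segs, spacer_seqs), collapse = "")
    feats <- data.frame(name = lay$name, ftype = lay$ftype,
                        strand = lay$strand, start = starts, end = ends,
                        wraps_origin = FALSE, anticodon = NA_character_,
                        stringsAsFactors = FALSE)
    genome <- annotated_genome("synthetic_mitogenome", sequence, feats)

    cds <- lay$ftype == "CDS"
    stop_class <- stop_class_from_length(lay$length)
    spacer_truth <- data.frame(upstream = lay$name,
                               downstream = c(lay$name[-1L], lay$name[1L]),
                               length = lay$spacer_after,
                               stringsAsFactors = FALSE)
    truth <- list(
      seed = spec$seed, at_target = spec$at_target,
      spec_hash = spec_hash(unclass(spec)),
      genome_length = nchar(sequence),
      features = cbind(feats[, c("name", "ftype", "strand", "start", "end")],
                       length = lay$length,
                       start_codon = ifelse(cds, substr(gene_seqs, 1L, 3L), NA),
                       stop_class = ifelse(cds, stop_class, NA)),
      spacers = spacer_truth,
      motif = if (is.null(spec$motif)) NULL else motif_truth,
      cr = c(list(start = cr_offset + 1L,
                  end = cr_offset + lay$length[lay$ftype == "control_region"]),
             shift_cr_truth(cr_truth, cr_offset)))
    list(genome = genome, truth = truth)
  })
}

# Translate CR-relative truth coordinates to genome coordinates.
shift_cr_truth <- function(cr_truth, offset) {
  arr <- cr_truth$arrays
  arr$start <- arr$start + offset; arr$end <- arr$end + offset
  blk <- cr_truth$blocks
  blk$start <- blk$start + offset; blk$end <- blk$end + offset
  hp <- cr_truth$hairpin
  for (f in c("start", "end", "loop_start", "loop_end"))
    hp[[f]] <- hp[[f]] + offset
  list(arrays = arr, blocks = blk, hairpin = hp)
}

#' Simulate a sequence pair under the Kimura two-parameter model
#'
#' One sequence is drawn uniformly over ACGT; the other is produced by
#' per-site independent substitution with the K2P transition-probability
#' matrix at total expected divergence `d` (branch-length convention matching
#' the distance estimator) and transition/transversion rate ratio `kappa`.
#'
#' @param n_sites number of sites.
#' @param d expected substitutions per site between the two sequences.
#' @param kappa transition/transversion rate ratio (alpha/beta; default 2).
#' @param seed optional seed (uses the current RNG stream when NULL).
#' @return list with elements `a` and `b` (nucleotide strings).
#' @export
evolve_pair_k2p <- function(n_sites, d, kappa = 2, seed = NULL) {
  run <- function() {
    a <- sample(DNA_BASES, n_sites, replace = TRUE)
    b <- k2p_mutate(a, d, kappa)
    list(a = paste(a, collapse = ""), b = paste(b, collapse = ""))
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# Apply K2P substitution at divergence d to a base vector.
k2p_mutate <- function(bases, d, kappa) {
  if (d == 0) return(bases)
  beta <- 1 / (kappa + 2)
  alpha <- kappa * beta          # alpha + 2 beta = 1; d = total rate * time
  p_ts <- 0.25 + 0.25 * exp(-4 * beta * d) - 0.5 * exp(-2 * (alpha + beta) * d)
  p_tv <- 0.5 - 0.5 * exp(-4 * beta * d)       # both transversions combined
  ts_partner <- c(A = "G", G = "A", C = "T", T = "C")
  tv_partner1 <- c(A = "C", G = "C", C = "A", T = "A")
  tv_partner2 <- c(A = "T", G = "T", C = "G", T = "G")
  u <- runif(length(bases))
  out <- bases
  ts <- u < p_ts
  tv1 <- !ts & u < p_ts + p_tv / 2
  tv2 <- !ts & !tv1 & u < p_ts + p_tv
  out[ts] <- ts_partner[bases[ts]]
  out[tv1] <- tv_partner1[bases[tv1]]
  out[tv2] <- tv_partner2[bases[tv2]]
  out
}

#' Simulate a codon alignment with per-position rate multipliers
#'
#' A star (tree-free pairwise) design: every taxon descends independently
#' from a common uniform-ACGT ancestor, with codon positions 1/2/3 evolving
#' at the stated relative rates. Used to emulate codon-position rate
#' heterogeneity and third-position saturation.
#'
#' @param n_taxa number of taxa.
#' @param n_codons codons per sequence.
#' @param branch_d expected substitutions per site on each tip branch at
#'   rate multiplier 1 (scalar or per-taxon vector).
#' @param rate_multipliers length-3 positive multipliers for codon positions
#'   1, 2, 3.
#' @param kappa transition/transversion rate ratio.
#' @param seed optional seed.
#' @return a [gene_alignment()] of class PCG with frame 0.
#' @export
synth_codon_alignment <- function(n_taxa = 6L, n_codons = 200L,
                                  branch_d = 0.1, rate_multipliers = c(1, 1, 1),
                                  kappa = 2, seed = NULL) {
  stopifnot(length(rate_multipliers) == 3L, all(rate_multipliers >= 0))
  run <- function() {
    L <- 3L * n_codons
    anc <- sample(DNA_BASES, L, replace = TRUE)
    pos <- rep(1:3, n_codons)
    bd <- rep_len(branch_d, n_taxa)
    seqs <- vapply(seq_len(n_taxa), function(i) {
      tip <- anc
      for (p in 1:3) {
        dp <- bd[i] * rate_multipliers[p]
        if (dp > 0)
          tip[pos == p] <- k2p_mutate(anc[pos == p], dp, kappa)
      }
      paste(tip, collapse = "")
    }, character(1L))
    gene_alignment("synthetic_pcg", "PCG",
                   setNames(seqs, paste0("t", seq_len(n_taxa))), frame = 0L)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Write a genome's sequence as FASTA
#' @param genome an `annotated_genome`.
#' @param path output path.
#' @export
write_genome_fasta <- function(genome, path) {
  writeLines(c(paste0(">", genome$id), genome$sequence), path)
  invisible(path)
}
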