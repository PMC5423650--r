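# Pipeline orchestration: each analysis stage as a subcommand with
# deterministic outputs and a machine-readable run manifest.

PIPELINE_SUBCOMMANDS <- c("annotate-report", "spacers", "codon-usage",
                          "control-region", "distances", "datasets",
                          "simulate")

#' Run an analysis stage
#'
#' Dispatches one of the pipeline subcommands on a configuration list and
#' writes its artifacts plus a `manifest.json` (inputs with checksums,
#' parameters, package version, outputs with checksums) into the output
#' directory. Outputs are deterministic for fixed inputs and seed; only the
#' manifest carries a timestamp.
#'
#' @param subcommand one of `annotate-report`, `spacers`, `codon-usage`,
#'   `control-region`, `distances`, `datasets`, `simulate`.
#' @param config named list of inputs and parameters; common fields:
#'   `features` (feature-table TSV), `fasta`, `out_dir`, `seed`. See the
#'   per-subcommand details below.
#' @details
#' * `annotate-report`: `features` (+ optional `fasta`) -> feature lengths
#'   TSV and a genome summary JSON (length, feature-class counts, composition
#'   when a real sequence is supplied).
#' * `spacers`: `features` -> spacer/overlap TSV.
#' * `codon-usage`: `features` + `fasta` -> codon usage/RSCU TSV.
#' * `control-region`: `fasta` (single region; or aligned multi-FASTA with
#'   `aligned = TRUE`) -> tandem repeats TSV, hairpin JSON, motif hits TSV
#'   (`pattern`, default `WACTTAA`), or conserved blocks TSV when aligned.
#' * `distances`: `fasta` (aligned) + `taxa` (label/species/genus TSV) ->
#'   triangular distance TSV, gap-summary JSON, NJ Newick.
#' * `datasets`: `genes` (TSV `file`, `gene`, `class`, `frame`) + `mode` ->
#'   PHYLIP/NEXUS/FASTA supermatrix + partition TSV.
#' * `simulate`: `seed` (+ optional `spec` JSON overriding generator
#'   defaults) -> genome FASTA, feature-table TSV, truth JSON.
#' @return invisibly, a list of output paths (plus the manifest path).
#' @export
mito_run <- function(subcommand = PIPELINE_SUBCOMMANDS, config = list()) {
  subcommand <- match.arg(subcommand)
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- switch(subcommand,
    "annotate-report" = run_annotate_report(config, out_dir),
    "spacers" = run_spacers(config, out_dir),
    "codon-usage" = run_codon_usage(config, out_dir),
    "control-region" = run_control_region(config, out_dir),
    "distances" = run_distances(config, out_dir),
    "datasets" = run_datasets(config, out_dir),
    "simulate" = run_simulate(config, out_dir))
  manifest <- file.path(out_dir, "manifest.json")
  inputs <- Filter(function(p) is.character(p) && length(p) == 1L && file.exists(p),
                   config[c("features", "fasta", "taxa", "genes", "spec")])
  jsonlite::write_json(list(
    subcommand = subcommand,
    parameters = config[setdiff(names(config), names(inputs))],
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    outputs = lapply(outputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    package_version = as.character(utils::packageVersion("mitocompare")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC")),
    manifest, auto_unbox = TRUE, pretty = TRUE, null = "null", digits = NA)
  invisible(c(outputs, manifest = manifest))
}

load_config_genome <- function(config) {
  if (is.null(config$features)) stop("config$features (feature table) required")
  read_genome(config$features, fasta = config$fasta,
              genome_length = config$genome_length,
              id = config$id, topology = config$topology %||% "circular")
}

run_annotate_report <- function(config, out_dir) {
  genome <- load_config_genome(config)
  lengths_path <- file.path(out_dir, "feature_lengths.tsv")
  tab <- feature_length_table(genome)
  write.table(tab, lengths_path, sep = "\t", quote = FALSE, row.names = FALSE)
  trna <- feature_length_table(genome, "tRNA")
  summary <- list(
    id = genome$id, genome_length = genome_length(genome),
    feature_counts = as.list(table(genome$features$ftype)),
    trna_length_min = attr(trna, "min"), trna_length_max = attr(trna, "max"),
    control_region_length =
      if (any(genome$features$ftype == "control_region"))
        feature_length(genome$features[genome$features$ftype == "control_region", ][1L, ],
                       genome_length(genome)) else NULL)
  if (!is.null(config$fasta)) {
    comp <- base_composition(genome$sequence)
    summary$at_fraction <- comp$at_fraction
    summary$at_skew <- comp$at_skew
    summary$gc_skew <- comp$gc_skew
  }
  summary_path <- file.path(out_dir, "genome_summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  list(feature_lengths = lengths_path, genome_summary = summary_path)
}

run_spacers <- function(config, out_dir) {
  genome <- load_config_genome(config)
  path <- file.path(out_dir, "spacers.tsv")
  write_spacer_report(compute_spacers_overlaps(genome), path)
  list(spacers = path)
}

run_codon_usage <- function(config, out_dir) {
  if (is.null(config$fasta)) stop("codon-usage requires config$fasta")
  genome <- load_config_genome(config)
  cds_idx <- which(genome$features$ftype == "CDS")
  cds <- vapply(cds_idx, function(i) extract_feature_sequence(genome, i),
                character(1L))
  usage <- codon_usage_rscu(cds, include_stops = !isFALSE(config$include_stops))
  path <- file.path(out_dir, "codon_usage.tsv")
  write_codon_usage(usage, path)
  list(codon_usage = path)
}

read_fasta_plain <- function(path) {
  lines <- readLines(path)
  heads <- grep("^>", lines)
  if (length(heads) == 0L) stop("no FASTA records in ", path)
  ends <- c(heads[-1L] - 1L, length(lines))
  setNames(
    vapply(seq_along(heads), function(i)
      toupper(paste(lines[(heads[i] + 1L):ends[i]], collapse = "")),
      character(1L)),
    sub("^>\\s*(\\S+).*", "\\1", lines[heads]))
}

run_control_region <- function(config, out_dir) {
  if (is.null(config$fasta)) stop("control-region requires config$fasta")
  seqs <- read_fasta_plain(config$fasta)
  outputs <- list()
  if (isTRUE(config$aligned)) {
    blocks <- find_conserved_blocks(
      seqs, min_width = config$min_width %||% 10L,
      column_threshold = config$column_threshold %||% 1.0,
      max_interruptions = config$max_interruptions %||% 1L)
    path <- file.path(out_dir, "conserved_blocks.tsv")
    write.table(blocks, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(list(conserved_blocks = path))
  }
  seq <- seqs[[1L]]
  reps <- find_tandem_repeats(
    seq, min_period = config$min_period %||% 3L,
    max_period = config$max_period %||% 200L,
    min_copies = config$min_copies %||% 2.0,
    min_identity = config$min_identity %||% 0.85)
  rep_path <- file.path(out_dir, "tandem_repeats.tsv")
  write.table(reps, rep_path, sep = "\t", quote = FALSE, row.names = FALSE)
  outputs$tandem_repeats <- rep_path

  hp <- predict_best_hairpin(
    seq, min_stem = config$min_stem %||% 5L,
    loop_min = config$loop_min %||% 3L, loop_max = config$loop_max %||% 20L,
    allow_gu = !isFALSE(config$allow_gu),
    max_stem_mismatch = config$max_stem_mismatch %||% 0L)
  hp_path <- file.path(out_dir, "hairpin.json")
  jsonlite::write_json(
    if (is.null(hp)) list(found = FALSE)
    else c(list(found = TRUE), unclass(hp)[setdiff(names(hp), "pairs")]),
    hp_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  outputs$hairpin <- hp_path

  hits <- scan_iupac_motif(seq, config$pattern %||% "WACTTAA",
                           both_strands = isTRUE(config$both_strands))
  motif_path <- file.path(out_dir, "motif_hits.tsv")
  write.table(hits, motif_path, sep = "\t", quote = FALSE, row.names = FALSE)
  outputs$motif_hits <- motif_path

  pt <- poly_t_stretch(seq)
  outputs$poly_t <- file.path(out_dir, "poly_t.json")
  jsonlite::write_json(pt, outputs$poly_t, auto_unbox = TRUE, digits = NA)
  outputs
}

run_distances <- function(config, out_dir) {
  if (is.null(config$fasta)) stop("distances requires config$fasta (aligned)")
  seqs <- read_fasta_plain(config$fasta)
  dm <- build_distance_matrix(seqs)
  outputs <- list(distance_matrix = file.path(out_dir, "distance_matrix.tsv"))
  write_distance_table(dm, outputs$distance_matrix)
  if (!is.null(config$taxa)) {
    taxa <- read.delim(config$taxa, stringsAsFactors = FALSE)
    gap <- barcoding_gap_summary(dm, taxa,
                                 focal_genus = config$focal_genus,
                                 outside_taxon = config$outside_taxon)
    outputs$gap_summary <- file.path(out_dir, "gap_summary.json")
    jsonlite::write_json(unclass(gap)[setdiff(names(gap), "category_counts")],
                         outputs$gap_summary, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  }
  if (length(seqs) >= 3L && !anyNA(dm$d)) {
    outputs$nj_tree <- file.path(out_dir, "nj_tree.nwk")
    writeLines(nj_newick(dm), outputs$nj_tree)
  }
  outputs
}

run_datasets <- function(config, out_dir) {
  if (is.null(config$genes)) stop("datasets requires config$genes (gene manifest TSV)")
  man <- read.delim(config$genes, stringsAsFactors = FALSE)
  base <- dirname(config$genes)
  alns <- lapply(seq_len(nrow(man)), function(i) {
    f <- man$file[i]
    if (!file.exists(f)) f <- file.path(base, man$file[i])
    gene_alignment(man$gene[i], man$class[i], read_fasta_plain(f),
                   frame = if ("frame" %in% names(man)) man$frame[i] else 0L)
  })
  mode <- config$mode %||% "ALL-123"
  sm <- build_supermatrix(alns, mode)
  tag <- tolower(gsub("-", "", mode))
  outputs <- list(
    phylip = file.path(out_dir, paste0("supermatrix_", tag, ".phy")),
    nexus = file.path(out_dir, paste0("supermatrix_", tag, ".nex")),
    fasta = file.path(out_dir, paste0("supermatrix_", tag, ".fasta")),
    partitions = file.path(out_dir, paste0("partitions_", tag, ".tsv")))
  write_phylip(sm, outputs$phylip)
  write_nexus(sm, outputs$nexus)
  write_supermatrix_fasta(sm, outputs$fasta)
  write_partition_table(sm, outputs$partitions)
  outputs
}

run_simulate <- function(config, out_dir) {
  overrides <- if (!is.null(config$spec) && file.exists(config$spec %||% ""))
    jsonlite::read_json(config$spec, simplifyVector = TRUE) else list()
  args <- list(seed = config$seed %||% 1L)
  for (f in c("at_target", "motif", "motif_spacer_after"))
    if (!is.null(overrides[[f]])) args[[f]] <- overrides[[f]]
  if (!is.null(overrides$cr_hairpin)) args$cr_hairpin <- as.list(overrides$cr_hairpin)
  if (!is.null(overrides$cr_tandem)) args$cr_tandem <- as.data.frame(overrides$cr_tandem)
  spec <- do.call(genome_spec, args)
  sim <- synth_mitogenome(spec)
  outputs <- list(fasta = file.path(out_dir, "genome.fasta"),
                  features = file.path(out_dir, "features.tsv"),
                  truth = file.path(out_dir, "truth.json"))
  write_genome_fasta(sim$genome, outputs$fasta)
  write_feature_table(sim$genome, outputs$features)
  jsonlite::write_json(sim$truth, outputs$truth, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  outputs
}
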