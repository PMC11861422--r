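# End-to-end orchestration: simulate a community, build the masked
# reference, map, compute coverage, calibrate (or use the reference
# model), call detections, compute demarcation indices, and build a
# marker-gene NJ tree. All randomness flows from explicit seeds in the
# config; outputs are bit-reproducible.

#' Demo pipeline configuration
#'
#' A small synthetic study: one ancestral genome and three relatives at
#' increasing divergence, a shared rRNA-like repeat planted in all four,
#' and a metagenome containing two of the species plus reads from an
#' off-reference relative. Sized to run in well under two minutes.
#'
#' @param out_dir Output directory for the run artifacts.
#' @param seed Master seed.
#' @return A config list accepted by [run_pipeline()].
#' @export
demo_config <- function(out_dir = tempfile("aquadetect_demo_"), seed = 1L) {
  list(
    out_dir = out_dir,
    seed = seed,
    genomes = list(
      list(id = "sp1", length = 120000, gc = 0.42),
      list(id = "sp2", parent = "sp1", rate = 0.08),
      list(id = "sp3", parent = "sp1", rate = 0.15),
      list(id = "sp4", parent = "sp2", rate = 0.12)
    ),
    repeat_length = 1500, repeat_copies = 1,
    community = list(
      members = c(sp1 = 0.6, sp3 = 0.4),
      n_reads = 4000, read_length = 150, error_rate = 0.005
    ),
    min_identity_pct = 95,
    calibrate = FALSE,
    breadth_cutoff_pct = 50, floor_pct = 10,
    fractions = c(0.05, 0.1, 0.2, 0.4, 0.7, 1),
    tree = list(marker_length = 1200, bootstrap = 100)
  )
}

.require_field <- function(config, field) {
  if (is.null(config[[field]]))
    .stopf("config error: required field '%s' is missing", field)
  config[[field]]
}

#' Run the full synthetic detection pipeline
#'
#' Executes simulate -> build reference -> map -> coverage -> (calibrate)
#' -> detect -> demarcate -> tree from a single config, writing a
#' detection TSV, ANI/dDDH matrices, a Newick tree, the threshold-model
#' JSON, the simulated genomes/reads (FASTA/FASTQ/BED) and a
#' machine-readable run log into `config$out_dir`.
#'
#' @param config Config list (see [demo_config()]) or path to a YAML file
#'   with the same structure.
#' @return Invisibly, a list with the in-memory results and the paths of
#'   all written artifacts.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) .stopf("config error: file '%s' not found", config)
    config <- yaml::read_yaml(config)
  }
  out_dir <- .require_field(config, "out_dir")
  seed <- as.integer(.require_field(config, "seed"))
  genome_spec <- .require_field(config, "genomes")
  comm <- .require_field(config, "community")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # -- genomes ----------------------------------------------------------
  genomes <- list()
  for (i in seq_along(genome_spec)) {
    gs <- genome_spec[[i]]
    id <- .require_field(gs, "id")
    if (!is.null(gs$parent)) {
      if (is.null(genomes[[gs$parent]]))
        .stopf("config error: parent '%s' of '%s' not defined before use",
               gs$parent, id)
      genomes[[id]] <- derive_relative(genomes[[gs$parent]], gs$rate,
                                       genome_id = id, seed = seed + i)
    } else {
      genomes[[id]] <- generate_genome(gs$length, gs$gc, genome_id = id,
                                       seed = seed + i)
    }
  }
  if (!is.null(config$repeat_length) && (config$repeat_copies %||% 0) > 0)
    genomes <- plant_shared_repeat(genomes, config$repeat_length,
                                   config$repeat_copies, seed = seed + 100L)

  # -- metagenome -------------------------------------------------------
  members <- unlist(comm$members)
  design <- community_design(members, n_reads = comm$n_reads,
                             read_length = comm$read_length %||% 150L,
                             substitution_error_rate = comm$error_rate %||% 0,
                             seed = seed + 200L)
  reads <- simulate_metagenome(design, genomes)

  # -- reference, mapping, coverage -------------------------------------
  ref <- build_reference(genomes)
  aln <- map_reads(reads, ref,
                   min_identity_pct = config$min_identity_pct %||% 95)
  profiles <- compute_coverage(aln, ref, total_reads = nrow(reads))

  # -- threshold model --------------------------------------------------
  model <- if (isTRUE(config$calibrate)) {
    series <- subsample_series(aln, ref,
                               fractions = config$fractions %||%
                                 c(0.01, 0.02, 0.05, 0.1, 0.2, 0.4, 0.7, 1),
                               total_reads = nrow(reads), seed = seed + 300L)
    fits <- lapply(series, function(s)
      tryCatch(fit_saturation(s), error = function(e) NULL))
    fits <- fits[!vapply(fits, is.null, logical(1))]
    if (length(fits)) select_min_asymptote(fits) else default_threshold_model()
  } else default_threshold_model()

  report <- detection_report(profiles, model, metagenome_id = "metagenome1",
                             breadth_cutoff_pct = config$breadth_cutoff_pct %||% 50,
                             floor_pct = config$floor_pct %||% 10)

  # -- demarcation indices ----------------------------------------------
  ids <- names(genomes)
  pairs <- t(utils::combn(ids, 2))
  demarcation <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    ga <- genomes[[pairs[i, 1]]]
    gb <- genomes[[pairs[i, 2]]]
    ani <- fragment_ani(ga, gb)
    ddh <- gbdp_d4(ga, gb)
    dec <- species_demarcation(ani, ddh)
    data.frame(genome_a = pairs[i, 1], genome_b = pairs[i, 2],
               ani_pct = ani$ani_pct, aligned_fraction = ani$aligned_fraction,
               d4_distance = ddh$d4_distance, ddh_pct = ddh$ddh_pct,
               same_species = dec$same_species, stringsAsFactors = FALSE)
  }))

  # -- marker tree ------------------------------------------------------
  tree <- NULL
  if (length(genomes) >= 3L) {
    mlen <- config$tree$marker_length %||% 1200L
    # relatives share contig structure, so leading columns are positional
    # homologs; use them as a marker alignment
    rows <- vapply(genomes, function(g) substr(g$contigs[1], 1L, mlen),
                   character(1))
    tree <- tryCatch({
      bt <- bootstrap_support(multiple_alignment(rows),
                              n_replicates = config$tree$bootstrap %||% 100L,
                              seed = seed + 400L)
      midpoint_root(bt)
    }, error = function(e) {
      warning(sprintf("marker tree skipped: %s", conditionMessage(e)),
              call. = FALSE)
      NULL
    })
  }

  # -- artifacts --------------------------------------------------------
  paths <- list(
    detection = file.path(out_dir, "detection.tsv"),
    demarcation = file.path(out_dir, "demarcation.tsv"),
    model = file.path(out_dir, "threshold_model.json"),
    reads = file.path(out_dir, "reads.fastq"),
    log = file.path(out_dir, "run_log.json"))
  write_report_tsv(report, paths$detection)
  write_report_tsv(demarcation, paths$demarcation)
  write_model_json(model, paths$model)
  write_fastq(reads, paths$reads)
  for (id in ids) {
    write_fasta(genomes[[id]], file.path(out_dir, paste0(id, ".fasta")))
    if (nrow(genomes[[id]]$masked_intervals))
      write_bed(genomes[[id]], file.path(out_dir, paste0(id, ".mask.bed")))
  }
  if (!is.null(tree)) {
    paths$tree <- file.path(out_dir, "marker_nj.nwk")
    write_newick(tree, paths$tree)
  }
  jsonlite::write_json(
    list(package = "aquadetect", version = REPORT_SCHEMA_VERSION,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         seed = seed, n_reads = nrow(reads), n_mapped = nrow(aln),
         model = list(a = model$a, b = model$b, c = model$c,
                      source = model$source),
         detected = report$genome_id[report$detected],
         outputs = unname(unlist(paths[names(paths) != "log"]))),
    paths$log, auto_unbox = TRUE, digits = NA, na = "null")

  invisible(list(genomes = genomes, reads = reads, ref = ref,
                 alignments = aln, profiles = profiles, model = model,
                 report = report, demarcation = demarcation, tree = tree,
                 paths = paths))
}
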