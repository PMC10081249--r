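#' Pipeline configuration
#'
#' Collects the input paths and analysis thresholds of the canonical
#' workflow. All thresholds default to the study's values: minimum/maximum
#' implied intron length 25 and 1,000,000 bp, minimum RIN 6, distance-profile
#' window 30 bp, modulo-3 maximum distance 100 bp (exclusive),
#' log10-coverage matching caliper 0.005, RIN matching caliper 0.05.
#'
#' @param annotation,genome,junctions,blacklist,metadata,minor_introns,
#'   conservation_track,constraint_track,model_dir Input paths (`junctions`
#'   is a named character vector or list, one file per sample, names =
#'   sample ids). All optional when `sim` is given.
#' @param sim A [sim_config()]; when supplied the pipeline generates its
#'   inputs instead of reading them.
#' @param junction_dialect Dialect for [read_junctions()].
#' @param min_intron,max_intron,min_rin,profile_window,mod3_max_dist,
#'   coverage_match,rin_match Thresholds (see above).
#' @param adjust_models,adjust_comparisons Multiplicity adjustment for the
#'   covariate models and the group comparisons.
#' @param allowed_chroms Chromosomes retained by QC (`NULL` = all).
#' @param seed Seed for any randomness not governed by `sim`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(annotation = NULL, genome = NULL,
                            junctions = NULL, blacklist = NULL,
                            metadata = NULL, minor_introns = NULL,
                            conservation_track = NULL,
                            constraint_track = NULL, model_dir = NULL,
                            sim = NULL,
                            junction_dialect = "regtools_bed12",
                            min_intron = 25L, max_intron = 1000000L,
                            min_rin = 6, profile_window = 30L,
                            mod3_max_dist = 100L, coverage_match = 0.005,
                            rin_match = 0.05,
                            adjust_models = "BH",
                            adjust_comparisons = "bonferroni",
                            allowed_chroms = NULL, seed = 1L) {
  cfg <- as.list(environment())
  if (is.null(cfg$sim)) {
    for (req in c("annotation", "genome", "junctions", "metadata")) {
      if (is.null(cfg[[req]])) {
        rlang::abort(paste0("pipeline_config: ", req,
                            " is required when no simulation is configured"))
      }
      paths <- unlist(cfg[[req]])
      missing <- paths[!file.exists(paths)]
      if (length(missing) > 0) {
        rlang::abort(paste0("input path does not exist: ",
                            paste(missing, collapse = ", ")))
      }
    }
  }
  structure(cfg, class = "pipeline_config")
}

# deterministic per-base score tracks over the splice-site windows of an
# annotation; stands in for conservation/constraint tracks on simulated runs
simulate_tracks <- function(annotation, seed, flank = 45L) {
  set.seed(seed)
  it <- annotation$introns
  win <- tibble::tibble(
    chrom = rep(it$chrom, 2),
    start = c(it$donor_pos - flank, it$acceptor_pos - flank),
    end = c(it$donor_pos + flank, it$acceptor_pos + flank)
  )
  win$start <- pmax(win$start, 1L)
  per_base <- win |>
    dplyr::reframe(chrom = rep(.data$chrom, .data$end - .data$start + 1L),
                   pos = unlist(purrr::map2(.data$start, .data$end, seq))) |>
    dplyr::distinct(.data$chrom, .data$pos)
  tibble::tibble(chrom = per_base$chrom, start = per_base$pos,
                 end = per_base$pos,
                 score = round(stats::runif(nrow(per_base)), 4))
}

#' Run the canonical splicing-fidelity workflow
#'
#' Executes, in order: input simulation or loading, junction QC,
#' classification and unique assignment, mis-splicing ratios and category
#' percentages, splice-site delta scores, novel-site geometry (distance
#' profile and modulo-3 summary), covariate assembly and linear models, and
#' (when the metadata defines two age groups with enough samples) a matched
#' two-group comparison. Every stage writes a TSV into `out_dir`, plus a
#' `manifest.json` recording the seed, thresholds and output checksums, so
#' reruns with the same configuration are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created).
#' @return Invisibly, a list with every stage's result and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(config$sim)) {
    sim <- simulate_dataset(config$sim)
    annotation <- sim$annotation
    genome <- sim$genome
    junctions <- sim$junctions
    metadata <- sim$metadata
    model <- toy_splice_model()
    cons_track <- simulate_tracks(annotation, config$sim$seed + 3L)
    cdts_track <- simulate_tracks(annotation, config$sim$seed + 4L)
    truth <- sim$truth
  } else {
    annotation <- read_gtf_annotation(config$annotation)
    genome <- as_genome(config$genome)
    metadata <- read_sample_metadata(config$metadata)
    jpaths <- unlist(config$junctions)
    ids <- if (!is.null(names(jpaths))) names(jpaths) else basename(jpaths)
    junctions <- purrr::map2_dfr(jpaths, ids, function(p, id)
      read_junctions(p, config$junction_dialect, sample_id = id))
    model <- if (!is.null(config$model_dir)) read_mes_model(config$model_dir)
    else toy_splice_model()
    cons_track <- if (!is.null(config$conservation_track))
      read_bedgraph(config$conservation_track) else NULL
    cdts_track <- if (!is.null(config$constraint_track))
      read_bedgraph(config$constraint_track) else NULL
    truth <- NULL
    if (!is.null(config$minor_introns)) {
      annotation <- flag_minor_introns(annotation,
                                       read_minor_intron_list(config$minor_introns))
    }
  }

  blacklist <- if (!is.null(config$blacklist)) read_blacklist(config$blacklist)
  else NULL
  qc <- qc_filter(junctions, samples = metadata, blacklist = blacklist,
                  min_intron = config$min_intron,
                  max_intron = config$max_intron,
                  allowed_chroms = config$allowed_chroms,
                  min_rin = config$min_rin)
  readr::write_tsv(qc$report, file.path(out_dir, "qc_report.tsv"))

  classified <- classify_and_assign(qc$junctions, annotation)
  readr::write_tsv(classified, file.path(out_dir, "classified_junctions.tsv"))

  msr <- compute_msr(classified, qc$junctions)
  readr::write_tsv(msr, file.path(out_dir, "msr.tsv"))
  pct <- category_percentages(classified, qc$junctions)
  readr::write_tsv(pct, file.path(out_dir, "category_percentages.tsv"))

  deltas <- delta_mes(classified, annotation, genome, model)
  readr::write_tsv(deltas, file.path(out_dir, "delta_mes.tsv"))

  dists <- junction_distances(classified, annotation)
  readr::write_tsv(dists, file.path(out_dir, "distances.tsv"))
  profile <- distance_profile(dists, window = config$profile_window)
  readr::write_tsv(profile, file.path(out_dir, "distance_profile.tsv"))
  mod3 <- modulo3_analysis(dists, max_dist = config$mod3_max_dist)
  readr::write_tsv(mod3, file.path(out_dir, "modulo3.tsv"))

  models <- NULL
  if (!is.null(cons_track) && !is.null(cdts_track)) {
    counts_gene <- gene_read_counts(classified, qc$junctions, annotation)
    gl <- gene_lengths(annotation, method = "merged_exons")
    gene_tpm <- tpm(counts_gene, gl)
    covs <- build_covariates(annotation, msr, gene_tpm, genome, model,
                             cons_track, cdts_track)
    readr::write_tsv(covs, file.path(out_dir, "covariates.tsv"))
    if (nrow(covs) > 2 * ncol(covs)) {
      models <- fit_msr_models(covs, adjust = config$adjust_models)
      readr::write_tsv(models$coefficients,
                       file.path(out_dir, "model_coefficients.tsv"))
    }
  }

  comparison <- NULL
  if (!is.null(metadata$age)) {
    young <- metadata$sample_id[metadata$age <= 39 & metadata$age >= 20]
    old <- metadata$sample_id[metadata$age >= 60 & metadata$age <= 79]
    if (length(young) >= 3 && length(old) >= 3) {
      msr_y <- compute_msr(classified, qc$junctions, sample_subset = young)
      msr_o <- compute_msr(classified, qc$junctions, sample_subset = old)
      comparison <- compare_msr_groups(msr_o, msr_y,
                                       alternative = "greater",
                                       adjust = config$adjust_comparisons)
      readr::write_tsv(comparison, file.path(out_dir, "age_comparison.tsv"))
    }
  }

  outputs <- list.files(out_dir, pattern = "\\.tsv$", full.names = TRUE)
  manifest <- list(
    seed = if (!is.null(config$sim)) config$sim$seed else config$seed,
    thresholds = config[c("min_intron", "max_intron", "min_rin",
                          "profile_window", "mod3_max_dist",
                          "coverage_match", "rin_match")],
    annotation_version = annotation$version_label,
    n_samples = nrow(metadata),
    outputs = as.list(stats::setNames(unname(tools::md5sum(outputs)),
                                      basename(outputs)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(annotation = annotation, qc = qc, classified = classified,
                 msr = msr, percentages = pct, deltas = deltas,
                 distances = dists, profile = profile, mod3 = mod3,
                 models = models, comparison = comparison, truth = truth,
                 manifest = manifest))
}

#' Gene-level read counts from classified junctions
#'
#' Sums annotated-junction reads per gene and sample; a simple expression
#' proxy used for the TPM covariate when no gene count matrix is supplied.
#'
#' @param classified Classified junction tibble.
#' @param counts Long junction count tibble.
#' @param annotation A `genome_annotation`.
#' @return Tibble `gene_id` plus one count column per sample.
#' @export
gene_read_counts <- function(classified, counts, annotation) {
  introns <- annotation$introns[, c("intron_id", "gene_id")]
  classified |>
    dplyr::filter(.data$category == "annotated") |>
    dplyr::inner_join(tibble::as_tibble(counts),
                      by = c("chrom", "start", "end",
                             orig_strand = "strand")) |>
    dplyr::inner_join(introns, by = c(assigned_intron_id = "intron_id")) |>
    dplyr::group_by(.data$gene_id, .data$sample_id) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "count",
                       values_fill = 0L)
}
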