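#' Pipeline configuration
#'
#' Everything a reproducible end-to-end run needs: input manifest, output
#' directory, normalization reference, segmentation parameters, QC
#' thresholds, statistics options and the RNG seed. The configuration is
#' fully serializable; [run_pipeline()] writes a JSON snapshot beside its
#' outputs and records the snapshot's MD5 hash in every result bundle.
#'
#' @param manifest path to the sample manifest CSV.
#' @param outdir output directory.
#' @param normalization a [normalization_reference()].
#' @param segmentation a [segmentation_params()].
#' @param qc_coloc_radius_um bleed-through colocalization radius
#'   (default 5).
#' @param qc_coloc_threshold flag a sample when more than this fraction of
#'   GFP objects colocalize with RFP objects (default 0.5).
#' @param hedges_correction `"exact"` or `"approx"`.
#' @param max_rotation_deg registration rotation search half-range.
#' @param rng_seed integer seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(manifest, outdir,
                            normalization = normalization_reference(),
                            segmentation = segmentation_params(),
                            qc_coloc_radius_um = 5,
                            qc_coloc_threshold = 0.5,
                            hedges_correction = "exact",
                            max_rotation_deg = 6,
                            rng_seed = 1L) {
  structure(list(manifest = manifest, outdir = outdir,
                 normalization = normalization, segmentation = segmentation,
                 qc_coloc_radius_um = qc_coloc_radius_um,
                 qc_coloc_threshold = qc_coloc_threshold,
                 hedges_correction = hedges_correction,
                 max_rotation_deg = max_rotation_deg,
                 rng_seed = as.integer(rng_seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with any subset of the [pipeline_config()] fields;
#'   `manifest` and `outdir` are required.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$manifest) || is.null(y$outdir))
    stop("pipeline config must set manifest and outdir")
  cfg <- pipeline_config(y$manifest, y$outdir)
  if (!is.null(y$normalization))
    cfg$normalization <- do.call(normalization_reference, y$normalization)
  if (!is.null(y$segmentation))
    cfg$segmentation <- do.call(segmentation_params, y$segmentation)
  for (f in c("qc_coloc_radius_um", "qc_coloc_threshold",
              "hedges_correction", "max_rotation_deg", "rng_seed"))
    if (!is.null(y[[f]])) cfg[[f]] <- y[[f]]
  cfg
}

config_snapshot <- function(config, path) {
  snap <- list(
    manifest = config$manifest,
    normalization = unclass(config$normalization),
    segmentation = unclass(config$segmentation),
    qc_coloc_radius_um = config$qc_coloc_radius_um,
    qc_coloc_threshold = config$qc_coloc_threshold,
    hedges_correction = config$hedges_correction,
    max_rotation_deg = config$max_rotation_deg,
    rng_seed = config$rng_seed)
  jsonlite::write_json(snap, path, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(path))
}

# process one sample: normalize, register, segment, measure. Returns
# biomarker rows, per-unit effects, registration and QC info.
process_sample <- function(record, config) {
  acq <- record$acquisitions
  per_tp <- list()
  for (tp in .timepoints) {
    stacks <- list()
    for (ch in .channels) {
      row <- acq[acq$timepoint == tp & acq$channel == ch, ]
      if (nrow(row) != 1)
        stop("sample ", record$sample_id, " lacks its ", tp,
             " acquisition for channel ", ch)
      meta_f <- acquisition_metadata(
        channel = ch, modality = "fluorescence",
        laser_power = row$laser_power, detector_gain = row$detector_gain,
        lateral_pixel_um = row$lateral_pixel_um,
        z_spacing_um = row$z_spacing_um,
        batch_id = row$batch_id, timepoint = tp)
      meta_r <- meta_f; meta_r$modality <- "reflectance"
      stacks[[ch]] <- bimodal_acquisition(
        read_stack(row$reflectance_path, meta_r),
        read_stack(row$fluorescence_path, meta_f))
    }
    # normalize fluorescence to the reference settings
    gfp <- normalize_stack(stacks$GFP_488$fluorescence, config$normalization)
    rfp <- normalize_stack(stacks$RFP_532$fluorescence, config$normalization)
    # register the RFP channel onto the GFP frame via z-sum reflectance
    t_hat <- estimate_rigid_transform(
      zsum_projection(stacks$GFP_488$reflectance),
      zsum_projection(stacks$RFP_532$reflectance),
      max_rotation_deg = config$max_rotation_deg)
    rfp <- apply_transform(rfp, invert_transform(t_hat))
    seg_gfp <- segment(gfp, config$segmentation)
    seg_rfp <- segment(rfp, config$segmentation)
    qc <- qc_bleedthrough(
      seg_gfp, seg_rfp,
      voxel_size_um = c(gfp$metadata$z_spacing_um,
                        gfp$metadata$lateral_pixel_um,
                        gfp$metadata$lateral_pixel_um),
      cell_radius_um = config$qc_coloc_radius_um,
      threshold = config$qc_coloc_threshold)
    mg <- measure(seg_gfp, "GFP_488", tp, record$sample_id)
    mr <- measure(seg_rfp, "RFP_532", tp, record$sample_id,
                  rois = record$tumor_rois)
    per_tp[[tp]] <- list(biomarkers = rbind(mg, mr), qc = qc,
                         transform = t_hat)
  }
  biomarkers <- rbind(per_tp$pre$biomarkers, per_tp$post$biomarkers)
  flagged <- per_tp$pre$qc$flagged || per_tp$post$qc$flagged

  effects <- list()
  skipped <- list()
  pre_tab <- per_tp$pre$biomarkers
  post_tab <- per_tp$post$biomarkers
  for (i in seq_len(nrow(pre_tab))) {
    if (pre_tab$roi_id[i] == "unassigned") next
    j <- which(post_tab$channel == pre_tab$channel[i] &
                 post_tab$roi_id == pre_tab$roi_id[i])
    if (length(j) != 1) next
    for (metric in c("n_objects", "total_fluorescence")) {
      eff <- tryCatch(
        treatment_effect(pre_tab[i, ], post_tab[j, ], metric),
        error = function(e) {
          skipped[[length(skipped) + 1]] <<- data.frame(
            sample_id = record$sample_id, roi_id = pre_tab$roi_id[i],
            metric = metric, reason = conditionMessage(e))
          NULL
        })
      if (!is.null(eff)) effects[[length(effects) + 1]] <- eff
    }
  }
  list(sample_id = record$sample_id, group = record$group,
       biomarkers = biomarkers,
       effects = if (length(effects)) do.call(rbind, effects) else NULL,
       skipped = if (length(skipped)) do.call(rbind, skipped) else NULL,
       qc_flagged = flagged,
       qc_fraction = max(per_tp$pre$qc$fraction_colocalized,
                         per_tp$post$qc$fraction_colocalized),
       transforms = list(pre = per_tp$pre$transform,
                         post = per_tp$post$transform))
}

#' Run the full analysis pipeline
#'
#' For every sample in the manifest: normalize fluorescence for laser
#' power and detector gain, register the RFP channel onto the GFP frame
#' from z-sum reflectance projections, segment both channels, compute
#' imaging biomarkers (whole-construct for GFP, per-tumor-ROI for RFP) and
#' per-unit treatment effects, then group statistics: pooled t-test and
#' Hedges' g per (channel, metric) comparing controls against treated
#' samples, an unbalanced two-way ANOVA of the object-count effect with
#' cell type and treatment as factors, and the dose-response summary.
#' QC-flagged samples (bleed-through) are excluded from all statistics.
#' Samples that fail to process are skipped and logged; the run aborts only
#' if no sample is readable.
#'
#' @param config a [pipeline_config()].
#' @return The result bundle, invisibly: a list with `biomarkers`,
#'   `effects`, `group_stats`, `anova`, `dose_response`, `qc_log`,
#'   `config_hash`. CSV/JSON files are written under `config$outdir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  records <- load_manifest(config$manifest)
  if (!length(records)) stop("fatal: manifest contains no samples")
  hash <- config_snapshot(config,
                          file.path(config$outdir, "config_snapshot.json"))

  results <- list(); failures <- list()
  for (rec in records) {
    res <- tryCatch(process_sample(rec, config), error = function(e) {
      failures[[length(failures) + 1]] <<- data.frame(
        sample_id = rec$sample_id, reason = conditionMessage(e))
      message("skipping sample ", rec$sample_id, ": ", conditionMessage(e))
      NULL
    })
    if (!is.null(res)) results[[length(results) + 1]] <- res
  }
  if (!length(results))
    stop("fatal: no sample in the manifest could be processed")

  biomarkers <- do.call(rbind, lapply(results, `[[`, "biomarkers"))
  group_of <- setNames(vapply(results, `[[`, character(1), "group"),
                       vapply(results, `[[`, character(1), "sample_id"))
  effects <- do.call(rbind, lapply(results, function(r) {
    if (is.null(r$effects)) return(NULL)
    cbind(r$effects, group = group_of[[r$sample_id]],
          qc_flagged = r$qc_flagged)
  }))
  qc_log <- do.call(rbind, lapply(results, function(r)
    data.frame(sample_id = r$sample_id, group = r$group,
               qc_flagged = r$qc_flagged,
               fraction_colocalized = r$qc_fraction)))
  skipped <- do.call(rbind, lapply(results, `[[`, "skipped"))

  clean <- effects[!effects$qc_flagged, , drop = FALSE]
  treated <- c("treated_1x", "treated_2x")

  # per (channel, metric) pooled t-test + Hedges' g, control vs treated
  group_stats <- list()
  for (ch in unique(clean$channel)) {
    for (metric in unique(clean$metric)) {
      sel <- clean$channel == ch & clean$metric == metric
      ctrl <- clean$percent_of_pre[sel & clean$group == "control"]
      trt <- clean$percent_of_pre[sel & clean$group %in% treated]
      if (length(ctrl) < 2 || length(trt) < 2) next
      cmp <- two_sample_t(summarize_values(ctrl, "control"),
                          summarize_values(trt, "treated"))
      g <- hedges_g(cmp$summary_a, cmp$summary_b,
                    correction = config$hedges_correction)
      group_stats[[length(group_stats) + 1]] <- data.frame(
        channel = ch, metric = metric,
        control_n = cmp$summary_a$n, control_mean = cmp$summary_a$mean,
        control_sd = cmp$summary_a$sd,
        treated_n = cmp$summary_b$n, treated_mean = cmp$summary_b$mean,
        treated_sd = cmp$summary_b$sd,
        t = cmp$t_statistic, df = cmp$degrees_of_freedom,
        p_value = cmp$p_value, hedges_g = g)
    }
  }
  group_stats <- if (length(group_stats)) do.call(rbind, group_stats) else NULL

  # two-way ANOVA on the object-count effect: cell type x treatment
  counts <- clean[clean$metric == "n_objects", , drop = FALSE]
  anova_tab <- NULL
  if (nrow(counts)) {
    adf <- data.frame(
      value = counts$percent_of_pre,
      cell_type = ifelse(counts$channel == "RFP_532", "cSCC",
                         "keratinocyte"),
      treatment = ifelse(counts$group == "control", "untreated", "treated"))
    anova_tab <- tryCatch(two_way_anova_unbalanced(adf),
                          error = function(e) NULL)
  }

  dose <- NULL
  rfp_counts <- counts[counts$channel == "RFP_532", , drop = FALSE]
  if (nrow(rfp_counts)) dose <- dose_response_summary(rfp_counts)

  write_tab <- function(x, name) {
    if (!is.null(x))
      write.csv(x, file.path(config$outdir, name), row.names = FALSE)
  }
  write_tab(biomarkers, "biomarkers.csv")
  write_tab(effects, "effects.csv")
  write_tab(group_stats, "group_stats.csv")
  write_tab(anova_tab, "anova.csv")
  write_tab(dose, "dose_response.csv")
  write_tab(qc_log, "qc_log.csv")
  write_tab(skipped, "excluded_units.csv")
  transforms <- do.call(rbind, lapply(results, function(r)
    do.call(rbind, lapply(.timepoints, function(tp) {
      t <- r$transforms[[tp]]
      data.frame(sample_id = r$sample_id, timepoint = tp,
                 rotation_deg = t$rotation_deg,
                 dy = unname(t$translation["dy"]),
                 dx = unname(t$translation["dx"]))
    }))))
  jsonlite::write_json(transforms,
                       file.path(config$outdir, "registration_transforms.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(failures) && length(failures))
    write_tab(do.call(rbind, failures), "failed_samples.csv")
  run_info <- list(config_hash = hash, seed = config$rng_seed,
                   n_samples = length(results),
                   n_failed = length(failures))
  jsonlite::write_json(run_info, file.path(config$outdir, "run_info.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(group_stats))
    jsonlite::write_json(
      list(config_hash = hash, group_stats = group_stats,
           anova = anova_tab, dose_response = dose),
      file.path(config$outdir, "stats.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(biomarkers = biomarkers, effects = effects,
                 group_stats = group_stats, anova = anova_tab,
                 dose_response = dose, qc_log = qc_log,
                 config_hash = hash))
}
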