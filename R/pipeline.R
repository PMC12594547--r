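run_param_defaults <- list(
  structural = list(n_edge_frames = 100L, n_edge_alines = 50L,
                    threshold_k = 4, percentile_cut = 0.05),
  oce = list(depth_offset_px = 0L, window_px = 10L, r2_threshold = 0.8),
  octa = list(kernel_px = 5L, depth_band = NULL, scales = c(1, 2, 4, 8),
              beta = 0.5, sample_every_um = 30, r2_min = 0.7),
  cohort = list(conf = 0.95)
)

#' Configuration of a pipeline run
#'
#' Bundles a modality, its input (a path to a stored dataset or a
#' [phantom_spec()] / cohort design to simulate), parameter overrides, the
#' RNG seed and the output directory. Overrides are validated against the
#' modality's defaults before any computation.
#'
#' @param modality one of `"structural"`, `"oce"`, `"octa"`, `"cohort"`.
#' @param input path prefix of a stored dataset, or `NULL` to simulate
#'   from `phantom` / `design`.
#' @param phantom a [phantom_spec()] used when `input` is `NULL` (image
#'   modalities).
#' @param design a cohort design list (see [generate_cohort()]) used when
#'   `modality = "cohort"`; must contain a `plan` entry or one is built
#'   with [make_comparison_plan()] defaults.
#' @param params named list of parameter overrides for the modality.
#' @param seed integer seed; overrides the phantom's seed.
#' @param out_dir output directory.
#' @return A `run_config` object.
#' @export
run_config <- function(modality = c("structural", "oce", "octa", "cohort"),
                       input = NULL, phantom = NULL, design = NULL,
                       params = list(), seed = 1L, out_dir = tempfile("run")) {
  modality <- match.arg(modality)
  defaults <- run_param_defaults[[modality]]
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown))
    stop("unknown parameter override(s) for modality '", modality, "': ",
         paste(unknown, collapse = ", "))
  if (!is.null(input) && !file.exists(paste0(input, ".json")) &&
      !file.exists(input))
    stop("input path does not exist: ", input)
  if (is.null(input)) {
    if (modality == "cohort") {
      if (is.null(design)) stop("cohort modality needs a design")
    } else if (is.null(phantom)) {
      stop("image modalities need either an input path or a phantom spec")
    }
  }
  structure(list(modality = modality, input = input, phantom = phantom,
                 design = design,
                 params = utils::modifyList(defaults, params,
                                            keep.null = TRUE),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

pkg_version <- function() {
  tryCatch(as.character(utils::packageVersion("dermoct")),
           error = function(e) "unknown")
}

#' Execute a configured pipeline run
#'
#' Runs the modality's stages in acquisition-processing order and writes
#' the stage outputs (CSV, containers) plus a JSON run record listing the
#' configuration echo, software version, seed, per-stage summaries, a
#' deviations log, and an md5 checksum for every output file. Identical
#' configuration and seed produce identical output checksums.
#'
#' @param config a [run_config()].
#' @return A `run_record` list (also written to `record.json` in the
#'   output directory).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- config$params
  deviations <- character(0)
  summaries <- list()
  files <- character(0)
  emit_csv <- function(df, name) {
    fp <- file.path(config$out_dir, name)
    utils::write.csv(df, fp, row.names = FALSE)
    files <<- c(files, fp)
    fp
  }

  if (config$modality == "structural") {
    vol <- if (!is.null(config$input)) read_volume(config$input)
    else {
      spec <- config$phantom; spec$seed <- config$seed
      generate_structural_volume(spec)$volume
    }
    th <- measure_thickness(vol,
                            n_edge_frames = p$n_edge_frames,
                            n_edge_alines = p$n_edge_alines,
                            threshold_k = p$threshold_k,
                            percentile_cut = p$percentile_cut)
    deviations <- c(deviations,
                    "pigment exclusion automated by percentile cut")
    emit_csv(data.frame(mean_um = th$mean_um, median_um = th$median_um,
                        n_alines_used = th$n_alines_used,
                        excluded_fraction = th$excluded_fraction),
             "thickness.csv")
    summaries$thickness <- list(mean_um = th$mean_um,
                                n_alines_used = th$n_alines_used)
  } else if (config$modality == "oce") {
    mb <- if (!is.null(config$input)) read_mb(config$input)
    else {
      spec <- config$phantom; spec$seed <- config$seed
      generate_oce_dataset(spec)$mb
    }
    ve <- estimate_group_velocity(mb, depth_offset_px = p$depth_offset_px,
                                  window_px = p$window_px,
                                  r2_threshold = p$r2_threshold)
    emit_csv(data.frame(side = c("left", "right", "mean"),
                        speed_m_s = c(ve$v_left_m_s, ve$v_right_m_s,
                                      ve$v_mean_m_s),
                        r2 = c(ve$fit_quality[["left"]],
                               ve$fit_quality[["right"]], NA)),
             "velocity.csv")
    summaries$velocity <- list(v_mean_m_s = ve$v_mean_m_s)
  } else if (config$modality == "octa") {
    st <- if (!is.null(config$input)) read_volume(config$input)
    else {
      spec <- config$phantom; spec$seed <- config$seed
      generate_octa_stack(spec)$stack
    }
    fmap <- correlation_map(st, kernel_px = p$kernel_px)
    band <- if (is.null(p$depth_band)) tissue_depth_band(st) else p$depth_band
    ef <- enface_flow(fmap, depth_band = band)
    vn <- vesselness(ef, scales = p$scales, beta = p$beta)
    lm_ <- segment_and_measure(vn, ef, st$geometry,
                               sample_every_um = p$sample_every_um,
                               r2_min = p$r2_min,
                               kernel_px = p$kernel_px)
    deviations <- c(deviations,
                    "lumen width measured automatically (Gaussian-fit FWHM of the perpendicular flow profile)")
    emit_csv(as.data.frame(lm_), "lumen.csv")
    emit_csv(summarize_lumens(lm_), "lumen_summary.csv")
    tp <- file.path(config$out_dir, "vesselness.tif")
    export_tiff(array(vn, c(1, nrow(vn), ncol(vn))), tp)
    files <- c(files, tp, paste0(tp, ".range.json"))
    summaries$octa <- list(n_profiles = nrow(lm_),
                           n_vessels = length(unique(lm_$vessel_id)))
  } else {                             # cohort
    cohort <- if (!is.null(config$input)) read_cohort(config$input)
    else generate_cohort(config$design, seed = config$seed)
    plan <- config$design$plan
    if (is.null(plan))
      plan <- make_comparison_plan(groups = unique(cohort$group),
                                   metrics = unique(cohort$metric),
                                   sites = "pooled",
                                   day_baseline = min(cohort$day),
                                   day_final = max(cohort$day))
    res <- run_study_analysis(cohort, plan, conf = p$conf)
    emit_csv(cohort, "cohort.csv")
    emit_csv(as.data.frame(res), "results.csv")
    summaries$cohort <- list(n_records = nrow(cohort),
                             n_comparisons = nrow(res))
  }

  checksums <- as.list(tools::md5sum(files))
  names(checksums) <- basename(files)
  record <- list(modality = config$modality,
                 params = config$params,
                 seed = config$seed,
                 version = pkg_version(),
                 timestamp = format(Sys.time(), tz = "UTC"),
                 summaries = summaries,
                 deviations = deviations,
                 files = checksums)
  jsonlite::write_json(record, file.path(config$out_dir, "record.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  class(record) <- "run_record"
  record
}

#' @export
print.run_record <- function(x, ...) {
  cat("<run_record>", x$modality, "seed", x$seed, "\n")
  cat("  files:", paste(names(x$files), collapse = ", "), "\n")
  invisible(x)
}
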