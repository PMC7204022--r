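# Batch orchestration: run the imaging pipeline over a directory of
# two-channel TIFFs producing one feature row per sample, then join the
# feature table with survival records and run the cohort statistics.
# Every run writes its configuration verbatim into the output directory so
# it can be replayed exactly.

#' Pipeline configuration
#'
#' @param channel_order "shg_first" or "tpe_first".
#' @param pixel_size_um optional metadata override.
#' @param gmm_seed seed for mixture-fit subsampling.
#' @param atc_se_scale structuring-element diameter as a multiple of the
#'   preliminary fiber thickness (>= 3).
#' @param min_branch_px CFL spur-pruning floor.
#' @param scan_metric "cox_p" or "logrank_p".
#' @param percentiles cutpoint candidate grid (percent units).
#' @param write_qc write QC PNGs and per-sample fit JSON.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(channel_order = "shg_first",
                            pixel_size_um = NA_real_, gmm_seed = 1L,
                            atc_se_scale = 3.5, min_branch_px = 3,
                            scan_metric = "cox_p",
                            percentiles = seq(10, 90, 10),
                            write_qc = FALSE) {
  structure(list(channel_order = channel_order,
                 pixel_size_um = pixel_size_um, gmm_seed = as.integer(gmm_seed),
                 atc_se_scale = atc_se_scale, min_branch_px = min_branch_px,
                 scan_metric = scan_metric, percentiles = percentiles,
                 write_qc = isTRUE(write_qc)),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as a flat key=value text file
#' @param config a `pipeline_config`.
#' @param path file path.
#' @export
write_config <- function(config, path) {
  kv <- vapply(names(config), function(k) {
    v <- config[[k]]
    sprintf("%s=%s", k, paste(format(v, digits = 15), collapse = ","))
  }, character(1))
  writeLines(kv, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  out <- pipeline_config()
  for (p in kv) {
    k <- p[1]; v <- strsplit(p[2], ",", fixed = TRUE)[[1]]
    v[v == "NA"] <- NA
    out[[k]] <- switch(k,
      channel_order = , scan_metric = v,
      write_qc = as.logical(v),
      gmm_seed = , min_branch_px = as.integer(v),
      as.numeric(v))
  }
  out
}

#' Profile one image end to end
#'
#' segment collagen (GMM on masked SHG) -> preliminary fiber thickness on
#' the whole collagen binary -> ATC/DTC split -> per-region features.
#'
#' @param img a [tma_image()].
#' @param config a [pipeline_config()].
#' @return a `feature_vector` with attribute `"qc"` (fit parameters,
#'   thresholds, preliminary CFT).
#' @export
profile_image <- function(img, config = pipeline_config()) {
  mask <- compute_sample_mask(img, seed = config$gmm_seed)
  fit <- fit_two_mode_gmm(img$shg[mask$mask], seed = config$gmm_seed)
  collagen <- binarize(img$shg, mask, fit$threshold, "shg")
  sk0 <- skeletonize(collagen, prune_spurs_px = config$min_branch_px)
  cft0 <- measure_cft(collagen, sk0, stat = "median")
  if (!is.finite(cft0)) cft0 <- 1
  cmap <- split_atc_dtc(img$shg, collagen, mask, cft0, config$atc_se_scale)
  fv <- profile_sample(img, mask, collagen, cmap, config$min_branch_px)
  attr(fv, "qc") <- list(
    sample_id = img$sample_id,
    gmm = list(weights = fit$weights, means = fit$means,
               variances = fit$variances, threshold = fit$threshold,
               converged = fit$converged, n_iter = fit$n_iter),
    preliminary_cft_px = cft0, se_diameter_px = cmap$se_diameter_px,
    mask_area_px = mask$area_px)
  fv
}

#' Batch-profile a set of images
#'
#' Failures are logged and skipped, never aborting the batch.
#'
#' @param image_paths character vector of TIFF paths.
#' @param out_dir output directory (created); features.csv, config.txt and,
#'   per sample, QC JSON (+ PNGs when `config$write_qc`).
#' @param config a [pipeline_config()].
#' @return list(features = data.frame, errors = named character vector,
#'   n_failed).
#' @export
run_profile <- function(image_paths, out_dir, config = pipeline_config()) {
  if (!length(image_paths)) stop("need at least one image path")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_config(config, file.path(out_dir, "config.txt"))
  rows <- list(); errors <- character(0)
  for (p in image_paths) {
    res <- tryCatch({
      img <- read_tma_image(p, channel_order = config$channel_order,
                            pixel_size_um = config$pixel_size_um)
      fv <- profile_image(img, config)
      qc <- attr(fv, "qc")
      jsonlite::write_json(qc, file.path(out_dir, paste0(img$sample_id, ".qc.json")),
                           auto_unbox = TRUE, digits = NA)
      as.data.frame(fv)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[p] <- conditionMessage(res)
      message(sprintf("collprof: skipping '%s': %s", p, conditionMessage(res)))
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  features <- if (length(rows)) do.call(rbind, rows) else NULL
  if (!is.null(features))
    write.csv(features, file.path(out_dir, "features.csv"), row.names = FALSE)
  list(features = features, errors = errors, n_failed = length(errors))
}

#' Cohort statistics over a feature table joined to survival records
#'
#' Scans every numeric feature for its best-separating percentile cutpoint
#' per endpoint, then fits the ATC-CFD x DTC-CFL four-group model at the
#' DFS-selected thresholds.
#'
#' @param features data.frame (or CSV path) with `sample_id` and feature
#'   columns as written by [run_profile()].
#' @param survival_data data.frame (or CSV path) with `patient_id`,
#'   `dfs_time`, `dfs_event` and optionally `os_time`, `os_event`;
#'   `sample_id` is matched against `patient_id`.
#' @param out_dir optional output directory for scan JSON, group CSV and KM
#'   plots.
#' @param config a [pipeline_config()].
#' @return list(scans = per-endpoint list of `threshold_scan`s,
#'   model = `four_group_model`, cohort = joined data.frame).
#' @export
run_cohort <- function(features, survival_data, out_dir = NULL,
                       config = pipeline_config()) {
  if (is.character(features)) features <- read.csv(features)
  if (is.character(survival_data)) survival_data <- read.csv(survival_data)
  if (!"patient_id" %in% names(survival_data))
    stop_collprof("collprof_schema_error", "survival table lacks 'patient_id'")
  if (anyDuplicated(survival_data$patient_id))
    stop_collprof("collprof_duplicate_key_error",
                  "duplicated patient_id in survival table")
  key <- if ("patient_id" %in% names(features)) "patient_id" else "sample_id"
  if (anyDuplicated(features[[key]]))
    stop_collprof("collprof_duplicate_key_error",
                  sprintf("duplicated %s in feature table", key))
  if (!"dfs_time" %in% names(survival_data) || !"dfs_event" %in% names(survival_data))
    stop_collprof("collprof_schema_error",
                  "survival table needs dfs_time and dfs_event columns")
  cohort <- merge(features, survival_data, by.x = key, by.y = "patient_id")
  if (nrow(cohort) < 20L)
    stop_collprof("collprof_insufficient_cohort_error",
                  sprintf("join yields %d patients; need >= 20", nrow(cohort)))
  endpoints <- intersect(c("dfs", "os"),
                         sub("_time$", "", grep("_time$", names(cohort), value = TRUE)))
  reserved <- c(key, unlist(lapply(endpoints, function(e) paste0(e, c("_time", "_event")))))
  feat_cols <- setdiff(names(cohort)[vapply(cohort, is.numeric, logical(1))], reserved)
  scans <- list()
  for (ep in endpoints) {
    scans[[ep]] <- list()
    for (fc in feat_cols) {
      s <- tryCatch(dichotomize_best_separation(
        cohort[[fc]], cohort[[paste0(ep, "_time")]], cohort[[paste0(ep, "_event")]],
        metric = config$scan_metric, percentiles = config$percentiles),
        collprof_error = function(e) NULL)
      if (!is.null(s)) scans[[ep]][[fc]] <- s
    }
  }
  model <- NULL
  if (all(c("atc_cfd", "dtc_cfl") %in% feat_cols) &&
      !is.null(scans$dfs$atc_cfd) && !is.null(scans$dfs$dtc_cfl)) {
    model <- four_group_stratify(cohort,
                                 thr_a = scans$dfs$atc_cfd$selected_threshold,
                                 thr_b = scans$dfs$dtc_cfl$selected_threshold,
                                 endpoints = endpoints)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_config(config, file.path(out_dir, "config.txt"))
    scan_json <- lapply(scans, function(eps) lapply(eps, function(s)
      list(selected_percentile = s$selected_percentile,
           selected_threshold = s$selected_threshold, p = s$selected_p,
           multiplicity_warning = s$multiplicity_warning,
           scan = s$scan)))
    jsonlite::write_json(scan_json, file.path(out_dir, "threshold_scans.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(model)) {
      write.csv(data.frame(patient_id = model$patient_id, group = model$labels),
                file.path(out_dir, "group_labels.csv"), row.names = FALSE)
      for (ep in names(model$endpoints)) {
        png(file.path(out_dir, sprintf("km_%s.png", ep)), 700, 600)
        plot(model, endpoint = ep)
        dev.off()
      }
    }
  }
  list(scans = scans, model = model, cohort = cohort)
}
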