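#' End-to-end run configuration
#'
#' Every defaulted value is recorded verbatim in the run manifest. The three
#' default site schemes mirror typical multi-site macaque acquisitions: a
#' two-shell 250/1000 s/mm^2 scheme with 6 + 64 directions, a single-shell
#' 1600 s/mm^2 scheme with 60 directions (above the DTI b-value ceiling
#' unless overridden), and a single-shell 1000 s/mm^2 scheme with 120
#' directions, on two vendors.
#'
#' @param seed integer; drives every random draw of the run.
#' @param out_dir output directory for artifacts (`NULL` = no files written).
#' @param grid_shape phantom grid (default 24^3, kept small so a full run is
#'   interactive).
#' @param noise_sd Rician noise level of the simulated DWI.
#' @param drift_slope relative drift per volume of the simulated DWI.
#' @param vc [variance_components()] of the simulated metric study.
#' @param subjects_per_site,sessions_per_subject layout of the metric study.
#' @param b0_threshold,shell_tolerance,max_dti_b,cv_mode knobs passed to the
#'   respective stages.
#' @param normalize_drift,do_powder_average,do_dti,do_qc,do_variability step
#'   switches.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 42L, out_dir = NULL,
                       grid_shape = c(24L, 24L, 24L),
                       noise_sd = 0.02, drift_slope = 0.002,
                       vc = variance_components(site_sd = 0.05,
                                                subject_sd = 0.04,
                                                session_sd = 0.02,
                                                voxel_sd = 0.02,
                                                grand_mean = 0.5),
                       subjects_per_site = c(4L, 6L, 4L),
                       sessions_per_subject = c(3L, 2L, 2L),
                       b0_threshold = 50, shell_tolerance = 50,
                       max_dti_b = 1300, cv_mode = "mask_mean",
                       normalize_drift = TRUE, do_powder_average = TRUE,
                       do_dti = TRUE, do_qc = TRUE, do_variability = TRUE) {
  cfg <- list(seed = as.integer(seed), out_dir = out_dir,
              grid_shape = as.integer(grid_shape), noise_sd = noise_sd,
              drift_slope = drift_slope, vc = vc,
              subjects_per_site = as.integer(subjects_per_site),
              sessions_per_subject = as.integer(sessions_per_subject),
              b0_threshold = b0_threshold, shell_tolerance = shell_tolerance,
              max_dti_b = max_dti_b, cv_mode = cv_mode,
              normalize_drift = isTRUE(normalize_drift),
              do_powder_average = isTRUE(do_powder_average),
              do_dti = isTRUE(do_dti), do_qc = isTRUE(do_qc),
              do_variability = isTRUE(do_variability))
  class(cfg) <- "run_config"
  cfg
}

#' Default multi-site gradient schemes
#'
#' Builds the gradient tables for the three default sites: interleaved b0
#' volumes (one at the start, one at the end, the rest evenly spread) so the
#' drift normalization has anchors across the whole series.
#'
#' @param seed direction-sampling seed.
#' @param b0_threshold passed to [gradient_table()].
#' @return Named list of [gradient_table()]s: `siteA` (5 b0, 6 @ 250 + 64 @
#'   1000), `siteB` (6 b0, 60 @ 1600), `siteC` (2 b0, 120 @ 1000).
#' @export
default_site_schemes <- function(seed = 1L, b0_threshold = 50) {
  scheme <- function(bvals_dw, dirs, n_b0) {
    n_dw <- length(bvals_dw)
    n <- n_dw + n_b0
    # b0 positions: first and last volume, remainder evenly interleaved
    pos <- unique(round(seq(1, n, length.out = n_b0)))
    bvals <- numeric(n); vecs <- matrix(0, 3, n)
    dw_slots <- setdiff(seq_len(n), pos)
    bvals[dw_slots] <- bvals_dw
    vecs[, dw_slots] <- dirs
    gradient_table(bvals, vecs, b0_threshold)
  }
  list(
    siteA = scheme(c(rep(250, 6), rep(1000, 64)),
                   cbind(sample_directions(6, seed), sample_directions(64, seed + 1L)),
                   5L),
    siteB = scheme(rep(1600, 60), sample_directions(60, seed + 2L), 6L),
    siteC = scheme(rep(1000, 120), sample_directions(120, seed + 3L), 2L))
}

#' Run the full synthetic study pipeline
#'
#' Generates a phantom and per-site DWI series, drift-normalizes them,
#' computes powder averages and model plans, fits the tensor model on the
#' first site whose sampling admits it, reports SNR/CNR, simulates the
#' hierarchical multi-site metric study and computes I2C2, the four CV
#' levels and the session-separation diagnostic. Deterministic given
#' `config$seed`. When `config$out_dir` is set, all intermediate volumes,
#' the model-plan JSON, the QC and variability CSVs and a manifest (seed,
#' config, hash) are written there.
#'
#' @param config a [run_config()].
#' @return A list of class `variability_report`: `plans`, `qc`, `dti_metrics`
#'   (summary table), `i2c2`, `cv_table`, `session_separation`, `seed`.
#' @export
run_study <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  if (!is.null(out)) dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  # keep the default 8/11/14-in-32 tissue proportions at any grid size
  r <- min(config$grid_shape) / 32
  spec <- phantom_spec(grid_shape = config$grid_shape,
                       radii = list(wm = 8 * r, gm = 11 * r, csf = 14 * r))
  masks <- stage("phantom", make_phantom_masks(spec))
  schemes <- stage("schemes",
                   default_site_schemes(config$seed,
                                        b0_threshold = config$b0_threshold))

  plans <- list(); qc_rows <- list(); dti_summary <- NULL
  dti_done <- FALSE
  for (i in seq_along(schemes)) {
    site <- names(schemes)[i]
    gtab <- schemes[[i]]
    dwi <- stage(paste0("simulate_dwi:", site),
                 simulate_dwi(spec, gtab, noise_sd = config$noise_sd,
                              drift = drift_spec(config$drift_slope),
                              seed = config$seed + i, masks = masks))
    if (config$normalize_drift)
      dwi <- stage(paste0("normalize_b0:", site), normalize_b0_drift(dwi))
    plan <- stage(paste0("plan:", site),
                  plan_models(gtab, shell_tolerance = config$shell_tolerance,
                              max_dti_b = config$max_dti_b))
    plans[[site]] <- plan
    pa <- if (config$do_powder_average)
      stage(paste0("powder_average:", site), powder_average(dwi)) else NULL
    if (config$do_qc)
      qc_rows[[site]] <- cbind(site = site,
                               stage(paste0("qc:", site), qc_report(dwi, masks)))
    if (config$do_dti && !dti_done && plan$dti_applicable) {
      fit <- stage(paste0("dti:", site),
                   fit_dti_wls(dwi, masks$brain, max_b = config$max_dti_b,
                               shell_tolerance = config$shell_tolerance))
      mets <- tensor_metrics(fit)
      vmaps <- validation_maps(dwi, fit)
      dti_summary <- data.frame(
        site = site,
        metric = c("fa", "md", "ad", "rd"),
        wm_mean = vapply(mets[c("fa", "md", "ad", "rd")],
                         function(m) mean(m[masks$wm]), 0),
        gm_mean = vapply(mets[c("fa", "md", "ad", "rd")],
                         function(m) mean(m[masks$gm]), 0),
        row.names = NULL, stringsAsFactors = FALSE)
      if (!is.null(out)) {
        for (nm in c("fa", "md", "ad", "rd"))
          write_volume(dwi_volume(mets[[nm]], spec$voxel_size),
                       file.path(out, paste0("dti_", nm, ".nii.gz")))
        write_volume(dwi_volume(vmaps$residuals, spec$voxel_size),
                     file.path(out, "dti_residuals.nii.gz"))
      }
      dti_done <- TRUE
    }
    if (!is.null(out)) {
      model_plan_json(plan, file.path(out, paste0("plan_", site, ".json")))
      if (!is.null(pa))
        write_volume(pa, file.path(out, paste0("pa_", site, ".nii.gz")))
    }
  }
  qc_table <- if (length(qc_rows)) do.call(rbind, c(qc_rows, make.row.names = FALSE))
              else NULL

  i2c2_val <- NA_real_; cv_table <- NULL; sess_sep <- NA_real_
  if (config$do_variability) {
    layout <- make_layout(subjects_per_site = config$subjects_per_site,
                          sessions_per_subject = config$sessions_per_subject)
    study <- stage("metric_study",
                   simulate_metric_study(layout, config$vc,
                                         grid_shape = config$grid_shape,
                                         mask = masks$wm,
                                         seed = config$seed + 100L))
    i2c2_val <- stage("i2c2", i2c2(study$stack))
    cv_table <- stage("cv_report",
                      cv_report(study$stack, masks$wm, metric = "synthetic",
                                tissue = "wm", mode = config$cv_mode))
    sess_sep <- tryCatch(as.numeric(session_separation(study$stack, masks$wm)),
                         error = function(e) NA_real_)
  }

  report <- structure(list(plans = plans, qc = qc_table,
                           dti_metrics = dti_summary, i2c2 = i2c2_val,
                           cv_table = cv_table,
                           session_separation = sess_sep,
                           seed = config$seed),
                      class = "variability_report")
  if (!is.null(out)) {
    if (!is.null(qc_table))
      utils::write.csv(qc_table, file.path(out, "qc.csv"), row.names = FALSE)
    if (!is.null(cv_table))
      utils::write.csv(cv_table, file.path(out, "variability.csv"),
                       row.names = FALSE)
    cfg_json <- file.path(out, "config.json")
    cfg_plain <- config
    cfg_plain$vc <- unclass(cfg_plain$vc)
    jsonlite::write_json(cfg_plain[setdiff(names(cfg_plain), "out_dir")],
                         cfg_json, auto_unbox = TRUE, digits = NA)
    manifest <- list(package = "dwivar",
                     version = as.character(utils::packageVersion("dwivar")),
                     seed = config$seed,
                     config_hash = unname(tools::md5sum(cfg_json)),
                     i2c2 = i2c2_val,
                     session_separation = sess_sep)
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.variability_report <- function(x, ...) {
  cat("<variability_report> seed ", x$seed, "\n", sep = "")
  cat("  I2C2: ", signif(x$i2c2, 4), "; session-separation F: ",
      signif(x$session_separation, 4), "\n", sep = "")
  if (!is.null(x$cv_table)) {
    cat("  CV levels:\n")
    print(x$cv_table, row.names = FALSE)
  }
  if (!is.null(x$qc)) {
    cat("  QC:\n")
    print(x$qc, row.names = FALSE)
  }
  invisible(x)
}
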