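#' Maximum spherical-harmonic order supported by a direction count
#'
#' A real symmetric (even-order) SH basis of order L has
#' `(L + 1) * (L + 2) / 2` coefficients; a full basis has `(L + 1)^2`. The
#' fit is determined only when the number of independent gradient directions
#' reaches the coefficient count, so the usable order is the largest L whose
#' basis still fits.
#'
#' @param n_dirs number of independent gradient directions (>= 1).
#' @return `sh_order_symmetric`: the largest even L with
#'   `(L + 1) * (L + 2) / 2 <= n_dirs`; `sh_order_full`: the largest L with
#'   `(L + 1)^2 <= n_dirs`. Both are floored at 0.
#' @export
sh_order_symmetric <- function(n_dirs) {
  n_dirs <- check_ndirs(n_dirs)
  L <- floor((-3 + sqrt(1 + 8 * n_dirs)) / 2)
  # guard float boundary, then floor to even (symmetric basis has even orders only)
  while ((L + 2) * (L + 3) / 2 <= n_dirs) L <- L + 1
  while (L > 0 && (L + 1) * (L + 2) / 2 > n_dirs) L <- L - 1
  L <- L - (L %% 2)
  as.integer(max(0, L))
}

#' @rdname sh_order_symmetric
#' @export
sh_order_full <- function(n_dirs) {
  n_dirs <- check_ndirs(n_dirs)
  L <- floor(sqrt(n_dirs)) - 1
  while ((L + 2)^2 <= n_dirs) L <- L + 1
  while (L > 0 && (L + 1)^2 > n_dirs) L <- L - 1
  as.integer(max(0, L))
}

check_ndirs <- function(n_dirs) {
  n_dirs <- as.numeric(n_dirs)
  if (length(n_dirs) != 1L || is.na(n_dirs) || n_dirs < 1)
    stop("n_dirs must be a single number >= 1", call. = FALSE)
  floor(n_dirs)
}

#' SH order for a multi-shell sampling
#'
#' The order is determined per shell from its own direction count and the
#' minimum over shells is selected, so the weakest shell bounds the basis.
#'
#' @param shells a [detect_shells()] result with at least one shell.
#' @param basis `"symmetric"` or `"full"`.
#' @return The selected order (integer).
#' @export
sh_order_multishell <- function(shells, basis = c("symmetric", "full")) {
  basis <- match.arg(basis)
  if (nrow(shells) == 0L) stop("no shells to configure", call. = FALSE)
  f <- if (basis == "symmetric") sh_order_symmetric else sh_order_full
  min(vapply(pmax(1L, shells$n_directions), f, 0L))
}

# per-fascicle parameter counts, in decreasing complexity; each fascicle
# compartment adds one fraction parameter on top
fascicle_model_params <- c(tensor = 6L, cylinder = 4L, stick = 3L)
.model_order <- names(fascicle_model_params)   # tensor > cylinder > stick

#' Multi-compartment (DIAMOND-style) parameter plan
#'
#' @param n_fascicles number of fascicle compartments (1-3; 0 only via `force`).
#' @param fascicle_model `"tensor"` (6 parameters), `"cylinder"` (4) or
#'   `"stick"` (3); each fascicle also carries one fraction parameter.
#' @param free_water whether an isotropic free-water compartment (2
#'   parameters) is present.
#' @param restriction_hindrance whether restriction/hindrance estimation is
#'   added (+1 parameter per fascicle).
#' @param forced plan imposed by the user rather than derived from the data.
#' @param feasible `FALSE` when even the minimal model exceeds the available
#'   directions.
#' @return An object of class `diamond_plan`; its `budget` field is the total
#'   parameter count, which doubles as the minimum number of gradient
#'   directions required to fit the model.
#' @export
diamond_plan <- function(n_fascicles = 3L, fascicle_model = "tensor",
                         free_water = TRUE, restriction_hindrance = FALSE,
                         forced = FALSE, feasible = TRUE) {
  if (!fascicle_model %in% names(fascicle_model_params))
    stop("unknown fascicle model: ", fascicle_model, call. = FALSE)
  structure(list(
    n_fascicles = as.integer(n_fascicles),
    fascicle_model = fascicle_model,
    free_water = isTRUE(free_water),
    restriction_hindrance = isTRUE(restriction_hindrance),
    forced = isTRUE(forced),
    feasible = isTRUE(feasible),
    budget = diamond_budget(n_fascicles, fascicle_model, free_water,
                            restriction_hindrance)),
    class = "diamond_plan")
}

#' Parameter budget of a compartment configuration
#'
#' `n_fascicles * (model parameters + 1 fraction + restriction/hindrance) +
#' 2 * free_water`.
#'
#' @inheritParams diamond_plan
#' @return Integer parameter count.
#' @export
diamond_budget <- function(n_fascicles, fascicle_model, free_water,
                           restriction_hindrance = FALSE) {
  per <- fascicle_model_params[[fascicle_model]] + 1L +
    as.integer(isTRUE(restriction_hindrance))
  as.integer(n_fascicles) * per + 2L * as.integer(isTRUE(free_water))
}

#' @export
print.diamond_plan <- function(x, ...) {
  cat("<diamond_plan> ", x$n_fascicles, " x ", x$fascicle_model,
      if (x$restriction_hindrance) " (+restriction/hindrance)",
      if (x$free_water) " + free water",
      " = ", x$budget, " parameters",
      if (x$forced) " [forced]", if (!x$feasible) " [infeasible]",
      "\n", sep = "")
  invisible(x)
}

#' Adapt the multi-compartment model to the available directions
#'
#' The optimal starting model is 3 fascicle compartments, each a full tensor
#' (6 parameters) plus one fraction, plus a 2-parameter free-water
#' compartment: 23 parameters, requiring at least 23 gradient directions.
#' When fewer directions are available, complexity is reduced one step at a
#' time in priority order — lower the fascicle model, drop to 2 fascicles,
#' remove free water, drop to 1 fascicle — re-checking the budget after each
#' step and cycling back to the first priority while still over budget. With
#' more than 23 directions, complexity is increased greedily in priority
#' order — raise the fascicle model, add restriction/hindrance estimation,
#' add fascicles (up to 3) — stopping before any step would exceed the
#' available directions.
#'
#' @param n_dirs_total independent gradient directions pooled over all shells.
#' @param force optional [diamond_plan()] to impose verbatim; it is returned
#'   with `forced = TRUE` regardless of the budget (the fitted model's
#'   uniqueness is then not guaranteed).
#' @param max_fascicles upper bound on fascicle compartments (default 3).
#' @return A [diamond_plan()]. When even the minimal model (1 stick fascicle,
#'   4 parameters) exceeds `n_dirs_total`, it is returned with
#'   `feasible = FALSE`.
#' @export
plan_diamond <- function(n_dirs_total, force = NULL, max_fascicles = 3L) {
  n <- check_ndirs(n_dirs_total)
  if (!is.null(force)) {
    if (!inherits(force, "diamond_plan"))
      stop("force must be a diamond_plan", call. = FALSE)
    force$forced <- TRUE
    force$feasible <- force$budget <= n
    return(force)
  }
  st <- list(f = 3L, model = "tensor", fw = TRUE, rh = FALSE)
  budget <- function(s) diamond_budget(s$f, s$model, s$fw, s$rh)

  if (budget(st) > n) {
    # one step per priority item, cycling until the budget fits
    lower_model <- function(s) {
      i <- match(s$model, .model_order)
      if (i < length(.model_order)) s$model <- .model_order[i + 1L] else s <- NULL
      s
    }
    steps <- list(
      lower_model,
      function(s) if (s$f > 2L) { s$f <- 2L; s } else NULL,
      function(s) if (s$fw) { s$fw <- FALSE; s } else NULL,
      function(s) if (s$f > 1L) { s$f <- 1L; s } else NULL)
    feasible <- TRUE
    repeat {
      applied <- FALSE
      for (step in steps) {
        cand <- step(st)
        if (!is.null(cand)) {
          st <- cand
          applied <- TRUE
          if (budget(st) <= n) break
        }
      }
      if (budget(st) <= n) break
      if (!applied) { feasible <- FALSE; break }
    }
    return(diamond_plan(st$f, st$model, st$fw, st$rh, feasible = feasible))
  }

  # at or above the starting budget: greedy increases that still fit
  raise_model <- function(s) {
    i <- match(s$model, .model_order)
    if (i > 1L) { s$model <- .model_order[i - 1L]; s } else NULL
  }
  inc_steps <- list(
    raise_model,
    function(s) if (!s$rh) { s$rh <- TRUE; s } else NULL,
    function(s) if (s$f < max_fascicles) { s$f <- s$f + 1L; s } else NULL)
  repeat {
    advanced <- FALSE
    for (step in inc_steps) {
      cand <- step(st)
      if (!is.null(cand) && budget(cand) <= n) {
        st <- cand
        advanced <- TRUE
        break
      }
    }
    if (!advanced) break
  }
  diamond_plan(st$f, st$model, st$fw, st$rh)
}

#' Assemble the full adaptive model plan for an acquisition
#'
#' From the gradient table alone: detects shells, decides DTI applicability
#' (at least 6 independent directions on shells at or below `max_dti_b`),
#' selects the per-basis SH orders by the per-shell-minimum rule, and budgets
#' the multi-compartment model from the direction count pooled over all
#' shells.
#'
#' @param gradients a [gradient_table()].
#' @param shell_tolerance passed to [detect_shells()].
#' @param max_dti_b highest shell used by the tensor fit (s/mm^2).
#' @param min_dti_dirs directions required by the tensor fit (6 unknowns).
#' @param force_diamond optional [diamond_plan()] override.
#' @return An object of class `model_plan` with fields `shells`,
#'   `dti_applicable`, `dti_n_directions`, `sh_order_sym`, `sh_order_full`,
#'   `diamond`, `forced`.
#' @export
plan_models <- function(gradients, shell_tolerance = 50, max_dti_b = 1300,
                        min_dti_dirs = 6L, force_diamond = NULL) {
  shells <- detect_shells(gradients, shell_tolerance)
  if (nrow(shells) == 0L)
    stop("no diffusion-weighted shells: cannot plan models", call. = FALSE)
  dti_shells <- tryCatch(filter_shells_for_dti(shells, max_dti_b),
                         error = function(e) NULL)
  dti_dirs <- if (is.null(dti_shells)) 0L else {
    members <- unlist(attr(dti_shells, "members"))
    count_unique_directions(gradients$bvecs[, members, drop = FALSE])
  }
  all_members <- unlist(attr(shells, "members"))
  n_total <- count_unique_directions(gradients$bvecs[, all_members, drop = FALSE])
  diamond <- plan_diamond(n_total, force = force_diamond)
  structure(list(
    shells = shells,
    dti_applicable = dti_dirs >= min_dti_dirs,
    dti_n_directions = dti_dirs,
    max_dti_b = max_dti_b,
    sh_order_sym = sh_order_multishell(shells, "symmetric"),
    sh_order_full = sh_order_multishell(shells, "full"),
    diamond = diamond,
    forced = diamond$forced),
    class = "model_plan")
}

#' @export
print.model_plan <- function(x, ...) {
  cat("<model_plan>\n  shells:", paste(signif(x$shells$center, 4), collapse = ", "),
      "s/mm^2\n  DTI:", if (x$dti_applicable) "applicable" else "not applicable",
      sprintf("(%d directions at b <= %g)", x$dti_n_directions, x$max_dti_b),
      "\n  SH order: symmetric", x$sh_order_sym, "| full", x$sh_order_full, "\n")
  print(x$diamond)
  invisible(x)
}

#' Serialize a model plan to JSON
#'
#' @param plan a [plan_models()] result.
#' @param path optional output path; when omitted the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
model_plan_json <- function(plan, path = NULL) {
  obj <- list(
    shells = data.frame(center = plan$shells$center,
                        n_volumes = plan$shells$n_volumes,
                        n_directions = plan$shells$n_directions),
    dti = list(applicable = plan$dti_applicable,
               n_directions = plan$dti_n_directions,
               max_b = plan$max_dti_b),
    sh_order = list(symmetric = plan$sh_order_sym, full = plan$sh_order_full),
    diamond = plan$diamond[c("n_fascicles", "fascicle_model", "free_water",
                             "restriction_hindrance", "forced", "feasible",
                             "budget")])
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Scale a non-dimensional parameter by the voxel size
#'
#' Spatial algorithm parameters (smoothing windows, knot spacings, ...) are
#' declared as dimensionless ratios and multiplied by the image's voxel size
#' at run time, so one configuration adapts to any spatial resolution.
#'
#' @param ratio dimensionless ratio (>= 0), possibly vectorized.
#' @param voxel_size mm, scalar or length 3.
#' @param reduction how to collapse anisotropic voxels when the consumer
#'   needs one number: `"vector"` (no collapse, per-axis result), `"min"`
#'   (conservative), `"max"`, `"mean"`.
#' @return `ratio * voxel_size`, collapsed per `reduction`; in mm.
#' @export
scale_parameter <- function(ratio, voxel_size,
                            reduction = c("vector", "min", "max", "mean")) {
  reduction <- match.arg(reduction)
  ratio <- as.numeric(ratio)
  voxel_size <- as.numeric(voxel_size)
  if (any(is.na(ratio)) || any(ratio < 0))
    stop("ratio must be >= 0", call. = FALSE)
  if (any(is.na(voxel_size)) || any(voxel_size <= 0))
    stop("voxel size must be strictly positive", call. = FALSE)
  vs <- switch(reduction,
    vector = voxel_size,
    min = min(voxel_size),
    max = max(voxel_size),
    mean = mean(voxel_size))
  ratio * vs
}
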