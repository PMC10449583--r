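#' Phantom specification
#'
#' A digital phantom of nested ellipsoids — a white-matter core, a gray-matter
#' shell and a CSF rim inside a zero-signal background — with per-tissue
#' baseline signal S0 and diffusion tensors. Default tensors are canonical
#' literature values giving realistic FA/MD contrast: WM
#' diag(1.7, 0.3, 0.3) x 1e-3 mm^2/s (principal axis along x), GM isotropic
#' 0.8e-3, CSF isotropic 3.0e-3; S0 of 0.7 / 1.0 / 2.0 (arbitrary units)
#' reproduces the usual b0 tissue ordering.
#'
#' @param grid_shape length-3 integer vector of voxels (default 32^3).
#' @param voxel_size mm, scalar or length 3 (default 1 mm isotropic).
#' @param radii named list of ellipsoid semi-axes in voxel units, strictly
#'   nested `wm < gm < csf`; scalars give spheres.
#' @param s0 named numeric vector of per-tissue baseline signals.
#' @param tensors named list of symmetric positive-definite 3x3 diffusion
#'   tensors (mm^2/s).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(32L, 32L, 32L),
                         voxel_size = c(1, 1, 1),
                         radii = list(wm = 8, gm = 11, csf = 14),
                         s0 = c(wm = 0.7, gm = 1.0, csf = 2.0),
                         tensors = list(
                           wm = diag(c(1.7e-3, 0.3e-3, 0.3e-3)),
                           gm = diag(rep(0.8e-3, 3)),
                           csf = diag(rep(3.0e-3, 3)))) {
  grid_shape <- as.integer(grid_shape)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  expand <- function(r) if (length(r) == 1L) rep(r, 3L) else as.numeric(r)
  radii <- lapply(radii[c("wm", "gm", "csf")], expand)
  if (!(all(radii$wm <= radii$gm) && all(radii$gm < radii$csf) &&
        any(radii$wm < radii$gm)))
    stop("ellipsoid radii must be strictly nested: wm < gm < csf", call. = FALSE)
  for (t in names(tensors)) {
    D <- tensors[[t]]
    if (any(abs(D - t(D)) > 1e-12) || any(eigen(D, symmetric = TRUE,
                                                only.values = TRUE)$values <= 0))
      stop(sprintf("%s tensor must be symmetric positive-definite", t),
           call. = FALSE)
  }
  structure(list(grid_shape = grid_shape, voxel_size = as.numeric(voxel_size),
                 radii = radii, s0 = s0, tensors = tensors),
            class = "phantom_spec")
}

ellipsoid_mask <- function(grid_shape, radii) {
  ctr <- (grid_shape + 1) / 2
  ax <- lapply(1:3, function(k) ((seq_len(grid_shape[k]) - ctr[k]) / radii[k])^2)
  r2 <- outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+")
  r2 <= 1
}

#' Build disjoint tissue masks from a phantom spec
#'
#' @param spec a [phantom_spec()].
#' @return A [tissue_masks()] whose brain mask is the union of the three
#'   tissues. A zero-extent WM region yields an empty WM mask with a warning.
#' @export
make_phantom_masks <- function(spec) {
  shp <- spec$grid_shape
  wm_ell <- if (all(spec$radii$wm > 0)) ellipsoid_mask(shp, spec$radii$wm)
            else array(FALSE, shp)
  gm_ell <- ellipsoid_mask(shp, spec$radii$gm)
  csf_ell <- ellipsoid_mask(shp, spec$radii$csf)
  wm <- wm_ell
  gm <- gm_ell & !wm_ell
  csf <- csf_ell & !gm_ell
  if (!any(wm)) warning("WM mask is empty", call. = FALSE)
  tissue_masks(wm, gm, csf)
}

#' Approximately uniform unit directions on the sphere
#'
#' Deterministic Fibonacci-lattice points, rotated by a seeded random rotation
#' so different seeds give different (but individually reproducible) schemes.
#' The minimum pairwise angular separation — after folding antipodes, since a
#' gradient and its negation probe the same diffusion direction — is attached
#' as the `"min_angle"` attribute (degrees).
#'
#' @param n number of directions (>= 1).
#' @param seed integer seed; fully determines the output.
#' @return A 3 x n matrix of unit column vectors.
#' @export
sample_directions <- function(n, seed = 1L) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be >= 1", call. = FALSE)
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  pts <- rbind(r * cos(phi), r * sin(phi), z)
  R <- random_rotation(seed)
  pts <- R %*% pts
  attr(pts, "min_angle") <- min_pairwise_angle(pts)
  pts
}

random_rotation <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  M <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(M)
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

min_pairwise_angle <- function(pts) {
  if (ncol(pts) < 2L) return(NA_real_)
  ct <- abs(crossprod(pts))            # antipodal fold
  diag(ct) <- 0
  acos(pmin(1, max(ct))) * 180 / pi
}

#' Signal drift specification
#'
#' Linear multiplicative intensity drift across the acquisition: volume at
#' 0-based index t is scaled by `1 + slope * t`, emulating the slow signal
#' change caused by gradient/coil heating over a long scan.
#'
#' @param slope relative drift per volume index (dimensionless).
#' @return An object of class `drift_spec`.
#' @export
drift_spec <- function(slope = 0) {
  structure(list(slope = as.numeric(slope), model = "linear"),
            class = "drift_spec")
}

drift_factors <- function(drift, n) {
  f <- 1 + drift$slope * (seq_len(n) - 1)
  if (any(f <= 0))
    stop("drift scale factors must stay positive over the series", call. = FALSE)
  f
}

#' Simulate a diffusion-weighted series from a phantom
#'
#' Noiseless signal `S(v, g) = S0(v) * exp(-b * g' D(v) g)` per tissue, scaled
#' by the per-volume drift factor, then Rician-corrupted:
#' `sqrt((S + e1)^2 + e2^2)` with `e1, e2 ~ N(0, noise_sd^2)`. Background
#' voxels (S = 0) therefore follow a Rayleigh distribution with mean
#' `noise_sd * sqrt(pi / 2)`. The seed fully determines the output.
#'
#' @param spec a [phantom_spec()].
#' @param gradients a [gradient_table()].
#' @param noise_sd Gaussian component SD, in signal units (0 = noiseless).
#' @param drift a [drift_spec()].
#' @param seed integer seed.
#' @param masks optional precomputed [make_phantom_masks()] result.
#' @return A [dwi_series()]; the tissue masks used are attached as the
#'   `"masks"` attribute.
#' @export
simulate_dwi <- function(spec, gradients, noise_sd = 0, drift = drift_spec(0),
                         seed = 1L, masks = NULL) {
  if (length(gradients) < 1L) stop("gradient table is empty", call. = FALSE)
  if (is.null(masks)) masks <- make_phantom_masks(spec)
  shp <- spec$grid_shape
  nvol <- length(gradients)
  vols <- array(0, c(shp, nvol))
  tissue_idx <- list(wm = which(masks$wm), gm = which(masks$gm),
                     csf = which(masks$csf))
  fac <- drift_factors(drift, nvol)
  nvox3 <- prod(shp)
  for (t in seq_len(nvol)) {
    b <- gradients$bvals[t]
    g <- gradients$bvecs[, t]
    sl <- array(0, shp)
    for (tis in names(tissue_idx)) {
      idx <- tissue_idx[[tis]]
      if (!length(idx)) next
      att <- if (b > 0 && sum(g^2) > 0)
        exp(-b * drop(t(g) %*% spec$tensors[[tis]] %*% g)) else 1
      sl[idx] <- spec$s0[[tis]] * att
    }
    vols[(t - 1L) * nvox3 + seq_len(nvox3)] <- sl * fac[t]
  }
  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    e1 <- array(stats::rnorm(length(vols), sd = noise_sd), dim(vols))
    e2 <- array(stats::rnorm(length(vols), sd = noise_sd), dim(vols))
    vols <- sqrt((vols + e1)^2 + e2^2)
  }
  out <- dwi_series(vols, gradients, voxel_size = spec$voxel_size)
  attr(out, "masks") <- masks
  out
}

#' Hierarchical variance components for a multi-site metric study
#'
#' @param site_sd,subject_sd,session_sd,voxel_sd standard deviations (>= 0) on
#'   the metric scale of the additive site, subject, session and voxel-noise
#'   effects.
#' @param grand_mean scalar or 3D array: the shared mean map.
#' @return An object of class `variance_components`.
#' @export
variance_components <- function(site_sd = 0, subject_sd = 0, session_sd = 0,
                                voxel_sd = 0, grand_mean = 1) {
  sds <- c(site_sd, subject_sd, session_sd, voxel_sd)
  if (any(sds < 0)) stop("variance-component SDs must be >= 0", call. = FALSE)
  structure(list(site_sd = site_sd, subject_sd = subject_sd,
                 session_sd = session_sd, voxel_sd = voxel_sd,
                 grand_mean = grand_mean),
            class = "variance_components")
}

#' Convenience constructor for a multi-site layout
#'
#' @param sites character vector of site names.
#' @param vendors vendor label per site.
#' @param subjects_per_site integer per site.
#' @param sessions_per_subject integer per site (every subject of a site gets
#'   this many sessions).
#' @return A [study_layout()].
#' @export
make_layout <- function(sites = c("siteA", "siteB", "siteC"),
                        vendors = c("vendor1", "vendor1", "vendor2"),
                        subjects_per_site = c(4L, 6L, 4L),
                        sessions_per_subject = c(3L, 2L, 2L)) {
  rows <- list()
  for (i in seq_along(sites)) {
    for (s in seq_len(subjects_per_site[i])) {
      subj <- sprintf("%s_sub%02d", sites[i], s)
      for (k in seq_len(sessions_per_subject[i])) {
        rows[[length(rows) + 1L]] <- data.frame(
          site = sites[i], vendor = vendors[i], subject = subj,
          session = sprintf("ses%02d", k), stringsAsFactors = FALSE)
      }
    }
  }
  df <- do.call(rbind, rows)
  study_layout(df$site, df$vendor, df$subject, df$session)
}

#' Simulate a hierarchical multi-site metric-map study
#'
#' Each session image is
#' `I[d,s,j](v) = mu(v) + beta_d + b_s + e_{s,j} + eps(v)` with independent
#' Gaussian site, subject, session and voxel effects drawn from the given
#' variance components — exactly the nested structure the reliability (I2C2)
#' and multi-level CV statistics are designed to decompose. The drawn effects
#' are returned for parameter-recovery tests.
#'
#' @param layout a [study_layout()].
#' @param vc a [variance_components()].
#' @param grid_shape grid for the generated maps (default 10^3 = 1000 voxels).
#' @param mask optional logical array (defaults to the full grid).
#' @param seed integer seed; fully determines the study.
#' @return A list with `stack` (a [metric_stack()]) and `effects` (the drawn
#'   site/subject/session effects, named).
#' @export
simulate_metric_study <- function(layout, vc, grid_shape = c(10L, 10L, 10L),
                                  mask = NULL, seed = 1L) {
  if (nrow(layout) < 1L) stop("layout is empty", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sites <- unique(layout$site)
  subjects <- unique(layout$subject)
  beta <- stats::setNames(stats::rnorm(length(sites), 0, vc$site_sd), sites)
  bsub <- stats::setNames(stats::rnorm(length(subjects), 0, vc$subject_sd),
                          subjects)
  mu <- if (length(vc$grand_mean) == 1L)
    array(vc$grand_mean, grid_shape) else as.array(vc$grand_mean)
  if (!identical(dim(mu), as.integer(grid_shape)))
    grid_shape <- dim(mu)
  n <- nrow(layout)
  esess <- stats::rnorm(n, 0, vc$session_sd)
  images <- vector("list", n)
  for (i in seq_len(n)) {
    eps <- if (vc$voxel_sd > 0)
      array(stats::rnorm(prod(grid_shape), 0, vc$voxel_sd), grid_shape)
    else array(0, grid_shape)
    images[[i]] <- mu + beta[[layout$site[i]]] + bsub[[layout$subject[i]]] +
      esess[i] + eps
  }
  list(stack = metric_stack(images, layout, mask),
       effects = list(site = beta, subject = bsub,
                      session = stats::setNames(
                        esess, paste(layout$subject, layout$session, sep = "/"))))
}

#' Write a complete synthetic study to disk
#'
#' Materializes a generated metric study (plus masks) as a directory tree of
#' NIfTI maps with a YAML layout config — the on-disk form [load_metric_stack()]
#' consumes.
#'
#' @param study result of [simulate_metric_study()].
#' @param dir output directory.
#' @param metric_name file stem for the written maps.
#' @param voxel_size mm.
#' @return The path of the written layout config, invisibly.
#' @export
write_metric_study <- function(study, dir, metric_name = "metric",
                               voxel_size = c(1, 1, 1)) {
  layout <- study$stack$index
  paths <- character(nrow(layout))
  for (i in seq_len(nrow(layout))) {
    d <- file.path(dir, layout$site[i], layout$subject[i], layout$session[i])
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    write_volume(dwi_volume(study$stack$images[[i]], voxel_size),
                 file.path(d, paste0(metric_name, ".nii.gz")))
    paths[i] <- d
  }
  lay <- study_layout(layout$site, layout$vendor, layout$subject,
                      layout$session, paths)
  cfg <- file.path(dir, "layout.yaml")
  write_study_layout(lay, cfg)
  invisible(cfg)
}
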