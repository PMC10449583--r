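#' Weighted-least-squares diffusion tensor fit
#'
#' Fits `log S = log S0 - b g' D g` per voxel. An ordinary least-squares fit
#' on the log-signal initializes the solution; `n_iter` reweighting passes
#' follow, with weights equal to the squared predicted signal (the canonical
#' WLS scheme: the log-transform makes the noise on low signals loudest, and
#' weighting by S^2 undoes that). Only shells at or below `max_b` are used
#' (see [filter_shells_for_dti()]); b0 volumes are always included. Negative
#' eigenvalues are preserved in the coefficients but clamped to zero when
#' scalar metrics are computed.
#'
#' @param dwi a [dwi_series()] with at least one b0 and at least 6
#'   independent directions on the retained shells.
#' @param mask logical 3D array of voxels to fit (default: all voxels with
#'   any non-zero signal).
#' @param max_b highest shell used (s/mm^2).
#' @param shell_tolerance passed to [detect_shells()].
#' @param n_iter number of WLS reweighting passes (default 1).
#' @return An object of class `tensor_fit`: per-voxel coefficients
#'   (`log_s0`, `dxx, dxy, dxz, dyy, dyz, dzz` in mm^2/s), sorted eigenvalues
#'   `evals` (descending), principal eigenvectors `evec1`, an RMS `residuals`
#'   map (signal units), the fitted `mask`, an `excluded` mask of all-zero
#'   voxels, and the volume indices used.
#' @export
fit_dti_wls <- function(dwi, mask = NULL, max_b = 1300, shell_tolerance = 50,
                        n_iter = 1L) {
  shells <- detect_shells(dwi$gradients, shell_tolerance)
  if (nrow(shells) == 0L)
    stop("no diffusion-weighted volumes to fit", call. = FALSE)
  dti_shells <- filter_shells_for_dti(shells, max_b)
  dw_idx <- sort(unlist(attr(dti_shells, "members")))
  b0_idx <- attr(dti_shells, "b0_indices")
  if (!length(b0_idx))
    stop("tensor fit requires at least one b0 volume", call. = FALSE)
  ndir <- count_unique_directions(dwi$gradients$bvecs[, dw_idx, drop = FALSE])
  if (ndir < 6L)
    stop(sprintf(
      "tensor fit requires >= 6 independent directions on shells at or below b = %g (found %d)",
      max_b, ndir), call. = FALSE)
  use <- sort(c(b0_idx, dw_idx))

  shp <- dim(dwi$volumes)[1:3]
  if (is.null(mask)) mask <- apply(dwi$volumes, 1:3, max) > 0
  mask <- array(as.logical(mask), shp)
  vox <- which(mask)
  nvol <- length(use)
  # design: log S = X %*% c(logS0, Dxx, Dxy, Dxz, Dyy, Dyz, Dzz)
  b <- dwi$gradients$bvals[use]
  g <- dwi$gradients$bvecs[, use, drop = FALSE]
  X <- cbind(1,
             -b * g[1, ]^2, -2 * b * g[1, ] * g[2, ], -2 * b * g[1, ] * g[3, ],
             -b * g[2, ]^2, -2 * b * g[2, ] * g[3, ], -b * g[3, ]^2)
  colnames(X) <- c("log_s0", "dxx", "dxy", "dxz", "dyy", "dyz", "dzz")

  S <- matrix(0, length(vox), nvol)
  for (j in seq_len(nvol)) {
    v <- dwi$volumes[, , , use[j]]
    S[, j] <- v[vox]
  }
  zero <- rowSums(S > 0) == 0L
  excluded <- array(FALSE, shp)
  if (any(zero)) {
    excluded[vox[zero]] <- TRUE
    S <- S[!zero, , drop = FALSE]
    vox <- vox[!zero]
  }
  if (!length(vox)) stop("no voxel with signal inside the mask", call. = FALSE)
  eps <- max(S) * 1e-12
  Y <- log(pmax(S, eps))

  XtX <- crossprod(X)
  beta <- t(solve(XtX, crossprod(X, t(Y))))      # nvox x 7, OLS init
  for (it in seq_len(n_iter)) {
    P <- beta %*% t(X)                           # predicted log-signal
    W <- exp(2 * P)                              # predicted signal squared
    for (i in seq_len(nrow(beta))) {
      w <- W[i, ]
      Xw <- X * w
      beta[i, ] <- tryCatch(
        solve(crossprod(X, Xw), crossprod(Xw, Y[i, ])),
        error = function(e) beta[i, ])
    }
  }

  pred <- exp(beta %*% t(X))
  rss <- sqrt(rowMeans((S - pred)^2))
  residuals <- array(0, shp)
  residuals[vox] <- rss

  evals <- matrix(0, nrow(beta), 3)
  evec1 <- matrix(0, nrow(beta), 3)
  for (i in seq_len(nrow(beta))) {
    D <- matrix(c(beta[i, "dxx"], beta[i, "dxy"], beta[i, "dxz"],
                  beta[i, "dxy"], beta[i, "dyy"], beta[i, "dyz"],
                  beta[i, "dxz"], beta[i, "dyz"], beta[i, "dzz"]), 3, 3)
    e <- eigen(D, symmetric = TRUE)
    evals[i, ] <- e$values                       # descending
    evec1[i, ] <- e$vectors[, 1]
  }

  fitted_mask <- array(FALSE, shp)
  fitted_mask[vox] <- TRUE
  structure(list(coefficients = beta, evals = evals, evec1 = evec1,
                 voxels = vox, grid_shape = shp, residuals = residuals,
                 mask = fitted_mask, excluded = excluded,
                 volumes_used = use, design = X),
            class = "tensor_fit")
}

#' @export
print.tensor_fit <- function(x, ...) {
  cat("<tensor_fit> ", length(x$voxels), " voxels, ",
      length(x$volumes_used), " volumes\n", sep = "")
  invisible(x)
}

fill_map <- function(values, voxels, shp, default = 0) {
  m <- array(default, shp)
  m[voxels] <- values
  m
}

#' Scalar tensor metrics
#'
#' Eigenvalue metrics from a tensor fit, with negative eigenvalues clamped to
#' zero: axial diffusivity `AD = lambda1`, radial diffusivity
#' `RD = (lambda2 + lambda3) / 2`, mean diffusivity `MD = mean(lambda)`, and
#' fractional anisotropy
#' `FA = sqrt(3/2 * sum((lambda - MD)^2) / sum(lambda^2))` (0 for an all-zero
#' tensor). RGB is the absolute principal eigenvector modulated by FA.
#'
#' @param fit a [fit_dti_wls()] result.
#' @return A list of 3D maps `fa`, `md`, `ad`, `rd` and a 4D `rgb`
#'   (x, y, z, component).
#' @export
tensor_metrics <- function(fit) {
  lam <- pmax(fit$evals, 0)
  md <- rowMeans(lam)
  ad <- lam[, 1]
  rd <- (lam[, 2] + lam[, 3]) / 2
  ss <- rowSums(lam^2)
  fa <- ifelse(ss > 0,
               sqrt(1.5 * rowSums((lam - md)^2) / ss), 0)
  shp <- fit$grid_shape
  rgb <- array(0, c(shp, 3L))
  for (k in 1:3)
    rgb[, , , k] <- fill_map(abs(fit$evec1[, k]) * fa, fit$voxels, shp)
  list(fa = fill_map(fa, fit$voxels, shp),
       md = fill_map(md, fit$voxels, shp),
       ad = fill_map(ad, fit$voxels, shp),
       rd = fill_map(rd, fit$voxels, shp),
       rgb = rgb)
}

#' Fit validation maps
#'
#' Three diagnostic maps: the RMS fit residual, the per-voxel standard
#' deviation across diffusion-weighted (non-b0) volumes — large values flag
#' pulsation and misalignment artifacts — and the physically-implausible
#' mask, true wherever any diffusion-weighted intensity exceeds the voxel's
#' mean b0 signal (attenuation can only reduce signal, so such voxels
#' violate the signal model).
#'
#' @param dwi the [dwi_series()] the fit was computed on.
#' @param fit a [fit_dti_wls()] result.
#' @return A list of maps `residuals`, `std_across_volumes`,
#'   `implausible_mask`.
#' @export
validation_maps <- function(dwi, fit) {
  b0_idx <- which(is_b0(dwi$gradients))
  dw_idx <- which(!is_b0(dwi$gradients))
  shp <- dim(dwi$volumes)[1:3]
  nvox <- prod(shp)
  b0_mean <- array(0, shp)
  for (i in b0_idx) b0_mean <- b0_mean + dwi$volumes[, , , i]
  b0_mean <- b0_mean / max(1L, length(b0_idx))
  dw_mat <- matrix(dwi$volumes[, , , dw_idx], nvox, length(dw_idx))
  implausible <- array(apply(dw_mat > as.vector(b0_mean), 1, any), shp)
  std_map <- array(apply(dw_mat, 1, stats::sd), shp)
  list(residuals = fit$residuals,
       std_across_volumes = std_map,
       implausible_mask = implausible)
}
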