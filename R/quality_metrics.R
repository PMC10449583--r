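#' Noise SD from b0 pair differences
#'
#' For every unordered pair of b0 volumes the difference map is formed; the
#' variance of all difference values pooled within the mask, halved, is the
#' per-image noise variance (the difference of two i.i.d. images has twice
#' the single-image variance). Averaging the raw pair differences themselves
#' would cancel to zero, so the pooled-variance reading is used instead,
#' with the factor-of-two correction exposed as a flag.
#'
#' @param b0s list of 3D arrays (or [dwi_volume()]s), or a 4D array of b0
#'   volumes; at least 2.
#' @param mask logical array with at least 2 voxels.
#' @param pair_correction divide the pooled difference variance by 2
#'   (default `TRUE`).
#' @return An object of class `noise_estimate` with fields `method`
#'   (`"b0_pairs"`), `sd`, `n_voxels`, `n_pairs`.
#' @export
estimate_noise_b0_pairs <- function(b0s, mask = NULL, pair_correction = TRUE) {
  if (is.array(b0s) && length(dim(b0s)) == 4L)
    b0s <- lapply(seq_len(dim(b0s)[4]), function(i) b0s[, , , i])
  b0s <- lapply(b0s, function(v) if (inherits(v, "dwi_volume")) v$data else v)
  if (length(b0s) < 2L)
    stop("b0-pair noise estimation requires >= 2 b0 volumes", call. = FALSE)
  shp <- dim(b0s[[1L]])
  if (is.null(mask)) mask <- array(TRUE, shp)
  vox <- which(mask)
  if (length(vox) < 2L) stop("mask must contain >= 2 voxels", call. = FALSE)
  diffs <- list()
  for (i in seq_along(b0s)[-length(b0s)])
    for (j in (i + 1L):length(b0s))
      diffs[[length(diffs) + 1L]] <- (b0s[[i]] - b0s[[j]])[vox]
  pooled <- unlist(diffs)
  v <- stats::var(pooled)
  if (pair_correction) v <- v / 2
  structure(list(method = "b0_pairs", sd = sqrt(v),
                 n_voxels = length(vox), n_pairs = length(diffs)),
            class = "noise_estimate")
}

#' @export
print.noise_estimate <- function(x, ...) {
  cat("<noise_estimate> method ", x$method, ", sd = ", signif(x$sd, 5),
      " (", x$n_voxels, " voxels)\n", sep = "")
  invisible(x)
}

otsu_threshold <- function(x, levels = 256L) {
  # standard between-class-variance maximization on a fixed-bin histogram
  rng <- range(x)
  if (diff(rng) == 0) stop("image is constant; cannot threshold", call. = FALSE)
  h <- graphics::hist(x, breaks = seq(rng[1], rng[2], length.out = levels + 1L),
                      plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sb2 <- rep(-Inf, length(p))
  sb2[valid] <- (mu_t * w0[valid] - mu[valid])^2 / (w0[valid] * w1[valid])
  mids[which.max(sb2)]
}

#' Background (air) mask of a b0 volume
#'
#' Foreground is found by an automatic histogram threshold (Otsu's
#' between-class-variance criterion — a surrogate for more elaborate
#' background-extraction schemes, and labelled as such in the estimate it
#' feeds); the background is the complement of the foreground dilated by
#' `dilate` voxels, minus an `edge_exclude`-voxel band at the field-of-view
#' boundary where readout artifacts live.
#'
#' @param b0 a [dwi_volume()] or 3D array (non-constant).
#' @param brain optional brain mask folded into the foreground.
#' @param dilate dilation margin in voxels (6-connectivity, default 3).
#' @param edge_exclude field-of-view edge band to drop (voxels, default 1).
#' @param min_voxels smallest acceptable background (default 100).
#' @return A logical 3D array.
#' @export
background_mask <- function(b0, brain = NULL, dilate = 3L, edge_exclude = 1L,
                            min_voxels = 100L) {
  arr <- if (inherits(b0, "dwi_volume")) b0$data else as.array(b0)
  thr <- otsu_threshold(as.vector(arr))
  fg <- arr > thr
  if (!is.null(brain)) fg <- fg | array(as.logical(brain), dim(arr))
  fg <- dilate_mask(fg, dilate)
  bg <- !fg
  if (edge_exclude > 0L) {
    d <- dim(bg)
    e <- edge_exclude
    keep <- array(FALSE, d)
    keep[(e + 1):(d[1] - e), (e + 1):(d[2] - e), (e + 1):(d[3] - e)] <- TRUE
    bg <- bg & keep
  }
  if (sum(bg) < min_voxels)
    stop(sprintf("background mask has only %d voxels (< %d): noise estimate would be unreliable",
                 sum(bg), min_voxels), call. = FALSE)
  bg
}

dilate_mask <- function(mask, iterations = 1L) {
  d <- dim(mask)
  for (it in seq_len(iterations)) {
    out <- mask
    out[-1, , ] <- out[-1, , ] | mask[-d[1], , ]
    out[-d[1], , ] <- out[-d[1], , ] | mask[-1, , ]
    out[, -1, ] <- out[, -1, ] | mask[, -d[2], ]
    out[, -d[2], ] <- out[, -d[2], ] | mask[, -1, ]
    out[, , -1] <- out[, , -1] | mask[, , -d[3]]
    out[, , -d[3]] <- out[, , -d[3]] | mask[, , -1]
    mask <- out
  }
  mask
}

#' Noise SD from the image background
#'
#' The SD of b0 intensities within a background (air) mask. In magnitude MR
#' images the background is Rayleigh-distributed, whose SD understates the
#' underlying Gaussian sigma by the factor `sqrt(2 - pi/2)`; the optional
#' correction divides it back out. The raw (uncorrected) SD is the default.
#'
#' @param b0 a [dwi_volume()] or 3D array.
#' @param bg_mask logical array, e.g. from [background_mask()].
#' @param rayleigh_correction apply `sd / sqrt(2 - pi/2)` (default `FALSE`).
#' @return A `noise_estimate` with method `"background"`.
#' @export
estimate_noise_background <- function(b0, bg_mask, rayleigh_correction = FALSE) {
  arr <- if (inherits(b0, "dwi_volume")) b0$data else as.array(b0)
  vox <- which(bg_mask)
  if (length(vox) < 2L) stop("background mask must contain >= 2 voxels", call. = FALSE)
  s <- stats::sd(arr[vox])
  if (rayleigh_correction) s <- s / sqrt(2 - pi / 2)
  structure(list(method = "background", sd = s, n_voxels = length(vox),
                 rayleigh_correction = rayleigh_correction),
            class = "noise_estimate")
}

#' Signal-to-noise ratio in a tissue region
#'
#' Mean b0 intensity within the tissue mask divided by the noise SD (from
#' either noise estimator).
#'
#' @param b0_mean mean-b0 [dwi_volume()] or 3D array.
#' @param noise a `noise_estimate`.
#' @param tissue non-empty logical mask.
#' @return A single number.
#' @export
snr <- function(b0_mean, noise, tissue) {
  arr <- if (inherits(b0_mean, "dwi_volume")) b0_mean$data else as.array(b0_mean)
  vox <- which(tissue)
  if (!length(vox)) stop("tissue mask is empty", call. = FALSE)
  if (!is.finite(noise$sd) || noise$sd <= 0)
    stop("noise SD is zero or undefined: SNR undefined", call. = FALSE)
  mean(arr[vox]) / noise$sd
}

#' Contrast-to-noise ratio between white and gray matter
#'
#' `|mean(WM) - mean(GM)| / sqrt(var(WM) + var(GM))` on the b0 (or any
#' scalar) image, with sample variances within each mask.
#'
#' @param b0_mean image as [dwi_volume()] or 3D array.
#' @param wm,gm non-empty, disjoint logical masks.
#' @return A single number.
#' @export
cnr <- function(b0_mean, wm, gm) {
  arr <- if (inherits(b0_mean, "dwi_volume")) b0_mean$data else as.array(b0_mean)
  if (!any(wm) || !any(gm)) stop("WM and GM masks must be non-empty", call. = FALSE)
  if (any(wm & gm)) stop("WM and GM masks overlap", call. = FALSE)
  xw <- arr[which(wm)]; xg <- arr[which(gm)]
  denom <- sqrt(stats::var(xw) + stats::var(xg))
  if (!is.finite(denom) || denom == 0)
    stop("zero within-tissue variance: CNR undefined", call. = FALSE)
  abs(mean(xw) - mean(xg)) / denom
}

#' Per-tissue SNR and WM/GM CNR report
#'
#' Computes the mean b0, estimates noise by b0 pairs when at least two b0
#' volumes exist (falling back to the background method otherwise, or when
#' requested) and reports SNR per tissue plus the WM-vs-GM CNR as a tidy
#' table.
#'
#' @param dwi a [dwi_series()].
#' @param masks a [tissue_masks()].
#' @param method `"auto"` (b0 pairs when available), `"b0_pairs"` or
#'   `"background"`.
#' @param rayleigh_correction passed to [estimate_noise_background()].
#' @return A data.frame with columns `measure`, `tissue`, `value`, `method`.
#' @export
qc_report <- function(dwi, masks, method = c("auto", "b0_pairs", "background"),
                      rayleigh_correction = FALSE) {
  method <- match.arg(method)
  b0_idx <- which(is_b0(dwi$gradients))
  if (!length(b0_idx)) stop("series contains no b0 volume", call. = FALSE)
  b0_mean <- extract_b0(dwi, "mean")
  if (method == "auto")
    method <- if (length(b0_idx) >= 2L) "b0_pairs" else "background"
  noise <- if (method == "b0_pairs") {
    b0_list <- lapply(b0_idx, function(i) dwi$volumes[, , , i])
    estimate_noise_b0_pairs(b0_list, masks$brain)
  } else {
    bg <- background_mask(b0_mean, masks$brain)
    estimate_noise_background(b0_mean, bg, rayleigh_correction)
  }
  rows <- lapply(c("wm", "gm", "csf"), function(t)
    data.frame(measure = "snr", tissue = t,
               value = snr(b0_mean, noise, masks[[t]]),
               method = noise$method, stringsAsFactors = FALSE))
  rows[[length(rows) + 1L]] <- data.frame(
    measure = "cnr", tissue = "wm_gm",
    value = cnr(b0_mean, masks$wm, masks$gm),
    method = "b0_contrast", stringsAsFactors = FALSE)
  do.call(rbind, rows)
}
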