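#' Contiguous groups of b0 volumes
#'
#' Interleaved b0 volumes anchor the drift-normalization scheme: each
#' contiguous run of b0 indices forms one group, summarized by its scalar
#' mean intensity.
#'
#' @param dwi a [dwi_series()] with at least one b0 volume.
#' @param mask optional logical array; scalar means are taken within it.
#' @return A data.frame of class `b0_groups` with columns `start`, `end`
#'   (1-based volume indices, inclusive), `center` (mean index) and `mean`
#'   (scalar mean intensity of the group's volumes).
#' @export
find_b0_groups <- function(dwi, mask = NULL) {
  b0 <- is_b0(dwi$gradients)
  if (!any(b0))
    stop("series contains no b0 volume (required for normalization and SNR)",
         call. = FALSE)
  r <- rle(b0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  starts <- starts[keep]; ends <- ends[keep]
  vox <- if (is.null(mask)) NULL else which(mask)
  means <- mapply(function(s, e) {
    v <- dwi$volumes[, , , s:e, drop = FALSE]
    if (is.null(vox)) mean(v)
    else mean(apply(v, 4, function(x) mean(x[vox])))
  }, starts, ends)
  out <- data.frame(start = starts, end = ends,
                    center = (starts + ends) / 2, mean = means)
  class(out) <- c("b0_groups", "data.frame")
  out
}

#' Extract b0 volume(s)
#'
#' The four extraction strategies offered to susceptibility-field estimation:
#' the first b0, all b0s, the mean over all b0s, or one mean per contiguous
#' b0 group.
#'
#' @param dwi a [dwi_series()].
#' @param strategy one of `"first"`, `"all"`, `"mean"`, `"series_means"`.
#' @return A single [dwi_volume()] (`first`, `mean`) or a list of them
#'   (`all`, `series_means`).
#' @export
extract_b0 <- function(dwi, strategy = c("first", "all", "mean", "series_means")) {
  strategy <- match.arg(strategy)
  b0_idx <- which(is_b0(dwi$gradients))
  if (!length(b0_idx)) stop("series contains no b0 volume", call. = FALSE)
  vol <- function(arr) dwi_volume(arr, dwi$voxel_size, dwi$affine)
  switch(strategy,
    first = vol(dwi$volumes[, , , b0_idx[1L]]),
    all = lapply(b0_idx, function(i) vol(dwi$volumes[, , , i])),
    mean = {
      acc <- array(0, dim(dwi$volumes)[1:3])
      for (i in b0_idx) acc <- acc + dwi$volumes[, , , i]
      vol(acc / length(b0_idx))
    },
    series_means = {
      grp <- find_b0_groups(dwi)
      lapply(seq_len(nrow(grp)), function(g) {
        idx <- grp$start[g]:grp$end[g]
        acc <- array(0, dim(dwi$volumes)[1:3])
        for (i in idx) acc <- acc + dwi$volumes[, , , i]
        vol(acc / length(idx))
      })
    })
}

#' Normalize signal drift against interleaved b0 groups
#'
#' Long acquisitions drift in intensity as gradients and RF coils heat up.
#' Every volume is rescaled to the scalar mean of the *first* b0 group (the
#' target T): volume t is multiplied by `T / R(t)`, where the reference R(t)
#' is piecewise-linear in volume index between the scalar means of the b0
#' groups bracketing t (`mode = "interpolate"`), or the nearest preceding /
#' following group mean alone (`mode = "before"` / `"after"`). Inside a b0
#' group R(t) is that group's own mean, so every output b0 group mean equals
#' T exactly; volumes before the first group or after the last use the
#' nearest group's mean. The operation is idempotent.
#'
#' @param dwi a [dwi_series()] with at least one b0 group.
#' @param mode reference construction; default `"interpolate"`.
#' @param mask optional mask for the group scalar means.
#' @return A drift-normalized [dwi_series()].
#' @export
normalize_b0_drift <- function(dwi, mode = c("interpolate", "before", "after"),
                               mask = NULL) {
  mode <- match.arg(mode)
  grp <- find_b0_groups(dwi, mask)
  target <- grp$mean[1L]
  nvol <- dim(dwi$volumes)[4L]
  ref <- numeric(nvol)
  for (t in seq_len(nvol)) {
    g_in <- which(grp$start <= t & t <= grp$end)
    if (length(g_in)) { ref[t] <- grp$mean[g_in[1L]]; next }
    before <- which(grp$end < t)
    after <- which(grp$start > t)
    before <- if (length(before)) max(before) else NA_integer_
    after <- if (length(after)) min(after) else NA_integer_
    ref[t] <- switch(mode,
      before = grp$mean[if (is.na(before)) after else before],
      after = grp$mean[if (is.na(after)) before else after],
      interpolate = {
        if (is.na(before)) grp$mean[after]
        else if (is.na(after)) grp$mean[before]
        else {
          t0 <- grp$end[before]; t1 <- grp$start[after]
          w <- (t - t0) / (t1 - t0)
          (1 - w) * grp$mean[before] + w * grp$mean[after]
        }
      })
  }
  if (any(ref <= 0))
    stop(sprintf("non-positive drift reference at volume(s) %s",
                 paste(which(ref <= 0), collapse = ", ")), call. = FALSE)
  out <- dwi$volumes
  for (t in seq_len(nvol)) out[, , , t] <- out[, , , t] * (target / ref[t])
  dwi_series(out, dwi$gradients, dwi$meta, dwi$voxel_size, dwi$affine)
}

#' Powder average (spherical mean) image
#'
#' Voxelwise mean over all diffusion-weighted (non-b0) volumes. Averaging
#' over gradient orientations yields an orientation-independent contrast that
#' separates WM from GM better than the b0 does, which is why it is the
#' preferred registration target; b0 volumes are excluded because they carry
#' no orientation and would dilute that contrast.
#'
#' @param dwi a [dwi_series()] with at least one diffusion-weighted volume.
#' @return A [dwi_volume()].
#' @export
powder_average <- function(dwi) {
  dw_idx <- which(!is_b0(dwi$gradients))
  if (!length(dw_idx))
    stop("series contains only b0 volumes; nothing to powder-average",
         call. = FALSE)
  acc <- array(0, dim(dwi$volumes)[1:3])
  for (i in dw_idx) acc <- acc + dwi$volumes[, , , i]
  dwi_volume(acc / length(dw_idx), dwi$voxel_size, dwi$affine)
}

fold_directions <- function(vecs, digits = 6L) {
  # canonical sign: first non-zero component positive (antipodal fold)
  v <- round(vecs, digits)
  for (j in seq_len(ncol(v))) {
    nz <- which(v[, j] != 0)
    if (length(nz) && v[nz[1L], j] < 0) v[, j] <- -v[, j]
  }
  v
}

count_unique_directions <- function(vecs, digits = 6L) {
  if (is.null(vecs) || ncol(vecs) == 0L) return(0L)
  v <- fold_directions(vecs, digits)
  nrow(unique(t(v)))
}

#' Group non-b0 volumes into shells
#'
#' One-dimensional clustering of the non-b0 b-values: sorted values are split
#' wherever the gap exceeds `tolerance`, and each cluster's center is the
#' mean of its members. The per-shell direction count folds antipodal vectors
#' together (g and -g probe the same diffusion direction).
#'
#' @param gradients a [gradient_table()].
#' @param tolerance maximum within-shell b-value gap (s/mm^2). Scanners jitter
#'   nominal b-values by a few s/mm^2, hence the non-zero default.
#' @return A data.frame of class `shell_table` with columns `center`,
#'   `n_volumes`, `n_directions`, plus a `members` attribute (list of volume
#'   index vectors) and `b0_indices` attribute.
#' @export
detect_shells <- function(gradients, tolerance = 50) {
  if (length(gradients) == 0L) stop("gradient table is empty", call. = FALSE)
  b0 <- is_b0(gradients)
  dw <- which(!b0)
  if (!length(dw)) {
    out <- data.frame(center = numeric(0), n_volumes = integer(0),
                      n_directions = integer(0))
  } else {
    ord <- dw[order(gradients$bvals[dw])]
    bv <- gradients$bvals[ord]
    new_shell <- c(TRUE, diff(bv) > tolerance)
    shell_id <- cumsum(new_shell)
    members <- split(ord, shell_id)
    out <- data.frame(
      center = vapply(members, function(i) mean(gradients$bvals[i]), 0),
      n_volumes = lengths(members),
      n_directions = vapply(members, function(i)
        count_unique_directions(gradients$bvecs[, i, drop = FALSE]), 0L))
    rownames(out) <- NULL
    attr(out, "members") <- unname(members)
  }
  attr(out, "b0_indices") <- which(b0)
  class(out) <- c("shell_table", "data.frame")
  out
}

#' Restrict shells to the DTI-valid b-value range
#'
#' The tensor model misrepresents the non-Gaussian signal observed at strong
#' diffusion weighting, so only shells up to `max_b` (default 1300 s/mm^2)
#' are used for the tensor fit; b0 volumes are always retained. Raising
#' `max_b` is possible but discouraged for in-vivo data.
#'
#' @param shells a [detect_shells()] result.
#' @param max_b highest admissible shell center (s/mm^2).
#' @return A filtered `shell_table`; errors if no shell survives.
#' @export
filter_shells_for_dti <- function(shells, max_b = 1300) {
  keep <- shells$center <= max_b
  if (!any(keep))
    stop(sprintf(
      "DTI not applicable: no shell at or below b = %g s/mm^2 (lowest shell: %g)",
      max_b, if (nrow(shells)) min(shells$center) else NA), call. = FALSE)
  out <- shells[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "members") <- attr(shells, "members")[keep]
  attr(out, "b0_indices") <- attr(shells, "b0_indices")
  class(out) <- c("shell_table", "data.frame")
  out
}

#' Compose the anatomical-to-diffusion transform
#'
#' Both the anatomical and the diffusion image are registered to a common
#' template; a final mid-space correction aligns the two template-space
#' images. The anatomical-to-diffusion mapping is the composition
#' `solve(t_dwi) %*% t_mid %*% t_t1w` (affine case).
#'
#' @param t_dwi 4x4 affine: diffusion space to template.
#' @param t_mid 4x4 affine: template-space correction between the registered
#'   anatomical and diffusion images.
#' @param t_t1w 4x4 affine: anatomical space to template.
#' @return A 4x4 affine matrix.
#' @export
compose_anat_to_dwi <- function(t_dwi, t_mid, t_t1w) {
  check_affine <- function(m, name) {
    m <- as.matrix(m)
    if (!all(dim(m) == c(4L, 4L)))
      stop(sprintf("%s must be 4x4", name), call. = FALSE)
    if (any(abs(m[4L, ] - c(0, 0, 0, 1)) > 1e-10))
      stop(sprintf("%s last row must be (0, 0, 0, 1)", name), call. = FALSE)
    if (abs(det(m)) < .Machine$double.eps)
      stop(sprintf("%s is singular", name), call. = FALSE)
    m
  }
  t_dwi <- check_affine(t_dwi, "t_dwi")
  t_mid <- check_affine(t_mid, "t_mid")
  t_t1w <- check_affine(t_t1w, "t_t1w")
  solve(t_dwi) %*% t_mid %*% t_t1w
}
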