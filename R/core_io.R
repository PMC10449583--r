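#' Gradient table
#'
#' Per-volume diffusion weightings (b-values, s/mm^2) and unit gradient
#' directions. Volumes whose b-value falls below `b0_threshold` are treated
#' as b0 (unweighted) volumes and their direction vectors are canonicalized
#' to exact zero.
#'
#' @param bvals numeric vector of b-values (s/mm^2, finite, >= 0).
#' @param bvecs 3 x N numeric matrix of gradient directions (one column per
#'   volume), or an N x 3 matrix which is transposed automatically.
#' @param b0_threshold b-values strictly below this (s/mm^2) mark b0 volumes.
#'   Scanners often report small residual b-values for unweighted volumes, so
#'   the default is 50 rather than 0.
#' @return An object of class `gradient_table` with fields `bvals` (length N),
#'   `bvecs` (3 x N), and `b0_threshold`.
#' @export
gradient_table <- function(bvals, bvecs, b0_threshold = 50) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != 3L && ncol(bvecs) == 3L) bvecs <- t(bvecs)
  if (nrow(bvecs) != 3L)
    stop("bvecs must be 3 x N or N x 3", call. = FALSE)
  if (length(bvals) != ncol(bvecs))
    stop(sprintf("gradient table length mismatch: %d b-values but %d directions",
                 length(bvals), ncol(bvecs)), call. = FALSE)
  if (any(!is.finite(bvals)) || any(!is.finite(bvecs)))
    stop("gradient table contains non-finite values", call. = FALSE)
  if (any(bvals < 0))
    stop("b-values must be non-negative", call. = FALSE)
  nrm <- sqrt(colSums(bvecs^2))
  is_b0 <- bvals < b0_threshold
  # b0 volumes carry no orientation: canonicalize near-zero vectors to zero
  bvecs[, is_b0 & nrm < 0.5] <- 0
  nrm <- sqrt(colSums(bvecs^2))
  bad <- !is_b0 & abs(nrm - 1) > 1e-3
  if (any(bad))
    stop(sprintf("gradient direction(s) %s not unit-norm",
                 paste(which(bad), collapse = ", ")), call. = FALSE)
  # renormalize within tolerance so downstream dot products are exact
  nz <- nrm > 0
  bvecs[, nz] <- sweep(bvecs[, nz, drop = FALSE], 2, nrm[nz], "/")
  structure(list(bvals = bvals, bvecs = bvecs, b0_threshold = b0_threshold),
            class = "gradient_table")
}

#' @export
print.gradient_table <- function(x, ...) {
  cat("<gradient_table> ", length(x$bvals), " volumes (",
      sum(is_b0(x)), " b0, threshold ", x$b0_threshold, " s/mm^2)\n", sep = "")
  invisible(x)
}

#' @export
length.gradient_table <- function(x) length(x$bvals)

#' Which volumes are b0?
#'
#' @param gtab a `gradient_table`.
#' @return Logical vector, one element per volume.
#' @export
is_b0 <- function(gtab) gtab$bvals < gtab$b0_threshold

parse_numeric_text <- function(txt, what) {
  if (length(txt) == 1L && file.exists(txt)) txt <- readLines(txt, warn = FALSE)
  vals <- suppressWarnings(lapply(strsplit(txt, "[[:space:]]+"), function(x) {
    x <- x[nzchar(x)]
    as.numeric(x)
  }))
  vals <- vals[lengths(vals) > 0L]
  if (any(vapply(vals, function(v) any(is.na(v)), logical(1))))
    stop(sprintf("%s: non-numeric token", what), call. = FALSE)
  vals
}

#' Read FSL-convention bvals/bvecs text
#'
#' `bvals` is one row (or column) of N whitespace-separated numbers; `bvecs`
#' is either 3 rows of N entries (row-per-axis, the FSL layout) or N rows of
#' 3 entries. The layout is auto-detected from the shape; a 3 x 3 file is
#' taken as row-per-axis.
#'
#' @param bvals,bvecs file paths or character vectors of lines.
#' @inheritParams gradient_table
#' @return A validated [gradient_table()].
#' @export
read_gradient_table <- function(bvals, bvecs, b0_threshold = 50) {
  bv <- parse_numeric_text(bvals, "bvals")
  bvals_num <- unlist(bv)
  rows <- parse_numeric_text(bvecs, "bvecs")
  len <- unique(lengths(rows))
  if (length(len) != 1L)
    stop("bvecs rows have unequal lengths", call. = FALSE)
  m <- do.call(rbind, rows)
  if (nrow(m) == 3L) {
    vecs <- m                      # 3 x N (row-per-axis), includes 3 x 3
  } else if (ncol(m) == 3L) {
    vecs <- t(m)                   # N x 3
  } else {
    stop("bvecs must be 3 x N or N x 3", call. = FALSE)
  }
  gradient_table(bvals_num, vecs, b0_threshold = b0_threshold)
}

#' Write bvals/bvecs in the 3 x N row-per-axis dialect
#'
#' @param gtab a `gradient_table`.
#' @param bvals_path,bvecs_path output file paths.
#' @return `gtab`, invisibly.
#' @export
write_gradient_table <- function(gtab, bvals_path, bvecs_path) {
  writeLines(paste(format(gtab$bvals, trim = TRUE, scientific = FALSE),
                   collapse = " "), bvals_path)
  writeLines(apply(gtab$bvecs, 1L, function(r)
    paste(sprintf("%.10g", r), collapse = " ")), bvecs_path)
  invisible(gtab)
}

#' Acquisition metadata from a BIDS-style JSON sidecar
#'
#' Extracts the phase-encoding axis, total readout time and slice timing used
#' to configure susceptibility/eddy correction. Missing optional fields are
#' reported as `NA` (explicitly absent), never silently defaulted.
#'
#' @param phase_encode_axis signed axis code: one of `"i"`, `"j"`, `"k"`,
#'   optionally suffixed `"-"` (e.g. `"j-"`), or `NA`.
#' @param total_readout_time seconds (> 0), or `NA`.
#' @param slice_timing optional numeric vector of slice acquisition times, or `NA`.
#' @return An object of class `acquisition_metadata`.
#' @export
acquisition_metadata <- function(phase_encode_axis = NA_character_,
                                 total_readout_time = NA_real_,
                                 slice_timing = NULL) {
  if (!is.na(phase_encode_axis) &&
      !grepl("^[ijk]-?$", phase_encode_axis))
    stop(sprintf("unrecognized phase-encoding axis code '%s'", phase_encode_axis),
         call. = FALSE)
  total_readout_time <- as.numeric(total_readout_time)
  if (!is.na(total_readout_time) && total_readout_time <= 0)
    stop("total readout time must be positive", call. = FALSE)
  structure(list(
    phase_encode_axis = phase_encode_axis,
    phase_encode_sign = if (is.na(phase_encode_axis)) NA_integer_
                        else if (endsWith(phase_encode_axis, "-")) -1L else 1L,
    total_readout_time = total_readout_time,
    slice_timing = if (is.null(slice_timing)) NULL else as.numeric(slice_timing)),
    class = "acquisition_metadata")
}

#' Read a JSON sidecar
#'
#' Field names follow the keys emitted by common DICOM converters
#' (`PhaseEncodingDirection`, `TotalReadoutTime`, `SliceTiming`); unknown keys
#' are preserved in the `extra` attribute but otherwise ignored.
#'
#' @param json a file path or a JSON string.
#' @return An [acquisition_metadata()] object.
#' @export
read_sidecar <- function(json) {
  obj <- tryCatch(jsonlite::fromJSON(json, simplifyVector = TRUE),
                  error = function(e)
                    stop("malformed sidecar JSON: ", conditionMessage(e),
                         call. = FALSE))
  if (!is.list(obj))
    stop("sidecar JSON must be an object", call. = FALSE)
  known <- c("PhaseEncodingDirection", "TotalReadoutTime", "SliceTiming")
  meta <- acquisition_metadata(
    phase_encode_axis = if (is.null(obj$PhaseEncodingDirection)) NA_character_
                        else as.character(obj$PhaseEncodingDirection),
    total_readout_time = if (is.null(obj$TotalReadoutTime)) NA_real_
                         else obj$TotalReadoutTime,
    slice_timing = obj$SliceTiming)
  attr(meta, "extra") <- obj[setdiff(names(obj), known)]
  meta
}

#' Write a JSON sidecar
#'
#' @param meta an `acquisition_metadata`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sidecar <- function(meta, path) {
  obj <- list()
  if (!is.na(meta$phase_encode_axis))
    obj$PhaseEncodingDirection <- meta$phase_encode_axis
  if (!is.na(meta$total_readout_time))
    obj$TotalReadoutTime <- meta$total_readout_time
  if (!is.null(meta$slice_timing))
    obj$SliceTiming <- meta$slice_timing
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' 4D diffusion-weighted series
#'
#' @param volumes numeric 4D array (x, y, z, volume), finite and >= 0.
#' @param gradients a [gradient_table()] whose length matches the 4th dimension.
#' @param meta an [acquisition_metadata()] (optional).
#' @param voxel_size,affine spatial geometry, as for [dwi_volume()].
#' @return An object of class `dwi_series`.
#' @export
dwi_series <- function(volumes, gradients, meta = acquisition_metadata(),
                       voxel_size = c(1, 1, 1), affine = NULL) {
  volumes <- as.array(volumes)
  if (length(dim(volumes)) != 4L)
    stop("volumes must be a 4D array", call. = FALSE)
  if (!inherits(gradients, "gradient_table"))
    stop("gradients must be a gradient_table", call. = FALSE)
  if (dim(volumes)[4L] != length(gradients))
    stop(sprintf("series has %d volumes but gradient table has %d entries",
                 dim(volumes)[4L], length(gradients)), call. = FALSE)
  if (any(!is.finite(volumes)) || any(volumes < 0))
    stop("intensities must be finite and non-negative", call. = FALSE)
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (is.null(affine)) affine <- diag(c(voxel_size, 1))
  structure(list(volumes = volumes, gradients = gradients, meta = meta,
                 voxel_size = voxel_size, affine = as.matrix(affine)),
            class = "dwi_series")
}

#' @export
print.dwi_series <- function(x, ...) {
  d <- dim(x$volumes)
  cat("<dwi_series> ", paste(d[1:3], collapse = " x "), " voxels, ",
      d[4L], " volumes (", sum(is_b0(x$gradients)), " b0)\n", sep = "")
  invisible(x)
}

#' Binary tissue masks on a common grid
#'
#' @param wm,gm,csf logical 3D arrays of one shape, pairwise disjoint.
#' @param brain optional logical array; must contain the union of the tissue
#'   masks. Defaults to that union.
#' @return An object of class `tissue_masks`.
#' @export
tissue_masks <- function(wm, gm, csf, brain = NULL) {
  wm <- array(as.logical(wm), dim(wm))
  gm <- array(as.logical(gm), dim(gm))
  csf <- array(as.logical(csf), dim(csf))
  if (!identical(dim(wm), dim(gm)) || !identical(dim(wm), dim(csf)))
    stop("tissue masks must share one shape", call. = FALSE)
  if (any(wm & gm) || any(wm & csf) || any(gm & csf))
    stop("tissue masks must be pairwise disjoint", call. = FALSE)
  union <- wm | gm | csf
  if (is.null(brain)) brain <- union
  brain <- array(as.logical(brain), dim(brain))
  if (!identical(dim(brain), dim(wm)))
    stop("brain mask shape differs from tissue masks", call. = FALSE)
  if (any(union & !brain))
    stop("tissue masks must lie inside the brain mask", call. = FALSE)
  structure(list(wm = wm, gm = gm, csf = csf, brain = brain),
            class = "tissue_masks")
}

#' Study layout: site / vendor / subject / session hierarchy
#'
#' A flat table with one row per session. Every session belongs to exactly one
#' subject, every subject to exactly one site, and every site carries exactly
#' one vendor label.
#'
#' @param site,vendor,subject,session character vectors of one length.
#' @param path optional per-session directory or key for metric maps.
#' @return A `data.frame` of class `study_layout`.
#' @export
study_layout <- function(site, vendor, subject, session, path = NA_character_) {
  df <- data.frame(site = as.character(site), vendor = as.character(vendor),
                   subject = as.character(subject),
                   session = as.character(session),
                   path = as.character(path), stringsAsFactors = FALSE)
  if (anyDuplicated(df[c("site", "subject", "session")]))
    stop("duplicate (site, subject, session) rows", call. = FALSE)
  # one vendor per site
  sv <- unique(df[c("site", "vendor")])
  if (anyDuplicated(sv$site))
    stop("a site maps to more than one vendor", call. = FALSE)
  # a subject id may not appear under two sites
  ss <- unique(df[c("site", "subject")])
  if (anyDuplicated(ss$subject))
    stop("a subject appears under more than one site", call. = FALSE)
  class(df) <- c("study_layout", "data.frame")
  df
}

#' Read / write a study layout config (YAML)
#'
#' Schema: `sites: {<site>: {vendor: <label>, subjects: {<subj>: {<sess>: <path>}}}}`.
#'
#' @param path YAML file path.
#' @return `read_study_layout` returns a [study_layout()].
#' @export
read_study_layout <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$sites)) stop("layout config has no 'sites' key", call. = FALSE)
  rows <- list()
  for (site in names(cfg$sites)) {
    sc <- cfg$sites[[site]]
    for (subj in names(sc$subjects)) {
      sess <- sc$subjects[[subj]]
      rows[[length(rows) + 1L]] <- data.frame(
        site = site, vendor = sc$vendor, subject = subj,
        session = names(sess),
        path = vapply(sess, function(p) if (is.null(p)) NA_character_ else as.character(p), ""),
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  study_layout(df$site, df$vendor, df$subject, df$session, df$path)
}

#' @rdname read_study_layout
#' @param layout a [study_layout()].
#' @export
write_study_layout <- function(layout, path) {
  sites <- list()
  for (site in unique(layout$site)) {
    ls <- layout[layout$site == site, ]
    subjects <- list()
    for (subj in unique(ls$subject)) {
      lss <- ls[ls$subject == subj, ]
      subjects[[subj]] <- as.list(stats::setNames(lss$path, lss$session))
    }
    sites[[site]] <- list(vendor = ls$vendor[1L], subjects = subjects)
  }
  yaml::write_yaml(list(sites = sites), path)
  invisible(path)
}

#' Stack of registered scalar metric maps
#'
#' All images share one grid; the index carries the study hierarchy. This is
#' the container the reliability (I2C2) and variability (CV) statistics
#' consume — both assume the maps are already registered to a common grid.
#'
#' @param images list of numeric 3D arrays of one shape.
#' @param index a [study_layout()] (or data.frame with columns site, vendor,
#'   subject, session), one row per image.
#' @param mask optional logical array restricting evaluation.
#' @return An object of class `metric_stack`.
#' @export
metric_stack <- function(images, index, mask = NULL) {
  if (length(images) == 0L)
    return(structure(list(images = list(), index = index[0, ], mask = mask),
                     class = "metric_stack"))
  if (nrow(index) != length(images))
    stop("index must have one row per image", call. = FALSE)
  shp <- dim(images[[1L]])
  ok <- vapply(images, function(im) identical(dim(im), shp), logical(1))
  if (!all(ok))
    stop(sprintf("image(s) %s are not on the common grid",
                 paste(which(!ok), collapse = ", ")), call. = FALSE)
  if (!is.null(mask)) {
    mask <- array(as.logical(mask), dim(mask))
    if (!identical(dim(mask), shp))
      stop("mask shape differs from images", call. = FALSE)
  }
  structure(list(images = images, index = as.data.frame(index), mask = mask),
            class = "metric_stack")
}

#' @export
print.metric_stack <- function(x, ...) {
  cat("<metric_stack> ", length(x$images), " images",
      if (length(x$images)) paste0(" on a ",
        paste(dim(x$images[[1]]), collapse = " x "), " grid"), "\n", sep = "")
  invisible(x)
}

#' @export
length.metric_stack <- function(x) length(x$images)

#' Load one metric's maps for every session of a study
#'
#' Reads `<path>/<metric_name>.nii[.gz]` for each session row of the layout
#' and enforces a common grid and affine — the CV/I2C2 statistics are only
#' meaningful on registered maps, so any mismatch is an error naming the
#' offending session.
#'
#' @param layout a [study_layout()] with per-session `path` entries.
#' @param metric_name file stem of the metric map (e.g. `"fa"`).
#' @param mask optional logical array passed to [metric_stack()].
#' @param affine_tol absolute tolerance for affine agreement.
#' @return A [metric_stack()].
#' @export
load_metric_stack <- function(layout, metric_name, mask = NULL, affine_tol = 1e-4) {
  if (nrow(layout) == 0L) return(metric_stack(list(), layout, mask))
  images <- vector("list", nrow(layout))
  ref_aff <- NULL; ref_dim <- NULL
  for (i in seq_len(nrow(layout))) {
    base <- file.path(layout$path[i], metric_name)
    f <- paste0(base, c(".nii.gz", ".nii"))
    f <- f[file.exists(f)][1L]
    if (is.na(f))
      stop(sprintf("no %s map for %s/%s/%s", metric_name,
                   layout$site[i], layout$subject[i], layout$session[i]),
           call. = FALSE)
    vol <- read_volume(f)
    if (is.null(ref_dim)) { ref_dim <- dim(vol$data); ref_aff <- vol$affine }
    if (!identical(dim(vol$data), ref_dim) ||
        !affines_match(vol$affine, ref_aff, affine_tol))
      stop(sprintf(
        "session %s/%s/%s is not on the common registered grid",
        layout$site[i], layout$subject[i], layout$session[i]), call. = FALSE)
    images[[i]] <- vol$data
  }
  metric_stack(images, layout, mask)
}
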