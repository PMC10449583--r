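#' Image intraclass correlation coefficient (I2C2)
#'
#' Test-retest reliability of image-valued measurements: one minus the ratio
#' of within-subject to total image variability,
#' \deqn{1 - \frac{\sum_s \sum_j \sum_v (I_{s,j}(v) - \bar I_s(v))^2 / \sum_s (N_s - 1)}
#'            {\sum_s \sum_j \sum_v (I_{s,j}(v) - \bar I(v))^2 / (N - 1)},}
#' where \eqn{\bar I_s} is subject s's mean image over its \eqn{N_s} sessions
#' and \eqn{\bar I} the grand mean image over all N sessions. Subjects with a
#' single session contribute to the total term only. 1 means perfectly
#' reproducible; 0 means within-subject variation as large as total.
#'
#' @param stack a [metric_stack()] with >= 2 subjects, at least one of which
#'   has >= 2 sessions.
#' @return A single number (<= 1). If all images are identical the
#'   within/total ratio is 0/0; the value is defined as 1 with a warning.
#' @export
i2c2 <- function(stack) {
  idx <- stack$index
  if (length(stack) < 2L || length(unique(idx$subject)) < 2L)
    stop("I2C2 requires >= 2 subjects", call. = FALSE)
  ns <- table(idx$subject)
  if (!any(ns >= 2L))
    stop("I2C2 requires at least one subject with >= 2 sessions", call. = FALSE)
  vox <- if (is.null(stack$mask)) seq_len(length(stack$images[[1L]]))
         else which(stack$mask)
  if (!length(vox)) stop("evaluation mask is empty", call. = FALSE)
  M <- vapply(stack$images, function(im) im[vox], numeric(length(vox)))
  grand <- rowMeans(M)
  ss_total <- sum((M - grand)^2)
  n_tot <- ncol(M)
  ss_within <- 0
  df_within <- 0
  for (s in names(ns)[ns >= 2L]) {
    cols <- which(idx$subject == s)
    sub_mean <- rowMeans(M[, cols, drop = FALSE])
    ss_within <- ss_within + sum((M[, cols, drop = FALSE] - sub_mean)^2)
    df_within <- df_within + (length(cols) - 1L)
  }
  ms_total <- ss_total / (n_tot - 1L)
  if (ms_total == 0) {
    warning("all images identical: I2C2 degenerate, returning 1", call. = FALSE)
    return(1)
  }
  ms_within <- ss_within / df_within
  1 - ms_within / ms_total
}

#' Coefficient of variation
#'
#' Sample SD (n - 1 denominator) over the mean of a group of per-image
#' scalar summaries. Scale-invariant for positive rescaling; undefined when
#' the mean is (near) zero.
#'
#' @param values numeric vector, length >= 2.
#' @param tol relative tolerance below which the mean counts as zero.
#' @return A single non-negative number.
#' @export
cv <- function(values, tol = 1e-12) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("CV requires >= 2 values", call. = FALSE)
  m <- mean(values)
  s <- stats::sd(values)
  if (abs(m) <= tol * max(1, s))
    stop("group mean is ~0: CV undefined", call. = FALSE)
  s / abs(m)
}

mask_summary <- function(image, vox) mean(image[vox])

#' Multi-level coefficient-of-variation report
#'
#' For every session image the metric is summarized by its mean within the
#' mask; the CV is then taken over four nested groupings:
#' \describe{
#'   \item{IS / MIS}{intra-subject: CV over a subject's repeated sessions;
#'     MIS is the mean of IS over subjects (only subjects with >= 2
#'     sessions).}
#'   \item{BS}{between-subject, per site, over session-averaged subjects.}
#'   \item{IV}{intra-vendor, over session-averaged subjects of that vendor's
#'     sites.}
#'   \item{BV}{between-vendor, over all session-averaged subjects.}
#' }
#' Session averaging precedes the BS/IV/BV levels so repetition noise does
#' not inflate the subject-level spread. A voxelwise mode (CV per voxel,
#' then averaged over the mask) is available for sensitivity analysis.
#'
#' @param stack a [metric_stack()]; its index must carry site, vendor,
#'   subject, session.
#' @param mask logical array; defaults to the stack's own mask, else the
#'   full grid.
#' @param metric,tissue labels copied into the output rows.
#' @param mode `"mask_mean"` (default) or `"voxelwise"`.
#' @return A data.frame with columns `level`, `group`, `metric`, `tissue`,
#'   `cv`, `n` (group size). Groups with < 2 members are skipped with a
#'   message.
#' @export
cv_report <- function(stack, mask = NULL, metric = "metric", tissue = "mask",
                      mode = c("mask_mean", "voxelwise")) {
  mode <- match.arg(mode)
  idx <- stack$index
  if (length(stack) < 1L) stop("empty metric stack", call. = FALSE)
  if (is.null(mask)) mask <- stack$mask
  vox <- if (is.null(mask)) seq_len(length(stack$images[[1L]]))
         else which(mask)
  if (!length(vox)) stop("evaluation mask is empty", call. = FALSE)
  M <- vapply(stack$images, function(im) im[vox], numeric(length(vox)))

  group_cv <- function(cols_list) {
    # cols_list: list of column index vectors, one per member (sessions of a
    # member are averaged first)
    if (mode == "mask_mean") {
      vals <- vapply(cols_list, function(cc)
        mean(colMeans(M[, cc, drop = FALSE])), 0)
      cv(vals)
    } else {
      member <- vapply(cols_list, function(cc)
        rowMeans(M[, cc, drop = FALSE]), numeric(length(vox)))
      mu <- rowMeans(member)
      s <- apply(member, 1, stats::sd)
      ok <- abs(mu) > 1e-12
      if (!any(ok)) stop("voxelwise CV undefined: zero means", call. = FALSE)
      mean(s[ok] / abs(mu[ok]))
    }
  }
  rows <- list()
  add <- function(level, group, value, n)
    rows[[length(rows) + 1L]] <<- data.frame(
      level = level, group = group, metric = metric, tissue = tissue,
      cv = value, n = n, stringsAsFactors = FALSE)

  # IS / MIS: per-subject over its sessions
  is_vals <- c()
  for (s in unique(idx$subject)) {
    cols <- which(idx$subject == s)
    if (length(cols) < 2L) next
    v <- group_cv(as.list(cols))
    add("IS", s, v, length(cols))
    is_vals <- c(is_vals, v)
  }
  if (length(is_vals)) add("MIS", "all", mean(is_vals), length(is_vals))

  subject_cols <- split(seq_len(nrow(idx)), idx$subject)
  subj_site <- vapply(subject_cols, function(cc) idx$site[cc[1L]], "")
  subj_vendor <- vapply(subject_cols, function(cc) idx$vendor[cc[1L]], "")

  for (site in unique(idx$site)) {
    members <- subject_cols[subj_site == site]
    if (length(members) < 2L) {
      message("BS-CV: site ", site, " has < 2 subjects, skipped")
      next
    }
    add("BS", site, group_cv(members), length(members))
  }
  for (vendor in unique(idx$vendor)) {
    members <- subject_cols[subj_vendor == vendor]
    if (length(members) < 2L) {
      message("IV-CV: vendor ", vendor, " has < 2 subjects, skipped")
      next
    }
    add("IV", vendor, group_cv(members), length(members))
  }
  if (length(subject_cols) >= 2L)
    add("BV", "all", group_cv(subject_cols), length(subject_cols))
  do.call(rbind, rows)
}

#' Session-separation diagnostic
#'
#' When repeated sessions cluster by acquisition time point rather than by
#' subject, a session effect dominates the repetitions. This diagnostic is a
#' one-way variance ratio on the per-image mask summaries grouped by session
#' index: between-session mean square over within-session mean square. Under
#' no session effect its expectation is about 1; values much larger than 1
#' reproduce the clustering-by-session signature.
#'
#' @param stack a [metric_stack()] whose sessions share index labels across
#'   subjects; subjects lacking the full session set are dropped (with a
#'   message).
#' @param mask evaluation mask (defaults to the stack's).
#' @return A single number: the F ratio. The between/within mean squares are
#'   attached as attributes.
#' @export
session_separation <- function(stack, mask = NULL) {
  idx <- stack$index
  sessions <- sort(unique(idx$session))
  if (length(sessions) < 2L)
    stop("session separation requires >= 2 session indices", call. = FALSE)
  if (is.null(mask)) mask <- stack$mask
  vox <- if (is.null(mask)) seq_len(length(stack$images[[1L]]))
         else which(mask)
  keep_subj <- names(which(tapply(idx$session, idx$subject,
                                  function(s) all(sessions %in% s))))
  if (length(keep_subj) < 2L)
    stop("session separation requires >= 2 subjects with all sessions",
         call. = FALSE)
  dropped <- setdiff(unique(idx$subject), keep_subj)
  if (length(dropped))
    message("session_separation: dropped incomplete subject(s) ",
            paste(dropped, collapse = ", "))
  rows <- which(idx$subject %in% keep_subj & idx$session %in% sessions)
  y <- vapply(rows, function(i) mask_summary(stack$images[[i]], vox), 0)
  g <- factor(idx$session[rows])
  fit <- stats::anova(stats::lm(y ~ g))
  ratio <- fit$`Mean Sq`[1L] / fit$`Mean Sq`[2L]
  attr(ratio, "ms_between") <- fit$`Mean Sq`[1L]
  attr(ratio, "ms_within") <- fit$`Mean Sq`[2L]
  ratio
}
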