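make_series <- function(bvals, values = NULL, grid = 4L) {
  n <- length(bvals)
  vecs <- matrix(0, 3, n)
  dw <- which(bvals > 0)
  if (length(dw)) vecs[, dw] <- sample_directions(length(dw), 1)
  if (is.null(values)) values <- rep(1, n)
  vols <- array(0, c(grid, grid, grid, n))
  for (i in seq_len(n)) vols[, , , i] <- values[i]
  dwi_series(vols, gradient_table(bvals, vecs))
}

test_that("b0 groups are contiguous runs in acquisition order", {
  bv <- c(0, 0, rep(1000, 10), 0, rep(1000, 10), 0)
  grp <- find_b0_groups(make_series(bv))
  expect_equal(grp$start, c(1L, 13L, 24L))
  expect_equal(grp$end, c(2L, 13L, 24L))

  all_b0 <- find_b0_groups(make_series(rep(0, 4)))
  expect_equal(nrow(all_b0), 1L)
  expect_equal(c(all_b0$start, all_b0$end), c(1L, 4L))

  expect_error(find_b0_groups(make_series(c(1000, 1000))), "no b0")
})

test_that("b0 extraction strategies agree with their definitions", {
  bv <- c(0, 1000, 0, 1000, 0)
  dwi <- make_series(bv, values = c(100, 50, 100, 50, 100))
  m <- extract_b0(dwi, "mean")
  expect_true(all(m$data == 100))
  expect_length(extract_b0(dwi, "all"), 3L)
  expect_length(extract_b0(dwi, "series_means"), 3L)
  # first equals all[[1]]
  expect_equal(extract_b0(dwi, "first")$data, extract_b0(dwi, "all")[[1]]$data)
  # series means on the 3-group example
  grp_means <- extract_b0(make_series(c(0, 0, rep(1000, 3), 0),
                                      values = c(90, 110, 1, 1, 1, 80)),
                          "series_means")
  expect_equal(vapply(grp_means, function(v) mean(v$data), 0), c(100, 80))
  expect_error(extract_b0(dwi, "bogus"))
})

test_that("drift normalization interpolates between bracketing b0 means", {
  # groups with means 100 (index 1) and 80 (index 11); DW at index 6
  vals <- c(100, rep(90, 9), 80)
  bv <- c(0, rep(1000, 9), 0)
  dwi <- make_series(bv, values = vals)
  out <- normalize_b0_drift(dwi)
  # halfway reference is (100 + 80) / 2 = 90 -> factor 100/90
  expect_equal(unique(as.vector(out$volumes[, , , 6])), 90 * 100 / 90,
               tolerance = 1e-12)
  # both b0 groups land exactly on the target
  expect_equal(unique(as.vector(out$volumes[, , , 11])), 100,
               tolerance = 1e-12)

  # no drift: identity
  flat <- make_series(c(0, 1000, 0), values = c(100, 50, 100))
  expect_equal(normalize_b0_drift(flat)$volumes, flat$volumes,
               tolerance = 1e-6)

  # before/after modes use a single bracketing group
  before <- normalize_b0_drift(dwi, mode = "before")
  expect_equal(unique(as.vector(before$volumes[, , , 6])), 90 * 100 / 100)
  after <- normalize_b0_drift(dwi, mode = "after")
  expect_equal(unique(as.vector(after$volumes[, , , 6])), 90 * 100 / 80)
})

test_that("drift normalization undoes a linear drift and is idempotent", {
  spec <- small_spec()
  tm <- make_phantom_masks(spec)
  g <- interleaved_scheme(12L, n_b0 = 4L)
  clean <- simulate_dwi(spec, g, noise_sd = 0, seed = 1, masks = tm)
  drifted <- simulate_dwi(spec, g, noise_sd = 0, drift = drift_spec(0.01),
                          seed = 1, masks = tm)
  restored <- normalize_b0_drift(drifted)
  rel <- abs(restored$volumes - clean$volumes) / pmax(clean$volumes, 1e-12)
  expect_lt(max(rel[clean$volumes > 0]), 1e-5)
  twice <- normalize_b0_drift(restored)
  expect_equal(twice$volumes, restored$volumes, tolerance = 1e-6)
})

test_that("powder average is the mean over non-b0 volumes only", {
  dwi <- make_series(c(0, 1000, 1000), values = c(9, 2, 4))
  expect_true(all(powder_average(dwi)$data == 3))
  one <- make_series(c(0, 1000), values = c(9, 5))
  expect_true(all(powder_average(one)$data == 5))
  expect_error(powder_average(make_series(c(0, 0))), "only b0")
})

test_that("powder average of isotropic tissue equals S0*exp(-b*MD) and is
           rotation/order invariant", {
  spec <- phantom_spec(grid_shape = c(12L, 12L, 12L),
                       radii = list(wm = 3, gm = 4, csf = 5))
  tm <- make_phantom_masks(spec)
  dirs <- sample_directions(20, 2)
  g <- gradient_table(c(0, rep(1000, 20)), cbind(0, dirs))
  dwi <- simulate_dwi(spec, g, noise_sd = 0, seed = 1, masks = tm)
  pa <- powder_average(dwi)
  # isotropic GM: every direction attenuates identically
  expect_equal(unique(pa$data[tm$gm]), spec$s0[["gm"]] * exp(-1000 * 0.8e-3),
               tolerance = 1e-9)
  # rotating the whole scheme changes nothing for isotropic voxels
  R <- dwivar:::random_rotation(9)
  g_rot <- gradient_table(g$bvals, cbind(0, R %*% dirs))
  pa_rot <- powder_average(simulate_dwi(spec, g_rot, noise_sd = 0, seed = 1,
                                        masks = tm))
  expect_equal(pa_rot$data[tm$gm], pa$data[tm$gm], tolerance = 1e-9)
  # volume order is irrelevant
  perm <- c(1, sample(2:21))
  g_perm <- gradient_table(g$bvals[perm], g$bvecs[, perm])
  dwi_perm <- dwi_series(dwi$volumes[, , , perm], g_perm)
  expect_equal(powder_average(dwi_perm)$data, pa$data, tolerance = 1e-12)
})

test_that("shell detection clusters b-values and partitions all volumes", {
  g <- gradient_table(c(0, rep(250, 6), rep(1000, 64)),
                      cbind(0, sample_directions(6, 1), sample_directions(64, 2)))
  sh <- detect_shells(g)
  expect_equal(sh$center, c(250, 1000))
  expect_equal(sh$n_directions, c(6L, 64L))

  single <- detect_shells(gradient_table(c(0, rep(1600, 60)),
                                         cbind(0, sample_directions(60, 1))))
  expect_equal(single$center, 1600)
  expect_equal(single$n_directions, 60L)

  # jittered b-values merge within tolerance
  gj <- gradient_table(c(995, 1000, 1005), sample_directions(3, 1))
  shj <- detect_shells(gj, tolerance = 50)
  expect_equal(nrow(shj), 1L)
  expect_equal(shj$center, 1000)

  # partition: every non-b0 index in exactly one shell
  members <- unlist(attr(sh, "members"))
  expect_setequal(members, which(!is_b0(g)))
  expect_equal(anyDuplicated(members), 0L)

  # antipodal pairs count as one direction
  v <- sample_directions(5, 1)
  ga <- gradient_table(rep(1000, 10), cbind(v, -v))
  expect_equal(detect_shells(ga)$n_directions, 5L)
})

test_that("the DTI shell filter enforces the b-value ceiling", {
  g3 <- gradient_table(c(0, rep(250, 6), rep(1000, 6), rep(2000, 6)),
                       cbind(0, sample_directions(6, 1), sample_directions(6, 2),
                             sample_directions(6, 3)))
  sh <- detect_shells(g3)
  kept <- filter_shells_for_dti(sh)
  expect_equal(kept$center, c(250, 1000))

  g1600 <- gradient_table(c(0, rep(1600, 10)),
                          cbind(0, sample_directions(10, 1)))
  sh1600 <- detect_shells(g1600)
  expect_error(filter_shells_for_dti(sh1600), "not applicable")
  raised <- filter_shells_for_dti(sh1600, max_b = 1600)
  expect_equal(raised$center, 1600)

  # all shells already below the ceiling: unchanged
  low <- detect_shells(gradient_table(c(rep(500, 6)), sample_directions(6, 1)))
  expect_equal(filter_shells_for_dti(low)$center, 500)
})

test_that("anatomical-to-diffusion composition matches the matrix product", {
  I4 <- diag(4)
  expect_equal(compose_anat_to_dwi(I4, I4, I4), I4)
  A <- rbind(cbind(dwivar:::random_rotation(1) * 1.1, c(3, -2, 1)), c(0, 0, 0, 1))
  expect_equal(compose_anat_to_dwi(A, I4, A), I4, tolerance = 1e-12)
  set.seed(42)
  for (k in 1:5) {
    mk <- function() rbind(cbind(matrix(stats::rnorm(9), 3) + diag(3) * 2,
                                 stats::rnorm(3)), c(0, 0, 0, 1))
    td <- mk(); tm_ <- mk(); tt <- mk()
    expect_equal(compose_anat_to_dwi(td, tm_, tt),
                 solve(td) %*% tm_ %*% tt, tolerance = 1e-10)
  }
  sing <- diag(c(1, 1, 0, 1)); sing[4, 4] <- 1
  expect_error(compose_anat_to_dwi(sing, I4, I4), "singular")
})
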