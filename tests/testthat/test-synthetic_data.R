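test_that("phantom masks are disjoint and match analytic ellipsoid volumes", {
  spec <- phantom_spec()          # 32^3, radii 8 / 11 / 14
  tm <- make_phantom_masks(spec)
  expect_true(all(c(sum(tm$wm), sum(tm$gm), sum(tm$csf)) > 0))
  expect_false(any(tm$wm & tm$gm) || any(tm$wm & tm$csf) || any(tm$gm & tm$csf))
  expect_true(all(tm$brain == (tm$wm | tm$gm | tm$csf)))

  # voxel counts vs continuous ellipsoid volumes, within discretization error
  vol_sphere <- function(r) 4 / 3 * pi * r^3
  # surface-voxel bound: shell of ~1 voxel around the surface
  for (case in list(list(n = sum(tm$wm), v = vol_sphere(8)),
                    list(n = sum(tm$wm) + sum(tm$gm), v = vol_sphere(11)),
                    list(n = sum(tm$brain), v = vol_sphere(14)))) {
    expect_lt(abs(case$n - case$v) / case$v, 0.1)
  }

  expect_error(phantom_spec(radii = list(wm = 10, gm = 8, csf = 14)), "nested")
  expect_warning(make_phantom_masks(
    phantom_spec(radii = list(wm = 0, gm = 8, csf = 14))), "empty")
  expect_error(phantom_spec(tensors = list(wm = diag(c(-1, 1, 1) * 1e-3),
                                           gm = diag(rep(1e-3, 3)),
                                           csf = diag(rep(1e-3, 3)))),
               "positive-definite")
})

test_that("direction sampling is deterministic, unit-norm and well spread", {
  d1 <- sample_directions(6, seed = 1)
  d2 <- sample_directions(6, seed = 1)
  expect_identical(d1, d2)
  expect_equal(sqrt(colSums(d1^2)), rep(1, 6), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(d1, sample_directions(6, seed = 2))))
  expect_equal(dim(sample_directions(1, 1)), c(3L, 1L))
  expect_error(sample_directions(0, 1), ">= 1")

  # minimum angular separation beats uniform-random sampling on average
  set.seed(7)
  rand_min <- replicate(100, {
    v <- matrix(stats::rnorm(3 * 64), 3)
    v <- sweep(v, 2, sqrt(colSums(v^2)), "/")
    ct <- abs(crossprod(v)); diag(ct) <- 0
    acos(pmin(1, max(ct))) * 180 / pi
  })
  fib_min <- attr(sample_directions(64, seed = 1), "min_angle")
  expect_gt(fib_min, mean(rand_min))
})

test_that("simulated signal matches the closed-form attenuation model", {
  spec <- small_spec()
  tm <- make_phantom_masks(spec)

  # b0, noiseless: exactly the S0 map
  g0 <- gradient_table(0, matrix(0, 3, 1))
  dwi0 <- simulate_dwi(spec, g0, noise_sd = 0, seed = 1, masks = tm)
  expect_equal(unique(dwi0$volumes[, , , 1][tm$wm]), spec$s0[["wm"]])
  expect_equal(unique(dwi0$volumes[, , , 1][tm$csf]), spec$s0[["csf"]])
  expect_true(all(dwi0$volumes[, , , 1][!tm$brain] == 0))

  # b=1000 along the WM principal axis: S0 * exp(-1.7)
  g1 <- gradient_table(c(0, 1000), cbind(c(0, 0, 0), c(1, 0, 0)))
  dwi1 <- simulate_dwi(spec, g1, noise_sd = 0, seed = 1, masks = tm)
  wm_sig <- unique(dwi1$volumes[, , , 2][tm$wm])
  expect_equal(wm_sig, spec$s0[["wm"]] * exp(-1.7), tolerance = 1e-9)
  # off-axis direction agrees with the quadratic-form oracle
  g2 <- gradient_table(1000, matrix(c(1, 1, 1) / sqrt(3)))
  dwi2 <- simulate_dwi(spec, g2, noise_sd = 0, seed = 1, masks = tm)
  expect_equal(unique(dwi2$volumes[, , , 1][tm$gm]),
               signal_oracle(spec$s0[["gm"]], spec$tensors$gm, 1000,
                             c(1, 1, 1) / sqrt(3)),
               tolerance = 1e-12)
})

test_that("background noise floor follows the Rayleigh mean", {
  spec <- phantom_spec(grid_shape = c(32L, 32L, 32L),
                       radii = list(wm = 4, gm = 5, csf = 6))
  tm <- make_phantom_masks(spec)
  sigma <- 5
  g <- gradient_table(0, matrix(0, 3, 1))
  dwi <- simulate_dwi(spec, g, noise_sd = sigma, seed = 11, masks = tm)
  bg <- dwi$volumes[, , , 1][!tm$brain]
  expect_gt(length(bg), 1e4)
  expect_equal(mean(bg), sigma * sqrt(pi / 2), tolerance = 0.02)
})

test_that("simulation is fully deterministic under a fixed seed", {
  spec <- small_spec()
  g <- interleaved_scheme(6L)
  a <- simulate_dwi(spec, g, noise_sd = 0.05, drift = drift_spec(0.01), seed = 5)
  b <- simulate_dwi(spec, g, noise_sd = 0.05, drift = drift_spec(0.01), seed = 5)
  expect_identical(a$volumes, b$volumes)
  c_ <- simulate_dwi(spec, g, noise_sd = 0.05, seed = 6)
  expect_false(identical(a$volumes, c_$volumes))
  expect_error(drift_factors(drift_spec(-0.5), 10), "positive")
})

test_that("metric study reproduces its hierarchical ground truth", {
  lay <- make_layout(sites = c("s1", "s2"), vendors = c("v1", "v2"),
                     subjects_per_site = c(3L, 3L),
                     sessions_per_subject = c(2L, 2L))
  # all SDs zero: every image equals the grand mean
  st0 <- simulate_metric_study(lay, variance_components(grand_mean = 2),
                               grid_shape = c(5L, 5L, 5L), seed = 1L)
  expect_true(all(vapply(st0$stack$images,
                         function(im) all(im == 2), logical(1))))

  # drawn effects are returned and actually present in the images
  vcs <- variance_components(site_sd = 1, subject_sd = 1, session_sd = 0.5,
                             voxel_sd = 0, grand_mean = 10)
  st <- simulate_metric_study(lay, vcs, grid_shape = c(4L, 4L, 4L), seed = 2L)
  idx <- st$stack$index
  for (i in seq_len(nrow(idx))) {
    expect_equal(mean(st$stack$images[[i]]),
                 10 + st$effects$site[[idx$site[i]]] +
                   st$effects$subject[[idx$subject[i]]] +
                   st$effects$session[[paste(idx$subject[i], idx$session[i],
                                             sep = "/")]],
                 tolerance = 1e-12)
  }
  # generated stack passes container validation (common grid)
  expect_s3_class(st$stack, "metric_stack")
})

test_that("site effects order the between-vendor above within-site spread", {
  lay <- make_layout(sites = c("s1", "s2", "s3"),
                     vendors = c("v1", "v1", "v2"),
                     subjects_per_site = c(4L, 4L, 4L),
                     sessions_per_subject = c(1L, 1L, 1L))
  hits <- 0L
  for (s in 1:20) {
    st <- simulate_metric_study(
      lay, variance_components(site_sd = 1, subject_sd = 0.05,
                               voxel_sd = 0.01, grand_mean = 5),
      grid_shape = c(4L, 4L, 4L), seed = s)
    tab <- cv_report(st$stack)
    bv <- tab$cv[tab$level == "BV"]
    bs <- tab$cv[tab$level == "BS"]
    if (bv > max(bs)) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})
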