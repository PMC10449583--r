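stack_from_values <- function(values_by_subject, grid = c(4L, 4L, 4L),
                              site = "s1", vendor = "v1") {
  # values_by_subject: list(subject = c(session values)); constant images
  rows <- list(); images <- list()
  for (subj in names(values_by_subject)) {
    vals <- values_by_subject[[subj]]
    for (k in seq_along(vals)) {
      rows[[length(rows) + 1L]] <- data.frame(
        site = site, vendor = vendor, subject = subj,
        session = sprintf("ses%02d", k), stringsAsFactors = FALSE)
      images[[length(images) + 1L]] <- array(vals[k], grid)
    }
  }
  metric_stack(images, do.call(rbind, rows))
}

test_that("I2C2 hits its boundary cases", {
  # identical sessions within each subject, subjects differ: exactly 1
  st <- stack_from_values(list(a = c(1, 1), b = c(2, 2), c = c(5, 5)))
  expect_equal(i2c2(st), 1)
  # all images identical: degenerate, 1 with a warning
  st_same <- stack_from_values(list(a = c(3, 3), b = c(3, 3)))
  expect_warning(v <- i2c2(st_same), "degenerate")
  expect_equal(v, 1)
  # guards
  st_one <- stack_from_values(list(a = c(1, 2)))
  expect_error(i2c2(st_one), "2 subjects")
  st_single <- stack_from_values(list(a = 1, b = 2))
  expect_error(i2c2(st_single), "2 sessions")
})

test_that("I2C2 recovers the intraclass correlation of the generator", {
  lay <- make_layout(sites = "s1", vendors = "v1", subjects_per_site = 20L,
                     sessions_per_subject = 3L)
  recover <- function(subject_sd, session_sd, seeds = 1:20) {
    mean(vapply(seeds, function(s) {
      st <- simulate_metric_study(
        lay, variance_components(subject_sd = subject_sd,
                                 session_sd = session_sd, voxel_sd = 0,
                                 grand_mean = 10),
        grid_shape = c(10L, 10L, 10L), seed = s)
      i2c2(st$stack)
    }, 0))
  }
  # sigma_b^2 / (sigma_b^2 + sigma_w^2)
  expect_equal(recover(2, 1), 0.8, tolerance = 0.05)
  expect_equal(recover(1, 1), 0.5, tolerance = 0.05)
  expect_equal(recover(0, 1), 0.0, tolerance = 0.05)
})

test_that("I2C2 is invariant to affine rescaling of all images", {
  lay <- make_layout(sites = "s1", vendors = "v1", subjects_per_site = 8L,
                     sessions_per_subject = 2L)
  st <- simulate_metric_study(lay, variance_components(subject_sd = 1,
                                                       session_sd = 0.5,
                                                       voxel_sd = 0.2,
                                                       grand_mean = 3),
                              grid_shape = c(6L, 6L, 6L), seed = 4)$stack
  base <- i2c2(st)
  for (ab in list(c(2.5, 0), c(-1, 7), c(0.01, -3))) {
    st2 <- st
    st2$images <- lapply(st$images, function(im) ab[1] * im + ab[2])
    expect_equal(i2c2(st2), base, tolerance = 1e-10)
  }
})

test_that("the CV is the sample SD over the mean, with guards", {
  expect_equal(cv(c(90, 100, 110)), 0.1)
  expect_equal(cv(c(7, 7, 7)), 0)
  expect_error(cv(5), ">= 2")
  expect_error(cv(c(-1, 1)), "undefined")
  # scale invariance
  set.seed(9)
  x <- stats::rnorm(50, 10, 2)
  for (a in c(0.5, 3, 100)) expect_equal(cv(a * x), cv(x), tolerance = 1e-12)
})

test_that("the CV report separates the four grouping levels", {
  # subject spread but no session noise: MIS ~ 0, BS > 0
  st <- stack_from_values(list(a = c(1, 1), b = c(2, 2), c = c(4, 4)))
  tab <- cv_report(st)
  expect_equal(tab$cv[tab$level == "MIS"], 0)
  expect_gt(tab$cv[tab$level == "BS"], 0.4)
  # BV equals BS for a single site
  expect_equal(tab$cv[tab$level == "BV"], tab$cv[tab$level == "BS"])

  # exchangeable sites: BV ~ IV ~ BS within Monte-Carlo error
  lay <- make_layout(sites = c("s1", "s2"), vendors = c("v1", "v2"),
                     subjects_per_site = c(30L, 30L),
                     sessions_per_subject = c(1L, 1L))
  devs <- replicate(20, NA_real_)
  for (s in 1:20) {
    stx <- simulate_metric_study(
      lay, variance_components(site_sd = 0, subject_sd = 0.5, voxel_sd = 0,
                               grand_mean = 10),
      grid_shape = c(4L, 4L, 4L), seed = s)$stack
    tt <- cv_report(stx)
    bv <- tt$cv[tt$level == "BV"]
    devs[s] <- max(abs(tt$cv[tt$level %in% c("BS", "IV")] - bv))
  }
  expect_lt(stats::median(devs), 0.05)

  # groups with < 2 members are skipped with a message
  lone <- stack_from_values(list(a = c(1, 2)))
  expect_message(tab_lone <- cv_report(lone), "skipped")
  expect_false("BS" %in% tab_lone$level)

  # voxelwise mode agrees with mask_mean on constant images
  st_const <- stack_from_values(list(a = c(1, 1), b = c(3, 3), c = c(5, 5)))
  t1 <- cv_report(st_const, mode = "mask_mean")
  t2 <- cv_report(st_const, mode = "voxelwise")
  expect_equal(t2$cv, t1$cv, tolerance = 1e-12)
})

test_that("session separation flags a shared session effect", {
  lay <- make_layout(sites = "s1", vendors = "v1", subjects_per_site = 10L,
                     sessions_per_subject = 2L)
  # null: i.i.d. summaries, F ratio ~ 1 in expectation
  ratios <- vapply(1:100, function(s) {
    st <- simulate_metric_study(
      lay, variance_components(subject_sd = 0, session_sd = 1, voxel_sd = 0,
                               grand_mean = 10),
      grid_shape = c(4L, 4L, 4L), seed = s)$stack
    as.numeric(session_separation(st))
  }, 0)
  # F(1, 18) under the null: mean 18/16 = 1.125, long right tail
  expect_gt(mean(ratios), 0.6)
  expect_lt(mean(ratios), 2)

  # a large additive offset on session 2 drives the ratio >> 1
  st <- simulate_metric_study(
    lay, variance_components(subject_sd = 0.1, session_sd = 0.01,
                             voxel_sd = 0, grand_mean = 10),
    grid_shape = c(4L, 4L, 4L), seed = 1)$stack
  ses2 <- which(st$index$session == "ses02")
  st$images[ses2] <- lapply(st$images[ses2], function(im) im + 5)
  expect_gt(as.numeric(session_separation(st)), 50)

  # single session: inapplicable
  one <- stack_from_values(list(a = 1, b = 2))
  expect_error(session_separation(one), ">= 2 session")

  # incomplete subjects are dropped, not mixed in
  mixed <- stack_from_values(list(a = c(1, 2), b = c(2, 3)))
  extra <- stack_from_values(list(c = 9), site = "s1")
  both <- metric_stack(c(mixed$images, extra$images),
                       rbind(mixed$index, extra$index))
  expect_message(session_separation(both), "dropped")
})

test_that("two identical runs produce bit-identical variability tables", {
  lay <- make_layout()
  run <- function() {
    st <- simulate_metric_study(lay, variance_components(site_sd = 0.1,
                                                         subject_sd = 0.1,
                                                         session_sd = 0.05,
                                                         voxel_sd = 0.05,
                                                         grand_mean = 1),
                                seed = 77L)$stack
    list(tab = cv_report(st), i2c2 = i2c2(st))
  }
  expect_identical(run(), run())
})
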