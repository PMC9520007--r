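test_that("resampling interpolates linearly onto the 0.1 um grid", {
  p <- resample_profile(data.frame(d = c(0, 0.2), v = c(10, 20)))
  expect_equal(p$distance, c(0, 0.1, 0.2))
  expect_equal(p$intensity[2], 15)

  # points already on the grid pass through unchanged
  d <- seq(0, 1, by = 0.1)
  q <- resample_profile(data.frame(d, v = d * 3))
  expect_equal(q$intensity, d * 3)

  expect_error(resample_profile(data.frame(d = 1, v = 1)), "two measured")
  expect_error(resample_profile(data.frame(d = c(1, 0.5), v = c(1, 2))),
               "strictly increasing")
})

test_that("image merging averages overlaps once and rejects gaps", {
  a <- intensity_profile(seq(0, 10, 0.1), rep(10, 101))
  b <- intensity_profile(seq(0, 10, 0.1), rep(20, 101))
  m <- merge_image_profiles(list(a, b), offsets = c(0, 5))
  expect_equal(profile_value_at(m, 2), 10)     # only image a
  expect_equal(profile_value_at(m, 7), 15)     # overlap: mean
  expect_equal(profile_value_at(m, 13), 20)    # only image b

  # merging two identical aligned profiles is the identity
  same <- merge_image_profiles(list(a, a))
  expect_equal(same$intensity, a$intensity)

  expect_error(merge_image_profiles(list(a, b), offsets = c(0, 20)), "gap")
})

test_that("peak finder returns the highest strict 5-um-window peak near the wall", {
  d <- seq(0, 120, by = 0.1)
  # monotone decay: boundary point is the peak, at 100%
  mono <- intensity_profile(d, 100 * exp(-d / 50), side = "cell_body")
  pk <- find_highest_peak(mono)
  expect_true(pk$found)
  expect_equal(pk$peak_distance, 0)
  expect_equal(pk$peak_normalized_intensity, 100)

  # local peak at 30 um at 60% of a global maximum at 80 um
  two <- intensity_profile(d, 60 * exp(-(d - 30)^2 / 8) +
                                100 * exp(-(d - 80)^2 / 8),
                           side = "cell_body")
  pk2 <- find_highest_peak(two)
  expect_equal(pk2$peak_distance, 30, tolerance = 1e-6)
  expect_equal(pk2$peak_normalized_intensity, 60, tolerance = 0.5)

  # a flat profile has no strict peak
  flat <- intensity_profile(d, rep(5, length(d)), side = "cell_body")
  expect_false(find_highest_peak(flat)$found)
})

test_that("cell-body QC applies the 85% rule inclusively", {
  d <- seq(0, 120, by = 0.1)
  mk <- function(h) intensity_profile(
    d, 100 * exp(-(d - 90)^2 / 8) + h * exp(-(d - 20)^2 / 8),
    side = "cell_body"
  )
  expect_equal(qc_cell_body(mk(90)), "pass")
  expect_equal(qc_cell_body(mk(70)), "damaged")
  expect_equal(qc_cell_body(mk(85)), "pass")    # boundary is inclusive
  # scaling invariance: QC uses normalized peaks only
  p <- mk(70)
  p$intensity <- p$intensity * 37
  expect_equal(qc_cell_body(p), "damaged")
  # short coverage cannot be judged
  short <- intensity_profile(seq(0, 60, 0.1), rep(10, 601),
                             side = "cell_body")
  expect_warning(expect_equal(qc_cell_body(short), "inconclusive"),
                 "less than 100")
})

test_that("normalization anchors the control mean at 100 um to 100", {
  d <- seq(0, 150, by = 0.1)
  ctrl1 <- intensity_profile(d, rep(40, length(d)))
  ctrl2 <- intensity_profile(d, rep(60, length(d)))
  smpl <- intensity_profile(d, rep(10, length(d)))
  out <- normalize_to_control(list(smpl), list(ctrl1, ctrl2))
  expect_equal(profile_value_at(out$control_mean, 100), 100)
  expect_equal(out$scale, 2)                     # anchored to mean 50
  expect_equal(out$profiles[[1]]$intensity[1], 20)

  # single control: the mean is itself
  one <- normalize_to_control(list(smpl), list(ctrl1))
  expect_equal(one$scale, 2.5)

  zero <- intensity_profile(d, rep(0, length(d)))
  expect_error(normalize_to_control(list(smpl), list(zero)), "positive")
})

test_that("reference distances invert the control decay exactly", {
  d <- seq(0, 420, by = 0.1)
  ctrl <- intensity_profile(d, 100 * exp(-(d - 100) / 200))
  refs <- find_reference_distances(ctrl)
  expect_equal(unname(refs["50"]), 100 + 200 * log(2), tolerance = 0.05)
  expect_equal(unname(refs["75"]), 100 + 200 * log(100 / 75),
               tolerance = 0.05)
  expect_true(refs["75"] < refs["50"] & refs["50"] < refs["25"])

  # monotone ordering holds for any strictly decreasing control
  set.seed(11)
  for (i in 1:10) {
    lam <- runif(1, 120, 400)
    ctrl_r <- intensity_profile(d, 100 * exp(-(d - 100) / lam))
    r <- find_reference_distances(ctrl_r)
    r <- r[!is.na(r)]
    expect_true(all(diff(r) > 0))
  }

  # plateau above 25%: that level is unavailable
  plateau <- intensity_profile(d, pmax(100 * exp(-(d - 100) / 200), 40))
  expect_true(is.na(find_reference_distances(plateau)["25"]))
})

test_that("Dixon screening removes at most the one suspect extreme", {
  expect_equal(dixon_outliers(c(10, 11, 12, 30)), 4L)   # Q = 0.9 > 0.765
  expect_equal(dixon_outliers(c(10, 11, 12, 13)), integer(0))
  expect_equal(dixon_outliers(c(10, 11, 30)), integer(0))   # n < 4: no-op
  expect_equal(dixon_outliers(rep(5, 6)), integer(0))       # zero range
  expect_equal(dixon_outliers(c(30, 12, 11, 10)), 1L)       # low/high symmetric
  expect_error(dixon_outliers(rnorm(40)), "up to 30")
})

test_that("knockdown classification follows the p-value bands", {
  # replicates exactly at the level: no effect
  m0 <- tibble::tibble(gene = "g", level = rep(c(75, 50, 25), each = 3),
                       normalized_intensity = rep(c(75, 50, 25), each = 3))
  r0 <- knockdown_test(m0)
  expect_equal(r0$classification, "none")
  expect_equal(r0$p_50, 1)

  # strong inhibition at the 50 level; p matches the closed form
  x <- c(30, 32, 31, 29)
  m1 <- tibble::tibble(gene = "g", level = 50, normalized_intensity = x)
  r1 <- knockdown_test(m1)
  expect_equal(r1$classification, "significant")
  expect_equal(r1$direction, "inhibit")
  expect_equal(r1$p_50, one_sample_t_p(x, 50), tolerance = 1e-12)

  # borderline: min p in (0.05, 0.1] -> may_influence
  m2 <- tibble::tibble(
    gene = "g", level = rep(c(75, 50, 25), each = 3),
    normalized_intensity = c(75, 75, 75, 44, 46, 48, 25, 25, 25)
  )
  r2 <- knockdown_test(m2)
  expect_gt(r2$p_50, 0.05)
  expect_lte(r2$p_50, 0.1)
  expect_equal(r2$classification, "may_influence")

  # too few replicates everywhere: undetermined
  thin <- tibble::tibble(gene = "g", level = 50, normalized_intensity = 40)
  expect_equal(knockdown_test(thin)$classification, "undetermined")
})

test_that("the screen is invariant to a global intensity rescaling", {
  pr <- synth_profiles(profile_spec(genes = c(KD1 = 0.6, NULL1 = 1),
                                    n_experiments = 3), seed = 31)
  scr <- nog_screen(pr$experiments)
  scaled <- pr$experiments
  for (e in seq_along(scaled)) {
    scaled[[e]]$controls <- lapply(scaled[[e]]$controls, function(p) {
      p$intensity <- p$intensity * 3.7; p
    })
    scaled[[e]]$samples <- lapply(scaled[[e]]$samples, function(l) {
      lapply(l, function(p) { p$intensity <- p$intensity * 3.7; p })
    })
  }
  scr2 <- nog_screen(scaled)
  expect_equal(scr$results$p_50, scr2$results$p_50, tolerance = 1e-9)
  expect_equal(scr$results$classification, scr2$results$classification)
})

test_that("damage propagation drops chambers, controls and thin genes", {
  # every control of every experiment damaged -> screen yields nothing
  pr <- synth_profiles(profile_spec(
    genes = c(KD1 = 0.6), n_experiments = 2, controls_per_experiment = 1,
    damaged = "control1"
  ), seed = 32)
  scr <- nog_screen(pr$experiments)
  expect_equal(nrow(scr$measurements), 0)
  expect_true(all(scr$qc$status[grepl("control", scr$qc$chamber)] ==
                    "damaged"))
})

test_that("without outlier pruning the one-sample t-test is calibrated", {
  # isolates the known inflation of the screen-then-test procedure: on
  # null knockdowns the plain t-test at each reference level rejects at
  # about the nominal rate, while Dixon pruning at n = 4 inflates it
  p_raw <- c()
  for (s in 1:100) {
    genes <- stats::setNames(rep(1, 4), sprintf("N%d", 1:4))
    pr <- synth_profiles(profile_spec(genes = genes), seed = 110000 + s)
    scr <- nog_screen(pr$experiments)
    raw <- scr$measurements |>
      dplyr::group_by(.data$gene, .data$level) |>
      dplyr::summarise(
        p = one_sample_t_p(.data$normalized_intensity, .data$level[1]),
        .groups = "drop"
      )
    p_raw <- c(p_raw, raw$p)
  }
  expect_lte(mean(p_raw <= 0.05), 0.095)
  expect_gte(mean(p_raw <= 0.05), 0.015)
})
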