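test_that("MRI volume converts to fat mass at 0.9 g/cm3", {
  expect_equal(fm_from_volume(0), 0)
  expect_equal(fm_from_volume(100), 90)
  expect_equal(fm_from_volume(50), 45)
  expect_error(fm_from_volume(-1), ">= 0")
})

test_that("composition interpolates linearly between imaging sessions", {
  comp <- tibble::tibble(day = c(0, 21), ffm_g = c(250, 260),
                         fm_g = c(30, 30))
  expect_equal(interpolate_composition(comp, 0),
               list(ffm_g = 250, fm_g = 30))
  expect_equal(interpolate_composition(comp, 7)$ffm_g, 253.3333,
               tolerance = 1e-4)
  expect_equal(interpolate_composition(comp, 15)$fm_g, 30)
  expect_error(interpolate_composition(comp, 25), "extrapolate")
})

test_that("interpolation validation regression behaves as an identity check", {
  bw <- seq(250, 350, length.out = 20)
  v <- validate_interpolation(bw, bw)
  expect_equal(v$slope, 1)
  expect_equal(v$r_squared, 1)
  v2 <- validate_interpolation(bw * 1.1, bw)
  expect_equal(v2$slope, 1.1, tolerance = 1e-9)
  expect_error(validate_interpolation(c(1, 2), c(1, 2)), "3 paired")
})

test_that("interpolated FFM+FM tracks measured BW in generated cohorts", {
  coh <- generate_cohort(cohort_config(n_rats = 24, seed = 3))
  pred <- meas <- numeric(0)
  for (i in seq_len(nrow(coh$sessions))) {
    id <- coh$sessions$rat_id[i]; d <- coh$sessions$day[i]
    comp <- coh$composition[coh$composition$rat_id == id &
                              coh$composition$mri_session %in% c(1, 2), ]
    bc <- interpolate_composition(comp, d)
    pred <- c(pred, bc$ffm_g + bc$fm_g)
    meas <- c(meas, coh$bodyweight$bw_g[coh$bodyweight$rat_id == id &
                                          coh$bodyweight$day == d])
  }
  v <- validate_interpolation(pred, meas)
  expect_gt(v$slope, 0.98)
  expect_lt(v$slope, 1.02)
  expect_gt(v$r_squared, 0.98)
})

test_that("median split halves an even cohort, with stable tie handling", {
  cl <- classify_cohort(c(1, 2, 3, 4), paste0("r", 1:4))
  expect_equal(as.character(cl$class), c("resistant", "resistant",
                                         "sensitive", "sensitive"))
  g <- rnorm(24)
  cl24 <- classify_cohort(g, sprintf("R%02d", 1:24), labels = c("CR", "CS"))
  expect_equal(unname(table(cl24$class)["CR"]), 12, ignore_attr = TRUE)
  expect_equal(unname(table(cl24$class)["CS"]), 12, ignore_attr = TRUE)
  # degenerate: all equal still yields an exact split, by stable id order
  expect_warning(cl_eq <- classify_cohort(rep(1, 24), sprintf("R%02d", 1:24)),
                 "tie")
  expect_equal(sum(cl_eq$class == "sensitive"), 12)
  expect_error(classify_cohort(c(1, 2, 3), 1:3), "even")
})

test_that("classification is invariant under strictly monotone transforms", {
  set.seed(42)
  for (rep in 1:10) {
    g <- rnorm(12)
    base <- classify_cohort(g, 1:12)$class
    expect_equal(classify_cohort(exp(g), 1:12)$class, base)
    expect_equal(classify_cohort(g^3 + 5 * g, 1:12)$class, base)
  }
})

test_that("fat-distribution stats: medians, half-IQR and paired Wilcoxon", {
  r <- tibble::tibble(
    rat_id = rep(paste0("r", 1:5), 2),
    timepoint = rep(c("a", "b"), each = 5),
    ratio = c(1, 2, 3, 4, 5, 1, 2, 3, 4, 5))
  fd <- fat_distribution_stats(r)
  expect_equal(unname(fd$summary$median), c(3, 3))
  expect_equal(unname(fd$summary$half_iqr), c(1, 1))  # type-7 quartiles: 2, 4
  expect_equal(fd$tests$p_value, 1)           # identical paired samples
  r_shift <- r
  r_shift$ratio[r_shift$timepoint == "b"] <- r_shift$ratio[1:5] + 2
  fd2 <- fat_distribution_stats(r_shift)
  expect_lt(fd2$tests$p_value, 0.1)
  expect_error(fat_distribution_stats(r[-1, ]), "unpaired")
})

test_that("adiposity helpers respect their definitions", {
  expect_equal(adiposity_pct(30, 300), 10)
  # adiposity strictly increases with FM at fixed BW
  expect_gt(adiposity_pct(40, 300), adiposity_pct(30, 300))
  expect_error(adiposity_pct(10, 0), "positive")
})
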