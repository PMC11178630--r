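fake_records <- function(fired, hit, ccl = ifelse(hit, 5, 0),
                         x = seq_along(fired), y = seq_along(fired)) {
  data.frame(step = seq_along(fired), i = 7L, j = 7L, x_mm = x, y_mm = y,
             depth_label = "apex", fired = fired, hit = hit,
             inside_gland = fired, ccl_mm = ccl,
             reward = ifelse(!fired, -1, ifelse(hit, 10, -2)))
}

test_that("hit rate is hits over fired needles", {
  r <- fake_records(fired = rep(TRUE, 5), hit = c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(hit_rate(r), 0.4)
  expect_equal(hit_rate(fake_records(rep(TRUE, 3), rep(TRUE, 3))), 1.0)
  expect_equal(hit_rate(fake_records(rep(TRUE, 3), rep(FALSE, 3))), 0.0)
  expect_warning(hr <- hit_rate(fake_records(rep(FALSE, 4), rep(FALSE, 4))),
                 "no fired")
  expect_true(is.nan(hr))
})

test_that("N.CCL uses the five-needle maximal chord denominator", {
  # lesion with a 10 mm maximal needle-axis chord
  r5 <- fake_records(rep(TRUE, 5), rep(TRUE, 5), ccl = rep(10, 5))
  expect_equal(n_ccl(r5, max_chord_mm = 10), 1.0)
  r1 <- fake_records(rep(TRUE, 5), c(TRUE, rep(FALSE, 4)),
                     ccl = c(10, 0, 0, 0, 0))
  expect_equal(n_ccl(r1, max_chord_mm = 10), 0.2)
  expect_equal(n_ccl(r1, max_chord_mm = 10, normalization = "single"), 1.0)
  expect_equal(ccl_total(r1), 10)
  expect_equal(n_ccl(fake_records(rep(TRUE, 3), rep(FALSE, 3)),
                     max_chord_mm = 10), 0)
})

test_that("raster N.CCL of five diametral needles is 1 within tolerance", {
  ph <- sphere_case(lesion_radius = 8, gland_radii = c(24, 20, 20),
                    shape = c(65, 65, 49))
  # five needles through the centre column at full lesion depth
  d <- dim(ph$lesion$voxels)
  cen <- round(mask_centroid(ph$lesion)) + 1
  vox <- array(0L, dim = d); vox[cen[1], cen[2], ] <- 1L
  traj <- mask_volume(vox, ph$lesion$spacing, ph$lesion$origin)
  ccl1 <- intersection_length(traj, ph$lesion)
  recs <- fake_records(rep(TRUE, 5), rep(TRUE, 5), ccl = rep(ccl1, 5))
  val <- n_ccl(recs, max_chord_mm = max_axis_chord_mm(ph$lesion))
  expect_lt(abs(val - 1), 0.1)
})

test_that("N.Coverage reproduces the printed formula on the hand example", {
  r <- fake_records(rep(TRUE, 5), rep(TRUE, 5),
                    x = c(-5, 5, 0, 0, 0), y = c(0, 0, -5, 5, 0))
  got <- n_coverage(r, area_mm2 = 100)
  expect_equal(got, sqrt(10) * sqrt(10) * pi / 100, tolerance = 1e-9)
  expect_lt(abs(got - 0.3142), 1e-4)
  # doubling the lesion area halves the coverage
  expect_equal(n_coverage(r, area_mm2 = 200), got / 2)
  # all needles at one node: zero spread
  r0 <- fake_records(rep(TRUE, 3), rep(TRUE, 3), x = rep(2, 3), y = rep(4, 3))
  expect_equal(n_coverage(r0, area_mm2 = 100), 0)
  expect_warning(nc <- n_coverage(fake_records(TRUE, TRUE), area_mm2 = 100),
                 "fewer than two")
  expect_true(is.nan(nc))
})

test_that("the CCL coefficient is a Pearson correlation across cases", {
  expect_equal(ccl_coefficient(c(10, 20, 30), c(1, 2, 3)), 1.0)
  expect_equal(ccl_coefficient(c(10, 20, 30), c(3, 2, 1)), -1.0)
  set.seed(8)
  expect_lt(abs(ccl_coefficient(rnorm(1000), rnorm(1000))), 0.1)
  expect_warning(cc <- ccl_coefficient(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_true(is.nan(cc))
  expect_error(ccl_coefficient(1:4, 1:3), "paired")
})

test_that("reports aggregate per-case metrics and recompute from the per-case table", {
  cases <- small_cohort(4, seed = 31)
  rep0 <- evaluate_policy(expert_agent("centre"), cases, seed = 1)
  expect_s3_class(rep0, "metrics_report")
  expect_equal(nrow(rep0$per_case), 4)
  expect_true(all(rep0$per_case$hr >= 0 & rep0$per_case$hr <= 1, na.rm = TRUE))
  # aggregate mean/sd equal recomputation from the per-case table
  expect_equal(unname(rep0$aggregate$hr["mean"]), mean(rep0$per_case$hr))
  expect_equal(unname(rep0$aggregate$hr["sd"]), sd(rep0$per_case$hr))
  expect_equal(unname(rep0$aggregate$ccl_mm["mean"]), mean(rep0$per_case$ccl_mm))
})

test_that("paired comparisons behave like a paired t-test", {
  cases <- small_cohort(5, seed = 32)
  a <- evaluate_policy(expert_agent("centre"), cases, seed = 1)
  # a report compared with itself: zero difference, t = 0, p = 1
  self <- compare_policies(a, a)
  expect_true(all(self$t == 0))
  expect_true(all(self$p == 1))
  expect_false(any(self$significant))
  # constant +1 shift with tiny noise: strongly significant
  b <- a
  set.seed(4)
  b$per_case$ccl_mm <- a$per_case$ccl_mm + 1 + rnorm(5, 0, 1e-4)
  cmp <- compare_policies(a, b, metrics = "ccl_mm")
  expect_lt(cmp$p, 0.001)
  # swapping the reports flips the t statistic's sign
  cmp_rev <- compare_policies(b, a, metrics = "ccl_mm")
  expect_equal(cmp_rev$t, -cmp$t, tolerance = 1e-9)
  # unpaired reports are refused
  c2 <- a
  c2$per_case$case_id[1] <- "SOMEONE_ELSE"
  expect_error(compare_policies(a, c2), "paired")
})
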