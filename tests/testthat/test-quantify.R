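test_that("the Poisson occupancy estimator matches its closed forms", {
  expect_equal(estimate_lambda(0, 20000)$lambda, 0)
  expect_equal(estimate_lambda(10000, 20000)$lambda, log(2))
  est <- estimate_lambda(c(0, 5000), c(100, 20000))
  expect_true(all(est$lambda >= 0))
  expect_true(all(est$var_lambda >= 0))
  sat <- estimate_lambda(150, 150)
  expect_true(sat$saturated)
  expect_identical(sat$lambda, Inf)
  expect_error(estimate_lambda(5, 0), ">= 1")
  expect_error(estimate_lambda(10, 5), "between 0")
})

test_that("a direct partition simulation is recovered within 3 standard errors", {
  # oracle: physically drop 5000 molecules into 20000 droplets and count
  # occupied ones, independent of the estimator under test
  set.seed(101)
  droplet_of <- sample.int(20000, 5000, replace = TRUE)
  occupied <- tabulate(droplet_of, nbins = 20000) > 0
  est <- estimate_lambda(sum(occupied), 20000)
  recovered <- est$lambda * 20000
  se <- sqrt(est$var_lambda) * 20000
  expect_lt(abs(recovered - 5000), 3 * se)
})

test_that("concentrations scale by droplet count and effective volume", {
  # lambda = 0.1 exactly: choose positives so that neg/total = exp(-0.1)
  pos <- round(20000 * (1 - exp(-0.1)))
  q <- quantify_wells(make_counts(pos, 20000), default_chains())
  expect_equal(q$copies_per_reaction, q$lambda * 20000)
  expect_equal(q$copies_per_ul_sample, q$lambda * 20000 / 0.05)
  expect_equal(q$copies_per_ul_sample, 40000, tolerance = 1e-3)
  expect_true(q$ci_low <= q$copies_per_ul_sample)
  expect_true(q$ci_high >= q$copies_per_ul_sample)
})

test_that("doubling every dilution factor halves the sample concentration exactly", {
  counts <- make_counts(3000, 20000)
  q1 <- quantify_wells(counts, list(default = methods_chain()))
  half <- with_extra_dilution(methods_chain(), 0.5)
  q2 <- quantify_wells(counts, list(default = half))
  expect_equal(q2$copies_per_ul_sample, 2 * q1$copies_per_ul_sample)
  expect_equal(q2$ci_low, 2 * q1$ci_low)
  expect_equal(q2$ci_high, 2 * q1$ci_high)
  # lambda itself is unchanged: it depends on classification only
  expect_equal(q2$lambda, q1$lambda)
})

test_that("interval bounds bracket the estimate and tighten with more droplets", {
  ci0 <- lambda_interval(0, 20000)
  expect_equal(ci0$low, 0)
  expect_gt(ci0$high, 0)
  p_hat <- 0.25
  w1 <- lambda_interval(20000 * p_hat, 20000)
  w2 <- lambda_interval(80000 * p_hat, 80000)
  expect_lt(w2$high - w2$low, w1$high - w1$low)
  # exact method engages for sparse classes
  expect_equal(lambda_interval(4, 15000)$method, "exact")
  expect_equal(lambda_interval(5000, 20000)$method, "wald")
  expect_error(lambda_interval(10, 100, level = 1.2), "in \\(0, 1\\)")
})

test_that("QC flags fire on saturation, droplet floor, subsampling and NTC", {
  chains <- default_chains()
  # copies/reaction = 2e5 > 1e5 ceiling
  sat <- qc_flags(quantify_wells(make_counts(19999, 20000), chains))
  expect_true(has_flag(sat, "SATURATED"))
  # all-positive well: saturated by construction
  allpos <- qc_flags(quantify_wells(make_counts(20000, 20000), chains))
  expect_true(has_flag(allpos, "SATURATED"))
  # just under the ceiling with ample droplets: clean
  ok <- qc_flags(quantify_wells(make_counts(10000, 20000), chains))
  expect_false(has_flag(ok, "SATURATED"))
  expect_identical(ok$flags, "")
  # droplet floor
  few <- qc_flags(quantify_wells(make_counts(500, 5000), chains))
  expect_true(has_flag(few, "TOO_FEW_DROPLETS"))
  # 4 positives of 15000: exact CI half-width far above 25%
  sub <- qc_flags(quantify_wells(make_counts(4, 15000), chains))
  expect_true(has_flag(sub, "HIGH_SUBSAMPLING_ERROR"))
  # NTC contamination propagates to same-target wells; clean NTC does not
  quant <- quantify_wells(dplyr::bind_rows(
    make_counts(3000, 20000, rt_condition = "RT_MINUS"),
    make_counts(12, 20000, rt_condition = "NTC", well_id = "NTC1")
  ), chains)
  expect_true(all(has_flag(qc_flags(quant), "NTC_CONTAMINATION")))
  quant_clean <- quantify_wells(dplyr::bind_rows(
    make_counts(3000, 20000, rt_condition = "RT_MINUS"),
    make_counts(0, 20000, rt_condition = "NTC", well_id = "NTC1")
  ), chains)
  expect_false(any(has_flag(qc_flags(quant_clean), "NTC_CONTAMINATION")))
})

test_that("merging wells sums counts and keeps provenance", {
  one <- make_counts(100, 10000)
  m1 <- merge_wells(one)
  expect_equal(m1$positives, 100)
  expect_equal(m1$total, 10000)
  two <- make_counts(c(100, 200), c(10000, 10000))
  m2 <- merge_wells(two)
  expect_equal(m2$positives, 300)
  expect_equal(m2$total, 20000)
  expect_equal(m2$n_wells, 2L)
  expect_setequal(m2$wells[[1]], two$well_id)
  mixed <- two; mixed$dilution_chain <- c("a", "b")
  expect_error(merge_wells(mixed), "different dilution chains")
})

test_that("pooling identical wells equals their precision-weighted combination", {
  w <- make_counts(c(150, 150), c(10000, 10000))
  pooled <- estimate_lambda(merge_wells(w)$positives, merge_wells(w)$total)
  each <- estimate_lambda(w$positives, w$total)
  weights <- 1 / each$var_lambda
  weighted <- sum(each$lambda * weights) / sum(weights)
  expect_equal(pooled$lambda, weighted, tolerance = 1e-9)
})

test_that("the occupancy estimator has negligible bias across the dynamic range", {
  # scaled-down consistency check; the full-size version runs in acceptance
  set.seed(202)
  for (lam in c(0.1, 1)) {
    neg <- rbinom(200, 20000, exp(-lam))
    est <- estimate_lambda(20000 - neg, 20000)
    expect_lt(abs(mean(est$lambda) / lam - 1), 0.01)
  }
})
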