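test_that("the Selfie statistic reproduces worked examples and edge cases", {
  expect_equal(round(selfie_statistic(1794, 608), 2), 1.95)
  expect_equal(round(selfie_statistic(470, 493), 3), -0.047)
  expect_equal(selfie_statistic(5, 5), 0)
  expect_error(selfie_statistic(10, 0), "undefined")
})

test_that("Selfie algebra is self-consistent: RT- * (1 + t/g) = RT+", {
  set.seed(11)
  for (i in 1:50) {
    rt_minus <- runif(1, 10, 5000)
    rt_plus <- runif(1, 0, 20000)
    tg <- selfie_statistic(rt_plus, rt_minus)
    expect_equal(rt_minus * tg + rt_minus, rt_plus)
    expect_equal(tg < 0, rt_plus < rt_minus)
    # unit invariance: a common volume scale cancels
    k <- runif(1, 0.01, 100)
    expect_equal(selfie_statistic(k * rt_plus, k * rt_minus), tg)
  }
})

test_that("percent differences match the printed worked examples", {
  expect_equal(round(percent_difference(6667, 6543), 1), 1.9)
  expect_equal(round(percent_difference(1160, 1045), 1), 11.0)
  expect_equal(round(percent_difference(847, 1045)), -19)
  expect_equal(round(percent_difference(8673, 7588)), 14)
  expect_equal(percent_difference(42, 42), 0)
  expect_error(percent_difference(1, 0), "nonzero")
})

test_that("silencing percentage matches the RNA-interference example", {
  expect_equal(round(silencing_percent(136, 83)), 39)
  expect_equal(silencing_percent(7, 7), 0)
  expect_equal(silencing_percent(100, 0), 100)
  expect_error(silencing_percent(0, 10), "> 0")
})

test_that("strand excess and transcripts per genome match printed arithmetic", {
  expect_equal(round(strand_excess(0.55, 0.37)), 49)
  expect_equal(strand_excess(0.4, 0.4), 0)
  expect_equal(transcripts_per_genome(27, 107), 2889)
  expect_equal(transcripts_per_genome(3.3, 1), 3.3)
  # brain H-strand transcripts per genome: product lands in the printed
  # mean +/- SEM band (600 +/- 51)
  expect_lt(abs(transcripts_per_genome(0.55, 1096) - 600), 51)
})

test_that("RNA copy number is the RT+ minus RT- difference with propagated error", {
  q <- quantified_pair(1794, 608, total = 20000)
  r <- rna_copies(q)
  expect_equal(r$rna_copies_per_ul,
               q$copies_per_ul_sample[q$rt_condition == "RT_PLUS"] -
                 q$copies_per_ul_sample[q$rt_condition == "RT_MINUS"])
  expect_equal(r$se^2,
               sum(q$se_copies_per_ul^2))
  same <- rna_copies(quantified_pair(500, 500))
  expect_equal(same$rna_copies_per_ul, 0)
})

test_that("transcripts_per_gene pairs wells and propagates uncertainty", {
  q <- quantified_pair(1681, 622, total = 20000)
  tg <- transcripts_per_gene(q)
  np <- q$copies_per_ul_sample[q$rt_condition == "RT_PLUS"]
  nm <- q$copies_per_ul_sample[q$rt_condition == "RT_MINUS"]
  expect_equal(tg$transcripts_per_gene, (np - nm) / nm)
  expect_true(tg$detected)
  expect_true(tg$ci_low < tg$transcripts_per_gene)
  expect_true(tg$ci_high > tg$transcripts_per_gene)

  # RT+ slightly below RT-: negative estimate, CI spans 0, not detected
  null_pair <- transcripts_per_gene(quantified_pair(590, 610))
  expect_lt(null_pair$transcripts_per_gene, 0)
  expect_false(null_pair$detected)
  expect_true(null_pair$ci_low < 0 && null_pair$ci_high > 0)

  # undetected gene and saturation become flags, not errors
  none <- transcripts_per_gene(quantified_pair(100, 0))
  expect_identical(none$flags, "GENE_NOT_DETECTED")
  expect_true(is.na(none$transcripts_per_gene))
  sat <- transcripts_per_gene(quantified_pair(20000, 500))
  expect_identical(sat$flags, "SATURATED")
})

test_that("copies per genome is the RT- ratio with a delta-method interval", {
  counts <- dplyr::bind_rows(
    make_counts(3000, 20000, target = "ref"),
    make_counts(3000, 20000, target = "mt", well_id = "W99")
  )
  q <- quantify_wells(counts, default_chains())
  cpg <- copies_per_genome(q, "ref")
  expect_equal(cpg$copies_per_genome, 1)
  expect_equal(cpg$reference_gene, "ref")
  expect_true(cpg$ci_low < 1 && cpg$ci_high > 1)
  expect_error(copies_per_genome(q, "nope"), "not found")

  # simulated multi-copy target at 107 copies/genome, pooled replicate wells
  set.seed(33)
  p <- simulation_params(gene_copies_per_genome = 107, transcripts_per_gene = 0,
                         copies_per_fragment = 1)
  p$dilution_chain <- with_extra_dilution(methods_chain(), 0.25)
  wells <- dplyr::bind_rows(lapply(1:4, function(r) {
    tg <- p; tg$gene_copies_per_genome <- 107
    ref <- p; ref$gene_copies_per_genome <- 1
    dplyr::bind_rows(
      simulate_selfie_pair(tg, target = "multi", replicate = r,
                           chain_id = "default")$wells,
      simulate_selfie_pair(ref, target = "ref", replicate = r,
                           chain_id = "default")$wells)
  }))
  cc <- merge_wells(classify_wells(droplet_wells(wells), consensus = FALSE))
  qq <- quantify_wells(cc, list(default = p$dilution_chain))
  est <- copies_per_genome(qq, "ref")
  expect_true(est$ci_low <= 107 && 107 <= est$ci_high)
})

test_that("proviral integrations add native copies to template genes", {
  # lambda ratio engineered near 28 proviruses per genome
  neg_ref <- round(20000 * exp(-0.05))
  neg_pro <- round(20000 * exp(-0.05 * 28))
  q <- quantify_wells(dplyr::bind_rows(
    make_counts(20000 - neg_ref, 20000, target = "Bax-72"),
    make_counts(20000 - neg_pro, 20000, target = "WPRE-106", well_id = "W99")
  ), default_chains())
  ipg <- integrations_per_genome(q, "WPRE-106", "Bax-72", native_copies = 1)
  expect_equal(ipg$integrations_per_genome, 28, tolerance = 0.01)
  expect_equal(ipg$total_template_genes - ipg$integrations_per_genome, 1)
  # untransduced control: zero provirus positives -> zero integrations
  q0 <- quantify_wells(dplyr::bind_rows(
    make_counts(20000 - neg_ref, 20000, target = "Bax-72"),
    make_counts(0, 20000, target = "WPRE-106", well_id = "W99")
  ), default_chains())
  ipg0 <- integrations_per_genome(q0, "WPRE-106", "Bax-72")
  expect_equal(ipg0$integrations_per_genome, 0)
})

test_that("strand report carries H, L, sum, excess and a consistency z-score", {
  rep1 <- strand_metrics(0.55, 0.37)
  expect_equal(rep1$estimate[rep1$metric == "percent_excess_H"],
               strand_excess(0.55, 0.37))
  expect_equal(strand_metrics(0.4, 0.4)$estimate[4], 0)
  h <- tibble::tibble(transcripts_per_gene = 0.58, se = 0.03)
  l <- tibble::tibble(transcripts_per_gene = 0.37, se = 0.03)
  comb <- tibble::tibble(transcripts_per_gene = 0.96, se = 0.04)
  rep2 <- strand_metrics(h, l, comb)
  z <- rep2$estimate[rep2$metric == "consistency_z"]
  expect_equal(z, (0.95 - 0.96) / sqrt(0.03^2 + 0.03^2 + 0.04^2))
  expect_lt(abs(z), 1.96)
})

test_that("replicate aggregation returns mean, SEM and n", {
  expect_equal(aggregate_replicates(c(2, 2, 2)),
               tibble::tibble(mean = 2, sem = 0, n = 3L))
  a <- aggregate_replicates(c(1, 2, 3))
  expect_equal(a$mean, 2)
  expect_equal(a$sem, 1 / sqrt(3), tolerance = 1e-6)
  set.seed(9)
  x <- rnorm(7)
  expect_equal(aggregate_replicates(x), aggregate_replicates(sample(x)))
  expect_true(is.na(aggregate_replicates(5)$sem))
  expect_error(aggregate_replicates(NA_real_), "non-missing")
})

test_that("group comparison: F statistic, Bonferroni arithmetic, degenerate case", {
  df0 <- data.frame(value = rep(c(1, 1), each = 4), group = rep(c("a", "b"), each = 4))
  fit0 <- compare_groups(df0)
  expect_equal(glance(fit0)$statistic, 0)
  expect_equal(glance(fit0)$p.value, 1)

  set.seed(21)
  df <- data.frame(value = rnorm(15), group = rep(c("a", "b", "c"), each = 5))
  fit <- compare_groups(df)
  td <- tidy(fit)
  expect_equal(nrow(td), 3)
  # adjusted p equals raw p times the number of pairs, capped at 1
  expect_equal(td$p.adjusted, pmin(1, td$p.value * 3))
  # raw pairwise p matches a direct pooled-variance t test
  tt <- t.test(df$value[df$group == "a"], df$value[df$group == "b"],
               var.equal = TRUE)
  expect_equal(td$p.value[td$group1 == "a" & td$group2 == "b"], tt$p.value)
  # F matches stats::aov directly
  expect_equal(glance(fit)$statistic,
               anova(aov(value ~ group, df))$`F value`[1])
  expect_error(compare_groups(df[df$group == "a", ]), "two groups")
})

test_that("ANOVA type-I error rate is nominal under the null", {
  set.seed(77)
  rejections <- vapply(1:1000, function(i) {
    df <- data.frame(value = rnorm(15), group = rep(c("a", "b", "c"), each = 5))
    glance(compare_groups(df))$p.value < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.03)
  expect_lte(mean(rejections), 0.07)
})
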