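test_that("parameter validation rejects unphysical settings", {
  expect_error(simulation_params(rt_efficiency = 0), "rt_efficiency")
  expect_error(simulation_params(rain_fraction = 0.5), "rain_fraction")
  expect_error(simulation_params(copies_per_fragment = 0.5), ">= 1")
  expect_error(simulation_params(genomes_per_ul = -1), ">= 0")
  p <- simulation_params(genomes_per_ul = 1e9)  # ~50k copies per droplet
  expect_error(simulate_selfie_pair(p), "saturation")
})

test_that("molecules are conserved across droplets and RT- carries no cDNA", {
  for (s in 1:5) {
    p <- simulation_params(transcripts_per_gene = 1.95, seed = s)
    sim <- simulate_selfie_pair(p)
    tr <- sim$truth
    expect_equal(sum(tr$occupancy_plus[[1]]), tr$molecules_plus)
    expect_equal(sum(tr$occupancy_minus[[1]]), tr$molecules_minus)
    expect_equal(tr$molecules_plus, tr$dna_plus + tr$cdna)
    expect_identical(tr$molecules_minus, tr$dna_minus)
    expect_lte(tr$cdna, tr$transcripts)
  }
})

test_that("identical parameters and seed give identical wells and files", {
  p <- simulation_params(droplet_count = 2000, seed = 99)
  a <- simulate_selfie_pair(p)
  b <- simulate_selfie_pair(p)
  expect_identical(a$wells$amplitudes, b$wells$amplitudes)
  expect_identical(a$truth, b$truth)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_amplitude_csv(a$wells, f1)
  write_amplitude_csv(b$wells, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("a zero-density sample yields all-negative wells", {
  p <- simulation_params(genomes_per_ul = 0, rain_fraction = 0, seed = 5)
  sim <- simulate_selfie_pair(p)
  expect_equal(sim$truth$molecules_plus, 0)
  expect_equal(sim$truth$molecules_minus, 0)
  cc <- classify_wells(sim$wells, manual = c(target = 5500))
  expect_true(all(cc$positives == 0))
})

test_that("with no transcripts the estimated t/g is centred on zero", {
  set.seed(123)
  p <- simulation_params(transcripts_per_gene = 0, genomes_per_ul = 40000)
  tg <- vapply(1:60, function(i) {
    sim <- simulate_selfie_pair(p)
    cc <- classify_wells(sim$wells, consensus = FALSE)
    q <- quantify_wells(cc, list(default = p$dilution_chain))
    transcripts_per_gene(q)$transcripts_per_gene
  }, double(1))
  expect_lt(abs(mean(tg)), 3 * stats::sd(tg) / sqrt(length(tg)))
})

test_that("the empty-droplet fraction follows the Poisson occupancy law", {
  # z-scores of the empty fraction against exp(-lambda) should be standard
  # normal across seeds (Kolmogorov-Smirnov on their probability transform)
  set.seed(321)
  lam_true <- 12000 * 0.05 / 20000  # expected molecules per droplet
  p <- simulation_params(transcripts_per_gene = 0)
  p_empty_exp <- exp(-lam_true)
  z <- vapply(1:50, function(i) {
    sim <- simulate_selfie_pair(p)
    empty <- mean(sim$truth$occupancy_minus[[1]] == 0)
    (empty - p_empty_exp) /
      sqrt(p_empty_exp * (1 - p_empty_exp) / 20000)
  }, double(1))
  # discrete counts can tie across seeds; the KS p-value remains conservative
  ks <- suppressWarnings(stats::ks.test(stats::pnorm(z), "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("RNase and dsDNase survival fractions act on the right pools", {
  p <- simulation_params(transcripts_per_gene = 2, rna_survival = 0,
                         dna_survival = 0.81, seed = 8)
  ec <- selfiedpcr:::expected_counts(p)
  expect_equal(ec$transcripts, 0)
  expect_equal(ec$fragments, 12000 * 0.05 * 0.81)
  p2 <- simulation_params(transcripts_per_gene = 2, dna_survival = 0.1, seed = 8)
  expect_equal(selfiedpcr:::expected_counts(p2)$fragments, 12000 * 0.05 * 0.1)
})

test_that("the tissue panel has the full assay x condition x replicate structure", {
  pan <- simulate_tissue_panel(truth = default_tissue_truth()[1:2, ],
                               n_replicates = 2, seed = 42)
  # 2 tissues x 5 assays x (2 replicates x RT+/RT- + 1 NTC) wells
  expect_equal(nrow(pan$wells), 2 * 5 * (2 * 2 + 1))
  expect_setequal(unique(pan$layout$rt_condition), c("RT_PLUS", "RT_MINUS", "NTC"))
  expect_true(all(pan$layout$dilution_chain %in% names(pan$chains)))
  check_layout(pan$layout)
  pan2 <- simulate_tissue_panel(truth = default_tissue_truth()[1:2, ],
                                n_replicates = 2, seed = 42)
  expect_identical(pan$wells$amplitudes, pan2$wells$amplitudes)
})

test_that("heart panel recovers H-strand transcripts per genome near truth", {
  set.seed(55)
  heart <- default_tissue_truth()[2, ]
  ests <- vapply(1:10, function(i) {
    pan <- simulate_tissue_panel(truth = heart, n_replicates = 2)
    cc <- classify_wells(pan$wells)
    q <- quantify_wells(cc, pan$chains)
    est <- q |> dplyr::filter(.data$rt_condition != "NTC")
    tg <- transcripts_per_gene(est)
    th <- mean(tg$transcripts_per_gene[tg$target == "mtDNA-67.H"])
    cpg <- copies_per_genome(est, "Gsk3b-81", targets = "mtDNA-67.H")
    transcripts_per_genome(th, mean(cpg$copies_per_genome))
  }, double(1))
  truth_tpgen <- 0.58 * 2302  # ~1335
  expect_lt(abs(mean(ests) / truth_tpgen - 1), 0.10)
})
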