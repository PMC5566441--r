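#' Ground-truth parameters for a simulated Selfie-dPCR experiment
#'
#' The generative model mirrors the wet protocol: a lysate with
#' `genomes_per_ul` genome equivalents per microlitre, each genome carrying
#' `gene_copies_per_genome` copies of the target gene and
#' `transcripts_per_gene` RNA transcripts per gene copy. The dilution chain
#' determines how much lysate reaches one reaction; amplifiable DNA
#' fragments (gene copies / `copies_per_fragment`, modelling tandem-copy
#' linkage of undigested DNA) and transcripts are drawn Poisson at their
#' expected per-reaction counts; reverse transcription converts each
#' transcript to cDNA with probability `rt_efficiency` in the RT+ aliquot
#' only. Molecules fall into droplets uniformly at random (equivalently,
#' independent Poisson occupancy). Droplet fluorescence is Gaussian around
#' a negative and a positive mode; a `rain_fraction` of the
#' template-containing droplets amplify only partially and are redrawn
#' uniformly between the modes ("rain").
#'
#' @param genomes_per_ul genome density of the lysate (genomes/ul).
#' @param gene_copies_per_genome copies of the gene per genome (1 for a
#'   single-copy gene, ~107 for an rRNA repeat, ~1000-2300 for mtDNA).
#' @param transcripts_per_gene RNA transcripts per gene copy (>= 0). For
#'   strand-specific mtDNA assays use `t_heavy` / `t_light` instead.
#' @param t_heavy,t_light heavy/light strand transcripts per mtDNA copy
#'   (used when `rt_primer` is `"H"`, `"L"` or `"HL"`).
#' @param rt_efficiency probability a primed transcript yields cDNA, (0, 1].
#' @param copies_per_fragment tandem gene copies per undigested DNA
#'   fragment (1 = fully digested).
#' @param droplet_count accepted droplets per well.
#' @param droplet_volume nominal droplet volume, nl.
#' @param dilution_chain a [dilution_chain()].
#' @param mu_neg,mu_pos,sigma,rain_fraction amplitude model: negative and
#'   positive mode means, common SD, and the fraction of occupied droplets
#'   redrawn uniformly between the modes ("rain", in \[0, 0.2\]).
#' @param rna_survival,dna_survival multiplicative survival of the RNA and
#'   DNA pools (models RNase / dsDNase treatments; 1 = untreated).
#' @param seed optional integer seed recorded with the parameters.
#' @return a validated list of class `simulation_params`.
#' @export
simulation_params <- function(genomes_per_ul = 12000,
                              gene_copies_per_genome = 1,
                              transcripts_per_gene = 2,
                              t_heavy = NULL, t_light = NULL,
                              rt_efficiency = 1,
                              copies_per_fragment = 1,
                              droplet_count = 20000,
                              droplet_volume = 0.85,
                              dilution_chain = methods_chain(),
                              mu_neg = 2000, mu_pos = 9000, sigma = 300,
                              rain_fraction = 0.01,
                              rna_survival = 1, dna_survival = 1,
                              seed = NULL) {
  p <- as.list(environment())
  if (p$genomes_per_ul < 0 || p$gene_copies_per_genome < 0 ||
      p$transcripts_per_gene < 0) {
    abort("Densities and counts must be >= 0.")
  }
  if (p$rt_efficiency <= 0 || p$rt_efficiency > 1) {
    abort("`rt_efficiency` must be in (0, 1].")
  }
  if (p$copies_per_fragment < 1) abort("`copies_per_fragment` must be >= 1.")
  if (p$rain_fraction < 0 || p$rain_fraction > 0.2) {
    abort("`rain_fraction` must be in [0, 0.2].")
  }
  if (p$droplet_count < 1 || p$droplet_volume <= 0) {
    abort("`droplet_count` and `droplet_volume` must be positive.")
  }
  if (p$rna_survival < 0 || p$rna_survival > 1 ||
      p$dna_survival < 0 || p$dna_survival > 1) {
    abort("Survival fractions must be in [0, 1].")
  }
  stopifnot(inherits(p$dilution_chain, "dilution_chain"))
  structure(p, class = "simulation_params")
}

# drop M molecules into n droplets uniformly; per-droplet occupancy counts
partition_molecules <- function(n_molecules, n_droplets) {
  if (n_molecules == 0) return(integer(n_droplets))
  tabulate(sample.int(n_droplets, n_molecules, replace = TRUE),
           nbins = n_droplets)
}

# occupancy -> fluorescence amplitudes; "rain" (partial amplification at
# intermediate amplitude) only happens in template-containing droplets
draw_amplitudes <- function(occupancy, params) {
  n <- length(occupancy)
  amp <- ifelse(occupancy > 0,
                rnorm(n, params$mu_pos, params$sigma),
                rnorm(n, params$mu_neg, params$sigma))
  if (params$rain_fraction > 0) {
    rain <- occupancy > 0 & runif(n) < params$rain_fraction
    amp[rain] <- runif(sum(rain), params$mu_neg, params$mu_pos)
  }
  amp
}

# one well from a molecule count; returns amplitudes + truth
simulate_well <- function(n_molecules, params) {
  if (n_molecules / params$droplet_count > 50) {
    abort("Expected occupancy exceeds 50 molecules per droplet: unphysical saturation.")
  }
  occ <- partition_molecules(n_molecules, params$droplet_count)
  list(amplitudes = draw_amplitudes(occ, params),
       occupancy = occ,
       true_positives = sum(occ > 0L))
}

# expected per-reaction molecule counts implied by the parameters
expected_counts <- function(params, rt_primer = "gene") {
  eff <- effective_sample_volume(params$dilution_chain)
  genes <- params$genomes_per_ul * eff * params$gene_copies_per_genome
  tpg <- switch(rt_primer,
                gene = params$transcripts_per_gene,
                H = params$t_heavy %||% abort("`t_heavy` not set."),
                L = params$t_light %||% abort("`t_light` not set."),
                HL = (params$t_heavy %||% abort("`t_heavy` not set.")) +
                  (params$t_light %||% abort("`t_light` not set.")),
                abort("`rt_primer` must be one of gene, H, L, HL."))
  list(fragments = genes / params$copies_per_fragment * params$dna_survival,
       transcripts = genes * tpg * params$rna_survival)
}

#' Simulate one RT+/RT- Selfie pair
#'
#' Draws the paired aliquots of one sample: both receive an independent
#' Poisson number of amplifiable DNA fragments; the RT+ aliquot
#' additionally receives `Binomial(Poisson(transcripts), rt_efficiency)`
#' cDNA molecules. The RT- aliquot never contains cDNA.
#'
#' @param params a [simulation_params()] object.
#' @param sample_id,target,replicate well metadata.
#' @param chain_id dilution-chain id recorded in the wells.
#' @param rt_primer `"gene"` for an ordinary assay, or `"H"`, `"L"`, `"HL"`
#'   for strand-specific mtDNA priming.
#' @param include_ntc also simulate a no-template control well.
#' @return a list with `wells` (a `droplet_wells` tibble: RT+, RT-, and
#'   optionally NTC) and `truth` (one-row tibble of all drawn counts).
#' @export
simulate_selfie_pair <- function(params, sample_id = "sample",
                                 target = "target", replicate = 1L,
                                 chain_id = "default",
                                 rt_primer = "gene",
                                 include_ntc = FALSE) {
  stopifnot(inherits(params, "simulation_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  exp_cts <- expected_counts(params, rt_primer)

  dna_minus <- rpois(1, exp_cts$fragments)
  dna_plus <- rpois(1, exp_cts$fragments)
  transcripts <- rpois(1, exp_cts$transcripts)
  cdna <- rbinom(1, transcripts, params$rt_efficiency)

  w_plus <- simulate_well(dna_plus + cdna, params)
  w_minus <- simulate_well(dna_minus, params)

  mk <- function(cond, w, idx) {
    tibble(well_id = sprintf("%s_%s_%s_r%d", sample_id, target, idx, replicate),
           sample_id = sample_id, target = target, rt_condition = cond,
           dilution_chain = chain_id, replicate = as.integer(replicate),
           channel = "ch1",
           accepted_droplets = params$droplet_count,
           amplitudes = list(w$amplitudes))
  }
  wells <- bind_rows(mk("RT_PLUS", w_plus, "plus"),
                     mk("RT_MINUS", w_minus, "minus"))
  truth <- tibble(sample_id = sample_id, target = target,
                  replicate = as.integer(replicate), rt_primer = rt_primer,
                  expected_fragments = exp_cts$fragments,
                  expected_transcripts = exp_cts$transcripts,
                  dna_plus = dna_plus, dna_minus = dna_minus,
                  transcripts = transcripts, cdna = cdna,
                  molecules_plus = dna_plus + cdna,
                  molecules_minus = dna_minus,
                  true_positives_plus = w_plus$true_positives,
                  true_positives_minus = w_minus$true_positives,
                  occupancy_plus = list(w_plus$occupancy),
                  occupancy_minus = list(w_minus$occupancy))
  if (include_ntc) {
    w_ntc <- simulate_well(0L, params)
    wells <- bind_rows(wells, mk("NTC", w_ntc, "ntc"))
  }
  list(wells = droplet_wells(wells), truth = truth)
}

#' Printed tissue-panel ground truth used by the simulator
#'
#' Per-tissue defaults for the single-copy gene (Gsk3b-like), the
#' multi-copy rRNA gene (RNA18S-like, 107 copies/genome) and mtDNA
#' (variable copies/genome, strand-specific transcription). Heart Gsk3b
#' transcription is set to 0 (no detectable transcription).
#'
#' @return a tibble with one row per tissue.
#' @export
default_tissue_truth <- function() {
  tibble(
    tissue = c("brain", "heart", "liver", "muscle"),
    gsk3b_tg = c(2.03, 0, 0.25, 0.25),
    rna18s_tg = c(349, 1496, 27, 6),
    rna18s_cpg = 107,
    mtdna_cpg = c(1096, 2302, 1759, 1774),
    t_heavy = c(0.55, 0.58, 1.70, 0.56),
    t_light = c(0.37, 0.37, 0.44, 0.36)
  )
}

#' Simulate a multi-tissue Selfie-dPCR plate
#'
#' For each tissue, five assays are generated: the single-copy reference
#' gene, the multi-copy rRNA gene, and mtDNA with heavy-, light- and
#' combined-strand RT priming, each as `n_replicates` RT+/RT- pairs plus
#' one NTC well. High-copy assays are automatically diluted (an extra
#' chain step) so the RT+ well lands near `target_occupancy` mean copies
#' per droplet, mirroring the characterization step used to stay inside
#' the dPCR dynamic range.
#'
#' @param truth per-tissue ground truth ([default_tissue_truth()]).
#' @param n_replicates RT+/RT- pairs per assay.
#' @param base_params a [simulation_params()] whose genome density,
#'   droplet and amplitude settings are shared by all assays.
#' @param target_occupancy aimed-for RT+ mean copies per droplet.
#' @param seed optional seed (set once for the whole plate).
#' @return a list with `wells` (`droplet_wells`), `layout`, `chains`
#'   (named list of [dilution_chain()]), and `truth` (assay-level tibble
#'   with expected counts).
#' @export
simulate_tissue_panel <- function(truth = default_tissue_truth(),
                                  n_replicates = 3L,
                                  base_params = simulation_params(),
                                  target_occupancy = 1.2,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  assays <- function(row) {
    tibble(assay = c("Gsk3b-81", "RNA18S-97", "mtDNA-67.H", "mtDNA-67.L",
                     "mtDNA-67.HL"),
           copies = c(1, row$rna18s_cpg, row$mtdna_cpg, row$mtdna_cpg,
                      row$mtdna_cpg),
           tpg = c(row$gsk3b_tg, row$rna18s_tg,
                   row$t_heavy, row$t_light, row$t_heavy + row$t_light),
           rt_primer = c("gene", "gene", "H", "L", "HL"))
  }
  all_wells <- list(); all_truth <- list(); chains <- list()
  for (i in seq_len(nrow(truth))) {
    row <- truth[i, ]
    for (j in seq_len(nrow(assays(row)))) {
      a <- assays(row)[j, ]
      eff0 <- effective_sample_volume(base_params$dilution_chain)
      expected_plus <- base_params$genomes_per_ul * eff0 * a$copies *
        (1 + a$tpg)
      f <- min(1, target_occupancy * base_params$droplet_count / expected_plus)
      chain_id <- paste(row$tissue, a$assay, sep = ".")
      chain <- with_extra_dilution(base_params$dilution_chain, f)
      chains[[chain_id]] <- chain
      p <- base_params
      p$dilution_chain <- chain
      p$gene_copies_per_genome <- a$copies
      p$transcripts_per_gene <- a$tpg
      p$t_heavy <- row$t_heavy
      p$t_light <- row$t_light
      p$seed <- NULL
      for (r in seq_len(n_replicates)) {
        sim <- simulate_selfie_pair(p, sample_id = row$tissue,
                                    target = a$assay, replicate = r,
                                    chain_id = chain_id,
                                    rt_primer = a$rt_primer,
                                    include_ntc = (r == 1L))
        all_wells[[length(all_wells) + 1L]] <- sim$wells
        all_truth[[length(all_truth) + 1L]] <- sim$truth |>
          mutate(tissue = row$tissue, assay = a$assay,
                 copies_per_genome = a$copies,
                 transcripts_per_gene = a$tpg)
      }
    }
  }
  wells <- droplet_wells(list_rbind(all_wells))
  layout <- wells |>
    select("well_id", "sample_id", "target", "rt_condition",
           "dilution_chain", "replicate")
  list(wells = wells, layout = layout, chains = chains,
       truth = list_rbind(all_truth) |> select(-"occupancy_plus", -"occupancy_minus"))
}

#' Tandem-copy linkage bias experiment
#'
#' Simulates a multi-copy gene whose copies sit on undigested DNA fragments
#' of `copies_per_fragment` tandem copies and estimates its copies per
#' genome against a single-copy reference. dPCR counts amplifiable
#' fragments, so the estimate is biased from `gene_copies_per_genome` down
#' toward `gene_copies_per_genome / copies_per_fragment`; at full linkage
#' it collapses to ~1 fragment per genome.
#'
#' @param copies_per_fragment integer grid of tandem-linkage values.
#' @param gene_copies_per_genome true copies per genome of the multi-copy
#'   target.
#' @param n_replicates wells pooled per estimate ([merge_wells()]).
#' @param base_params shared [simulation_params()].
#' @param seed optional seed.
#' @return a `linkage_curve` tibble: `copies_per_fragment,
#'   expected_fragments_per_genome, estimate, ci_low, ci_high`.
#' @export
linkage_bias_experiment <- function(copies_per_fragment = c(1, 2, 4, 8, 16,
                                                            32, 64, 107),
                                    gene_copies_per_genome = 107,
                                    n_replicates = 3L,
                                    base_params = simulation_params(),
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  run_assay <- function(p, target, copies, k) {
    p$gene_copies_per_genome <- copies
    p$copies_per_fragment <- k
    p$transcripts_per_gene <- 0
    sims <- map(seq_len(n_replicates), function(r) {
      simulate_selfie_pair(p, sample_id = "linkage", target = target,
                           replicate = r)$wells
    })
    droplet_wells(list_rbind(sims))
  }
  rows <- map(copies_per_fragment, function(k) {
    p <- base_params; p$seed <- NULL
    wells <- bind_rows(run_assay(p, "multicopy", gene_copies_per_genome, k),
                       run_assay(p, "reference", 1, 1))
    counts <- classify_wells(droplet_wells(wells), consensus = FALSE)
    merged <- merge_wells(counts)
    quant <- quantify_wells(merged, chains = list(default = p$dilution_chain),
                            droplet_volume = p$droplet_volume)
    cpg <- copies_per_genome(quant, reference_target = "reference")
    tibble(copies_per_fragment = k,
           expected_fragments_per_genome = gene_copies_per_genome / k,
           estimate = cpg$copies_per_genome,
           ci_low = cpg$ci_low, ci_high = cpg$ci_high)
  }) |> list_rbind()
  class(rows) <- unique(c("linkage_curve", class(rows)))
  rows
}
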