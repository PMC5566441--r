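#' The Selfie statistic: transcripts per gene
#'
#' `(rt_plus - rt_minus) / rt_minus` on matched units (copies/ul or
#' copies/reaction -- the ratio cancels volumes). The RT+ aliquot measures
#' gene DNA plus cDNA from its transcripts; the RT- aliquot measures gene
#' DNA only, so the ratio is the absolute number of RNA transcripts per
#' copy of the encoding gene. Negative values are reported as-is (sampling
#' noise around zero transcription).
#'
#' @param rt_plus,rt_minus copy-number estimates on matched units
#'   (vectorized). `rt_minus` must be > 0.
#' @return transcripts per gene (dimensionless, may be negative).
#' @examples
#' selfie_statistic(1794, 608)  # ~1.95
#' @export
selfie_statistic <- function(rt_plus, rt_minus) {
  if (any(rt_minus <= 0)) {
    abort("`rt_minus` must be > 0: the gene was not detected, transcripts per gene is undefined.")
  }
  (rt_plus - rt_minus) / rt_minus
}

#' Signed percent difference between observed and expected values
#'
#' `100 * (observed - expected) / expected`.
#'
#' @param observed,expected numeric (vectorized); `expected` must be nonzero.
#' @return percent, signed.
#' @examples
#' percent_difference(6667, 6543)  # ~1.9
#' @export
percent_difference <- function(observed, expected) {
  if (any(expected == 0)) abort("`expected` must be nonzero.")
  100 * (observed - expected) / expected
}

#' Percent silencing of expression by RNA interference
#'
#' `100 * (unsilenced - silenced) / unsilenced`, from transcripts-per-genome
#' values measured without and with the silencing construct.
#'
#' @param unsilenced baseline transcripts per genome (> 0).
#' @param silenced transcripts per genome under silencing.
#' @return percent silencing.
#' @examples
#' silencing_percent(136, 83)  # ~39
#' @export
silencing_percent <- function(unsilenced, silenced) {
  if (any(unsilenced <= 0)) abort("`unsilenced` baseline must be > 0.")
  100 * (unsilenced - silenced) / unsilenced
}

#' Percent excess of heavy-strand over light-strand transcription
#'
#' `100 * (h - l) / l`, both in transcripts per mtDNA copy.
#'
#' @param h,l strand-specific transcripts per mtDNA copy; `l` must be > 0.
#' @return percent excess of H over L.
#' @examples
#' strand_excess(0.55, 0.37)  # ~49
#' @export
strand_excess <- function(h, l) {
  if (any(l <= 0)) abort("`l` must be > 0.")
  100 * (h - l) / l
}

#' Transcripts per genome
#'
#' Product of transcripts per gene and gene copies per genome.
#'
#' @param t_per_gene transcripts per gene.
#' @param copies_per_genome gene copies per genome.
#' @return transcripts per genome.
#' @examples
#' transcripts_per_genome(27, 107)  # 2889
#' @export
transcripts_per_genome <- function(t_per_gene, copies_per_genome) {
  t_per_gene * copies_per_genome
}

# delta-method variance of a ratio a/b of independent estimates
ratio_var <- function(a, b, va, vb) {
  (a / b)^2 * (va / a^2 + vb / b^2)
}

#' Transcripts per gene for every RT+/RT- pair of a plate
#'
#' Pairs RT_PLUS and RT_MINUS wells by (sample, target, replicate) and
#' computes the Selfie statistic on `copies_per_ul_sample`, with a
#' delta-method confidence interval from the two independent occupancy
#' variances. `detected` is `TRUE` when the interval excludes 0. Pairs with
#' a saturated member are flagged `SATURATED` and pairs whose RT- estimate
#' is 0 are flagged `GENE_NOT_DETECTED`; both get `NA` estimates rather
#' than an undefined division.
#'
#' @param quantified a `concentration_tbl` from [quantify_wells()].
#' @param level confidence level for the delta-method interval.
#' @return a `selfie_results` tibble: one row per pair with
#'   `transcripts_per_gene, se, ci_low, ci_high, detected, flags`, plus the
#'   underlying RT+/RT- concentrations.
#' @export
transcripts_per_gene <- function(quantified, level = 0.95) {
  pairs <- selfie_pairs(quantified)
  z <- qnorm(1 - (1 - level) / 2)
  out <- pairs |>
    mutate(
      undefined = .data$sat_plus | .data$sat_minus | .data$n_minus <= 0,
      transcripts_per_gene = ifelse(.data$undefined, NA_real_,
                                    (.data$n_plus - .data$n_minus) / .data$n_minus),
      se = ifelse(.data$undefined, NA_real_,
                  sqrt(ratio_var(.data$n_plus, .data$n_minus,
                                 .data$v_plus, .data$v_minus))),
      ci_low = .data$transcripts_per_gene - z * .data$se,
      ci_high = .data$transcripts_per_gene + z * .data$se,
      detected = !.data$undefined & (.data$ci_low > 0 | .data$ci_high < 0),
      flags = case_when(
        .data$sat_plus | .data$sat_minus ~ "SATURATED",
        .data$n_minus <= 0 ~ "GENE_NOT_DETECTED",
        .default = ""
      )
    ) |>
    select(-"undefined")
  class(out) <- unique(c("selfie_results", class(out)))
  out
}

#' Absolute RNA copy number for every RT+/RT- pair
#'
#' The difference RT+ minus RT- on matched units: the number of transcripts
#' converted to cDNA, per ul of sample and per reaction, with a propagated
#' (sum of variances) confidence interval.
#'
#' @inheritParams transcripts_per_gene
#' @return a tibble with `rna_copies_per_ul`, `rna_copies_per_reaction`,
#'   `se`, `ci_low`, `ci_high` per pair.
#' @export
rna_copies <- function(quantified, level = 0.95) {
  pairs <- selfie_pairs(quantified)
  z <- qnorm(1 - (1 - level) / 2)
  pairs |>
    mutate(
      undefined = .data$sat_plus | .data$sat_minus,
      rna_copies_per_ul = ifelse(.data$undefined, NA_real_,
                                 .data$n_plus - .data$n_minus),
      rna_copies_per_reaction = .data$rna_copies_per_ul * .data$eff_minus,
      se = ifelse(.data$undefined, NA_real_, sqrt(.data$v_plus + .data$v_minus)),
      ci_low = .data$rna_copies_per_ul - z * .data$se,
      ci_high = .data$rna_copies_per_ul + z * .data$se
    ) |>
    select(-"undefined")
}

# long concentration table -> one row per RT+/RT- pair
selfie_pairs <- function(quantified) {
  need <- c("sample_id", "target", "replicate", "rt_condition",
            "copies_per_ul_sample", "se_copies_per_ul", "saturated",
            "effective_volume")
  miss <- setdiff(need, names(quantified))
  if (length(miss)) abort(paste0("Expected a quantified table with column(s): ",
                                 toString(miss)))
  take <- function(cond, prefix) {
    df <- quantified |> filter(.data$rt_condition == cond)
    out <- tibble(sample_id = df$sample_id, target = df$target,
                  replicate = df$replicate)
    out[[paste0("n_", prefix)]] <- df$copies_per_ul_sample
    out[[paste0("se_", prefix)]] <- df$se_copies_per_ul
    out[[paste0("sat_", prefix)]] <- df$saturated
    out[[paste0("eff_", prefix)]] <- df$effective_volume
    out
  }
  pairs <- inner_join(take("RT_PLUS", "plus"), take("RT_MINUS", "minus"),
                      by = c("sample_id", "target", "replicate"))
  if (!nrow(pairs)) abort("No RT_PLUS / RT_MINUS pairs found.")
  pairs |>
    mutate(v_plus = .data$se_plus^2, v_minus = .data$se_minus^2)
}

#' Gene copies per genome
#'
#' Ratio of a target's DNA copy number (RT- estimate) to that of a
#' single-copy reference gene measured on the same sample, each through its
#' own dilution chain (`copies_per_ul_sample` normalizes the analyzed
#' volumes). Delta-method confidence interval from the two independent
#' occupancy variances.
#'
#' @param quantified a `concentration_tbl`; only RT_MINUS rows are used.
#' @param reference_target name of the single-copy reference target.
#' @param targets targets to normalize (default: all non-reference).
#' @param level confidence level.
#' @return a tibble with one row per (sample, target, replicate):
#'   `copies_per_genome, se, ci_low, ci_high, reference_gene`.
#' @export
copies_per_genome <- function(quantified, reference_target, targets = NULL,
                              level = 0.95) {
  dna <- quantified |> filter(.data$rt_condition == "RT_MINUS")
  ref <- dna |> filter(.data$target == reference_target)
  if (!nrow(ref)) abort(paste0("Reference target not found: ", reference_target))
  if (any(ref$copies_per_ul_sample <= 0)) {
    abort("Single-copy reference estimate is 0; copies per genome is undefined.")
  }
  tgt <- dna |> filter(.data$target != reference_target)
  if (!is.null(targets)) tgt <- tgt |> filter(.data$target %in% targets)
  z <- qnorm(1 - (1 - level) / 2)
  tgt |>
    inner_join(ref |>
                 select("sample_id", "replicate",
                        ref_n = "copies_per_ul_sample",
                        ref_se = "se_copies_per_ul"),
               by = c("sample_id", "replicate")) |>
    mutate(copies_per_genome = .data$copies_per_ul_sample / .data$ref_n,
           se = sqrt(ratio_var(.data$copies_per_ul_sample, .data$ref_n,
                               .data$se_copies_per_ul^2, .data$ref_se^2)),
           ci_low = .data$copies_per_genome - z * .data$se,
           ci_high = .data$copies_per_genome + z * .data$se,
           reference_gene = reference_target) |>
    select("sample_id", "target", "replicate", "copies_per_genome",
           "se", "ci_low", "ci_high", "reference_gene")
}

#' Strand-specific mitochondrial transcription report
#'
#' Combines heavy-strand, light-strand and (optionally) combined-priming
#' Selfie results for the same mtDNA amplicon into one report: H, L, their
#' sum, the combined measurement, the percent excess of H over L
#' (`100 * (H - L) / L`), and a consistency z-score between the sum of the
#' separate strand measurements and the combined measurement (which should
#' agree when strand-specific priming is clean).
#'
#' @param h,l,combined either single-row `selfie_results` or numeric
#'   estimates; `combined` may be `NULL`. Standard errors are taken from
#'   `se` columns when available.
#' @return a tibble with one row per reported metric (`estimate`, `se`).
#' @export
strand_metrics <- function(h, l, combined = NULL) {
  get_est <- function(x) if (is.data.frame(x)) x$transcripts_per_gene[1] else as.numeric(x)[1]
  get_se <- function(x) if (is.data.frame(x) && "se" %in% names(x)) x$se[1] else NA_real_
  eh <- get_est(h); el <- get_est(l)
  seh <- get_se(h); sel <- get_se(l)
  sum_est <- eh + el
  sum_se <- sqrt(seh^2 + sel^2)
  rows <- tibble(
    metric = c("H", "L", "H_plus_L", "percent_excess_H"),
    estimate = c(eh, el, sum_est, strand_excess(eh, el)),
    se = c(seh, sel, sum_se,
           abs(100 / el) * sqrt(seh^2 + (eh / el)^2 * sel^2))
  )
  if (!is.null(combined)) {
    ec <- get_est(combined); sec <- get_se(combined)
    zc <- (sum_est - ec) / sqrt(sum_se^2 + sec^2)
    rows <- bind_rows(rows,
                      tibble(metric = c("combined", "consistency_z"),
                             estimate = c(ec, zc), se = c(sec, NA_real_)))
  }
  rows
}

#' Proviral integrations per genome
#'
#' Copy number of a provirus marker (e.g. WPRE) relative to a single-copy
#' genome reference measured on the same lysate, plus the total number of
#' template genes per genome (integrations + native copies).
#'
#' @param quantified a `concentration_tbl` containing RT_MINUS rows for the
#'   provirus marker and the reference gene.
#' @param provirus_target name of the provirus marker target.
#' @param reference_target name of the single-copy genome reference.
#' @param native_copies native copies of the transduced gene per genome.
#' @param level confidence level.
#' @return a tibble with `integrations_per_genome, total_template_genes,
#'   se, ci_low, ci_high` per (sample, replicate).
#' @export
integrations_per_genome <- function(quantified, provirus_target,
                                    reference_target, native_copies = 1,
                                    level = 0.95) {
  copies_per_genome(quantified, reference_target,
                    targets = provirus_target, level = level) |>
    rename(integrations_per_genome = "copies_per_genome") |>
    mutate(total_template_genes = .data$integrations_per_genome + native_copies)
}

#' Replicate summary: mean, SEM, n
#'
#' @param x numeric vector of replicate-level estimates (NAs dropped).
#' @return a tibble with `mean`, `sem` (sample SD / sqrt(n); `NA` when
#'   n = 1) and `n`.
#' @export
aggregate_replicates <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0L) abort("No non-missing values to aggregate.")
  tibble(mean = mean(x), sem = if (n >= 2L) sd(x) / sqrt(n) else NA_real_, n = n)
}

#' One-way ANOVA with Bonferroni post hoc pairwise comparisons
#'
#' Fits a one-way analysis of variance across groups and runs all pairwise
#' two-sample t tests (pooled-variance), multiplying each raw p-value by
#' the number of pairs and capping at 1 (Bonferroni). When every group has
#' zero within-group variance and all means are equal, F is reported as 0
#' with p = 1.
#'
#' @param data a data frame.
#' @param value name of the numeric response column.
#' @param group name of the grouping column.
#' @return an object of class `selfie_anova`; see [tidy.selfie_anova()] and
#'   [glance.selfie_anova()].
#' @export
compare_groups <- function(data, value = "value", group = "group") {
  y <- data[[value]]
  g <- factor(data[[group]])
  if (nlevels(g) < 2L) abort("Need at least two groups.")
  if (any(table(g) < 2L)) abort("Every group needs n >= 2.")
  group_sds <- tapply(y, g, sd)
  group_means <- tapply(y, g, mean)
  if (all(group_sds == 0)) {
    # degenerate: no within-group variance; F is 0/0 when means also agree
    fit <- NULL
    if (max(group_means) - min(group_means) == 0) {
      fstat <- 0; pval <- 1
    } else {
      fstat <- Inf; pval <- 0
    }
    df1 <- nlevels(g) - 1L
    df2 <- length(y) - nlevels(g)
  } else {
    fit <- aov(y ~ g)
    tab <- anova(fit)
    fstat <- tab$`F value`[1]
    pval <- tab$`Pr(>F)`[1]
    df1 <- tab$Df[1]
    df2 <- tab$Df[2]
  }
  lev <- levels(g)
  pairs_idx <- utils::combn(lev, 2L)
  n_pairs <- ncol(pairs_idx)
  pw <- map(seq_len(n_pairs), function(i) {
    a <- y[g == pairs_idx[1, i]]; b <- y[g == pairs_idx[2, i]]
    if (sd(a) == 0 && sd(b) == 0) {
      diff <- mean(a) - mean(b)
      tibble(group1 = pairs_idx[1, i], group2 = pairs_idx[2, i],
             estimate = diff, p.value = if (diff == 0) 1 else 0)
    } else {
      tt <- t.test(a, b, var.equal = TRUE)
      tibble(group1 = pairs_idx[1, i], group2 = pairs_idx[2, i],
             estimate = unname(tt$estimate[1] - tt$estimate[2]),
             p.value = tt$p.value)
    }
  }) |> list_rbind() |>
    mutate(p.adjusted = pmin(1, .data$p.value * n_pairs))
  structure(list(fit = fit, statistic = fstat, p.value = pval,
                 df = df1, df.residual = df2,
                 pairwise = pw, n_groups = nlevels(g)),
            class = "selfie_anova")
}

#' @export
print.selfie_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df, x$df.residual, x$statistic, x$p.value))
  cat(sprintf("%d Bonferroni-adjusted pairwise comparisons\n", nrow(x$pairwise)))
  invisible(x)
}

#' Tidy the pairwise comparisons of a [compare_groups()] fit
#' @param x a `selfie_anova` object.
#' @param ... unused.
#' @return a tibble with one row per group pair: `group1, group2, estimate,
#'   p.value, p.adjusted`.
#' @export
tidy.selfie_anova <- function(x, ...) x$pairwise

#' One-row summary of a [compare_groups()] fit
#' @param x a `selfie_anova` object.
#' @param ... unused.
#' @return a tibble with `statistic` (F), `df`, `df.residual`, `p.value`,
#'   `n_groups`.
#' @export
glance.selfie_anova <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, df.residual = x$df.residual,
         p.value = x$p.value, n_groups = x$n_groups)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Write a long results table as delimited text
#'
#' Header: `sample,target,metric,estimate,ci_low,ci_high,n,flags`.
#'
#' @param results tibble with those columns (see [selfie_run()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(results, path) {
  readr::write_csv(results, path)
  invisible(path)
}
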