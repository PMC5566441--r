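#' Poisson occupancy estimate of mean copies per droplet
#'
#' At random partitioning, the per-droplet copy number is Poisson, so the
#' mean copies per droplet is `lambda = -log(negatives / total)`. The
#' delta-method variance is `(1 - p_neg) / (total * p_neg)` with
#' `p_neg = negatives / total`. A well with no negative droplets is
#' saturated: lambda is unbounded and no numeric estimate is emitted.
#'
#' @param positives,total droplet counts (vectorized).
#' @return a tibble with `lambda`, `var_lambda`, `saturated`.
#' @export
estimate_lambda <- function(positives, total) {
  if (any(total < 1)) abort("`total` must be >= 1.")
  if (any(positives < 0) || any(positives > total)) {
    abort("`positives` must be between 0 and `total`.")
  }
  negatives <- total - positives
  sat <- negatives == 0
  p_neg <- ifelse(sat, NA_real_, negatives / total)
  tibble(lambda = ifelse(sat, Inf, -log(p_neg)),
         var_lambda = ifelse(sat, NA_real_, (1 - p_neg) / (total * p_neg)),
         saturated = sat)
}

#' Confidence interval for the per-droplet mean occupancy
#'
#' Normal (Wald) interval on lambda via the delta-method variance, replaced
#' by an exact Clopper-Pearson interval on the negative fraction
#' (transformed through `-log`) whenever either class has fewer than
#' `exact_threshold` droplets, where the normal approximation fails.
#' Saturated wells (no negatives) get `NA` bounds.
#'
#' @param positives,total droplet counts (vectorized).
#' @param level confidence level in (0, 1).
#' @param exact_threshold class-count floor below which the exact binomial
#'   interval is used.
#' @return a tibble with `low`, `high`, `method` (`"wald"` or `"exact"`).
#' @export
lambda_interval <- function(positives, total, level = 0.95,
                            exact_threshold = 30L) {
  if (level <= 0 || level >= 1) abort("`level` must be in (0, 1).")
  est <- estimate_lambda(positives, total)
  negatives <- total - positives
  alpha <- 1 - level
  z <- qnorm(1 - alpha / 2)

  use_exact <- positives < exact_threshold | negatives < exact_threshold
  # Wald on lambda
  low_w <- pmax(0, est$lambda - z * sqrt(est$var_lambda))
  high_w <- est$lambda + z * sqrt(est$var_lambda)
  # Clopper-Pearson on p_neg, transformed through -log (monotone decreasing)
  p_low <- ifelse(negatives == 0, 0,
                  qbeta(alpha / 2, negatives, positives + 1))
  p_high <- ifelse(positives == 0, 1,
                   qbeta(1 - alpha / 2, negatives + 1, positives))
  low_e <- -log(p_high)
  high_e <- ifelse(p_low > 0, -log(p_low), Inf)

  out <- tibble(
    low = ifelse(use_exact, low_e, low_w),
    high = ifelse(use_exact, high_e, high_w),
    method = ifelse(use_exact, "exact", "wald")
  )
  out$low[est$saturated] <- NA_real_
  out$high[est$saturated] <- NA_real_
  out$method[est$saturated] <- NA_character_
  out
}

#' Convert classified counts to absolute concentrations
#'
#' For each well: `lambda` (mean copies/droplet), `copies_per_reaction =
#' lambda * total`, and `copies_per_ul_sample = copies_per_reaction /
#' effective_sample_volume(chain)` -- the number of target copies per ul of
#' the original solubilized sample. Confidence bounds are the
#' [lambda_interval()] transformed by the same scale factor.
#'
#' @param counts a `classified_counts` tibble (or any tibble with
#'   `positives, negatives, total, dilution_chain` and metadata columns).
#' @param chains a named list of [dilution_chain()] objects keyed by the
#'   `dilution_chain` column, or a single chain used for all wells.
#' @param droplet_volume nominal droplet volume in nl (metadata; absolute
#'   ratios and per-sample volumes do not depend on it).
#' @param level confidence level for the intervals.
#' @return a `concentration_tbl` tibble with `lambda, var_lambda,
#'   copies_per_reaction, copies_per_ul_sample, se_copies_per_ul, ci_low,
#'   ci_high, saturated` added to the metadata columns.
#' @export
quantify_wells <- function(counts, chains, droplet_volume = 0.85,
                           level = 0.95) {
  if (inherits(chains, "dilution_chain")) chains <- list(default = chains)
  ids <- counts$dilution_chain %||% rep("default", nrow(counts))
  missing_chain <- setdiff(unique(ids), names(chains))
  if (length(missing_chain)) {
    abort(paste0("No dilution chain supplied for id(s): ", toString(missing_chain)))
  }
  eff <- unname(map_dbl(chains, effective_sample_volume)[ids])

  est <- estimate_lambda(counts$positives, counts$total)
  ci <- lambda_interval(counts$positives, counts$total, level = level)
  scale <- counts$total / eff

  out <- counts |>
    mutate(lambda = est$lambda,
           var_lambda = est$var_lambda,
           saturated = est$saturated,
           n_droplets = .data$total,
           droplet_volume = droplet_volume,
           effective_volume = eff,
           copies_per_reaction = est$lambda * .data$total,
           copies_per_ul_sample = est$lambda * scale,
           se_copies_per_ul = sqrt(est$var_lambda) * scale,
           ci_low = ci$low * scale,
           ci_high = ci$high * scale,
           ci_method = ci$method)
  class(out) <- unique(c("concentration_tbl", class(out)))
  out
}

#' Default quality-control thresholds
#'
#' @param dynamic_range dynamic-range ceiling in copies per reaction
#'   (default `1e5`, the droplet platform's stated upper limit).
#' @param droplet_floor minimum accepted droplets per well.
#' @param ntc_ceiling maximum tolerated positive droplets in an NTC well.
#' @param subsampling_cap maximum relative CI half-width before the
#'   subsampling-error flag is raised.
#' @return a named list of thresholds.
#' @export
qc_defaults <- function(dynamic_range = 1e5, droplet_floor = 1e4,
                        ntc_ceiling = 5, subsampling_cap = 0.25) {
  list(dynamic_range = dynamic_range, droplet_floor = droplet_floor,
       ntc_ceiling = ntc_ceiling, subsampling_cap = subsampling_cap)
}

#' Attach quality-control flags to concentration estimates
#'
#' Flags per well, joined with `;` in a `flags` column:
#' * `SATURATED` -- no negative droplets, or copies/reaction above the
#'   dynamic-range ceiling;
#' * `TOO_FEW_DROPLETS` -- fewer accepted droplets than the floor;
#' * `HIGH_SUBSAMPLING_ERROR` -- relative CI half-width above the cap;
#' * `NTC_CONTAMINATION` -- the same-target NTC well has more positives
#'   than the NTC ceiling.
#'
#' @param quantified a `concentration_tbl` ([quantify_wells()]).
#' @param ntc optional tibble of NTC wells (columns `target, positives`);
#'   by default NTC rows found inside `quantified` are used.
#' @param qc thresholds from [qc_defaults()].
#' @return `quantified` with a `flags` character column.
#' @export
qc_flags <- function(quantified, ntc = NULL, qc = qc_defaults()) {
  if (is.null(ntc) && "rt_condition" %in% names(quantified)) {
    ntc <- quantified |> filter(.data$rt_condition == "NTC")
  }
  ntc_bad <- character()
  if (!is.null(ntc) && nrow(ntc)) {
    ntc_bad <- unique(ntc$target[ntc$positives > qc$ntc_ceiling])
  }
  rel_hw <- with(quantified,
                 ifelse(is.na(ci_low) | copies_per_ul_sample <= 0, NA_real_,
                        (ci_high - ci_low) / 2 / copies_per_ul_sample))
  flags <- pmap(list(
    sat = quantified$saturated |
      (!is.na(quantified$copies_per_reaction) &
         quantified$copies_per_reaction > qc$dynamic_range),
    few = quantified$total < qc$droplet_floor,
    sub = !is.na(rel_hw) & rel_hw > qc$subsampling_cap,
    con = quantified$target %in% ntc_bad
  ), function(sat, few, sub, con) {
    paste(c(if (sat) "SATURATED", if (few) "TOO_FEW_DROPLETS",
            if (sub) "HIGH_SUBSAMPLING_ERROR", if (con) "NTC_CONTAMINATION"),
          collapse = ";")
  })
  quantified$flags <- unlist(flags)
  quantified
}

#' Test whether rows carry a given QC flag
#' @param x a tibble with a `flags` column, or a character vector of flags.
#' @param flag flag name, e.g. `"SATURATED"`.
#' @return logical vector.
#' @export
has_flag <- function(x, flag) {
  f <- if (is.data.frame(x)) x$flags else x
  vapply(strsplit(f %||% "", ";", fixed = TRUE),
         function(parts) flag %in% parts, logical(1))
}

#' Pool replicate wells before estimation
#'
#' Sums positive/negative counts across wells that share sample, target and
#' RT condition (partitions of one merged reaction); threshold provenance
#' is retained per source well in list-columns.
#'
#' @param counts a `classified_counts` tibble.
#' @return one row per (sample, target, rt_condition) with summed counts,
#'   `wells` and `thresholds` list-columns, and `n_wells`.
#' @export
merge_wells <- function(counts) {
  need <- c("sample_id", "target", "rt_condition")
  miss <- setdiff(need, names(counts))
  if (length(miss)) abort(paste0("merge_wells needs column(s): ", toString(miss)))
  out <- counts |>
    group_by(.data$sample_id, .data$target, .data$rt_condition) |>
    summarise(positives = sum(.data$positives),
              negatives = sum(.data$negatives),
              total = sum(.data$total),
              n_wells = n(),
              wells = list(.data$well_id),
              thresholds = list(.data$threshold),
              dilution_chain = {
                dc <- unique(.data$dilution_chain)
                if (length(dc) > 1) {
                  abort("Cannot merge wells with different dilution chains.")
                }
                dc
              },
              replicate = NA_integer_,
              well_id = paste(.data$well_id, collapse = "+"),
              .groups = "drop")
  class(out) <- unique(c("classified_counts", class(out)))
  out
}

#' Write a concentration table as delimited text
#'
#' Header: `sample,target,rt_condition,lambda,copies_per_reaction,
#' copies_per_ul_sample,ci_low,ci_high,flags`.
#'
#' @param quantified a `concentration_tbl`, ideally after [qc_flags()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_concentrations <- function(quantified, path) {
  readr::write_csv(
    tibble(sample = quantified$sample_id, target = quantified$target,
           rt_condition = quantified$rt_condition, lambda = quantified$lambda,
           copies_per_reaction = quantified$copies_per_reaction,
           copies_per_ul_sample = quantified$copies_per_ul_sample,
           ci_low = quantified$ci_low, ci_high = quantified$ci_high,
           flags = quantified$flags %||% ""),
    path)
  invisible(path)
}
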