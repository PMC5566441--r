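#' Automatic fluorescence threshold for one well
#'
#' Deterministic stand-in for the droplet reader's automatic threshold:
#' a two-class variance-maximizing (Otsu-style) split of the amplitude
#' histogram (256 bins spanning the observed range), with the threshold
#' placed at the split point. If the distribution is degenerate or
#' effectively unimodal -- the two candidate classes have means closer than
#' twice the larger class standard deviation -- no valley separates the
#' modes, and a flagged threshold at `max(amplitude) + 1` is returned so the
#' well classifies as all-negative.
#'
#' With very rare positives (below roughly 0.2% of droplets) the
#' between-class variance of the true split can fall below that of a split
#' inside the negative mode; use a manual or consensus threshold for such
#' wells (see the `manual` and `consensus` arguments of [classify_wells()]).
#'
#' @param amplitudes numeric vector of droplet fluorescence values.
#' @param bins number of histogram bins.
#' @param min_droplets minimum droplets required (contract floor).
#' @return a list with `threshold` (scalar), `method` (`"AUTO"`), and
#'   `flagged` (`TRUE` when no valley was found).
#' @export
auto_threshold <- function(amplitudes, bins = 256L, min_droplets = 100L) {
  if (length(amplitudes) < min_droplets) {
    abort(sprintf("auto_threshold requires >= %d droplets, got %d.",
                  min_droplets, length(amplitudes)))
  }
  flagged_result <- function() {
    list(threshold = max(amplitudes) + 1, method = "AUTO", flagged = TRUE)
  }
  rng <- range(amplitudes)
  if (diff(rng) == 0) return(flagged_result())

  breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
  idx <- findInterval(amplitudes, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  h <- tabulate(idx, nbins = bins)
  mids <- (breaks[-1L] + breaks[-(bins + 1L)]) / 2
  w1 <- cumsum(h)[-bins]
  m1 <- cumsum(h * mids)[-bins]
  tot <- length(amplitudes)
  mtot <- sum(h * mids)
  w2 <- tot - w1
  ok <- w1 > 0 & w2 > 0
  # between-class variance, up to a constant factor: (m1*tot - mtot*w1)^2/(w1*w2)
  between <- rep(-Inf, bins - 1L)
  between[ok] <- (m1[ok] * tot - mtot * w1[ok])^2 / (w1[ok] * w2[ok])
  k <- which.max(between)  # first maximum: deterministic tie-break
  thr <- breaks[k + 1L]

  lower <- amplitudes[amplitudes <= thr]
  upper <- amplitudes[amplitudes > thr]
  if (!length(lower) || !length(upper)) return(flagged_result())
  # unimodality guard: a mid-mode split of a single Gaussian gives class
  # means ~1.6 sigma apart with class SDs ~0.6 sigma (ratio ~2.7); genuine
  # mode pairs sit far beyond 4x the within-class spread
  sep <- mean(upper) - mean(lower)
  spread <- 4 * max(sd0(lower), sd0(upper), 1e-12)
  if (sep < spread) return(flagged_result())
  list(threshold = thr, method = "AUTO", flagged = FALSE)
}

sd0 <- function(x) if (length(x) > 1L) sd(x) else 0

#' Classify droplets of one well against a threshold
#'
#' A droplet is positive when its amplitude is strictly greater than the
#' threshold (droplets exactly at the threshold count as negative).
#'
#' @param amplitudes numeric vector of droplet fluorescence values.
#' @param threshold finite scalar threshold.
#' @return a tibble with `positives, negatives, total, threshold`.
#' @export
classify_droplets <- function(amplitudes, threshold) {
  if (!length(amplitudes)) abort("Cannot classify an empty well.")
  if (!is.finite(threshold)) abort("`threshold` must be finite.")
  pos <- sum(amplitudes > threshold)
  tibble(positives = pos, negatives = length(amplitudes) - pos,
         total = length(amplitudes), threshold = threshold)
}

#' Classify every well of a plate
#'
#' Applies [auto_threshold()] per well unless a manual threshold for the
#' well's target is supplied; NTC wells and wells whose automatic threshold
#' was flagged fall back to the consensus (median unflagged) threshold of
#' their target when one exists.
#'
#' @param wells a `droplet_wells` tibble.
#' @param manual optional named numeric vector of per-target manual
#'   thresholds, e.g. `c("Gsk3b-81" = 4000)`.
#' @param consensus use per-target consensus thresholds for NTC/flagged
#'   wells (default `TRUE`).
#' @param min_droplets forwarded to [auto_threshold()].
#' @return a `classified_counts` tibble: one row per well with
#'   `positives, negatives, total, threshold, method, threshold_flagged`.
#' @export
classify_wells <- function(wells, manual = NULL, consensus = TRUE,
                           min_droplets = 100L) {
  stopifnot(inherits(wells, "droplet_wells") || is.data.frame(wells))
  auto <- map(wells$amplitudes, auto_threshold, min_droplets = min_droplets)
  out <- wells |>
    mutate(threshold = map_dbl(auto, "threshold"),
           method = "AUTO",
           threshold_flagged = map_dbl(auto, "flagged") > 0)

  if (consensus) {
    cons <- out |>
      filter(!.data$threshold_flagged, .data$rt_condition != "NTC") |>
      group_by(.data$target) |>
      summarise(consensus = median(.data$threshold), .groups = "drop")
    out <- out |>
      left_join(cons, by = "target") |>
      mutate(use_cons = (.data$threshold_flagged | .data$rt_condition == "NTC") &
               !is.na(.data$consensus),
             threshold = ifelse(.data$use_cons, .data$consensus, .data$threshold),
             threshold_flagged = .data$threshold_flagged & !.data$use_cons) |>
      select(-"consensus", -"use_cons")
  }
  if (!is.null(manual)) {
    hit <- match(out$target, names(manual))
    out <- out |>
      mutate(threshold = ifelse(!is.na(hit), unname(manual)[hit], .data$threshold),
             method = ifelse(!is.na(hit), "MANUAL", .data$method),
             threshold_flagged = ifelse(!is.na(hit), FALSE, .data$threshold_flagged))
  }
  counts <- map2(out$amplitudes, out$threshold,
                 function(a, t) classify_droplets(a, t)[, c("positives", "negatives")])
  out <- out |>
    mutate(positives = map_dbl(counts, "positives"),
           negatives = map_dbl(counts, "negatives"),
           total = .data$accepted_droplets) |>
    select("well_id", "sample_id", "target", "rt_condition", "dilution_chain",
           "replicate", "positives", "negatives", "total", "threshold",
           "method", "threshold_flagged")
  class(out) <- unique(c("classified_counts", class(out)))
  out
}

#' Write classified counts as delimited text
#'
#' Header: `well,target,rt_condition,positives,negatives,total,threshold,method`.
#'
#' @param counts a `classified_counts` tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_classified_counts <- function(counts, path) {
  readr::write_csv(
    tibble(well = counts$well_id, target = counts$target,
           rt_condition = counts$rt_condition, positives = counts$positives,
           negatives = counts$negatives, total = counts$total,
           threshold = counts$threshold, method = counts$method),
    path)
  invisible(path)
}
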