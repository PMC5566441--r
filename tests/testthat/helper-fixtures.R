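# classified-counts rows with full metadata, for unit tests that start
# from droplet counts rather than amplitudes
make_counts <- function(positives, total, sample_id = "s1", target = "tgt",
                        rt_condition = "RT_MINUS", replicate = 1L,
                        chain = "default", well_id = NULL,
                        threshold = 5000) {
  n <- length(positives)
  df <- tibble::tibble(
    well_id = well_id %||% sprintf("W%02d", seq_len(n)),
    sample_id = rep_len(sample_id, n),
    target = rep_len(target, n),
    rt_condition = rep_len(rt_condition, n),
    dilution_chain = rep_len(chain, n),
    replicate = as.integer(rep_len(replicate, n)),
    positives = positives,
    negatives = total - positives,
    total = total,
    threshold = rep_len(threshold, n),
    method = "MANUAL",
    threshold_flagged = FALSE
  )
  class(df) <- unique(c("classified_counts", class(df)))
  df
}

`%||%` <- function(x, y) if (is.null(x)) y else x

default_chains <- function() list(default = methods_chain())

# a pair of quantified RT+/RT- rows built directly from counts
quantified_pair <- function(pos_plus, pos_minus, total = 20000,
                            sample_id = "s1", target = "tgt",
                            replicate = 1L) {
  counts <- dplyr::bind_rows(
    make_counts(pos_plus, total, sample_id, target, "RT_PLUS", replicate),
    make_counts(pos_minus, total, sample_id, target, "RT_MINUS", replicate)
  )
  quantify_wells(counts, default_chains())
}

# small droplet_wells tibble from explicit amplitude vectors
make_wells <- function(amps, target = "tgt", sample_id = "s1",
                       rt_condition = NULL) {
  n <- length(amps)
  rt <- rt_condition %||% rep_len(c("RT_PLUS", "RT_MINUS", "NTC"), n)
  droplet_wells(tibble::tibble(
    well_id = sprintf("W%02d", seq_len(n)),
    sample_id = rep_len(sample_id, n),
    target = rep_len(target, n),
    rt_condition = rt[seq_len(n)],
    dilution_chain = "default",
    replicate = 1L,
    accepted_droplets = lengths(amps),
    amplitudes = amps
  ))
}
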