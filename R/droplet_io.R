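#' Read a plate layout table
#'
#' Delimited text (comma default, tab accepted) with header
#' `well,sample,target,rt_condition,dilution_chain,replicate`. Well ids must
#' be unique, `rt_condition` must be one of `RT_PLUS`, `RT_MINUS`, `NTC`,
#' every RT_PLUS well must have an RT_MINUS partner for the same
#' (sample, target, replicate), and (unless `require_ntc = FALSE`) every
#' target must carry at least one NTC well.
#'
#' @param path file path.
#' @param delim field delimiter; `NULL` sniffs comma vs tab from the header.
#' @param require_ntc require >= 1 NTC well per target.
#' @return a tibble with columns `well_id, sample_id, target, rt_condition,
#'   dilution_chain, replicate`.
#' @export
read_plate_layout <- function(path, delim = NULL, require_ntc = TRUE) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  delim <- delim %||% sniff_delim(path)
  df <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    well = readr::col_character(), sample = readr::col_character(),
    target = readr::col_character(), rt_condition = readr::col_character(),
    dilution_chain = readr::col_character(), replicate = readr::col_integer()
  ), progress = FALSE)
  need <- c("well", "sample", "target", "rt_condition", "dilution_chain", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort(paste0("Layout is missing column(s): ", toString(miss)))
  layout <- tibble(well_id = df$well, sample_id = df$sample, target = df$target,
                   rt_condition = df$rt_condition,
                   dilution_chain = df$dilution_chain, replicate = df$replicate)
  check_layout(layout, require_ntc = require_ntc)
  layout
}

#' Validate a plate layout tibble
#' @param layout tibble as returned by [read_plate_layout()].
#' @param require_ntc require >= 1 NTC well per target.
#' @return the layout, invisibly; aborts on violation.
#' @export
check_layout <- function(layout, require_ntc = TRUE) {
  dup <- unique(layout$well_id[duplicated(layout$well_id)])
  if (length(dup)) abort(paste0("Duplicate well id(s) in layout: ", toString(dup)))
  bad <- setdiff(unique(layout$rt_condition), c("RT_PLUS", "RT_MINUS", "NTC"))
  if (length(bad)) abort(paste0("Unknown rt_condition value(s): ", toString(bad)))
  plus <- layout |> filter(.data$rt_condition == "RT_PLUS")
  minus <- layout |> filter(.data$rt_condition == "RT_MINUS")
  orphan <- anti_join(plus, minus, by = c("sample_id", "target", "replicate"))
  if (nrow(orphan)) {
    abort(paste0("RT_PLUS well(s) without an RT_MINUS partner: ",
                 toString(orphan$well_id),
                 ". The Selfie statistic is undefined without the RT- duplicate."))
  }
  if (require_ntc) {
    no_ntc <- setdiff(unique(layout$target),
                      unique(layout$target[layout$rt_condition == "NTC"]))
    if (length(no_ntc)) {
      abort(paste0("Target(s) without an NTC well: ", toString(no_ntc)))
    }
  }
  invisible(layout)
}

#' Read a droplet amplitude table and assemble wells
#'
#' Long-format delimited text, one row per accepted droplet, header
#' `well,channel,amplitude` (comma default, tab accepted). Every well in the
#' file must be present in the layout; wells present in the layout but
#' absent from the file are simply not returned.
#'
#' @param path file path.
#' @param layout plate layout tibble ([read_plate_layout()]).
#' @param delim field delimiter; `NULL` sniffs comma vs tab.
#' @return a `droplet_wells` tibble: one row per (well, channel) with the
#'   layout metadata, `accepted_droplets`, and an `amplitudes` list-column.
#' @export
read_amplitude_table <- function(path, layout, delim = NULL) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  delim <- delim %||% sniff_delim(path)
  df <- suppressWarnings(readr::read_delim(path, delim = delim,
    col_types = readr::cols(
      well = readr::col_character(), channel = readr::col_character(),
      amplitude = readr::col_double()
    ), progress = FALSE, lazy = FALSE))
  miss <- setdiff(c("well", "channel", "amplitude"), names(df))
  if (length(miss)) abort(paste0("Amplitude table is missing column(s): ", toString(miss)))
  probs <- readr::problems(df)
  if (nrow(probs)) {
    abort(paste0("Non-numeric or malformed amplitude value(s) at data row(s): ",
                 toString(head(probs$row, 10))))
  }
  if (anyNA(df$amplitude)) {
    abort(paste0("Missing amplitude value(s) at data row(s): ",
                 toString(head(which(is.na(df$amplitude)), 10))))
  }
  unknown <- setdiff(unique(df$well), layout$well_id)
  if (length(unknown)) {
    abort(paste0("Amplitude table contains well(s) absent from the layout: ",
                 toString(unknown)))
  }
  wells <- df |>
    group_by(well_id = .data$well, channel = .data$channel) |>
    summarise(amplitudes = list(.data$amplitude), .groups = "drop") |>
    mutate(accepted_droplets = lengths(.data$amplitudes)) |>
    inner_join(layout, by = "well_id") |>
    select("well_id", "sample_id", "target", "rt_condition",
           "dilution_chain", "replicate", "channel",
           "accepted_droplets", "amplitudes")
  droplet_wells(wells)
}

#' Construct / validate a droplet-wells tibble
#'
#' One row per well: metadata columns, `accepted_droplets`, and an
#' `amplitudes` list-column of finite fluorescence values (arbitrary units).
#'
#' @param df a data frame with columns `well_id, sample_id, target,
#'   rt_condition, dilution_chain, replicate, accepted_droplets, amplitudes`
#'   (a `channel` column is added if absent).
#' @return the validated tibble with class `droplet_wells`.
#' @export
droplet_wells <- function(df) {
  df <- as_tibble(df)
  if (!"channel" %in% names(df)) df$channel <- "ch1"
  need <- c("well_id", "sample_id", "target", "rt_condition", "dilution_chain",
            "replicate", "channel", "accepted_droplets", "amplitudes")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort(paste0("droplet_wells is missing column(s): ", toString(miss)))
  if (!is.list(df$amplitudes)) abort("`amplitudes` must be a list-column.")
  n <- lengths(df$amplitudes)
  if (any(df$accepted_droplets != n)) {
    abort("`accepted_droplets` must equal the number of amplitude values in every well.")
  }
  if (any(n < 1L)) abort("Every analyzable well must contain at least one droplet.")
  if (!all(map_dbl(df$amplitudes, function(a) all(is.finite(a))) == 1)) {
    abort("All amplitudes must be finite.")
  }
  class(df) <- unique(c("droplet_wells", class(df)))
  df
}

#' Write wells back to the amplitude-table dialect
#'
#' Emits the long `well,channel,amplitude` format read by
#' [read_amplitude_table()]; the round trip preserves the amplitude multiset
#' of every well exactly.
#'
#' @param wells a `droplet_wells` tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_amplitude_csv <- function(wells, path) {
  long <- wells |>
    select(well = "well_id", "channel", "amplitudes") |>
    unnest("amplitudes") |>
    rename(amplitude = "amplitudes")
  readr::write_csv(long, path)
  invisible(path)
}

#' Write a plate layout table
#' @param layout layout tibble (columns as in [read_plate_layout()] output).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_plate_layout <- function(layout, path) {
  readr::write_csv(
    tibble(well = layout$well_id, sample = layout$sample_id,
           target = layout$target, rt_condition = layout$rt_condition,
           dilution_chain = layout$dilution_chain, replicate = layout$replicate),
    path)
  invisible(path)
}

sniff_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}
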