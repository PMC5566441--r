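#' Dilution chains: volume bookkeeping from lysate to dPCR reaction
#'
#' A dilution chain records how a solubilized sample travels from the lysate
#' tube into the final dPCR reaction: the volume of sample that enters the
#' chain, and for each subsequent step the aliquot taken from the previous
#' pool and the final volume after adding the other reagents or diluent.
#' The quantity that matters downstream is the *effective sample volume*:
#' how many microlitres of original lysate end up inside one reaction.
#'
#' The default protocol chain is: up to 0.5 ul lysate into a 5 ul
#' pre-annealing mix, all 5 ul into a 10 ul reverse-transcription reaction,
#' all 10 ul diluted to 95 ul, and 9.5 ul of that dilution dispensed into
#' the 20 ul dPCR reaction, giving 0.5 x 9.5/95 = 0.05 ul of sample per
#' reaction.
#'
#' @param sample_volume volume of lysate entering the chain, in ul.
#' @param aliquots numeric vector: volume drawn from the previous pool at
#'   each step, in ul. The first aliquot is drawn from the sample itself.
#' @param final_volumes numeric vector, same length as `aliquots`: pool
#'   volume after each step, in ul.
#' @param reaction_volume optional final dPCR reaction volume, in ul (kept
#'   as metadata; it does not enter the effective-volume calculation).
#' @return an object of class `dilution_chain`.
#' @examples
#' effective_sample_volume(methods_chain())  # 0.05
#' @export
dilution_chain <- function(sample_volume, aliquots = sample_volume,
                           final_volumes = sample_volume,
                           reaction_volume = NULL) {
  if (length(aliquots) != length(final_volumes)) {
    abort("`aliquots` and `final_volumes` must have the same length.")
  }
  vols <- c(sample_volume, aliquots, final_volumes, reaction_volume)
  if (any(!is.finite(vols)) || any(vols <= 0)) {
    abort("All chain volumes must be finite and > 0.")
  }
  pools <- c(sample_volume, head(final_volumes, -1L))
  if (any(aliquots > pools + 1e-12)) {
    abort("Each aliquot must not exceed the volume of the pool it is drawn from.")
  }
  structure(
    list(sample_volume = sample_volume, aliquots = aliquots,
         final_volumes = final_volumes, reaction_volume = reaction_volume),
    class = "dilution_chain"
  )
}

#' @export
print.dilution_chain <- function(x, ...) {
  cat(sprintf("<dilution_chain> %g ul sample, %d step(s), effective %g ul/reaction\n",
              x$sample_volume, length(x$aliquots), effective_sample_volume(x)))
  invisible(x)
}

#' Default protocol dilution chain
#'
#' Lysate (0.5 ul by default) -> 5 ul pre-annealing -> 10 ul RT ->
#' 95 ul dilution -> 9.5 ul into the 20 ul dPCR reaction.
#'
#' @param sample_volume lysate volume entering the pre-annealing step, ul.
#' @return a [dilution_chain()].
#' @export
methods_chain <- function(sample_volume = 0.5) {
  dilution_chain(sample_volume,
                 aliquots      = c(sample_volume, 5, 10, 9.5),
                 final_volumes = c(5, 10, 95, 20),
                 reaction_volume = 20)
}

#' Effective sample volume per dPCR reaction
#'
#' Volume of original lysate contained in one reaction:
#' `sample_volume * prod(aliquot_i / pool_{i-1})`, where `pool_0` is the
#' sample itself. Multiplicative: concatenating chains multiplies their
#' dilution factors.
#'
#' @param chain a [dilution_chain()].
#' @return effective sample volume in ul (scalar > 0).
#' @export
effective_sample_volume <- function(chain) {
  stopifnot(inherits(chain, "dilution_chain"))
  pools <- c(chain$sample_volume, head(chain$final_volumes, -1L))
  chain$sample_volume * prod(chain$aliquots / pools)
}

#' Dilution factor of a chain (effective volume / input volume)
#' @param chain a [dilution_chain()].
#' @return dimensionless fraction in (0, 1].
#' @export
dilution_factor <- function(chain) {
  effective_sample_volume(chain) / chain$sample_volume
}

#' Concatenate two dilution chains
#'
#' The second chain's input must be drawn from the first chain's final pool,
#' i.e. `tail(a$final_volumes, 1) == b$sample_volume`.
#'
#' @param a,b [dilution_chain()] objects.
#' @return a single [dilution_chain()] whose dilution factor is the product
#'   of the two.
#' @export
chain_concat <- function(a, b) {
  stopifnot(inherits(a, "dilution_chain"), inherits(b, "dilution_chain"))
  if (!isTRUE(all.equal(tail(a$final_volumes, 1L), b$sample_volume))) {
    abort("Chains do not connect: second chain's sample volume must equal the first chain's last pool volume.")
  }
  dilution_chain(a$sample_volume,
                 aliquots      = c(a$aliquots, b$aliquots),
                 final_volumes = c(a$final_volumes, b$final_volumes),
                 reaction_volume = b$reaction_volume)
}

#' Append an extra dilution step to a chain
#'
#' Adds a step that carries a fraction `factor` of the last pool forward at
#' unchanged pool volume (an aliquot topped up with diluent). Used to bring
#' high-copy targets into the dPCR dynamic range.
#'
#' @param chain a [dilution_chain()].
#' @param factor fraction in (0, 1] of the last pool carried forward.
#' @return a [dilution_chain()].
#' @export
with_extra_dilution <- function(chain, factor) {
  stopifnot(inherits(chain, "dilution_chain"))
  if (!is.finite(factor) || factor <= 0 || factor > 1) {
    abort("`factor` must be in (0, 1].")
  }
  if (factor == 1) return(chain)
  v <- tail(chain$final_volumes, 1L)
  k <- length(chain$aliquots)
  # insert before the final draw so the last recorded step still feeds the reaction
  dilution_chain(chain$sample_volume,
                 aliquots      = c(head(chain$aliquots, k - 1L), factor * v_prev(chain), tail(chain$aliquots, 1L)),
                 final_volumes = c(head(chain$final_volumes, k - 1L), v_prev(chain), tail(chain$final_volumes, 1L)),
                 reaction_volume = chain$reaction_volume)
}

# pool volume feeding the final draw
v_prev <- function(chain) {
  k <- length(chain$final_volumes)
  if (k >= 2L) chain$final_volumes[k - 1L] else chain$sample_volume
}

#' Write / read a set of dilution chains as delimited text
#'
#' Long format, one row per step:
#' `chain,sample_volume,step,aliquot,final_volume,reaction_volume`.
#'
#' @param chains named list of [dilution_chain()] objects.
#' @param path file path.
#' @return `write_dilution_chains()` returns `path` invisibly;
#'   `read_dilution_chains()` returns a named list of chains.
#' @export
write_dilution_chains <- function(chains, path) {
  stopifnot(is.list(chains), !is.null(names(chains)))
  rows <- imap(chains, function(ch, id) {
    tibble(chain = id,
           sample_volume = ch$sample_volume,
           step = seq_along(ch$aliquots),
           aliquot = ch$aliquots,
           final_volume = ch$final_volumes,
           reaction_volume = ch$reaction_volume %||% NA_real_)
  })
  readr::write_csv(list_rbind(rows), path)
  invisible(path)
}

#' @rdname write_dilution_chains
#' @export
read_dilution_chains <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    chain = readr::col_character(), sample_volume = readr::col_double(),
    step = readr::col_integer(), aliquot = readr::col_double(),
    final_volume = readr::col_double(), reaction_volume = readr::col_double()
  ), progress = FALSE)
  chains <- df |>
    group_by(.data$chain) |>
    arrange(.data$step, .by_group = TRUE) |>
    group_map(function(g, key) {
      rv <- g$reaction_volume[1]
      dilution_chain(g$sample_volume[1], g$aliquot, g$final_volume,
                     reaction_volume = if (is.na(rv)) NULL else rv)
    })
  names(chains) <- sort(unique(df$chain))
  chains
}
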