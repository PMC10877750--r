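#' Composite solvent greenness score
#'
#' Geometric mean of the four solvent sustainability sub-scores:
#' `G = (H * S * E * W)^(1/4)`, where H, S, E and W grade health, safety,
#' environment and waste on a (0, 10] scale. G is monotone in each sub-score,
#' permutation-invariant, and always lies between the smallest and largest
#' input.
#'
#' @param h,s,e,w Sub-scores in (0, 10]; vectors are scored elementwise.
#' @return G, dimensionless.
#' @examples
#' g_score(4, 9, 4, 9) # 6
#' @export
g_score <- function(h, s, e, w) {
  v <- cbind(h, s, e, w)
  if (any(v <= 0)) rlang::abort("Sub-scores must be > 0.")
  if (any(v > 10)) rlang::abort("Sub-scores must be <= 10.")
  (h * s * e * w)^(1 / 4)
}

#' Score solvents from a sub-score table
#'
#' @param scores Data frame with columns `h`, `s`, `e`, `w` (and any id
#'   columns, e.g. `solvent`).
#' @return `scores` with a `g` column appended.
#' @export
solvent_greenness <- function(scores) {
  need <- c("h", "s", "e", "w")
  if (!all(need %in% names(scores))) {
    rlang::abort("`scores` needs columns h, s, e, w.")
  }
  dplyr::mutate(scores, g = g_score(.data$h, .data$s, .data$e, .data$w))
}

#' Published composite greenness scores of candidate solvents
#'
#' Reference G values reported for the solvents weighed during method
#' development (the sub-scores behind them come from an external solvent
#' sustainability guide and are not shipped): ethanol 6.6, DMSO 6.4,
#' methanol 5.8. Documented constants, not recomputed.
#'
#' @return Tibble: `solvent`, `g`.
#' @export
reference_solvent_scores <- function() {
  tibble::tibble(solvent = c("ethanol", "dmso", "methanol"),
                 g = c(6.6, 6.4, 5.8))
}
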