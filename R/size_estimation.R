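#' Estimate the size of the true interactome
#'
#' Solves the mixture equation
#' `n_interactome * sensitivity + (n_all_pairs - n_interactome) * (1 - specificity) = n_predict`
#' for `n_interactome`: the predictions are modelled as true interactions
#' recovered at the validated sensitivity plus non-interacting pairs leaking
#' through at the false-positive rate. Requires
#' `sensitivity > 1 - specificity`, otherwise the equation is ill-posed. A
#' negative solution is reported as an infeasibility diagnosis (with a
#' warning), never clamped.
#'
#' @param n_predict Number of predicted associations.
#' @param n_all_pairs Number of candidate gene pairs, e.g.
#'   `n_genes * (n_genes - 1) / 2`. Always an explicit input.
#' @param sensitivity,specificity Validated prediction performance, in
#'   `(0, 1]` and `[0, 1]`.
#' @return A one-row tibble: `n_interactome`, `pairs_per_interaction`
#'   (`n_all_pairs / n_interactome`), `expected_covered`
#'   (`sensitivity * n_interactome`, the predicted true interactions),
#'   `expected_precision` (`expected_covered / n_predict`) and `feasible`.
#' @export
estimate_interactome_size <- function(n_predict, n_all_pairs,
                                      sensitivity, specificity) {
  stopifnot(
    n_predict >= 0, n_all_pairs > 0, n_predict <= n_all_pairs,
    sensitivity > 0, sensitivity <= 1,
    specificity >= 0, specificity <= 1
  )
  fpr <- 1 - specificity
  if (sensitivity <= fpr) {
    abort(sprintf(
      "ill-posed equation: sensitivity (%g) must exceed 1 - specificity (%g)",
      sensitivity, fpr
    ))
  }
  n_int <- (n_predict - fpr * n_all_pairs) / (sensitivity - fpr)
  feasible <- n_int >= 0
  if (!feasible) {
    warn(sprintf(
      "negative interactome size (%g): predictions fewer than the expected false positives alone",
      n_int
    ))
  }
  tibble(
    n_interactome = n_int,
    pairs_per_interaction = n_all_pairs / n_int,
    expected_covered = sensitivity * n_int,
    expected_precision = sensitivity * n_int / n_predict,
    feasible = feasible
  )
}

#' Forward prediction count for a known interactome size
#'
#' The forward form of the size-estimation equation; useful as a round-trip
#' check and for planning.
#'
#' @inheritParams estimate_interactome_size
#' @param n_interactome True interactome size.
#' @return Expected number of predicted associations.
#' @export
expected_predictions <- function(n_interactome, n_all_pairs,
                                 sensitivity, specificity) {
  n_interactome * sensitivity +
    (n_all_pairs - n_interactome) * (1 - specificity)
}

#' Support rate as a rounded percentage
#'
#' `100 * n_supported / n_reported`, rounded half-up to two decimals (the
#' convention used when reporting how many annotations of a tool are backed
#' by published results).
#'
#' @param n_supported,n_reported Non-negative counts,
#'   `n_supported <= n_reported`, `n_reported > 0`.
#' @return The percentage, a bare number.
#' @export
support_rate <- function(n_supported, n_reported) {
  if (n_reported == 0) abort("n_reported must be positive")
  stopifnot(n_supported >= 0, n_supported <= n_reported)
  pct <- 100 * n_supported / n_reported
  floor(pct * 100 + 0.5) / 100
}
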