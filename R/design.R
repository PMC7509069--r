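#' Specify a longitudinal simulation design
#'
#' Bundles the factors of one simulation condition: the number of attributes
#' `k`, items `j`, examinees `n`, the item-discrimination regime, the number
#' of time points, the initial per-attribute mastery probabilities with their
#' latent (tetrachoric-style) correlation, and the per-interval attribute
#' transition generators.
#'
#' Defaults reproduce the published study conditions: three time points,
#' initial mastery `(0.4, 0.4, 0.2)` for `k = 3` and
#' `(0.4, 0.4, 0.3, 0.3, 0.2, 0.2)` for `k = 6`, latent correlation `0.5`,
#' and the tabulated transition generators for both attribute counts. The
#' high regime draws slip/guess from `U(0, 0.2)`, the mixed regime from
#' `U(0, 0.4)`.
#'
#' @param k Number of attributes (3 or 6 have built-in defaults; any `k >= 1`
#'   is allowed if `initial_mastery` and `transitions` are supplied).
#' @param j Number of items.
#' @param n Number of examinees.
#' @param regime `"high"` or `"mixed"` item-discrimination regime.
#' @param t_points Number of time points.
#' @param initial_mastery Per-attribute initial mastery probabilities.
#' @param correlation Exchangeable latent correlation among attributes at
#'   the first time point, in `[0, 1)`.
#' @param transitions List of `t_points - 1` intervals, each a list of `k`
#'   row-stochastic 2x2 matrices (rows: from non-mastery/mastery).
#' @return A list of class `"study_design"`.
#' @examples
#' study_design(k = 3, j = 20, n = 500, regime = "high")
#' @export
study_design <- function(k = 3, j = 20, n = 500,
                         regime = c("high", "mixed"),
                         t_points = 3,
                         initial_mastery = NULL,
                         correlation = 0.5,
                         transitions = NULL) {
  regime <- match.arg(regime)
  if (is.null(initial_mastery)) {
    initial_mastery <- switch(as.character(k),
      "3" = c(0.4, 0.4, 0.2),
      "6" = c(0.4, 0.4, 0.3, 0.3, 0.2, 0.2),
      abort("Supply `initial_mastery` explicitly for k other than 3 or 6."))
  }
  if (length(initial_mastery) != k) abort("`initial_mastery` must have length k.")
  assert_prob(initial_mastery, "initial_mastery")
  if (correlation < 0 || correlation >= 1) abort("`correlation` must lie in [0, 1).")
  if (is.null(transitions) && t_points > 1) {
    transitions <- switch(as.character(k),
      "3" = cda_fixture("transitions_k3"),
      "6" = cda_fixture("transitions_k6"),
      abort("Supply `transitions` explicitly for k other than 3 or 6."))
    transitions <- rep(transitions, length.out = t_points - 1)
  }
  if (t_points > 1) {
    if (length(transitions) != t_points - 1) {
      abort("`transitions` must supply one interval per consecutive wave pair.")
    }
    for (iv in transitions) {
      if (length(iv) != k) abort("Each interval needs one 2x2 matrix per attribute.")
      for (m in iv) assert_row_stochastic(m, "transition matrix")
    }
  }
  structure(
    list(k = k, j = j, n = n, regime = regime, t_points = t_points,
         initial_mastery = initial_mastery, correlation = correlation,
         transitions = transitions),
    class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf(
    "Longitudinal design: k = %d attributes, j = %d items, n = %d, %s regime, %d wave(s)\n",
    x$k, x$j, x$n, x$regime, x$t_points))
  cat("initial mastery:", paste(x$initial_mastery, collapse = ", "),
      sprintf("(latent correlation %.2f)\n", x$correlation))
  invisible(x)
}

#' Draw item parameters for a design
#'
#' Slip and guess are drawn independently per item from the regime's uniform
#' range: `U(0, 0.2)` under high discrimination, `U(0, 0.4)` under mixed.
#'
#' @param design A [study_design()].
#' @param seed Optional seed for a reproducible draw.
#' @return A tibble with columns `item`, `slip`, `guess`.
#' @export
draw_item_params <- function(design, seed = NULL) {
  upper <- if (design$regime == "high") 0.2 else 0.4
  draw <- function() tibble(
    item = seq_len(design$j),
    slip = runif(design$j, 0, upper),
    guess = runif(design$j, 0, upper))
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' The 40-item Q matrix used in double-length designs
#'
#' The published study varies test length between 20 and 40 items but prints
#' only the 20-item Q matrices. The 40-item designs here stack the 20-item Q
#' twice, which preserves each attribute's coverage profile exactly; fresh
#' slip/guess values are drawn from the regime's range via
#' [draw_item_params()].
#'
#' @param q A 20-item [q_matrix()] (any Q matrix is accepted).
#' @return A [q_matrix()] with twice the rows of `q`.
#' @export
stack_q <- function(q) {
  q_matrix(rbind(unclass(q), unclass(q)), quiet = TRUE,
           attribute_ids = colnames(q))
}
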