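# Markov-chain layer of the model: initial-state probabilities and
# transition matrices are estimated by count normalization from the
# wave-wise classifications; the observation model is the trained SSOM and
# is never re-estimated (no Baum-Welch).

#' Estimate initial-state probabilities
#'
#' Empirical class frequencies at the first wave (the Markov chain's
#' initial distribution).
#'
#' @param assignments Integer state assignments (0-based) at wave 1.
#' @param n_states Number of states; defaults to `max(assignments) + 1`.
#' @return A tibble with `state` (0-based), `label` (when `n_states` is a
#'   power of two, the mastery-pattern string) and `probability`.
#' @export
estimate_initial <- function(assignments, n_states = NULL) {
  if (length(assignments) == 0) abort("Need at least one examinee.")
  assignments <- as.integer(assignments)
  if (is.null(n_states)) n_states <- max(assignments) + 1L
  if (any(assignments < 0 | assignments >= n_states)) {
    abort("`assignments` must lie in [0, n_states).")
  }
  counts <- tabulate(assignments + 1L, nbins = n_states)
  k <- log2(n_states)
  tibble(
    state = 0:(n_states - 1L),
    label = if (k == round(k)) pattern_labels(k) else as.character(0:(n_states - 1L)),
    probability = counts / sum(counts))
}

#' Estimate a transition matrix between two waves
#'
#' Maximum-likelihood count normalization: `counts[i, j]` is the number of
#' examinees in state `i` at the earlier wave and state `j` at the later
#' wave; probabilities are row-normalized counts. Rows never observed are
#' reported as `NaN` rather than an arbitrary distribution. An optional
#' additive smoothing constant can regularize sparse (e.g. 64 x 64)
#' pattern-level matrices.
#'
#' @param from,to Aligned integer state assignments (0-based) at
#'   consecutive waves.
#' @param n_states Number of states.
#' @param smoothing Additive (pseudo-count) smoothing, default 0.
#' @return A list of class `"transition_estimate"`: `counts`,
#'   `probabilities` (both `n_states x n_states`), `n` and `smoothing`.
#' @export
estimate_transitions <- function(from, to, n_states = NULL, smoothing = 0) {
  if (length(from) != length(to)) abort("`from` and `to` must align examinee-by-examinee.")
  if (length(from) == 0) abort("Need at least one examinee.")
  from <- as.integer(from); to <- as.integer(to)
  if (is.null(n_states)) n_states <- max(from, to) + 1L
  if (any(c(from, to) < 0 | c(from, to) >= n_states)) {
    abort("State assignments must lie in [0, n_states).")
  }
  counts <- matrix(0L, n_states, n_states)
  for (i in seq_along(from)) {
    counts[from[i] + 1L, to[i] + 1L] <- counts[from[i] + 1L, to[i] + 1L] + 1L
  }
  k <- log2(n_states)
  labs <- if (k == round(k)) pattern_labels(k) else as.character(0:(n_states - 1L))
  dimnames(counts) <- list(from = labs, to = labs)
  sm <- counts + smoothing
  rs <- rowSums(sm)
  probabilities <- sm / rs              # rows with rs = 0 become NaN
  structure(list(counts = counts, probabilities = probabilities,
                 n = length(from), smoothing = smoothing),
            class = "transition_estimate")
}

#' @export
print.transition_estimate <- function(x, ...) {
  cat(sprintf("Transition estimate from %d examinees (smoothing %g):\n",
              x$n, x$smoothing))
  print(round(x$probabilities, 3))
  invisible(x)
}

#' @describeIn estimate_transitions Long-format tibble of the estimate.
#' @param x A `"transition_estimate"`.
#' @param ... Unused.
#' @export
tidy.transition_estimate <- function(x, ...) {
  labs <- rownames(x$counts)
  tidyr::expand_grid(from = labs, to = labs) |>
    dplyr::mutate(
      count = as.vector(t(x$counts)),
      probability = as.vector(t(x$probabilities)))
}

#' Per-attribute transition estimates from pattern assignments
#'
#' Decodes pattern assignments into attribute bits and estimates one 2x2
#' transition matrix per attribute. Because each attribute bit is a
#' deterministic function of the pattern, summing pattern-level transition
#' counts over the bit partition reproduces these counts exactly.
#'
#' @param from,to Aligned 0-based pattern assignments at consecutive waves.
#' @param k Number of attributes.
#' @return A named list of `K` `"transition_estimate"` objects.
#' @export
attribute_transitions <- function(from, to, k) {
  bits_from <- decode_pattern(from, k)
  bits_to <- decode_pattern(to, k)
  out <- lapply(seq_len(k), function(a) {
    estimate_transitions(bits_from[, a], bits_to[, a], n_states = 2L)
  })
  names(out) <- paste0("A", seq_len(k))
  out
}

#' Correct transition rate of estimated state trajectories
#'
#' The primary definition is the per-examinee ordered-pair agreement rate:
#' the fraction of examinees whose estimated `(state_t, state_{t+1})` pair
#' equals the true pair — both endpoints must be right. A secondary
#' matrix-level score, `1 - mean |A_est - A_true|` over cells whose true or
#' estimated row is occupied, is reported alongside for users who read the
#' criterion as a distance between estimated and true transition matrices.
#'
#' @param true_from,true_to Aligned true states (0-based) at waves `t`,
#'   `t+1`.
#' @param est_from,est_to Aligned estimated states at the same waves.
#' @param n_states Number of states (needed for the matrix-level score).
#' @return A tibble with `pairwise_rate`, `matrix_score`, `n`.
#' @export
correct_transition_rate <- function(true_from, true_to, est_from, est_to,
                                    n_states = NULL) {
  lens <- lengths(list(true_from, true_to, est_from, est_to))
  if (length(unique(lens)) != 1) abort("All four assignment vectors must align.")
  if (is.null(n_states)) n_states <- max(true_from, true_to, est_from, est_to) + 1L
  pairwise <- mean(true_from == est_from & true_to == est_to)
  a_true <- estimate_transitions(true_from, true_to, n_states)$probabilities
  a_est <- estimate_transitions(est_from, est_to, n_states)$probabilities
  occupied <- !is.nan(rowSums(a_true)) & !is.nan(rowSums(a_est))
  matrix_score <- if (any(occupied)) {
    1 - mean(abs(a_est[occupied, , drop = FALSE] - a_true[occupied, , drop = FALSE]))
  } else NA_real_
  tibble(pairwise_rate = pairwise, matrix_score = matrix_score,
         n = length(true_from))
}

#' Forward mastery trajectories from transition generators
#'
#' Chapman-Kolmogorov forward products: starting from per-attribute initial
#' mastery probabilities, each interval's 2x2 generator advances the
#' mastery probability, giving the expected mastery curve and per-interval
#' growth rate.
#'
#' @param initial_mastery Per-attribute mastery probabilities at wave 1.
#' @param transitions List of intervals, each a list of `K` 2x2 matrices
#'   (as in [study_design()]).
#' @return A tibble with `attribute`, `wave`, `mastery`, `growth`.
#' @export
forward_mastery <- function(initial_mastery, transitions) {
  assert_prob(initial_mastery, "initial_mastery")
  k <- length(initial_mastery)
  t_points <- length(transitions) + 1L
  mastery <- matrix(NA_real_, t_points, k)
  mastery[1, ] <- initial_mastery
  for (t in seq_along(transitions)) {
    iv <- transitions[[t]]
    if (length(iv) != k) abort("Each interval needs one matrix per attribute.")
    for (a in seq_len(k)) {
      assert_row_stochastic(iv[[a]], "transition matrix")
      p <- mastery[t, a]
      mastery[t + 1, a] <- (1 - p) * iv[[a]][1, 2] + p * iv[[a]][2, 2]
    }
  }
  grid <- tidyr::expand_grid(attribute = paste0("A", seq_len(k)),
                             wave = seq_len(t_points))
  a_idx <- match(grid$attribute, paste0("A", seq_len(k)))
  now <- mastery[cbind(grid$wave, a_idx)]
  prev <- mastery[cbind(pmax(grid$wave - 1, 1), a_idx)]
  dplyr::mutate(grid, mastery = now,
                growth = dplyr::if_else(.data$wave == 1, NA_real_, now - prev))
}

#' @describeIn forward_mastery Mastery-trajectory plot (one line per
#'   attribute).
#' @param object A tibble returned by `forward_mastery()`.
#' @param ... Unused.
#' @export
plot_mastery <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$wave, y = .data$mastery,
                               colour = .data$attribute)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Time point", y = "Attribute mastery probability",
                  colour = "Attribute")
}
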