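# End-to-end runners: simulate -> train SSOM on ideal responses -> classify
# every wave -> score accuracy and transitions, replicated under one root
# seed; and the two-wave empirical workflow on user response files.

default_ssom_config <- function(k, j = NULL) {
  if (k <= 3) ssom_config(grid = c(10, 10), iterations = 2)
  else ssom_config(grid = c(20, 20), iterations = 4)
}

#' Run one simulation condition
#'
#' For each replication: simulate a longitudinal sample from the design,
#' build an ideal-response training set, train the SSOM, classify every
#' wave, and score attribute/pattern accuracy (ACCR/PCCR) against the true
#' profiles and transition recovery (correct transition rate) against the
#' true state pairs. Results are aggregated as means with standard errors.
#'
#' The training set labels ideal responses by their mastery pattern;
#' `training_weights = "population"` (default) draws patterns from the
#' design's copula-implied distribution, `"uniform"` enumerates them
#' equally.
#'
#' @param design A [study_design()].
#' @param q A [q_matrix()]; defaults to the built-in 20-item fixture for
#'   `design$k` (stacked to 40 items when `design$j` is twice the fixture).
#' @param params Fixed item parameters, or `NULL` to redraw from the
#'   regime's range each replication.
#' @param config An [ssom_config()]; defaults follow the published
#'   architecture (10x10 grid, 2 iterations for three attributes; 20x20,
#'   4 iterations for six).
#' @param replications Number of replications.
#' @param seed Root seed; every replication derives its own substreams.
#' @param training_weights `"population"`, `"uniform"`, or a numeric vector
#'   of `2^K` weights.
#' @param training_size Training rows per replication. The default,
#'   `max(design$n, 2^k * 32)`, keeps the training set at least as large as
#'   the sample while guaranteeing enough draws to represent rare patterns
#'   when the class count grows (an average of 32 rows per pattern).
#' @return A list of class `"cda_condition"` with tibbles `accuracy`
#'   (summary), `transition` (summary), `accuracy_raw`, `transition_raw`.
#' @examples
#' \donttest{
#' d <- study_design(k = 3, j = 20, n = 200)
#' res <- run_condition(d, params = cda_fixture("params_high_20"),
#'                      replications = 2, seed = 1)
#' res$accuracy
#' }
#' @export
run_condition <- function(design, q = NULL, params = NULL, config = NULL,
                          replications = 10, seed = 1,
                          training_weights = "population",
                          training_size = NULL) {
  if (is.null(q)) {
    q <- cda_fixture(if (design$k == 3) "q3_20" else "q6_20")
    if (design$j == 2 * nrow(q)) q <- stack_q(q)
  }
  if (nrow(q) != design$j) abort("Q matrix size does not match `design$j`.")
  if (is.null(config)) config <- default_ssom_config(design$k)
  if (is.null(training_size)) training_size <- max(design$n, 2^design$k * 32)
  rep_seeds <- child_seeds(seed, paste0("rep", seq_len(replications)))

  acc_raw <- list(); trans_raw <- list()
  for (r in seq_len(replications)) {
    seeds <- child_seeds(rep_seeds[[r]], c("sim", "train_set", "ssom"))
    sim <- sim_longitudinal(design, q, params = params, seed = seeds[["sim"]])
    ts <- build_training_set(q, size = training_size,
                             weights = training_weights,
                             initial_mastery = design$initial_mastery,
                             correlation = design$correlation,
                             seed = seeds[["train_set"]])
    fit <- ssom(ts$inputs, ts$labels, n_class = 2^design$k, config = config,
                seed = seeds[["ssom"]])
    est <- lapply(sim$responses, function(x) predict(fit, x))
    true <- lapply(sim$profiles, encode_pattern)
    acc_raw[[r]] <- purrr::map_dfr(seq_len(design$t_points), function(t) {
      accuracy_report(sim$profiles[[t]], decode_pattern(est[[t]], design$k),
                      wave = t)
    }) |> dplyr::mutate(replication = r)
    if (design$t_points > 1) {
      trans_raw[[r]] <- purrr::map_dfr(seq_len(design$t_points - 1), function(t) {
        correct_transition_rate(true[[t]], true[[t + 1]], est[[t]], est[[t + 1]],
                                n_states = 2^design$k) |>
          dplyr::mutate(interval = sprintf("T%d-T%d", t, t + 1))
      }) |> dplyr::mutate(replication = r)
    }
  }
  acc_raw <- dplyr::bind_rows(acc_raw)
  trans_raw <- dplyr::bind_rows(trans_raw)
  trans_sum <- if (nrow(trans_raw)) {
    trans_raw |>
      dplyr::group_by(.data$interval) |>
      dplyr::summarise(
        mean_rate = mean(.data$pairwise_rate),
        se = stats::sd(.data$pairwise_rate) / sqrt(dplyr::n()),
        mean_matrix_score = mean(.data$matrix_score),
        replications = dplyr::n(),
        .groups = "drop")
  } else tibble()
  structure(
    list(accuracy = summarize_accuracy(acc_raw),
         transition = trans_sum,
         accuracy_raw = acc_raw,
         transition_raw = trans_raw,
         design = design, seed = seed, replications = replications),
    class = "cda_condition")
}

#' @export
print.cda_condition <- function(x, ...) {
  print(x$design)
  cat(sprintf("%d replication(s), root seed %s\n\n", x$replications, x$seed))
  pc <- dplyr::filter(x$accuracy, .data$criterion == "PCCR")
  cat("Mean PCCR by wave:\n")
  print(as.data.frame(pc[c("wave", "mean_rate", "se")]), row.names = FALSE)
  if (nrow(x$transition)) {
    cat("\nMean correct transition rate by interval:\n")
    print(as.data.frame(x$transition[c("interval", "mean_rate", "se")]),
          row.names = FALSE)
  }
  invisible(x)
}

check_wave_alignment <- function(waves) {
  ids <- lapply(waves, function(w) {
    if (is.data.frame(w) && "examinee" %in% names(w)) as.character(w$examinee) else NULL
  })
  if (all(!vapply(ids, is.null, logical(1)))) {
    ref <- ids[[1]]
    for (t in seq_along(ids)[-1]) {
      if (!identical(ids[[t]], ref)) {
        off <- union(setdiff(ids[[t]], ref), setdiff(ref, ids[[t]]))
        abort(paste0("Examinee IDs do not align across waves; offenders: ",
                     paste(head(off, 10), collapse = ", ")))
      }
    }
  } else {
    ns <- vapply(waves, nrow, integer(1))
    if (length(unique(ns)) != 1) {
      abort("Waves must contain the same examinees (row counts differ).")
    }
  }
  invisible(waves)
}

wave_matrix <- function(w) {
  if (is.data.frame(w) && "examinee" %in% names(w)) {
    as_binary_matrix(w[setdiff(names(w), "examinee")], "responses")
  } else {
    as_binary_matrix(w, "responses")
  }
}

#' Two-wave (or longer) empirical workflow
#'
#' Because true attribute patterns are unobservable in field data, the SSOM
#' is trained on the ideal responses implied by the Q matrix, labelled by
#' their generating patterns; the trained network then classifies each
#' wave's observed responses. Returns per-wave mastery probabilities,
#' per-attribute and pattern-level transition estimates, and per-examinee
#' pattern trajectories.
#'
#' @param waves List of response sets (tibbles from [read_responses()] or
#'   binary matrices), one per time point, aligned by examinee.
#' @param q A [q_matrix()].
#' @param config An [ssom_config()]; default follows the published
#'   empirical architecture (9x9 grid, 3 iterations).
#' @param training_size Ideal-response training rows.
#' @param training_weights Passed to [build_training_set()] (uniform by
#'   default: field data carry no population weights).
#' @param seed Root seed.
#' @return A list of class `"cda_empirical"`: `mastery` (per wave x
#'   attribute), `initial` (wave-1 pattern distribution),
#'   `attribute_transitions` and `pattern_transitions` (per interval),
#'   `trajectories` (per-examinee pattern labels by wave), and the fitted
#'   `ssom`.
#' @export
run_empirical <- function(waves, q,
                          config = ssom_config(grid = c(9, 9), iterations = 3),
                          training_size = 2^ncol(q) * 50,
                          training_weights = "uniform",
                          seed = 1) {
  if (length(waves) < 2) abort("Need at least two waves.")
  check_wave_alignment(waves)
  mats <- lapply(waves, wave_matrix)
  for (m in mats) {
    if (ncol(m) != nrow(q)) abort("Every wave must have one column per Q-matrix item.")
  }
  k <- ncol(q)
  seeds <- child_seeds(seed, c("train_set", "ssom"))
  ts <- build_training_set(q, size = training_size, weights = training_weights,
                           seed = seeds[["train_set"]])
  fit <- ssom(ts$inputs, ts$labels, n_class = 2^k, config = config,
              seed = seeds[["ssom"]])
  est <- lapply(mats, function(m) predict(fit, m))
  profiles <- lapply(est, decode_pattern, k = k)
  mastery <- purrr::map_dfr(seq_along(profiles), function(t) {
    tibble(wave = t, attribute = colnames(q),
           mastery = colMeans(profiles[[t]]))
  })
  intervals <- seq_len(length(mats) - 1)
  attr_trans <- lapply(intervals, function(t) {
    at <- attribute_transitions(est[[t]], est[[t + 1]], k)
    names(at) <- colnames(q)
    at
  })
  pat_trans <- lapply(intervals, function(t) {
    estimate_transitions(est[[t]], est[[t + 1]], n_states = 2^k)
  })
  names(attr_trans) <- names(pat_trans) <-
    sprintf("T%d-T%d", intervals, intervals + 1)
  ids <- if (is.data.frame(waves[[1]]) && "examinee" %in% names(waves[[1]])) {
    as.character(waves[[1]]$examinee)
  } else as.character(seq_len(nrow(mats[[1]])))
  trajectories <- tibble(examinee = ids)
  for (t in seq_along(est)) {
    trajectories[[paste0("T", t)]] <- pattern_labels(k)[est[[t]] + 1]
  }
  structure(
    list(mastery = mastery,
         initial = estimate_initial(est[[1]], n_states = 2^k),
         attribute_transitions = attr_trans,
         pattern_transitions = pat_trans,
         trajectories = trajectories,
         ssom = fit),
    class = "cda_empirical")
}

#' @export
print.cda_empirical <- function(x, ...) {
  cat("Empirical longitudinal diagnosis\n\n")
  cat("Estimated attribute mastery by wave:\n")
  print(as.data.frame(tidyr::pivot_wider(x$mastery,
                                         names_from = "wave",
                                         names_prefix = "T",
                                         values_from = "mastery")),
        row.names = FALSE)
  for (iv in names(x$pattern_transitions)) {
    cat(sprintf("\nPattern transition matrix %s:\n", iv))
    print(round(x$pattern_transitions[[iv]]$probabilities, 2))
  }
  invisible(x)
}
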