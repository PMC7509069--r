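#' Attribute-level classification accuracy (ACCR)
#'
#' Per-attribute fraction of examinees whose estimated mastery bit matches
#' the true bit.
#'
#' @param true,est Binary matrices (examinees x attributes) of true and
#'   estimated profiles.
#' @return Named numeric vector of length `K`.
#' @export
accr <- function(true, est) {
  true <- as_binary_matrix(true, "true")
  est <- as_binary_matrix(est, "est")
  if (!all(dim(true) == dim(est))) abort("`true` and `est` must have equal shape.")
  out <- colMeans(true == est)
  names(out) <- colnames(true) %||% paste0("A", seq_len(ncol(true)))
  out
}

#' Pattern-level classification accuracy (PCCR)
#'
#' Fraction of examinees whose whole estimated mastery pattern matches the
#' truth on every attribute simultaneously. Always bounded above by the
#' smallest attribute-level ACCR.
#'
#' @inheritParams accr
#' @return A single rate in `[0, 1]`.
#' @export
pccr <- function(true, est) {
  true <- as_binary_matrix(true, "true")
  est <- as_binary_matrix(est, "est")
  if (!all(dim(true) == dim(est))) abort("`true` and `est` must have equal shape.")
  mean(rowSums(true == est) == ncol(true))
}

#' Accuracy report for one wave
#'
#' @inheritParams accr
#' @param wave Optional time-point label.
#' @return A tibble with one row per attribute plus one `pattern` row:
#'   columns `wave`, `criterion` (`"ACCR"`/`"PCCR"`), `attribute`, `rate`,
#'   `n`.
#' @export
accuracy_report <- function(true, est, wave = NA_integer_) {
  a <- accr(true, est)
  dplyr::bind_rows(
    tibble(wave = wave, criterion = "ACCR", attribute = names(a),
           rate = unname(a), n = nrow(as_binary_matrix(true, "true"))),
    tibble(wave = wave, criterion = "PCCR", attribute = "pattern",
           rate = pccr(true, est), n = nrow(as_binary_matrix(true, "true"))))
}

#' Aggregate accuracy reports over replications
#'
#' Means with standard errors per criterion x attribute x wave, in the
#' layout of a simulation-study summary table.
#'
#' @param reports A tibble of stacked [accuracy_report()] rows, with an
#'   added `replication` column.
#' @return A tibble with `wave`, `criterion`, `attribute`, `mean_rate`,
#'   `se`, `replications`.
#' @export
summarize_accuracy <- function(reports) {
  if (nrow(reports) == 0) abort("Need at least one report.")
  n_attr <- reports |>
    dplyr::filter(.data$criterion == "ACCR") |>
    dplyr::distinct(.data$replication, .data$wave, .data$attribute) |>
    dplyr::count(.data$replication, .data$wave) |>
    dplyr::pull(.data$n)
  if (length(unique(n_attr)) > 1) {
    abort("All reports must share the same attribute count.")
  }
  reports |>
    dplyr::group_by(.data$wave, .data$criterion, .data$attribute) |>
    dplyr::summarise(
      mean_rate = mean(.data$rate),
      se = stats::sd(.data$rate) / sqrt(dplyr::n()),
      replications = dplyr::n(),
      .groups = "drop")
}

#' @describeIn summarize_accuracy Dot-and-error-bar plot of a summary.
#' @param object Output of `summarize_accuracy()`.
#' @param ... Unused.
#' @export
plot_accuracy <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = factor(.data$wave), y = .data$mean_rate,
                               colour = .data$attribute, group = .data$attribute)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_rate - .data$se,
                   ymax = .data$mean_rate + .data$se),
      width = 0.1) +
    ggplot2::facet_wrap(~.data$criterion) +
    ggplot2::labs(x = "Time point", y = "Classification accuracy",
                  colour = NULL)
}
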