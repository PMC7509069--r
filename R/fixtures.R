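# Built-in study designs: the published 20-item Q matrices with their
# slip/guess draws, the empirical 8-item reading Q, and the per-attribute
# transition generators for the three- and six-attribute conditions.

.q3_20_tab <- matrix(c(
  # A1 A2 A3   s.high g.high s.mixed g.mixed
  1, 1, 0, 0.16, 0.04, 0.33, 0.10,
  0, 1, 1, 0.17, 0.15, 0.24, 0.28,
  1, 1, 0, 0.01, 0.10, 0.26, 0.24,
  1, 1, 1, 0.17, 0.05, 0.12, 0.22,
  0, 1, 1, 0.10, 0.13, 0.37, 0.15,
  0, 1, 0, 0.12, 0.07, 0.35, 0.04,
  1, 0, 0, 0.07, 0.15, 0.09, 0.34,
  1, 0, 1, 0.08, 0.17, 0.39, 0.14,
  0, 1, 0, 0.03, 0.10, 0.19, 0.36,
  0, 1, 1, 0.16, 0.07, 0.31, 0.30,
  1, 0, 1, 0.10, 0.17, 0.11, 0.38,
  0, 1, 0, 0.16, 0.11, 0.30, 0.04,
  1, 0, 1, 0.13, 0.10, 0.33, 0.19,
  0, 1, 1, 0.03, 0.13, 0.09, 0.18,
  1, 0, 1, 0.05, 0.17, 0.37, 0.39,
  1, 1, 0, 0.05, 0.01, 0.29, 0.06,
  1, 0, 1, 0.14, 0.05, 0.39, 0.10,
  1, 0, 0, 0.10, 0.17, 0.31, 0.01,
  0, 1, 0, 0.11, 0.03, 0.12, 0.19,
  0, 1, 1, 0.14, 0.18, 0.18, 0.06), ncol = 7, byrow = TRUE)

.q6_20_tab <- matrix(c(
  # A1..A6   s.high g.high s.mixed g.mixed
  1, 0, 1, 1, 0, 0, 0.08, 0.17, 0.40, 0.35,
  1, 1, 0, 0, 0, 1, 0.00, 0.05, 0.35, 0.09,
  1, 0, 1, 1, 0, 1, 0.03, 0.15, 0.21, 0.22,
  0, 1, 0, 1, 1, 0, 0.11, 0.05, 0.40, 0.21,
  1, 0, 0, 0, 1, 0, 0.03, 0.14, 0.39, 0.03,
  0, 0, 1, 0, 0, 1, 0.03, 0.13, 0.02, 0.02,
  1, 1, 0, 1, 0, 1, 0.19, 0.02, 0.31, 0.16,
  1, 1, 1, 1, 1, 0, 0.18, 0.19, 0.03, 0.14,
  1, 0, 0, 1, 0, 0, 0.07, 0.06, 0.28, 0.16,
  1, 1, 0, 0, 0, 0, 0.03, 0.19, 0.30, 0.00,
  0, 0, 0, 1, 0, 0, 0.08, 0.16, 0.06, 0.05,
  0, 0, 0, 1, 0, 0, 0.06, 0.05, 0.11, 0.32,
  1, 0, 0, 1, 0, 0, 0.00, 0.00, 0.32, 0.21,
  0, 1, 0, 0, 1, 1, 0.12, 0.04, 0.33, 0.00,
  1, 1, 1, 1, 1, 1, 0.05, 0.04, 0.08, 0.11,
  0, 1, 0, 1, 1, 1, 0.15, 0.06, 0.12, 0.12,
  0, 0, 1, 0, 0, 0, 0.05, 0.16, 0.32, 0.09,
  1, 1, 0, 0, 0, 1, 0.07, 0.01, 0.22, 0.04,
  1, 0, 0, 0, 0, 1, 0.06, 0.05, 0.32, 0.05,
  1, 1, 1, 1, 0, 1, 0.20, 0.04, 0.14, 0.23), ncol = 10, byrow = TRUE)

.q_empirical_tab <- matrix(c(
  1, 0, 0,
  1, 0, 0,
  0, 1, 0,
  0, 1, 0,
  0, 0, 1,
  0, 0, 1,
  0, 0, 1,
  0, 1, 0), ncol = 3, byrow = TRUE)

.trans2 <- function(p00, p01, p10, p11) {
  matrix(c(p00, p01, p10, p11), nrow = 2, byrow = TRUE,
         dimnames = list(from = c("0", "1"), to = c("0", "1")))
}

# Per-attribute conditional transition generators; element [[interval]][[attribute]].
.transitions_k3 <- list(
  "T1-T2" = list(
    A1 = .trans2(0.55, 0.45, 0.03, 0.97),
    A2 = .trans2(0.71, 0.29, 0.03, 0.97),
    A3 = .trans2(0.93, 0.07, 0.87, 0.13)),
  "T2-T3" = list(
    A1 = .trans2(0.66, 0.34, 0.06, 0.94),
    A2 = .trans2(0.82, 0.18, 0.05, 0.95),
    A3 = .trans2(0.90, 0.10, 0.54, 0.46))
)

.transitions_k6 <- list(
  "T1-T2" = list(
    A1 = .trans2(0.45, 0.55, 0.03, 0.97),
    A2 = .trans2(0.56, 0.44, 0.04, 0.96),
    A3 = .trans2(0.61, 0.39, 0.13, 0.87),
    A4 = .trans2(0.72, 0.28, 0.25, 0.75),
    A5 = .trans2(0.78, 0.22, 0.43, 0.57),
    A6 = .trans2(0.83, 0.17, 0.54, 0.46)),
  "T2-T3" = list(
    A1 = .trans2(0.36, 0.64, 0.02, 0.98),
    A2 = .trans2(0.42, 0.58, 0.05, 0.95),
    A3 = .trans2(0.54, 0.46, 0.14, 0.86),
    A4 = .trans2(0.46, 0.54, 0.06, 0.94),
    A5 = .trans2(0.42, 0.58, 0.18, 0.82),
    A6 = .trans2(0.59, 0.41, 0.12, 0.88))
)

.item_params <- function(tab, regime) {
  cols <- if (regime == "high") 0:1 else 2:3
  k <- ncol(tab) - 4
  tibble(
    item = seq_len(nrow(tab)),
    slip = tab[, k + 1 + cols[1]],
    guess = tab[, k + 2 + cols[1]]
  )
}

#' Built-in design fixtures
#'
#' Returns exact in-memory copies of the published design tables: the
#' three- and six-attribute 20-item Q matrices with their high/mixed
#' slip-guess draws, the 8-item empirical reading-assessment Q matrix, and
#' the per-attribute conditional transition generators for both attribute
#' counts.
#'
#' @param name One of `"q3_20"`, `"q6_20"`, `"q_empirical"`,
#'   `"transitions_k3"`, `"transitions_k6"`, `"params_high_20"`,
#'   `"params_mixed_20"`, `"params6_high_20"`, `"params6_mixed_20"`.
#' @return A [q_matrix()], a tibble of item parameters (`item`, `slip`,
#'   `guess`), or a nested list of 2x2 row-stochastic matrices indexed by
#'   interval then attribute.
#' @examples
#' cda_fixture("q_empirical")
#' cda_fixture("transitions_k3")[["T1-T2"]]$A1
#' @export
cda_fixture <- function(name) {
  switch(name,
    q3_20 = q_matrix(.q3_20_tab[, 1:3], quiet = TRUE),
    q6_20 = q_matrix(.q6_20_tab[, 1:6], quiet = TRUE),
    q_empirical = q_matrix(.q_empirical_tab,
                           attribute_ids = c("Acquisition", "Integration", "Evaluation")),
    transitions_k3 = .transitions_k3,
    transitions_k6 = .transitions_k6,
    params_high_20 = .item_params(.q3_20_tab, "high"),
    params_mixed_20 = .item_params(.q3_20_tab, "mixed"),
    params6_high_20 = .item_params(.q6_20_tab, "high"),
    params6_mixed_20 = .item_params(.q6_20_tab, "mixed"),
    abort(sprintf("Unknown fixture `%s`.", name))
  )
}
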