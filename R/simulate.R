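#' Ideal responses under the conjunctive DINA rule
#'
#' Item `j` has ideal response 1 for a profile exactly when the profile
#' masters every attribute the Q matrix requires for that item
#' (`eta = prod_k alpha_k^{q_jk}`). Ideal responses are the noise-free limit
#' of the DINA model and double as the training inputs for the supervised
#' self-organizing map.
#'
#' @param profiles Binary matrix (examinees x attributes) or single profile
#'   vector.
#' @param q A [q_matrix()].
#' @return Integer 0/1 matrix, examinees x items (a vector input gives a
#'   one-row matrix).
#' @examples
#' q <- cda_fixture("q_empirical")
#' ideal_responses(c(1, 0, 0), q)
#' @export
ideal_responses <- function(profiles, q) {
  if (is.null(dim(profiles))) profiles <- matrix(profiles, nrow = 1)
  m <- as_binary_matrix(profiles, "profiles")
  if (ncol(m) != ncol(q)) {
    abort(sprintf("Profiles have %d attributes but the Q matrix has %d.",
                  ncol(m), ncol(q)))
  }
  need <- rowSums(q)                       # attributes required per item
  have <- m %*% t(unclass(q))              # required attributes mastered
  eta <- matrix(as.integer(sweep(have, 2, need, `==`)), nrow = nrow(m))
  colnames(eta) <- rownames(q)
  eta
}

#' Enumerate colliding ideal-response patterns
#'
#' Two mastery patterns collide when they share an identical ideal-response
#' vector under a Q matrix, in which case no response-based classifier can
#' separate them. Collisions are found by brute-force enumeration of all
#' `2^K` patterns.
#'
#' @param q A [q_matrix()].
#' @return A tibble with one row per pattern: `pattern` (index), `label`,
#'   and `group` (patterns sharing a `group` collide).
#' @export
ideal_response_collisions <- function(q) {
  k <- ncol(q)
  idx <- 0:(2^k - 1)
  iv <- ideal_responses(decode_pattern(idx, k), q)
  key <- apply(iv, 1, paste, collapse = "")
  tibble(pattern = idx, label = pattern_labels(k),
         group = as.integer(factor(key, levels = unique(key))))
}

#' Simulate dichotomous item responses under the DINA model
#'
#' Given true profiles, each response is an independent Bernoulli draw with
#' success probability `(1 - s_j)` when the examinee masters all required
#' attributes and `g_j` otherwise.
#'
#' @param profiles Binary matrix (examinees x attributes).
#' @param q A [q_matrix()].
#' @param params Item-parameter tibble with columns `slip` and `guess`
#'   (length = number of items).
#' @param seed Optional seed.
#' @return Integer 0/1 matrix, examinees x items.
#' @export
sim_item_responses <- function(profiles, q, params, seed = NULL) {
  if (nrow(params) != nrow(q)) abort("`params` must have one row per item.")
  assert_prob(params$slip, "slip")
  assert_prob(params$guess, "guess")
  eta <- ideal_responses(profiles, q)
  p <- sweep(eta, 2, 1 - params$slip, `*`) +
    sweep(1 - eta, 2, params$guess, `*`)
  draw <- function() {
    x <- matrix(rbinom(length(p), 1, p), nrow = nrow(p))
    colnames(x) <- colnames(eta)
    x
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Sample correlated initial attribute profiles
#'
#' Profiles at the first time point are drawn from a Gaussian copula:
#' latent standard-normal scores with exchangeable correlation `rho` are
#' thresholded per attribute at the `(1 - p_k)` quantile, so each attribute's
#' marginal mastery rate is exactly `p_k` while attributes remain positively
#' associated. The exchangeable structure is realized by the one-factor
#' construction `Z_k = sqrt(rho) W + sqrt(1 - rho) E_k`.
#'
#' @param n Number of examinees.
#' @param initial_mastery Per-attribute mastery probabilities.
#' @param correlation Exchangeable latent correlation in `[0, 1)`.
#' @param seed Optional seed.
#' @return Integer 0/1 matrix, `n` x `K`.
#' @export
sim_initial_profiles <- function(n, initial_mastery, correlation = 0.5, seed = NULL) {
  assert_prob(initial_mastery, "initial_mastery")
  if (correlation < 0 || correlation >= 1) {
    abort("`correlation` must lie in [0, 1) (exchangeable one-factor structure).")
  }
  k <- length(initial_mastery)
  thr <- qnorm(1 - initial_mastery)
  draw <- function() {
    w <- rnorm(n)
    z <- sqrt(correlation) * w +
      sqrt(1 - correlation) * matrix(rnorm(n * k), n, k)
    m <- matrix(as.integer(sweep(z, 2, thr, `>`)), n, k)
    colnames(m) <- paste0("A", seq_len(k))
    m
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Advance attribute profiles one interval along their Markov chains
#'
#' Each attribute evolves independently given its current state through its
#' own 2x2 conditional transition matrix (rows: from non-mastery, from
#' mastery).
#'
#' @param profiles Binary matrix (examinees x attributes).
#' @param transitions List of `K` row-stochastic 2x2 matrices.
#' @param seed Optional seed.
#' @return Integer 0/1 matrix of the same shape.
#' @export
advance_profiles <- function(profiles, transitions, seed = NULL) {
  m <- as_binary_matrix(profiles, "profiles")
  if (length(transitions) != ncol(m)) {
    abort("`transitions` must supply one 2x2 matrix per attribute.")
  }
  for (tm in transitions) assert_row_stochastic(tm, "transition matrix")
  draw <- function() {
    out <- m
    for (k in seq_len(ncol(m))) {
      p_gain <- transitions[[k]][1, 2]   # P(1 | was 0)
      p_keep <- transitions[[k]][2, 2]   # P(1 | was 1)
      p <- ifelse(m[, k] == 1, p_keep, p_gain)
      out[, k] <- rbinom(nrow(m), 1, p)
    }
    out
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Simulate a full longitudinal sample
#'
#' Draws wave-1 profiles from the design's Gaussian copula, advances them
#' through the per-interval transition generators, and simulates DINA
#' responses independently at every wave. All randomness derives from the
#' single `seed` through named substreams, so each wave is reproducible in
#' isolation.
#'
#' @param design A [study_design()].
#' @param q A [q_matrix()] with `design$j` items.
#' @param params Item-parameter tibble (columns `slip`, `guess`); defaults
#'   to a fresh draw from the design's regime.
#' @param seed Root seed.
#' @return A nested tibble of class `"cda_sim"` with one row per wave and
#'   columns `wave`, `profiles` (list of N x K matrices) and `responses`
#'   (list of N x J matrices), plus attributes `design`, `params`, `seed`.
#' @examples
#' d <- study_design(k = 3, j = 20, n = 50)
#' sim <- sim_longitudinal(d, cda_fixture("q3_20"),
#'                         cda_fixture("params_high_20"), seed = 1)
#' sim
#' @export
sim_longitudinal <- function(design, q, params = NULL, seed = 1) {
  if (nrow(q) != design$j) abort("Q matrix size does not match `design$j`.")
  seeds <- child_seeds(seed, c("params", "initial",
                               paste0("trans", seq_len(max(design$t_points - 1, 0))),
                               paste0("resp", seq_len(design$t_points))))
  if (is.null(params)) params <- draw_item_params(design, seeds[["params"]])
  profiles <- vector("list", design$t_points)
  responses <- vector("list", design$t_points)
  profiles[[1]] <- sim_initial_profiles(design$n, design$initial_mastery,
                                        design$correlation, seeds[["initial"]])
  if (design$t_points > 1) {
    for (t in 2:design$t_points) {
      profiles[[t]] <- advance_profiles(profiles[[t - 1]],
                                        design$transitions[[t - 1]],
                                        seeds[[paste0("trans", t - 1)]])
    }
  }
  for (t in seq_len(design$t_points)) {
    responses[[t]] <- sim_item_responses(profiles[[t]], q, params,
                                         seeds[[paste0("resp", t)]])
  }
  out <- tibble(wave = seq_len(design$t_points),
                profiles = profiles, responses = responses)
  structure(out, design = design, params = params, seed = seed,
            class = c("cda_sim", class(out)))
}

#' Write a longitudinal sample to disk
#'
#' Emits one response CSV per wave, one profile CSV per wave, and a JSON
#' manifest recording the design, seed, and file paths.
#'
#' @param sim A `"cda_sim"` from [sim_longitudinal()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
write_longitudinal <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  design <- attr(sim, "design")
  paths <- list()
  for (t in sim$wave) {
    rp <- file.path(dir, sprintf("responses_T%d.csv", t))
    pp <- file.path(dir, sprintf("profiles_T%d.csv", t))
    readr::write_csv(as_tibble(sim$responses[[t]], .name_repair = "unique_quiet"), rp)
    readr::write_csv(as_tibble(sim$profiles[[t]], .name_repair = "unique_quiet"), pp)
    paths[[sprintf("T%d", t)]] <- list(responses = rp, profiles = pp)
  }
  manifest <- file.path(dir, "manifest.json")
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    abort("Writing the manifest requires the jsonlite package.")
  }
  jsonlite::write_json(
    list(design = design[c("k", "j", "n", "regime", "t_points",
                           "initial_mastery", "correlation")],
         seed = attr(sim, "seed"), files = paths),
    manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Build an ideal-response training set for the SSOM
#'
#' Training pairs the ideal response of each mastery pattern (input) with
#' the pattern itself (label). With `weights = "uniform"` and a `size` that
#' is a multiple of `2^K`, patterns are enumerated in equal numbers
#' (exact stratification); otherwise patterns are drawn with the given
#' probabilities. `weights = "population"` uses the pattern distribution
#' implied by a Gaussian copula with the supplied marginals and correlation.
#'
#' @param q A [q_matrix()].
#' @param size Number of training rows.
#' @param weights `"uniform"`, `"population"`, or a numeric vector of `2^K`
#'   non-negative weights over pattern indices `0 .. 2^K - 1`.
#' @param initial_mastery,correlation Population parameters, used when
#'   `weights = "population"`.
#' @param seed Optional seed for weighted draws.
#' @return A list with `inputs` (size x J matrix of ideal responses) and
#'   `labels` (integer pattern indices).
#' @export
build_training_set <- function(q, size,
                               weights = "uniform",
                               initial_mastery = NULL, correlation = 0.5,
                               seed = NULL) {
  k <- ncol(q)
  n_pat <- 2^k
  if (is.character(weights)) {
    weights <- match.arg(weights, c("uniform", "population"))
    if (weights == "uniform") {
      w <- rep(1 / n_pat, n_pat)
      if (size %% n_pat == 0) {
        idx <- rep(0:(n_pat - 1), each = size / n_pat)
        return(list(inputs = ideal_responses(decode_pattern(idx, k), q),
                    labels = idx))
      }
    } else {
      if (is.null(initial_mastery)) {
        abort("`weights = \"population\"` needs `initial_mastery`.")
      }
      w <- pattern_distribution(initial_mastery, correlation)$probability
    }
  } else {
    if (length(weights) != n_pat || any(weights < 0) || sum(weights) <= 0) {
      abort(sprintf("`weights` must be %d non-negative values with positive sum.", n_pat))
    }
    w <- weights / sum(weights)
  }
  draw <- function() sample(0:(n_pat - 1), size, replace = TRUE, prob = w)
  idx <- if (is.null(seed)) draw() else with_seed(seed, draw())
  list(inputs = ideal_responses(decode_pattern(idx, k), q), labels = idx)
}

#' Pattern distribution implied by the Gaussian copula
#'
#' Computes the exact probability of every mastery pattern under the
#' one-factor exchangeable copula used by [sim_initial_profiles()], by 1-D
#' Gauss quadrature over the shared factor.
#'
#' @inheritParams sim_initial_profiles
#' @return A tibble with `pattern`, `label`, `probability` (sums to 1).
#' @export
pattern_distribution <- function(initial_mastery, correlation = 0.5) {
  assert_prob(initial_mastery, "initial_mastery")
  k <- length(initial_mastery)
  thr <- qnorm(1 - initial_mastery)
  pats <- decode_pattern(0:(2^k - 1), k)
  prob <- vapply(seq_len(nrow(pats)), function(i) {
    a <- pats[i, ]
    f <- function(w) {
      # P(mastery_k | W = w) per attribute, conditional independence given W
      pk <- pnorm((sqrt(correlation) * w - rep(thr, each = length(w))) /
                    sqrt(1 - correlation))
      dim(pk) <- c(length(w), k)
      cond <- pk
      cond[, a == 0] <- 1 - pk[, a == 0, drop = FALSE]
      apply(cond, 1, prod) * stats::dnorm(w)
    }
    stats::integrate(f, -8.5, 8.5, rel.tol = 1e-10)$value
  }, numeric(1))
  tibble(pattern = 0:(2^k - 1), label = pattern_labels(k),
         probability = prob / sum(prob))
}
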