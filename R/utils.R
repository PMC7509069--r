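# Internal validators and seeded substream helpers.

assert_binary <- function(x, what) {
  if (!is.numeric(x) && !is.logical(x)) {
    abort(sprintf("`%s` must be numeric 0/1, not %s.", what, class(x)[1]))
  }
  bad <- !(x %in% c(0, 1))
  if (any(bad)) {
    abort(sprintf(
      "`%s` must contain only 0/1 values (found %s).",
      what, paste(unique(x[bad])[seq_len(min(3, sum(bad)))], collapse = ", ")
    ))
  }
  invisible(x)
}

assert_prob <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0 | x > 1)) {
    abort(sprintf("`%s` must be probabilities in [0, 1].", what))
  }
  invisible(x)
}

# Coerce a data frame / matrix of 0-1 scores to an integer matrix, keeping
# dimnames. An optional leading identifier column in data frames is detected
# by non-numeric type and moved to rownames.
as_binary_matrix <- function(x, what = "x") {
  if (is.data.frame(x)) {
    if (ncol(x) > 1 && !is.numeric(x[[1]])) {
      ids <- as.character(x[[1]])
      x <- x[-1]
      m <- as.matrix(x)
      rownames(m) <- ids
    } else {
      m <- as.matrix(x)
    }
  } else {
    m <- as.matrix(x)
  }
  storage.mode(m) <- "integer"
  assert_binary(m, what)
  m
}

assert_row_stochastic <- function(m, what, tol = 1e-8) {
  assert_prob(as.numeric(m), what)
  rs <- rowSums(m)
  if (any(abs(rs - 1) > tol)) {
    abort(sprintf("Rows of `%s` must sum to 1 (worst deviation %.3g).",
                  what, max(abs(rs - 1))))
  }
  invisible(m)
}

# Derive named child seeds from one root seed without disturbing the caller's
# RNG state more than once. Values stay below 2^31.
child_seeds <- function(seed, names) {
  stopifnot(length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  setNames(sample.int(.Machine$integer.max - 1L, length(names)), names)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}
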