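# Independent brute-force oracles used across tests. These deliberately
# avoid the package's fast paths.

# Exhaustive winner scan: squared Euclidean distance column by column.
brute_winner <- function(x, w_in) {
  d <- apply(w_in, 2, function(w) sum((x - w)^2))
  which.min(d)
}

# Minimum-Hamming-distance assignment to the 2^K ideal response vectors,
# ties to the lowest pattern index.
hamming_classify <- function(x_matrix, q) {
  k <- ncol(q)
  iv <- ideal_responses(decode_pattern(0:(2^k - 1), k), q)
  apply(x_matrix, 1, function(x) {
    which.min(rowSums(sweep(iv, 2, x, `!=`))) - 1L
  })
}

# 1-nearest-neighbor over the training rows (Euclidean), ties to the first.
nn_classify <- function(x_matrix, train_x, train_labels) {
  apply(x_matrix, 1, function(x) {
    train_labels[which.min(colSums((t(train_x) - x)^2))]
  })
}

# Standard bivariate normal orthant probability P(Z1 > 0, Z2 > 0) for
# correlation rho (closed form).
orthant_upper <- function(rho) 1 / 4 + asin(rho) / (2 * pi)
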