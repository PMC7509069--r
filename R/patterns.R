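#' Encode attribute-mastery profiles as pattern indices
#'
#' An attribute-mastery profile is a binary vector of length `K` saying which
#' of the `K` attributes an examinee has mastered. Profiles are put in
#' one-to-one correspondence with the integers `0 .. 2^K - 1` by reading the
#' profile as a binary number with the *first* attribute as the most
#' significant bit, so for `K = 3` the patterns sort lexicographically
#' `000, 001, 010, ..., 111` onto `0:7`.
#'
#' @param profiles A binary matrix (examinees x attributes), or a single
#'   profile given as a vector. Data frames are accepted.
#' @return An integer vector of pattern indices in `[0, 2^K - 1]`.
#' @examples
#' encode_pattern(c(1, 0, 1))      # 5
#' decode_pattern(0:7, k = 3)      # all 8 profiles in order
#' @seealso [decode_pattern()]
#' @export
encode_pattern <- function(profiles) {
  if (is.null(dim(profiles))) profiles <- matrix(profiles, nrow = 1)
  m <- as_binary_matrix(profiles, "profiles")
  k <- ncol(m)
  if (k < 1) abort("`profiles` must have at least one attribute column.")
  as.integer(m %*% 2^((k - 1):0))
}

#' Decode pattern indices back to attribute-mastery profiles
#'
#' @param index Integer vector of pattern indices in `[0, 2^K - 1]`.
#' @param k Number of attributes.
#' @return A binary integer matrix with `length(index)` rows and `k` columns.
#' @export
decode_pattern <- function(index, k) {
  index <- as.integer(index)
  if (anyNA(index) || any(index < 0) || any(index > 2^k - 1)) {
    abort(sprintf("`index` must lie in [0, %d] for k = %d.", 2^k - 1L, k))
  }
  m <- vapply(seq_len(k), function(j) as.integer((index %/% 2^(k - j)) %% 2),
              integer(length(index)))
  m <- matrix(as.integer(m), nrow = length(index), ncol = k)
  colnames(m) <- paste0("A", seq_len(k))
  m
}

#' Pattern labels in lexicographic order
#'
#' Returns the `2^k` mastery-pattern strings (`"000"`, `"001"`, ...) in the
#' order used by [encode_pattern()].
#'
#' @param k Number of attributes.
#' @return A character vector of length `2^k`.
#' @export
pattern_labels <- function(k) {
  apply(decode_pattern(0:(2^k - 1), k), 1, paste, collapse = "")
}
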