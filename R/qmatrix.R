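#' Construct a Q matrix
#'
#' The Q matrix is the backbone of any cognitive diagnosis model: a binary
#' items-by-attributes incidence matrix in which `q[j, k] = 1` declares that
#' item `j` requires attribute `k`. Every item must require at least one
#' attribute.
#'
#' A Q matrix is *complete* when every attribute can be told apart from the
#' empty profile, i.e. each attribute is measured in isolation by at least
#' one item. Incomplete Q matrices are accepted with a warning, because some
#' operational tests are incomplete by design; completeness is checked with
#' [q_completeness()].
#'
#' @param x Binary matrix or data frame (items x attributes).
#' @param item_ids,attribute_ids Optional labels; defaults are `Item1..J` and
#'   `A1..K`.
#' @param quiet If `TRUE`, suppress the incompleteness warning.
#' @return An integer matrix of class `"q_matrix"`.
#' @examples
#' q <- q_matrix(rbind(c(1, 0), c(0, 1), c(1, 1)))
#' q_completeness(q)
#' @export
q_matrix <- function(x, item_ids = NULL, attribute_ids = NULL, quiet = FALSE) {
  m <- as_binary_matrix(x, "q matrix")
  if (nrow(m) < 1 || ncol(m) < 1) abort("A Q matrix needs at least one item and one attribute.")
  empty <- rowSums(m) == 0
  if (any(empty)) {
    abort(sprintf("Every item must require at least one attribute; item row(s) %s are all zero.",
                  paste(which(empty), collapse = ", ")))
  }
  rownames(m) <- item_ids %||% rownames(m) %||% paste0("Item", seq_len(nrow(m)))
  colnames(m) <- attribute_ids %||% colnames(m) %||% paste0("A", seq_len(ncol(m)))
  class(m) <- c("q_matrix", class(m))
  if (!quiet) {
    comp <- q_completeness(m)
    if (!comp$complete) {
      warn(paste0(
        "Q matrix is incomplete: attribute(s) ",
        paste(comp$unidentified, collapse = ", "),
        " are never measured in isolation, so some mastery patterns share ",
        "identical ideal responses."
      ))
    }
  }
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.q_matrix <- function(x, ...) {
  cat(sprintf("Q matrix: %d items x %d attributes (%s)\n",
              nrow(x), ncol(x),
              if (q_completeness(x)$complete) "complete" else "incomplete"))
  print(unclass(x), ...)
  invisible(x)
}

#' Check Q-matrix completeness
#'
#' An attribute is identified on its own when some item measures it and
#' nothing else. When no such item exists the all-zero profile and the
#' profile mastering only that attribute produce identical ideal responses
#' and cannot be distinguished by any classifier. The stricter question --
#' which whole mastery patterns collide -- is answered by
#' [ideal_response_collisions()].
#'
#' @param q A [q_matrix()].
#' @return A list with `complete` (logical) and `unidentified` (attribute
#'   labels lacking a single-attribute item).
#' @export
q_completeness <- function(q) {
  single <- rowSums(q) == 1
  covered <- colSums(q[single, , drop = FALSE]) > 0
  list(complete = all(covered), unidentified = colnames(q)[!covered])
}

#' Read a Q matrix from a delimited file
#'
#' @param path File path.
#' @param delim Field delimiter, `","` (CSV, default) or `"\t"` (TSV).
#' @param header Does the file carry a header row of attribute labels?
#' @param quiet Passed to [q_matrix()].
#' @return A [q_matrix()].
#' @export
read_q_matrix <- function(path, delim = ",", header = FALSE, quiet = FALSE) {
  df <- readr::read_delim(path, delim = delim, col_names = header,
                          show_col_types = FALSE, progress = FALSE)
  bad <- !vapply(df, is.numeric, logical(1))
  if (any(bad)) {
    abort(sprintf("Non-binary cells in column(s) %s of %s.",
                  paste(which(bad), collapse = ", "), path))
  }
  m <- as.matrix(df)
  nonbin <- which(!(m %in% c(0, 1)))
  if (length(nonbin)) {
    rows <- unique((nonbin - 1) %% nrow(m) + 1)
    abort(sprintf("Non-binary cell(s) in row(s) %s of %s.",
                  paste(head(rows, 5), collapse = ", "), path))
  }
  q_matrix(m, attribute_ids = if (header) colnames(df) else NULL, quiet = quiet)
}

#' Read a dichotomous response matrix from a delimited file
#'
#' Rows are examinees and columns are items; an optional leading
#' non-numeric column is treated as examinee identifiers.
#'
#' @inheritParams read_q_matrix
#' @param header Does the file carry a header row?
#' @return A tibble with an `examinee` identifier column followed by one
#'   integer 0/1 column per item.
#' @export
read_responses <- function(path, delim = ",", header = TRUE) {
  df <- readr::read_delim(path, delim = delim, col_names = header,
                          show_col_types = FALSE, progress = FALSE)
  m <- as_binary_matrix(df, "responses")
  out <- as_tibble(m, .name_repair = "minimal")
  names(out) <- paste0("Item", seq_len(ncol(m)))
  dplyr::bind_cols(
    tibble(examinee = rownames(m) %||% as.character(seq_len(nrow(m)))),
    out
  )
}
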