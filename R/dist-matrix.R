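#' Construct a distance matrix object
#'
#' A `dist_matrix` is a square symmetric matrix of pairwise dissimilarities
#' with a zero diagonal, nonnegative entries, and sample identifiers attached
#' as row/column names. It is the common currency of the package: every
#' dissimilarity function returns one, and the mediation tests consume aligned
#' triples of them.
#'
#' @param values Square numeric matrix of dissimilarities.
#' @param ids Character vector of sample identifiers, one per row. Defaults to
#'   the rownames of `values`, or `s1..sn` when absent.
#' @param symmetrize If `TRUE`, replace `values` by `(values + t(values)) / 2`
#'   before validation; useful for matrices read from text with round-off.
#' @param tol Symmetry tolerance (maximum absolute row/column discrepancy).
#'
#' @return An object of class `dist_matrix`: the numeric matrix with ids as
#'   dimnames.
#' @export
#'
#' @examples
#' d <- dist_matrix(matrix(c(0, 2, 2, 0), 2), ids = c("a", "b"))
#' sample_ids(d)
dist_matrix <- function(values, ids = NULL, symmetrize = FALSE, tol = 1e-12) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  n <- nrow(values)
  if (n < 2L || ncol(values) != n) {
    stop("`values` must be square with n >= 2", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("distance matrix entries must be finite", call. = FALSE)
  }
  if (symmetrize) values <- (values + t(values)) / 2
  asym <- max(abs(values - t(values)))
  if (asym > tol) {
    stop(sprintf("matrix is not symmetric (max discrepancy %.3g > tol %.3g)",
                 asym, tol), call. = FALSE)
  }
  values <- (values + t(values)) / 2
  if (any(values < 0)) stop("distances must be nonnegative", call. = FALSE)
  if (max(abs(diag(values))) > tol) {
    stop("diagonal must be zero", call. = FALSE)
  }
  diag(values) <- 0
  if (is.null(ids)) ids <- rownames(values)
  if (is.null(ids)) ids <- paste0("s", seq_len(n))
  ids <- as.character(ids)
  if (length(ids) != n) stop("`ids` must have one entry per sample", call. = FALSE)
  if (anyDuplicated(ids)) stop("sample ids must be unique", call. = FALSE)
  dimnames(values) <- list(ids, ids)
  structure(values, class = c("dist_matrix", "matrix", "array"))
}

#' Test for and coerce to dist_matrix
#'
#' `as_dist_matrix()` accepts a `dist_matrix`, a square numeric matrix, or a
#' [stats::dist] object.
#'
#' @param x Object to test or coerce.
#' @param ... Passed on to [dist_matrix()].
#' @return `is_dist_matrix()` returns a logical; `as_dist_matrix()` a
#'   `dist_matrix`.
#' @export
is_dist_matrix <- function(x) inherits(x, "dist_matrix")

#' @rdname is_dist_matrix
#' @export
as_dist_matrix <- function(x, ...) {
  if (is_dist_matrix(x)) return(x)
  if (inherits(x, "dist")) {
    m <- as.matrix(x)
    return(dist_matrix(m, ids = rownames(m), ...))
  }
  if (is.matrix(x)) return(dist_matrix(x, ...))
  stop("cannot coerce object of class ", paste(class(x), collapse = "/"),
       " to dist_matrix", call. = FALSE)
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("<dist_matrix: %d samples>\n", nrow(x)))
  print(unclass(x), ...)
  invisible(x)
}

#' Sample identifiers of a dist_matrix or abundance table
#'
#' @param x A `dist_matrix` or a matrix with rownames.
#' @return Character vector of sample ids.
#' @export
sample_ids <- function(x) rownames(x)

n_samples <- function(x) nrow(x)

#' Permute the rows and columns of a distance matrix
#'
#' Applies one permutation jointly to rows and columns, so entry `(i, j)` of
#' the result is entry `(perm[i], perm[j])` of the input. Sample ids stay with
#' their positions, which is exactly what breaks the linkage between this
#' matrix and any other matrix indexed by the same ids -- the operation at the
#' heart of the permutation null.
#'
#' @param d A `dist_matrix`.
#' @param perm Integer vector, a permutation of `1:n`.
#' @return A `dist_matrix` of the same size.
#' @export
permute_dist_matrix <- function(d, perm) {
  d <- as_dist_matrix(d)
  n <- nrow(d)
  perm <- as.integer(perm)
  if (length(perm) != n || anyNA(perm) || !setequal(perm, seq_len(n))) {
    stop("`perm` must be a permutation of 1..n", call. = FALSE)
  }
  v <- unclass(d)[perm, perm, drop = FALSE]
  dimnames(v) <- dimnames(d)
  structure(v, class = class(d))
}

stop_if_misaligned <- function(...) {
  mats <- list(...)
  ids <- lapply(mats, sample_ids)
  n <- vapply(mats, nrow, 1L)
  if (length(unique(n)) != 1L) {
    stop("distance matrices have different sizes: ",
         paste(n, collapse = ", "), call. = FALSE)
  }
  for (i in seq_along(ids)[-1]) {
    if (!identical(ids[[1]], ids[[i]])) {
      stop("sample ids are not aligned across distance matrices; ",
           "use align_samples() first", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Read and write square distance matrices as tab-delimited text
#'
#' The on-disk format is a header row of sample ids and a first column of
#' sample ids, tab-delimited. `read_dist_matrix()` checks symmetry to `tol`
#' and can optionally symmetrize by averaging.
#'
#' @param path File path.
#' @param symmetrize Average the matrix with its transpose before validating.
#' @param tol Symmetry tolerance on read.
#' @return `read_dist_matrix()` returns a `dist_matrix`;
#'   `write_dist_matrix()` returns `path` invisibly.
#' @export
read_dist_matrix <- function(path, symmetrize = FALSE, tol = 1e-8) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE, comment.char = "")
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric entries in ", path, call. = FALSE)
  if (!identical(rownames(m), colnames(m))) {
    stop("row and column ids disagree in ", path, call. = FALSE)
  }
  dist_matrix(m, symmetrize = symmetrize, tol = tol)
}

#' @rdname read_dist_matrix
#' @param d A `dist_matrix` to write.
#' @export
write_dist_matrix <- function(d, path) {
  d <- as_dist_matrix(d)
  df <- data.frame(id = sample_ids(d), unclass(d), check.names = FALSE)
  names(df)[1] <- ""
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
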