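#' Center a distance matrix
#'
#' Two centering schemes underpin the energy statistics in this package.
#'
#' `double_center()` applies the classical product-moment ("V") centering
#' \deqn{A_{jk} = d_{jk} - \bar d_{j.} - \bar d_{.k} + \bar d_{..},}
#' after which every row and column sums to zero. Mean elementwise products of
#' two such matrices give the (biased) squared distance covariance V-statistic.
#'
#' `u_center()` applies the U-centering of the unbiased theory: for
#' off-diagonal entries
#' \deqn{\tilde A_{ij} = d_{ij} - \frac{1}{n-2}\sum_k d_{ik}
#'   - \frac{1}{n-2}\sum_k d_{kj} + \frac{1}{(n-1)(n-2)}\sum_{kl} d_{kl},}
#' with the diagonal set to zero. Inner products of U-centered matrices,
#' scaled by \eqn{1/(n(n-3))}, are unbiased estimators of squared distance
#' covariance and are the building blocks of bias-corrected distance
#' correlation and partial distance correlation. U-centering needs `n >= 4`.
#'
#' @param d A `dist_matrix` (or anything [as_dist_matrix()] accepts).
#' @return A `centered_matrix`: numeric matrix with attribute
#'   `kind = "V"` or `kind = "U"`.
#' @seealso [dcor()], [bcdcor()], [pdcor()]
#' @export
#'
#' @examples
#' d <- dist_matrix(as.matrix(dist(1:5)))
#' rowSums(double_center(d))  # all ~0
double_center <- function(d) {
  d <- as_dist_matrix(d)
  v <- unclass(d)
  a <- v - rowMeans(v)
  a <- sweep(a, 2L, colMeans(v)) + mean(v)
  new_centered(a, kind = "V")
}

#' @rdname double_center
#' @export
u_center <- function(d) {
  d <- as_dist_matrix(d)
  n <- nrow(d)
  if (n < 4L) stop("U-centering requires n >= 4", call. = FALSE)
  v <- unclass(d)
  rs <- rowSums(v)
  cs <- colSums(v)
  g <- sum(v)
  a <- v - rs / (n - 2) - rep(cs / (n - 2), each = n) + g / ((n - 1) * (n - 2))
  dim(a) <- c(n, n)
  diag(a) <- 0
  dimnames(a) <- dimnames(v)
  new_centered(a, kind = "U")
}

new_centered <- function(m, kind) {
  structure(m, kind = kind, class = c("centered_matrix", "matrix", "array"))
}

#' @export
print.centered_matrix <- function(x, ...) {
  cat(sprintf("<centered_matrix (%s-centered): %d x %d>\n",
              attr(x, "kind"), nrow(x), ncol(x)))
  print(matrix(as.numeric(x), nrow(x), dimnames = dimnames(x)), ...)
  invisible(x)
}

centering_kind <- function(x) attr(x, "kind")

# Unbiased inner product of two U-centered matrices.
u_inner <- function(a, b) {
  n <- nrow(a)
  sum(a * b) / (n * (n - 3))
}
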