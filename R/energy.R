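#' Distance correlation between two distance matrices
#'
#' `dcor()` computes the V-statistic distance correlation: with `A`, `B` the
#' double-centered matrices, `dCov^2 = mean(A * B)` over all `n^2` cells and
#' `dCor = dCov / sqrt(dCov_xx * dCov_yy)` where `dCov_xx = sqrt(mean(A * A))`.
#' Tiny negative values of the mean product, pure rounding artifacts, are
#' clamped to zero before the square root. When either marginal distance
#' covariance vanishes (a constant sample), the correlation is 0 by
#' convention. `dcor()` lies in `[0, 1]`.
#'
#' `bcdcor()` computes the bias-corrected distance correlation `R*`: the
#' cosine of the U-centered matrices under the unbiased inner product
#' `<A, B> = sum(A * B) / (n (n - 3))`. Unlike the V-statistic it may be
#' negative in finite samples; it requires `n >= 4`.
#'
#' @param dx,dy `dist_matrix` objects (or coercible), same samples in the
#'   same order.
#' @return A single number.
#' @seealso [pdcor()] for the partial version, [modima_test()] for the
#'   mediation test built from these.
#' @export
#'
#' @examples
#' x <- matrix(rnorm(40), 20)
#' y <- x + matrix(rnorm(40, sd = 0.3), 20)
#' dcor(dist_euclidean(x), dist_euclidean(y))
dcor <- function(dx, dy) {
  dx <- as_dist_matrix(dx); dy <- as_dist_matrix(dy)
  stop_if_misaligned(dx, dy)
  a <- double_center(dx)
  b <- double_center(dy)
  vxy <- sqrt(max(mean(a * b), 0))
  vx <- sqrt(max(mean(a * a), 0))
  vy <- sqrt(max(mean(b * b), 0))
  den <- sqrt(vx * vy)
  if (den <= 1e-12) return(0)
  vxy / den
}

#' @rdname dcor
#' @export
bcdcor <- function(dx, dy) {
  dx <- as_dist_matrix(dx); dy <- as_dist_matrix(dy)
  stop_if_misaligned(dx, dy)
  a <- u_center(dx)
  b <- u_center(dy)
  bcdcor_from_inner(u_inner(a, b), u_inner(a, a), u_inner(b, b))
}

bcdcor_from_inner <- function(ip_xy, ip_xx, ip_yy) {
  den <- sqrt(ip_xx * ip_yy)
  if (!is.finite(den) || den <= 1e-12) return(0)
  ip_xy / den
}

#' Partial distance correlation
#'
#' The partial distance correlation of `X` and `Y` removing `Z`, built from
#' bias-corrected distance correlations:
#' \deqn{pdCor(X, Y; Z) = \frac{R^*_{XY} - R^*_{XZ} R^*_{YZ}}
#'   {\sqrt{(1 - R^{*2}_{XZ})(1 - R^{*2}_{YZ})}}.}
#' When the denominator is degenerate (one of the `R*` factors is within
#' 1e-12 of +/-1) the value is 0 by convention, with a warning, so that
#' permutation loops never abort. Note that zero partial distance correlation
#' does not imply conditional independence: for `M` and `Y` independent
#' linear combinations of a common `X`, `pdcor(M, Y; X) > 0` even
#' asymptotically.
#'
#' @param dx,dy,dz Aligned `dist_matrix` objects; the relation of `dx` and
#'   `dy` is assessed removing `dz`.
#' @param denominator `"standard"` (default) uses
#'   `sqrt((1 - R*_xz^2) (1 - R*_yz^2))`, the definition of the partial
#'   correlation literature. `"printed"` swaps the second factor for
#'   `(1 - R*_xy^2)`, a variant that circulates in print; it is provided for
#'   audit only.
#' @return A single number in `[-1, 1]`.
#' @export
pdcor <- function(dx, dy, dz, denominator = c("standard", "printed")) {
  denominator <- match.arg(denominator)
  dx <- as_dist_matrix(dx); dy <- as_dist_matrix(dy); dz <- as_dist_matrix(dz)
  stop_if_misaligned(dx, dy, dz)
  a <- u_center(dx); b <- u_center(dy); c <- u_center(dz)
  ip <- function(u, v) u_inner(u, v)
  rxy <- bcdcor_from_inner(ip(a, b), ip(a, a), ip(b, b))
  rxz <- bcdcor_from_inner(ip(a, c), ip(a, a), ip(c, c))
  ryz <- bcdcor_from_inner(ip(b, c), ip(b, b), ip(c, c))
  partial_from_marginals(rxy, rxz, ryz, denominator)
}

# Shared partial-correlation arithmetic for both the Pearson and the R* case.
partial_from_marginals <- function(rxy, rxz, ryz,
                                   denominator = "standard") {
  d2 <- if (denominator == "printed") (1 - rxy^2) else (1 - ryz^2)
  den <- sqrt((1 - rxz^2) * d2)
  if (!is.finite(den) || den <= 1e-12) {
    warning("degenerate denominator in partial correlation; returning 0",
            call. = FALSE)
    return(0)
  }
  (rxy - rxz * ryz) / den
}

#' Pearson partial correlation of numeric vectors
#'
#' The classical first-order partial correlation
#' `(r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`, identical to the
#' correlation of the OLS residuals of `x` on `z` and `y` on `z`. Degenerate
#' denominators return 0 with a warning.
#'
#' @param x,y,z Numeric vectors of equal length (at least 3), each
#'   non-constant.
#' @inheritParams pdcor
#' @return A single number in `[-1, 1]`.
#' @export
pearson_partial <- function(x, y, z, denominator = c("standard", "printed")) {
  denominator <- match.arg(denominator)
  stopifnot(length(x) == length(y), length(x) == length(z))
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0 || stats::sd(z) == 0) {
    stop("constant input vector: partial correlation undefined", call. = FALSE)
  }
  partial_from_marginals(stats::cor(x, y), stats::cor(x, z), stats::cor(y, z),
                         denominator)
}
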