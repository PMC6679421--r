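#' The MODIMA distance mediation statistic
#'
#' For aligned exposure, mediator and response distance matrices the
#' multivariate omnibus distance mediation statistic is the product of two
#' factors: the distance correlation between exposure and mediator, and the
#' partial distance correlation between mediator and response given the
#' exposure,
#' \deqn{S_d = dCor(d_{XX}, d_{MM}) \times pdCor(M, Y; X).}
#' Both dependence links of a mediated pathway (exposure to mediator,
#' mediator to response net of exposure) must be present for the product to
#' be large.
#'
#' With `variant = "bias-corrected"` (default) the first factor is the
#' bias-corrected distance correlation `R*`; with `variant = "v-statistic"`
#' it is the plain V-statistic [dcor()]. The partial factor is always built
#' from bias-corrected correlations, as partial distance correlation is
#' defined on the unbiased inner product.
#'
#' @param dx,dm,dy Aligned `dist_matrix` objects for exposure, mediator and
#'   response (n >= 4).
#' @param variant `"bias-corrected"` or `"v-statistic"` for the
#'   exposure-mediator factor.
#' @return A list with `statistic`, `factor_xm`, `factor_my_given_x`.
#' @seealso [modima_test()] for the permutation test.
#' @export
#'
#' @examples
#' set.seed(1)
#' x <- rnorm(30); m <- x + rnorm(30, sd = 0.5); y <- m + rnorm(30, sd = 0.5)
#' modima_statistic(dist_euclidean(x), dist_euclidean(m), dist_euclidean(y))
modima_statistic <- function(dx, dm, dy,
                             variant = c("bias-corrected", "v-statistic")) {
  variant <- match.arg(variant)
  pre <- modima_prepare(dx, dm, dy, variant)
  out <- modima_eval(pre)
  list(statistic = out[["statistic"]],
       factor_xm = out[["factor_xm"]],
       factor_my_given_x = out[["factor_my_given_x"]])
}

# Precompute everything permutation-invariant: centered matrices and the
# inner products that do not involve the permuted term.
modima_prepare <- function(dx, dm, dy, variant) {
  dx <- as_dist_matrix(dx); dm <- as_dist_matrix(dm); dy <- as_dist_matrix(dy)
  stop_if_misaligned(dx, dm, dy)
  n <- nrow(dx)
  if (n < 4L) stop("MODIMA requires n >= 4", call. = FALSE)
  ux <- u_center(dx); um <- u_center(dm); uy <- u_center(dy)
  pre <- list(
    n = n, variant = variant,
    ux = unclass(ux), um = unclass(um), uy = unclass(uy),
    ip_xx = u_inner(ux, ux), ip_mm = u_inner(um, um), ip_yy = u_inner(uy, uy),
    ip_xm = u_inner(ux, um), ip_xy = u_inner(ux, uy), ip_my = u_inner(um, uy)
  )
  if (variant == "v-statistic") {
    vx <- unclass(double_center(dx)); vm <- unclass(double_center(dm))
    pre$vx <- vx
    pre$vm <- vm
    pre$v_xx <- mean(vx * vx)
    pre$v_mm <- mean(vm * vm)
    pre$v_xm <- mean(vx * vm)
  }
  pre
}

# Evaluate (statistic, factors) from a prepared state, optionally with the
# exposure or response matrices permuted by `perm`.
modima_eval <- function(pre, perm = NULL, permuted_term = NULL) {
  n <- pre$n
  sc <- n * (n - 3)
  ip_xm <- pre$ip_xm; ip_xy <- pre$ip_xy; ip_my <- pre$ip_my
  v_xm <- pre$v_xm
  if (!is.null(perm)) {
    if (permuted_term == "exposure") {
      uxp <- pre$ux[perm, perm]
      ip_xm <- sum(uxp * pre$um) / sc
      ip_xy <- sum(uxp * pre$uy) / sc
      if (pre$variant == "v-statistic") {
        v_xm <- mean(pre$vx[perm, perm] * pre$vm)
      }
    } else {
      uyp <- pre$uy[perm, perm]
      ip_xy <- sum(pre$ux * uyp) / sc
      ip_my <- sum(pre$um * uyp) / sc
    }
  }
  r_xm <- bcdcor_from_inner(ip_xm, pre$ip_xx, pre$ip_mm)
  r_xy <- bcdcor_from_inner(ip_xy, pre$ip_xx, pre$ip_yy)
  r_my <- bcdcor_from_inner(ip_my, pre$ip_mm, pre$ip_yy)
  f2 <- {
    den <- sqrt((1 - r_xm^2) * (1 - r_xy^2))
    if (!is.finite(den) || den <= 1e-12) 0 else (r_my - r_xm * r_xy) / den
  }
  f1 <- if (pre$variant == "v-statistic") {
    num <- sqrt(max(v_xm, 0))
    den <- sqrt(sqrt(max(pre$v_xx, 0) * max(pre$v_mm, 0)))
    if (den <= 1e-12) 0 else num / den
  } else {
    r_xm
  }
  c(statistic = f1 * f2, factor_xm = f1, factor_my_given_x = f2)
}

#' MODIMA adaptive permutation test
#'
#' Computes the observed [modima_statistic()] and its permutation null. The
#' null is generated adaptively: the factor with the smaller magnitude is the
#' weaker link of the mediation chain, so its matrix is the one scrambled.
#' When `|dCor(X, M)| < |pdCor(M, Y; X)|` the rows and columns of the
#' exposure matrix are permuted jointly; otherwise (including ties) the
#' response matrix is. The full statistic is recomputed for each of `q`
#' permutations, and
#' \deqn{p = \frac{1}{q} \sum_{i=1}^q 1\{S_d \le S_d^{(i)}\},}
#' the frequency with which the permuted statistic reaches the observed one.
#' This estimator can return an exact 0; set `positive_p = TRUE` for the
#' `(1 + count) / (1 + q)` variant that cannot.
#'
#' The identity permutation is not excluded from the draw: its probability is
#' negligible and excluding it would bias the null.
#'
#' @inheritParams modima_statistic
#' @param q Number of permutations (>= 1).
#' @param seed Integer seed for the permutation draw; `NULL` uses the current
#'   RNG state.
#' @param positive_p Use the add-one permutation p-value, guaranteed > 0.
#' @return An object of class `modima_test`: a list with the observed
#'   `statistic`, `factor_xm`, `factor_my_given_x`, `p_value`,
#'   `n_permutations`, `permuted_statistics` (length `q`), `permuted_term`
#'   (`"exposure"` or `"response"`), `variant`, `n`, `seed`.
#' @export
#'
#' @examples
#' set.seed(7)
#' x <- rnorm(40); m <- x + rnorm(40); y <- m + rnorm(40)
#' fit <- modima_test(dist_euclidean(x), dist_euclidean(m), dist_euclidean(y),
#'                    q = 199, seed = 1)
#' fit
#' glance(fit)
modima_test <- function(dx, dm, dy, q = 999, seed = NULL,
                        variant = c("bias-corrected", "v-statistic"),
                        positive_p = FALSE) {
  variant <- match.arg(variant)
  q <- as.integer(q)
  if (is.na(q) || q < 1L) stop("`q` must be a positive integer", call. = FALSE)
  pre <- modima_prepare(dx, dm, dy, variant)
  obs <- modima_eval(pre)
  term <- if (abs(obs[["factor_xm"]]) < abs(obs[["factor_my_given_x"]])) {
    "exposure"
  } else {
    "response"
  }
  if (!is.null(seed)) set.seed(seed)
  perms <- numeric(q)
  for (i in seq_len(q)) {
    p <- sample.int(pre$n)
    perms[i] <- modima_eval(pre, p, term)[["statistic"]]
  }
  structure(
    list(
      statistic = obs[["statistic"]],
      factor_xm = obs[["factor_xm"]],
      factor_my_given_x = obs[["factor_my_given_x"]],
      p_value = perm_p_value(obs[["statistic"]], perms, positive_p),
      n_permutations = q,
      permuted_statistics = perms,
      permuted_term = term,
      variant = variant,
      n = pre$n,
      seed = seed
    ),
    class = "modima_test"
  )
}

perm_p_value <- function(observed, permuted, positive_p = FALSE) {
  hits <- sum(permuted >= observed)
  if (positive_p) (1 + hits) / (1 + length(permuted)) else hits / length(permuted)
}

#' @export
print.modima_test <- function(x, ...) {
  cat("\tMODIMA distance mediation test\n\n")
  cat(sprintf("statistic = %.4g  (dCor[X,M] = %.4g, pdCor[M,Y|X] = %.4g)\n",
              x$statistic, x$factor_xm, x$factor_my_given_x))
  cat(sprintf("p-value = %.4g  (%d permutations of the %s matrix)\n",
              x$p_value, x$n_permutations, x$permuted_term))
  cat(sprintf("n = %d, variant = %s\n", x$n, x$variant))
  invisible(x)
}

#' Univariate single-mediator product-of-correlations statistic
#'
#' The baseline univariate analogue of MODIMA: the product of the Pearson
#' correlation between exposure and mediator and the correlation between the
#' residuals of mediator-on-exposure and response-on-exposure regressions,
#' \deqn{S(X, M, Y) = \rho_{X,M} \; \rho_{r_{M|X}, r_{Y|X}}.}
#' If a residual vector is constant (e.g. the mediator is an exact linear
#' function of the exposure) the statistic is 0 by convention, with a
#' warning.
#'
#' @param x,m,y Numeric vectors of equal length (>= 3); `x` non-constant.
#' @return A single number.
#' @seealso [smm_test()] for the permutation test.
#' @export
smm_statistic <- function(x, m, y) {
  check_smm_inputs(x, m, y)
  out <- smm_stat_core(x, m, y)
  if (attr(out, "degenerate")) {
    warning("constant residual: statistic is 0 by convention", call. = FALSE)
  }
  as.numeric(out["statistic"])
}

check_smm_inputs <- function(x, m, y) {
  stopifnot(length(x) == length(m), length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0) stop("constant exposure vector", call. = FALSE)
  invisible(TRUE)
}

# Returns c(statistic, f1, f2) with a "degenerate" attribute; silent, for
# use inside permutation loops.
smm_stat_core <- function(x, m, y) {
  degenerate <- FALSE
  f1 <- if (stats::sd(m) == 0) {
    degenerate <- TRUE
    0
  } else {
    stats::cor(x, m)
  }
  xc <- x - mean(x)
  beta_m <- sum(xc * m) / sum(xc * xc)
  beta_y <- sum(xc * y) / sum(xc * xc)
  rm_ <- m - mean(m) - beta_m * xc
  ry_ <- y - mean(y) - beta_y * xc
  f2 <- if (stats::sd(rm_) <= .Machine$double.eps^0.5 * max(1, stats::sd(m)) ||
            stats::sd(ry_) <= .Machine$double.eps^0.5 * max(1, stats::sd(y))) {
    degenerate <- TRUE
    0
  } else {
    stats::cor(rm_, ry_)
  }
  structure(c(statistic = f1 * f2, f1 = f1, f2 = f2), degenerate = degenerate)
}

#' Permutation test for the univariate single-mediator statistic
#'
#' Applies the same adaptive permutation logic as [modima_test()] to
#' [smm_statistic()]: the exposure vector is permuted when
#' `|cor(x, m)|` is the smaller factor in magnitude, otherwise the response
#' vector; the full statistic is recomputed per permutation and the p-value
#' is the frequency with which the permuted statistic reaches the observed.
#'
#' @inheritParams smm_statistic
#' @inheritParams modima_test
#' @return An object of class `smm_test` with `statistic`, `p_value`,
#'   `n_permutations`, `permuted_statistics`, `permuted_term`, `n`, `seed`.
#' @export
smm_test <- function(x, m, y, q = 999, seed = NULL, positive_p = FALSE) {
  check_smm_inputs(x, m, y)
  q <- as.integer(q)
  if (is.na(q) || q < 1L) stop("`q` must be a positive integer", call. = FALSE)
  obs <- smm_stat_core(x, m, y)
  term <- if (abs(obs["f1"]) < abs(obs["f2"])) "exposure" else "response"
  if (!is.null(seed)) set.seed(seed)
  n <- length(x)
  perms <- numeric(q)
  for (i in seq_len(q)) {
    p <- sample.int(n)
    perms[i] <- if (term == "exposure") {
      smm_stat_core(x[p], m, y)["statistic"]
    } else {
      smm_stat_core(x, m, y[p])["statistic"]
    }
  }
  structure(
    list(
      statistic = as.numeric(obs["statistic"]),
      factor_xm = as.numeric(obs["f1"]),
      factor_my_given_x = as.numeric(obs["f2"]),
      p_value = perm_p_value(obs["statistic"], perms, positive_p),
      n_permutations = q,
      permuted_statistics = perms,
      permuted_term = term,
      n = n,
      seed = seed
    ),
    class = "smm_test"
  )
}

#' @export
print.smm_test <- function(x, ...) {
  cat("\tSingle-mediator product-of-correlations permutation test\n\n")
  cat(sprintf("statistic = %.4g  (cor[X,M] = %.4g, cor[rM|X, rY|X] = %.4g)\n",
              x$statistic, x$factor_xm, x$factor_my_given_x))
  cat(sprintf("p-value = %.4g  (%d permutations of the %s vector)\n",
              x$p_value, x$n_permutations, x$permuted_term))
  invisible(x)
}
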