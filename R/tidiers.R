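#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy summaries of mediation test results
#'
#' `tidy()` returns one row per component of the statistic (the two factors
#' and their product); `glance()` returns a one-row summary of the whole
#' test.
#'
#' @param x A `modima_test` or `smm_test` object.
#' @param ... Unused, for generic consistency.
#' @return A tibble.
#' @method tidy modima_test
#' @export
tidy.modima_test <- function(x, ...) {
  tibble::tibble(
    term = c("dcor_xm", "pdcor_my_given_x", "modima"),
    estimate = c(x$factor_xm, x$factor_my_given_x, x$statistic)
  )
}

#' @rdname tidy.modima_test
#' @method tidy smm_test
#' @export
tidy.smm_test <- function(x, ...) {
  tibble::tibble(
    term = c("cor_xm", "cor_residuals_my_given_x", "smm"),
    estimate = c(x$factor_xm, x$factor_my_given_x, x$statistic)
  )
}

#' @rdname tidy.modima_test
#' @method glance modima_test
#' @export
glance.modima_test <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic,
    factor_xm = x$factor_xm,
    factor_my_given_x = x$factor_my_given_x,
    p.value = x$p_value,
    n_permutations = x$n_permutations,
    permuted_term = x$permuted_term,
    variant = x$variant,
    n = x$n,
    method = "modima"
  )
}

#' @rdname tidy.modima_test
#' @method glance smm_test
#' @export
glance.smm_test <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic,
    factor_xm = x$factor_xm,
    factor_my_given_x = x$factor_my_given_x,
    p.value = x$p_value,
    n_permutations = x$n_permutations,
    permuted_term = x$permuted_term,
    variant = NA_character_,
    n = x$n,
    method = "smm"
  )
}
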