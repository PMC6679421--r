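#' Parameters of the single-mediator linear model
#'
#' The single-mediator model links a univariate exposure `X`, mediator `M`
#' and response `Y` through three linear paths:
#' \deqn{M = i_3 + \alpha X + \varepsilon_3, \qquad
#'       Y = i_2 + \gamma X + \beta M + \varepsilon_2,}
#' with `X` and the noise terms independent Gaussians. `alpha` is the
#' exposure-to-mediator path, `beta` the mediator-to-response path and
#' `gamma` the direct exposure-to-response path; mediation is present
#' exactly when both `alpha` and `beta` are nonzero. All standard deviations
#' default to 1 and the intercepts to 0 (intercepts do not affect any of the
#' correlation-based statistics in this package).
#'
#' @param alpha,beta,gamma Path coefficients.
#' @param sd_x,sd_m_noise,sd_y_noise Positive standard deviations of the
#'   exposure and of the mediator/response noise.
#' @param i1,i2,i3 Intercepts.
#' @return An object of class `smm_params` (a validated list).
#' @export
smm_params <- function(alpha = 0, beta = 0, gamma = 0,
                       sd_x = 1, sd_m_noise = 1, sd_y_noise = 1,
                       i1 = 0, i2 = 0, i3 = 0) {
  sds <- c(sd_x = sd_x, sd_m_noise = sd_m_noise, sd_y_noise = sd_y_noise)
  if (any(!is.finite(sds)) || any(sds <= 0)) {
    stop("standard deviations must be positive", call. = FALSE)
  }
  structure(
    list(alpha = alpha, beta = beta, gamma = gamma,
         sd_x = sd_x, sd_m_noise = sd_m_noise, sd_y_noise = sd_y_noise,
         i1 = i1, i2 = i2, i3 = i3),
    class = "smm_params"
  )
}

#' Simulate from the single-mediator linear model
#'
#' Draws `x ~ N(0, sd_x^2)`, `m = i3 + alpha x + eps_m`,
#' `y = i2 + gamma x + beta m + eps_y` with independent Gaussian noise.
#'
#' @param params An [smm_params()] object.
#' @param n Number of observations (>= 2).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A tibble with columns `x`, `m`, `y`.
#' @export
#'
#' @examples
#' d <- simulate_smm(smm_params(alpha = 1, beta = 1), n = 100, seed = 1)
#' cor(d$x, d$m)  # ~ 1/sqrt(2)
simulate_smm <- function(params, n, seed = NULL) {
  stopifnot(inherits(params, "smm_params"))
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("`n` must be an integer >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  x <- stats::rnorm(n, 0, params$sd_x)
  m <- params$i3 + params$alpha * x + stats::rnorm(n, 0, params$sd_m_noise)
  y <- params$i2 + params$gamma * x + params$beta * m +
    stats::rnorm(n, 0, params$sd_y_noise)
  tibble::tibble(x = x, m = m, y = y)
}
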