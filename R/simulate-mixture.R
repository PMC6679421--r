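#' Simulate exposure-microbiome-response triples via a two-population mixture
#'
#' The multivariate-mediator analogue of [simulate_smm()]: the mediator is a
#' taxon count table whose composition drifts between two reference
#' Dirichlet-multinomial populations as a function of the exposure. For each
#' subject `i`:
#'
#' 1. `x_i ~ N(0, 1)`;
#' 2. a mixture weight `w_i` couples exposure and composition. The default
#'    `mixing = "bernoulli"` rule draws
#'    `w_i ~ Bernoulli(plogis(alpha * x_i))`, i.e. each subject's community
#'    comes from one of the two populations, with the share of subjects
#'    drawing from each population governed by `alpha` and the exposure;
#'    `mixing = "logistic"` instead uses the deterministic interpolation
#'    `w_i = plogis(alpha * x_i)`. The subject's mean composition is
#'    `(1 - w_i) pi_a + w_i pi_b` and its overdispersion
#'    `(1 - w_i) theta_a + w_i theta_b`;
#' 3. counts are drawn Dirichlet-multinomial at depth `depth`;
#' 4. `y_i = gamma * x_i + beta * w_i + eps_i`, `eps_i ~ N(0, sd_y^2)` with
#'    `sd_y = 0.01` by default, so the response is essentially deterministic
#'    in the exposure and the mixture weight.
#'
#' With `alpha = 0` the weights carry no exposure signal, so the mediator is
#' exchangeable and independent of the exposure and the mediation null holds
#' exactly; increasing `alpha` strengthens the exposure-to-mediator path
#' monotonically. Under the default Bernoulli rule the weights still vary
#' across subjects at `alpha = 0`, so the mediator-to-response path `beta`
#' remains a real path there -- mirroring the role of `beta` in the
#' single-mediator model -- whereas the deterministic logistic rule
#' degenerates to `w_i = 1/2` for every subject at `alpha = 0`, severing the
#' `beta` path and turning that cell into the complete null. The response is
#' tied to the weight `w`, not to the realized counts; `beta` therefore
#' measures the response's dependence on the composition signal rather than
#' on sampling noise.
#'
#' Both rules are defensible readings of a two-population mixture design;
#' pass any `mixing = function(alpha, x)` returning weights in `[0, 1]` to
#' swap in an alternative.
#'
#' @param params An [smm_params()] object supplying `alpha`, `beta`,
#'   `gamma` (its SD fields are ignored here except through `sd_y`).
#' @param pop_a,pop_b [dm_params()] objects with identical taxon sets (the
#'   bundled [synthetic_oral_params()] pair by default use 21 taxa).
#' @param n Number of subjects.
#' @param depth Sequencing depth per subject.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param sd_y Response noise SD.
#' @param mixing `"bernoulli"` (default), `"logistic"`, or a function
#'   `(alpha, x) -> weights in [0, 1]`.
#' @return A list with `x` (numeric), `counts` (samples-by-taxa matrix),
#'   `y` (numeric), and the mixture weights `w`.
#' @export
#'
#' @examples
#' pops <- list(a = synthetic_oral_params("saliva"),
#'              b = synthetic_oral_params("tonsils"))
#' sim <- simulate_multimediator(smm_params(alpha = 1, beta = 1),
#'                               pops$a, pops$b, n = 30, depth = 1000,
#'                               seed = 1)
#' dim(sim$counts)
simulate_multimediator <- function(params, pop_a, pop_b, n, depth = 10000,
                                   seed = NULL, sd_y = 0.01,
                                   mixing = c("bernoulli", "logistic")) {
  stopifnot(inherits(params, "smm_params"),
            inherits(pop_a, "dm_params"), inherits(pop_b, "dm_params"))
  if (!identical(names(pop_a$pi), names(pop_b$pi))) {
    only_a <- setdiff(names(pop_a$pi), names(pop_b$pi))
    only_b <- setdiff(names(pop_b$pi), names(pop_a$pi))
    stop("taxon sets of the two populations differ",
         if (length(only_a)) paste0("; only in pop_a: ", paste(only_a, collapse = ", ")),
         if (length(only_b)) paste0("; only in pop_b: ", paste(only_b, collapse = ", ")),
         call. = FALSE)
  }
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("`n` must be >= 2", call. = FALSE)
  if (is.character(mixing)) {
    mixing <- switch(match.arg(mixing),
      bernoulli = function(alpha, x) {
        stats::rbinom(length(x), 1L, stats::plogis(alpha * x))
      },
      logistic = function(alpha, x) stats::plogis(alpha * x)
    )
  }
  if (!is.null(seed)) set.seed(seed)
  x <- stats::rnorm(n, 0, 1)
  w <- mixing(params$alpha, x)
  if (any(w < 0 | w > 1)) stop("mixing weights must lie in [0, 1]", call. = FALSE)
  p <- length(pop_a$pi)
  pi_rows <- outer(1 - w, pop_a$pi) + outer(w, pop_b$pi)
  theta_i <- (1 - w) * pop_a$theta + w * pop_b$theta
  props <- rdirichlet_rows(n, pi_rows, theta_i)
  counts <- t(vapply(seq_len(n),
                     function(i) stats::rmultinom(1, depth, props[i, ])[, 1],
                     integer(p)))
  dimnames(counts) <- list(paste0("s", seq_len(n)), names(pop_a$pi))
  y <- params$gamma * x + params$beta * w + stats::rnorm(n, 0, sd_y)
  list(x = x, counts = counts, y = y, w = w)
}

#' Random rooted binary tree with exponential branch lengths
#'
#' Generates a random rooted bifurcating topology by sequential random
#' attachment (via [ape::rtree()]) with independent Exponential(1) branch
#' lengths, the construction used for simulating phylogenies over synthetic
#' taxon sets.
#'
#' @param n_tips Number of tips (>= 2).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param tip_labels Optional labels, length `n_tips`; defaults to
#'   `t1..tn` to match the default taxon ids of [dm_params()].
#' @return A rooted `phylo` object with `n_tips` tips and `n_tips - 1`
#'   internal nodes.
#' @export
random_rooted_tree <- function(n_tips, seed = NULL, tip_labels = NULL) {
  n_tips <- as.integer(n_tips)
  if (is.na(n_tips) || n_tips < 2L) stop("`n_tips` must be >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rtree(n_tips, rooted = TRUE, br = function(k) stats::rexp(k, 1))
  if (is.null(tip_labels)) tip_labels <- paste0("t", seq_len(n_tips))
  if (length(tip_labels) != n_tips) {
    stop("`tip_labels` must have length `n_tips`", call. = FALSE)
  }
  tr$tip.label <- tip_labels[seq_len(n_tips)]
  tr
}
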