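#' Run a type-I-error / power simulation grid
#'
#' Simulates datasets over a factorial grid of path coefficients and sample
#' sizes, applies the requested mediation tests to each, and records the
#' fraction of rejections at a significance threshold. Two designs are
#' available:
#'
#' * `design = "single"`: the univariate single-mediator linear model
#'   ([simulate_smm()]), Euclidean distances, testable by both `"modima"`
#'   and the `"smm"` baseline;
#' * `design = "mixture"`: the two-population Dirichlet-multinomial
#'   microbiome mixture ([simulate_multimediator()]); the mediator distance
#'   is computed with each requested `metrics` entry (`"bray"`, `"jsd"`,
#'   `"jaccard"`, `"unifrac-unweighted"`, `"unifrac-weighted"`,
#'   `"unifrac-generalized"`), exposure and response use Euclidean distance,
#'   and only `"modima"` applies.
#'
#' All randomness flows from the single `seed`: a stream of per-cell seeds
#' is drawn first, then per-dataset seeds within each cell, so any cell (and
#' any dataset within it) can be reproduced independently of the rest of the
#' grid.
#'
#' @param alpha,beta,gamma,n Numeric vectors; the grid is their full cross.
#' @param design `"single"` or `"mixture"`.
#' @param methods Character subset of `c("modima", "smm")`.
#' @param metrics Mediator distance metrics (mixture design); ignored for
#'   the single design, which is Euclidean throughout.
#' @param n_datasets Simulated datasets per cell.
#' @param q Permutations per test.
#' @param threshold Significance threshold; a dataset counts as rejected
#'   when `p < threshold`.
#' @param seed Master seed for the whole grid.
#' @param variant Passed to [modima_test()].
#' @param pop_a,pop_b,tree,depth Mixture-design inputs: two [dm_params()]
#'   populations (default: the bundled [synthetic_oral_params()] pair), a
#'   rooted tree covering their taxa (default: a seeded
#'   [random_rooted_tree()]) and the sequencing depth.
#' @param gunifrac_alpha Exponent for generalized UniFrac.
#' @return A tibble of class `modima_grid` with one row per
#'   (alpha, beta, gamma, n, method, metric) cell and columns
#'   `rejection_fraction`, `n_datasets`, `n_permutations`, `threshold`.
#' @export
#'
#' @examples
#' g <- run_grid(alpha = c(0, 1), beta = 1, gamma = 0, n = 20,
#'               n_datasets = 20, q = 49, seed = 1)
#' g
run_grid <- function(alpha = 0, beta = 0, gamma = 0, n = 50,
                     design = c("single", "mixture"),
                     methods = c("modima", "smm"),
                     metrics = NULL,
                     n_datasets = 200, q = 99, threshold = 0.05,
                     seed = 1,
                     variant = c("bias-corrected", "v-statistic"),
                     pop_a = NULL, pop_b = NULL, tree = NULL,
                     depth = 10000, gunifrac_alpha = 0.5) {
  design <- match.arg(design)
  variant <- match.arg(variant)
  methods <- match.arg(methods, several.ok = TRUE)
  if (n_datasets < 1L || q < 1L) {
    stop("`n_datasets` and `q` must be >= 1", call. = FALSE)
  }
  if (length(alpha) == 0 || length(beta) == 0 || length(gamma) == 0 ||
      length(n) == 0) {
    stop("empty grid", call. = FALSE)
  }
  if (design == "single") {
    metrics <- "euclidean"
  } else {
    if ("smm" %in% methods) {
      stop("the smm baseline is univariate; use methods = \"modima\" ",
           "with the mixture design", call. = FALSE)
    }
    if (is.null(metrics)) metrics <- "bray"
    metrics <- match.arg(
      metrics,
      c("bray", "jsd", "jaccard", "unifrac-unweighted", "unifrac-weighted",
        "unifrac-generalized"),
      several.ok = TRUE
    )
    if (is.null(pop_a)) pop_a <- synthetic_oral_params("saliva")
    if (is.null(pop_b)) pop_b <- synthetic_oral_params("tonsils")
    if (is.null(tree) && any(startsWith(metrics, "unifrac"))) {
      tree <- random_rooted_tree(length(pop_a$pi), seed = seed,
                                 tip_labels = names(pop_a$pi))
    }
  }

  cells <- expand.grid(alpha = alpha, beta = beta, gamma = gamma, n = n,
                       KEEP.OUT.ATTRS = FALSE)
  set.seed(seed)
  cell_seeds <- sample.int(.Machine$integer.max - 1L, nrow(cells))

  rows <- purrr::map(seq_len(nrow(cells)), function(ci) {
    cell <- cells[ci, ]
    params <- smm_params(alpha = cell$alpha, beta = cell$beta,
                         gamma = cell$gamma)
    set.seed(cell_seeds[ci])
    ds_seeds <- sample.int(.Machine$integer.max - 1L, n_datasets)
    rej <- matrix(0L, length(methods) * length(metrics), 1)
    labels <- expand.grid(method = methods, metric = metrics,
                          stringsAsFactors = FALSE)
    for (d in seq_len(n_datasets)) {
      ps <- grid_one_dataset(design, params, cell$n, ds_seeds[d], q, variant,
                             methods, metrics, pop_a, pop_b, tree, depth,
                             gunifrac_alpha)
      rej <- rej + (ps < threshold)
    }
    tibble::tibble(
      alpha = cell$alpha, beta = cell$beta, gamma = cell$gamma,
      n = as.integer(cell$n),
      method = labels$method, metric = labels$metric,
      rejection_fraction = as.numeric(rej) / n_datasets,
      n_datasets = as.integer(n_datasets), n_permutations = as.integer(q),
      threshold = threshold
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("modima_grid", class(out))
  out
}

# p-values for one simulated dataset, in the row order of
# expand.grid(method = methods, metric = metrics).
grid_one_dataset <- function(design, params, n, ds_seed, q, variant,
                             methods, metrics, pop_a, pop_b, tree, depth,
                             gunifrac_alpha) {
  if (design == "single") {
    dat <- simulate_smm(params, n, seed = ds_seed)
    dx <- dist_euclidean(dat$x); dm <- dist_euclidean(dat$m)
    dy <- dist_euclidean(dat$y)
    vapply(methods, function(meth) {
      if (meth == "modima") {
        modima_test(dx, dm, dy, q = q, seed = ds_seed, variant = variant)$p_value
      } else {
        smm_test(dat$x, dat$m, dat$y, q = q, seed = ds_seed)$p_value
      }
    }, numeric(1))
  } else {
    dat <- simulate_multimediator(params, pop_a, pop_b, n, depth = depth,
                                  seed = ds_seed)
    ids <- rownames(dat$counts)
    dx <- dist_euclidean(dat$x, ids = ids)
    dy <- dist_euclidean(dat$y, ids = ids)
    unlist(lapply(metrics, function(metric) {
      dm <- mediator_distance(dat$counts, metric, tree, gunifrac_alpha)
      modima_test(dx, dm, dy, q = q, seed = ds_seed, variant = variant)$p_value
    }))
  }
}

#' Compute a mediator distance matrix by metric name
#'
#' Dispatch helper mapping the metric names used by [run_grid()] and the
#' command-line interface onto the dissimilarity functions.
#'
#' @param counts Samples-by-taxa count matrix.
#' @param metric One of `"euclidean"`, `"bray"`, `"jsd"`, `"jaccard"`,
#'   `"unifrac-unweighted"`, `"unifrac-weighted"`, `"unifrac-generalized"`.
#' @param tree Rooted `phylo`, required for the UniFrac metrics.
#' @param gunifrac_alpha Generalized-UniFrac exponent.
#' @return A `dist_matrix`.
#' @export
mediator_distance <- function(counts, metric, tree = NULL,
                              gunifrac_alpha = 0.5) {
  switch(
    metric,
    "euclidean" = dist_euclidean(as.matrix(counts)),
    "bray" = dist_bray_curtis(counts),
    "jsd" = dist_jsd(counts),
    "jaccard" = dist_jaccard(counts),
    "unifrac-unweighted" = dist_unifrac(counts, need_tree(tree), "unweighted"),
    "unifrac-weighted" = dist_unifrac(counts, need_tree(tree), "weighted"),
    "unifrac-generalized" = dist_unifrac(counts, need_tree(tree), "generalized",
                                         alpha = gunifrac_alpha),
    stop("unknown metric '", metric, "'; valid metrics: euclidean, bray, ",
         "jsd, jaccard, unifrac-unweighted, unifrac-weighted, ",
         "unifrac-generalized", call. = FALSE)
  )
}

need_tree <- function(tree) {
  if (is.null(tree)) stop("UniFrac metrics require a rooted tree", call. = FALSE)
  tree
}

#' Plot rejection-rate curves from a simulation grid
#'
#' Rejection fraction against sample size, one colour per method/metric,
#' faceted by the exposure-to-mediator (`alpha`) and mediator-to-response
#' (`beta`) paths, with the direct path `gamma` mapped to line type. The
#' nominal threshold is drawn as a horizontal reference.
#'
#' @param object A `modima_grid` tibble from [run_grid()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot modima_grid
#' @export
autoplot.modima_grid <- function(object, ...) {
  object$series <- paste(object$method, object$metric, sep = " / ")
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$n, y = .data$rejection_fraction,
    colour = .data$series, linetype = factor(.data$gamma)
  )) +
    ggplot2::geom_hline(yintercept = unique(object$threshold),
                        colour = "grey40", linewidth = 0.3) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.4) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$beta),
                        cols = ggplot2::vars(.data$alpha),
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "sample size", y = "rejection fraction",
                  colour = "test", linetype = "gamma") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
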