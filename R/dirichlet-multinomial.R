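#' Dirichlet-multinomial parameters
#'
#' Overdispersed taxon counts are modeled by the Dirichlet-multinomial
#' compound distribution, parameterized by the mean taxon proportions `pi`
#' and a single overdispersion parameter `theta` in `[0, 1)`. Internally the
#' Dirichlet concentration is `pi * (1 - theta) / theta`, so `theta -> 0`
#' recovers the plain multinomial and larger `theta` spreads the per-sample
#' compositions further from `pi`.
#'
#' @param pi Nonnegative vector of mean proportions, summing to 1 (within
#'   1e-9).
#' @param theta Overdispersion in `[0, 1)`.
#' @param taxon_ids Optional taxon names; defaults to `names(pi)` or
#'   `t1..tp`.
#' @return An object of class `dm_params`.
#' @export
dm_params <- function(pi, theta, taxon_ids = NULL) {
  pi <- as.numeric(pi)
  if (any(pi < 0)) stop("`pi` must be nonnegative", call. = FALSE)
  if (abs(sum(pi) - 1) > 1e-9) {
    stop("`pi` must sum to 1 (got ", format(sum(pi)), ")", call. = FALSE)
  }
  if (!is.numeric(theta) || length(theta) != 1L || theta < 0 || theta >= 1) {
    stop("`theta` must be a single value in [0, 1)", call. = FALSE)
  }
  if (is.null(taxon_ids)) taxon_ids <- names(pi)
  if (is.null(taxon_ids)) taxon_ids <- paste0("t", seq_along(pi))
  names(pi) <- taxon_ids
  structure(list(pi = pi, theta = theta), class = "dm_params")
}

#' @export
print.dm_params <- function(x, ...) {
  cat(sprintf("<dm_params: %d taxa, theta = %.4g>\n", length(x$pi), x$theta))
  invisible(x)
}

#' Draw Dirichlet-multinomial count samples
#'
#' For each sample, proportions are drawn from
#' `Dirichlet(pi * (1 - theta) / theta)` and counts from a multinomial of
#' size `depth` on those proportions. With `theta = 0` the draw is a plain
#' multinomial at `pi`.
#'
#' @param params A [dm_params()] object.
#' @param n Number of samples.
#' @param depth Sequencing depth (total count per sample, >= 1).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param sample_ids Optional sample names.
#' @return A samples-by-taxa integer count matrix with every row summing to
#'   `depth`.
#' @export
sample_dm <- function(params, n, depth, seed = NULL, sample_ids = NULL) {
  stopifnot(inherits(params, "dm_params"))
  n <- as.integer(n); depth <- as.integer(depth)
  if (is.na(n) || n < 1L) stop("`n` must be >= 1", call. = FALSE)
  if (is.na(depth) || depth < 1L) stop("`depth` must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  p <- length(params$pi)
  props <- rdirichlet_rows(n, matrix(params$pi, n, p, byrow = TRUE),
                           rep(params$theta, n))
  counts <- t(vapply(seq_len(n),
                     function(i) stats::rmultinom(1, depth, props[i, ])[, 1],
                     integer(p)))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(n))
  dimnames(counts) <- list(sample_ids, names(params$pi))
  counts
}

# One Dirichlet draw per row, with row-specific mean vector and theta.
rdirichlet_rows <- function(n, pi_rows, theta) {
  p <- ncol(pi_rows)
  out <- matrix(0, n, p)
  for (i in seq_len(n)) {
    if (theta[i] == 0) {
      out[i, ] <- pi_rows[i, ]
    } else {
      shape <- pi_rows[i, ] * (1 - theta[i]) / theta[i]
      g <- ifelse(shape > 0, stats::rgamma(p, shape = shape), 0)
      if (sum(g) == 0) {
        # pathological draw (all-zero gammas); fall back to the mean
        out[i, ] <- pi_rows[i, ]
      } else {
        out[i, ] <- g / sum(g)
      }
    }
  }
  out
}

#' Method-of-moments fit of Dirichlet-multinomial parameters
#'
#' Estimates `pi` from the pooled proportions and `theta` from the excess of
#' the between-sample variance of the per-sample proportions over the
#' multinomial expectation. Writing `N_i` for the depths,
#' `v_j` for the across-sample variance of taxon `j`'s proportion and
#' `pi_j (1 - pi_j)` for the binomial variance factor, the estimator solves
#' `sum_j v_j = sum_j pi_j (1 - pi_j) (a + (1 - a) theta)` with
#' `a = mean(1 / N_i)`, and clamps the result to `[0, 1)`.
#'
#' @param counts Samples-by-taxa count matrix with at least 2 samples and 2
#'   taxa, positive depths.
#' @return A [dm_params()] object.
#' @export
#'
#' @examples
#' p0 <- dm_params(rep(0.25, 4), theta = 0.1)
#' counts <- sample_dm(p0, n = 100, depth = 2000, seed = 1)
#' fit_dm(counts)
fit_dm <- function(counts) {
  counts <- check_abundance(counts, "Dirichlet-multinomial fit")
  if (nrow(counts) < 2L) {
    stop("need >= 2 samples to estimate overdispersion", call. = FALSE)
  }
  if (ncol(counts) < 2L) stop("need >= 2 taxa", call. = FALSE)
  depths <- rowSums(counts)
  pi_hat <- colSums(counts) / sum(counts)
  props <- counts / depths
  v <- apply(props, 2L, stats::var)
  binom <- pi_hat * (1 - pi_hat)
  a <- mean(1 / depths)
  denom <- sum(binom) * (1 - a)
  theta_hat <- if (denom <= 0) 0 else (sum(v) - a * sum(binom)) / denom
  theta_hat <- min(max(theta_hat, 0), 1 - 1e-8)
  dm_params(pi_hat / sum(pi_hat), theta_hat, taxon_ids = colnames(counts))
}

#' Read and write Dirichlet-multinomial parameter files
#'
#' Plain-text format: a comment line `# theta <value>` followed by a
#' tab-delimited table with columns `taxon` and `pi`.
#'
#' @param path File path.
#' @return `read_dm_params()` returns a [dm_params()] object.
#' @export
read_dm_params <- function(path) {
  lines <- readLines(path)
  theta_line <- grep("^#\\s*theta\\b", lines, value = TRUE)
  if (length(theta_line) != 1L) {
    stop("expected exactly one '# theta <value>' line in ", path, call. = FALSE)
  }
  theta <- as.numeric(sub("^#\\s*theta\\s+", "", theta_line))
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  dm_params(df$pi / sum(df$pi), theta, taxon_ids = df$taxon)
}

#' @rdname read_dm_params
#' @param params A [dm_params()] object.
#' @export
write_dm_params <- function(params, path) {
  stopifnot(inherits(params, "dm_params"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# theta %.12g", params$theta), con)
  utils::write.table(
    data.frame(taxon = names(params$pi), pi = unname(params$pi)),
    con, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Bundled synthetic oral-community parameter sets
#'
#' Two synthetic 21-taxon Dirichlet-multinomial parameter sets emulating a
#' pair of related oral body-site communities (saliva-like and tonsil-like):
#' overlapping taxa with shifted rank abundances and mild overdispersion of
#' the magnitude typical for 16S surveys. They are generated synthetically
#' and bundled as plain text; they are stand-ins, not estimates from any
#' real survey, and exist so the mixture simulation has a self-contained
#' default.
#'
#' @param which `"saliva"` or `"tonsils"`.
#' @return A [dm_params()] object with 21 taxa.
#' @export
synthetic_oral_params <- function(which = c("saliva", "tonsils")) {
  which <- match.arg(which)
  path <- system.file("extdata",
                      sprintf("dm_params_synthetic_%s.tsv", which),
                      package = "modima", mustWork = TRUE)
  read_dm_params(path)
}
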