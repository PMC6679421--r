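#' Pairwise Euclidean distance matrix
#'
#' @param x Numeric matrix, samples in rows (a single vector is treated as a
#'   one-column matrix).
#' @param ids Optional sample ids; defaults to rownames.
#' @return A `dist_matrix`.
#' @export
dist_euclidean <- function(x, ids = NULL) {
  if (is.vector(x) && is.numeric(x)) x <- matrix(x, ncol = 1)
  if (!is.numeric(x)) stop("`x` must be numeric", call. = FALSE)
  if (anyNA(x) || any(!is.finite(x))) {
    stop("non-finite entries in `x`", call. = FALSE)
  }
  m <- as.matrix(stats::dist(x, method = "euclidean"))
  if (is.null(ids)) ids <- rownames(x)  # NULL unless the input was labeled
  dimnames(m) <- NULL
  dist_matrix(m, ids = ids, tol = 1e-8)
}

check_abundance <- function(counts, metric, allow_zero_samples = FALSE) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) stop("abundance table must be numeric", call. = FALSE)
  if (anyNA(counts) || any(!is.finite(counts))) {
    stop("non-finite abundance values", call. = FALSE)
  }
  if (any(counts < 0)) stop("negative abundances", call. = FALSE)
  zero <- rowSums(counts) == 0
  if (!allow_zero_samples && any(zero)) {
    stop(metric, " is undefined for all-zero samples: ",
         paste(rownames(counts)[zero], collapse = ", "), call. = FALSE)
  }
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("s", seq_len(nrow(counts)))
  }
  counts
}

#' Beta-diversity dissimilarity matrices for abundance tables
#'
#' All functions take a samples-by-taxa matrix of nonnegative counts (or
#' relative abundances) and return a `dist_matrix`.
#'
#' `dist_bray_curtis()` is the quantitative Bray-Curtis dissimilarity
#' `sum |u_k - v_k| / sum (u_k + v_k)`.
#'
#' `dist_jaccard()` is the presence/absence Jaccard dissimilarity
#' `1 - |A intersect B| / |A union B|` on the supports (taxa with positive
#' count); abundances beyond presence are ignored.
#'
#' `dist_jsd()` is the Jensen-Shannon divergence between the samples'
#' proportion vectors, natural-log base, with the `0 log 0 = 0` convention;
#' it is bounded by `log(2)`. Each sample is normalized to proportions
#' internally, so the result is invariant to per-sample scaling. Set
#' `sqrt = TRUE` for the square-root form, which is a metric.
#'
#' @param counts Samples-by-taxa nonnegative numeric matrix with sample ids
#'   as rownames.
#' @param sqrt Return the square root of the divergence (a true metric)
#'   instead of the divergence itself.
#' @return A `dist_matrix` with entries in `[0, 1]` (Bray-Curtis, Jaccard)
#'   or `[0, log 2]` (JSD).
#' @export
dist_bray_curtis <- function(counts) {
  counts <- check_abundance(counts, "Bray-Curtis")
  as_dist_matrix(vegan::vegdist(counts, method = "bray"))
}

#' @rdname dist_bray_curtis
#' @export
dist_jaccard <- function(counts) {
  counts <- check_abundance(counts, "Jaccard", allow_zero_samples = TRUE)
  if (sum(rowSums(counts) == 0) >= 2L) {
    stop("Jaccard is undefined between two empty samples", call. = FALSE)
  }
  as_dist_matrix(as.matrix(vegan::vegdist(counts, method = "jaccard",
                                          binary = TRUE)))
}

#' @rdname dist_bray_curtis
#' @export
dist_jsd <- function(counts, sqrt = FALSE) {
  counts <- check_abundance(counts, "Jensen-Shannon divergence")
  p <- counts / rowSums(counts)
  n <- nrow(p)
  # entropy term sum p log p with 0 log 0 = 0
  plogp <- function(m) {
    out <- m * log(m)
    out[m == 0] <- 0
    out
  }
  h <- rowSums(plogp(p))  # negative entropy per sample
  d <- matrix(0, n, n, dimnames = list(rownames(p), rownames(p)))
  for (i in seq_len(n - 1)) {
    pi_ <- p[i, ]
    for (j in (i + 1):n) {
      m <- (pi_ + p[j, ]) / 2
      jsd <- (h[i] + h[j]) / 2 - sum(plogp(m))
      d[i, j] <- d[j, i] <- max(jsd, 0)
    }
  }
  if (sqrt) d <- base::sqrt(d)
  dist_matrix(d, tol = 1e-8)
}

#' UniFrac dissimilarities over a rooted tree
#'
#' Computes unweighted, weighted (normalized or raw) or generalized UniFrac
#' between all pairs of samples. Every taxon with a positive count must be a
#' tip of `tree`; tips absent from the table are treated as zero-abundance.
#' Writing `A_e`, `B_e` for the summed proportions of the tips descending
#' from branch `e` in the two samples, and `b_e` for the branch length:
#'
#' * unweighted: `sum b_e |1(A_e>0) - 1(B_e>0)| / sum b_e 1(A_e>0 or B_e>0)`
#' * weighted (normalized): `sum b_e |A_e - B_e| / sum b_e (A_e + B_e)`
#' * weighted (raw, `normalized = FALSE`): `sum b_e |A_e - B_e|`
#' * generalized: `sum b_e (A_e+B_e)^alpha |A_e-B_e|/(A_e+B_e) /
#'     sum b_e (A_e+B_e)^alpha`, with branches where `A_e + B_e = 0`
#'     contributing nothing.
#'
#' Generalized UniFrac at `alpha = 1` coincides with the normalized weighted
#' form; `alpha = 0.5` (the default) tempers the weight of highly abundant
#' lineages.
#'
#' @param counts Samples-by-taxa matrix of nonnegative counts; column names
#'   are matched against tip labels.
#' @param tree A rooted `phylo` tree with branch lengths.
#' @param variant One of `"unweighted"`, `"weighted"`, `"generalized"`.
#' @param alpha Abundance exponent for the generalized variant.
#' @param normalized For the weighted variant, divide by the total
#'   abundance-weighted branch length so values lie in `[0, 1]`.
#' @return A `dist_matrix`.
#' @export
dist_unifrac <- function(counts, tree,
                         variant = c("unweighted", "weighted", "generalized"),
                         alpha = 0.5, normalized = TRUE) {
  variant <- match.arg(variant)
  counts <- check_abundance(counts, "UniFrac")
  if (!inherits(tree, "phylo")) stop("`tree` must be a phylo object", call. = FALSE)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  if (any(tree$edge.length < 0)) stop("negative branch lengths", call. = FALSE)
  if (all(tree$edge.length == 0)) {
    stop("all branch lengths are zero: UniFrac degenerate", call. = FALSE)
  }
  present <- colnames(counts)[colSums(counts) > 0]
  missing <- setdiff(present, tree$tip.label)
  if (length(missing) > 0) {
    stop("taxa with positive counts absent from the tree: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }

  n <- nrow(counts)
  ntip <- length(tree$tip.label)
  prop <- counts / rowSums(counts)
  # proportions aligned to tip order; tips absent from the table get 0
  q <- matrix(0, n, ntip, dimnames = list(rownames(counts), tree$tip.label))
  shared <- intersect(colnames(counts), tree$tip.label)
  q[, shared] <- prop[, shared, drop = FALSE]

  # accumulate per-node descendant-tip proportion mass in postorder
  edge <- tree$edge
  nnode <- ntip + tree$Nnode
  acc <- matrix(0, n, nnode)
  acc[, seq_len(ntip)] <- q
  for (k in ape::postorder(tree)) {
    acc[, edge[k, 1]] <- acc[, edge[k, 1]] + acc[, edge[k, 2]]
  }
  em <- acc[, edge[, 2], drop = FALSE]  # samples x edges: mass under each branch
  b <- tree$edge.length

  d <- matrix(0, n, n, dimnames = list(rownames(counts), rownames(counts)))
  for (i in seq_len(n - 1)) {
    ai <- em[i, ]
    for (j in (i + 1):n) {
      bj <- em[j, ]
      d[i, j] <- d[j, i] <- switch(
        variant,
        unweighted = {
          pa <- ai > 0; pb <- bj > 0
          den <- sum(b[pa | pb])
          if (den == 0) 0 else sum(b[xor(pa, pb)]) / den
        },
        weighted = {
          num <- sum(b * abs(ai - bj))
          if (!normalized) num
          else {
            den <- sum(b * (ai + bj))
            if (den == 0) 0 else num / den
          }
        },
        generalized = {
          s <- ai + bj
          keep <- s > 0
          w <- b[keep] * s[keep]^alpha
          den <- sum(w)
          if (den == 0) 0 else sum(w * abs(ai - bj)[keep] / s[keep]) / den
        }
      )
    }
  }
  dist_matrix(d, tol = 1e-8)
}

#' Parse and write Newick trees
#'
#' Thin wrappers around [ape::read.tree()] / [ape::write.tree()] adding the
#' validation this package relies on: the tree must parse, be rooted, carry
#' branch lengths, and have unique tip labels.
#'
#' @param text Newick string (use `path` for a file).
#' @param path File path.
#' @return A `phylo` object; `write_newick()` returns its `path` invisibly.
#' @export
parse_newick <- function(text = NULL, path = NULL) {
  if (is.null(text) == is.null(path)) {
    stop("supply exactly one of `text` or `path`", call. = FALSE)
  }
  tr <- tryCatch(
    if (is.null(path)) ape::read.tree(text = text) else ape::read.tree(path),
    error = function(e) NULL
  )
  if (is.null(tr) || !inherits(tr, "phylo")) {
    stop("failed to parse Newick input (check parentheses and terminating ';')",
         call. = FALSE)
  }
  dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
  if (length(dup) > 0) {
    stop("duplicate tip labels: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (!ape::is.rooted(tr)) stop("tree must be rooted", call. = FALSE)
  tr
}

#' @rdname parse_newick
#' @param tree A `phylo` object.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
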