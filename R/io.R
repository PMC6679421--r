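#' Read a tab-delimited abundance or data table
#'
#' Expects a header row of feature/taxon ids and a first column of sample
#' ids. Set `transpose = TRUE` for files with taxa in rows and samples in
#' columns.
#'
#' @param path File path.
#' @param transpose Transpose after reading (taxa-in-rows files).
#' @return A numeric matrix, samples in rows, with ids as dimnames.
#' @export
read_abundance_table <- function(path, transpose = FALSE) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t", row.names = NULL,
                           check.names = FALSE, comment.char = "",
                           stringsAsFactors = FALSE)
  ids <- as.character(raw[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    lines <- which(ids %in% dup) + 1L  # +1 for the header line
    stop("duplicate sample ids in ", path, ": ",
         paste(dup, collapse = ", "),
         " (lines ", paste(lines, collapse = ", "), ")", call. = FALSE)
  }
  body <- raw[, -1, drop = FALSE]
  bad <- which(!vapply(body, is.numeric, logical(1)))
  if (length(bad) > 0) {
    stop("non-numeric column(s) in ", path, ": ",
         paste(names(body)[bad], collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(body)
  rownames(m) <- ids
  if (transpose) m <- t(m)
  m
}

#' @rdname read_abundance_table
#' @param x Numeric matrix with sample ids as rownames.
#' @export
write_abundance_table <- function(x, path) {
  df <- data.frame(id = rownames(x), x, check.names = FALSE)
  names(df)[1] <- ""
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align a collection of tables and distance matrices on shared samples
#'
#' Reorders every input to the sorted intersection of their sample ids, so
#' downstream results do not depend on input file ordering. Samples missing
#' from any input are dropped with a message.
#'
#' @param ... Named inputs: samples-by-feature matrices (ids in rownames)
#'   and/or `dist_matrix` objects.
#' @return A named list of the inputs, all restricted and reordered to the
#'   common id set.
#' @export
#'
#' @examples
#' a <- matrix(1:6, 3, dimnames = list(c("s1", "s2", "s3"), NULL))
#' b <- dist_euclidean(matrix(rnorm(4), 2), ids = c("s3", "s1"))
#' lapply(align_samples(a = a, b = b), sample_ids)
align_samples <- function(...) {
  inputs <- list(...)
  if (length(inputs) < 1L) stop("nothing to align", call. = FALSE)
  ids <- lapply(inputs, sample_ids)
  if (any(vapply(ids, is.null, logical(1)))) {
    stop("every input needs sample ids (rownames)", call. = FALSE)
  }
  common <- sort(Reduce(intersect, ids))
  if (length(common) == 0L) {
    stop("no samples shared across inputs", call. = FALSE)
  }
  dropped <- unique(unlist(lapply(ids, setdiff, common)))
  if (length(dropped) > 0) {
    message("dropping ", length(dropped), " sample(s) absent from some input: ",
            paste(dropped, collapse = ", "))
  }
  lapply(inputs, function(x) {
    if (is_dist_matrix(x)) {
      dist_matrix(unclass(x)[common, common, drop = FALSE], ids = common)
    } else {
      x[common, , drop = FALSE]
    }
  })
}
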