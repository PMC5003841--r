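# PCA ordination of arrays for the global time-course view.

#' PCA projection of arrays
#'
#' Genes are centered to zero mean across arrays (no unit-variance scaling,
#' the standard treatment of log-expression data); components come from the
#' singular value decomposition and each array (replicate) is projected.
#' Component signs follow a deterministic convention: the largest-magnitude
#' gene loading of each component is positive.
#'
#' @param matrix expression matrix (genes x arrays, log2).
#' @param n_components number of components to return, at most
#'   `min(genes, arrays)`.
#' @return list of class `ordination_result` with `coordinates` (arrays x
#'   components matrix, rownames = array names), `explained_variance`
#'   (fraction per returned component, non-increasing), `rotation` (gene
#'   loadings) and `center` (gene means).
#' @export
pca_project <- function(matrix, n_components = 2L) {
  if (any(!is.finite(matrix))) stop("expression matrix must be complete")
  k_max <- min(nrow(matrix), ncol(matrix))
  if (n_components < 1L || n_components > k_max) {
    stop("n_components must be between 1 and ", k_max)
  }
  pc <- stats::prcomp(t(matrix), center = TRUE, scale. = FALSE)
  keep <- seq_len(n_components)
  rot <- pc$rotation[, keep, drop = FALSE]
  scores <- pc$x[, keep, drop = FALSE]
  # sign convention: largest-|loading| gene positive per component
  for (j in keep) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ev <- (pc$sdev^2 / sum(pc$sdev^2))[keep]
  structure(list(coordinates = scores, explained_variance = ev,
                 rotation = rot, center = pc$center),
            class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  cat("ordination_result:", nrow(x$coordinates), "arrays x",
      ncol(x$coordinates), "components\n")
  cat("explained variance:",
      paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = " "),
      "\n")
  invisible(x)
}

#' Joint PCA of two datasets over their shared genes
#'
#' Restricts both matrices to shared gene ids, concatenates arrays and
#' centers jointly, so a study can be ordinated together with a reference
#' dataset.
#'
#' @param matrix,reference expression matrices sharing gene ids.
#' @param n_components number of components.
#' @return `ordination_result` over the combined arrays.
#' @export
pca_project_joint <- function(matrix, reference, n_components = 2L) {
  shared <- intersect(rownames(matrix), rownames(reference))
  if (length(shared) < 2L) stop("fewer than 2 shared gene ids")
  combined <- cbind(matrix[shared, , drop = FALSE],
                    reference[shared, , drop = FALSE])
  if (anyDuplicated(colnames(combined))) {
    stop("array names collide between the two datasets")
  }
  pca_project(combined, n_components = n_components)
}
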