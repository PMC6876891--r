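# Basic QC and linear dimension reduction. All downstream kernels and
# densities operate in the PCA embedding produced here; a linear, orthogonal
# reduction is deliberate - it keeps the whole pipeline invariant under
# rotations of the input coordinates.

#' Filter low-coverage genes and cells
#'
#' Removes genes expressed (non-zero) in fewer than `min_cells_per_gene`
#' cells, then cells expressing fewer than `min_genes_per_cell` of the
#' remaining genes. Thresholds of zero leave the matrix untouched.
#'
#' @param x expression matrix (cells x genes) or data frame with a leading
#'   cell-id column.
#' @param min_cells_per_gene,min_genes_per_cell non-negative thresholds.
#' @return filtered expression matrix.
#' @export
qc_filter <- function(x, min_cells_per_gene = 0, min_genes_per_cell = 0) {
  stopifnot(min_cells_per_gene >= 0, min_genes_per_cell >= 0)
  x <- as_expression_matrix(x)
  keep_genes <- colSums(x != 0) >= min_cells_per_gene
  if (!any(keep_genes)) stop("qc_filter removed every gene")
  x <- x[, keep_genes, drop = FALSE]
  keep_cells <- rowSums(x != 0) >= min_genes_per_cell
  if (!any(keep_cells)) stop("qc_filter removed every cell")
  removed <- c(genes = sum(!keep_genes), cells = sum(!keep_cells))
  if (any(removed > 0)) {
    message(sprintf("qc_filter: removed %d gene(s) and %d cell(s)",
                    removed["genes"], removed["cells"]))
  }
  x[keep_cells, , drop = FALSE]
}

#' Reduce an expression matrix to a low-dimensional embedding
#'
#' Centred principal component analysis: an orthogonal linear projection onto
#' the top `m` variance directions. Component signs follow the convention
#' that each component's largest-magnitude loading is positive, making the
#' result deterministic.
#'
#' @param x expression matrix (cells x genes), data frame, or `ldd_dataset`.
#' @param m number of components to keep (default 2).
#' @param log1p apply `log(1 + x)` before centring.
#' @param seed unused (PCA is deterministic); kept so the preprocessing call
#'   signature matches the stochastic stages of the pipeline.
#' @return An `ldd_embedding`: list with `coords` (cells x m), nonincreasing
#'   `component_variances`, and `cell_ids`.
#' @export
reduce_dimensions <- function(x, m = 2, log1p = FALSE, seed = NULL) {
  x <- as_expression_matrix(x)
  if (m < 2) stop("the embedding needs at least m = 2 dimensions")
  if (m > min(dim(x))) stop("m must not exceed min(n_cells, n_genes)")
  if (log1p) {
    if (any(x < 0)) stop("log1p requested but the matrix has negative values")
    x <- log1p(x)
  }
  if (all(abs(sweep(x, 2, colMeans(x))) < .Machine$double.eps * 100)) {
    stop("zero-variance matrix: PCA is undefined")
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  if (ncol(pc$x) < m) stop("matrix rank too low for m = ", m, " components")
  flip <- vapply(seq_len(m), function(j) {
    v <- pc$rotation[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  coords <- sweep(pc$x[, seq_len(m), drop = FALSE], 2, flip, `*`)
  colnames(coords) <- paste0("PC", seq_len(m))
  structure(list(coords = coords,
                 component_variances = pc$sdev[seq_len(m)]^2,
                 cell_ids = rownames(x)),
            class = "ldd_embedding")
}

#' @export
print.ldd_embedding <- function(x, ...) {
  cat(sprintf("<ldd_embedding> %d cells x %d components; variances: %s\n",
              nrow(x$coords), ncol(x$coords),
              paste(signif(x$component_variances, 3), collapse = ", ")))
  invisible(x)
}

#' Coerce to a cells x genes numeric matrix
#'
#' Accepts a numeric matrix (row names as cell ids), a data frame whose first
#' character column holds cell ids, or an `ldd_dataset`.
#'
#' @param x object to coerce.
#' @return numeric matrix with cell ids as row names.
#' @export
as_expression_matrix <- function(x) {
  if (inherits(x, "ldd_dataset")) x <- x$expression
  if (is.data.frame(x)) {
    id_col <- which(vapply(x, is.character, logical(1)))[1]
    if (!is.na(id_col)) {
      ids <- x[[id_col]]
      x <- as.matrix(x[, -id_col, drop = FALSE])
      rownames(x) <- ids
    } else {
      x <- as.matrix(x)
    }
  }
  stopifnot(is.matrix(x), is.numeric(x))
  if (is.null(rownames(x))) rownames(x) <- sprintf("cell_%04d", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- sprintf("var_%03d", seq_len(ncol(x)))
  .validate_expression(x, rownames(x), colnames(x))
}

.embedding_coords <- function(x) {
  if (inherits(x, "ldd_embedding")) return(x$coords)
  if (is.matrix(x)) return(x)
  stop("expected an ldd_embedding or a coordinate matrix")
}
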