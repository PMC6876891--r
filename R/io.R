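# Reading and writing expression matrices (CSV/TSV with a header row, or
# MatrixMarket triplets with *_cells.txt / *_genes.txt name sidecars) and the
# labelled benchmark datasets.

.validate_expression <- function(values, cell_ids, gene_ids) {
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)
    bad <- utils::head(bad, 5)
    stop("non-finite expression values, e.g. at ",
         paste(sprintf("(cell %s, gene %s)", cell_ids[bad[, 1]],
                       gene_ids[bad[, 2]]), collapse = ", "))
  }
  if (anyDuplicated(cell_ids)) stop("duplicate cell ids: ",
                                    paste(unique(cell_ids[duplicated(cell_ids)]),
                                          collapse = ", "))
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids: ",
                                    paste(unique(gene_ids[duplicated(gene_ids)]),
                                          collapse = ", "))
  if (nrow(values) < 2) stop("an expression matrix needs at least 2 cells")
  dimnames(values) <- list(cell_ids, gene_ids)
  values
}

#' Load an expression matrix
#'
#' Reads a cells x genes matrix from delimited text (`csv`/`tsv`, first
#' column holding cell ids, header row holding gene ids) or MatrixMarket
#' (`mtx`, with `<base>_cells.txt` and `<base>_genes.txt` sidecar files, one
#' id per line). Values must be finite and ids unique.
#'
#' @param path file path; the format is inferred from the extension unless
#'   `format` is given.
#' @param format one of `"csv"`, `"tsv"`, `"mtx"`.
#' @param transpose set to `TRUE` for files stored genes x cells.
#' @return numeric matrix (cells x genes) with cell/gene ids as dimnames.
#' @export
load_expression <- function(path, format = NULL, transpose = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) {
    format <- tolower(tools::file_ext(path))
    if (format == "txt") format <- "tsv"
  }
  format <- match.arg(format, c("csv", "tsv", "mtx"))
  if (format %in% c("csv", "tsv")) {
    reader <- if (format == "csv") readr::read_csv else readr::read_tsv
    df <- reader(path, show_col_types = FALSE, progress = FALSE)
    ids <- as.character(df[[1]])
    values <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(values) <- "double"
    rownames(values) <- ids
  } else {
    values <- as.matrix(Matrix::readMM(path))
    base <- sub("\\.mtx$", "", path)
    cells_file <- paste0(base, "_cells.txt")
    genes_file <- paste0(base, "_genes.txt")
    if (!file.exists(cells_file) || !file.exists(genes_file)) {
      stop("mtx sidecar files not found: ", cells_file, " / ", genes_file)
    }
    rownames(values) <- readLines(cells_file)
    colnames(values) <- readLines(genes_file)
  }
  if (transpose) values <- t(values)
  .validate_expression(values, rownames(values), colnames(values))
}

#' Write a labelled benchmark dataset to disk
#'
#' Writes the expression matrix plus a sidecar cell table (`cell_id`,
#' `true_time`, `lineage`, `stage`) so the dataset round-trips through
#' [load_expression()].
#'
#' @param dataset an `ldd_dataset` from one of the simulators.
#' @param dir output directory (created if missing).
#' @param format `"csv"` or `"mtx"`.
#' @param prefix file name prefix.
#' @return (invisibly) the paths written.
#' @export
write_dataset <- function(dataset, dir, format = c("csv", "mtx"),
                          prefix = "dataset") {
  format <- match.arg(format)
  stopifnot(inherits(dataset, "ldd_dataset"))
  if (nrow(dataset$expression) == 0) stop("refusing to write an empty dataset (0 cells)")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  expr <- dataset$expression
  paths <- character(0)
  if (format == "csv") {
    f <- file.path(dir, paste0(prefix, "_expression.csv"))
    readr::write_csv(dplyr::bind_cols(tibble::tibble(cell_id = rownames(expr)),
                                      tibble::as_tibble(expr)), f)
    paths <- f
  } else {
    f <- file.path(dir, paste0(prefix, "_expression.mtx"))
    Matrix::writeMM(Matrix::Matrix(expr, sparse = TRUE), f)
    writeLines(rownames(expr), file.path(dir, paste0(prefix, "_expression_cells.txt")))
    writeLines(colnames(expr), file.path(dir, paste0(prefix, "_expression_genes.txt")))
    paths <- c(f, file.path(dir, paste0(prefix, "_expression_cells.txt")),
               file.path(dir, paste0(prefix, "_expression_genes.txt")))
  }
  labels_path <- file.path(dir, paste0(prefix, "_cells.tsv"))
  readr::write_tsv(dataset$cells, labels_path)
  invisible(c(paths, labels_path))
}
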