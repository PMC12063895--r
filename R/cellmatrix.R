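#' Single-cell count container
#'
#' Light container for raw counts (genes x cells sparse matrix), per-cell
#' metadata and, once \code{\link{normalize_expression}} has run, a
#' normalized log1p counts-per-10k view.
#'
#' @param counts genes x cells \code{dgCMatrix} (or coercible) of nonnegative
#'   integer counts.
#' @param cells data.frame with at least cell_id, cell_type, group; one row
#'   per column of \code{counts}.
#' @param norm optional normalized view with identical dimensions.
#' @return A \code{CellMatrix}.
#' @export
cell_matrix <- function(counts, cells, norm = NULL) {
  counts <- methods::as(counts, "CsparseMatrix")
  if (ncol(counts) != nrow(cells))
    stop("metadata rows must match count-matrix columns")
  need <- c("cell_id", "cell_type", "group")
  miss <- setdiff(need, names(cells))
  if (length(miss)) stop("cell metadata missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(counts@x < 0)) stop("counts must be nonnegative")
  structure(list(counts = counts, cells = cells, genes = rownames(counts),
                 norm = norm),
            class = "CellMatrix")
}

#' @export
print.CellMatrix <- function(x, ...) {
  cat(sprintf("CellMatrix: %d genes x %d cells (%d cell types; %s)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$cells$cell_type)),
              if (is.null(x$norm)) "raw counts" else "normalized view present"))
  invisible(x)
}

#' Number of cells in a CellMatrix
#' @param cm a \code{CellMatrix}.
#' @return integer count of cells.
#' @export
n_cell <- function(cm) {
  stopifnot(inherits(cm, "CellMatrix"))
  ncol(cm$counts)
}

subset_cells <- function(cm, keep) {
  cell_matrix(cm$counts[, keep, drop = FALSE],
              cm$cells[keep, , drop = FALSE],
              norm = if (is.null(cm$norm)) NULL else cm$norm[, keep, drop = FALSE])
}

subset_genes <- function(cm, keep) {
  cell_matrix(cm$counts[keep, , drop = FALSE], cm$cells,
              norm = if (is.null(cm$norm)) NULL else cm$norm[keep, , drop = FALSE])
}
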