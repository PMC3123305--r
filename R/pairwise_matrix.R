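#' Labelled symmetric pairwise matrix
#'
#' A thin wrapper around a symmetric numeric matrix carrying an orientation
#' flag (\code{"similarity"} matrices have a unit diagonal, \code{"dissimilarity"}
#' matrices a zero diagonal) and the name of the quantity it holds.  All
#' plot-by-plot and species-by-species outputs of the package use this class.
#'
#' @param values symmetric numeric matrix with row and column names.
#' @param orientation \code{"similarity"} or \code{"dissimilarity"}.
#' @param metric_name short name of the quantity stored (e.g. \code{"patristic"}).
#' @param tol symmetry tolerance.
#' @return the matrix with class \code{"pairwise_matrix"} and attributes
#'   \code{orientation} and \code{metric_name}.
#' @examples
#' m <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
#' pairwise_matrix(m, "dissimilarity", "toy")
#' @export
pairwise_matrix <- function(values, orientation = c("dissimilarity", "similarity"),
                            metric_name = "distance", tol = 1e-8) {
  orientation <- match.arg(orientation)
  if (!.is_square_numeric(values))
    stop("'values' must be a square numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must carry row and column labels")
  if (!identical(rownames(values), colnames(values)))
    stop("row and column labels differ")
  if (anyDuplicated(rownames(values)))
    stop("duplicate labels in pairwise matrix")
  if (any(!is.finite(values)))
    stop("non-finite values in pairwise matrix")
  if (max(abs(values - t(values))) > tol)
    stop("matrix is not symmetric")
  values <- (values + t(values)) / 2
  target <- if (orientation == "similarity") 1 else 0
  if (max(abs(diag(values) - target)) > tol)
    stop(sprintf("diagonal must be %g for a %s matrix", target, orientation))
  diag(values) <- target
  structure(values,
            class = c("pairwise_matrix", "matrix", "array"),
            orientation = orientation,
            metric_name = metric_name)
}

#' @export
print.pairwise_matrix <- function(x, ...) {
  cat(sprintf("pairwise_matrix: %s (%s), %d labels\n",
              attr(x, "metric_name"), attr(x, "orientation"), nrow(x)))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x))), drop = FALSE], ...)
  if (nrow(x) > 6L) cat(sprintf("... %d more rows/columns\n", nrow(x) - 6L))
  invisible(x)
}

# strip class/attrs, keep dimnames
.pm_values <- function(x) {
  y <- unclass(x)
  attr(y, "orientation") <- NULL
  attr(y, "metric_name") <- NULL
  y
}

#' Labels of a pairwise matrix
#' @param x a \code{pairwise_matrix}.
#' @return character vector of labels.
#' @export
pm_labels <- function(x) rownames(x)
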