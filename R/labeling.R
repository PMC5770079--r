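#' Default apoptosis marker genes
#'
#' The executioner caspases whose combined expression is used as the
#' cell-death readout.
#'
#' @return Character vector \code{c("CASP3", "CASP6", "CASP7")}.
#' @export
default_marker_genes <- function() c("CASP3", "CASP6", "CASP7")

#' Compute per-cell death probability from caspase markers
#'
#' For each cell the three marker expressions are summed and the sum divided
#' by the maximum combined value over all cells, giving a death probability
#' P in [0, 1] with the arg-max cell at exactly 1. A cell is classed
#' \code{"high"} (likely to die) when P >= 0.5, \code{"low"} otherwise; the
#' boundary value 0.5 is high, matching the intervals [0, 0.5) and [0.5, 1].
#'
#' The combined expression is taken on the scale of the supplied matrix; the
#' default analysis uses the raw (RPKM-like) scale, where the readout is the
#' literal sum of marker expression.
#'
#' @param m An \code{expr_matrix} containing the three marker genes.
#' @param marker_genes Character vector of exactly three marker gene ids
#'   (default \code{CASP3, CASP6, CASP7}).
#' @return An object of class \code{"fate_labels"}: a data.frame with columns
#'   \code{cell_id}, \code{p_death}, \code{fate_class} (factor, levels
#'   \code{low}/\code{high}), carrying the marker set as an attribute.
#' @examples
#' m <- expression_matrix(
#'   cbind(CASP3 = c(1, 2, 4), CASP6 = c(0.5, 1, 2), CASP7 = c(0.5, 1, 2)),
#'   c("CASP3", "CASP6", "CASP7"), c("c1", "c2", "c3"))
#' compute_death_probability(m)
#' @export
compute_death_probability <- function(m, marker_genes = default_marker_genes()) {
  if (length(marker_genes) != 3L)
    stop("exactly three marker genes are required")
  missing <- setdiff(marker_genes, gene_ids(m))
  if (length(missing))
    stop("marker gene(s) absent from matrix: ", paste(missing, collapse = ", "))
  combined <- rowSums(unclass(m)[, marker_genes, drop = FALSE])
  mx <- max(combined)
  if (mx <= 0)
    stop("degenerate labels: combined marker expression is zero in every cell")
  p <- combined / mx
  fate_labels(cell_ids(m), p, marker_genes = marker_genes)
}

#' Construct fate labels from death probabilities
#'
#' @param cell_ids Character vector of cell identifiers.
#' @param p_death Numeric vector in [0, 1], one per cell.
#' @param marker_genes Optional marker set recorded as an attribute.
#' @return A \code{"fate_labels"} data.frame.
#' @export
fate_labels <- function(cell_ids, p_death, marker_genes = NULL) {
  if (length(cell_ids) != length(p_death))
    stop("cell_ids and p_death lengths differ")
  if (any(p_death < 0 | p_death > 1))
    stop("p_death values must lie in [0, 1]")
  out <- data.frame(
    cell_id = as.character(cell_ids),
    p_death = as.numeric(p_death),
    fate_class = factor(ifelse(p_death >= 0.5, "high", "low"),
                        levels = c("low", "high")),
    stringsAsFactors = FALSE
  )
  structure(out, marker_genes = marker_genes,
            class = c("fate_labels", "data.frame"))
}

#' @export
print.fate_labels <- function(x, ...) {
  cat(sprintf("fate_labels: %d cells, %d high (p >= 0.5), %d low\n",
              nrow(x), sum(x$fate_class == "high"),
              sum(x$fate_class == "low")))
  print.data.frame(utils::head(x, 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Drop the marker genes from the predictor matrix
#'
#' The caspase markers define the response and must not appear among the
#' predictors; this removes their columns. Markers absent from the matrix
#' are skipped with a warning.
#'
#' @param m An \code{expr_matrix}.
#' @param marker_genes Gene ids to remove (default \code{CASP3, CASP6,
#'   CASP7}).
#' @return The matrix without the marker columns.
#' @export
exclude_marker_genes <- function(m, marker_genes = default_marker_genes()) {
  if (length(marker_genes) == 0L) return(m)
  absent <- setdiff(marker_genes, gene_ids(m))
  if (length(absent))
    warning("marker gene(s) not present, skipped: ",
            paste(absent, collapse = ", "))
  keep <- setdiff(gene_ids(m), marker_genes)
  m[, keep]
}
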