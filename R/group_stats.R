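#' Two-sample Student's t-test
#'
#' Classic pooled-variance two-sample t statistic with a two-sided p-value
#' on \code{n_a + n_b - 2} degrees of freedom (Student's test proper). An
#' unequal-variance (Welch) option is provided.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param var_equal Pool the variances (default \code{TRUE}).
#' @return List with \code{t}, \code{p_value}, \code{df}.
#' @export
two_sample_t_test <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 observations")
  if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b))
    return(list(t = 0, p_value = 1, df = length(a) + length(b) - 2L))
  tt <- stats::t.test(a, b, var.equal = var_equal)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter))
}

#' Extent of difference between two group means
#'
#' \code{1 - mean_a / mean_b}; with group a = healthy and group b = disease,
#' a positive extent means the disease group has the higher mean.
#'
#' @param mean_a,mean_b Group means; \code{mean_b} must be non-zero.
#' @return The extent, unbounded real.
#' @examples
#' extent_of_difference(1, 2)  # 0.5
#' @export
extent_of_difference <- function(mean_a, mean_b) {
  if (mean_b == 0) stop("undefined extent: reference mean is zero")
  1 - mean_a / mean_b
}

#' Compare marker expression between donor groups
#'
#' For each requested gene (and, optionally, the combined sum over all
#' requested genes) computes group means, the Student's t-test, a
#' significance flag at \code{alpha}, and the extent of difference
#' \code{1 - mean_a / mean_b}.
#'
#' @param m An \code{expr_matrix} with a per-cell donor-group attribute (or
#'   supply \code{groups}).
#' @param genes Gene ids to compare (default: the caspase markers).
#' @param groups Optional per-cell group labels overriding the matrix
#'   attribute.
#' @param group_a,group_b Labels of the two groups; \code{group_b} is the
#'   reference (disease) group of the extent statistic.
#' @param combined Also test the summed expression over \code{genes}
#'   (default \code{TRUE}).
#' @param alpha Significance level (default 0.05).
#' @param var_equal Pooled-variance t-test (default \code{TRUE}).
#' @return data.frame with one row per gene plus a \code{"combined"} row:
#'   \code{label}, \code{mean_a}, \code{mean_b}, \code{t_statistic},
#'   \code{p_value}, \code{significant}, \code{extent}.
#' @export
compare_groups <- function(m, genes = default_marker_genes(), groups = NULL,
                           group_a = NULL, group_b = NULL, combined = TRUE,
                           alpha = 0.05, var_equal = TRUE) {
  if (is.null(groups)) groups <- donor_groups(m)
  if (is.null(groups)) stop("no donor-group labels available")
  lev <- unique(groups)
  if (is.null(group_a)) group_a <- lev[1L]
  if (is.null(group_b)) group_b <- setdiff(lev, group_a)[1L]
  if (is.na(group_b)) stop("need two distinct groups")
  missing <- setdiff(genes, gene_ids(m))
  if (length(missing))
    stop("gene(s) absent from matrix: ", paste(missing, collapse = ", "))
  ia <- groups == group_a
  ib <- groups == group_b
  v <- unclass(m)[, genes, drop = FALSE]
  cols <- lapply(genes, function(g) v[, g])
  labels <- genes
  if (combined && length(genes) > 1L) {
    cols <- c(cols, list(rowSums(v)))
    labels <- c(labels, "combined")
  }
  rows <- lapply(seq_along(cols), function(i) {
    x <- cols[[i]]
    tt <- two_sample_t_test(x[ia], x[ib], var_equal = var_equal)
    ma <- mean(x[ia]); mb <- mean(x[ib])
    data.frame(label = labels[i], mean_a = ma, mean_b = mb,
               t_statistic = tt$t, p_value = tt$p_value,
               significant = tt$p_value < alpha,
               extent = if (mb != 0) 1 - ma / mb else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
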