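#' Specify a polynomial cell-fate model
#'
#' A polynomial of degree n in l gene expression values, optionally augmented
#' with pairwise product cross terms:
#' \deqn{P = b + \sum_{m=1}^{l}\sum_{p=1}^{n} k_{mp} x_m^p
#'         + \sum_{(i,j)} k'_{ij} x_i x_j}
#' The spec fully determines the design matrix: an intercept column, then for
#' each power p = 1..degree the genes in list order raised to p, then one
#' product column per cross pair, giving \code{1 + l*degree + M} parameters.
#'
#' @param genes Ordered gene ids (order = importance rank).
#' @param degree Polynomial degree, 1, 2 or 3.
#' @param cross_pairs List of length-2 character vectors; members must be in
#'   \code{genes}.
#' @return An object of class \code{"poly_spec"}.
#' @examples
#' poly_spec(c("TP53", "MDM2"), degree = 2,
#'           cross_pairs = list(c("TP53", "MDM2")))
#' @export
poly_spec <- function(genes, degree = 1L, cross_pairs = list()) {
  degree <- as.integer(degree)
  if (!degree %in% 1:3) stop("degree must be 1, 2 or 3")
  genes <- as.character(genes)
  if (length(genes) == 0L) stop("at least one gene is required")
  if (anyDuplicated(genes)) stop("duplicate genes in spec")
  cross_pairs <- lapply(cross_pairs, as.character)
  for (p in cross_pairs) {
    if (length(p) != 2L) stop("each cross pair must name exactly two genes")
    if (!all(p %in% genes))
      stop("cross-pair gene(s) not in gene list: ",
           paste(setdiff(p, genes), collapse = ", "))
  }
  structure(list(genes = genes, degree = degree, cross_pairs = cross_pairs),
            class = "poly_spec")
}

#' @export
print.poly_spec <- function(x, ...) {
  cat(sprintf("poly_spec: degree %d, %d genes, %d cross terms (%d parameters)\n",
              x$degree, length(x$genes), length(x$cross_pairs), n_params(x)))
  invisible(x)
}

#' Number of parameters of a polynomial spec
#'
#' \code{1 + l * degree + M} for l genes and M cross pairs (intercept
#' included).
#'
#' @param spec A \code{poly_spec} or \code{fatepoly} fit.
#' @return Integer parameter count.
#' @export
n_params <- function(spec) {
  if (inherits(spec, "fatepoly")) spec <- spec$spec
  1L + length(spec$genes) * spec$degree + length(spec$cross_pairs)
}

#' Build the polynomial design matrix
#'
#' Columns are ordered: intercept, then for each power p = 1..degree the
#' genes in spec order raised to p, then the cross-product columns in pair
#' order. Column names are \code{"(Intercept)"}, \code{"<gene>^p"} and
#' \code{"<gene_i>:<gene_j>"}.
#'
#' @param m An \code{expr_matrix} (or plain numeric matrix with gene column
#'   names) containing every spec gene.
#' @param spec A \code{poly_spec}.
#' @return Numeric matrix with \code{nrow(m)} rows and \code{n_params(spec)}
#'   columns.
#' @export
build_design_matrix <- function(m, spec) {
  v <- unclass(m)
  missing <- setdiff(spec$genes, colnames(v))
  if (length(missing))
    stop("spec gene(s) absent from matrix: ", paste(missing, collapse = ", "))
  x <- v[, spec$genes, drop = FALSE]
  design_from_values(x, spec$degree, length(spec$cross_pairs),
                     pair_index(spec))
}

# Cross pairs as column-index pairs into the spec gene order.
pair_index <- function(spec) {
  if (!length(spec$cross_pairs)) return(NULL)
  t(vapply(spec$cross_pairs,
           function(p) match(p, spec$genes), integer(2L)))
}

# Positional design builder shared by build_design_matrix and the stability
# sampler (where points carry rank positions, not gene names). x is an
# n x l matrix of predictor values in importance-rank order.
design_from_values <- function(x, degree, n_pairs, pair_idx,
                               col_genes = colnames(x)) {
  n <- nrow(x)
  l <- ncol(x)
  ncols <- 1L + l * degree + n_pairs
  out <- matrix(NA_real_, n, ncols)
  out[, 1L] <- 1
  nm <- character(ncols)
  nm[1L] <- "(Intercept)"
  if (is.null(col_genes)) col_genes <- paste0("x", seq_len(l))
  for (p in seq_len(degree)) {
    cols <- 1L + (p - 1L) * l + seq_len(l)
    out[, cols] <- x^p
    nm[cols] <- if (p == 1L) col_genes else paste0(col_genes, "^", p)
  }
  if (n_pairs > 0L) {
    for (k in seq_len(n_pairs)) {
      i <- pair_idx[k, 1L]; j <- pair_idx[k, 2L]
      out[, 1L + l * degree + k] <- x[, i] * x[, j]
      nm[1L + l * degree + k] <- paste0(col_genes[i], ":", col_genes[j])
    }
  }
  colnames(out) <- nm
  out
}

#' Ordinary least squares with a rank-revealing solver
#'
#' Solves min ||X b - p||^2 by singular value decomposition. Singular values
#' below \code{max(dim(X)) * eps * max(sv)} are treated as zero; for
#' rank-deficient systems the minimum-norm solution is returned with a
#' warning, and an under-determined system (fewer rows than columns) also
#' warns. No regularisation is applied.
#'
#' @param design Numeric design matrix (rows = observations).
#' @param p Numeric response vector, length \code{nrow(design)}.
#' @return List with \code{coefficients}, \code{rank}, \code{fitted},
#'   \code{residuals}.
#' @export
fit_least_squares <- function(design, p) {
  design <- as.matrix(design)
  p <- as.numeric(p)
  if (nrow(design) != length(p))
    stop("design rows and response length differ")
  if (nrow(design) < ncol(design))
    warning("under-determined system: fewer observations (", nrow(design),
            ") than parameters (", ncol(design), ")")
  sv <- svd(design)
  tol <- max(dim(design)) * .Machine$double.eps * max(sv$d, 0)
  pos <- sv$d > tol
  rank <- sum(pos)
  if (rank < ncol(design))
    warning("rank-deficient design (rank ", rank, " < ", ncol(design),
            " columns); minimum-norm solution returned")
  dinv <- ifelse(pos, 1 / sv$d, 0)
  coefficients <- sv$v %*% (dinv * crossprod(sv$u, p))
  coefficients <- drop(coefficients)
  names(coefficients) <- colnames(design)
  fitted <- drop(design %*% coefficients)
  list(coefficients = coefficients, rank = rank, fitted = fitted,
       residuals = p - fitted)
}

#' Fit a polynomial cell-fate model
#'
#' The central fitting function: builds the design matrix implied by
#' \code{spec} (or by \code{degree}/\code{cross_pairs} over all genes of
#' \code{m}) and estimates the coefficients by ordinary least squares against
#' the per-cell death probability. Predicted probabilities are not clipped to
#' [0, 1]; downstream classification applies the 0.5 threshold.
#'
#' @param m An \code{expr_matrix} of predictor expression values
#'   (conventionally log-scale).
#' @param labels A \code{fate_labels} object or numeric vector of death
#'   probabilities aligned with the rows of \code{m}.
#' @param spec A \code{poly_spec}; if \code{NULL}, one is built from
#'   \code{degree} and \code{cross_pairs} using every gene of \code{m}.
#' @param degree,cross_pairs Used only when \code{spec} is \code{NULL}.
#' @return An object of class \code{"fatepoly"} with components \code{spec},
#'   \code{coefficients} (intercept first, then per-power gene blocks, then
#'   cross terms), \code{rank}, \code{fitted.values}, \code{residuals},
#'   \code{sigma} (residual standard deviation) and \code{n_obs}.
#' @examples
#' set.seed(1)
#' x <- matrix(runif(60), 20, 3, dimnames = list(NULL, c("g1", "g2", "g3")))
#' m <- expression_matrix(x, colnames(x), paste0("c", 1:20))
#' p <- pmin(1, pmax(0, 0.2 + 0.5 * x[, 1] - 0.1 * x[, 2]))
#' fit <- fate_polyfit(m, p, degree = 1)
#' coef(fit)
#' @export
fate_polyfit <- function(m, labels, spec = NULL, degree = 1L,
                         cross_pairs = list()) {
  p <- if (inherits(labels, "fate_labels")) labels$p_death else as.numeric(labels)
  if (length(p) != nrow(m)) stop("labels do not match the number of cells")
  if (is.null(spec)) {
    genes <- if (inherits(m, "expr_matrix") || !is.null(colnames(m)))
      colnames(m) else stop("spec is NULL and matrix has no gene names")
    spec <- poly_spec(genes, degree = degree, cross_pairs = cross_pairs)
  }
  X <- build_design_matrix(m, spec)
  ls <- fit_least_squares(X, p)
  dfres <- max(nrow(X) - ls$rank, 1L)
  structure(list(spec = spec,
                 coefficients = ls$coefficients,
                 rank = ls$rank,
                 fitted.values = ls$fitted,
                 residuals = ls$residuals,
                 sigma = sqrt(sum(ls$residuals^2) / dfres),
                 n_obs = nrow(X)),
            class = "fatepoly")
}

#' @export
print.fatepoly <- function(x, ...) {
  cat(sprintf("Polynomial cell-fate model (degree %d, %d genes, %d cross terms)\n",
              x$spec$degree, length(x$spec$genes),
              length(x$spec$cross_pairs)))
  cat(sprintf("  %d parameters fitted to %d cells; residual sd %.4g\n",
              n_params(x), x$n_obs, x$sigma))
  cat("Coefficients:\n")
  print(utils::head(round(x$coefficients, 5L), 10L))
  if (length(x$coefficients) > 10L) cat("...\n")
  invisible(x)
}

#' @export
summary.fatepoly <- function(object, ...) {
  rss <- sum(object$residuals^2)
  p <- object$fitted.values + object$residuals
  tss <- sum((p - mean(p))^2)
  out <- list(spec = object$spec, coefficients = object$coefficients,
              n_obs = object$n_obs, rank = object$rank,
              sigma = object$sigma, rss = rss,
              r.squared = if (tss > 0) 1 - rss / tss else NA_real_,
              train_accuracy = interval_accuracy(object$fitted.values, p))
  class(out) <- "summary.fatepoly"
  out
}

#' @export
print.summary.fatepoly <- function(x, ...) {
  cat(sprintf("Polynomial cell-fate model: degree %d, %d genes, %d cross terms\n",
              x$spec$degree, length(x$spec$genes), length(x$spec$cross_pairs)))
  cat(sprintf("  observations: %d   parameters: %d (rank %d)\n",
              x$n_obs, length(x$coefficients), x$rank))
  cat(sprintf("  residual sd: %.4g   R-squared: %.4f\n", x$sigma, x$r.squared))
  cat(sprintf("  training interval accuracy (0.5 threshold): %.4f\n",
              x$train_accuracy))
  invisible(x)
}

#' @export
coef.fatepoly <- function(object, ...) object$coefficients

#' @export
residuals.fatepoly <- function(object, ...) object$residuals

#' @export
fitted.fatepoly <- function(object, ...) object$fitted.values

#' Predict death probabilities from a fitted polynomial model
#'
#' @param object A \code{fatepoly} fit.
#' @param newdata An \code{expr_matrix} (or named numeric matrix) containing
#'   the spec genes; omitted = training fitted values.
#' @param ... Unused.
#' @return Numeric vector of predicted death probabilities; values may fall
#'   outside [0, 1] (no clipping).
#' @export
predict.fatepoly <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  X <- build_design_matrix(newdata, object$spec)
  drop(X %*% object$coefficients)
}

#' Simulate responses from a fitted polynomial model
#'
#' Draws Gaussian noise with the fit's residual standard deviation around the
#' fitted values (or around predictions on \code{newdata}).
#'
#' @param object A \code{fatepoly} fit.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional integer seed.
#' @param newdata Optional matrix of predictor values.
#' @param ... Unused.
#' @return A data.frame with \code{nsim} columns.
#' @export
simulate.fatepoly <- function(object, nsim = 1, seed = NULL, newdata = NULL,
                              ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- if (is.null(newdata)) object$fitted.values else
    predict(object, newdata)
  out <- as.data.frame(replicate(nsim, mu + stats::rnorm(length(mu),
                                                         sd = object$sigma)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot observed versus fitted death probabilities
#'
#' Scatter of fitted against observed per-cell death probability with the
#' 0.5 classification threshold marked; points in the off-diagonal quadrants
#' are interval misclassifications.
#'
#' @param x A \code{fatepoly} fit.
#' @param ... Passed to \code{plot}.
#' @export
plot.fatepoly <- function(x, ...) {
  obs <- x$fitted.values + x$residuals
  graphics::plot(obs, x$fitted.values,
                 xlab = "observed death probability",
                 ylab = "fitted death probability",
                 main = sprintf("degree-%d polynomial fit", x$spec$degree),
                 ...)
  graphics::abline(h = 0.5, v = 0.5, lty = 2, col = "grey40")
  graphics::abline(0, 1, col = "red")
  invisible(x)
}
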