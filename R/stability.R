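#' Sample expression points for stability analysis
#'
#' Draws \code{n_points} high-dimensional points, one dimension per gene,
#' each coordinate sampled independently and uniformly within that gene's
#' observed [min, max] over all cells. Deterministic given the seed, so the
#' same point set can be reused for every model with the same gene count —
#' required for MVAV values to be comparable across model settings.
#'
#' @param m An \code{expr_matrix} on the scale the models were fitted on.
#' @param genes Gene ids defining the dimensions, in importance-rank order.
#' @param n_points Number of points (default 10000).
#' @param seed Integer seed.
#' @return Numeric matrix \code{n_points x length(genes)} with gene column
#'   names.
#' @export
sample_stability_points <- function(m, genes, n_points = 10000L, seed = 1L) {
  v <- unclass(m)
  missing <- setdiff(genes, colnames(v))
  if (length(missing))
    stop("gene(s) absent from matrix: ", paste(missing, collapse = ", "))
  lo <- apply(v[, genes, drop = FALSE], 2L, min)
  hi <- apply(v[, genes, drop = FALSE], 2L, max)
  if (any(lo == hi))
    warning("constant gene(s) yield degenerate sampling dimension(s): ",
            paste(genes[lo == hi], collapse = ", "))
  pts <- with_seed(seed, {
    u <- matrix(stats::runif(n_points * length(genes)), n_points,
                length(genes))
    sweep(sweep(u, 2L, hi - lo, "*"), 2L, lo, "+")
  })
  colnames(pts) <- genes
  pts
}

# Predictions of each model at each point: points are in importance-rank
# order, and dimension i maps to the i-th ranked gene of each model, so
# models whose selected genes differ (correlation-mode folds) are evaluated
# positionally. Returns an n_points x n_models matrix.
prediction_matrix <- function(models, points) {
  l <- length(models[[1L]]$spec$genes)
  preds <- vapply(models, function(mod) {
    spec <- mod$spec
    if (length(spec$genes) != l)
      stop("all models must share the same gene count")
    X <- design_from_values(points, spec$degree,
                            length(spec$cross_pairs), pair_index(spec),
                            col_genes = colnames(points))
    drop(X %*% mod$coefficients)
  }, numeric(nrow(points)))
  matrix(preds, nrow = nrow(points))
}

#' Per-point prediction variance over a set of refitted models
#'
#' Evaluates every model at every sampled point and returns, for each point,
#' the sample variance (n-1 denominator) of the predictions across models.
#' Point dimension i maps to the i-th importance-ranked gene of each model.
#'
#' @param models List of \code{fatepoly} fits sharing a gene count (e.g. the
#'   100 models of a 10x10 cross-validation).
#' @param points Matrix from \code{\link{sample_stability_points}}.
#' @return Numeric vector of length \code{nrow(points)}, all entries >= 0.
#' @export
point_prediction_variances <- function(models, points) {
  if (length(models) < 2L)
    stop("at least two models are required to compute variances")
  preds <- prediction_matrix(models, points)
  n <- ncol(preds)
  mu <- rowMeans(preds)
  rowSums((preds - mu)^2) / (n - 1)
}

#' Mean value of all variances (MVAV)
#'
#' The arithmetic mean of the per-point prediction variances; smaller MVAV
#' means a more stable model.
#'
#' @param variances Non-empty numeric vector of non-negative variances.
#' @return Non-negative scalar.
#' @export
compute_mvav <- function(variances) {
  if (length(variances) == 0L) stop("empty variance vector")
  if (any(variances < 0)) stop("variances must be non-negative")
  mean(variances)
}

#' Per-parameter min/max ranges over refitted models
#'
#' For each coefficient position (intercept first, then the per-power gene
#' blocks in importance-rank order, then cross terms) reports the minimum,
#' maximum and width over the supplied models.
#'
#' @param models List of \code{fatepoly} fits with equal parameter counts.
#' @return data.frame with columns \code{position}, \code{term}, \code{min},
#'   \code{max}, \code{width}.
#' @export
parameter_range_report <- function(models) {
  np <- vapply(models, function(m) length(m$coefficients), integer(1L))
  if (length(unique(np)) != 1L)
    stop("models have differing parameter counts: ",
         paste(unique(np), collapse = ", "))
  cc <- vapply(models, coef, numeric(np[1L]))
  cc <- matrix(cc, nrow = np[1L])
  lo <- apply(cc, 1L, min)
  hi <- apply(cc, 1L, max)
  terms <- names(coef(models[[1L]]))
  if (is.null(terms)) terms <- paste0("p", seq_len(np[1L]))
  data.frame(position = seq_len(np[1L]),
             term = terms,
             min = lo, max = hi, width = hi - lo,
             stringsAsFactors = FALSE)
}

#' Gamma fit and goodness-of-fit check for the variance distribution
#'
#' Fits a gamma distribution to the positive prediction variances by maximum
#' likelihood and tests agreement with a one-sample Kolmogorov-Smirnov test
#' against the fitted distribution. Zeros are excluded (their count is
#' reported). Note the test is anti-conservative because the same data are
#' used for fitting and testing; the p-value is reported as an informal
#' check, not corrected.
#'
#' @param variances Numeric vector of non-negative variances.
#' @param alpha Significance level for the pass flag (default 0.05).
#' @return List with \code{shape}, \code{scale}, \code{p_value},
#'   \code{pass} (p >= alpha), \code{n_used}, \code{n_zero}, and empirical
#'   \code{pdf}/\code{cdf} tables for plotting.
#' @export
fit_variance_distribution <- function(variances, alpha = 0.05) {
  if (any(variances < 0)) stop("variances must be non-negative")
  v <- variances[variances > 0]
  n_zero <- length(variances) - length(v)
  if (length(v) < 50L)
    stop("insufficient data: fewer than 50 positive variances")
  fit <- fitdistrplus::fitdist(v, "gamma", method = "mle", lower = c(0, 0))
  shape <- unname(fit$estimate["shape"])
  rate <- unname(fit$estimate["rate"])
  ks <- suppressWarnings(stats::ks.test(v, "pgamma", shape = shape,
                                        rate = rate))
  h <- graphics::hist(v, breaks = 50L, plot = FALSE)
  sv <- sort(v)
  list(shape = shape, scale = 1 / rate, p_value = ks$p.value,
       pass = ks$p.value >= alpha, n_used = length(v), n_zero = n_zero,
       pdf = data.frame(mid = h$mids, density = h$density),
       cdf = data.frame(value = sv,
                        prob = seq_along(sv) / length(sv)))
}

#' Full stability report for a set of refitted models
#'
#' Combines the per-parameter ranges, the per-point prediction variances at
#' a shared sampled point set, the MVAV, and the gamma-distribution check
#' into one report.
#'
#' @param models List of \code{fatepoly} fits (typically the 100 models of a
#'   repeated cross-validation).
#' @param points Point matrix from \code{\link{sample_stability_points}};
#'   reuse one point set across model settings with the same gene count.
#' @param alpha Significance level for the gamma goodness-of-fit flag.
#' @return An object of class \code{"stability_report"} with components
#'   \code{param_ranges}, \code{point_variances}, \code{mvav},
#'   \code{gamma_fit} and \code{n_models}.
#' @export
stability_report <- function(models, points, alpha = 0.05) {
  pv <- point_prediction_variances(models, points)
  gf <- tryCatch(fit_variance_distribution(pv, alpha = alpha),
                 error = function(e) NULL)
  structure(list(param_ranges = parameter_range_report(models),
                 point_variances = pv,
                 mvav = compute_mvav(pv),
                 gamma_fit = gf,
                 n_models = length(models)),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("Stability report over %d models, %d sampled points\n",
              x$n_models, length(x$point_variances)))
  cat(sprintf("  MVAV: %.6g\n", x$mvav))
  cat(sprintf("  widest parameter range: %.4g (%s)\n",
              max(x$param_ranges$width),
              x$param_ranges$term[which.max(x$param_ranges$width)]))
  if (!is.null(x$gamma_fit))
    cat(sprintf("  gamma fit: shape %.3f, scale %.3g, KS p = %.3g (%s)\n",
                x$gamma_fit$shape, x$gamma_fit$scale, x$gamma_fit$p_value,
                if (x$gamma_fit$pass) "pass" else "fail"))
  invisible(x)
}

#' Plot a stability report
#'
#' Two base-graphics panels: per-parameter coefficient ranges (min-max bars
#' by position) and the histogram of per-point prediction variances with the
#' fitted gamma density overlaid when available.
#'
#' @param x A \code{stability_report}.
#' @param ... Unused.
#' @export
plot.stability_report <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  pr <- x$param_ranges
  graphics::plot(pr$position, (pr$min + pr$max) / 2, ylim = range(pr$min, pr$max),
                 pch = 20, xlab = "parameter position (importance order)",
                 ylab = "coefficient", main = "parameter ranges")
  graphics::segments(pr$position, pr$min, pr$position, pr$max)
  graphics::hist(x$point_variances, breaks = 50L, freq = FALSE,
                 xlab = "prediction variance", main = "variance distribution")
  if (!is.null(x$gamma_fit)) {
    xs <- seq(0, max(x$point_variances), length.out = 200L)
    graphics::lines(xs, stats::dgamma(xs, shape = x$gamma_fit$shape,
                                      scale = x$gamma_fit$scale), col = "red")
  }
  invisible(x)
}
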