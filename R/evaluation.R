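#' Random fold assignment for k-fold cross-validation
#'
#' Cells are randomly divided into \code{n_folds} nearly equal subsets:
#' fold sizes differ by at most one, folds are disjoint and exhaustive, and
#' the assignment is deterministic given \code{seed}.
#'
#' @param n_cells Number of cells.
#' @param n_folds Number of folds (>= 2, <= \code{n_cells}).
#' @param seed Integer seed.
#' @return List of \code{n_folds} integer index vectors.
#' @export
make_folds <- function(n_cells, n_folds = 10L, seed = 1L) {
  n_folds <- as.integer(n_folds)
  if (n_folds < 2L) stop("n_folds must be at least 2")
  if (n_folds > n_cells)
    stop("n_folds (", n_folds, ") exceeds the number of cells (", n_cells, ")")
  perm <- with_seed(seed, sample.int(n_cells))
  fold_of <- rep(seq_len(n_folds), length.out = n_cells)
  unname(split(perm, fold_of))
}

#' Interval-agreement prediction accuracy
#'
#' A prediction is correct when the predicted and actual death probabilities
#' fall in the same interval, [0, 0.5) or [0.5, 1]. Predictions outside
#' [0, 1] classify by the same 0.5 threshold.
#'
#' @param predicted,actual Numeric vectors of equal positive length.
#' @return Fraction correct, in [0, 1].
#' @examples
#' interval_accuracy(c(0.6, 0.2, 0.7), c(0.9, 0.1, 0.4))  # 2/3
#' @export
interval_accuracy <- function(predicted, actual) {
  if (length(predicted) != length(actual))
    stop("predicted and actual lengths differ")
  if (length(predicted) == 0L) stop("empty prediction vector")
  mean((predicted >= 0.5) == (actual >= 0.5))
}

#' Configuration for repeated cross-validation
#'
#' @param n_folds Folds per repeat (default 10).
#' @param n_repeats Number of repeats (default 10); the defaults give the
#'   standard 10x10 design with 100 fitted models.
#' @param seed Integer master seed; repeat r partitions cells with sub-seed
#'   \code{seed + r} for auditability.
#' @param degree Polynomial degree.
#' @param mode \code{"correlation"} (per-fold Spearman selection of
#'   \code{top_k} genes, and of \code{n_pairs} gene pairs when positive) or
#'   \code{"pathway"} (the fixed \code{feature_set} in every fold).
#' @param top_k Genes selected per training fold in correlation mode.
#' @param n_pairs Cross-term pairs per training fold in correlation mode
#'   (0 = none).
#' @param feature_set Fixed \code{feature_set} for pathway mode.
#' @return A \code{"cv_config"} list.
#' @export
cv_config <- function(n_folds = 10L, n_repeats = 10L, seed = 1L,
                      degree = 1L, mode = c("correlation", "pathway"),
                      top_k = 30L, n_pairs = 0L, feature_set = NULL) {
  mode <- match.arg(mode)
  if (n_folds < 2L) stop("n_folds must be at least 2")
  if (n_repeats < 1L) stop("n_repeats must be at least 1")
  if (mode == "pathway" && is.null(feature_set))
    stop("pathway mode requires a feature_set")
  structure(list(n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats),
                 seed = as.integer(seed), degree = as.integer(degree),
                 mode = mode, top_k = as.integer(top_k),
                 n_pairs = as.integer(n_pairs), feature_set = feature_set),
            class = "cv_config")
}

#' Repeated k-fold cross-validation of the polynomial cell-fate model
#'
#' For every repeat a fresh random fold partition is drawn; within each fold,
#' feature selection (correlation mode) uses the training cells only, the
#' polynomial model is fitted on the training cells, and the interval
#' accuracy is measured on the held-out cells. The 10x10 default yields 100
#' fitted models; every cell is tested exactly once per repeat. Fully
#' reproducible from the config seed.
#'
#' @param m An \code{expr_matrix} of predictor expression (marker genes
#'   already excluded; conventionally log-scale).
#' @param labels A \code{fate_labels} object or numeric death-probability
#'   vector aligned with \code{m}.
#' @param cfg A \code{\link{cv_config}}.
#' @return An object of class \code{"fate_cv"}: fold accuracies (repeats x
#'   folds matrix), \code{mean_accuracy}, the list of fitted
#'   \code{fatepoly} models, the per-fold \code{feature_set}s, the fold
#'   partitions and the config.
#' @export
run_repeated_cv <- function(m, labels, cfg) {
  p <- if (inherits(labels, "fate_labels")) labels$p_death else as.numeric(labels)
  if (length(p) != nrow(m)) stop("labels do not match the number of cells")
  acc <- matrix(NA_real_, cfg$n_repeats, cfg$n_folds,
                dimnames = list(paste0("repeat", seq_len(cfg$n_repeats)),
                                paste0("fold", seq_len(cfg$n_folds))))
  models <- vector("list", cfg$n_repeats * cfg$n_folds)
  featsets <- vector("list", cfg$n_repeats * cfg$n_folds)
  folds_by_repeat <- vector("list", cfg$n_repeats)
  k <- 0L
  for (r in seq_len(cfg$n_repeats)) {
    folds <- make_folds(nrow(m), cfg$n_folds, seed = cfg$seed + r)
    folds_by_repeat[[r]] <- folds
    for (f in seq_len(cfg$n_folds)) {
      test_idx <- folds[[f]]
      train_idx <- setdiff(seq_len(nrow(m)), test_idx)
      mtr <- m[train_idx, ]
      fs <- if (cfg$mode == "correlation") {
        sel <- select_top_correlated(mtr, p[train_idx], cfg$top_k)
        if (cfg$n_pairs > 0L) rank_gene_pairs(mtr, sel, cfg$n_pairs) else sel
      } else {
        cfg$feature_set
      }
      spec <- poly_spec(fs$genes, degree = cfg$degree,
                        cross_pairs = fs$cross_pairs)
      fit <- fate_polyfit(mtr, p[train_idx], spec = spec)
      pred <- predict(fit, m[test_idx, ])
      k <- k + 1L
      acc[r, f] <- interval_accuracy(pred, p[test_idx])
      models[[k]] <- fit
      featsets[[k]] <- fs
    }
  }
  structure(list(accuracies = acc,
                 mean_accuracy = mean(acc),
                 models = models,
                 feature_sets = featsets,
                 folds = folds_by_repeat,
                 config = cfg),
            class = "fate_cv")
}

#' @export
print.fate_cv <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Repeated CV: %d repeats x %d folds (%s mode, degree %d)\n",
              cfg$n_repeats, cfg$n_folds, cfg$mode, cfg$degree))
  cat(sprintf("  mean interval accuracy: %.4f (fold range %.4f - %.4f)\n",
              x$mean_accuracy, min(x$accuracies), max(x$accuracies)))
  invisible(x)
}

#' @export
summary.fate_cv <- function(object, ...) {
  out <- list(mean_accuracy = object$mean_accuracy,
              sd_accuracy = stats::sd(as.vector(object$accuracies)),
              per_repeat = rowMeans(object$accuracies),
              n_models = length(object$models),
              config = object$config)
  class(out) <- "summary.fate_cv"
  out
}

#' @export
print.summary.fate_cv <- function(x, ...) {
  cat(sprintf("Mean accuracy over %d models: %.4f (sd %.4f)\n",
              x$n_models, x$mean_accuracy, x$sd_accuracy))
  cat("Per-repeat means:\n")
  print(round(x$per_repeat, 4L))
  invisible(x)
}
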