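#' Run the full cell-fate analysis over a settings grid
#'
#' End-to-end orchestration: simulate (or read) an expression matrix, label
#' cells from the caspase markers, exclude the markers, log-transform the
#' predictors, then sweep a grid of model settings, cross-validating each
#' and measuring stability on a shared sampled point set per gene count.
#' Produces accuracy and MVAV tables (rows = degree or setting, columns =
#' gene counts), per-setting stability summaries, TSV outputs and a
#' machine-readable run manifest.
#'
#' Grid cells that are not applicable (too few genes to supply the requested
#' number of cross-term pairs) are reported as \code{NA}.
#'
#' @param config A named list, or the path to a YAML/JSON file, with
#'   elements: \code{sim} (arguments to \code{\link{simulation_config}}) or
#'   \code{expression} (path to an expression table, cells x genes);
#'   \code{mode} ("correlation" or "pathway"); \code{degrees} (correlation
#'   mode; default 1:3); \code{gene_counts} (correlation mode; default
#'   c(5, 10, 30)); \code{pair_counts} (optional; adds a degree-2-with-pairs
#'   grid); \code{pathway_genes}/\code{regulatory_pairs} (pathway mode;
#'   defaults \code{\link{apoptosis_genes}} /
#'   \code{\link{default_regulatory_pairs}}); \code{n_repeats},
#'   \code{n_folds}, \code{n_points}, \code{seed}.
#' @param out_dir Output directory for TSV tables and the manifest
#'   (created if needed); \code{NULL} = no files written.
#' @return An object of class \code{"run_manifest"}: config echo, seed,
#'   package version, the accuracy/MVAV tables, stability reports, output
#'   paths and per-stage wall-clock timings.
#' @export
run_full_analysis <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_config(config)
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  mode <- if (is.null(config$mode)) "correlation" else config$mode
  n_repeats <- if (is.null(config$n_repeats)) 10L else as.integer(config$n_repeats)
  n_folds <- if (is.null(config$n_folds)) 10L else as.integer(config$n_folds)
  n_points <- if (is.null(config$n_points)) 10000L else as.integer(config$n_points)

  # --- data stage -----------------------------------------------------------
  if (!is.null(config$expression)) {
    m_raw <- read_expression_matrix(config$expression)
  } else {
    sim_args <- if (is.null(config$sim)) list() else config$sim
    if (is.null(sim_args$seed)) sim_args$seed <- seed
    ds <- do.call(simulation_config, sim_args)
    m_raw <- simulate_dataset(ds)$matrix
  }
  labels <- compute_death_probability(m_raw)
  pred <- log_transform(exclude_marker_genes(m_raw))
  timings["data"] <- proc.time()[["elapsed"]] - t0

  results <- list()
  if (mode == "correlation") {
    degrees <- if (is.null(config$degrees)) 1:3 else config$degrees
    gene_counts <- if (is.null(config$gene_counts)) c(5L, 10L, 30L) else
      as.integer(config$gene_counts)
    acc <- matrix(NA_real_, length(degrees), length(gene_counts),
                  dimnames = list(paste0("degree", degrees), gene_counts))
    mvav <- acc
    for (ci in seq_along(gene_counts)) {
      k <- gene_counts[ci]
      global_sel <- select_top_correlated(pred, labels, k)
      pts <- sample_stability_points(pred, global_sel$genes,
                                     n_points = n_points, seed = seed + k)
      for (di in seq_along(degrees)) {
        cv <- run_repeated_cv(pred, labels,
                              cv_config(n_folds, n_repeats, seed,
                                        degree = degrees[di],
                                        mode = "correlation", top_k = k))
        st <- stability_report(cv$models, pts)
        acc[di, ci] <- cv$mean_accuracy
        mvav[di, ci] <- st$mvav
        results[[sprintf("degree%d_genes%d", degrees[di], k)]] <-
          list(cv = cv, stability = st)
      }
    }
    tables <- list(accuracy = acc, mvav = mvav)
    if (!is.null(config$pair_counts)) {
      pair_counts <- as.integer(config$pair_counts)
      pacc <- matrix(NA_real_, length(pair_counts), length(gene_counts),
                     dimnames = list(paste0("pairs", pair_counts),
                                     gene_counts))
      pmvav <- pacc
      for (ci in seq_along(gene_counts)) {
        k <- gene_counts[ci]
        global_sel <- select_top_correlated(pred, labels, k)
        pts <- sample_stability_points(pred, global_sel$genes,
                                       n_points = n_points, seed = seed + k)
        for (pi in seq_along(pair_counts)) {
          if (choose(k, 2L) < pair_counts[pi]) next  # not applicable
          cv <- run_repeated_cv(pred, labels,
                                cv_config(n_folds, n_repeats, seed,
                                          degree = 2L, mode = "correlation",
                                          top_k = k,
                                          n_pairs = pair_counts[pi]))
          st <- stability_report(cv$models, pts)
          pacc[pi, ci] <- cv$mean_accuracy
          pmvav[pi, ci] <- st$mvav
          results[[sprintf("pairs%d_genes%d", pair_counts[pi], k)]] <-
            list(cv = cv, stability = st)
        }
      }
      tables$pair_accuracy <- pacc
      tables$pair_mvav <- pmvav
    }
  } else if (mode == "pathway") {
    genes <- if (is.null(config$pathway_genes)) apoptosis_genes() else
      config$pathway_genes
    pairs <- if (is.null(config$regulatory_pairs)) default_regulatory_pairs()
      else lapply(config$regulatory_pairs, as.character)
    missing <- setdiff(genes, gene_ids(pred))
    if (length(missing))
      stop("pathway gene(s) absent from expression matrix: ",
           paste(utils::head(missing, 5L), collapse = ", "),
           if (length(missing) > 5L) ", ..." else "")
    fs_plain <- pathway_feature_set(genes, list())
    fs_cross <- pathway_feature_set(genes, pairs)
    settings <- list(
      degree1 = list(degree = 1L, fs = fs_plain),
      degree2 = list(degree = 2L, fs = fs_plain),
      degree2_cross = list(degree = 2L, fs = fs_cross),
      degree3 = list(degree = 3L, fs = fs_plain))
    pts <- sample_stability_points(pred, genes, n_points = n_points,
                                   seed = seed + length(genes))
    acc <- mvav <- stats::setNames(rep(NA_real_, length(settings)),
                                   names(settings))
    for (s in names(settings)) {
      cv <- run_repeated_cv(pred, labels,
                            cv_config(n_folds, n_repeats, seed,
                                      degree = settings[[s]]$degree,
                                      mode = "pathway",
                                      feature_set = settings[[s]]$fs))
      st <- stability_report(cv$models, pts)
      acc[s] <- cv$mean_accuracy
      mvav[s] <- st$mvav
      results[[s]] <- list(cv = cv, stability = st)
    }
    tables <- list(accuracy = rbind(accuracy = acc),
                   mvav = rbind(mvav = mvav))
  } else stop("unknown mode: ", mode)
  timings["grid"] <- proc.time()[["elapsed"]] - t0 - sum(timings)

  # --- outputs --------------------------------------------------------------
  paths <- character()
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(tables)) {
      f <- file.path(out_dir, paste0(nm, ".tsv"))
      utils::write.table(data.frame(setting = rownames(tables[[nm]]),
                                    tables[[nm]], check.names = FALSE),
                         f, sep = "\t", quote = FALSE, row.names = FALSE)
      paths[nm] <- f
    }
  }
  timings["write"] <- proc.time()[["elapsed"]] - t0 - sum(timings)
  manifest <- structure(list(
    config = config, seed = seed, mode = mode,
    version = as.character(utils::packageVersion("polyfate")),
    tables = tables, results = results, paths = paths,
    timings = timings), class = "run_manifest")
  if (!is.null(out_dir)) {
    stopifnot(all(file.exists(paths)))
    mf <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(list(config = config, seed = seed, mode = mode,
                              version = manifest$version,
                              paths = as.list(paths),
                              timings = as.list(round(timings, 3))),
                         mf, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    manifest$paths["manifest"] <- mf
  }
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("polyfate run (%s mode, seed %d, v%s)\n", x$mode, x$seed,
              x$version))
  cat("Accuracy:\n"); print(round(x$tables$accuracy, 4L))
  cat("MVAV:\n"); print(signif(x$tables$mvav, 4L))
  if (length(x$paths)) cat("Outputs:", paste(x$paths, collapse = ", "), "\n")
  invisible(x)
}
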