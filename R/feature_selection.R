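#' The 32-gene apoptosis-pathway feature list
#'
#' The common apoptosis-pathway genes used in pathway mode, covering the
#' death-receptor, endoplasmic-reticulum, TP53-dependent and mitochondrial
#' arms of the pathway.
#'
#' @return Character vector of 32 gene symbols.
#' @export
apoptosis_genes <- function() {
  c("APAF1", "ATF4", "BAK1", "BAX", "BCL2", "BCL2L1", "BID", "CAPN1",
    "CAPN2", "CASP8", "CASP9", "CASP10", "CYCS", "DAXX", "DDIT3",
    "DIABLO", "EIF2AK3", "EIF2S1", "ERN1", "FADD", "FAS", "ITPR1",
    "MAP3K5", "MAPK8", "MAPK9", "MAPK10", "MDM2", "TNFRSF1A", "TRADD",
    "TRAF2", "TP53", "XIAP")
}

#' Default regulatory cross-term gene pairs
#'
#' Six regulatory/binding relationships within the apoptosis gene list used
#' as product cross terms in pathway mode: TP53 activates transcription of
#' MDM2; FADD recruits CASP8 at the death receptor; TNFRSF1A recruits TRADD;
#' BAX is antagonised by BCL2; cytochrome c (CYCS) binds APAF1 in the
#' apoptosome; DIABLO antagonises XIAP. Only the TP53-MDM2 relationship is
#' fixed by the method's definition; the remaining five are this package's
#' documented default and are fully configurable.
#'
#' @return A list of six length-2 character vectors.
#' @export
default_regulatory_pairs <- function() {
  list(c("TP53", "MDM2"), c("FADD", "CASP8"), c("TNFRSF1A", "TRADD"),
       c("BAX", "BCL2"), c("CYCS", "APAF1"), c("DIABLO", "XIAP"))
}

#' Spearman's rank correlation coefficient
#'
#' The Pearson correlation of average ranks: ties receive the mean of the
#' ranks they span. Measures monotone association and is invariant under
#' strictly increasing transforms of either argument.
#'
#' @param x,y Numeric vectors of equal length >= 3, neither constant.
#' @return The correlation in [-1, 1].
#' @examples
#' spearman_rho(1:4, c(10, 20, 30, 40))  # 1
#' spearman_rho(1:4, c(8, 6, 4, 2))      # -1
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("at least 3 observations are required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant input vector")
  stats::cor(x, y, method = "spearman")
}

#' Construct a feature set
#'
#' @param genes Ordered gene ids; order encodes importance rank (1 =
#'   strongest).
#' @param cross_pairs List of length-2 character vectors naming gene pairs
#'   for product cross terms; every member must appear in \code{genes}.
#' @param mode \code{"correlation"} or \code{"pathway"}.
#' @param rho Optional named vector of correlation values backing the
#'   ordering.
#' @return An object of class \code{"feature_set"}.
#' @export
feature_set <- function(genes, cross_pairs = list(),
                        mode = c("correlation", "pathway"), rho = NULL) {
  mode <- match.arg(mode)
  genes <- as.character(genes)
  if (length(genes) == 0L) stop("feature set needs at least one gene")
  if (anyDuplicated(genes)) stop("duplicate genes in feature set")
  cross_pairs <- lapply(cross_pairs, as.character)
  for (p in cross_pairs) {
    if (length(p) != 2L) stop("each cross pair must name exactly two genes")
    if (!all(p %in% genes))
      stop("cross-pair gene(s) not in feature list: ",
           paste(setdiff(p, genes), collapse = ", "))
  }
  structure(list(genes = genes, cross_pairs = cross_pairs, mode = mode,
                 rho = rho),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("feature_set [%s]: %d genes, %d cross pairs\n", x$mode,
              length(x$genes), length(x$cross_pairs)))
  cat("  genes:", paste(utils::head(x$genes, 8L), collapse = ", "),
      if (length(x$genes) > 8L) "..." else "", "\n")
  if (length(x$cross_pairs))
    cat("  pairs:",
        paste(vapply(utils::head(x$cross_pairs, 6L),
                     paste, "", collapse = "x"), collapse = ", "), "\n")
  invisible(x)
}

#' Rank genes by correlation with the death probability
#'
#' Computes Spearman's rho between every gene's expression and the per-cell
#' death probability, orders genes by |rho| descending (ties broken by input
#' column order for reproducibility), and returns the top k as a
#' correlation-mode feature set.
#'
#' @param m An \code{expr_matrix} with marker genes already excluded.
#' @param labels A \code{fate_labels} object (or numeric p_death vector)
#'   aligned with the rows of \code{m}.
#' @param k Number of genes to keep; must not exceed \code{ncol(m)}.
#' @return A \code{feature_set} with \code{mode = "correlation"} and the
#'   selected genes' rho values attached.
#' @export
select_top_correlated <- function(m, labels, k) {
  p <- if (inherits(labels, "fate_labels")) labels$p_death else as.numeric(labels)
  if (length(p) != nrow(m)) stop("labels do not match the number of cells")
  if (k < 1L || k > ncol(m))
    stop("k must be between 1 and the number of genes (", ncol(m), ")")
  if (stats::sd(p) == 0)
    stop("undefined correlation: death probabilities are constant")
  rho <- as.vector(stats::cor(unclass(m), p, method = "spearman"))
  names(rho) <- gene_ids(m)
  # constant genes have undefined rho; they can never be selected
  rho[is.na(rho)] <- 0
  ord <- order(-abs(rho), seq_along(rho))
  sel <- ord[seq_len(k)]
  feature_set(gene_ids(m)[sel], mode = "correlation", rho = rho[sel])
}

#' Rank gene pairs for cross terms by pairwise correlation
#'
#' All unordered pairs among the feature genes are ranked by the absolute
#' Spearman correlation of their expression profiles; the top
#' \code{n_pairs} become the cross-term pairs of the returned feature set.
#'
#' @param m An \code{expr_matrix} containing the feature genes.
#' @param features A \code{feature_set} with at least two genes.
#' @param n_pairs Number of pairs to keep; must not exceed
#'   \code{choose(length(genes), 2)} (too few genes for the requested number
#'   of pairs is an error, mirroring settings that are not applicable).
#' @return The feature set with \code{cross_pairs} filled in rank order.
#' @export
rank_gene_pairs <- function(m, features, n_pairs) {
  genes <- features$genes
  if (length(genes) < 2L) stop("at least two genes are needed to form pairs")
  max_pairs <- choose(length(genes), 2L)
  if (n_pairs < 1L || n_pairs > max_pairs)
    stop("too few genes to provide ", n_pairs, " gene pairs (max ",
         max_pairs, ")")
  missing <- setdiff(genes, gene_ids(m))
  if (length(missing))
    stop("feature gene(s) absent from matrix: ",
         paste(missing, collapse = ", "))
  rr <- stats::cor(unclass(m)[, genes, drop = FALSE], method = "spearman")
  idx <- which(upper.tri(rr), arr.ind = TRUE)
  # order pairs as (1,2), (1,3), (2,3), ... for a deterministic tie-break
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  vals <- rr[idx]
  vals[is.na(vals)] <- 0
  ord <- order(-abs(vals), seq_along(vals))[seq_len(n_pairs)]
  pairs <- lapply(ord, function(i) c(genes[idx[i, 1L]], genes[idx[i, 2L]]))
  feature_set(genes, cross_pairs = pairs, mode = features$mode,
              rho = features$rho)
}

#' Build a pathway-mode feature set
#'
#' Uses a fixed gene list (default: the 32 apoptosis-pathway genes) with
#' cross terms given by known regulatory gene pairs rather than data-driven
#' correlation ranking.
#'
#' @param gene_list Character vector of gene ids, in the order they should
#'   enter the model.
#' @param regulatory_pairs List of length-2 character vectors; every member
#'   must be in \code{gene_list}.
#' @return A \code{feature_set} with \code{mode = "pathway"}.
#' @examples
#' fs <- pathway_feature_set()
#' length(fs$genes)         # 32
#' length(fs$cross_pairs)   # 6
#' @export
pathway_feature_set <- function(gene_list = apoptosis_genes(),
                                regulatory_pairs = default_regulatory_pairs()) {
  feature_set(gene_list, cross_pairs = regulatory_pairs, mode = "pathway")
}
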