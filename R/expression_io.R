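#' Construct an expression matrix
#'
#' The canonical container of the package: a cells x genes matrix of
#' non-negative RPKM-like expression values with gene and cell identifiers,
#' an optional per-cell donor-group label, and a scale flag recording whether
#' the values are raw or log-transformed.
#'
#' @param values Numeric matrix, rows = cells, columns = genes. Raw-scale
#'   values must be non-negative.
#' @param gene_ids Character vector of unique gene identifiers, one per column.
#' @param cell_ids Character vector of unique cell identifiers, one per row.
#' @param donor_group Optional per-cell group label (e.g. \code{"healthy"} /
#'   \code{"T2D"}), recycled checks applied; \code{NULL} if absent.
#' @param scale Either \code{"raw"} or \code{"log"}.
#' @return An object of class \code{"expr_matrix"}: the numeric matrix with
#'   dimnames set and attributes \code{scale} and \code{donor_group}.
#' @examples
#' m <- expression_matrix(matrix(1:6, 3, 2), c("g1", "g2"), c("c1", "c2", "c3"))
#' dim(m)
#' @export
expression_matrix <- function(values, gene_ids, cell_ids, donor_group = NULL,
                              scale = c("raw", "log")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (length(gene_ids) != ncol(values))
    stop("length(gene_ids) must equal ncol(values)")
  if (length(cell_ids) != nrow(values))
    stop("length(cell_ids) must equal nrow(values)")
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (anyDuplicated(gene_ids))
    stop("duplicate gene identifiers: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(cell_ids))
    stop("duplicate cell identifiers: ",
         paste(unique(cell_ids[duplicated(cell_ids)]), collapse = ", "))
  if (anyNA(values)) stop("expression values contain NA")
  if (scale == "raw" && any(values < 0))
    stop("raw-scale expression values must be non-negative")
  if (!is.null(donor_group)) {
    if (length(donor_group) != nrow(values))
      stop("donor_group must have one entry per cell")
    donor_group <- as.character(donor_group)
  }
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(values, scale = scale, donor_group = donor_group,
            class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d cells x %d genes [%s scale]%s\n",
              nrow(x), ncol(x), expr_scale(x),
              if (is.null(donor_groups(x))) "" else ", with donor groups"))
  if (nrow(x) > 0 && ncol(x) > 0) {
    show <- unclass(x)[seq_len(min(5L, nrow(x))), seq_len(min(5L, ncol(x))),
                       drop = FALSE]
    print(show)
    if (nrow(x) > 5L || ncol(x) > 5L) cat("...\n")
  }
  invisible(x)
}

#' Accessors for expr_matrix metadata
#'
#' @param m An \code{expr_matrix}.
#' @return \code{gene_ids}/\code{cell_ids}: character vectors;
#'   \code{expr_scale}: \code{"raw"} or \code{"log"}; \code{donor_groups}:
#'   per-cell labels or \code{NULL}.
#' @export
gene_ids <- function(m) colnames(m)

#' @rdname gene_ids
#' @export
cell_ids <- function(m) rownames(m)

#' @rdname gene_ids
#' @export
expr_scale <- function(m) attr(m, "scale")

#' @rdname gene_ids
#' @export
donor_groups <- function(m) attr(m, "donor_group")

# Subset an expr_matrix preserving class and attributes. Always returns a
# matrix (drop is ignored); donor groups are subset along with the cells.
#' @export
`[.expr_matrix` <- function(x, i, j, ...) {
  grp <- donor_groups(x)
  sc <- expr_scale(x)
  v <- unclass(x)
  if (missing(i)) i <- seq_len(nrow(v))
  if (missing(j)) j <- seq_len(ncol(v))
  out <- v[i, j, drop = FALSE]
  if (!is.null(grp)) grp <- grp[i]
  expression_matrix(out, colnames(out), rownames(out), donor_group = grp,
                    scale = sc)
}

#' Read an expression matrix from delimited text or MatrixMarket files
#'
#' Delimited input (TSV or CSV, chosen by file extension) must carry one
#' header row of identifiers and one identifier column (the first). MTX input
#' is a MatrixMarket triplet file accompanied by two plain-text identifier
#' files, one id per line, ordered as the matrix rows/columns.
#'
#' @param path Path to the \code{.tsv}/\code{.csv}/\code{.txt} table or the
#'   \code{.mtx} file.
#' @param orientation \code{"cells_by_genes"} (rows are cells; the canonical
#'   layout) or \code{"genes_by_cells"} (input is transposed on read). Never
#'   guessed.
#' @param row_ids_file,col_ids_file For MTX input: files listing the
#'   identifiers of the MTX rows and columns respectively.
#' @param scale Scale flag to record on the result (default \code{"raw"}).
#' @return An \code{expr_matrix} in cells x genes orientation.
#' @export
read_expression_matrix <- function(path,
                                   orientation = c("cells_by_genes",
                                                   "genes_by_cells"),
                                   row_ids_file = NULL, col_ids_file = NULL,
                                   scale = "raw") {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    if (is.null(row_ids_file) || is.null(col_ids_file))
      stop("MTX input requires row_ids_file and col_ids_file")
    vals <- as.matrix(Matrix::readMM(path))
    rid <- readLines(row_ids_file)
    cid <- readLines(col_ids_file)
    rid <- rid[nzchar(rid)]
    cid <- cid[nzchar(cid)]
    if (length(rid) != nrow(vals) || length(cid) != ncol(vals))
      stop("identifier file lengths do not match MTX dimensions")
    dimnames(vals) <- list(rid, cid)
  } else {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(tab[[1L]])
    vals <- as.matrix(tab[, -1L, drop = FALSE])
    if (!is.numeric(vals)) stop("non-numeric expression values in ", path)
    # data.frame subsetting deduplicates names; restore the originals so
    # duplicated identifiers are caught by the constructor
    colnames(vals) <- colnames(tab)[-1L]
    rownames(vals) <- ids
  }
  if (orientation == "genes_by_cells") vals <- t(vals)
  expression_matrix(vals, colnames(vals), rownames(vals), scale = scale)
}

#' Write an expression matrix as TSV
#'
#' Writes the canonical cells x genes layout: a header of gene identifiers
#' preceded by a \code{cell_id} column. Values round-trip through
#' \code{\link{read_expression_matrix}} to within 1e-9.
#'
#' @param m An \code{expr_matrix}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_expression_matrix <- function(m, path) {
  df <- data.frame(cell_id = cell_ids(m), unclass(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Log-transform an expression matrix
#'
#' Applies the elementwise transform \code{log2(x + offset)} (defaults:
#' base 2, offset 1, the common single-cell convention), so zero maps to
#' zero. RPKM-like data are strongly right-skewed and are modelled on this
#' scale.
#'
#' @param m A raw-scale \code{expr_matrix}.
#' @param base Logarithm base (default 2).
#' @param offset Pseudocount added before taking the log (default 1).
#' @return An \code{expr_matrix} with \code{scale = "log"}; identifiers and
#'   shape preserved.
#' @examples
#' m <- expression_matrix(matrix(c(0, 1, 7, 3), 2, 2),
#'                        c("g1", "g2"), c("c1", "c2"))
#' log_transform(m)
#' @export
log_transform <- function(m, base = 2, offset = 1) {
  if (expr_scale(m) != "raw")
    stop("matrix is already log-scaled")
  vals <- log(unclass(m) + offset, base = base)
  expression_matrix(vals, gene_ids(m), cell_ids(m),
                    donor_group = donor_groups(m), scale = "log")
}

#' Read an analysis configuration from YAML or JSON
#'
#' @param path A \code{.yaml}/\code{.yml} or \code{.json} file holding gene
#'   lists, cross-term pairs, thresholds and seeds.
#' @return A named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}
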