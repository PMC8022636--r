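#' Validate an expression matrix
#'
#' An expression matrix is an n x f numeric matrix: one row per gene (unique
#' row names are the gene identifiers) and one column per measured condition
#' or time point (column names are the feature labels). Values are assumed to
#' be pre-normalized (e.g. log2 ratios); missing or non-numeric entries are
#' rejected rather than imputed.
#'
#' @param values numeric matrix, or an object coercible to one.
#' @param gene_ids optional character vector of row identifiers; defaults to
#'   existing row names.
#' @param feature_labels optional character vector of column labels; defaults
#'   to existing column names.
#' @return the validated numeric matrix with row and column names set.
#' @export
as_expression_matrix <- function(values, gene_ids = NULL, feature_labels = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values))
    stop("expression values must be numeric")
  if (nrow(values) < 2L || ncol(values) < 2L)
    stop("an expression matrix needs at least 2 genes and 2 features")
  if (anyNA(values) || any(!is.finite(values)))
    stop("expression matrix contains missing or non-finite values")
  if (!is.null(gene_ids)) rownames(values) <- as.character(gene_ids)
  if (!is.null(feature_labels)) colnames(values) <- as.character(feature_labels)
  if (is.null(rownames(values)))
    rownames(values) <- paste0("g", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("f", seq_len(ncol(values)))
  if (anyDuplicated(rownames(values))) {
    dup <- rownames(values)[duplicated(rownames(values))][1L]
    stop(sprintf("duplicate gene identifier: '%s'", dup))
  }
  values
}

#' Read an expression matrix from delimited text
#'
#' Reads a header-ed TSV/CSV file shaped like a standard expression table:
#' an identifier column followed by numeric feature columns. The delimiter is
#' never guessed; a silent misparse is worse than an error.
#'
#' @param path file to read.
#' @param delimiter field separator, tab by default.
#' @param id_column 1-based index of the identifier column.
#' @return numeric expression matrix (genes x features) with gene ids as row
#'   names and feature labels as column names, preserving file order.
#' @export
read_expression <- function(path, delimiter = "\t", id_column = 1L) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  nf <- utils::count.fields(path, sep = delimiter, quote = "\"",
                            comment.char = "")
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop(sprintf("ragged row at line %d of '%s': %d fields, expected %d",
                 bad, path, nf[bad], nf[1L]))
  }
  raw <- utils::read.table(path, sep = delimiter, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           comment.char = "", quote = "\"")
  if (ncol(raw) < 3L) stop("expected an id column plus at least 2 feature columns")
  ids <- raw[[id_column]]
  if (anyDuplicated(ids))
    stop(sprintf("duplicate gene identifier: '%s'",
                 ids[duplicated(ids)][1L]))
  num <- raw[, -id_column, drop = FALSE]
  vals <- matrix(NA_real_, nrow(num), ncol(num))
  for (j in seq_len(ncol(num))) {
    v <- suppressWarnings(as.numeric(num[[j]]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1L]
      stop(sprintf("non-numeric value '%s' at row '%s', column '%s'",
                   num[[j]][i], ids[i], colnames(num)[j]))
    }
    vals[, j] <- v
  }
  as_expression_matrix(vals, gene_ids = ids, feature_labels = colnames(num))
}

#' Write an expression matrix as delimited text
#'
#' Values are printed with 17 significant digits so a write-then-read round
#' trip reproduces them bit-identically.
#'
#' @param x expression matrix.
#' @param path output file.
#' @param delimiter field separator.
#' @param id_label header label for the identifier column.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, delimiter = "\t", id_label = "gene") {
  x <- as_expression_matrix(x)
  txt <- format(x, digits = 17, trim = TRUE, scientific = FALSE)
  tab <- cbind(rownames(x), txt)
  colnames(tab) <- c(id_label, colnames(x))
  utils::write.table(tab, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Cluster-ordered (Eisen-style) heatmap export
#'
#' Reorders the rows of an expression matrix so that genes of the same
#' cluster are contiguous — the row ordering used in Eisen-plot heatmaps of
#' co-expressed gene groups. Clusters appear in ascending index order and the
#' input order is preserved within each cluster (a stable permutation: the
#' multiset of rows is unchanged).
#'
#' @param x expression matrix.
#' @param labels integer cluster index per gene (1-based, length `nrow(x)`).
#' @param path optional TSV path; when given, the reordered table (id column,
#'   cluster column, features) is written there.
#' @param png optional PNG path; when given, a raster heatmap of the
#'   reordered matrix is rendered with a blue-white-red palette.
#' @return data.frame with columns `gene`, `cluster`, then the features,
#'   rows in cluster order.
#' @export
cluster_heatmap <- function(x, labels, path = NULL, png = NULL) {
  x <- as_expression_matrix(x)
  labels <- as.integer(labels)
  if (length(labels) != nrow(x))
    stop("labels must have one entry per gene")
  if (any(labels < 1L))
    stop("cluster label out of range: labels are 1-based cluster indices")
  ord <- order(labels, seq_along(labels))
  out <- data.frame(gene = rownames(x)[ord], cluster = labels[ord],
                    x[ord, , drop = FALSE],
                    check.names = FALSE, row.names = NULL)
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  if (!is.null(png)) {
    grDevices::png(png, width = 640, height = 640)
    on.exit(grDevices::dev.off(), add = TRUE)
    pal <- grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(64)
    m <- as.matrix(x[ord, , drop = FALSE])
    graphics::image(t(m)[, rev(seq_len(nrow(m))), drop = FALSE],
                    col = pal, axes = FALSE,
                    main = "cluster-ordered expression")
  }
  out
}
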