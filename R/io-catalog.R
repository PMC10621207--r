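#' Validate and canonicalize a mutation catalog
#'
#' A mutation catalog is a samples x 179 matrix of non-negative integer
#' counts whose columns are the canonical categories from
#' [catalog_categories()] (96 SBS then 83 indel). Columns supplied in any
#' order are reordered; unknown or missing labels are errors.
#'
#' @param counts Numeric matrix with sample rownames and category colnames.
#' @return Integer matrix in canonical column order.
#' @export
as_catalog <- function(counts) {
  counts <- as.matrix(counts)
  canon <- catalog_categories()
  if (is.null(colnames(counts))) {
    stop("catalog must carry category column names", call. = FALSE)
  }
  unknown <- setdiff(colnames(counts), canon)
  if (length(unknown) > 0L) {
    stop("unknown catalog categories: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(canon, colnames(counts))
  if (length(missing) > 0L) {
    stop("catalog is missing ", length(missing), " categories (first: ",
         missing[1], ")", call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate sample ids in catalog", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("catalog counts must be non-negative integers", call. = FALSE)
  }
  out <- counts[, canon, drop = FALSE]
  storage.mode(out) <- "integer"
  out
}

#' Read / write mutation catalogs as TSV
#'
#' The on-disk format is a tab-separated table with a `sample_id` column and
#' one column per category label. `read_catalog(write_catalog(x))` is the
#' identity, and column order on disk is irrelevant (canonicalized on read).
#'
#' @param path File path.
#' @return `read_catalog`: integer matrix as from [as_catalog()].
#' @export
read_catalog <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% colnames(tab)) {
    stop("catalog TSV must have a 'sample_id' column", call. = FALSE)
  }
  m <- as.matrix(tab[, setdiff(colnames(tab), "sample_id"), drop = FALSE])
  rownames(m) <- tab$sample_id
  as_catalog(m)
}

#' @rdname read_catalog
#' @param catalog Catalog matrix.
#' @export
write_catalog <- function(catalog, path) {
  catalog <- as_catalog(catalog)
  tab <- data.frame(sample_id = rownames(catalog), catalog,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene x sample expression matrix
#'
#' Two formats are supported: a TSV with genes in rows (first column gene
#' ids, remaining columns samples), and a MatrixMarket triplet file with
#' sidecar files listing gene and barcode identifiers (one per line).
#' Duplicate gene ids are resolved by keeping the row with the highest total
#' signal, with a warning.
#'
#' @param path Path to the TSV or `.mtx` file.
#' @param format `"tsv"` or `"mtx_triplet"`.
#' @param genes_path,barcodes_path Sidecar paths for `mtx_triplet`; default
#'   to `genes.tsv` / `barcodes.tsv` next to the matrix.
#' @return A base matrix (TSV) or `dgCMatrix` (MTX) with gene rownames and
#'   sample colnames.
#' @export
read_expression <- function(path, format = c("tsv", "mtx_triplet"),
                            genes_path = NULL, barcodes_path = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    genes <- as.character(tab[[1]])
    m <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- genes
  } else {
    m <- Matrix::readMM(path)
    if (is.null(genes_path)) genes_path <- file.path(dirname(path), "genes.tsv")
    if (is.null(barcodes_path)) barcodes_path <- file.path(dirname(path), "barcodes.tsv")
    genes <- readLines(genes_path)
    barcodes <- readLines(barcodes_path)
    if (nrow(m) != length(genes) || ncol(m) != length(barcodes)) {
      stop("MTX dimensions (", nrow(m), " x ", ncol(m),
           ") do not match sidecars (", length(genes), " genes, ",
           length(barcodes), " barcodes)", call. = FALSE)
    }
    m <- methods::as(m, "CsparseMatrix")
    rownames(m) <- genes
    colnames(m) <- barcodes
  }
  dedupe_genes(m)
}

dedupe_genes <- function(m) {
  if (!anyDuplicated(rownames(m))) return(m)
  totals <- Matrix::rowSums(m)
  ord <- order(totals, decreasing = TRUE)
  keep <- ord[!duplicated(rownames(m)[ord])]
  warning(length(ord) - length(keep),
          " duplicate gene id row(s) dropped (kept highest-total rows)",
          call. = FALSE)
  m[sort(keep), , drop = FALSE]
}
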