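#' Read a molecule table from TSV
#'
#' The molecule-table dialect is a plain TSV with header columns
#' \code{barcode}, \code{umi}, \code{gene}, \code{reads}; the literal gene
#' token \code{"-"} marks molecules that mapped to more than one gene
#' (ambiguous records are preserved here and discarded by
#' [buildCUHistograms()]). Plain and gzip-compressed (.gz) files are
#' supported.
#'
#' @param path path to the TSV file.
#' @return A [MoleculeTable-class].
#' @seealso [writeMoleculeTable()]
#' @export
readMoleculeTable <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character",
                          quote = "", comment.char = "")
  req <- c("barcode", "umi", "gene", "reads")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop(sprintf("molecule table '%s' is missing column(s): %s",
                 path, paste(miss, collapse = ", ")))
  reads <- suppressWarnings(as.integer(df$reads))
  if (anyNA(reads))
    stop(sprintf("molecule table '%s': non-integer read count at row %d",
                 path, which(is.na(reads))[1L]))
  if (any(reads < 1L))
    stop(sprintf("molecule table '%s': read count < 1 at row %d",
                 path, which(reads < 1L)[1L]))
  MoleculeTable(df$barcode, df$umi, df$gene, reads)
}

#' Write a molecule table to TSV
#'
#' @param table a [MoleculeTable-class].
#' @param path output path (".gz" suffix writes gzip).
#' @return \code{path}, invisibly.
#' @export
writeMoleculeTable <- function(table, path) {
  stopifnot(is(table, "MoleculeTable"))
  con <- openOut(path)
  on.exit(close(con))
  utils::write.table(table@records, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

openOut <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
}

#' Read a sparse gene-by-cell UMI count matrix
#'
#' Reads MatrixMarket coordinate format plus one-column gene and barcode
#' label files (the 10x-style mtx/genes/barcodes triplet). The total UMI
#' count is always recomputed from the entries, never trusted from metadata.
#'
#' @param mtx path to the MatrixMarket file.
#' @param genes path to the gene labels, one per line.
#' @param barcodes path to the cell barcode labels, one per line.
#' @return A [Matrix::dgCMatrix-class] with genes as rownames and barcodes
#'   as colnames.
#' @export
readCountMatrix <- function(mtx, genes, barcodes) {
  m <- as(Matrix::readMM(mtx), "CsparseMatrix")
  g <- readLines(genes)
  b <- readLines(barcodes)
  if (length(g) != nrow(m))
    stop(sprintf("gene labels (%d) do not match matrix rows (%d)",
                 length(g), nrow(m)))
  if (length(b) != ncol(m))
    stop(sprintf("barcode labels (%d) do not match matrix columns (%d)",
                 length(b), ncol(m)))
  dimnames(m) <- list(g, b)
  m
}

#' Write a sparse count matrix as MatrixMarket plus label files
#'
#' Written in coordinate real general format with 1-based indices; fractional
#' (corrected) entries are allowed.
#'
#' @param matrix a genes-by-cells matrix with dimnames.
#' @param mtx,genes,barcodes output paths.
#' @return \code{mtx}, invisibly.
#' @export
writeCountMatrix <- function(matrix, mtx, genes, barcodes) {
  m <- as(as(matrix, "dMatrix"), "CsparseMatrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("count matrix must carry gene rownames and barcode colnames")
  Matrix::writeMM(m, mtx)
  writeLines(rownames(m), genes)
  writeLines(colnames(m), barcodes)
  invisible(mtx)
}

#' Total UMIs in a count matrix
#'
#' @param matrix a genes-by-cells count matrix.
#' @return The grand total of all entries.
#' @export
totalUMIs <- function(matrix) sum(matrix)

#' Read per-gene CU histograms from a long-format TSV
#'
#' Expected columns: \code{gene}, \code{copies}, \code{molecules}. Copy
#' levels must be >= 1; molecule counts may be fractional.
#'
#' @param path path to the TSV.
#' @return A [CUHistogramList-class] named by gene.
#' @seealso [writeCUHistograms()]
#' @export
readCUHistograms <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "",
                          colClasses = c(gene = "character"))
  req <- c("gene", "copies", "molecules")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop(sprintf("histogram file '%s' is missing column(s): %s",
                 path, paste(miss, collapse = ", ")))
  if (nrow(df) && any(df$copies < 1))
    stop(sprintf("histogram file '%s': copy level < 1 at row %d",
                 path, which(df$copies < 1)[1L]))
  hl <- lapply(split(df, df$gene), function(d)
    CUHistogram(d$molecules, copies = d$copies, gene = d$gene[1L]))
  CUHistogramList(hl)
}

#' Write per-gene CU histograms to a long-format TSV
#'
#' Copy levels with zero molecules are omitted.
#'
#' @param hists a [CUHistogramList-class] or named list of
#'   [CUHistogram-class].
#' @param path output path (".gz" suffix writes gzip).
#' @return \code{path}, invisibly.
#' @export
writeCUHistograms <- function(hists, path) {
  rows <- lapply(hists, function(h) {
    keep <- h@molecules != 0
    data.frame(gene = h@gene, copies = h@copies[keep],
               molecules = h@molecules[keep], stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(df))
    df <- data.frame(gene = character(0), copies = integer(0),
                     molecules = numeric(0))
  con <- openOut(path)
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}
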