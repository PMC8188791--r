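#' Build per-gene CU histograms and the UMI count matrix
#'
#' Molecules mapping to more than one gene (gene \code{"-"}) are discarded.
#' For each remaining gene the copies-per-UMI histogram pools molecules
#' across all cells, and the count matrix entry (gene, cell) is the number of
#' distinct molecules of that gene in that cell. When \code{minCellUMIs} is
#' set, cells are filtered on the matrix first and histograms are built from
#' the surviving cells only, so that histogram totals always match matrix row
#' sums.
#'
#' @param table a [MoleculeTable-class].
#' @param minCellUMIs optional minimum UMIs per cell (see [filterCells()]);
#'   \code{NULL} keeps all cells.
#' @return A list with elements \code{histograms} (a
#'   [CUHistogramList-class]) and \code{matrix} (sparse genes-by-cells
#'   dgCMatrix).
#' @examples
#' tab <- MoleculeTable(rep("c1", 3), c("u1", "u2", "u3"), rep("A", 3),
#'                      c(1L, 1L, 3L))
#' buildCUHistograms(tab)$histograms[["A"]]
#' @export
buildCUHistograms <- function(table, minCellUMIs = NULL) {
  stopifnot(is(table, "MoleculeTable"))
  df <- table@records
  df <- df[df$gene != "-", , drop = FALSE]
  if (!nrow(df)) {
    warning("no unambiguous molecules left; returning empty outputs")
    return(list(histograms = CUHistogramList(list()),
                matrix = emptyCountMatrix()))
  }
  genes <- sort(unique(df$gene))
  cells <- sort(unique(df$barcode))
  mat <- Matrix::sparseMatrix(
    i = match(df$gene, genes), j = match(df$barcode, cells),
    x = 1, dims = c(length(genes), length(cells)),
    dimnames = list(genes, cells))
  mat <- as(mat, "CsparseMatrix")
  if (!is.null(minCellUMIs)) {
    mat <- filterCells(mat, minCellUMIs)
    df <- df[df$barcode %in% colnames(mat), , drop = FALSE]
    if (!nrow(df)) {
      warning("no molecules left after cell filtering")
      return(list(histograms = CUHistogramList(list()), matrix = mat))
    }
    genes <- rownames(mat)
  }
  hl <- lapply(split(df$reads, factor(df$gene, levels = genes)), function(r) {
    tab <- table(r)
    CUHistogram(as.numeric(tab), copies = as.integer(names(tab)))
  })
  for (g in names(hl)) hl[[g]]@gene <- g
  list(histograms = CUHistogramList(hl), matrix = mat)
}

emptyCountMatrix <- function() {
  Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                       dims = c(0L, 0L),
                       dimnames = list(character(0), character(0)))
}

#' Filter cells by total UMI count
#'
#' Keeps cells whose column sum is at least \code{minUMIs} (inclusive: the
#' usual quality filter drops cells with \emph{fewer} than the threshold).
#'
#' @param matrix genes-by-cells count matrix.
#' @param minUMIs minimum UMIs per retained cell (default 200).
#' @return The matrix restricted to surviving columns.
#' @export
filterCells <- function(matrix, minUMIs = 200) {
  stopifnot(minUMIs >= 1)
  keep <- Matrix::colSums(matrix) >= minUMIs
  if (!any(keep)) warning("all cells removed by the UMI filter")
  matrix[, keep, drop = FALSE]
}

#' Filter genes by total molecule count
#'
#' Keeps genes whose histogram mass N is at least \code{minMolecules}. Use
#' 200 for cross-dataset saturation comparisons and 30 for within-dataset
#' FSCM distributions; low-N histograms give unstable metrics and
#' predictions.
#'
#' @param hists a [CUHistogramList-class].
#' @param minMolecules minimum molecules per retained gene.
#' @return The filtered [CUHistogramList-class].
#' @export
filterGenesByMolecules <- function(hists, minMolecules) {
  stopifnot(minMolecules >= 1)
  keep <- nMolecules(hists) >= minMolecules
  CUHistogramList(as.list(hists)[keep])
}

#' @rdname saturationMetrics
#' @export
setMethod("saturationMetrics", "CUHistogram", function(x, ...) {
  n <- nMolecules(x)
  if (n <= 0)
    stop(sprintf("saturation metrics undefined for empty histogram (gene '%s')",
                 x@gene))
  h1 <- sum(x@molecules[x@copies == 1L])
  h2 <- sum(x@molecules[x@copies == 2L])
  fscm <- h1 / n
  fdcm <- h2 / n
  c(fscm = fscm, fdcm = fdcm, fmcm = 1 - fscm - fdcm, nUMIs = n)
})

#' @rdname saturationMetrics
#' @export
setMethod("saturationMetrics", "CUHistogramList", function(x, ...) {
  m <- t(vapply(x, saturationMetrics, numeric(4)))
  data.frame(gene = names(x), fscm = m[, "fscm"], fdcm = m[, "fdcm"],
             fmcm = m[, "fmcm"], nUMIs = m[, "nUMIs"],
             row.names = NULL, stringsAsFactors = FALSE)
})
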