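#' Counts per million
#'
#' Scales per-gene totals so that they sum to 1e6 over the included genes.
#' When genes are filtered (e.g. the 100-CPM floor used before computing
#' concordance), CPM must be recomputed over the surviving genes only, which
#' \code{includeGenes} does in one step.
#'
#' @param geneTotals named nonnegative numeric vector of per-gene totals (or
#'   CPM values to be rescaled).
#' @param includeGenes optional character vector of genes to keep.
#' @return named numeric vector summing to 1e6.
#' @export
toCPM <- function(geneTotals, includeGenes = NULL) {
  if (!is.null(includeGenes)) {
    stopifnot(length(includeGenes) > 0)
    geneTotals <- geneTotals[intersect(names(geneTotals), includeGenes)]
  }
  tot <- sum(geneTotals)
  if (tot <= 0) stop("cannot compute CPM: total count is zero")
  1e6 * geneTotals / tot
}

#' Mean per-cell gene expression of a count matrix, in CPM
#'
#' Each cell is CPM-normalized, then expression is averaged across cells
#' (the convention used for all dataset-level expression profiles here).
#' Cells with zero totals are excluded from the mean.
#'
#' @param matrix genes-by-cells count matrix.
#' @return named numeric vector of mean CPM per gene.
#' @export
meanExpression <- function(matrix) {
  cs <- Matrix::colSums(matrix)
  keep <- cs > 0
  if (!any(keep)) stop("no cells with nonzero totals")
  m <- matrix[, keep, drop = FALSE]
  v <- 1e6 * as.numeric(m %*% (1 / cs[keep])) / sum(keep)
  names(v) <- rownames(matrix)
  v
}

#' Drop low-expression genes and recompute CPM
#'
#' Genes below \code{minCPM} give unstable unseen-molecule predictions; they
#' are removed and CPM is recomputed over the remaining genes.
#'
#' @param cpm named CPM vector.
#' @param minCPM floor (default 100).
#' @return named CPM vector over the surviving genes, re-summing to 1e6.
#' @export
filterByCPM <- function(cpm, minCPM = 100) {
  keep <- cpm >= minCPM
  if (!any(keep)) stop("all genes fall below the CPM floor")
  toCPM(cpm[keep])
}

#' Lin's concordance correlation coefficient
#'
#' Measures agreement with the identity line: unlike Pearson correlation it
#' penalizes location and scale shifts, not just decorrelation:
#' \deqn{CCC = \frac{2\,cov(a,b)}{var(a) + var(b) + (\bar a - \bar b)^2}}
#' with population (1/n) moments. Equals 1 iff a = b elementwise.
#'
#' @param a,b numeric vectors of equal length >= 2, on the same scale
#'   (log2(CPM+1) throughout the correction pipeline).
#' @return number in [-1, 1]. When both vectors are constant the value is 1
#'   if the constants agree and 0 otherwise.
#' @examples
#' ccc(c(1, 2, 3), c(2, 3, 4))  # 4/7
#' @export
ccc <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  n <- length(a)
  ma <- mean(a); mb <- mean(b)
  va <- sum((a - ma)^2) / n
  vb <- sum((b - mb)^2) / n
  if (va + vb == 0) return(if (ma == mb) 1 else 0)
  cab <- sum((a - ma) * (b - mb)) / n
  2 * cab / (va + vb + (ma - mb)^2)
}

#' Mean squared error
#'
#' @param a,b numeric vectors of equal length.
#' @return mean of squared differences.
#' @export
mse <- function(a, b) {
  stopifnot(length(a) == length(b))
  mean((a - b)^2)
}

#' Mann-Whitney AUC
#'
#' Area under the ROC curve computed as the normalized Mann-Whitney
#' U statistic: the probability that a randomly chosen positive outranks a
#' randomly chosen negative, ties counting one half.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels logical or 0/1 vector; both classes must be present.
#' @return number in [0, 1].
#' @export
mwAUC <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(labels))
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be present to compute an AUC")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
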