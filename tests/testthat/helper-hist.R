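# build a CU histogram from raw per-molecule read counts (zeros dropped)
histFromCounts <- function(x, gene = NA_character_) {
  x <- x[x > 0]
  tb <- table(x)
  CUHistogram(as.numeric(tb), copies = as.integer(names(tb)), gene = gene)
}

# random histogram list with NB-ish shapes, for round-trip / filter oracles
randomHistList <- function(nGenes, seed, maxN = 500) {
  set.seed(seed)
  hl <- lapply(seq_len(nGenes), function(k) {
    n <- sample.int(maxN, 1L) + 20L
    histFromCounts(stats::rnbinom(n, mu = stats::runif(1, 0.5, 6), size = 1),
                   gene = sprintf("g%04d", k))
  })
  names(hl) <- vapply(hl, geneName, character(1))
  CUHistogramList(hl)
}

# small random sparse integer count matrix with dimnames
randomCountMatrix <- function(nGenes, nCells, seed, density = 0.2) {
  set.seed(seed)
  nnz <- max(1L, round(nGenes * nCells * density))
  ij <- unique(cbind(sample.int(nGenes, nnz, replace = TRUE),
                     sample.int(nCells, nnz, replace = TRUE)))
  m <- Matrix::sparseMatrix(i = ij[, 1], j = ij[, 2],
                            x = sample.int(50, nrow(ij), replace = TRUE),
                            dims = c(nGenes, nCells),
                            dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                                            sprintf("c%03d", seq_len(nCells))))
  as(m, "CsparseMatrix")
}
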