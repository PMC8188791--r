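#' Predict per-gene molecule counts from CU histograms
#'
#' Runs the chosen unseen-molecule estimator on every gene's histogram,
#' pooled across all cells. Genes whose histograms are degenerate (too few
#' molecules or copy levels) or for which the estimator is unstable keep
#' their observed count and are flagged as not applied.
#'
#' @param hists a [CUHistogramList-class].
#' @param method "ztnb" (default), "ds" or "gt".
#' @param t extrapolation factor >= 0.
#' @param mt DS truncation level (default 2).
#' @param minMolecules ZTNB minimum molecules (default 20).
#' @param allowExtrapolation passed to [goodToulmin()].
#' @return data.frame with columns gene, N, cG (predicted distinct
#'   molecules) and applied.
#' @export
predictGeneCounts <- function(hists, method = c("ztnb", "ds", "gt"), t,
                              mt = 2L, minMolecules = 20,
                              allowExtrapolation = FALSE) {
  method <- match.arg(method)
  stopifnot(t >= 0)
  res <- lapply(hists, function(h) {
    N <- nMolecules(h)
    pred <- tryCatch({
      switch(method,
        ztnb = ztnbPredict(ztnbFit(h, minMolecules = minMolecules), t),
        ds = dsPredict(h, t, mt = mt),
        gt = goodToulmin(h, t, allowExtrapolation = allowExtrapolation))
    },
      umisat_degenerate_histogram = function(e) NULL,
      umisat_estimator_unstable = function(e) NULL)
    if (is.null(pred)) c(N = N, cG = N, applied = 0)
    else c(N = N, cG = pred@distinct, applied = 1)
  })
  m <- do.call(rbind, res)
  data.frame(gene = names(hists), N = m[, "N"], cG = m[, "cG"],
             applied = m[, "applied"] == 1, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Scale a count matrix by per-gene unseen-molecule predictions
#'
#' Each gene's row is rescaled so that its new total equals
#' \eqn{m_g = (T/P) c_g}, where T is the observed grand total, P the sum of
#' predicted counts and \eqn{c_g} the gene's prediction. Scaling by T/P keeps
#' the corrected matrix on the observed sequencing-depth scale: its grand
#' total equals T, so corrected counts remain directly CPM-comparable with
#' the input.
#'
#' @param matrix genes-by-cells count matrix with gene rownames.
#' @param predictions data.frame from [predictGeneCounts()] (columns gene,
#'   cG; N and applied are carried through when present) or a named numeric
#'   vector of \eqn{c_g}.
#' @param method,t provenance recorded in the result.
#' @return list with the corrected \code{matrix} (fractional entries) and a
#'   [CorrectionResult-class] \code{result}.
#' @export
applyCorrection <- function(matrix, predictions, method = NA_character_,
                            t = NA_real_) {
  if (is.numeric(predictions))
    predictions <- data.frame(gene = names(predictions), cG = predictions,
                              stringsAsFactors = FALSE)
  genes <- rownames(matrix)
  idx <- match(genes, predictions$gene)
  if (anyNA(idx))
    stop(sprintf("no prediction for gene(s): %s",
                 paste(utils::head(genes[is.na(idx)], 5), collapse = ", ")))
  cG <- predictions$cG[idx]
  rowTot <- Matrix::rowSums(matrix)
  if (any(cG < rowTot - 1e-9 * pmax(rowTot, 1)))
    warning("some predicted counts fall below observed totals; ",
            "estimators should only add molecules - check the caller")
  T <- sum(rowTot)
  P <- sum(cG)
  if (P <= 0) stop("total predicted count must be positive")
  mG <- (T / P) * cG
  scale <- ifelse(rowTot > 0, mG / rowTot, 1)
  corrected <- Matrix::Diagonal(x = scale) %*% matrix
  dimnames(corrected) <- dimnames(matrix)
  corrected <- as(corrected, "CsparseMatrix")
  applied <- if ("applied" %in% names(predictions))
    predictions$applied[idx] else rep(TRUE, length(idx))
  res <- new("CorrectionResult",
             perGene = data.frame(gene = genes, N = rowTot, cG = cG, mG = mG,
                                  applied = applied, row.names = NULL,
                                  stringsAsFactors = FALSE),
             totalObserved = T, totalPredicted = P,
             method = method, t = t)
  list(matrix = corrected, result = res)
}

#' Map one vector of values onto the quantiles of another
#'
#' Each source value is sent through the source empirical CDF to the target
#' empirical quantile function (linear interpolation between order
#' statistics). With equal lengths the output's order statistics are exactly
#' the target's; ranks of the source are preserved. Used to align saturation
#' metrics (FSCM/FDCM) of pool-source datasets with the dataset being
#' predicted before pooling.
#'
#' @param source,target nonempty numeric vectors.
#' @return numeric vector, same length and rank order as \code{source}.
#' @export
quantileNormalize <- function(source, target) {
  stopifnot(length(source) > 0, length(target) > 0)
  n <- length(source)
  r <- rank(source, ties.method = "first")
  probs <- if (n == 1L) 0.5 else (r - 1) / (n - 1)
  as.numeric(stats::quantile(target, probs = probs, type = 7, names = FALSE))
}

#' Pool per-gene saturation metrics across datasets into 3-bin histograms
#'
#' Sparse per-gene histograms in a single dataset make prediction unstable;
#' borrowing information from similar datasets mitigates this. Source
#' datasets' FSCM/FDCM are first quantile-normalized to the target (the
#' datasets differ in saturation), then pooled with the target by a per-gene
#' UMI-weighted mean. The third fraction is FMCM = 1 - FSCM - FDCM (floored
#' at 0 and renormalized if normalization pushed the sum above 1). Each gene
#' gets a 3-bin histogram \{1: fscm n, 2: fdcm n, 3: fmcm n\} with n the
#' target's UMI count, suitable for [dsPredict()] with mt = 2.
#'
#' @param target data.frame with columns gene, fscm, fdcm, nUMIs (e.g. from
#'   \code{saturationMetrics()} on a [CUHistogramList-class]).
#' @param sources list of data.frames with the same columns.
#' @param normalize quantile-normalize sources to the target first
#'   (default TRUE).
#' @return A [CUHistogramList-class] of 3-bin histograms, one per target
#'   gene.
#' @export
poolHistograms <- function(target, sources = list(), normalize = TRUE) {
  req <- c("gene", "fscm", "fdcm", "nUMIs")
  stopifnot(all(req %in% names(target)),
            all(vapply(sources, function(s) all(req %in% names(s)),
                       logical(1))))
  if (normalize)
    sources <- lapply(sources, function(s) {
      s$fscm <- quantileNormalize(s$fscm, target$fscm)
      s$fdcm <- quantileNormalize(s$fdcm, target$fdcm)
      s
    })
  all <- c(list(target), sources)
  hl <- lapply(seq_len(nrow(target)), function(k) {
    g <- target$gene[k]
    rows <- do.call(rbind, lapply(all, function(s)
      s[s$gene == g, req, drop = FALSE]))
    w <- rows$nUMIs
    if (sum(w) <= 0) w <- rep(1, nrow(rows))
    fscm <- sum(w * rows$fscm) / sum(w)
    fdcm <- sum(w * rows$fdcm) / sum(w)
    fmcm <- max(1 - fscm - fdcm, 0)
    bins <- c(fscm, fdcm, fmcm)
    bins <- bins / sum(bins)
    n <- target$nUMIs[k]
    CUHistogram(bins * n, copies = 1:3, gene = g)
  })
  names(hl) <- target$gene
  CUHistogramList(hl)
}

#' Analytic binomial downsampling of a CU histogram
#'
#' Computes the expected histogram after each read survives independently
#' with probability x: \eqn{h'(j) = \sum_i dbinom(j, i, x) h(i)}. Unlike
#' random read subsampling this is noise-free. The zero bin h'(0) is the
#' expected number of molecules lost; the surviving molecule count is
#' \eqn{n = \sum_{j \ge 1} h'(j)}. Reads are conserved in expectation:
#' \eqn{\sum_j j h'(j) = x \sum_i i h(i)}.
#'
#' @param h a [CUHistogram-class].
#' @param x retained-read fraction in (0, 1].
#' @return list with \code{histogram} (the j >= 1 part, fractional
#'   molecule counts), \code{lost} (h'(0)) and \code{n}.
#' @examples
#' binomialDownsampleHist(CUHistogram(c(`2` = 10)), 0.5)$n  # 7.5
#' @export
binomialDownsampleHist <- function(h, x) {
  stopifnot(is(h, "CUHistogram"))
  if (x <= 0 || x > 1) stop("retained-read fraction x must be in (0, 1]")
  if (!length(h@copies))
    return(list(histogram = h, lost = 0, n = 0))
  maxI <- max(h@copies)
  j <- 0:maxI
  P <- outer(j, h@copies, function(jj, ii)
    stats::dbinom(jj, size = ii, prob = x))
  hp <- as.numeric(P %*% h@molecules)
  keep <- j >= 1L & hp > 0
  list(histogram = CUHistogram(hp[keep], copies = j[keep], gene = h@gene),
       lost = hp[1L], n = sum(hp[j >= 1L]))
}

## expected surviving molecules after binomial thinning at fraction x;
## closed form for the j >= 1 mass of binomialDownsampleHist (a molecule with
## i copies survives with probability 1 - (1-x)^i).
survivingMolecules <- function(copies, molecules, x) {
  sum(molecules * (1 - (1 - x)^as.numeric(copies)))
}

#' Batch-correct a deeper dataset toward a shallower one
#'
#' Two datasets with similar per-gene amplification but different reads per
#' molecule show a depth-driven batch effect: extra reads find new molecules
#' at gene-specific rates. Rather than extrapolating the shallow dataset,
#' the deeper one is analytically downsampled: every gene's CU histogram is
#' binomially thinned at read fraction x, CPM is recomputed, and each gene's
#' entries are multiplied by \eqn{f_g = e_{a,g}/e_{b,g}} (CPM after / CPM
#' before). With \code{x = "auto"} the fraction is scanned over
#' 0.01, 0.02, ..., 1.00 and the x maximizing Lin's CCC between the two
#' datasets' mean log2(CPM+1) profiles (on shared genes) is chosen, smallest
#' x on ties.
#'
#' @param deepMatrix genes-by-cells count matrix of the more saturated
#'   dataset.
#' @param deepHists [CUHistogramList-class] for the deep dataset's genes.
#' @param shallowMatrix count matrix of the less saturated dataset (used only
#'   to drive the CCC grid search and reporting).
#' @param x retained-read fraction in (0, 1], or "auto".
#' @return list with the corrected deep \code{matrix} and a
#'   [DownsampleCorrection-class] \code{correction}.
#' @export
batchCorrect <- function(deepMatrix, deepHists, shallowMatrix, x = "auto") {
  genes <- rownames(deepMatrix)
  hl <- as.list(deepHists)[intersect(names(deepHists), genes)]
  cp <- lapply(hl, function(h) h@copies)
  ml <- lapply(hl, function(h) h@molecules)
  N <- setNames(numeric(length(genes)), genes)
  N[names(hl)] <- vapply(hl, nMolecules, numeric(1))
  shared <- intersect(genes, rownames(shallowMatrix))

  fAt <- function(xx) {
    n <- N
    n[names(hl)] <- mapply(survivingMolecules, cp, ml,
                           MoreArgs = list(x = xx))
    eB <- 1e6 * N / sum(N)
    eA <- 1e6 * n / sum(n)
    f <- ifelse(N > 0, eA / eB, 1)
    list(f = f, eB = eB, eA = eA)
  }
  grid <- data.frame(x = numeric(0), ccc = numeric(0))
  if (identical(x, "auto")) {
    if (length(shared) < 2L)
      stop("AUTO grid search needs at least 2 shared genes")
    shallowProf <- meanExpression(shallowMatrix)
    cccAt <- function(xx) {
      f <- fAt(xx)$f
      prof <- meanExpression(Matrix::Diagonal(x = f) %*% deepMatrix)
      names(prof) <- genes
      ccc(log2(prof[shared] + 1), log2(shallowProf[shared] + 1))
    }
    xs <- seq(0.01, 1, by = 0.01)
    cccs <- vapply(xs, cccAt, numeric(1))
    grid <- data.frame(x = xs, ccc = cccs)
    x <- xs[which.max(cccs)]   # which.max takes the first (smallest x) tie
    chosenBy <- "ccc-grid"
  } else {
    if (!is.numeric(x) || x <= 0 || x > 1)
      stop("x must be in (0, 1] or \"auto\"")
    chosenBy <- "fixed"
  }
  res <- fAt(x)
  corrected <- Matrix::Diagonal(x = res$f) %*% deepMatrix
  dimnames(corrected) <- dimnames(deepMatrix)
  corrected <- as(corrected, "CsparseMatrix")
  corr <- new("DownsampleCorrection", x = x,
              perGene = data.frame(gene = genes, cpmBefore = res$eB,
                                   cpmAfter = res$eA, fG = res$f,
                                   row.names = NULL,
                                   stringsAsFactors = FALSE),
              chosenBy = chosenBy, cccGrid = grid)
  list(matrix = corrected, correction = corr)
}
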