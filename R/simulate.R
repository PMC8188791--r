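#' Simulate per-molecule read counts for one gene
#'
#' Each of the gene's molecules is amplified and sequenced independently; the
#' observed read count per molecule follows a negative binomial with
#' gene-specific mean (amplification level) and size (dispersion). Molecules
#' drawing zero reads exist in the library but are invisible after UMI
#' collapsing — they are returned here so generators can keep ground truth.
#'
#' @param nMolecules number of true distinct molecules.
#' @param nbMean NB mean (> 0), the expected reads per molecule.
#' @param nbSize NB size/dispersion (> 0).
#' @param seed optional integer seed.
#' @return integer vector of length \code{nMolecules}, zeros included.
#' @export
simulateGene <- function(nMolecules, nbMean, nbSize, seed = NULL) {
  stopifnot(nMolecules >= 0, nbMean > 0, nbSize > 0)
  if (!is.null(seed)) set.seed(seed)
  stats::rnbinom(nMolecules, mu = nbMean, size = nbSize)
}

#' Specification of a simulated UMI dataset
#'
#' @param genes data.frame with columns gene, nMolecules, nbMean, nbSize.
#' @param nCells number of cells; molecules are allocated to cells by a
#'   multinomial draw with \code{cellWeights} (uniform by default).
#' @param readFraction sequencing depth as a fraction of the generated reads,
#'   in (0, 1]; applied as independent binomial thinning per molecule.
#' @param seed integer seed driving every random draw of the dataset.
#' @param umiLength UMI length in bases (default 12).
#' @param cellWeights optional per-cell allocation weights.
#' @return a validated list of class \code{simSpec}.
#' @seealso [simulateDataset()]
#' @export
simSpec <- function(genes, nCells = 1L, readFraction = 1, seed = 1L,
                    umiLength = 12L, cellWeights = NULL) {
  stopifnot(is.data.frame(genes),
            all(c("gene", "nMolecules", "nbMean", "nbSize") %in%
                  names(genes)),
            all(genes$nMolecules >= 0), all(genes$nbMean > 0),
            all(genes$nbSize > 0), nCells >= 1,
            readFraction > 0, readFraction <= 1, umiLength >= 1)
  if (!is.null(cellWeights)) stopifnot(length(cellWeights) == nCells,
                                       all(cellWeights >= 0))
  structure(list(genes = genes, nCells = as.integer(nCells),
                 readFraction = readFraction, seed = as.integer(seed),
                 umiLength = as.integer(umiLength),
                 cellWeights = cellWeights),
            class = "simSpec")
}

randomUMIs <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE),
              nrow = n)
  apply(m, 1L, paste0, collapse = "")
}

#' Simulate a UMI-collapsed molecule table with ground truth
#'
#' For every gene, molecule read counts are drawn from the gene's negative
#' binomial amplification model, molecules are allocated to cells, distinct
#' UMIs are generated per molecule (collisions within a cell-gene group are
#' redrawn), and reads are thinned to \code{readFraction} by binomial
#' sampling per molecule. Molecules with zero surviving reads are dropped
#' from the observed table but tracked in the ground truth.
#'
#' @param spec a [simSpec()].
#' @return list with \code{table} (a [MoleculeTable-class] of observed
#'   molecules) and \code{truth}, a data.frame with one row per gene:
#'   nMolecules (true), ampReads (reads before thinning), ampNonzero
#'   (molecules with >= 1 read before thinning), observedMolecules,
#'   observedReads.
#' @export
simulateDataset <- function(spec) {
  stopifnot(inherits(spec, "simSpec"))
  set.seed(spec$seed)
  g <- spec$genes
  ## collision guard: probability of any UMI collision within the largest
  ## cell-gene group must stay below 1% (birthday bound), else redrawing
  ## masks a biased UMI distribution
  expPerCell <- max(g$nMolecules) / spec$nCells
  kMax <- expPerCell + 6 * sqrt(max(expPerCell, 1))
  if (1 - exp(-kMax^2 / (2 * 4^spec$umiLength)) > 0.01)
    stop("UMI collision risk above 1% for the requested molecule counts; ",
         "increase umiLength")
  weights <- spec$cellWeights
  if (is.null(weights)) weights <- rep(1, spec$nCells)
  cellIds <- sprintf("cell%0*d", nchar(spec$nCells), seq_len(spec$nCells))

  rows <- vector("list", nrow(g))
  truth <- g
  truth$ampReads <- 0
  truth$ampNonzero <- 0L
  truth$observedMolecules <- 0L
  truth$observedReads <- 0
  for (k in seq_len(nrow(g))) {
    n <- g$nMolecules[k]
    amp <- stats::rnbinom(n, mu = g$nbMean[k], size = g$nbSize[k])
    obs <- stats::rbinom(n, size = amp, prob = spec$readFraction)
    truth$ampReads[k] <- sum(as.numeric(amp))
    truth$ampNonzero[k] <- sum(amp > 0L)
    seen <- obs > 0L
    truth$observedMolecules[k] <- sum(seen)
    truth$observedReads[k] <- sum(as.numeric(obs[seen]))
    if (!any(seen)) next
    cell <- sample.int(spec$nCells, sum(seen), replace = TRUE,
                       prob = weights)
    umi <- randomUMIs(sum(seen), spec$umiLength)
    ## redraw UMI collisions within each (cell, gene) group
    repeat {
      dup <- duplicated(paste(cell, umi))
      if (!any(dup)) break
      umi[dup] <- randomUMIs(sum(dup), spec$umiLength)
    }
    rows[[k]] <- data.frame(barcode = cellIds[cell], umi = umi,
                            gene = g$gene[k], reads = obs[seen],
                            stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, c(rows[!vapply(rows, is.null, logical(1))],
                         list(make.row.names = FALSE)))
  if (is.null(df))
    df <- data.frame(barcode = character(0), umi = character(0),
                     gene = character(0), reads = integer(0))
  list(table = MoleculeTable(df$barcode, df$umi, df$gene, df$reads),
       truth = truth)
}

#' Randomly subsample reads in a molecule table
#'
#' Each molecule's read count is replaced by a Binomial(reads, fraction)
#' draw; molecules losing all reads are removed. This is the stochastic
#' counterpart of [binomialDownsampleHist()].
#'
#' @param table a [MoleculeTable-class].
#' @param fraction retained-read fraction in (0, 1].
#' @param seed optional integer seed.
#' @return a [MoleculeTable-class].
#' @export
downsampleReads <- function(table, fraction, seed = NULL) {
  stopifnot(is(table, "MoleculeTable"), fraction > 0, fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  df <- table@records
  df$reads <- stats::rbinom(nrow(df), size = df$reads, prob = fraction)
  df <- df[df$reads > 0L, , drop = FALSE]
  MoleculeTable(df$barcode, df$umi, df$gene, df$reads)
}

#' Differential-expression benchmark under amplification bias
#'
#' Generates gene pairs where half are truly differentially expressed by
#' \code{foldChange}, with per-gene amplification levels (NB means) drawn
#' from \code{amplificationSampler}, and reports per-pair detection scores
#' (absolute log2 expression ratios) before and after correction, ready for
#' [mwAUC()] against the true labels.
#'
#' Two scenarios:
#' \describe{
#' \item{"amplification"}{Both genes of a pair live in one dataset; their
#'   amplification levels are drawn independently, so uncorrected counts
#'   confound expression with amplification. Scores are reported for
#'   uncorrected counts and for ZTNB- and DS-corrected library-size
#'   estimates (extrapolated to saturation).}
#' \item{"batch"}{One gene per pair, measured in two batches whose read
#'   depths differ by \code{depthRatio} but share the gene's amplification.
#'   Reported are signed log2 CPM fold changes across batches (lfc columns),
#'   uncorrected and after binomial downsampling of the deeper batch at
#'   x = depthRatio, plus their absolute values. CPM renormalization shifts
#'   every gene's fold change when a sizable fraction of genes is truly DE,
#'   so detection in this scenario should score the signed lfc; the per-gene
#'   amplification is returned so false-positive structure (apparent DE
#'   driven by amplification, visible in the truly-equal genes' lfc) can be
#'   quantified.}
#' }
#'
#' @param nPairs number of gene pairs (default 100; half truly DE).
#' @param foldChange true expression fold change of DE pairs (> 1).
#' @param baseMolecules true molecules of a non-elevated gene (default 2000).
#' @param nbSize NB dispersion of the amplification model (default 1).
#' @param scenario "amplification" or "batch".
#' @param depthRatio batch scenario: the shallow batch's read fraction
#'   relative to the deep one (default 0.5).
#' @param amplificationSampler function(n) returning n NB means; default
#'   log-uniform on [0.5, 16].
#' @param seed integer seed.
#' @return data.frame with one row per pair: \code{trueDE} plus, for the
#'   amplification scenario, scoreUncorrected / scoreZTNB / scoreDS; for the
#'   batch scenario, amp, lfcUncorrected / lfcDownsampled and the
#'   corresponding absolute scores.
#' @export
simulateDEBenchmark <- function(nPairs = 100L, foldChange = 2,
                                baseMolecules = 2000L, nbSize = 1,
                                scenario = c("amplification", "batch"),
                                depthRatio = 0.5,
                                amplificationSampler = NULL, seed = 1L) {
  scenario <- match.arg(scenario)
  stopifnot(foldChange > 1, nPairs >= 2, baseMolecules > 0)
  if (is.null(amplificationSampler))
    amplificationSampler <- function(n) exp(stats::runif(n, log(0.5),
                                                         log(16)))
  set.seed(seed)
  trueDE <- rep(c(TRUE, FALSE), length.out = nPairs)[sample.int(nPairs)]

  histOf <- function(counts) {
    counts <- counts[counts > 0L]
    tab <- table(counts)
    CUHistogram(as.numeric(tab), copies = as.integer(names(tab)))
  }
  satEstimate <- function(h, method) {
    N <- nMolecules(h)
    tryCatch({
      if (method == "ztnb") ztnbFit(h)@L
      else dsPredict(h, t = 1e20, mt = 2L)@distinct
    },
      umisat_degenerate_histogram = function(e) N,
      umisat_estimator_unstable = function(e) N)
  }

  if (scenario == "amplification") {
    nA <- rep(baseMolecules, nPairs)
    nB <- ifelse(trueDE, round(baseMolecules * foldChange), baseMolecules)
    ampA <- amplificationSampler(nPairs)
    ampB <- amplificationSampler(nPairs)
    out <- lapply(seq_len(nPairs), function(k) {
      cA <- stats::rnbinom(nA[k], mu = ampA[k], size = nbSize)
      cB <- stats::rnbinom(nB[k], mu = ampB[k], size = nbSize)
      hA <- histOf(cA); hB <- histOf(cB)
      obsA <- nMolecules(hA); obsB <- nMolecules(hB)
      c(scoreUncorrected = abs(log2((obsB + 1) / (obsA + 1))),
        scoreZTNB = abs(log2((satEstimate(hB, "ztnb") + 1) /
                               (satEstimate(hA, "ztnb") + 1))),
        scoreDS = abs(log2((satEstimate(hB, "ds") + 1) /
                             (satEstimate(hA, "ds") + 1))))
    })
    m <- do.call(rbind, out)
    return(data.frame(pair = seq_len(nPairs), trueDE = trueDE,
                      ampA = ampA, ampB = ampB, m,
                      stringsAsFactors = FALSE))
  }

  ## batch scenario: same gene at two depths sharing one amplification level
  amp <- amplificationSampler(nPairs)
  n1 <- rep(baseMolecules, nPairs)
  n2 <- ifelse(trueDE, round(baseMolecules * foldChange), baseMolecules)
  obs1 <- numeric(nPairs)
  obs2 <- numeric(nPairs)
  hists1 <- vector("list", nPairs)
  for (k in seq_len(nPairs)) {
    c1 <- stats::rnbinom(n1[k], mu = amp[k], size = nbSize)
    c2full <- stats::rnbinom(n2[k], mu = amp[k], size = nbSize)
    c2 <- stats::rbinom(n2[k], size = c2full, prob = depthRatio)
    hists1[[k]] <- histOf(c1)
    obs1[k] <- nMolecules(hists1[[k]])
    obs2[k] <- sum(c2 > 0L)
  }
  down1 <- vapply(hists1, function(h)
    survivingMolecules(h@copies, h@molecules, depthRatio), numeric(1))
  cpm1 <- 1e6 * obs1 / sum(obs1)
  cpm2 <- 1e6 * obs2 / sum(obs2)
  cpm1d <- 1e6 * down1 / sum(down1)
  lfcU <- log2((cpm2 + 1) / (cpm1 + 1))
  lfcD <- log2((cpm2 + 1) / (cpm1d + 1))
  data.frame(pair = seq_len(nPairs), trueDE = trueDE, amp = amp,
             lfcUncorrected = lfcU, lfcDownsampled = lfcD,
             scoreUncorrected = abs(lfcU), scoreDownsampled = abs(lfcD),
             stringsAsFactors = FALSE)
}
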