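#' @import methods
#' @importFrom S4Vectors SimpleList
NULL

setClassUnion("integerOrNA", c("integer", "logical"))

#' CUHistogram: a per-gene copies-per-UMI histogram
#'
#' A CU histogram records, for one gene, how many UMI-collapsed molecules
#' were observed with exactly \code{i} read copies. It is the sole input to
#' all unseen-molecule estimators. Molecule counts may be fractional (e.g.
#' after analytic binomial downsampling or cross-dataset pooling).
#'
#' @slot copies integer vector of copy levels, all >= 1, strictly increasing.
#' @slot molecules numeric vector of molecule counts (>= 0), parallel to
#'   \code{copies}.
#' @slot gene single character, the gene this histogram belongs to.
#'
#' @seealso [CUHistogram()] for the constructor, [nMolecules()],
#'   [nReads()], [saturationMetrics()].
#' @export
setClass("CUHistogram",
  slots = c(copies = "integer", molecules = "numeric", gene = "character"),
  prototype = prototype(copies = integer(0), molecules = numeric(0),
                        gene = NA_character_))

setValidity("CUHistogram", function(object) {
  msg <- character(0)
  if (length(object@copies) != length(object@molecules))
    msg <- c(msg, "'copies' and 'molecules' must have equal length")
  if (length(object@copies) && any(object@copies < 1L))
    msg <- c(msg, "all copy levels must be >= 1")
  if (length(object@copies) > 1L && any(diff(object@copies) <= 0L))
    msg <- c(msg, "'copies' must be strictly increasing")
  if (length(object@molecules) && any(object@molecules < 0))
    msg <- c(msg, "molecule counts must be nonnegative")
  if (length(object@gene) != 1L)
    msg <- c(msg, "'gene' must be a single string")
  if (length(msg)) msg else TRUE
})

#' Construct a CU histogram
#'
#' @param counts either a named numeric vector (names = copy levels) or a
#'   numeric vector of molecule counts parallel to \code{copies}.
#' @param copies integer copy levels; ignored when \code{counts} is named.
#' @param gene gene identifier.
#'
#' @return A [CUHistogram-class] object. Zero-count copy levels are dropped
#'   and levels are sorted.
#' @examples
#' h <- CUHistogram(c(`1` = 9, `2` = 1), gene = "ACTB")
#' nMolecules(h)
#' @export
CUHistogram <- function(counts, copies = NULL, gene = NA_character_) {
  if (is.null(copies)) {
    if (is.null(names(counts)))
      stop("'counts' must be named by copy level when 'copies' is absent")
    copies <- as.integer(names(counts))
  }
  counts <- as.numeric(counts)
  keep <- counts != 0
  copies <- as.integer(copies)[keep]
  counts <- counts[keep]
  o <- order(copies)
  new("CUHistogram", copies = copies[o], molecules = counts[o],
      gene = as.character(gene))
}

#' CUHistogramList: a collection of per-gene CU histograms
#'
#' A [S4Vectors::SimpleList] whose elements are [CUHistogram-class] objects,
#' named by gene.
#'
#' @export
setClass("CUHistogramList", contains = "SimpleList",
         prototype = prototype(elementType = "CUHistogram"))

#' @param ... CUHistogram objects, or a single list of them. Names default to
#'   each histogram's gene slot.
#' @rdname CUHistogramList-class
#' @export
CUHistogramList <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1L]]) &&
      !is(args[[1L]], "CUHistogram"))
    args <- args[[1L]]
  if (is.null(names(args)) && length(args))
    names(args) <- vapply(args, function(h) h@gene, character(1))
  new("CUHistogramList", SimpleList(args))
}

#' MoleculeTable: UMI-collapsed molecule records
#'
#' One record per UMI-collapsed molecule: cell barcode, UMI sequence, gene
#' assignment and read count. Molecules that mapped to more than one gene are
#' kept with the sentinel gene \code{"-"} until [buildCUHistograms()]
#' discards them.
#'
#' @slot records data.frame with columns barcode, umi, gene (character) and
#'   reads (integer >= 1); (barcode, umi, gene) triples unique.
#' @export
setClass("MoleculeTable", slots = c(records = "data.frame"))

setValidity("MoleculeTable", function(object) {
  df <- object@records
  req <- c("barcode", "umi", "gene", "reads")
  if (!all(req %in% names(df)))
    return(paste("missing column(s):",
                 paste(setdiff(req, names(df)), collapse = ", ")))
  if (nrow(df) && any(df$reads < 1L))
    return("all read counts must be >= 1")
  if (anyDuplicated(df[c("barcode", "umi", "gene")]))
    return("(barcode, umi, gene) triples must be unique")
  TRUE
})

#' Construct a molecule table
#'
#' @param barcode,umi,gene character vectors; \code{gene} uses \code{"-"} for
#'   ambiguous (multi-gene) molecules.
#' @param reads integer read counts, all >= 1.
#' @return A [MoleculeTable-class].
#' @export
MoleculeTable <- function(barcode = character(0), umi = character(0),
                          gene = character(0), reads = integer(0)) {
  new("MoleculeTable", records = data.frame(
    barcode = as.character(barcode), umi = as.character(umi),
    gene = as.character(gene), reads = as.integer(reads),
    stringsAsFactors = FALSE))
}

#' ZTNBFit: zero-truncated negative binomial fit to a CU histogram
#'
#' Result of fitting a negative binomial amplification model to an observed
#' (zero-truncated) copies-per-UMI histogram by EM, estimating the molecules
#' that received zero reads.
#'
#' @slot mu fitted NB mean (> 0).
#' @slot size fitted NB dispersion parameter (> 0).
#' @slot L estimated total molecules including unseen ones (>= N).
#' @slot z estimated zero-copy molecules, \code{L - N}.
#' @slot N observed molecules.
#' @slot logLik final complete-data (zero-completed) log-likelihood.
#' @slot converged whether the relative log-likelihood change fell below
#'   tolerance before the iteration cap.
#' @slot nIter EM iterations performed.
#' @export
setClass("ZTNBFit",
  slots = c(mu = "numeric", size = "numeric", L = "numeric", z = "numeric",
            N = "numeric", logLik = "numeric", converged = "logical",
            nIter = "integer"))

setValidity("ZTNBFit", function(object) {
  if (object@mu <= 0 || object@size <= 0) return("mu and size must be > 0")
  if (object@L < object@N - 1e-6 * object@N) return("L must be >= N")
  TRUE
})

#' PredictionResult: an unseen-molecule prediction at extrapolation factor t
#'
#' Produced by [goodToulmin()], [ztnbPredict()] and [dsPredict()]. The total
#' read count is imagined multiplied by \code{t + 1}; \code{distinct} is the
#' predicted number of molecules seen at least once at that depth.
#'
#' @slot method one of "good_toulmin", "ztnb", "ds".
#' @slot t extrapolation factor (>= 0).
#' @slot distinct predicted distinct molecules at the new depth.
#' @slot newMolecules \code{distinct - N}.
#' @slot N observed molecules at the current depth.
#' @slot mt histogram truncation level (DS only, NA otherwise).
#' @slot clamped TRUE when a negative Good-Toulmin sum was floored at -N.
#' @export
setClass("PredictionResult",
  slots = c(method = "character", t = "numeric", distinct = "numeric",
            newMolecules = "numeric", N = "numeric", mt = "integerOrNA",
            clamped = "logical"),
  prototype = prototype(mt = NA_integer_, clamped = FALSE))

setValidity("PredictionResult", function(object) {
  if (object@distinct < 0) return("distinct molecules must be >= 0")
  if (!object@method %in% c("good_toulmin", "ztnb", "ds"))
    return("unknown method")
  TRUE
})

#' CorrectionResult: per-gene unseen-molecule correction of a count matrix
#'
#' Bookkeeping for [applyCorrection()]: for each gene the predicted molecule
#' count \eqn{c_g} and the corrected row total \eqn{m_g = (T/P) c_g}, where
#' T is the observed grand total and P the predicted grand total. The
#' corrected matrix conserves the grand total T.
#'
#' @slot perGene data.frame with columns gene, N, cG, mG, applied.
#' @slot totalObserved total observed UMIs T.
#' @slot totalPredicted total predicted UMIs P.
#' @slot method estimator used.
#' @slot t extrapolation factor used.
#' @export
setClass("CorrectionResult",
  slots = c(perGene = "data.frame", totalObserved = "numeric",
            totalPredicted = "numeric", method = "character", t = "numeric"))

#' DownsampleCorrection: binomial-downsampling batch correction record
#'
#' @slot x retained-read fraction in (0, 1].
#' @slot perGene data.frame with columns gene, cpmBefore, cpmAfter, fG.
#' @slot chosenBy "fixed" or "ccc-grid".
#' @slot cccGrid data.frame (x, ccc) scanned by the AUTO search; empty for
#'   fixed x.
#' @export
setClass("DownsampleCorrection",
  slots = c(x = "numeric", perGene = "data.frame", chosenBy = "character",
            cccGrid = "data.frame"),
  prototype = prototype(cccGrid = data.frame(x = numeric(0),
                                             ccc = numeric(0))))

setValidity("DownsampleCorrection", function(object) {
  if (object@x <= 0 || object@x > 1) return("x must be in (0, 1]")
  if (nrow(object@perGene) && any(object@perGene$fG < 0))
    return("scale factors must be >= 0")
  TRUE
})
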