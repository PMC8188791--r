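#' @rdname CUHistogram-class
#' @param x,object a CUHistogram (or CUHistogramList where documented).
#' @export
setGeneric("copies", function(x) standardGeneric("copies"))

#' @rdname CUHistogram-class
#' @export
setGeneric("molecules", function(x) standardGeneric("molecules"))

#' @rdname CUHistogram-class
#' @export
setGeneric("geneName", function(x) standardGeneric("geneName"))

#' Total observed molecules in a CU histogram
#'
#' \code{nMolecules} is the histogram mass N = sum h(i); \code{nReads} is the
#' read total sum i * h(i).
#' @param x a [CUHistogram-class] or [CUHistogramList-class].
#' @return numeric scalar (or named vector for a list).
#' @export
setGeneric("nMolecules", function(x) standardGeneric("nMolecules"))

#' @rdname nMolecules
#' @export
setGeneric("nReads", function(x) standardGeneric("nReads"))

#' Saturation metrics of a CU histogram
#'
#' FSCM is the fraction of molecules observed with exactly one read copy,
#' FDCM with exactly two, and FMCM (= 1 - FSCM - FDCM) with more than two.
#' High FSCM signals low sequencing saturation: many molecules are expected
#' to remain unseen.
#'
#' @param x a [CUHistogram-class] or a [CUHistogramList-class].
#' @param ... unused.
#' @return For a single histogram, a named numeric vector
#'   \code{c(fscm, fdcm, fmcm, nUMIs)}; for a list, a data.frame with one row
#'   per gene (columns gene, fscm, fdcm, fmcm, nUMIs).
#' @examples
#' saturationMetrics(CUHistogram(c(`1` = 9, `2` = 1)))
#' @export
setGeneric("saturationMetrics",
           function(x, ...) standardGeneric("saturationMetrics"))
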