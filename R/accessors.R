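#' @rdname CUHistogram-class
#' @export
setMethod("copies", "CUHistogram", function(x) x@copies)

#' @rdname CUHistogram-class
#' @export
setMethod("molecules", "CUHistogram", function(x) x@molecules)

#' @rdname CUHistogram-class
#' @export
setMethod("geneName", "CUHistogram", function(x) x@gene)

#' @rdname nMolecules
#' @export
setMethod("nMolecules", "CUHistogram", function(x) sum(x@molecules))

#' @rdname nMolecules
#' @export
setMethod("nReads", "CUHistogram",
          function(x) sum(as.numeric(x@copies) * x@molecules))

#' @rdname nMolecules
#' @export
setMethod("nMolecules", "CUHistogramList", function(x)
  vapply(x, nMolecules, numeric(1)))

#' @rdname nMolecules
#' @export
setMethod("nReads", "CUHistogramList", function(x)
  vapply(x, nReads, numeric(1)))

setMethod("show", "CUHistogram", function(object) {
  cat(sprintf("CUHistogram for gene '%s': %g molecules, %g reads, %d copy levels\n",
              object@gene, nMolecules(object), nReads(object),
              length(object@copies)))
  if (length(object@copies)) {
    n <- min(length(object@copies), 8L)
    cat("  copies:   ", paste(object@copies[seq_len(n)], collapse = " "),
        if (length(object@copies) > n) "..." else "", "\n")
    cat("  molecules:", paste(signif(object@molecules[seq_len(n)], 4),
                              collapse = " "),
        if (length(object@copies) > n) "..." else "", "\n")
  }
  invisible(NULL)
})

setMethod("show", "MoleculeTable", function(object) {
  df <- object@records
  amb <- sum(df$gene == "-")
  cat(sprintf("MoleculeTable: %d molecules, %d cells, %d genes (%d ambiguous records), %g reads\n",
              nrow(df), length(unique(df$barcode)),
              length(unique(df$gene[df$gene != "-"])), amb,
              sum(as.numeric(df$reads))))
  invisible(NULL)
})

#' @rdname MoleculeTable-class
#' @param x a MoleculeTable.
#' @param ... unused.
#' @export
setMethod("as.data.frame", "MoleculeTable", function(x, ...) x@records)

setMethod("show", "ZTNBFit", function(object) {
  cat(sprintf("ZTNBFit: mu = %.4g, size = %.4g\n", object@mu, object@size))
  cat(sprintf("  observed N = %g, estimated total L = %.4g (unseen z = %.4g)\n",
              object@N, object@L, object@z))
  cat(sprintf("  logLik = %.6g, %s in %d iterations\n", object@logLik,
              if (object@converged) "converged" else "NOT converged",
              object@nIter))
  invisible(NULL)
})

setMethod("show", "PredictionResult", function(object) {
  cat(sprintf("PredictionResult (%s%s): t = %g\n", object@method,
              if (!is.na(object@mt)) sprintf(", mt = %d", object@mt) else "",
              object@t))
  cat(sprintf("  observed N = %g -> predicted distinct = %.6g (new: %.6g)%s\n",
              object@N, object@distinct, object@newMolecules,
              if (isTRUE(object@clamped)) " [clamped]" else ""))
  invisible(NULL)
})

setMethod("show", "CorrectionResult", function(object) {
  cat(sprintf("CorrectionResult (%s, t = %g): %d genes, %d corrected\n",
              object@method, object@t, nrow(object@perGene),
              sum(object@perGene$applied)))
  cat(sprintf("  observed T = %g, predicted P = %.6g\n",
              object@totalObserved, object@totalPredicted))
  invisible(NULL)
})

setMethod("show", "DownsampleCorrection", function(object) {
  cat(sprintf("DownsampleCorrection: x = %.3g (%s), %d genes\n",
              object@x, object@chosenBy, nrow(object@perGene)))
  invisible(NULL)
})
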