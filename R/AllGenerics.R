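#' Accessors for repeat hits and screen results
#'
#' @param x a [RepeatHit-class], [FlipperScreen-class] or [FitResult-class]
#'   object as appropriate.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("repeatPeriod", function(x) standardGeneric("repeatPeriod"))
#' @rdname accessors
#' @export
setGeneric("repeatCopies", function(x) standardGeneric("repeatCopies"))
#' @rdname accessors
#' @export
setGeneric("repeatIdentity", function(x) standardGeneric("repeatIdentity"))
#' @rdname accessors
#' @export
setGeneric("repeatConsensus", function(x) standardGeneric("repeatConsensus"))
#' @rdname accessors
#' @export
setGeneric("repeatSpan", function(x) standardGeneric("repeatSpan"))
#' @rdname accessors
#' @export
setGeneric("hitScore", function(x) standardGeneric("hitScore"))
#' @rdname accessors
#' @export
setGeneric("candidates", function(x) standardGeneric("candidates"))
#' @rdname accessors
#' @export
setGeneric("stageCounts", function(x) standardGeneric("stageCounts"))
#' @rdname accessors
#' @export
setGeneric("filterConfig", function(x) standardGeneric("filterConfig"))
#' @rdname accessors
#' @export
setGeneric("fitParams", function(x) standardGeneric("fitParams"))
#' @rdname accessors
#' @export
setGeneric("fitDerived", function(x) standardGeneric("fitDerived"))

#' @rdname accessors
setMethod("repeatPeriod", "RepeatHit", function(x) x@period)
#' @rdname accessors
setMethod("repeatCopies", "RepeatHit", function(x) x@copies)
#' @rdname accessors
setMethod("repeatIdentity", "RepeatHit", function(x) x@identity)
#' @rdname accessors
setMethod("repeatConsensus", "RepeatHit", function(x) x@consensus)
#' @rdname accessors
setMethod("repeatSpan", "RepeatHit", function(x) c(start = x@start, end = x@end))
#' @rdname accessors
setMethod("hitScore", "RepeatHit", function(x) x@score)
#' @rdname accessors
setMethod("candidates", "FlipperScreen", function(x) x@candidates)
#' @rdname accessors
setMethod("stageCounts", "FlipperScreen", function(x) x@stageCounts)
#' @rdname accessors
setMethod("filterConfig", "FlipperScreen", function(x) x@config)
#' @rdname accessors
setMethod("fitParams", "FitResult", function(x) x@params)
#' @rdname accessors
setMethod("fitDerived", "FitResult", function(x) x@derived)

setMethod("show", "RepeatHit", function(object) {
  cat(sprintf(
    "RepeatHit: span %d-%d, period %d, %.2f copies, identity %.3f, score %.1f\n  consensus: %s\n",
    object@start, object@end, object@period, object@copies,
    object@identity, object@score, object@consensus
  ))
})

setMethod("show", "RepeatConfig", function(object) {
  cat(sprintf(
    "RepeatConfig: period [%d, %d], minCopies %d, minIdentity %.2f, minDistinct %d, jitter %d\n",
    object@periodMin, object@periodMax, object@minCopies,
    object@minIdentity, object@minDistinct, object@jitter
  ))
})

setMethod("show", "FilterConfig", function(object) {
  cat("FilterConfig\n")
  cat(sprintf("  length band : [%d, %d] residues\n", object@lengthMin, object@lengthMax))
  cat(sprintf("  pI band     : [%.2f, %.2f]\n", object@piMin, object@piMax))
  cat(sprintf("  min fracZeta: %.3f  min fracPhi: %.3f\n",
              object@minFracZeta, object@minFracPhi))
  cat(sprintf("  sticker     : >= %d phi, >= %d zeta in consensus\n",
              object@minPhiSticker, object@minZetaSticker))
  cat(sprintf("  disorder    : >= %.2f (%s), matureTrim %d\n",
              object@minDisorder, object@disorderSource, object@matureTrim))
  cat("  "); show(object@repeatConfig)
})

setMethod("show", "DisorderProfile", function(object) {
  cat(sprintf("DisorderProfile (%s): %d residues, fraction disordered %.3f\n",
              object@source, length(object@scores), mean(object@calls)))
})

setMethod("show", "FlipperScreen", function(object) {
  cat("FlipperScreen\n  stage survivors:\n")
  for (nm in names(object@stageCounts))
    cat(sprintf("    %-10s %d\n", nm, object@stageCounts[[nm]]))
  cat(sprintf("  candidates passing all stages: %d of %d\n",
              sum(object@candidates$passAll, na.rm = TRUE),
              nrow(object@candidates)))
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult (%s)\n", object@model))
  p <- object@params
  for (nm in names(p)) {
    if (length(object@se) && nm %in% names(object@se))
      cat(sprintf("  %-6s %.6g  (se %.3g)\n", nm, p[[nm]], object@se[[nm]]))
    else cat(sprintf("  %-6s %.6g\n", nm, p[[nm]]))
  }
  d <- object@derived
  for (nm in names(d)) cat(sprintf("  %-6s %.6g (derived)\n", nm, d[[nm]]))
  cat(sprintf("  RSS %.6g\n", object@rss))
})
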