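## Accessors (slots are never touched directly by user code) and show
## methods.

#' @rdname BeadChain
#' @param object,x a BeadChain / ScatteringCurve / TubuleAxis / EnsembleFit.
#' @export
setGeneric("nBeads", function(x) standardGeneric("nBeads"))

#' @rdname BeadChain
#' @export
setGeneric("beadCoords", function(x) standardGeneric("beadCoords"))

#' @rdname BeadChain
#' @export
setGeneric("beadResidues", function(x) standardGeneric("beadResidues"))

#' @rdname BeadChain
#' @export
setGeneric("chainLabels", function(x) standardGeneric("chainLabels"))

#' @rdname BeadChain
#' @export
setGeneric("modelId", function(x) standardGeneric("modelId"))

#' @rdname BeadChain
#' @export
setMethod("nBeads", "BeadChain", function(x) nrow(x@coords))

#' @rdname BeadChain
#' @export
setMethod("beadCoords", "BeadChain", function(x) x@coords)

#' @rdname BeadChain
#' @export
setMethod("beadResidues", "BeadChain", function(x) x@residues)

#' @rdname BeadChain
#' @export
setMethod("chainLabels", "BeadChain", function(x) x@chains)

#' @rdname BeadChain
#' @export
setMethod("modelId", "BeadChain", function(x) x@modelId)

#' Split a multi-chain BeadChain into one BeadChain per chain label
#'
#' @param x a [BeadChain-class].
#' @return Named list of single-chain [BeadChain-class] objects, in
#'   order of first appearance of each chain label.
#' @export
splitChains <- function(x) {
  stopifnot(is(x, "BeadChain"))
  labs <- unique(x@chains)
  out <- lapply(labs, function(l) {
    i <- x@chains == l
    BeadChain(x@coords[i, , drop = FALSE], x@residues[i], x@chains[i],
              modelId = x@modelId, source = x@source)
  })
  names(out) <- labs
  out
}

setMethod("show", "BeadChain", function(object) {
  cat(sprintf("BeadChain: %d beads, %d chain(s), model %d\n",
              nrow(object@coords), length(unique(object@chains)),
              object@modelId))
  ext <- apply(object@coords, 2, range)
  cat(sprintf("  extent (nm): x %.2f..%.2f  y %.2f..%.2f  z %.2f..%.2f\n",
              ext[1, 1], ext[2, 1], ext[1, 2], ext[2, 2], ext[1, 3], ext[2, 3]))
  if (nzchar(object@source)) cat("  source:", object@source, "\n")
})

#' @rdname ScatteringCurve
#' @param x a ScatteringCurve.
#' @export
setGeneric("qValues", function(x) standardGeneric("qValues"))

#' @rdname ScatteringCurve
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname ScatteringCurve
#' @export
setGeneric("sigmas", function(x) standardGeneric("sigmas"))

#' @rdname ScatteringCurve
#' @export
setGeneric("curveId", function(x) standardGeneric("curveId"))

#' @rdname ScatteringCurve
#' @export
setMethod("qValues", "ScatteringCurve", function(x) x@q)

#' @rdname ScatteringCurve
#' @export
setMethod("intensities", "ScatteringCurve", function(x) x@intensity)

#' @rdname ScatteringCurve
#' @export
setMethod("sigmas", "ScatteringCurve", function(x) x@sigma)

#' @rdname ScatteringCurve
#' @export
setMethod("curveId", "ScatteringCurve", function(x) x@id)

setMethod("show", "ScatteringCurve", function(object) {
  kind <- if (length(object@sigma)) "experimental" else "theoretical"
  cat(sprintf("ScatteringCurve (%s): %d points, q %.4g..%.4g nm^-1",
              kind, length(object@q), min(object@q), max(object@q)))
  if (nzchar(object@id)) cat(sprintf("  [%s]", object@id))
  cat("\n")
})

#' @rdname TubuleAxis
#' @param x a TubuleAxis.
#' @export
setGeneric("axisPoints", function(x) standardGeneric("axisPoints"))

#' @rdname TubuleAxis
#' @export
setMethod("axisPoints", "TubuleAxis", function(x) x@points)

#' @rdname TubuleAxis
#' @export
setGeneric("axisParams", function(x) standardGeneric("axisParams"))

#' @rdname TubuleAxis
#' @export
setMethod("axisParams", "TubuleAxis",
          function(x) c(window = x@window, step = x@step))

setMethod("show", "TubuleAxis", function(object) {
  cat(sprintf("TubuleAxis: %d points (window %d, step %d), length %.2f nm\n",
              nrow(object@points), object@window, object@step,
              contourLength(object)))
})

#' @rdname EnsembleFit
#' @param x an EnsembleFit.
#' @export
setGeneric("ensembleWeights", function(x) standardGeneric("ensembleWeights"))

#' @rdname EnsembleFit
#' @export
setMethod("ensembleWeights", "EnsembleFit",
          function(x) setNames(x@weights, x@ids))

#' @rdname EnsembleFit
#' @export
setGeneric("fitChi2", function(x) standardGeneric("fitChi2"))

#' @rdname EnsembleFit
#' @export
setMethod("fitChi2", "EnsembleFit", function(x) x@chi2)

#' @rdname EnsembleFit
#' @export
setGeneric("fittedCurve", function(x) standardGeneric("fittedCurve"))

#' @rdname EnsembleFit
#' @export
setMethod("fittedCurve", "EnsembleFit", function(x) x@fitted)

setMethod("show", "EnsembleFit", function(object) {
  cat(sprintf("EnsembleFit: chi2 = %.4g, scale = %.4g, %d distinct member(s)\n",
              object@chi2, object@scale, length(object@ids)))
  w <- sort(setNames(object@weights, object@ids), decreasing = TRUE)
  for (i in seq_along(w))
    cat(sprintf("  %-24s %5.1f%%\n", names(w)[i], 100 * w[i]))
})
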