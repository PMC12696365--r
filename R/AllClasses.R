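## Central S4 containers. One bead == one residue throughout; all
## coordinates are stored in nanometres (PDB files are the only Angstrom
## surface) and q is stored in nm^-1.

#' BeadChain: an ordered coarse-grained bead model
#'
#' One bead per residue, in sequence order. Coordinates are in
#' nanometres. Multi-chain structures (e.g. dimers) carry a per-bead
#' chain label; `modelId` is the 0-based frame index of the PDB MODEL
#' the chain came from.
#'
#' @slot coords numeric matrix, one row per bead, three columns (nm).
#' @slot residues character vector of one-letter residue codes, one per
#'   bead (`"X"` for non-standard residues).
#' @slot chains character vector of per-bead chain identifiers.
#' @slot modelId integer scalar, 0-based model/frame index.
#' @slot source free-text provenance.
#'
#' @aliases BeadChain-class
#' @exportClass BeadChain
setClass("BeadChain",
  representation(
    coords   = "matrix",
    residues = "character",
    chains   = "character",
    modelId  = "integer",
    source   = "character"
  )
)

setValidity("BeadChain", function(object) {
  msgs <- character(0)
  x <- object@coords
  if (!is.numeric(x) || ncol(x) != 3L)
    msgs <- c(msgs, "coords must be a numeric matrix with 3 columns")
  else {
    if (nrow(x) < 1L) msgs <- c(msgs, "a BeadChain needs at least one bead")
    if (!all(is.finite(x))) msgs <- c(msgs, "coords must all be finite")
  }
  if (length(object@residues) != nrow(x))
    msgs <- c(msgs, "residues must have one code per bead")
  if (length(object@chains) != nrow(x))
    msgs <- c(msgs, "chains must have one label per bead")
  if (length(object@modelId) != 1L || is.na(object@modelId))
    msgs <- c(msgs, "modelId must be a single integer")
  if (length(msgs)) msgs else TRUE
})

#' Construct a BeadChain
#'
#' @param coords numeric matrix (n x 3) of bead positions in nm.
#' @param residues one-letter residue codes; recycled single code
#'   allowed (default `"G"`).
#' @param chains per-bead chain labels; recycled single label allowed
#'   (default `"A"`).
#' @param modelId 0-based model index.
#' @param source free-text provenance string.
#' @return A [BeadChain-class] object.
#' @examples
#' bc <- BeadChain(matrix(rnorm(30), ncol = 3))
#' nBeads(bc)
#' @export
BeadChain <- function(coords, residues = "G", chains = "A",
                      modelId = 0L, source = "") {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  n <- nrow(coords)
  if (length(residues) == 1L) residues <- rep(residues, n)
  if (length(chains) == 1L) chains <- rep(chains, n)
  new("BeadChain", coords = coords, residues = as.character(residues),
      chains = as.character(chains), modelId = as.integer(modelId),
      source = as.character(source)[1L])
}

#' ScatteringCurve: a SAXS intensity profile
#'
#' Holds either an experimental curve (with per-point uncertainties) or
#' a theoretical curve (empty `sigma`). q is in nm^-1 and strictly
#' increasing.
#'
#' @slot q scattering vector grid (nm^-1), strictly increasing, >= 0.
#' @slot intensity positive intensities, same length as q.
#' @slot sigma per-point uncertainties (positive), or `numeric(0)` for a
#'   theoretical curve.
#' @slot id conformer descriptor or data-set label.
#'
#' @aliases ScatteringCurve-class
#' @exportClass ScatteringCurve
setClass("ScatteringCurve",
  representation(q = "numeric", intensity = "numeric",
                 sigma = "numeric", id = "character")
)

setValidity("ScatteringCurve", function(object) {
  msgs <- character(0)
  q <- object@q
  if (length(q) < 1L) msgs <- c(msgs, "empty q grid")
  if (any(q < 0)) msgs <- c(msgs, "q must be non-negative")
  if (length(q) > 1L && any(diff(q) <= 0))
    msgs <- c(msgs, "q must be strictly increasing")
  if (length(object@intensity) != length(q))
    msgs <- c(msgs, "intensity and q lengths differ")
  if (any(!is.finite(object@intensity)) || any(object@intensity <= 0))
    msgs <- c(msgs, "intensity must be positive and finite")
  ns <- length(object@sigma)
  if (ns != 0L && ns != length(q))
    msgs <- c(msgs, "sigma must be empty or match q in length")
  if (ns > 0L && any(object@sigma <= 0))
    msgs <- c(msgs, "all sigma must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' Construct a ScatteringCurve
#'
#' @param q scattering vector grid in nm^-1 (strictly increasing).
#' @param intensity positive intensities.
#' @param sigma uncertainties; omit for a theoretical curve.
#' @param id label (conformer descriptor for pool members).
#' @return A [ScatteringCurve-class] object.
#' @export
ScatteringCurve <- function(q, intensity, sigma = numeric(0), id = "") {
  new("ScatteringCurve", q = as.numeric(q),
      intensity = as.numeric(intensity), sigma = as.numeric(sigma),
      id = as.character(id)[1L])
}

#' TubuleAxis: the smoothed curvilinear axis of a conformer
#'
#' Polyline of windowed centres of mass taken along the sequence; point
#' k is the unweighted mean of beads `[k*step, k*step + window)`
#' (0-based, half-open), with one extra point anchored at the final
#' window when the chain length minus the window is not a multiple of
#' the step.
#'
#' @slot points numeric matrix of axis points (nm).
#' @slot window window length in residues.
#' @slot step step between window starts in residues.
#'
#' @aliases TubuleAxis-class
#' @exportClass TubuleAxis
setClass("TubuleAxis",
  representation(points = "matrix", window = "integer", step = "integer")
)

setValidity("TubuleAxis", function(object) {
  msgs <- character(0)
  if (nrow(object@points) < 1L) msgs <- c(msgs, "axis needs >= 1 point")
  if (ncol(object@points) != 3L) msgs <- c(msgs, "axis points must be 3-D")
  if (object@step < 1L || object@step > object@window)
    msgs <- c(msgs, "need 0 < step <= window")
  if (length(msgs)) msgs else TRUE
})

#' EnsembleFit: a weighted conformer sub-ensemble fitted to SAXS data
#'
#' Result of the genetic-algorithm ensemble selection: the selected
#' conformers with their multiplicities (a conformer may appear several
#' times in the chromosome, which is what produces its weight), the
#' reduced chi-squared of the fit, the analytically optimal scale
#' factor, the fitted curve on the experimental grid, and the per
#' generation best-chi2 trace.
#'
#' @slot ids conformer descriptors of the distinct selected members.
#' @slot multiplicities how many chromosome slots each id occupies.
#' @slot weights multiplicities / ensemble size (sum to 1).
#' @slot chi2 reduced chi-squared of the best ensemble.
#' @slot scale optimal multiplicative scale applied to the model curve.
#' @slot fitted the scaled ensemble-average curve on the experimental grid.
#' @slot trace best chi2 after each generation (non-increasing).
#' @slot params the GA parameter list used (including the seed).
#'
#' @aliases EnsembleFit-class
#' @exportClass EnsembleFit
setClass("EnsembleFit",
  representation(ids = "character", multiplicities = "integer",
                 weights = "numeric", chi2 = "numeric", scale = "numeric",
                 fitted = "ScatteringCurve", trace = "numeric",
                 params = "list")
)

setValidity("EnsembleFit", function(object) {
  msgs <- character(0)
  if (length(object@weights) &&
      abs(sum(object@weights) - 1) > 1e-8)
    msgs <- c(msgs, "weights must sum to 1")
  if (object@chi2 < 0) msgs <- c(msgs, "chi2 must be >= 0")
  if (length(object@ids) != length(object@multiplicities) ||
      length(object@ids) != length(object@weights))
    msgs <- c(msgs, "ids, multiplicities and weights lengths differ")
  if (length(msgs)) msgs else TRUE
})
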