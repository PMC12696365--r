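## Hierarchical size metrics for tubular conformers. Three length
## scales: the averaged contour length (ACL) of the windowed
## centre-of-mass axis, the maximum Euclidean extent (MaxE), and the
## tube radius R_t (90th percentile of bead-to-axis distances), plus
## the conventional R_g and Kirkwood R_h and the shape ratios built
## from them.

#' Extract the curvilinear tubule axis by windowed centres of mass
#'
#' Takes the unweighted centre of mass of `window`-residue stretches
#' every `step` residues along the sequence. Because the sequence order
#' approximates the order in which residues pack into the tubule, this
#' polyline traces the tubule's central axis while smoothing out
#' backbone detail. When `(n - window)` is not a multiple of `step`, a
#' final point anchored at the last full window is appended so the axis
#' reaches the chain end.
#'
#' @param chain a [BeadChain-class] with at least `window` beads.
#' @param window window length in residues. Defaults to 150: shorter
#'   windows under-smooth the backbone, windows beyond ~400 residues
#'   wash out the tubule shape.
#' @param step step between window starts in residues (default 10).
#' @return A [TubuleAxis-class].
#' @export
computeAxis <- function(chain, window = 150L, step = 10L) {
  stopifnot(is(chain, "BeadChain"))
  window <- as.integer(window); step <- as.integer(step)
  if (step < 1L || step > window) stop("need 0 < step <= window")
  n <- nBeads(chain)
  if (n < window)
    stop("chain has ", n, " beads but the window is ", window,
         "; use a smaller window (>= ~150 residues is still advisable)")
  x <- beadCoords(chain)
  cs <- rbind(0, apply(x, 2, cumsum))
  starts <- seq(0L, n - window, by = step)
  if ((n - window) %% step != 0L) starts <- c(starts, n - window)
  pts <- (cs[starts + window + 1L, , drop = FALSE] -
          cs[starts + 1L, , drop = FALSE]) / window
  new("TubuleAxis", points = pts, window = window, step = step)
}

#' Averaged contour length of an axis polyline
#'
#' Sum of consecutive point-to-point distances; 0 for a single-point
#' axis. Note the windowed axis starts and ends half a window inside
#' the chain, so the estimate under-reports the generating axis length
#' by roughly one window's worth of arc at each end.
#'
#' @param axis a [TubuleAxis-class] (or a plain point matrix).
#' @return Length in nm.
#' @export
contourLength <- function(axis) {
  p <- if (is(axis, "TubuleAxis")) axis@points else as.matrix(axis)
  if (nrow(p) < 2L) return(0)
  sum(sqrt(rowSums(diff(p)^2)))
}

#' Maximum Euclidean extent of a bead set
#'
#' Exact maximum pairwise distance, computed in blocks so large chains
#' do not materialise the full distance matrix.
#'
#' @param chain a [BeadChain-class] or coordinate matrix (>= 2 beads).
#' @return MaxE in nm.
#' @export
maxEuclidean <- function(chain) {
  x <- if (is(chain, "BeadChain")) beadCoords(chain) else as.matrix(chain)
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 beads")
  if (n <= 2500L) return(max(dist(x)))
  block <- 1000L
  best <- 0
  sq <- rowSums(x^2)
  for (i0 in seq(1L, n, by = block)) {
    i1 <- min(n, i0 + block - 1L)
    g <- -2 * x[i0:i1, , drop = FALSE] %*% t(x)
    g <- g + outer(sq[i0:i1], rep(1, n)) + outer(rep(1, i1 - i0 + 1L), sq)
    best <- max(best, max(g))
  }
  sqrt(max(best, 0))
}

#' Tube radius: percentile of bead-to-axis radial distances
#'
#' For each bead, the distance to the nearest point on the axis
#' *polyline* (point-to-segment, not vertex-only); R_t is the 90th
#' percentile of that distribution (linear-interpolation, type-7
#' quantile, so results are bit-reproducible).
#'
#' @param chain a [BeadChain-class].
#' @param axis a [TubuleAxis-class] for the same chain.
#' @param percentile percentile of the radial-distance distribution
#'   (default 90).
#' @return Radius in nm.
#' @export
tubeRadius <- function(chain, axis, percentile = 90) {
  stopifnot(is(chain, "BeadChain"), is(axis, "TubuleAxis"))
  d <- beadAxisDistances(beadCoords(chain), axis@points)
  unname(quantile(d, percentile / 100, type = 7))
}

# min distance from each row of x to the polyline with vertices p
beadAxisDistances <- function(x, p) {
  m <- nrow(p)
  if (m == 0L) stop("empty axis")
  if (m == 1L)
    return(sqrt(rowSums(sweep(x, 2, p[1, ])^2)))
  best <- rep(Inf, nrow(x))
  for (j in seq_len(m - 1L)) {
    a <- p[j, ]; ab <- p[j + 1L, ] - a
    len2 <- sum(ab^2)
    xa <- sweep(x, 2, a)
    t <- if (len2 > 0) pmin(1, pmax(0, (xa %*% ab) / len2)) else 0
    dd <- rowSums((xa - outer(as.vector(t), ab))^2)
    best <- pmin(best, dd)
  }
  sqrt(best)
}

#' Radius of gyration (equal bead masses)
#'
#' `sqrt(mean(|r_i - centroid|^2))`.
#'
#' @param chain a [BeadChain-class] or coordinate matrix.
#' @return R_g in nm.
#' @export
radiusOfGyration <- function(chain) {
  x <- if (is(chain, "BeadChain")) beadCoords(chain) else as.matrix(chain)
  ctr <- colMeans(x)
  sqrt(mean(rowSums(sweep(x, 2, ctr)^2)))
}

#' Kirkwood hydrodynamic radius
#'
#' Double-sum estimate `R_h = N^2 / sum_{i != j} 1 / r_ij`. Note the
#' Kirkwood estimate of a bead-filled uniform ball is 5R/6 (giving
#' R_g/R_h ~ 0.93), not the hydrodynamic-theory R (ratio 0.77); use
#' [calibrateShapeClasses()] when classifying Kirkwood-based shape
#' factors.
#'
#' @param chain a [BeadChain-class] or coordinate matrix with >= 2
#'   beads and no coincident beads.
#' @return R_h in nm.
#' @export
kirkwoodRh <- function(chain) {
  x <- if (is(chain, "BeadChain")) beadCoords(chain) else as.matrix(chain)
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 beads")
  d <- dist(x)
  if (any(d == 0)) {
    hit <- which(as.matrix(d) == 0 & upper.tri(diag(n)), arr.ind = TRUE)[1, ]
    stop("coincident beads at indices ", hit[1], " and ", hit[2])
  }
  n^2 / (2 * sum(1 / d))
}

#' Classify conformer shape from the R_g/R_h shape factor
#'
#' On the hydrodynamic-theory scale a globular (spherical) protein has
#' R_g/R_h ~ 0.77, a coil ~ 1.0 and an extended rod ~ 1.7; the default
#' boundaries 0.85 (spherical|coil) and 1.35 (coil|rod) separate those
#' references. Because the Kirkwood estimator sits on a different
#' scale, a calibration regenerated from synthetic references with the
#' *same* estimator (see [calibrateShapeClasses()]) can be supplied
#' instead.
#'
#' @param shapeFactor positive R_g/R_h value(s).
#' @param calibration optional result of [calibrateShapeClasses()];
#'   when `NULL` the literature-scale default boundaries are used.
#' @return Character vector in `{"spherical", "coil", "rod"}`.
#' @export
classifyShape <- function(shapeFactor, calibration = NULL) {
  if (any(!is.finite(shapeFactor)) || any(shapeFactor <= 0))
    stop("shapeFactor must be positive")
  b <- unname(if (is.null(calibration)) c(0.85, 1.35)
              else calibration$boundaries)
  unname(ifelse(shapeFactor < b[1], "spherical",
                ifelse(shapeFactor < b[2], "coil", "rod")))
}

#' Self-consistent shape-class calibration
#'
#' Generates synthetic ball, coil and rod references, measures their
#' R_g/R_h with the package's own (Kirkwood) estimator, and places the
#' class boundaries at the midpoints between consecutive reference
#' values. This removes the dependence on which hydrodynamic estimator
#' the literature thresholds assume.
#'
#' @param nBeads beads per reference structure.
#' @param seed RNG seed for the reference structures.
#' @return `list(references = named numeric, boundaries = numeric(2))`.
#' @export
calibrateShapeClasses <- function(nBeads = 2000L, seed = 1L) {
  sf <- function(obj) radiusOfGyration(obj$chain) / kirkwoodRh(obj$chain)
  refs <- c(spherical = sf(makeBall(nBeads, radius = 5, seed = seed)),
            coil = sf(makeCoil(nBeads, bondLength = 0.38, seed = seed)),
            rod = sf(makeRod(nBeads, length = 50, diameter = 1,
                             seed = seed)))
  refs <- sort(refs)
  list(references = refs,
       boundaries = unname(c((refs[1] + refs[2]) / 2,
                             (refs[2] + refs[3]) / 2)))
}

#' All tubule metrics for one conformer
#'
#' Computes R_g, Kirkwood R_h, MaxE and, when the chain is at least one
#' window long, the axis-derived ACL and R_t; returns the shape ratios
#' R_g/R_h (the shape factor), R_g/MaxE and R_g/R_t together with the
#' shape class. Chains shorter than the window get `NA` for the
#' axis-dependent fields rather than an error, so the size-assay driver
#' can sweep short constructs.
#'
#' @inheritParams computeAxis
#' @param percentile percentile for [tubeRadius()].
#' @param calibration optional shape calibration, see [classifyShape()].
#' @return A `TubuleMetrics` list with fields `acl`, `maxe`, `rt`,
#'   `rg`, `rh`, `shape_factor`, `rg_over_maxe`, `rg_over_rt`,
#'   `shape_class`, `window`, `step`.
#' @export
shapeMetrics <- function(chain, window = 150L, step = 10L, percentile = 90,
                         calibration = NULL) {
  stopifnot(is(chain, "BeadChain"))
  n <- nBeads(chain)
  rg <- radiusOfGyration(chain)
  rh <- kirkwoodRh(chain)
  maxe <- maxEuclidean(chain)
  if (n >= window) {
    ax <- computeAxis(chain, window, step)
    acl <- contourLength(ax)
    rt <- tubeRadius(chain, ax, percentile)
  } else {
    acl <- NA_real_; rt <- NA_real_
  }
  sf <- rg / rh
  out <- list(acl = acl, maxe = maxe, rt = rt, rg = rg, rh = rh,
              shape_factor = sf,
              rg_over_maxe = rg / maxe,
              rg_over_rt = if (is.na(rt)) NA_real_ else rg / rt,
              shape_class = classifyShape(sf, calibration),
              window = as.integer(window), step = as.integer(step))
  class(out) <- "TubuleMetrics"
  out
}

#' @export
print.TubuleMetrics <- function(x, ...) {
  cat("TubuleMetrics:\n")
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.3f", v)
  cat(sprintf("  ACL %s nm  MaxE %s nm  R_t %s nm\n",
              fmt(x$acl), fmt(x$maxe), fmt(x$rt)))
  cat(sprintf("  R_g %s nm  R_h %s nm  R_g/R_h %s  R_g/MaxE %s\n",
              fmt(x$rg), fmt(x$rh), fmt(x$shape_factor),
              fmt(x$rg_over_maxe)))
  cat("  shape class:", x$shape_class, "\n")
  invisible(x)
}

#' @export
as.data.frame.TubuleMetrics <- function(x, ...) {
  data.frame(acl = x$acl, maxe = x$maxe, rt = x$rt, rg = x$rg, rh = x$rh,
             shape_factor = x$shape_factor,
             rg_over_maxe = x$rg_over_maxe, rg_over_rt = x$rg_over_rt,
             shape_class = x$shape_class, stringsAsFactors = FALSE)
}
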