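## Synthetic ground-truth structures. These generators define the
## conditions under which the metric engine is validated: tubular bead
## chains with known contour length and tube radius, and sphere / rod /
## coil references with closed-form radii of gyration. Every generator
## records its ground truth before any estimator runs and is fully
## reproducible from its seed.

groundTruth <- function(shape, seed, trueAcl = NA_real_, trueRt = NA_real_,
                        trueRg = NA_real_) {
  structure(list(shape_label = shape, seed = seed, true_acl = trueAcl,
                 true_rt_percentile = trueRt, true_rg = trueRg),
            class = "GroundTruth")
}

#' @export
print.GroundTruth <- function(x, ...) {
  cat("GroundTruth:", x$shape_label, "(seed", x$seed, ")\n")
  if (!is.na(x$true_acl)) cat("  true ACL:", x$true_acl, "nm\n")
  if (!is.na(x$true_rt_percentile))
    cat("  true R_t (90th pct):", signif(x$true_rt_percentile, 4), "nm\n")
  if (!is.na(x$true_rg)) cat("  true R_g:", signif(x$true_rg, 4), "nm\n")
  invisible(x)
}

# Rodrigues rotation of v about unit axis k by angle a
rotateAbout <- function(v, k, a) {
  v * cos(a) + pracmaCross(k, v) * sin(a) + k * sum(k * v) * (1 - cos(a))
}

pracmaCross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# orthonormal pair spanning the plane perpendicular to unit vector d
perpBasis <- function(d) {
  ref <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- pracmaCross(d, ref)
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- pracmaCross(d, e1)
  list(e1 = e1, e2 = e2)
}

#' Generate a synthetic tubular bead chain with known geometry
#'
#' The axis is a discrete worm-like curve: unit steps of
#' `segmentLength` whose direction turns by a uniformly drawn angle
#' bounded by `maxTurnAngle` at each step, so the total axis length is
#' exactly `axisLength`. Beads are assigned to axis stations *in
#' sequence order* (mirroring how residues pack into the tubule) with
#' radial offsets uniform in the disk of radius `tubeRadius`, whose
#' 90th-percentile radial distance is analytically
#' `sqrt(0.9) * tubeRadius`.
#'
#' @param nBeads number of beads (>= 400 recommended for tubule-like
#'   statistics).
#' @param axisLength total axis contour length (nm).
#' @param tubeRadius disk radius for the radial offsets (nm).
#' @param segmentLength axis step length (nm).
#' @param maxTurnAngle maximum turning angle per step (radians, < pi).
#' @param seed RNG seed (reproducible: same seed, same coordinates).
#' @param labeled if `TRUE`, beads with radial offset < 0.5*tubeRadius
#'   get hydrophobic codes (A/G) and outer beads polar codes (Q/Y/S), a
#'   construction used to test burial statistics; otherwise all beads
#'   are `"G"`.
#' @return `list(chain = BeadChain, truth = GroundTruth)`.
#' @examples
#' tube <- makeTube(1000, axisLength = 50, tubeRadius = 2, seed = 1)
#' tube$truth
#' @export
makeTube <- function(nBeads, axisLength = 50, tubeRadius = 2,
                     segmentLength = 0.5, maxTurnAngle = 0.15,
                     seed = 1, labeled = FALSE) {
  if (segmentLength <= 0) stop("segmentLength must be > 0")
  if (maxTurnAngle < 0 || maxTurnAngle >= pi)
    stop("maxTurnAngle must be in [0, pi)")
  if (tubeRadius <= 0 || axisLength <= 0) stop("dimensions must be > 0")
  if (tubeRadius >= axisLength)
    stop("tubeRadius must be smaller than axisLength")
  set.seed(seed)
  nSeg <- max(1L, round(axisLength / segmentLength))
  segLen <- axisLength / nSeg
  dirs <- matrix(0, nSeg, 3)
  d <- c(0, 0, 1)
  for (j in seq_len(nSeg)) {
    if (j > 1L && maxTurnAngle > 0) {
      b <- perpBasis(d)
      phi <- runif(1, 0, 2 * pi)
      axis_k <- cos(phi) * b$e1 + sin(phi) * b$e2
      d <- rotateAbout(d, axis_k, runif(1, 0, maxTurnAngle))
      d <- d / sqrt(sum(d^2))
    }
    dirs[j, ] <- d
  }
  verts <- rbind(c(0, 0, 0), apply(dirs * segLen, 2, cumsum))

  s <- (seq_len(nBeads) - 0.5) / nBeads * axisLength
  segIdx <- pmin(nSeg, floor(s / segLen) + 1L)
  u <- tubeRadius * sqrt(runif(nBeads))
  phi <- runif(nBeads, 0, 2 * pi)
  coords <- matrix(0, nBeads, 3)
  for (i in seq_len(nBeads)) {
    j <- segIdx[i]
    base <- verts[j, ] + (s[i] - (j - 1) * segLen) * dirs[j, ]
    b <- perpBasis(dirs[j, ])
    coords[i, ] <- base + u[i] * (cos(phi[i]) * b$e1 + sin(phi[i]) * b$e2)
  }
  res <- if (labeled) {
    inner <- u < 0.5 * tubeRadius
    ifelse(inner, sample(c("A", "G"), nBeads, replace = TRUE),
           sample(c("Q", "Y", "S"), nBeads, replace = TRUE))
  } else rep("G", nBeads)
  list(chain = BeadChain(coords, res, source = sprintf(
         "synthetic tube: L=%g nm, r=%g nm, seed=%d", axisLength,
         tubeRadius, seed)),
       truth = groundTruth("tube", seed, trueAcl = axisLength,
                           trueRt = sqrt(0.9) * tubeRadius))
}

#' Uniform-ball, rod and Gaussian-coil reference structures
#'
#' Reference shapes with closed-form radii of gyration:
#' * ball: beads uniform in a solid sphere, R_g = sqrt(3/5) * radius;
#' * rod: beads uniform in a cylinder, R_g = sqrt(L^2/12 + d^2/8);
#' * coil: fixed-bond-length random walk, R_g ~ b * sqrt(n/6).
#'
#' @param nBeads number of beads (>= 2).
#' @param radius ball radius (nm).
#' @param seed RNG seed.
#' @return `list(chain = BeadChain, truth = GroundTruth)`.
#' @export
makeBall <- function(nBeads, radius, seed = 1) {
  if (radius <= 0) stop("radius must be > 0")
  if (nBeads < 2) stop("need at least 2 beads")
  set.seed(seed)
  dir <- matrix(rnorm(3 * nBeads), ncol = 3)
  dir <- dir / sqrt(rowSums(dir^2))
  r <- radius * runif(nBeads)^(1 / 3)
  list(chain = BeadChain(dir * r,
         source = sprintf("synthetic ball: R=%g nm, seed=%d", radius, seed)),
       truth = groundTruth("sphere", seed, trueRg = sqrt(3 / 5) * radius))
}

#' @rdname makeBall
#' @param length rod length (nm).
#' @param diameter rod diameter (nm).
#' @export
makeRod <- function(nBeads, length, diameter, seed = 1) {
  if (length <= 0 || diameter <= 0) stop("dimensions must be > 0")
  if (nBeads < 2) stop("need at least 2 beads")
  set.seed(seed)
  z <- runif(nBeads, -length / 2, length / 2)
  rho <- (diameter / 2) * sqrt(runif(nBeads))
  phi <- runif(nBeads, 0, 2 * pi)
  coords <- cbind(rho * cos(phi), rho * sin(phi), z)
  list(chain = BeadChain(coords,
         source = sprintf("synthetic rod: L=%g, d=%g nm, seed=%d",
                          length, diameter, seed)),
       truth = groundTruth("rod", seed,
                           trueRg = sqrt(length^2 / 12 + diameter^2 / 8)))
}

#' @rdname makeBall
#' @param bondLength step length of the random walk (nm).
#' @export
makeCoil <- function(nBeads, bondLength = 0.38, seed = 1) {
  if (bondLength <= 0) stop("bondLength must be > 0")
  if (nBeads < 2) stop("need at least 2 beads")
  set.seed(seed)
  step <- matrix(rnorm(3 * (nBeads - 1)), ncol = 3)
  step <- step / sqrt(rowSums(step^2)) * bondLength
  coords <- rbind(c(0, 0, 0), apply(step, 2, cumsum))
  list(chain = BeadChain(coords,
         source = sprintf("synthetic coil: b=%g nm, n=%d, seed=%d",
                          bondLength, nBeads, seed)),
       truth = groundTruth("coil", seed,
                           trueRg = bondLength * sqrt(nBeads / 6)))
}

#' Mix theoretical curves into a synthetic "experimental" SAXS curve
#'
#' I = sum(w_i * I_i) with optional multiplicative Gaussian noise of
#' relative scale `noiseSigmaFrac`; the sigma column is
#' `noiseSigmaFrac * I` (or 1% of I when the noise level is zero, so
#' the curve remains usable in chi-squared fits).
#'
#' @param curves list of [ScatteringCurve-class] on one common q grid.
#' @param weights non-negative weights summing to 1.
#' @param noiseSigmaFrac relative noise level.
#' @param seed RNG seed for the noise.
#' @return A [ScatteringCurve-class] with uncertainties.
#' @export
makeMixtureCurve <- function(curves, weights, noiseSigmaFrac = 0, seed = 1) {
  stopifnot(length(curves) == length(weights))
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8)
    stop("weights must be non-negative and sum to 1")
  q <- curves[[1]]@q
  for (cv in curves)
    if (length(cv@q) != length(q) || any(abs(cv@q - q) > 1e-12))
      stop("component curves must share one q grid")
  I <- Reduce(`+`, Map(function(cv, w) w * cv@intensity, curves, weights))
  if (noiseSigmaFrac > 0) {
    set.seed(seed)
    I <- I * (1 + noiseSigmaFrac * rnorm(length(I)))
    if (any(I <= 0)) stop("noise level too large: non-positive intensity")
  }
  sig <- if (noiseSigmaFrac > 0) noiseSigmaFrac * I else 0.01 * I
  ScatteringCurve(q, I, sig, id = sprintf("mixture(%s)",
    paste(signif(weights, 3), collapse = ":")))
}

#' Spidroin-like block sequence generator
#'
#' Builds an idealised repetitive core: `nRepeats` copies of a Gly-rich
#' span (GGX pattern, X cycling over Gln/Tyr/Ser/Arg) followed by a
#' poly(Ala) run, emulating the 5-10 residue Ala and 17-25 residue
#' Gly-rich repeat architecture of MaSp proteins.
#'
#' @param nRepeats number of (Gly-rich + polyA) repeat units.
#' @param polyALen poly(Ala) run length.
#' @param glyRichLen Gly-rich span length.
#' @return A single character string.
#' @export
makeSpidroinSequence <- function(nRepeats = 16, polyALen = 8,
                                 glyRichLen = 22) {
  xres <- c("Q", "Y", "S", "R")
  unit <- function(k) {
    g <- character(glyRichLen)
    xi <- 0L
    for (i in seq_len(glyRichLen)) {
      if (i %% 3 == 0) {
        xi <- xi + 1L
        g[i] <- xres[((k + xi) %% length(xres)) + 1L]
      } else g[i] <- "G"
    }
    paste0(paste(g, collapse = ""), strrep("A", polyALen))
  }
  paste(vapply(seq_len(nRepeats), unit, character(1)), collapse = "")
}

#' Synthetic surrogate for the MaSp1 repetitive core
#'
#' A deterministic 2,880-residue sequence built so that the 15-residue
#' repeat `GQGGAGAAAAAAAAG` occurs exactly 39 times and the combined
#' Gly+Ala fraction is exactly 75.0%, the two published summary
#' statistics of the *Latrodectus hesperus* MaSp1 repetitive core. The
#' real (copyrighted) sequence is not bundled; this surrogate carries
#' the same motif and composition statistics by construction, with
#' Ala-free GGX filler between motif copies so no accidental extra
#' motif occurrences can arise.
#'
#' @return A single character string of length 2880.
#' @export
makeMaspCoreSurrogate <- function() {
  motif <- "GQGGAGAAAAAAAAG"          # G5 A9 Q1
  nMotif <- 39L
  total <- 2880L
  fillerTotal <- total - nMotif * nchar(motif)   # 2295
  gaTarget <- as.integer(0.75 * total)           # 2160
  gaInMotifs <- nMotif * 14L                     # 546
  nX <- fillerTotal - (gaTarget - gaInMotifs)    # non-G/A residues: 681
  # filler = nX GGX triplets + pure-G padding, interleaved deterministically
  xres <- c("Q", "Y", "S", "R")
  triplets <- paste0("GG", xres[(seq_len(nX) - 1L) %% 4L + 1L])
  nPadG <- fillerTotal - 3L * nX                 # 252
  # spread the padding G's roughly evenly between triplets
  pad <- integer(nX + 1L)
  pad[round(seq(1, nX + 1L, length.out = nPadG))] <-
    pad[round(seq(1, nX + 1L, length.out = nPadG))] + 1L
  while (sum(pad) < nPadG) pad[1L] <- pad[1L] + 1L
  filler <- paste0(paste0(strrep("G", pad[seq_len(nX)]), triplets,
                          collapse = ""), strrep("G", pad[nX + 1L]))
  stopifnot(nchar(filler) == fillerTotal)
  # split the filler into nMotif pieces and interleave with motif copies
  sizes <- rep(fillerTotal %/% nMotif, nMotif)
  extra <- fillerTotal %% nMotif
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  pieces <- substring(filler, starts, ends)
  out <- paste0(paste0(pieces, motif, collapse = ""))
  stopifnot(nchar(out) == total)
  out
}
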