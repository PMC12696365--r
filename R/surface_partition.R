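## Rolling-ball solvent accessibility on bead spheres (Shrake-Rupley
## with a deterministic golden-spiral point lattice), burial
## classification against a random-coil reference, per-residue-type
## enrichment tables, and the continuum cylinder-shell packing model.

# deterministic, roughly uniform unit-sphere lattice (golden spiral)
sphereLattice <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- pi * (3 - sqrt(5)) * (i - 0.5)
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area of bead spheres (Shrake-Rupley)
#'
#' Each bead is a sphere of radius `beadRadius`; a probe of radius
#' `probeRadius` is rolled over it by testing a fixed lattice of
#' `nSpherePoints` quadrature points on the expanded sphere of radius
#' `beadRadius + probeRadius` against all neighbouring expanded
#' spheres. Deterministic given the lattice size; because the lattice
#' is fixed in space, areas are rotation invariant only to within the
#' quadrature resolution (well under 2% at the default density).
#'
#' The default bead radius of 0.30 nm is the effective radius of the
#' mean amino-acid residue volume (0.113 nm^3); 0.14 nm is the water
#' probe.
#'
#' @param chain a [BeadChain-class] without duplicate coordinates.
#' @param beadRadius single radius (nm) or named vector by one-letter
#'   residue code.
#' @param probeRadius probe radius in nm.
#' @param nSpherePoints quadrature points per bead (>= 92).
#' @return Numeric vector of per-bead accessible areas (nm^2).
#' @export
beadSASA <- function(chain, beadRadius = 0.30, probeRadius = 0.14,
                     nSpherePoints = 960L) {
  stopifnot(is(chain, "BeadChain"))
  if (nSpherePoints < 92L) stop("nSpherePoints must be >= 92")
  if (probeRadius < 0) stop("probeRadius must be >= 0")
  x <- beadCoords(chain)
  n <- nrow(x)
  radii <- resolveRadii(beadRadius, beadResidues(chain))
  if (n > 1L && any(dist(x) == 0)) stop("duplicate bead coordinates")
  lat <- sphereLattice(as.integer(nSpherePoints))
  rexp <- radii + probeRadius
  # neighbour lists from the pairwise distances (chains here are small
  # enough that the full dist fits comfortably)
  nb <- vector("list", n)
  if (n > 1L) {
    dm <- as.matrix(dist(x))
    cutoff <- outer(rexp, rexp, `+`)
    for (i in seq_len(n)) nb[[i]] <- setdiff(which(dm[i, ] < cutoff[i, ]), i)
  }
  areas <- numeric(n)
  for (i in seq_len(n)) {
    pts <- sweep(lat * rexp[i], 2, x[i, ], `+`)
    acc <- rep(TRUE, nrow(pts))
    for (j in nb[[i]]) {
      if (!any(acc)) break
      dd <- (pts[, 1] - x[j, 1])^2 + (pts[, 2] - x[j, 2])^2 +
            (pts[, 3] - x[j, 3])^2
      acc <- acc & dd > rexp[j]^2
    }
    areas[i] <- 4 * pi * rexp[i]^2 * mean(acc)
  }
  areas
}

resolveRadii <- function(beadRadius, residues) {
  if (length(beadRadius) == 1L && is.null(names(beadRadius)))
    return(rep(beadRadius, length(residues)))
  miss <- setdiff(unique(residues), names(beadRadius))
  if (length(miss))
    stop("no bead radius for residue type(s): ", paste(miss, collapse = ", "))
  unname(beadRadius[residues])
}

#' Random-coil reference areas per residue type
#'
#' The reference exposure of a residue type is the accessible area of
#' the central bead in a collinear 3-bead construct at 0.38 nm bond
#' spacing -- the bead-level analogue of the Gly-X-Gly tripeptide
#' reference used by residue-level exposure classifiers.
#'
#' @param residueTypes one-letter codes to compute references for.
#' @inheritParams beadSASA
#' @return Named numeric vector of reference areas (nm^2).
#' @export
coilReferenceAreas <- function(residueTypes, beadRadius = 0.30,
                               probeRadius = 0.14, nSpherePoints = 960L) {
  residueTypes <- unique(residueTypes)
  vapply(residueTypes, function(rt) {
    tri <- BeadChain(rbind(c(-0.38, 0, 0), c(0, 0, 0), c(0.38, 0, 0)),
                     residues = rt)
    beadSASA(tri, beadRadius, probeRadius, nSpherePoints)[2L]
  }, numeric(1))
}

#' Classify beads as buried / intermediate / exposed
#'
#' A bead's exposure ratio is its area over the random-coil reference
#' for its residue type; ratios below the buried threshold (default
#' 0.2) are "buried", above the exposed threshold (default 0.5)
#' "exposed", and the rest -- beads with exposure similar to the
#' random-coil value -- "intermediate" (near the surface).
#'
#' @param areas per-bead areas from [beadSASA()].
#' @param chain the [BeadChain-class] the areas belong to.
#' @param thresholds `c(buried = 0.2, exposed = 0.5)` exposure-ratio
#'   cutoffs.
#' @param reference optional named reference areas (computed with
#'   [coilReferenceAreas()] when omitted; pass matching radii if you
#'   changed them).
#' @inheritParams beadSASA
#' @return Character vector in `{"buried", "intermediate", "exposed"}`.
#' @export
classifyBurial <- function(areas, chain,
                           thresholds = c(buried = 0.2, exposed = 0.5),
                           reference = NULL, beadRadius = 0.30,
                           probeRadius = 0.14, nSpherePoints = 960L) {
  stopifnot(is(chain, "BeadChain"), length(areas) == nBeads(chain))
  res <- beadResidues(chain)
  if (is.null(reference))
    reference <- coilReferenceAreas(unique(res), beadRadius, probeRadius,
                                    nSpherePoints)
  miss <- setdiff(unique(res), names(reference))
  if (length(miss))
    stop("no reference area for residue type(s): ",
         paste(miss, collapse = ", "))
  ratio <- unname(areas / reference[res])
  ifelse(ratio < thresholds[["buried"]], "buried",
         ifelse(ratio > thresholds[["exposed"]], "exposed", "intermediate"))
}

#' Burial statistics per residue type
#'
#' Counts and fractions of buried / intermediate / exposed beads for
#' each residue type plus an `ALL` row with the overall three-way
#' split.
#'
#' @param classes per-bead classes from [classifyBurial()].
#' @param chain the corresponding [BeadChain-class].
#' @return A data.frame (one row per residue type plus `ALL`) with
#'   counts `n`, `buried`, `intermediate`, `exposed` and the matching
#'   fractions.
#' @export
burialTable <- function(classes, chain) {
  stopifnot(is(chain, "BeadChain"), length(classes) == nBeads(chain))
  res <- beadResidues(chain)
  lv <- c("buried", "intermediate", "exposed")
  rowFor <- function(sel, label) {
    tab <- table(factor(classes[sel], levels = lv))
    n <- sum(tab)
    data.frame(residue = label, n = n,
               buried = as.integer(tab["buried"]),
               intermediate = as.integer(tab["intermediate"]),
               exposed = as.integer(tab["exposed"]),
               f_buried = as.numeric(tab["buried"]) / n,
               f_intermediate = as.numeric(tab["intermediate"]) / n,
               f_exposed = as.numeric(tab["exposed"]) / n,
               stringsAsFactors = FALSE)
  }
  types <- sort(unique(res))
  out <- do.call(rbind, c(lapply(types, function(t) rowFor(res == t, t)),
                          list(rowFor(rep(TRUE, length(res)), "ALL"))))
  rownames(out) <- NULL
  out
}

#' Continuum cylinder-shell packing model
#'
#' Models the tubule as a cylinder of radius `radius` and length
#' `length` whose surface layer (including the end caps) is a shell of
#' thickness `thickness`; the bulk (buried) fraction is the volume
#' ratio `((R - t)^2 (L - 2t)) / (R^2 L)`. With the tubule geometry of
#' a 50 nm cylinder of 4 nm diameter and a shell one effective residue
#' radius (0.3 nm) thick this yields the ~70/30 bulk/surface split.
#' The sphere-packing fraction `n * v / (pi R^2 L)` is reported as a
#' plausibility check when a residue count is supplied.
#'
#' @param radius cylinder radius R (nm).
#' @param length cylinder length L (nm); requires `L > 2 * thickness`.
#' @param thickness shell thickness t (nm), `0 < t < R`. The default
#'   0.3 nm is the effective radius of the 0.113 nm^3 mean residue
#'   volume.
#' @param nResidues optional residue count for the packing fraction.
#' @param residueVolume per-residue volume (nm^3).
#' @return `list(buried_fraction, surface_fraction, packing_fraction)`.
#' @examples
#' cylinderShellSplit(radius = 2, length = 50)  # the 70-30 split
#' @export
cylinderShellSplit <- function(radius, length, thickness = 0.3,
                               nResidues = NULL, residueVolume = 0.113) {
  if (!(thickness >= 0 && thickness < radius))
    stop("need 0 <= thickness < radius")
  if (2 * thickness >= length) stop("need length > 2 * thickness")
  buried <- ((radius - thickness)^2 * (length - 2 * thickness)) /
            (radius^2 * length)
  pack <- if (is.null(nResidues)) NA_real_ else
    nResidues * residueVolume / (pi * radius^2 * length)
  list(buried_fraction = buried, surface_fraction = 1 - buried,
       packing_fraction = pack)
}
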