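## Rigid-body superposition (Kabsch), stapling of terminal-domain
## structures onto core chains, and template-guided dimer assembly.

#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Least-squares proper rotation + translation taking `mobile` onto
#' `target`; the reflection branch of the SVD solution is corrected so
#' `det(R) = +1` always, including for mirror-image inputs.
#'
#' @param mobile,target equal-length coordinate matrices (>= 3
#'   non-collinear points).
#' @param allowDegenerate allow collinear anchor sets (the rotation
#'   about the common line is then arbitrary but the least-squares fit
#'   is still attained); used by [stapleTermini()], whose straight
#'   bead anchors are legitimately collinear.
#' @return A `RigidTransform` list with `rotation` (3x3), `translation`
#'   (length 3) and `rmsd` (nm) over the fitted points. Apply with
#'   [applyTransform()].
#' @export
kabschSuperpose <- function(mobile, target, allowDegenerate = FALSE) {
  A <- as.matrix(mobile); B <- as.matrix(target)
  if (!all(dim(A) == dim(B))) stop("coordinate sets differ in size")
  if (nrow(A) < 3L) stop("need at least 3 anchor points")
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  if (!allowDegenerate && (qr(A0)$rank < 2L || qr(B0)$rank < 2L))
    stop("anchor points are collinear; superposition is ill-defined")
  H <- t(A0) %*% B0
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- cb - as.vector(R %*% ca)
  fitted <- t(R %*% t(A)) + matrix(tr, nrow(A), 3, byrow = TRUE)
  structure(list(rotation = R, translation = tr,
                 rmsd = sqrt(mean(rowSums((fitted - B)^2)))),
            class = "RigidTransform")
}

#' @export
print.RigidTransform <- function(x, ...) {
  cat(sprintf("RigidTransform: rmsd = %.4g nm, det(R) = %+.3f\n",
              x$rmsd, det(x$rotation)))
  invisible(x)
}

#' Apply a rigid transform to coordinates or a BeadChain
#'
#' @param x a [BeadChain-class] or coordinate matrix.
#' @param transform a `RigidTransform` from [kabschSuperpose()].
#' @return Object of the same type with transformed coordinates.
#' @export
applyTransform <- function(x, transform) {
  doit <- function(m)
    t(transform$rotation %*% t(m)) +
      matrix(transform$translation, nrow(m), 3, byrow = TRUE)
  if (is(x, "BeadChain")) {
    BeadChain(doit(beadCoords(x)), beadResidues(x), chainLabels(x),
              modelId = modelId(x), source = x@source)
  } else doit(as.matrix(x))
}

#' Staple terminal domains onto a core chain
#'
#' The N-terminal structure is rigidly superposed so its last
#' `anchorLength` beads match the core's first `anchorLength` beads
#' (the C-terminal structure symmetrically at the other end); the
#' overlapping anchor beads are merged once, keeping the core copy.
#' The core's internal coordinates are never moved. Anchors whose
#' superposition rmsd exceeds `maxAnchorRmsd` abort with an error;
#' seam bead spacings outside [0.2, 0.8] nm give a warning.
#'
#' @param core,nterm,cterm [BeadChain-class] objects; `nterm`/`cterm`
#'   may be `NULL` to staple only one end.
#' @param anchorLength number of overlap beads per seam (>= 3).
#' @param maxAnchorRmsd acceptance threshold for the anchor rmsd (nm).
#' @return A [BeadChain-class] of length
#'   `len(nterm) + len(core) + len(cterm) - 2 * anchorLength`.
#' @export
stapleTermini <- function(core, nterm = NULL, cterm = NULL,
                          anchorLength = 5L, maxAnchorRmsd = 0.5) {
  stopifnot(is(core, "BeadChain"))
  a <- as.integer(anchorLength)
  if (a < 3L) stop("anchorLength must be >= 3")
  if (nBeads(core) < a) stop("core shorter than the anchor")
  cx <- beadCoords(core)
  pieces_coords <- list(); pieces_res <- list()

  if (!is.null(nterm)) {
    stopifnot(is(nterm, "BeadChain"))
    n <- nBeads(nterm)
    if (n <= a) stop("nterm must be longer than the anchor")
    tf <- kabschSuperpose(beadCoords(nterm)[(n - a + 1L):n, , drop = FALSE],
                          cx[1:a, , drop = FALSE], allowDegenerate = TRUE)
    if (tf$rmsd > maxAnchorRmsd)
      stop(sprintf("N-terminal anchor rmsd %.3f nm exceeds limit %.3f nm",
                   tf$rmsd, maxAnchorRmsd))
    moved <- applyTransform(beadCoords(nterm), tf)
    pieces_coords <- c(pieces_coords, list(moved[1:(n - a), , drop = FALSE]))
    pieces_res <- c(pieces_res, list(beadResidues(nterm)[1:(n - a)]))
  }
  pieces_coords <- c(pieces_coords, list(cx))
  pieces_res <- c(pieces_res, list(beadResidues(core)))
  if (!is.null(cterm)) {
    stopifnot(is(cterm, "BeadChain"))
    m <- nBeads(cterm)
    if (m <= a) stop("cterm must be longer than the anchor")
    nc <- nBeads(core)
    tf <- kabschSuperpose(beadCoords(cterm)[1:a, , drop = FALSE],
                          cx[(nc - a + 1L):nc, , drop = FALSE],
                          allowDegenerate = TRUE)
    if (tf$rmsd > maxAnchorRmsd)
      stop(sprintf("C-terminal anchor rmsd %.3f nm exceeds limit %.3f nm",
                   tf$rmsd, maxAnchorRmsd))
    moved <- applyTransform(beadCoords(cterm), tf)
    pieces_coords <- c(pieces_coords, list(moved[(a + 1L):m, , drop = FALSE]))
    pieces_res <- c(pieces_res, list(beadResidues(cterm)[(a + 1L):m]))
  }
  coords <- do.call(rbind, pieces_coords)
  out <- BeadChain(coords, unlist(pieces_res), modelId = modelId(core),
                   source = paste0("stapled: ", core@source))
  seam <- sqrt(rowSums(diff(coords)^2))
  bad <- which(seam < 0.2 | seam > 0.8)
  # only complain about spacings created at the seams, not inside pieces
  seamIdx <- integer(0)
  if (!is.null(nterm)) seamIdx <- c(seamIdx, nBeads(nterm) - a)
  if (!is.null(cterm)) seamIdx <- c(seamIdx, nBeads(out) - (nBeads(cterm) - a))
  if (length(intersect(bad, seamIdx)))
    warning("seam bead spacing outside [0.2, 0.8] nm at join(s): ",
            paste(intersect(bad, seamIdx), collapse = ", "))
  out
}

#' Build a dimer by aligning two monomers on a two-chain template
#'
#' Each monomer's anchor beads (by default its first
#' `template-chain-length` beads, i.e. the N-terminal region) are
#' superposed onto the corresponding template chain; the transformed
#' monomers become chains A and B of the dimer. Inter-monomer contacts
#' closer than `clashDistance` are reported as warnings, not errors --
#' combinatorial dimers built from independently folded conformers are
#' expected to clash occasionally and are used only for scattering.
#'
#' @param monoA,monoB monomer [BeadChain-class] objects.
#' @param template a two-chain [BeadChain-class] (e.g. a dimerisation
#'   crystal structure reduced to beads).
#' @param anchorMap optional `list(a = <indices into monoA>, b =
#'   <indices into monoB>)`; each must match its template chain
#'   length. Both entries are required when supplied.
#' @param clashDistance contact-warning threshold (nm).
#' @return A two-chain [BeadChain-class] with chains `"A"` and `"B"`
#'   and attribute `minInterDistance`.
#' @export
buildDimer <- function(monoA, monoB, template, anchorMap = NULL,
                       clashDistance = 0.2) {
  stopifnot(is(monoA, "BeadChain"), is(monoB, "BeadChain"),
            is(template, "BeadChain"))
  tchains <- splitChains(template)
  if (length(tchains) != 2L)
    stop("template must have exactly 2 chains, found ", length(tchains))
  n1 <- nBeads(tchains[[1]]); n2 <- nBeads(tchains[[2]])
  if (is.null(anchorMap)) {
    anchorMap <- list(a = seq_len(n1), b = seq_len(n2))
  } else {
    if (is.null(anchorMap$a) || is.null(anchorMap$b))
      stop("anchorMap must provide entries 'a' and 'b'")
  }
  if (length(anchorMap$a) != n1 || length(anchorMap$b) != n2)
    stop("anchor lengths must match the template chain lengths")
  place <- function(mono, anchor, tmpl) {
    tf <- kabschSuperpose(beadCoords(mono)[anchor, , drop = FALSE],
                          beadCoords(tmpl), allowDegenerate = TRUE)
    list(chain = applyTransform(mono, tf), rmsd = tf$rmsd)
  }
  pa <- place(monoA, anchorMap$a, tchains[[1]])
  pb <- place(monoB, anchorMap$b, tchains[[2]])
  xa <- beadCoords(pa$chain); xb <- beadCoords(pb$chain)
  dmin <- minCrossDistance(xa, xb)
  if (dmin < clashDistance)
    warning(sprintf("inter-monomer contact %.3f nm below clash distance %.3f nm",
                    dmin, clashDistance))
  out <- BeadChain(rbind(xa, xb),
                   c(beadResidues(monoA), beadResidues(monoB)),
                   c(rep("A", nrow(xa)), rep("B", nrow(xb))),
                   source = "dimer")
  attr(out, "minInterDistance") <- dmin
  attr(out, "anchorRmsd") <- c(a = pa$rmsd, b = pb$rmsd)
  out
}

minCrossDistance <- function(xa, xb) {
  best <- Inf
  block <- 1000L
  sb <- rowSums(xb^2)
  for (i0 in seq(1L, nrow(xa), by = block)) {
    i1 <- min(nrow(xa), i0 + block - 1L)
    g <- outer(rowSums(xa[i0:i1, , drop = FALSE]^2), sb, `+`) -
      2 * xa[i0:i1, , drop = FALSE] %*% t(xb)
    best <- min(best, min(g))
  }
  sqrt(max(best, 0))
}

#' All ordered dimers from a monomer pool
#'
#' Combinatorial, ordered pairing: a pool of n monomers yields n^2
#' dimers (pairing a 29-monomer pool gives 841).
#'
#' @param monomers list of [BeadChain-class] monomers (named if you
#'   want meaningful dimer ids).
#' @inheritParams buildDimer
#' @return Named list of dimers; names are `"<i>_<j>"` built from the
#'   monomer names.
#' @export
buildDimerPool <- function(monomers, template, anchorMap = NULL,
                           clashDistance = 0.2) {
  stopifnot(is.list(monomers), length(monomers) >= 1L)
  nm <- names(monomers)
  if (is.null(nm)) nm <- sprintf("%04d", seq_along(monomers))
  out <- list()
  for (i in seq_along(monomers))
    for (j in seq_along(monomers)) {
      d <- suppressWarnings(
        buildDimer(monomers[[i]], monomers[[j]], template, anchorMap,
                   clashDistance))
      out[[paste(nm[i], nm[j], sep = "_")]] <- d
    }
  out
}
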