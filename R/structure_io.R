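## File formats: bead-model PDB (read through bio3d, written with a
## minimal fixed-width writer so coarse-grained beads appear as CA
## records that standard viewers can open), FASTA through Biostrings,
## and 3-column SAXS .dat files.

CANONICAL_AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Read a (possibly multi-model) PDB file as bead chains
#'
#' One bead per residue: the representative atom (default `"CA"`, which
#' is also how CG beads are written by [writeBeadPDB()]) or, when a
#' residue has no atom of that name, the centroid of its atoms.
#' Coordinates are converted from Angstrom to nm.
#'
#' @param path PDB file.
#' @param modelSelect `"all"` (default) or a vector of 0-based model
#'   indices.
#' @param atomName representative atom name per residue.
#' @return List of [BeadChain-class], one per selected MODEL, with
#'   `modelId` 0, 1, ... in file order.
#' @export
readBeadPDB <- function(path, modelSelect = "all", atomName = "CA") {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
    error = function(e) stop("unreadable PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  if (nrow(at) == 0L) stop("no ATOM/HETATM records in ", path)
  key <- paste(at$chain, at$resno, at$insert, sep = "|")
  groups <- split(seq_len(nrow(at)), factor(key, levels = unique(key)))
  rep_idx <- lapply(groups, function(ix) {
    hit <- ix[at$elety[ix] == atomName]
    if (length(hit)) hit[1L] else ix      # centroid fallback
  })
  nres <- length(groups)
  if (nres == 0L) stop("zero residues after filtering in ", path)
  res3 <- vapply(groups, function(ix) at$resid[ix[1L]], character(1))
  res1 <- suppressWarnings(bio3d::aa321(res3))
  res1[is.na(res1) | !(res1 %in% CANONICAL_AA)] <- "X"
  chn <- vapply(groups, function(ix) {
    ch <- at$chain[ix[1L]]
    if (is.na(ch) || !nzchar(ch)) "A" else ch
  }, character(1))

  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  nmod <- nrow(xyz)
  sel <- if (identical(modelSelect, "all")) 0:(nmod - 1L)
         else as.integer(modelSelect)
  if (any(sel < 0L | sel >= nmod))
    stop("modelSelect out of range: file has ", nmod, " model(s)")

  lapply(sel, function(m) {
    cm <- matrix(xyz[m + 1L, ], ncol = 3L, byrow = TRUE)
    bead <- t(vapply(rep_idx, function(ix) colMeans(cm[ix, , drop = FALSE]),
                     numeric(3)))
    if (!all(is.finite(bead)))
      stop("non-finite coordinates in model ", m, " of ", path)
    BeadChain(bead * 0.1, res1, chn, modelId = m, source = path)
  })
}

#' Write bead chains to a PDB file
#'
#' Beads are written as CA records (Gly for unknown residue codes) with
#' nm converted back to Angstrom; a list of chains becomes a
#' MODEL/ENDMDL multi-model file. Fixed-width `%8.3f` coordinates give a
#' write/read round trip exact to 1e-3 Angstrom.
#'
#' @param x a [BeadChain-class] or list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeBeadPDB <- function(x, path) {
  if (is(x, "BeadChain")) x <- list(x)
  stopifnot(all(vapply(x, is, logical(1), "BeadChain")))
  aa123 <- function(a) {
    r <- suppressWarnings(bio3d::aa123(a))
    r[is.na(r) | r == "XXX"] <- "GLY"
    r
  }
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(x) > 1L
  for (m in seq_along(x)) {
    bc <- x[[m]]
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    xyz <- bc@coords * 10            # nm -> Angstrom
    res3 <- aa123(bc@residues)
    lines <- sprintf(
      "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
      seq_len(nrow(xyz)) %% 100000L, res3, substr(bc@chains, 1, 1),
      seq_len(nrow(xyz)) %% 10000L, xyz[, 1], xyz[, 2], xyz[, 3])
    writeLines(lines, con)
    writeLines("TER", con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a 3-column SAXS curve (q, I, sigma)
#'
#' Comment lines (`#`) and non-numeric header lines are skipped; extra
#' columns beyond the third are ignored; rows with q <= 0 or I <= 0 are
#' dropped with a message.
#'
#' @param path .dat file with whitespace-separated columns.
#' @param unit `"nm^-1"` (default) or `"A^-1"`; Angstrom^-1 input is
#'   converted to the internal nm^-1.
#' @param sigmaPolicy what to do when the sigma column is missing:
#'   `"error"` (default; silently invented uncertainties distort chi2)
#'   or `"fraction"`, which sets sigma = `sigmaFraction * I`.
#' @param sigmaFraction relative sigma used under
#'   `sigmaPolicy = "fraction"`.
#' @return A [ScatteringCurve-class] with uncertainties.
#' @export
readSAXS <- function(path, unit = c("nm^-1", "A^-1"),
                     sigmaPolicy = c("error", "fraction"),
                     sigmaFraction = 0.01) {
  unit <- match.arg(unit)
  sigmaPolicy <- match.arg(sigmaPolicy)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  rows <- lapply(strsplit(lines, "[[:space:]]+"), function(tok) {
    v <- suppressWarnings(as.numeric(tok))
    if (anyNA(v) || length(v) < 2L) NULL else v
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) < 2L) stop("fewer than 2 usable data rows in ", path)
  ncols <- min(vapply(rows, length, integer(1)))
  if (ncols < 3L && sigmaPolicy == "error")
    stop("no sigma column in ", path,
         "; set sigmaPolicy = \"fraction\" to use sigma = ",
         sigmaFraction, " * I")
  m <- do.call(rbind, lapply(rows, function(v) v[seq_len(min(3L, ncols))]))
  keep <- m[, 1] > 0 & m[, 2] > 0
  if (sum(!keep) > 0)
    message("readSAXS: dropped ", sum(!keep), " row(s) with q <= 0 or I <= 0")
  m <- m[keep, , drop = FALSE]
  if (nrow(m) < 2L) stop("fewer than 2 usable data rows in ", path)
  q <- m[, 1]
  if (unit == "A^-1") q <- q * 10
  if (any(diff(q) <= 0)) stop("non-monotone q grid in ", path)
  sig <- if (ncols >= 3L) m[, 3] else sigmaFraction * m[, 2]
  ScatteringCurve(q, m[, 2], sig, id = basename(path))
}

#' Write a ScatteringCurve to a 3-column .dat file
#'
#' @param curve a [ScatteringCurve-class]; theoretical curves are
#'   written with a zero sigma column.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSAXS <- function(curve, path) {
  stopifnot(is(curve, "ScatteringCurve"))
  sig <- if (length(curve@sigma)) curve@sigma else rep(0, length(curve@q))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# q(nm^-1) I sigma  [%s]", curve@id), con)
  writeLines(sprintf("%.8g %.8g %.8g", curve@q, curve@intensity, sig), con)
  invisible(path)
}

#' Read / write FASTA sequence records
#'
#' Thin wrappers around Biostrings that enforce the 20-canonical-letter
#' alphabet. `readSequences` errors on an empty file and reports the
#' 0-based position of the first illegal letter.
#'
#' @param path FASTA file.
#' @return `readSequences`: a named character vector of sequences.
#' @export
readSequences <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) stop("cannot parse FASTA '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  seqs <- setNames(as.character(set), names(set))
  for (nm in names(seqs)) assertCanonical(seqs[[nm]], nm)
  seqs
}

#' @rdname readSequences
#' @param records named character vector of amino-acid sequences.
#' @param width line-wrap width.
#' @export
writeSequences <- function(records, path, width = 60L) {
  stopifnot(is.character(records), length(records) >= 1L)
  if (is.null(names(records)))
    names(records) <- paste0("seq", seq_along(records))
  for (nm in names(records)) assertCanonical(records[[nm]], nm)
  set <- Biostrings::AAStringSet(records)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

assertCanonical <- function(seq, label = "sequence") {
  if (!nzchar(seq)) stop("empty sequence in record '", label, "'")
  ch <- strsplit(seq, "")[[1]]
  bad <- which(!(ch %in% CANONICAL_AA))
  if (length(bad))
    stop("illegal residue letter '", ch[bad[1]], "' in record '", label,
         "' at 0-based position ", bad[1] - 1L)
  invisible(TRUE)
}
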