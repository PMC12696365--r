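## Amphiphilic block architecture of spidroin sequences: poly(Ala) /
## Gly-rich segmentation, composition and motif statistics, and the
## mutant-series generators (all-Gly, all-Ala, blockified, knockouts,
## scrambles, poly(Ala) consolidation). All intervals are 0-based,
## half-open [start, end).

seqChars <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) stop("empty sequence")
  strsplit(seq, "")[[1]]
}

#' Segment a sequence into poly(Ala), Gly-rich and other blocks
#'
#' Poly(Ala) blocks are maximal runs of `A` of length >= `minPolyA`
#' (the native runs are 5-10 residues; the default of 4 keeps
#' poly(Gly-Ala) stretches from merging into them). The remaining
#' spans are `gly_rich` when their Gly fraction reaches
#' `glyRichThreshold`, else `other`. Blocks tile the sequence with no
#' gaps or overlaps.
#'
#' @param seq amino-acid string.
#' @param minPolyA minimum poly(Ala) run length.
#' @param glyRichThreshold Gly fraction for the gly_rich class.
#' @return data.frame with columns `kind`, `start`, `end` (0-based
#'   half-open), `length`, `gly_fraction`, `ala_fraction`.
#' @examples
#' segmentBlocks("GQGGAGAAAAAAAAG")
#' @export
segmentBlocks <- function(seq, minPolyA = 4L, glyRichThreshold = 0.4) {
  ch <- seqChars(seq)
  r <- rle(ch == "A")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  isPolyA <- r$values & r$lengths >= minPolyA
  blocks <- list()
  i <- 1L
  while (i <= length(r$lengths)) {
    if (isPolyA[i]) {
      blocks <- c(blocks, list(c(starts[i], ends[i], 1L)))
      i <- i + 1L
    } else {
      j <- i
      while (j < length(r$lengths) && !isPolyA[j + 1L]) j <- j + 1L
      blocks <- c(blocks, list(c(starts[i], ends[j], 0L)))
      i <- j + 1L
    }
  }
  out <- do.call(rbind, lapply(blocks, function(b) {
    span <- ch[b[1]:b[2]]
    gf <- mean(span == "G"); af <- mean(span == "A")
    kind <- if (b[3] == 1L) "polyA"
            else if (gf >= glyRichThreshold) "gly_rich" else "other"
    data.frame(kind = kind, start = b[1] - 1L, end = b[2],
               length = b[2] - b[1] + 1L,
               gly_fraction = gf, ala_fraction = af,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Residue composition of a sequence
#'
#' @param seq amino-acid string.
#' @param topK how many of the most frequent residues to report the
#'   combined coverage of (default 6, matching the observation that a
#'   handful of residue types dominate spidroin cores).
#' @return `list(counts, fractions, gly_ala_fraction, top_k_residues,
#'   top_k_coverage, length)`.
#' @export
residueComposition <- function(seq, topK = 6L) {
  ch <- seqChars(seq)
  counts <- table(factor(ch, levels = CANONICAL_AA))
  counts <- counts[counts > 0]
  fr <- as.numeric(counts) / length(ch)
  names(fr) <- names(counts)
  ord <- order(fr, decreasing = TRUE)
  k <- min(topK, length(fr))
  list(counts = setNames(as.integer(counts), names(counts)),
       fractions = fr,
       gly_ala_fraction = sum(fr[names(fr) %in% c("G", "A")]),
       top_k_residues = names(fr)[ord[seq_len(k)]],
       top_k_coverage = sum(fr[ord[seq_len(k)]]),
       length = length(ch))
}

#' Count motif occurrences
#'
#' Non-overlapping, left-to-right greedy count by default; the
#' overlapping mode counts every start index. A motif longer than the
#' sequence counts 0 (not an error).
#'
#' @param seq amino-acid string.
#' @param motif non-empty motif string.
#' @param overlapping count overlapping occurrences?
#' @return Integer count.
#' @export
countMotif <- function(seq, motif, overlapping = FALSE) {
  stopifnot(nzchar(motif))
  if (nchar(motif) > nchar(seq)) return(0L)
  if (overlapping) {
    hits <- gregexpr(paste0("(?=", escapeRegex(motif), ")"), seq,
                     perl = TRUE)[[1]]
  } else {
    hits <- gregexpr(motif, seq, fixed = TRUE)[[1]]
  }
  if (hits[1] == -1L) 0L else length(hits)
}

escapeRegex <- function(s) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", s)

#' Mutant-series sequence operations
#'
#' Generates the standard mutant constructs used to probe how the
#' amphiphilic block pattern controls tubule formation:
#' * `all_gly` / `all_ala`: every residue becomes Gly / Ala;
#' * `blockify_GA`: all non-Gly/Ala residues become Gly, leaving the
#'   native Gly/Ala block pattern with no polar X residues;
#' * `knockout`: every occurrence of `knockoutResidue` is replaced by
#'   `replacement` (default Gly); an absent residue warns and returns
#'   the sequence unchanged;
#' * `scramble`: a uniform random permutation (seeded);
#' * `consolidate_polyA`: removes all poly(Ala)-block residues and
#'   reinserts them as `nRegions` equal-as-possible contiguous
#'   A-stretches at evenly spaced points of the depleted sequence.
#'
#' Every operation preserves sequence length; scramble and
#' consolidation additionally preserve the residue multiset.
#'
#' @param seq amino-acid string.
#' @param operation one of `"all_gly"`, `"all_ala"`, `"blockify_GA"`,
#'   `"knockout"`, `"scramble"`, `"consolidate_polyA"`.
#' @param knockoutResidue one-letter code for `knockout`.
#' @param replacement replacement code for `knockout` (default `"G"`).
#' @param nRegions number of poly(Ala) stretches for
#'   `consolidate_polyA`.
#' @param seed RNG seed for `scramble`.
#' @param minPolyA passed to [segmentBlocks()] for consolidation.
#' @return The mutated sequence string.
#' @export
mutateSequence <- function(seq,
                           operation = c("all_gly", "all_ala",
                                         "blockify_GA", "knockout",
                                         "scramble", "consolidate_polyA"),
                           knockoutResidue = "Y", replacement = "G",
                           nRegions = 1L, seed = 1L, minPolyA = 4L) {
  operation <- match.arg(operation)
  ch <- seqChars(seq)
  n <- length(ch)
  out <- switch(operation,
    all_gly = rep("G", n),
    all_ala = rep("A", n),
    blockify_GA = ifelse(ch %in% c("G", "A"), ch, "G"),
    knockout = {
      if (!any(ch == knockoutResidue)) {
        warning("knockout residue '", knockoutResidue,
                "' absent; sequence unchanged")
        ch
      } else ifelse(ch == knockoutResidue, replacement, ch)
    },
    scramble = {
      set.seed(seed)
      ch[sample.int(n)]
    },
    consolidate_polyA = {
      blocks <- segmentBlocks(seq, minPolyA = minPolyA)
      pa <- blocks[blocks$kind == "polyA", , drop = FALSE]
      nA <- sum(pa$length)
      if (nA == 0L) stop("no poly(Ala) blocks to consolidate")
      nRegions <- as.integer(nRegions)
      if (nRegions < 1L || nRegions > nA)
        stop("nRegions must be between 1 and the poly(Ala) residue count (",
             nA, ")")
      inPolyA <- rep(FALSE, n)
      for (k in seq_len(nrow(pa)))
        inPolyA[(pa$start[k] + 1L):pa$end[k]] <- TRUE
      depleted <- ch[!inPolyA]
      ld <- length(depleted)
      sizes <- rep(nA %/% nRegions, nRegions)
      if (nA %% nRegions > 0)
        sizes[seq_len(nA %% nRegions)] <- sizes[seq_len(nA %% nRegions)] + 1L
      cuts <- round(seq_len(nRegions) * ld / (nRegions + 1L))
      pieces <- character(0)
      prev <- 0L
      for (k in seq_len(nRegions)) {
        pieces <- c(pieces, depleted[seq_len(cuts[k] - prev) + prev],
                    rep("A", sizes[k]))
        prev <- cuts[k]
      }
      c(pieces, if (prev < ld) depleted[(prev + 1L):ld] else character(0))
    })
  paste(out, collapse = "")
}

#' Repeat-unit statistics of a block map
#'
#' @param seq amino-acid string.
#' @param blocks optional precomputed [segmentBlocks()] result.
#' @param ... passed to [segmentBlocks()] when `blocks` is missing.
#' @return `list(n_polyA, polyA_lengths, gly_rich_lengths,
#'   alternation_index)` where the alternation index is the fraction
#'   of poly(Ala) blocks flanked by gly_rich blocks on both sides.
#' @export
repeatUnitStats <- function(seq, blocks = NULL, ...) {
  if (is.null(blocks)) blocks <- segmentBlocks(seq, ...)
  pa <- which(blocks$kind == "polyA")
  flanked <- vapply(pa, function(i) {
    i > 1L && i < nrow(blocks) &&
      blocks$kind[i - 1L] == "gly_rich" && blocks$kind[i + 1L] == "gly_rich"
  }, logical(1))
  list(n_polyA = length(pa),
       polyA_lengths = blocks$length[pa],
       gly_rich_lengths = blocks$length[blocks$kind == "gly_rich"],
       alternation_index = if (length(pa)) mean(flanked) else NA_real_)
}
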