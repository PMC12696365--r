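test_that("block segmentation finds poly(Ala) runs and tiles the sequence", {
  b <- segmentBlocks("GQGGAGAAAAAAAAG")
  pa <- b[b$kind == "polyA", ]
  expect_equal(nrow(pa), 1L)
  expect_equal(pa$start, 6L)   # 0-based, half-open [6, 14)
  expect_equal(pa$end, 14L)
  expect_equal(pa$length, 8L)

  expect_equal(segmentBlocks("AAAA")$kind, "polyA")
  expect_equal(segmentBlocks("GGGGG")$kind, "gly_rich")

  # tiling invariant: no gaps, no overlaps, full coverage
  set.seed(61)
  for (i in 1:10) {
    s <- paste(sample(c("A", "G", "Q", "Y", "S"), 200, replace = TRUE,
                      prob = c(0.35, 0.4, 0.1, 0.1, 0.05)), collapse = "")
    b <- segmentBlocks(s)
    expect_equal(b$start[1], 0L)
    expect_equal(b$end[nrow(b)], 200L)
    if (nrow(b) > 1)
      expect_equal(b$start[-1], b$end[-nrow(b)])
  }
  expect_error(segmentBlocks(""), "empty")
})

test_that("composition tables count residues exactly", {
  comp <- residueComposition("GQGGAGAAAAAAAAG")
  expect_equal(unname(comp$counts[c("A", "G", "Q")]), c(9L, 5L, 1L))
  expect_equal(unname(comp$fractions["A"]), 9 / 15)
  expect_equal(comp$gly_ala_fraction, 14 / 15)
  expect_equal(residueComposition("AAAA")$gly_ala_fraction, 1)
  expect_equal(sum(comp$fractions), 1)
})

test_that("motif counting is greedy non-overlapping with an overlapping mode", {
  m15 <- "GQGGAGAAAAAAAAG"
  expect_equal(countMotif(strrep(m15, 3), m15), 3L)
  expect_equal(countMotif("AAAA", "AA"), 2L)
  expect_equal(countMotif("AAAA", "AA", overlapping = TRUE), 3L)
  expect_equal(countMotif(m15, m15), 1L)
  expect_equal(countMotif("GAG", "GAGA"), 0L)
})

test_that("the surrogate MaSp1 core carries the published summary statistics", {
  s <- makeMaspCoreSurrogate()
  expect_equal(nchar(s), 2880L)
  expect_equal(countMotif(s, "GQGGAGAAAAAAAAG"), 39L)
  expect_equal(countMotif(s, "GQGGAGAAAAAAAAG", overlapping = TRUE), 39L)
  expect_equal(residueComposition(s)$gly_ala_fraction, 0.75)
  # the motif accounts for ~20% of the core
  expect_equal(39 * 15 / 2880, 0.203, tolerance = 0.01)
  # deterministic
  expect_identical(s, makeMaspCoreSurrogate())
})

test_that("mutation operators preserve length (and multiset where promised)", {
  expect_equal(mutateSequence("GQA", "all_gly"), "GGG")
  expect_equal(mutateSequence("GQA", "all_ala"), "AAA")
  expect_equal(mutateSequence("GQAYS", "blockify_GA"), "GGAGG")
  expect_equal(mutateSequence("GYG", "knockout", knockoutResidue = "Y"),
               "GGG")
  expect_equal(mutateSequence("GYG", "knockout", knockoutResidue = "Y",
                              replacement = "A"), "GAG")
  expect_warning(out <- mutateSequence("GAG", "knockout",
                                       knockoutResidue = "Y"),
                 "absent")
  expect_equal(out, "GAG")

  s <- makeSpidroinSequence(8)
  for (op in c("all_gly", "all_ala", "blockify_GA", "knockout",
               "scramble", "consolidate_polyA"))
    expect_equal(nchar(suppressWarnings(
      mutateSequence(s, op, knockoutResidue = "Y", nRegions = 2))),
      nchar(s))

  # scramble: any seed preserves the residue multiset
  for (seed in 1:5) {
    sc <- mutateSequence(s, "scramble", seed = seed)
    expect_equal(sort(strsplit(sc, "")[[1]]), sort(strsplit(s, "")[[1]]))
  }
  expect_false(mutateSequence(s, "scramble", seed = 1) ==
               mutateSequence(s, "scramble", seed = 2))
})

test_that("poly(Ala) consolidation rebuilds the requested block count", {
  s <- makeSpidroinSequence(8, polyALen = 8, glyRichLen = 22)
  totalA <- sum(strsplit(s, "")[[1]] == "A")
  for (n in c(1L, 2L, 4L)) {
    cons <- mutateSequence(s, "consolidate_polyA", nRegions = n)
    expect_equal(nchar(cons), nchar(s))
    expect_equal(sort(strsplit(cons, "")[[1]]), sort(strsplit(s, "")[[1]]))
    runs <- rle(strsplit(cons, "")[[1]] == "A")
    expect_equal(sum(runs$values), n)
    # equal-as-possible stretch sizes
    sz <- runs$lengths[runs$values]
    expect_lte(max(sz) - min(sz), 1L)
    expect_equal(sum(sz), totalA)
  }
  expect_error(mutateSequence(s, "consolidate_polyA", nRegions = 10000),
               "poly\\(Ala\\) residue count")
})

test_that("repeat-unit statistics summarise the block architecture", {
  s <- makeSpidroinSequence(16, polyALen = 8, glyRichLen = 22)
  st <- repeatUnitStats(s)
  expect_equal(st$n_polyA, 16L)
  expect_true(all(st$polyA_lengths == 8L))
  # the final poly(Ala) block sits at the sequence end, so it is the
  # only one not flanked by Gly-rich spans on both sides
  expect_equal(st$alternation_index, 15 / 16)

  expect_equal(repeatUnitStats("AAAA")$n_polyA, 1L)
  expect_equal(repeatUnitStats("AAAA")$alternation_index, 0)
  expect_equal(repeatUnitStats(strrep("G", 50))$n_polyA, 0L)
})
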