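# Node truth and the four tree-search sub-algorithms.

test_that("sufficient regime: node truth needs strictly more than 85% mutant", {
  # 6/7 = 85.7% -> true; 5/7 = 71.4% -> false
  expect_equal(truthCase(6, 0, 1, "sufficient")$truth, "true")
  expect_equal(truthCase(5, 0, 2, "sufficient")$truth, "false")
  # exactly 85%: 17/20 -> false; just above: 851/1000 -> true
  expect_equal(truthCase(17, 0, 3, "sufficient")$truth, "false")
  expect_equal(truthCase(851, 0, 149, "sufficient")$truth, "true")
})

test_that("insufficient regime drops reference-derived mutants from both sides", {
  # 10 markers: 2 mutant-by-reference dropped, 1 mutant call, 7 ancestral
  # -> 1/8 = 12.5% > 5% -> true
  got <- truthCase(1, 2, 7, "insufficient")
  expect_equal(got$truth, "true")
  expect_equal(got$pct_mutant, 1 / 8)
  expect_equal(got$n_used, 8L)
  # exactly 5%: 1/20 -> false; just above: 51/1000 -> true
  expect_equal(truthCase(1, 0, 19, "insufficient")$truth, "false")
  expect_equal(truthCase(51, 0, 949, "insufficient")$truth, "true")
  # the same 6/7 node is judged differently by regime
  expect_equal(truthCase(6, 0, 1, "insufficient")$truth, "true")
})

test_that("a node with no usable state is indeterminate", {
  fx <- fictiveFixture()
  states <- buildStatusTable(fx$markers, fx$profile, fx$reference)
  # a node defined only by an indel marker has no usable state
  tr <- PhyloTree(data.frame(name = c("R", "Q"), parent = c(NA, "R"),
                             markers = I(list(character(0), "IND1"))))
  q <- new("QualityVerdict", score = 1, category = "sufficient",
           nPanelCalled = 1L, nConsistent = 1L, panelSize = 1L,
           threshold = 0.5)
  got <- nodeTruth(tr, "Q", states, fx$markers, q)
  expect_equal(got$truth, "indeterminate")
  expect_equal(got$n_used, 0L)
})

test_that("the fictive walkthrough reproduces every stage", {
  fx <- fictiveFixture()
  res <- assignHaplogroup(fx$profile, fx$tree, fx$markers, fx$reference)
  expect_equal(qualityCategory(assignmentQuality(res)), "sufficient")
  expect_equal(res@vertical, c("X1a", "Z2b*", "Z2b3a"))
  expect_equal(res@horizontal, "Z2b")
  expect_equal(res@combinatorial, c("Z2b*", "Z2b3a"))
  expect_equal(res@specific, "Z2b3a")
  expect_equal(finalHaplogroups(res), "Z2b3a")
  expect_equal(res@finalMutationBased, "Z-M8")
})

test_that("sub-algorithms match brute force on random trees and statuses", {
  for (seed in 1:40) {
    tr <- randomTree(seed)
    st <- randomStatuses(tr, seed + 1000L)
    v <- verticalScan(tr, st)
    h <- horizontalDescend(tr, st)
    expect_identical(v, bfVertical(tr, st))
    expect_identical(h, bfHorizontal(tr, st))
    expect_identical(combineVerticalHorizontal(v, h, tr), bfCombine(v, h, tr))
    expect_identical(mostSpecific(v, tr), bfSpecific(v, tr))
    # chain invariant
    comb <- combineVerticalHorizontal(v, h, tr)
    expect_true(all(mostSpecific(comb, tr) %in% comb))
    expect_true(all(comb %in% v))
  }
})

test_that("horizontal returns empty when no internal child of the root is true", {
  fx <- fictiveFixture()
  st <- mkStatuses(fx$tree, true = c("X1a", "Z1"))
  expect_equal(horizontalDescend(fx$tree, st), character(0))
  expect_equal(verticalScan(fx$tree, st), c("X1a", "Z1"))
})

test_that("indeterminate internal nodes pass the descent through without being returned", {
  tr <- PhyloTree(data.frame(
    name = c("R", "A", "A1", "A1a", "A1a1"),
    parent = c(NA, "R", "A", "A1", "A1a"), stringsAsFactors = FALSE))
  st <- mkStatuses(tr, true = c("A", "A1a"), indeterminate = "A1")
  expect_equal(horizontalDescend(tr, st), "A1a")
  st2 <- mkStatuses(tr, true = "A", indeterminate = "A1")
  expect_equal(horizontalDescend(tr, st2), "A")
})

test_that("most-specific keeps incomparable candidates and resolves paragroups", {
  fx <- fictiveFixture()
  expect_equal(mostSpecific(c("Z2b*", "Z2b3a"), fx$tree), "Z2b3a")
  expect_equal(mostSpecific(c("X1a", "Z1"), fx$tree), c("X1a", "Z1"))
  expect_equal(mostSpecific("X1a", fx$tree), "X1a")
  expect_equal(mostSpecific(c("Z", "Z2", "Z2b3a"), fx$tree), "Z2b3a")
})

test_that("mutation-based nomenclature uses the main letter and first marker", {
  tr <- PhyloTree(data.frame(
    name = c("Root", "R1b1b2a2", "R1b1b2a2*", "I1", "I1*", "E"),
    parent = c(NA, "Root", "R1b1b2a2", "Root", "I1", "Root"),
    markers = I(list(character(0), "P312", character(0), "M253",
                     character(0), character(0)))))
  mt <- mkMarkerTable(
    list(name = "P312", pos_hg19 = 1L, ancestral = "A", mutant = "C"),
    list(name = "M253", pos_hg19 = 2L, ancestral = "G", mutant = "A"))
  expect_equal(toMutationNomenclature(tr, "R1b1b2a2*", mt), "R-P312*")
  expect_equal(toMutationNomenclature(tr, "I1*", mt), "I-M253*")
  expect_equal(toMutationNomenclature(tr, "Root", mt), "Root")
  noMk <- toMutationNomenclature(tr, "E", mt)
  expect_equal(as.character(noMk), "E-?")
  expect_match(attr(noMk, "warning"), "E")
})

test_that("zero-error profiles recover the simulated leaf for every leaf", {
  fx <- makeFixture(nLevels = 4L, branching = 2L, markersPerBranch = 2L,
                    seed = 3L)
  for (leaf in treeLeaves(fx@tree)) {
    p <- simulateProfile(fx, leaf, 0, 0, seed = 8L)
    res <- assignHaplogroup(p, fx@tree, fx@markers, fx@reference)
    expect_equal(qualityCategory(assignmentQuality(res)), "sufficient")
    expect_identical(finalHaplogroups(res), leaf)
    expect_identical(oracleAssign(p, fx), leaf)
  }
})

test_that("empty horizontal falls back to the most specific vertical leaves with a warning", {
  fx <- makeFixture(nLevels = 3L, branching = 2L, markersPerBranch = 1L,
                    seed = 6L)
  leaf <- treeLeaves(fx@tree)[[1L]]
  p <- simulateProfile(fx, leaf, 0, 0.9, seed = 12L)
  res <- assignHaplogroup(p, fx@tree, fx@markers, fx@reference)
  expect_equal(qualityCategory(assignmentQuality(res)), "insufficient")
  if (length(res@horizontal) == 0L) {
    expect_true(any(grepl("only the vertical", assignmentWarnings(res))))
    expect_identical(finalHaplogroups(res),
                     mostSpecific(res@vertical, fx@tree))
  }
  expect_true(any(grepl("insufficient", assignmentWarnings(res))))
})

test_that("an engineered insufficient profile can return two incompatible leaves", {
  fx <- makeFixture(nLevels = 3L, branching = 2L, markersPerBranch = 1L,
                    referenceLineages = "A1a", seed = 4L)
  # derived calls on the two deepest branches of two different main
  # haplogroups; everything else uncalled -> insufficient regime keeps both
  df <- fx@markers@markers
  pick <- names(fx@markerNode)[fx@markerNode %in% c("A2a", "B2a")]
  rows <- df[df$name %in% pick, ]
  p <- SnpProfile(data.frame(position = rows$pos_hg19,
                             ref_allele = rows$ancestral,
                             obs_allele = rows$mutant), "hg19")
  res <- assignHaplogroup(p, fx@tree, fx@markers, fx@reference)
  expect_equal(qualityCategory(assignmentQuality(res)), "insufficient")
  expect_true(all(c("A2a", "B2a") %in% finalHaplogroups(res)))
  expect_gte(length(assignmentWarnings(res)), 1L)
})
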