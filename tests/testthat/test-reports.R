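# Curation reports and output files.

test_that("derived markers absent from the tree are listed with synonyms", {
  fx <- fictiveFixture()
  states <- buildStatusTable(fx$markers, fx$profile, fx$reference)
  cnt <- findConvNotTree(states, fx$markers, fx$tree)
  expect_equal(cnt$marker, "L999")
  expect_equal(cnt$synonyms, "S999")
})

test_that("markers present in the tree under a synonym only are not listed", {
  fx <- fictiveFixture()
  # M5 (derived here) appears in the tree only as its synonym P5
  p <- mkProfile(501L, "G", "C")
  states <- buildStatusTable(fx$markers, p, fx$reference)
  expect_equal(statusStates(states)$state[
    statusStates(states)$marker == "M5"], 1L)
  cnt <- findConvNotTree(states, fx$markers, fx$tree)
  expect_false("M5" %in% cnt$marker)
})

test_that("all derived markers in the tree give an empty list", {
  fx <- fictiveFixture()
  p <- mkProfile(401L, "C", "T")   # only the Z marker derived
  states <- buildStatusTable(fx$markers, p, fx$reference)
  expect_equal(nrow(findConvNotTree(states, fx$markers, fx$tree)), 0L)
})

test_that("calls partition into known markers and novel SNPs", {
  fx <- fictiveFixture()
  yupp <- findYuppSnps(fx$profile, fx$markers)
  expect_equal(yupp$position, 1201L)
  known <- markerPositions(fx$markers, "hg19")
  calls <- profileCalls(fx$profile)$position
  inKnown <- calls %in% known[!is.na(known)]
  inYupp <- calls %in% yupp$position
  expect_true(all(xor(inKnown, inYupp)))

  allKnown <- mkProfile(c(101L, 201L), c("A", "A"), c("G", "C"))
  expect_equal(nrow(findYuppSnps(allKnown, fx$markers)), 0L)
})

test_that("planted novel positions are recovered exactly", {
  fx <- makeFixture(nLevels = 3L, branching = 2L, markersPerBranch = 1L,
                    seed = 13L)
  leaf <- treeLeaves(fx@tree)[[3L]]
  p <- simulateProfile(fx, leaf, 0, 0, seed = 2L)
  known <- markerPositions(fx@markers, "hg19")
  novelPos <- setdiff(seq_len(50L), known)[1:4]
  planted <- rbind(profileCalls(p),
                   data.frame(position = novelPos,
                              ref_allele = baseAt(fx@reference, novelPos),
                              obs_allele = "A", stringsAsFactors = FALSE))
  planted$obs_allele[planted$position %in% novelPos] <-
    ifelse(planted$ref_allele[planted$position %in% novelPos] == "A", "C", "A")
  p2 <- SnpProfile(planted, "hg19")
  got <- findYuppSnps(p2, fx@markers)
  expect_setequal(got$position, novelPos)
})

test_that("report files are byte-identical across re-runs and carry the result", {
  fx <- fictiveFixture()
  res <- assignHaplogroup(fx$profile, fx$tree, fx$markers, fx$reference)
  states <- buildStatusTable(fx$markers, fx$profile, fx$reference)
  cnt <- findConvNotTree(states, fx$markers, fx$tree)
  yupp <- findYuppSnps(fx$profile, fx$markers)
  d1 <- tempfile(); d2 <- tempfile()
  writeReports(res, states, cnt, yupp, d1)
  writeReports(res, states, cnt, yupp, d2)
  for (f in c("analysis.txt", "snp_status.tsv", "conv_not_tree.tsv",
              "new_snps.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  analysis <- readLines(file.path(d1, "analysis.txt"))
  expect_true(any(grepl("final_alphanumeric\tZ2b3a", analysis, fixed = TRUE)))
  expect_true(any(grepl("quality_category\tsufficient", analysis,
                        fixed = TRUE)))
  status <- read.delim(file.path(d1, "snp_status.tsv"))
  expect_equal(nrow(status), length(fx$markers))
})

test_that("reports also write cleanly when no marker is excluded", {
  fx <- makeFixture(nLevels = 2L, branching = 2L, markersPerBranch = 1L,
                    seed = 8L)
  leaf <- treeLeaves(fx@tree)[[2L]]
  p <- simulateProfile(fx, leaf, 0, 0, seed = 1L)
  res <- assignHaplogroup(p, fx@tree, fx@markers, fx@reference,
                          params = AssignParams(exclusions = character(0)))
  states <- buildStatusTable(fx@markers, p, fx@reference,
                             exclusions = character(0))
  expect_equal(nrow(statusExcluded(states)), 0L)
  d <- tempfile()
  writeReports(res, states, findConvNotTree(states, fx@markers, fx@tree),
               findYuppSnps(p, fx@markers), d)
  status <- read.delim(file.path(d, "snp_status.tsv"))
  expect_equal(nrow(status), length(fx@markers))
})

test_that("an insufficient run writes the caution and empty lists keep headers", {
  fx <- fictiveFixture()
  empty <- SnpProfile(data.frame(), "hg19")
  res <- assignHaplogroup(empty, fx$tree, fx$markers, fx$reference)
  states <- buildStatusTable(fx$markers, empty, fx$reference)
  d <- tempfile()
  writeReports(res, states,
               findConvNotTree(states, fx$markers, fx$tree),
               findYuppSnps(empty, fx$markers), d)
  analysis <- readLines(file.path(d, "analysis.txt"))
  expect_true(any(grepl("insufficient", analysis)))
  yuppLines <- readLines(file.path(d, "new_snps.tsv"))
  expect_equal(yuppLines, "position\tref_allele\tobs_allele")
})
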