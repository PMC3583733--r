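# Allelic-state determination and the status table.

# M173-style marker: A ancestral, C mutant, at position 5
statusMarkers <- function() mkMarkerTable(
  list(name = "M173", synonyms = c("P241", "Page29"),
       pos_hg18 = 5L, pos_hg19 = 5L, ancestral = "A", mutant = "C"))

refAllAncestral <- function() mkRef(rep("A", 10))

test_that("a called mutant allele gives state 1 with called provenance", {
  mt <- statusMarkers()
  p <- mkProfile(5L, "A", "C")
  st <- determineState(getMarker(mt, "M173"), p, refAllAncestral())
  expect_equal(st$state, 1L)
  expect_equal(st$provenance, "called")
})

test_that("an uncalled marker falls back to the reference base", {
  mt <- statusMarkers()
  p <- mkProfile(integer(0), character(0), character(0))
  st <- determineState(getMarker(mt, "M173"), p, refAllAncestral())
  expect_equal(st$state, 0L)
  expect_equal(st$provenance, "reference")

  refDerived <- mkRef(rep("C", 10))
  st <- determineState(getMarker(mt, "M173"), p, refDerived)
  expect_equal(st$state, 1L)    # composite reference: derived is legitimate
  expect_equal(st$provenance, "reference")
})

test_that("states match a brute-force enumeration over bases and strands", {
  # oracle: direct match wins; otherwise complement (strand rescue) when
  # enabled; otherwise other (-1)
  oracle <- function(obs, anc, mut, rescue) {
    if (obs == mut) return(1L)
    if (obs == anc) return(0L)
    if (rescue) {
      comp <- c(A = "T", C = "G", G = "C", T = "A")[[obs]]
      if (comp == mut) return(1L)
      if (comp == anc) return(0L)
    }
    -1L
  }
  bases <- c("A", "C", "G", "T")
  for (anc in bases) for (mut in setdiff(bases, anc)) {
    mt <- mkMarkerTable(list(name = "X", pos_hg19 = 5L,
                             ancestral = anc, mutant = mut))
    for (obs in bases) for (rescue in c(TRUE, FALSE)) {
      p <- mkProfile(5L, anc, obs)
      got <- determineState(getMarker(mt, "X"), p, refAllAncestral(),
                            strandRescue = rescue)
      expect_equal(got$state, oracle(obs, anc, mut, rescue),
                   label = paste(anc, mut, obs, rescue))
    }
  }
})

test_that("the status table partitions markers into scored and excluded", {
  mt <- mkMarkerTable(
    list(name = "A1", pos_hg19 = 1L, ancestral = "A", mutant = "C"),
    list(name = "A2", pos_hg19 = 2L, ancestral = "G", mutant = "T"),
    list(name = "A3", pos_hg19 = 3L, ancestral = "C", mutant = "G"),
    list(name = "IND", pos_hg19 = 4L, ancestral = "4G", mutant = "3G"),
    list(name = "V218", pos_hg19 = 5L, ancestral = "A", mutant = "G"),
    list(name = "NOPOS", pos_hg18 = 9L, ancestral = "A", mutant = "G"))
  p <- mkProfile(1L, "A", "C")
  ref <- mkRef(c("A", "G", "C", "A", "A", "A"))
  st <- buildStatusTable(mt, p, ref)
  expect_equal(nrow(statusStates(st)), 3L)
  expect_equal(nrow(statusExcluded(st)), 3L)
  expect_equal(nrow(statusStates(st)) + nrow(statusExcluded(st)), length(mt))
  expect_setequal(statusExcluded(st)$marker, c("IND", "V218", "NOPOS"))
  expect_match(statusExcluded(st)$reason[statusExcluded(st)$marker == "IND"],
               "indel")
  expect_match(statusExcluded(st)$reason[statusExcluded(st)$marker == "V218"],
               "exclusion")
  got <- statusStates(st)
  expect_equal(got$state[got$marker == "A1"], 1L)
  expect_equal(got$provenance[got$marker == "A1"], "called")
  expect_equal(got$state[got$marker == "A2"], 0L)
  expect_equal(got$provenance[got$marker == "A2"], "reference")
})

test_that("the status table is independent of marker row order", {
  mt1 <- mkMarkerTable(
    list(name = "B1", pos_hg19 = 1L, ancestral = "A", mutant = "C"),
    list(name = "B2", pos_hg19 = 2L, ancestral = "G", mutant = "T"))
  mt2 <- mkMarkerTable(
    list(name = "B2", pos_hg19 = 2L, ancestral = "G", mutant = "T"),
    list(name = "B1", pos_hg19 = 1L, ancestral = "A", mutant = "C"))
  p <- mkProfile(2L, "G", "T")
  ref <- mkRef(c("A", "G"))
  expect_equal(statusStates(buildStatusTable(mt1, p, ref)),
               statusStates(buildStatusTable(mt2, p, ref)))
})

test_that("co-located markers each get their own state from the same call", {
  mt <- mkMarkerTable(
    list(name = "C1", pos_hg19 = 7L, ancestral = "A", mutant = "C"),
    list(name = "C2", pos_hg19 = 7L, ancestral = "C", mutant = "A"))
  p <- mkProfile(7L, "A", "C")
  st <- statusStates(buildStatusTable(mt, p, mkRef(rep("A", 7))))
  expect_equal(st$state[st$marker == "C1"], 1L)
  expect_equal(st$state[st$marker == "C2"], 0L)
})

test_that("zero-error fixture profiles never produce 'other' states and mark exactly the path", {
  fx <- makeFixture(nLevels = 3L, branching = 2L, markersPerBranch = 1L,
                    seed = 5L)
  for (leaf in treeLeaves(fx@tree)) {
    p <- simulateProfile(fx, leaf, 0, 0, seed = 9L)
    st <- statusStates(buildStatusTable(fx@markers, p, fx@reference,
                                        exclusions = character(0)))
    expect_false(any(st$state == -1L))
    expect_setequal(st$marker[st$state == 1L], fx@truth[[leaf]])
  }
})
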