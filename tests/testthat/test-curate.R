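# Evidence curation: ontology handling, PPI filtering, redundancy
# elimination and reference-set construction.

# Toy molecular-interaction ontology:
#   MI:0001 (interaction root)
#     MI:0915 physical association
#       MI:0407 direct interaction
#         MI:0055 fret
#       MI:0004 affinity chromatography
#         MI:0096 pull down
#     MI:0208 genetic interaction
toyMI <- function() {
  ontologyFromEdges(
    child = c("MI:0915", "MI:0208", "MI:0407", "MI:0004", "MI:0055",
              "MI:0096"),
    parent = c("MI:0001", "MI:0001", "MI:0915", "MI:0915", "MI:0407",
               "MI:0004"))
}

evRec <- function(a, b, type = "MI:0915", method = "MI:0096", pub = "pub1",
                  db = "biogrid") {
  data.frame(protein_a = a, protein_b = b, interaction_type = type,
             detection_method = method, publication_id = pub,
             source_db = db, stringsAsFactors = FALSE)
}

test_that("ontology ancestry matches an independent closure and reads both formats", {
  ont <- randomOntologyEdges(nTerms = 15, seed = 3)
  onto <- ontologyFromEdges(ont$child, ont$parent)
  for (t in sample(ont$terms, 6))
    expect_setequal(ontologyAncestors(onto, t),
                    oracleAncestors(ont$child, ont$parent, t))
  # edge-TSV and OBO readers agree
  tsv <- tempfile(fileext = ".tsv")
  writeLines(paste(ont$child, ont$parent, sep = "\t"), tsv)
  obo <- tempfile(fileext = ".obo")
  stanzas <- vapply(ont$terms, function(t) {
    isa <- ont$parent[ont$child == t]
    paste(c("[Term]", paste0("id: ", t),
            if (length(isa)) paste0("is_a: ", isa, " ! x"), ""),
          collapse = "\n")
  }, character(1))
  writeLines(c("format-version: 1.2", "", stanzas), obo)
  o1 <- readOntology(tsv)
  o2 <- readOntology(obo)
  for (t in sample(ont$terms, 4))
    expect_setequal(ontologyAncestors(o1, t), ontologyAncestors(o2, t))
  # cycles are rejected
  expect_error(ontologyFromEdges(c("a", "b"), c("b", "a")), "acyclic")
})

test_that("PPI filtering keeps physical descendants-or-self and drops the rest", {
  onto <- toyMI()
  recs <- rbind(evRec("A", "B", type = "MI:0208"),        # genetic: out
                evRec("A", "C", type = "MI:0407"),        # physical: in
                evRec("A", "D", type = "MI:0915"),        # root itself: in
                evRec("A", "E", type = "MI:0001"))        # above root: out
  out <- filterPPI(recs, onto)
  expect_setequal(out$protein_b, c("C", "D"))
  expect_warning(filterPPI(rbind(recs, evRec("A", "F", type = "MI:9999")),
                           onto),
                 "unresolvable")
})

test_that("explicit duplicates collapse; implicit (ancestor) duplicates keep the specific term", {
  onto <- toyMI()
  # same pair, same publication, identical method term from two databases
  r1 <- rbind(evRec("A", "B", db = "biogrid"), evRec("B", "A", db = "intact"))
  d1 <- deduplicateEvidence(r1, onto)
  expect_identical(nrow(d1), 1L)
  # method and its descendant within one publication: descendant wins
  r2 <- rbind(evRec("A", "B", method = "MI:0004"),
              evRec("A", "B", method = "MI:0096", db = "intact"))
  d2 <- deduplicateEvidence(r2, onto)
  expect_identical(nrow(d2), 1L)
  expect_identical(d2$detection_method, "MI:0096")
  # unrelated methods in one publication are both kept
  r3 <- rbind(evRec("A", "B", method = "MI:0055"),
              evRec("A", "B", method = "MI:0096"))
  expect_identical(nrow(deduplicateEvidence(r3, onto)), 2L)
  # same pair in two publications: never merged
  r4 <- rbind(evRec("A", "B", pub = "pub1"), evRec("A", "B", pub = "pub2"))
  expect_identical(nrow(deduplicateEvidence(r4, onto)), 2L)
})

test_that("chained ancestry collapses to one record per redundancy class", {
  onto <- toyMI()
  # MI:0915 <- MI:0407 <- MI:0055 is one chain; MI:0096 links to MI:0915
  # through MI:0004; at the top MI:0915 connects everything
  recs <- rbind(evRec("A", "B", method = "MI:0915"),
                evRec("A", "B", method = "MI:0407"),
                evRec("A", "B", method = "MI:0055"))
  d <- deduplicateEvidence(recs, onto)
  expect_identical(nrow(d), 1L)
  expect_identical(d$detection_method, "MI:0055")
})

test_that("deduplication is idempotent and counts ignore record duplication", {
  set.seed(18)
  for (i in 1:8) {
    ont <- randomOntologyEdges(nTerms = 10, seed = i)
    onto <- ontologyFromEdges(ont$child, ont$parent)
    recs <- randomEvidence(ont, nRec = 35, seed = i + 100)
    d1 <- deduplicateEvidence(recs, onto)
    d2 <- deduplicateEvidence(d1, onto)
    expect_equal(d2[order(d2$pair_id, d2$publication_id,
                          d2$detection_method), ],
                 d1[order(d1$pair_id, d1$publication_id,
                          d1$detection_method), ],
                 ignore_attr = TRUE)
    # duplicating records under a new source never changes evidence counts
    extra <- recs[sample(nrow(recs), 10), ]
    extra$source_db <- "mirror_db"
    dMerged <- deduplicateEvidence(rbind(recs, extra), onto)
    expect_identical(countEvidence(dMerged), countEvidence(d1))
    # record order does not matter either
    dShuf <- deduplicateEvidence(recs[sample(nrow(recs)), ], onto)
    expect_identical(countEvidence(dShuf), countEvidence(d1))
  }
})

test_that("reference sets partition the universe by evidence count and GO filter", {
  onto <- toyMI()
  universe <- c("BAIT", sprintf("Y%d", 1:6))
  recs <- rbind(
    evRec("BAIT", "Y1", pub = "p1"), evRec("BAIT", "Y1", pub = "p2"),
    evRec("BAIT", "Y1", pub = "p3"),                       # 3 pieces: positive
    evRec("BAIT", "Y2", pub = "p1"), evRec("BAIT", "Y2", pub = "p2"),
    evRec("Y3", "BAIT", pub = "p1"))
  recs$pair_id <- pairKey(recs$protein_a, recs$protein_b)
  go <- data.frame(protein = c("Y4", "Y5"),
                   term = c("GO:0016567", "GO:0000001"),
                   stringsAsFactors = FALSE)
  ref <- buildReference(recs, "BAIT", universe, minEvidence = 3,
                        goAnnotations = go,
                        excludedGoTerms = "GO:0016567")
  expect_identical(positives(ref), "Y1")
  # Y2 (2 records) and Y3 (1 record) are unlabeled, Y4 is GO-excluded
  expect_setequal(negatives(ref), c("Y5", "Y6"))
  labels <- c(positives(ref), negatives(ref))
  expect_identical(anyDuplicated(labels), 0L)
  expect_setequal(setdiff(universe, c(labels, "BAIT")), c("Y2", "Y3", "Y4"))
  expect_error(buildReference(recs, "NOPE", universe), "NOPE")
  # transitive GO exclusion through the ontology
  goOnto <- ontologyFromEdges("GO:0000001", "GO:0016567")
  ref2 <- buildReference(recs, "BAIT", universe, minEvidence = 3,
                         goAnnotations = go,
                         excludedGoTerms = "GO:0016567",
                         goOntology = goOnto)
  expect_identical(negatives(ref2), "Y6")
})
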