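# Fixture builders shared across tests. Everything is generated in code;
# no data files.

# Build a PairSignalSet directly from a replicate matrix, bypassing the
# normalization chain, for tests that exercise the scoring layer alone.
psFromMatrix <- function(mat, bait, prey, censored = NULL, detLimit = -5) {
  if (is.null(rownames(mat)))
    rownames(mat) <- paste(bait, prey, sep = ".")
  if (is.null(censored))
    censored <- matrix(FALSE, nrow(mat), ncol(mat), dimnames = dimnames(mat))
  rd <- S4Vectors::DataFrame(
    bait = bait, prey = prey,
    mean_log2 = rowMeans(mat, na.rm = TRUE),
    below_detection_frac = rowMeans(censored, na.rm = TRUE),
    detection_limit_log2 = detLimit,
    row.names = rownames(mat))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2signal = mat, belowDetection = censored),
    rowData = rd)
  new("PairSignalSet", se)
}

# A small two-bait screen simulation with defaults chosen for fast tests.
smallScreenSim <- function(nPrey = 30, baits = c("B1", "B2"),
                           edges = NULL, seed = 42, replicates = 3,
                           noiseSd = 0.2, kSelf = 1e-7, ...) {
  preys <- sprintf("Y%03d", seq_len(nPrey))
  prot <- proteinUniverse(
    c(baits, preys),
    c(rep(2e4, length(baits)), 10^seq(1.5, 5.5, length.out = nPrey)),
    "cytoplasm")
  net <- if (is.null(edges)) ppiNetwork() else edges
  design <- screenDesign(baits = baits, preys = preys,
                         replicates = replicates, seed = seed,
                         noiseSd = noiseSd, kSelf = kSelf, ...)
  list(prot = prot, net = net, design = design,
       sim = simulateScreen(prot, net, design))
}

# Random evidence table over a small protein set and a random ontology DAG
# (edges always point from later to earlier terms, hence acyclic).
randomOntologyEdges <- function(nTerms = 12, seed = 1) {
  set.seed(seed)
  terms <- sprintf("MI:%04d", seq_len(nTerms))
  child <- character(); parent <- character()
  for (i in 2:nTerms) {
    for (p in sample(seq_len(i - 1), min(i - 1, sample(1:2, 1)))) {
      child <- c(child, terms[i]); parent <- c(parent, terms[p])
    }
  }
  list(terms = terms, child = child, parent = parent)
}

randomEvidence <- function(ont, nRec = 40, seed = 2) {
  set.seed(seed)
  prots <- c("UPF1", "NMD2", "DCP2", "XRN1", "LSM1")
  a <- sample(prots, nRec, replace = TRUE)
  b <- sample(prots, nRec, replace = TRUE)
  data.frame(
    protein_a = a, protein_b = b,
    interaction_type = sample(ont$terms, nRec, replace = TRUE),
    detection_method = sample(ont$terms, nRec, replace = TRUE),
    publication_id = sample(sprintf("pub%d", 1:6), nRec, replace = TRUE),
    source_db = sample(c("biogrid", "intact", "dip", "mint"), nRec,
                       replace = TRUE),
    stringsAsFactors = FALSE)
}
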