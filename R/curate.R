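# Building positive / negative reference sets from interaction-evidence
# tables: filtering to physical interactions, ontology-aware elimination of
# explicit and implicit redundancies between database records, evidence
# counting, and GO-based filtering of the negative set.
#
# Evidence tables are PSI-MI-TAB-derived TSVs with columns
#   protein_a, protein_b, interaction_type, detection_method,
#   publication_id, source_db
# Ontologies (molecular-interaction terms, GO) arrive as OBO files or
# two-column child/parent edge TSVs; all term relations used here are
# child -> parent (is_a).

.EVIDENCE_COLS <- c("protein_a", "protein_b", "interaction_type",
                    "detection_method", "publication_id", "source_db")

#' Build an Ontology from a child/parent edge list
#'
#' @param child,parent character vectors of term ids; each edge states that
#'   \code{child} is a (more specific) descendant of \code{parent}.
#' @param terms optional character vector of additional isolated term ids.
#' @return an \code{\linkS4class{Ontology}}.
#' @export
#' @examples
#' onto <- ontologyFromEdges(c("MI:0915", "MI:0407"), c("MI:0190", "MI:0915"))
#' ontologyAncestors(onto, "MI:0407")
ontologyFromEdges <- function(child, parent, terms = character()) {
  if (length(child) != length(parent))
    .stopf("child and parent must have equal length")
  ids <- unique(c(child, parent, terms))
  g <- igraph::graph_from_data_frame(
    data.frame(from = child, to = parent, stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = ids, stringsAsFactors = FALSE))
  new("Ontology", terms = ids, graph = g)
}

#' Read an ontology file
#'
#' Accepts either a minimal OBO file (\code{[Term]} stanzas with \code{id:}
#' and \code{is_a:} lines) or a headerless/headered two-column TSV of
#' child/parent edges (a header line is detected and skipped when its first
#' field is not a term id appearing elsewhere).
#'
#' @param path file path.
#' @param format \code{"auto"}, \code{"obo"} or \code{"edges"}.
#' @return an \code{\linkS4class{Ontology}}.
#' @export
readOntology <- function(path, format = c("auto", "obo", "edges")) {
  format <- match.arg(format)
  if (!file.exists(path)) .stopf("ontology file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (format == "auto")
    format <- if (any(grepl("^\\[Term\\]", lines))) "obo" else "edges"
  if (format == "obo") {
    ids <- character(); child <- character(); parent <- character()
    cur <- NA_character_
    inTerm <- FALSE
    for (ln in lines) {
      if (grepl("^\\[", ln)) {
        inTerm <- grepl("^\\[Term\\]", ln)
        cur <- NA_character_
      } else if (inTerm && grepl("^id:", ln)) {
        cur <- trimws(sub("^id:", "", ln))
        ids <- c(ids, cur)
      } else if (inTerm && grepl("^is_a:", ln) && !is.na(cur)) {
        p <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
        child <- c(child, cur)
        parent <- c(parent, p)
      }
    }
    return(ontologyFromEdges(child, parent, terms = ids))
  }
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("child", "parent"))
  # tolerate a header row
  if (nrow(df) && df$child[1] %in% c("child", "term", "id"))
    df <- df[-1, , drop = FALSE]
  ontologyFromEdges(df$child, df$parent)
}

#' Ancestors (or descendants) of a term, including the term itself
#'
#' @param ontology an \code{\linkS4class{Ontology}}.
#' @param term a term id.
#' @return character vector of term ids reachable via child -> parent edges
#'   (\code{ontologyAncestors}) or the reverse (\code{ontologyDescendants});
#'   both include \code{term}. Unknown terms return \code{character(0)}.
#' @export
ontologyAncestors <- function(ontology, term) {
  if (!term %in% ontology@terms) return(character())
  names(igraph::subcomponent(ontology@graph, term, mode = "out"))
}

#' @rdname ontologyAncestors
#' @export
ontologyDescendants <- function(ontology, term) {
  if (!term %in% ontology@terms) return(character())
  names(igraph::subcomponent(ontology@graph, term, mode = "in"))
}

#' Read an interaction-evidence table
#'
#' @param path TSV with header columns \code{protein_a, protein_b,
#'   interaction_type, detection_method, publication_id, source_db}.
#' @return data.frame of evidence records with an added unordered
#'   \code{pair_id}.
#' @export
readEvidence <- function(path) {
  if (!file.exists(path)) .stopf("evidence file not found: %s", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          colClasses = "character")
  .requireColumns(df, .EVIDENCE_COLS, "evidence table")
  df$pair_id <- pairKey(df$protein_a, df$protein_b)
  df
}

#' Filter evidence records to physical protein-protein interactions
#'
#' Retains records whose \code{interaction_type} is a descendant-or-self of
#' the configured physical-interaction root term, discarding genetic and
#' protein-nucleic-acid interaction records. Records with interaction types
#' absent from the ontology are dropped with a warning.
#'
#' @param records evidence data.frame (see \code{\link{readEvidence}}).
#' @param ontology the molecular-interaction \code{\linkS4class{Ontology}}.
#' @param root the physical-interaction root term id (PSI-MI "physical
#'   association", MI:0915, by default).
#' @return the retained records.
#' @export
filterPPI <- function(records, ontology, root = "MI:0915") {
  if (!root %in% ontology@terms)
    .stopf("root term '%s' absent from the ontology", root)
  physical <- ontologyDescendants(ontology, root)
  known <- records$interaction_type %in% ontology@terms
  if (any(!known))
    .warnf("dropping %d record(s) with unresolvable interaction_type",
           sum(!known))
  records[known & records$interaction_type %in% physical, , drop = FALSE]
}

# Is term a an ancestor-or-self of term b?  Precomputed ancestor lists keyed
# by term keep the dedup quadratic only within tiny groups.
.ancestorClosure <- function(ontology, terms) {
  u <- unique(terms)
  cl <- lapply(u, function(t) ontologyAncestors(ontology, t))
  names(cl) <- u
  cl
}

#' Eliminate explicit and implicit redundancies between evidence records
#'
#' Databases frequently hold the same experimental observation several
#' times: identically (explicit redundancy) or annotated at different
#' granularity of the molecular-interaction detection-method vocabulary
#' (implicit redundancy, e.g. "pull down" vs. its parent "affinity
#' chromatography technology"). Within each (pair, publication) group, two
#' records are redundant when one's detection method is an ancestor-or-self
#' of the other's; each redundancy class (connected component of that
#' relation) keeps exactly one record, the one with the most specific term
#' (ties broken by source_db, then method id, lexicographically).
#' Cross-publication records are never merged. Records whose detection
#' method is absent from the ontology are compared by identity only.
#'
#' @param records evidence data.frame.
#' @param ontology the molecular-interaction \code{\linkS4class{Ontology}}.
#' @return the deduplicated records; idempotent.
#' @export
deduplicateEvidence <- function(records, ontology) {
  if (!nrow(records)) return(records)
  if (!"pair_id" %in% colnames(records))
    records$pair_id <- pairKey(records$protein_a, records$protein_b)
  anc <- .ancestorClosure(ontology, records$detection_method)
  grp <- paste(records$pair_id, records$publication_id, sep = "\r")
  keep <- logical(nrow(records))
  for (g in unique(grp)) {
    i <- which(grp == g)
    n <- length(i)
    if (n == 1L) { keep[i] <- TRUE; next }
    meth <- records$detection_method[i]
    # redundancy relation: one method reachable from the other (or equal)
    rel <- matrix(FALSE, n, n)
    for (a in seq_len(n)) for (b in seq_len(n)) {
      if (a == b) { rel[a, b] <- TRUE; next }
      ia <- anc[[meth[a]]]; ib <- anc[[meth[b]]]
      rel[a, b] <- meth[a] %in% ib || meth[b] %in% ia ||
        meth[a] == meth[b]
    }
    comp <- .components(rel)
    for (cmp in unique(comp)) {
      j <- i[comp == cmp]
      keep[.pickMostSpecific(records, j, anc)] <- TRUE
    }
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Connected components of a symmetric logical relation matrix.
.components <- function(rel) {
  n <- nrow(rel)
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(rel[v, ] & is.na(comp)))
    }
  }
  comp
}

# Among record indices j, pick the one whose method has no descendant in the
# class (most specific); ties by source_db then method id.
.pickMostSpecific <- function(records, j, anc) {
  meth <- records$detection_method[j]
  # a record is dominated if another record's method strictly descends from it
  dominated <- vapply(seq_along(j), function(a) {
    any(vapply(seq_along(j), function(b) {
      a != b && meth[a] != meth[b] && meth[a] %in% anc[[meth[b]]]
    }, logical(1)))
  }, logical(1))
  cand <- j[!dominated]
  if (!length(cand)) cand <- j
  o <- order(records$source_db[cand], records$detection_method[cand],
             cand)
  cand[o[1]]
}

#' Count deduplicated evidence per pair
#'
#' @param records deduplicated evidence data.frame.
#' @return named integer vector, evidence count per \code{pair_id}.
#' @export
countEvidence <- function(records) {
  if (!nrow(records)) return(stats::setNames(integer(), character()))
  tab <- table(records$pair_id)
  stats::setNames(as.integer(tab), names(tab))
}

#' Build a positive / negative reference set for one bait
#'
#' Positives are preys whose deduplicated evidence count with the bait
#' reaches \code{minEvidence} (three pieces of experimental evidence by
#' default, the usual high-confidence cut). Negatives are preys of the
#' universe with zero recorded evidence for the bait that are additionally
#' not annotated with any of the excluded GO terms — directly, or through
#' any annotated term that descends from an excluded term when a GO ontology
#' is supplied. Everything else is unlabeled.
#'
#' @param records deduplicated evidence data.frame
#'   (\code{\link{deduplicateEvidence}}).
#' @param bait bait protein id; must belong to \code{universe}.
#' @param universe character vector of all candidate prey ids.
#' @param minEvidence integer >= 1.
#' @param goAnnotations optional data.frame with columns \code{protein},
#'   \code{term}.
#' @param excludedGoTerms character vector of GO term ids whose annotation
#'   disqualifies a protein from the negative set.
#' @param goOntology optional GO \code{\linkS4class{Ontology}} for
#'   transitive (is_a) exclusion.
#' @return a \code{\linkS4class{ReferenceSet}}.
#' @export
buildReference <- function(records, bait, universe, minEvidence = 3L,
                           goAnnotations = NULL,
                           excludedGoTerms = character(),
                           goOntology = NULL) {
  minEvidence <- as.integer(minEvidence)
  if (minEvidence < 1L) .stopf("minEvidence must be >= 1")
  if (!bait %in% universe)
    .stopf("bait '%s' absent from the prey universe", bait)
  withBait <- records[records$protein_a == bait |
                        records$protein_b == bait, , drop = FALSE]
  partner <- ifelse(withBait$protein_a == bait, withBait$protein_b,
                    withBait$protein_a)
  counts <- table(factor(partner, levels = unique(partner)))
  counts <- stats::setNames(as.integer(counts), names(counts))
  pos <- intersect(names(counts)[counts >= minEvidence], universe)
  anyEvidence <- intersect(names(counts), universe)
  excluded <- character()
  if (!is.null(goAnnotations) && length(excludedGoTerms)) {
    .requireColumns(goAnnotations, c("protein", "term"), "GO annotations")
    bad <- excludedGoTerms
    if (!is.null(goOntology))
      bad <- unique(unlist(lapply(excludedGoTerms, function(t)
        ontologyDescendants(goOntology, t))))
    excluded <- unique(goAnnotations$protein[goAnnotations$term %in% bad])
  }
  neg <- setdiff(universe, c(anyEvidence, excluded, bait))
  new("ReferenceSet", bait = bait, positives = pos, negatives = neg,
      evidenceCounts = counts, minEvidence = minEvidence)
}
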