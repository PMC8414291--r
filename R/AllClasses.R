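#' @import methods
NULL

setClassUnion("functionOrNULL", c("function", "NULL"))

#' OntologyGraph: an in-memory parsed ontology
#'
#' Holds the concept and property sets of one ontology together with
#' their lexical annotations (local names, labels, synonyms, comments),
#' the subclass/part-of hierarchy as directed child-to-parent edges,
#' disjointness and explicit intra-ontology equivalence axioms, and the
#' raw triples the ontology was parsed from.
#'
#' @slot id Ontology identifier (usually derived from the file name or
#'   base URI).
#' @slot concepts Character vector of concept identifiers (URIs).
#' @slot properties Character vector of property identifiers.
#' @slot individuals Character vector of individual identifiers (stored
#'   but unused by the matchers; instance matching is out of scope).
#' @slot triples data.frame with columns \code{subject},
#'   \code{predicate}, \code{object}, \code{objectType} (one of
#'   \code{"uri"}, \code{"literal"}, \code{"blank"}).
#' @slot localNames Named character vector, element URI to local name.
#' @slot labels,synonyms,comments Named lists of character vectors keyed
#'   by element URI; no empty strings.
#' @slot hierarchy data.frame with columns \code{child}, \code{parent}:
#'   directed hierarchy edges over concepts (subclass and any configured
#'   part-of predicates). Acyclic.
#' @slot disjoint data.frame with columns \code{a}, \code{b}: unordered
#'   disjointness assertions between concepts.
#' @slot equivalents data.frame with columns \code{a}, \code{b}:
#'   explicit intra-ontology equivalence axioms.
#' @slot propertyInfo data.frame with columns \code{uri}, \code{domain},
#'   \code{range} (NA when absent).
#'
#' @seealso [parseOntology()], [hierarchyContext()], [semanticSubgraph()]
#' @export
setClass("OntologyGraph", representation(
  id = "character",
  concepts = "character",
  properties = "character",
  individuals = "character",
  triples = "data.frame",
  localNames = "character",
  labels = "list",
  synonyms = "list",
  comments = "list",
  hierarchy = "data.frame",
  disjoint = "data.frame",
  equivalents = "data.frame",
  propertyInfo = "data.frame"
))

setValidity("OntologyGraph", function(object) {
  msgs <- character(0)
  h <- object@hierarchy
  if (nrow(h) > 0) {
    bad <- !(h$child %in% object@concepts) | !(h$parent %in% object@concepts)
    if (any(bad))
      msgs <- c(msgs, "hierarchy edge endpoint is not a known concept")
    # subclass hierarchy must be a DAG
    g <- igraph::graph_from_data_frame(h[, c("child", "parent")],
                                       directed = TRUE)
    if (!igraph::is_dag(g))
      msgs <- c(msgs, "hierarchy contains a cycle")
  }
  for (nm in c("labels", "synonyms", "comments")) {
    vals <- unlist(slot(object, nm), use.names = FALSE)
    if (length(vals) && any(!nzchar(vals)))
      msgs <- c(msgs, sprintf("%s contain empty strings", nm))
  }
  if (length(msgs)) msgs else TRUE
})

#' VirtualDocument: a weighted bag of terms for one element
#'
#' Describes one ontology element in one clue dimension as a map from
#' token to positive weight. The composite document is the alpha-weighted
#' sum of the per-dimension documents.
#'
#' @slot element Element identifier.
#' @slot dimension One of \code{"term"}, \code{"struct"}, \code{"ext"},
#'   \code{"rps"}, \code{"composite"}.
#' @slot weights Named numeric vector, token to weight (> 0).
#' @export
setClass("VirtualDocument", representation(
  element = "character",
  dimension = "character",
  weights = "numeric"
))

setValidity("VirtualDocument", function(object) {
  ok <- c("term", "struct", "ext", "rps", "composite")
  if (!(object@dimension %in% ok))
    return(sprintf("dimension must be one of %s", paste(ok, collapse = ", ")))
  w <- object@weights
  if (length(w)) {
    if (is.null(names(w)) || any(!nzchar(names(w))))
      return("weights must be a named vector with non-empty token names")
    if (any(w <= 0)) return("all weights must be > 0")
    if (anyDuplicated(names(w))) return("duplicate token in weights")
  }
  TRUE
})

#' Lexicon: a synonym dictionary plus cross-references
#'
#' Stands in for external thesauri (WordNet-like general dictionaries or
#' domain lexica such as UBERON/UMLS). The synonym map is reverse-closed
#' at construction: \code{b in Syn(a)} implies \code{a in Syn(b)}.
#' Cross-references pair identifiers across two ontologies and can serve
#' as a reference alignment.
#'
#' @slot synonyms Named list, term to character vector of synonyms.
#' @slot crossRefs data.frame with columns \code{source}, \code{target}.
#' @seealso [readLexicon()], [buildExtDoc()], [referenceFromCrossrefs()]
#' @export
setClass("Lexicon", representation(
  synonyms = "list",
  crossRefs = "data.frame"
))

#' EmbeddingProvider: deterministic token-to-vector lookup
#'
#' Serves the representation-learning clue dimension. A provider either
#' wraps a fixed vocabulary matrix (plain-text word2vec files) or a
#' deterministic generator function (the toy provider used in tests).
#' Lookups are pure: the same token always yields the same vector.
#' Out-of-vocabulary tokens map to the zero vector; multi-token terms
#' are averaged upstream.
#'
#' @slot dimension Embedding dimensionality.
#' @slot vectors Numeric matrix with one row per vocabulary token
#'   (rownames are tokens); may have zero rows when a generator is used.
#' @slot generator Optional function(token) returning a numeric vector
#'   of length \code{dimension}, or NULL.
#' @seealso [readEmbeddings()], [toyEmbeddingProvider()], [buildRpsVector()]
#' @export
setClass("EmbeddingProvider", representation(
  dimension = "integer",
  vectors = "matrix",
  generator = "functionOrNULL"
))

#' SimilarityMatrix: scored source-by-target concept pairs
#'
#' Dense value matrix in \[0, 1\] plus a parallel status matrix recording
#' for each pair whether its similarity was actually computed, skipped by
#' a positive reduction set, skipped by a negative reduction set, or
#' never visited. Skipped pairs read as similarity 0.
#'
#' @slot sourceIds,targetIds Ordered identifier vectors (n1, n2).
#' @slot values Numeric n1 x n2 matrix of similarities in \[0, 1\].
#' @slot status Integer n1 x n2 matrix; see [statusCodes()].
#' @seealso [runMatcher()], [lomHybrid()], [extractAlignment()]
#' @export
setClass("SimilarityMatrix", representation(
  sourceIds = "character",
  targetIds = "character",
  values = "matrix",
  status = "matrix"
))

setValidity("SimilarityMatrix", function(object) {
  n1 <- length(object@sourceIds); n2 <- length(object@targetIds)
  if (!all(dim(object@values) == c(n1, n2)))
    return("values dimensions do not match id vectors")
  if (!all(dim(object@status) == c(n1, n2)))
    return("status dimensions do not match id vectors")
  v <- object@values
  if (length(v) && (min(v) < -1e-12 || max(v) > 1 + 1e-12))
    return("similarities must lie in [0, 1]")
  if (!all(object@status %in% 0:3))
    return("status codes must be 0 (uncomputed), 1 (computed), 2 (skipped positive), 3 (skipped negative)")
  TRUE
})

#' AnchorState: reduction-anchor bookkeeping
#'
#' Carries the thresholds and constraint switches of the reduction-anchor
#' algorithms together with the positive/negative anchor sets discovered
#' during a run (both the raw anchors and their extensions through
#' intra-ontology equivalent concepts).
#'
#' @slot ptValue Positive anchor threshold: a computed similarity
#'   strictly above it makes the pair a P-Anchor.
#' @slot ntValue Negative anchor threshold: strictly below it makes the
#'   pair an N-Anchor.
#' @slot topK Number of P-AnchorsE retained per concept (1 to 4).
#' @slot nScale Radius of the neighborhood ball used by negative
#'   propagation.
#' @slot tItems SDD constraint: anchors propagate only from concepts
#'   whose description document has more than this many distinct tokens.
#' @slot eqValue Intra-ontology name-similarity threshold above which two
#'   concepts count as equivalent for anchor extension.
#' @slot ssg,sdd Logical switches for the semantic-subgraph and
#'   description-document constraints on negative propagation.
#' @slot pa,pae,na,nae Named lists: source concept to character vector of
#'   target concepts (anchors and extended anchors).
#' @seealso [anchorState()], [lomPE()], [lomNE()], [lomHybrid()]
#' @export
setClass("AnchorState", representation(
  ptValue = "numeric",
  ntValue = "numeric",
  topK = "integer",
  nScale = "integer",
  tItems = "integer",
  eqValue = "numeric",
  ssg = "logical",
  sdd = "logical",
  pa = "list",
  pae = "list",
  na = "list",
  nae = "list"
))

setValidity("AnchorState", function(object) {
  if (object@ptValue < 0 || object@ntValue < 0)
    return("thresholds must be non-negative")
  if (object@topK < 1L || object@topK > 4L)
    return("topK must be between 1 and 4")
  if (object@nScale < 0L) return("nScale must be >= 0")
  if (object@tItems < 0L) return("tItems must be >= 0")
  TRUE
})

#' ReductionStats: computation/skip accounting for one reduction run
#'
#' @slot computed Number of pairs whose similarity was computed.
#' @slot skippedPositive,skippedNegative Pairs skipped by positive /
#'   negative reduction sets.
#' @slot n1,n2 Concept counts of the two ontologies.
#' @seealso [benefitRate()]
#' @export
setClass("ReductionStats", representation(
  computed = "numeric",
  skippedPositive = "numeric",
  skippedNegative = "numeric",
  n1 = "numeric",
  n2 = "numeric"
))

setValidity("ReductionStats", function(object) {
  tot <- object@computed + object@skippedPositive + object@skippedNegative
  if (object@n1 > 0 && object@n2 > 0 && tot > object@n1 * object@n2 + 1e-9)
    return("computed + skipped exceeds n1 * n2")
  TRUE
})

#' Alignment: a set of correspondences between two ontologies
#'
#' Each correspondence maps a source element to a target element with a
#' relation symbol (only equivalence, \code{"="}, is in scope) and a
#' confidence in \[0, 1\]. Extracted alignments are one-to-one; reference
#' alignments loaded from cross-references may be many-to-many.
#'
#' @slot ontology1,ontology2 Identifiers of the aligned ontologies.
#' @slot pairs data.frame with columns \code{source}, \code{target},
#'   \code{relation}, \code{confidence}.
#' @seealso [extractAlignment()], [evaluateAlignment()],
#'   [readAlignment()], [writeAlignment()]
#' @export
setClass("Alignment", representation(
  ontology1 = "character",
  ontology2 = "character",
  pairs = "data.frame"
))

setValidity("Alignment", function(object) {
  p <- object@pairs
  need <- c("source", "target", "relation", "confidence")
  if (!all(need %in% names(p)))
    return("pairs must have columns source, target, relation, confidence")
  if (nrow(p)) {
    if (any(p$confidence < 0 | p$confidence > 1))
      return("confidence must lie in [0, 1]")
    if (any(p$relation != "="))
      return("only equivalence correspondences (relation \"=\") are supported")
    if (anyDuplicated(paste(p$source, p$target)))
      return("duplicate correspondence")
  }
  TRUE
})

#' MatcherConfig: one matcher's clue selection and parameters
#'
#' Thirteen presets (M1 to M13) fix which clues feed the matcher: M1
#' compares non-ID local names by edit similarity; M2/M3 use label
#' (+ synonym) documents; M4 to M8 add property, direct-, local- or
#' global-hierarchy structure; M9/M10 expand documents through a general
#' or domain lexicon; M11 to M13 add an embedding similarity combined at
#' the matrix level.
#'
#' @slot matcherId Preset name (\code{"M1"}..\code{"M13"}) or
#'   \code{"custom"}.
#' @slot useName Use the local-name edit-similarity clue.
#' @slot termFields Lexical fields feeding the terminological document:
#'   subset of \code{"label"}, \code{"synonym"}, \code{"comment"},
#'   \code{"localname"}.
#' @slot structMode Structural document mode: \code{"none"},
#'   \code{"property"}, \code{"direct"}, \code{"local"}, \code{"global"}.
#' @slot useExt Expand documents through a [Lexicon].
#' @slot useRps Add the embedding (representation learning) similarity.
#' @slot alpha Length-4 clue weights (term, struct, ext, rps) used when
#'   composing documents.
#' @slot matrixWeights Named weights for matrix-level combination of the
#'   dimension similarity matrices produced by this matcher.
#' @slot threshold Alignment extraction threshold in \[0, 1\].
#' @slot decay Per-level decay for global-hierarchy documents, in (0, 1].
#' @seealso [matcherPreset()], [runMatcher()]
#' @export
setClass("MatcherConfig", representation(
  matcherId = "character",
  useName = "logical",
  termFields = "character",
  structMode = "character",
  useExt = "logical",
  useRps = "logical",
  alpha = "numeric",
  matrixWeights = "numeric",
  threshold = "numeric",
  decay = "numeric"
))

setValidity("MatcherConfig", function(object) {
  if (!(object@structMode %in% c("none", "property", "direct", "local",
                                 "global")))
    return("invalid structMode")
  if (length(object@alpha) != 4L || any(object@alpha < 0) ||
      any(object@alpha > 1))
    return("alpha must be four weights in [0, 1]")
  if (all(object@alpha == 0)) return("at least one alpha must be > 0")
  if (object@threshold < 0 || object@threshold > 1)
    return("threshold must lie in [0, 1]")
  if (object@decay <= 0 || object@decay > 1)
    return("decay must lie in (0, 1]")
  if (length(object@matrixWeights) && sum(object@matrixWeights) <= 0)
    return("matrixWeights must sum to > 0")
  TRUE
})
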