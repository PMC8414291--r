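## Ontology graph construction and hierarchy accessors.

.DEFAULT_SYNONYM_PREDICATES <- c(
  "rdfs:seeAlso", "owl:sameAs",
  "oboInOwl:hasExactSynonym", "oboInOwl:hasRelatedSynonym"
)

localNameOf <- function(uri) {
  vapply(uri, function(u) {
    if (grepl("#", u, fixed = TRUE)) return(sub("^.*#", "", u))
    sub("^.*/", "", u)
  }, character(1), USE.NAMES = FALSE)
}

#' Parse an RDF/XML or Turtle ontology file
#'
#' Reads the file into an [OntologyGraph-class]: concept and property
#' sets, labels, synonyms, comments, the subclass (and configured
#' part-of) hierarchy, disjointness and equivalence axioms, and property
#' domains/ranges. A subclass axiom whose parent is an anonymous
#' restriction is resolved by traversing the blank node to the nearest
#' named class; the edge is kept when the restriction's property is
#' listed in \code{hierarchyPredicates}.
#'
#' @param path Path to a \code{.ttl} (Turtle) or \code{.owl}/\code{.rdf}
#'   (RDF/XML) file.
#' @param dialect \code{"auto"} (by extension), \code{"rdfxml"}, or
#'   \code{"turtle"}.
#' @param hierarchyPredicates Predicates (curies or full URIs) treated
#'   as hierarchy edges in addition to the implicit
#'   \code{rdfs:subClassOf}; e.g. a part-of property for anatomical
#'   ontologies. Default: subclass only.
#' @param synonymPredicates Predicates whose objects are collected as
#'   synonyms. URI-valued objects contribute their local name.
#' @param id Ontology identifier; defaults to the file base name.
#' @return An [OntologyGraph-class].
#' @examples
#' ttl <- c(
#'   "@prefix : <http://example.org/onto#> .",
#'   "@prefix owl: <http://www.w3.org/2002/07/owl#> .",
#'   "@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .",
#'   ":FootBone a owl:Class ; rdfs:label \"foot bone\" ;",
#'   "  rdfs:subClassOf :LimbBone .",
#'   ":LimbBone a owl:Class ; rdfs:label \"limb bone\" .")
#' f <- tempfile(fileext = ".ttl"); writeLines(ttl, f)
#' g <- parseOntology(f)
#' concepts(g)
#' @export
parseOntology <- function(path,
                          dialect = c("auto", "rdfxml", "turtle"),
                          hierarchyPredicates = character(0),
                          synonymPredicates = .DEFAULT_SYNONYM_PREDICATES,
                          id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    stop(sprintf("ontology file '%s' does not exist", path), call. = FALSE)
  if (dialect == "auto") {
    ext <- tolower(sub("^.*\\.", "", path))
    dialect <- switch(ext,
      ttl = "turtle", turtle = "turtle",
      owl = "rdfxml", rdf = "rdfxml", xml = "rdfxml",
      stop(sprintf("cannot infer RDF dialect from extension '.%s'; pass dialect=", ext),
           call. = FALSE))
  }
  triples <- if (dialect == "turtle") {
    parseTurtle(paste(readLines(path, warn = FALSE), collapse = "\n"))
  } else {
    parseRdfXml(path)
  }
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  buildOntologyGraph(triples, id = id,
                     hierarchyPredicates = hierarchyPredicates,
                     synonymPredicates = synonymPredicates)
}

#' Build an OntologyGraph from a triple table
#'
#' Lower-level constructor used by [parseOntology()] and by the
#' synthetic generator. See [parseOntology()] for the semantics of the
#' predicate configuration.
#'
#' @param triples data.frame with columns \code{subject},
#'   \code{predicate}, \code{object}, \code{objectType}.
#' @inheritParams parseOntology
#' @return An [OntologyGraph-class].
#' @export
buildOntologyGraph <- function(triples, id = "ontology",
                               hierarchyPredicates = character(0),
                               synonymPredicates = .DEFAULT_SYNONYM_PREDICATES) {
  stopifnot(is.data.frame(triples))
  rdfType <- expandCurie("rdf:type")
  owlClass <- expandCurie("owl:Class")
  owlRestriction <- expandCurie("owl:Restriction")
  subClassOf <- expandCurie("rdfs:subClassOf")
  hierPreds <- unique(expandCurie(hierarchyPredicates))

  isBlank <- function(x) startsWith(x, "_:")

  typeOf <- triples[triples$predicate == rdfType & triples$objectType == "uri", ]
  classIds <- unique(typeOf$subject[typeOf$object == owlClass &
                                      !isBlank(typeOf$subject)])
  propTypes <- expandCurie(c("owl:ObjectProperty", "owl:DatatypeProperty",
                             "owl:AnnotationProperty", "rdf:Property"))
  propIds <- unique(typeOf$subject[typeOf$object %in% propTypes &
                                     !isBlank(typeOf$subject)])
  indivIds <- unique(typeOf$subject[
    typeOf$object == expandCurie("owl:NamedIndividual") &
      !isBlank(typeOf$subject)])

  ## --- hierarchy edges -------------------------------------------------
  # index triples by subject for blank-node resolution
  bySubject <- split(seq_len(nrow(triples)), triples$subject)

  # resolve a node (possibly blank) to named parent classes; blank
  # restriction nodes contribute their filler class when the restriction
  # property is configured as hierarchical; other blank nodes are
  # traversed recursively through their own subclass/filler links.
  someFrom <- expandCurie(c("owl:someValuesFrom", "owl:allValuesFrom"))
  onProp <- expandCurie("owl:onProperty")
  resolveParents <- function(node, depth = 0L) {
    if (!isBlank(node)) return(node)
    if (depth > 10L) return(character(0))
    rows <- triples[bySubject[[node]], , drop = FALSE]
    if (is.null(rows) || nrow(rows) == 0L) return(character(0))
    isRestr <- any(rows$predicate == rdfType & rows$object == owlRestriction)
    out <- character(0)
    if (isRestr) {
      p <- rows$object[rows$predicate == onProp]
      filler <- rows$object[rows$predicate %in% someFrom]
      if (length(p) && length(filler) && p[1] %in% hierPreds)
        out <- c(out, unlist(lapply(filler, resolveParents, depth + 1L)))
    } else {
      # e.g. intersectionOf chains or nested descriptions: follow any
      # subclass or filler links out of the blank node
      follow <- rows$object[rows$predicate %in% c(subClassOf, someFrom)]
      out <- c(out, unlist(lapply(follow, resolveParents, depth + 1L)))
    }
    out
  }

  edgeList <- list()
  addEdge <- function(child, parent, pred) {
    edgeList[[length(edgeList) + 1L]] <<-
      list(child = child, parent = parent, predicate = pred)
  }
  sub_rows <- triples[triples$predicate == subClassOf, , drop = FALSE]
  for (k in seq_len(nrow(sub_rows))) {
    ch <- sub_rows$subject[k]; pa <- sub_rows$object[k]
    if (isBlank(ch)) next
    for (p in resolveParents(pa)) addEdge(ch, p, "rdfs:subClassOf")
  }
  # direct part-of style edges between named classes
  for (hp in hierPreds) {
    hrows <- triples[triples$predicate == hp & triples$objectType == "uri", ,
                     drop = FALSE]
    for (k in seq_len(nrow(hrows))) {
      if (isBlank(hrows$subject[k]) || isBlank(hrows$object[k])) next
      addEdge(hrows$subject[k], hrows$object[k], curie(hp))
    }
  }
  hierarchy <- if (length(edgeList)) {
    h <- data.frame(
      child = vapply(edgeList, `[[`, character(1), "child"),
      parent = vapply(edgeList, `[[`, character(1), "parent"),
      predicate = vapply(edgeList, `[[`, character(1), "predicate"),
      stringsAsFactors = FALSE)
    h[!duplicated(h[, c("child", "parent")]) & h$child != h$parent, ,
      drop = FALSE]
  } else {
    data.frame(child = character(0), parent = character(0),
               predicate = character(0), stringsAsFactors = FALSE)
  }

  # concepts = declared classes plus named hierarchy endpoints
  conceptIds <- unique(c(classIds, hierarchy$child, hierarchy$parent))

  ## --- lexical annotations --------------------------------------------
  collectLiteral <- function(pred) {
    rows <- triples[triples$predicate == expandCurie(pred) &
                      triples$objectType == "literal" &
                      nzchar(triples$object), , drop = FALSE]
    split(rows$object, rows$subject)
  }
  labels <- collectLiteral("rdfs:label")
  comments <- collectLiteral("rdfs:comment")

  synPreds <- expandCurie(synonymPredicates)
  srows <- triples[triples$predicate %in% synPreds, , drop = FALSE]
  synVals <- ifelse(srows$objectType == "uri",
                    gsub("_", " ", localNameOf(srows$object)),
                    srows$object)
  keep <- nzchar(synVals) & srows$objectType != "blank"
  synonyms <- split(synVals[keep], srows$subject[keep])
  synonyms <- lapply(synonyms, unique)

  ## --- disjointness / equivalence / property info ---------------------
  collectPairs <- function(pred) {
    rows <- triples[triples$predicate == expandCurie(pred) &
                      triples$objectType == "uri", , drop = FALSE]
    rows <- rows[!isBlank(rows$subject), , drop = FALSE]
    data.frame(a = rows$subject, b = rows$object, stringsAsFactors = FALSE)
  }
  disjoint <- collectPairs("owl:disjointWith")
  equivalents <- collectPairs("owl:equivalentClass")
  names(disjoint) <- names(equivalents) <- c("a", "b")

  dom <- triples[triples$predicate == expandCurie("rdfs:domain"), , drop = FALSE]
  rng <- triples[triples$predicate == expandCurie("rdfs:range"), , drop = FALSE]
  propertyInfo <- data.frame(uri = propIds, stringsAsFactors = FALSE)
  propertyInfo$domain <- vapply(propIds, function(p) {
    d <- dom$object[dom$subject == p]
    if (length(d)) d[1] else NA_character_
  }, character(1), USE.NAMES = FALSE)
  propertyInfo$range <- vapply(propIds, function(p) {
    r <- rng$object[rng$subject == p]
    if (length(r)) r[1] else NA_character_
  }, character(1), USE.NAMES = FALSE)

  allIds <- unique(c(conceptIds, propIds))
  localNames <- structure(localNameOf(allIds), names = allIds)

  methods::new("OntologyGraph",
    id = id,
    concepts = conceptIds,
    properties = propIds,
    individuals = indivIds,
    triples = triples,
    localNames = localNames,
    labels = labels[names(labels) %in% allIds],
    synonyms = synonyms[names(synonyms) %in% allIds],
    comments = comments[names(comments) %in% allIds],
    hierarchy = hierarchy,
    disjoint = disjoint,
    equivalents = equivalents,
    propertyInfo = propertyInfo)
}

## ---- accessors -------------------------------------------------------

#' @rdname OntologyGraph-class
#' @aliases concepts,OntologyGraph-method
#' @export
setMethod("concepts", "OntologyGraph", function(x) x@concepts)

#' @rdname OntologyGraph-class
#' @export
setMethod("ontologyProperties", "OntologyGraph", function(x) x@properties)

#' @rdname OntologyGraph-class
#' @export
setMethod("ontologyId", "OntologyGraph", function(x) x@id)

#' @rdname OntologyGraph-class
#' @export
setMethod("elementLabels", "OntologyGraph", function(x, element) {
  out <- x@labels[[element]]
  if (is.null(out)) character(0) else out
})

#' @rdname OntologyGraph-class
#' @export
setMethod("elementSynonyms", "OntologyGraph", function(x, element) {
  out <- x@synonyms[[element]]
  if (is.null(out)) character(0) else out
})

#' @rdname OntologyGraph-class
#' @export
setMethod("hierarchyEdges", "OntologyGraph", function(x) x@hierarchy)

setMethod("show", "OntologyGraph", function(object) {
  cat(sprintf("OntologyGraph '%s'\n", object@id))
  cat(sprintf("  %d concepts, %d properties, %d hierarchy edges\n",
              length(object@concepts), length(object@properties),
              nrow(object@hierarchy)))
  cat(sprintf("  %d labels, %d synonyms, %d triples\n",
              length(unlist(object@labels)), length(unlist(object@synonyms)),
              nrow(object@triples)))
})

## ---- hierarchy machinery --------------------------------------------

## Precomputed index over one ontology's hierarchy: igraph object plus
## per-concept adjacency. Ancestor/descendant closures and neighborhood
## balls are computed on demand and memoized.
ontologyIndex <- function(g) {
  ids <- g@concepts
  h <- g@hierarchy
  ig <- igraph::graph_from_data_frame(
    d = h[, c("child", "parent"), drop = FALSE],
    directed = TRUE,
    vertices = data.frame(name = ids, stringsAsFactors = FALSE))
  env <- new.env(parent = emptyenv())
  env$g <- g
  env$ids <- ids
  env$ig <- ig
  env$igUndirected <- igraph::as_undirected(ig, mode = "collapse")
  env$parents <- lapply(
    structure(ids, names = ids),
    function(x) h$parent[h$child == x])
  env$children <- lapply(
    structure(ids, names = ids),
    function(x) h$child[h$parent == x])
  env$anc <- new.env(parent = emptyenv())
  env$dec <- new.env(parent = emptyenv())
  env$ball <- new.env(parent = emptyenv())
  env
}

## Transitive closure over hierarchy edges; mode "out" follows
## child -> parent (ancestors), "in" the reverse (descendants).
closureOf <- function(idx, e, mode) {
  cacheName <- if (mode == "out") "anc" else "dec"
  cache <- idx[[cacheName]]
  if (!is.null(cache[[e]])) return(cache[[e]])
  vs <- igraph::subcomponent(idx$ig, e, mode = mode)
  out <- setdiff(names(vs), e)
  assign(e, out, envir = cache)
  out
}

## Undirected ball of radius r around e (including e), memoized per radius.
ballOf <- function(idx, e, r) {
  key <- sprintf("%s|%d", e, r)
  if (!is.null(idx$ball[[key]])) return(idx$ball[[key]])
  vs <- igraph::ego(idx$igUndirected, order = r, nodes = e)[[1]]
  out <- names(vs)
  assign(key, out, envir = idx$ball)
  out
}

siblingsOf <- function(idx, e) {
  pars <- idx$parents[[e]]
  if (length(pars) == 0L) return(character(0))
  setdiff(unique(unlist(idx$children[pars], use.names = FALSE)), e)
}

#' Hierarchical context of a concept
#'
#' Returns the ancestors (transitive closure of parent edges),
#' descendants, siblings (concepts sharing at least one parent),
#' disjoint concepts, the neighborhood ball \code{Nb} of radius
#' \code{nScale} in the undirected hierarchy graph, and the undirected
#' degree of the concept.
#'
#' @param g An [OntologyGraph-class].
#' @param element Concept identifier.
#' @param nScale Non-negative ball radius; \code{Nb} at radius 0 is the
#'   concept itself.
#' @return A list with components \code{element}, \code{ancestors},
#'   \code{descendants}, \code{siblings}, \code{disjoint},
#'   \code{neighbors}, \code{degree}.
#' @export
hierarchyContext <- function(g, element, nScale = 1L) {
  stopifnot(methods::is(g, "OntologyGraph"))
  if (!(element %in% g@concepts))
    stop(sprintf("unknown concept '%s'", element), call. = FALSE)
  if (nScale < 0) stop("nScale must be >= 0", call. = FALSE)
  idx <- ontologyIndex(g)
  dis <- unique(c(g@disjoint$b[g@disjoint$a == element],
                  g@disjoint$a[g@disjoint$b == element]))
  list(
    element = element,
    ancestors = closureOf(idx, element, "out"),
    descendants = closureOf(idx, element, "in"),
    siblings = siblingsOf(idx, element),
    disjoint = dis,
    neighbors = ballOf(idx, element, as.integer(nScale)),
    degree = length(idx$parents[[element]]) + length(idx$children[[element]])
  )
}

#' Semantic subgraph of a concept
#'
#' The local structural context used by the local-hierarchy matcher and
#' the SSG propagation constraint: all concepts within undirected
#' distance \code{radius} of the concept, plus its siblings.
#'
#' @inheritParams hierarchyContext
#' @param radius Non-negative integer; default 2.
#' @return Character vector of concept identifiers (always contains
#'   \code{element}).
#' @export
semanticSubgraph <- function(g, element, radius = 2L) {
  stopifnot(methods::is(g, "OntologyGraph"))
  if (!(element %in% g@concepts))
    stop(sprintf("unknown concept '%s'", element), call. = FALSE)
  if (radius < 0) stop("radius must be >= 0", call. = FALSE)
  idx <- ontologyIndex(g)
  unique(c(ballOf(idx, element, as.integer(radius)), siblingsOf(idx, element)))
}

## ---- Turtle serialization -------------------------------------------

## Serialize an OntologyGraph to Turtle. Labels/synonyms/comments are
## written with the standard predicates; hierarchy edges re-use the
## predicate recorded at parse/generation time (part-of edges are
## emitted as direct triples).
writeOntologyTurtle <- function(g, path) {
  esc <- function(s) gsub("\"", "\\\\\"", s)
  ln <- c(
    "@prefix rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#> .",
    "@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .",
    "@prefix owl: <http://www.w3.org/2002/07/owl#> .",
    "@prefix oboInOwl: <http://www.geneontology.org/formats/oboInOwl#> .",
    "")
  h <- g@hierarchy
  for (cid in g@concepts) {
    parts <- sprintf("<%s> a owl:Class", cid)
    for (lb in g@labels[[cid]] %||% character(0))
      parts <- c(parts, sprintf("rdfs:label \"%s\"", esc(lb)))
    for (sy in g@synonyms[[cid]] %||% character(0))
      parts <- c(parts, sprintf("oboInOwl:hasRelatedSynonym \"%s\"", esc(sy)))
    for (cm in g@comments[[cid]] %||% character(0))
      parts <- c(parts, sprintf("rdfs:comment \"%s\"", esc(cm)))
    rows <- which(h$child == cid)
    for (k in rows) {
      if (h$predicate[k] == "rdfs:subClassOf") {
        parts <- c(parts, sprintf("rdfs:subClassOf <%s>", h$parent[k]))
      } else {
        parts <- c(parts, sprintf("<%s> <%s>",
                                  expandCurie(h$predicate[k]), h$parent[k]))
      }
    }
    ln <- c(ln, paste0(paste(parts, collapse = " ;\n    "), " ."))
  }
  for (p in g@properties) {
    parts <- sprintf("<%s> a owl:ObjectProperty", p)
    pi <- g@propertyInfo
    row <- pi[pi$uri == p, , drop = FALSE]
    if (nrow(row) == 1L) {
      if (!is.na(row$domain)) parts <- c(parts, sprintf("rdfs:domain <%s>", row$domain))
      if (!is.na(row$range)) parts <- c(parts, sprintf("rdfs:range <%s>", row$range))
    }
    for (lb in g@labels[[p]] %||% character(0))
      parts <- c(parts, sprintf("rdfs:label \"%s\"", esc(lb)))
    ln <- c(ln, paste0(paste(parts, collapse = " ;\n    "), " ."))
  }
  writeLines(ln, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
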