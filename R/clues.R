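## Virtual-document builders for the four clue dimensions.

#' Construct a VirtualDocument
#'
#' @param element Element identifier.
#' @param dimension Clue dimension.
#' @param weights Named numeric vector of positive token weights.
#' @return A [VirtualDocument-class].
#' @export
virtualDocument <- function(element, dimension, weights = numeric(0)) {
  if (length(weights)) {
    weights <- weights[weights > 0]
    weights <- weights[order(names(weights))]
  }
  methods::new("VirtualDocument", element = element, dimension = dimension,
               weights = weights)
}

#' @rdname VirtualDocument-class
#' @export
setMethod("termWeights", "VirtualDocument", function(x) x@weights)

#' @rdname VirtualDocument-class
#' @export
setMethod("itemCount", "VirtualDocument", function(x) length(x@weights))

setMethod("show", "VirtualDocument", function(object) {
  cat(sprintf("VirtualDocument [%s] for %s: %d tokens\n", object@dimension,
              object@element, length(object@weights)))
  if (length(object@weights)) {
    w <- sort(object@weights, decreasing = TRUE)
    shown <- utils::head(w, 8)
    cat("  ", paste(sprintf("%s(%.3g)", names(shown), shown),
                    collapse = " "), "\n")
  }
})

## Tokens of one element's lexical fields, as a count bag. ID-form local
## names contribute nothing.
.elementTermTokens <- function(g, e, fields = c("localname", "label",
                                                "synonym", "comment")) {
  out <- character(0)
  if ("localname" %in% fields) {
    ln <- g@localNames[[e]]
    if (!is.null(ln) && !isIdLike(ln)) out <- c(out, tokenizeTerms(ln))
  }
  grab <- function(slotName) {
    vals <- slot(g, slotName)[[e]]
    if (is.null(vals)) character(0)
    else unlist(lapply(vals, tokenizeTerms), use.names = FALSE)
  }
  if ("label" %in% fields) out <- c(out, grab("labels"))
  if ("synonym" %in% fields) out <- c(out, grab("synonyms"))
  if ("comment" %in% fields) out <- c(out, grab("comments"))
  out
}

#' Build the terminological virtual document of an element
#'
#' Collects the tokens of the element's local name (unless it is in ID
#' form), labels, synonyms, and comments; weights are raw occurrence
#' counts.
#'
#' @param g An [OntologyGraph-class].
#' @param element Element identifier.
#' @param fields Which lexical fields contribute; defaults to all four.
#' @return A [VirtualDocument-class] with dimension \code{"term"}.
#' @export
buildTermDoc <- function(g, element,
                         fields = c("localname", "label", "synonym",
                                    "comment")) {
  stopifnot(methods::is(g, "OntologyGraph"))
  if (!(element %in% g@concepts) && !(element %in% g@properties))
    stop(sprintf("unknown element '%s'", element), call. = FALSE)
  toks <- .elementTermTokens(g, element, fields)
  virtualDocument(element, "term", countBag(toks))
}

#' Build the structural virtual document of an element
#'
#' Describes an element by the terminological content of its structural
#' context, always merged with the element's own terminological
#' document. Modes: \code{"property"} adds the names, domains, and
#' ranges of properties attached to the concept; \code{"direct"} adds
#' the term documents of parents, children, siblings, and disjoint
#' concepts; \code{"local"} those of the semantic subgraph;
#' \code{"global"} the transitive ancestors and descendants with token
#' weights scaled by \code{decay^depth} (depth capped at 5).
#'
#' @inheritParams buildTermDoc
#' @param mode One of \code{"property"}, \code{"direct"},
#'   \code{"local"}, \code{"global"}.
#' @param decay Per-level decay in (0, 1] for \code{"global"} mode.
#' @param fields Lexical fields used for the term documents.
#' @param idx Optional precomputed index from \code{ontologyIndex};
#'   internal use.
#' @return A [VirtualDocument-class] with dimension \code{"struct"}.
#' @export
buildStructDoc <- function(g, element,
                           mode = c("direct", "property", "local", "global"),
                           decay = 0.5,
                           fields = c("localname", "label", "synonym",
                                      "comment"),
                           idx = NULL) {
  stopifnot(methods::is(g, "OntologyGraph"))
  mode <- match.arg(mode)
  if (!(element %in% g@concepts))
    stop(sprintf("unknown concept '%s'", element), call. = FALSE)
  if (decay <= 0 || decay > 1) stop("decay must be in (0, 1]", call. = FALSE)
  if (is.null(idx)) idx <- ontologyIndex(g)

  own <- countBag(.elementTermTokens(g, element, fields))
  bags <- list(own)

  termBagOf <- function(ids, weight = 1) {
    lapply(ids, function(x) {
      b <- countBag(.elementTermTokens(g, x, fields))
      b * weight
    })
  }

  if (mode == "property") {
    pi <- g@propertyInfo
    attached <- pi$uri[(!is.na(pi$domain) & pi$domain == element) |
                         (!is.na(pi$range) & pi$range == element)]
    for (p in attached) {
      bags <- c(bags, list(countBag(.elementTermTokens(g, p, fields))))
      row <- pi[pi$uri == p, , drop = FALSE]
      ends <- stats::na.omit(c(row$domain, row$range))
      bags <- c(bags, termBagOf(ends[ends %in% g@concepts]))
    }
  } else if (mode == "direct") {
    ctxIds <- unique(c(idx$parents[[element]], idx$children[[element]],
                       siblingsOf(idx, element),
                       g@disjoint$b[g@disjoint$a == element],
                       g@disjoint$a[g@disjoint$b == element]))
    bags <- c(bags, termBagOf(setdiff(ctxIds, element)))
  } else if (mode == "local") {
    ctxIds <- setdiff(
      unique(c(ballOf(idx, element, 2L), siblingsOf(idx, element))),
      element)
    bags <- c(bags, termBagOf(ctxIds))
  } else { # global
    maxDepth <- 5L
    for (dir in c("out", "in")) {
      frontier <- element
      seen <- element
      for (depth in seq_len(maxDepth)) {
        nxt <- unique(unlist(
          lapply(frontier, function(x)
            if (dir == "out") idx$parents[[x]] else idx$children[[x]]),
          use.names = FALSE))
        nxt <- setdiff(nxt, seen)
        if (length(nxt) == 0L) break
        bags <- c(bags, termBagOf(nxt, weight = decay^depth))
        seen <- c(seen, nxt)
        frontier <- nxt
      }
    }
  }
  virtualDocument(element, "struct", mergeBags(bags))
}

#' Build the external-knowledge virtual document of an element
#'
#' Expands the element's terminological document with the synonyms of
#' its labels and internal synonyms looked up in a [Lexicon-class]
#' (full-phrase match first, then per token; the lexicon is
#' reverse-closed at construction). With an empty lexicon the term
#' document is returned unchanged.
#'
#' @inheritParams buildTermDoc
#' @param lex A [Lexicon-class].
#' @return A [VirtualDocument-class] with dimension \code{"ext"}.
#' @export
buildExtDoc <- function(g, element, lex,
                        fields = c("localname", "label", "synonym",
                                   "comment")) {
  stopifnot(methods::is(g, "OntologyGraph"), methods::is(lex, "Lexicon"))
  term <- buildTermDoc(g, element, fields)
  if (length(lex@synonyms) == 0L)
    return(virtualDocument(element, "ext", term@weights))
  phrases <- c(g@labels[[element]] %||% character(0),
               g@synonyms[[element]] %||% character(0))
  extra <- unlist(lapply(phrases, function(ph) {
    syns <- lexiconLookup(lex, ph)
    unlist(lapply(syns, tokenizeTerms), use.names = FALSE)
  }), use.names = FALSE)
  virtualDocument(element, "ext",
                  mergeBags(list(term@weights, countBag(extra))))
}

#' Build the representation-learning vector of an element
#'
#' The element vector is the mean of the provider's token vectors over
#' the tokens of its labels and synonyms, unit-normalized. A fully
#' out-of-vocabulary element yields the zero vector; similarities
#' against it are defined as 0.
#'
#' @inheritParams buildTermDoc
#' @param provider An [EmbeddingProvider-class].
#' @return Numeric vector of length \code{provider@dimension}.
#' @export
buildRpsVector <- function(g, element, provider) {
  stopifnot(methods::is(g, "OntologyGraph"),
            methods::is(provider, "EmbeddingProvider"))
  phrases <- c(g@labels[[element]] %||% character(0),
               g@synonyms[[element]] %||% character(0))
  if (length(phrases) == 0L) {
    ln <- g@localNames[[element]]
    if (!is.null(ln) && !isIdLike(ln)) phrases <- ln
  }
  toks <- unique(unlist(lapply(phrases, tokenizeTerms), use.names = FALSE))
  if (length(toks) == 0L) return(numeric(provider@dimension))
  vs <- vapply(toks, function(t) providerVector(provider, t),
               numeric(provider@dimension))
  v <- rowMeans(matrix(vs, nrow = provider@dimension))
  nrm <- sqrt(sum(v^2))
  if (nrm > 0) v / nrm else v
}

#' Compose per-dimension documents with clue weights
#'
#' The composite clue of an element is the weighted sum of its
#' per-dimension virtual documents: each token's weight is
#' \code{sum_k alpha_k * weight_k(token)}. The representation-learning
#' dimension participates only when supplied as a bag; dense embedding
#' vectors are combined at the matrix level instead.
#'
#' @param docs Named list of [VirtualDocument-class] objects; names are
#'   a subset of \code{"term"}, \code{"struct"}, \code{"ext"},
#'   \code{"rps"}.
#' @param alpha Numeric weights in \[0, 1\], recycled/matched by the
#'   names of \code{docs}; at least one must be positive.
#' @return A [VirtualDocument-class] with dimension \code{"composite"}.
#' @export
compositeDoc <- function(docs, alpha) {
  stopifnot(length(docs) > 0)
  if (is.null(names(alpha))) {
    stopifnot(length(alpha) == length(docs))
    names(alpha) <- names(docs)
  }
  if (any(alpha < 0) || any(alpha > 1))
    stop("alpha weights must lie in [0, 1]", call. = FALSE)
  if (all(alpha[names(docs)] == 0))
    stop("at least one clue weight must be > 0", call. = FALSE)
  bags <- lapply(names(docs), function(d) {
    w <- alpha[[d]]
    if (is.null(w) || w == 0) return(numeric(0))
    docs[[d]]@weights * w
  })
  el <- docs[[1]]@element
  virtualDocument(el, "composite", mergeBags(bags))
}
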