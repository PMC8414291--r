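## TF-IDF weighting over virtual-document corpora.
##
## The corpus for one clue dimension is the union of both ontologies'
## documents of that dimension, so the inverse document frequency
## reflects cross-ontology discriminativeness. The IDF variant used is
## (1/2) * (1 + log2(N/n)): a token present in every document keeps a
## floor weight of 0.5 rather than vanishing.

#' Build a TF-IDF corpus from virtual documents
#'
#' @param docs List of [VirtualDocument-class] objects (typically all
#'   documents of one dimension across both ontologies).
#' @return A \code{DocumentCorpus} object (list with \code{N}, the
#'   document count, and \code{df}, the per-token document frequency).
#' @export
buildCorpus <- function(docs) {
  stopifnot(length(docs) > 0)
  tokenSets <- lapply(docs, function(d) names(d@weights))
  all <- unlist(tokenSets, use.names = FALSE)
  df <- table(all)
  out <- list(N = length(docs),
              df = structure(as.integer(df), names = names(df)))
  class(out) <- "DocumentCorpus"
  out
}

#' @export
print.DocumentCorpus <- function(x, ...) {
  cat(sprintf("DocumentCorpus: %d documents, %d distinct tokens\n",
              x$N, length(x$df)))
  invisible(x)
}

## IDF for a token-frequency vector n given corpus size N.
.idf <- function(n, N) 0.5 * (1 + log2(N / n))

#' TF-IDF vector of a document within a corpus
#'
#' Token weight is \code{(w/W) * (1/2) * (1 + log2(N/n))}, where
#' \code{w} is the token's weight in the document, \code{W} the total
#' document weight, \code{N} the corpus document count, and \code{n}
#' the number of documents containing the token.
#'
#' @param doc A [VirtualDocument-class].
#' @param corpus A \code{DocumentCorpus} from [buildCorpus()].
#' @return Named numeric vector of TF-IDF weights (empty for an empty
#'   document).
#' @export
tfidfVector <- function(doc, corpus) {
  stopifnot(methods::is(doc, "VirtualDocument"),
            inherits(corpus, "DocumentCorpus"))
  w <- doc@weights
  if (length(w) == 0L) return(structure(numeric(0), names = character(0)))
  W <- sum(w)
  n <- corpus$df[names(w)]
  n[is.na(n)] <- 1L
  (w / W) * .idf(as.numeric(n), corpus$N)
}

#' Cosine similarity of two documents under TF-IDF weighting
#'
#' Returns 0 when either document is empty. Symmetric and invariant to
#' a positive rescaling of either document's weights.
#'
#' @param a,b [VirtualDocument-class] objects drawn from \code{corpus}.
#' @param corpus A \code{DocumentCorpus}.
#' @return Similarity in \[0, 1\].
#' @export
docSimilarity <- function(a, b, corpus) {
  va <- tfidfVector(a, corpus)
  vb <- tfidfVector(b, corpus)
  if (length(va) == 0L || length(vb) == 0L) return(0)
  shared <- intersect(names(va), names(vb))
  if (length(shared) == 0L) return(0)
  num <- sum(va[shared] * vb[shared])
  num / (sqrt(sum(va^2)) * sqrt(sum(vb^2)))
}

## Row-normalized TF-IDF matrix over a document list; rows are
## elements, columns the corpus vocabulary. Dense; the package targets
## desk-scale ontologies.
tfidfMatrix <- function(docs, corpus) {
  vocab <- names(corpus$df)
  m <- matrix(0, nrow = length(docs), ncol = length(vocab),
              dimnames = list(vapply(docs, function(d) d@element,
                                     character(1)), vocab))
  for (i in seq_along(docs)) {
    v <- tfidfVector(docs[[i]], corpus)
    if (length(v)) m[i, names(v)] <- v
  }
  nrm <- sqrt(rowSums(m^2))
  nz <- nrm > 0
  m[nz, ] <- m[nz, , drop = FALSE] / nrm[nz]
  m
}
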