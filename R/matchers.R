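## Matcher presets and similarity-matrix computation.

#' Matcher preset configurations (M1 to M13)
#'
#' Returns the [MatcherConfig-class] for one of the thirteen standard
#' matchers. M1 compares non-ID local names by normalized edit
#' similarity. M2/M3 are terminological (label; label + synonym). M4 to
#' M8 add structural context to the label + synonym document: property
#' attributes (M4), direct hierarchy neighbors (M5), both (M6), the
#' local semantic subgraph (M7), or the decayed global hierarchy (M8).
#' M9/M10 expand documents through a general or domain-specific lexicon.
#' M11 to M13 add an embedding-based similarity, combined with the
#' terminological matrix at equal weight; they differ only in which
#' embedding provider the caller supplies (general or domain model).
#'
#' @param id Preset name, \code{"M1"} .. \code{"M13"}.
#' @param threshold Extraction threshold stored in the config.
#' @param decay Global-hierarchy decay per level.
#' @return A [MatcherConfig-class].
#' @export
matcherPreset <- function(id, threshold = 0.8, decay = 0.5) {
  base <- list(useName = FALSE, termFields = c("label", "synonym"),
               structMode = "none", useExt = FALSE, useRps = FALSE)
  spec <- switch(id,
    M1 = list(useName = TRUE, termFields = character(0)),
    M2 = list(termFields = "label"),
    M3 = list(),
    M4 = list(structMode = "property"),
    M5 = list(structMode = "direct"),
    M6 = list(structMode = c("property", "direct")),
    M7 = list(structMode = "local"),
    M8 = list(structMode = "global"),
    M9 = list(useExt = TRUE),
    M10 = list(useExt = TRUE),
    M11 = list(useRps = TRUE),
    M12 = list(useRps = TRUE),
    M13 = list(useRps = TRUE),
    stop(sprintf("unknown matcher preset '%s'", id), call. = FALSE))
  cfg <- utils::modifyList(base, spec)
  dims <- c(
    if (cfg$useName) "name",
    if (!cfg$useName) "doc",
    if (cfg$useRps) "rps")
  mw <- structure(rep(1, length(dims)), names = dims)
  methods::new("MatcherConfig",
    matcherId = id,
    useName = cfg$useName,
    termFields = cfg$termFields,
    structMode = cfg$structMode,
    useExt = cfg$useExt,
    useRps = cfg$useRps,
    alpha = c(1, 1, 1, 1),
    matrixWeights = mw,
    threshold = threshold,
    decay = decay)
}

## Normalized name strings of an element for the name matcher: the
## local name with separators mapped to spaces, lowercased; empty when
## the local name is in ID form.
.nameStrings <- function(g, e) {
  ln <- g@localNames[[e]]
  if (is.null(ln) || isIdLike(ln)) return(character(0))
  tolower(gsub("[_-]+", " ", ln))
}

## Build the per-element documents of the matcher's document dimension.
.matcherDocs <- function(g, cfg, lex, idx) {
  ids <- g@concepts
  fields <- cfg@termFields
  if (cfg@useExt) {
    lapply(structure(ids, names = ids),
           function(e) buildExtDoc(g, e, lex, fields = fields))
  } else if (!identical(cfg@structMode, "none")) {
    lapply(structure(ids, names = ids), function(e) {
      bags <- lapply(cfg@structMode, function(m)
        buildStructDoc(g, e, mode = m, decay = cfg@decay,
                       fields = fields, idx = idx)@weights)
      virtualDocument(e, "struct", mergeBags(bags))
    })
  } else {
    lapply(structure(ids, names = ids),
           function(e) buildTermDoc(g, e, fields = fields))
  }
}

## Prepared matcher state: everything needed to score any source row
## against any subset of target columns. Shared by the exhaustive
## matcher and the reduction drivers so that both compute identical
## values for every pair they both visit.
matcherContext <- function(g1, g2, cfg, lex = NULL, emb = NULL) {
  stopifnot(methods::is(cfg, "MatcherConfig"))
  if (cfg@useExt && is.null(lex))
    stop(sprintf("matcher %s requires a lexicon", cfg@matcherId),
         call. = FALSE)
  if (cfg@useRps && is.null(emb))
    stop(sprintf("matcher %s requires an embedding provider",
                 cfg@matcherId), call. = FALSE)
  idx1 <- ontologyIndex(g1)
  idx2 <- ontologyIndex(g2)
  ctx <- list(g1 = g1, g2 = g2, cfg = cfg, idx1 = idx1, idx2 = idx2,
              ids1 = g1@concepts, ids2 = g2@concepts,
              weights = cfg@matrixWeights / sum(cfg@matrixWeights))
  if ("doc" %in% names(cfg@matrixWeights)) {
    docs1 <- .matcherDocs(g1, cfg, lex, idx1)
    docs2 <- .matcherDocs(g2, cfg, lex, idx2)
    corpus <- buildCorpus(c(docs1, docs2))
    ctx$docs1 <- docs1
    ctx$docs2 <- docs2
    ctx$corpus <- corpus
    ctx$X <- tfidfMatrix(docs1, corpus)
    # stored transposed: pair scores are per-column dot products, so a
    # row computed over any column subset is bitwise identical to the
    # same row computed exhaustively
    ctx$Yt <- t(tfidfMatrix(docs2, corpus))
  }
  if (cfg@useRps) {
    r1 <- vapply(ctx$ids1, function(e) buildRpsVector(g1, e, emb),
                 numeric(emb@dimension))
    r2 <- vapply(ctx$ids2, function(e) buildRpsVector(g2, e, emb),
                 numeric(emb@dimension))
    ctx$R1 <- t(matrix(r1, nrow = emb@dimension))
    ctx$R2t <- matrix(r2, nrow = emb@dimension)
  }
  if (cfg@useName) {
    ctx$names1 <- lapply(structure(ctx$ids1, names = ctx$ids1),
                         function(e) .nameStrings(g1, e))
    ctx$names2 <- lapply(structure(ctx$ids2, names = ctx$ids2),
                         function(e) .nameStrings(g2, e))
  }
  ctx
}

## Similarity of source row i against target columns jIdx. The single
## entry point for pair scoring: all matching drivers call this.
simRow <- function(ctx, i, jIdx) {
  if (length(jIdx) == 0L) return(numeric(0))
  w <- ctx$weights
  out <- numeric(length(jIdx))
  if ("doc" %in% names(w) && !is.null(ctx$X)) {
    d <- colSums(ctx$X[i, ] * ctx$Yt[, jIdx, drop = FALSE])
    out <- out + w[["doc"]] * d
  }
  if ("rps" %in% names(w) && !is.null(ctx$R1)) {
    r <- colSums(ctx$R1[i, ] * ctx$R2t[, jIdx, drop = FALSE])
    out <- out + w[["rps"]] * pmax(r, 0)
  }
  if ("name" %in% names(w) && !is.null(ctx$names1)) {
    s <- ctx$names1[[i]]
    nm <- vapply(jIdx, function(j)
      maxEditSimilarity(s, ctx$names2[[j]]), numeric(1))
    out <- out + w[["name"]] * nm
  }
  pmin(pmax(out, 0), 1)
}

#' Run a matcher over two ontologies
#'
#' Computes the similarity matrix of a matcher configuration, either
#' exhaustively or under one of the reduction-anchor drivers that skip
#' pairs predicted ignorable ([lomPE()], [lomNE()], [lomHybrid()]).
#' Pairs the driver computed carry the exact same similarity the
#' exhaustive matcher would assign; skipped pairs are marked in the
#' status matrix and read as similarity 0.
#'
#' @param g1,g2 [OntologyGraph-class] source and target ontologies.
#' @param cfg A [MatcherConfig-class], e.g. from [matcherPreset()].
#' @param lex Optional [Lexicon-class] (required by M9/M10).
#' @param emb Optional [EmbeddingProvider-class] (required by
#'   M11 to M13).
#' @param reduction One of \code{"none"}, \code{"pe"}, \code{"ne"},
#'   \code{"hybrid"}.
#' @param anchors An [AnchorState-class] carrying the reduction
#'   parameters (ignored for \code{reduction = "none"}).
#' @return For \code{reduction = "none"}, a [SimilarityMatrix-class];
#'   otherwise a list with components \code{matrix}, \code{anchors}
#'   (updated [AnchorState-class]), and \code{stats}
#'   ([ReductionStats-class]).
#' @export
runMatcher <- function(g1, g2, cfg, lex = NULL, emb = NULL,
                       reduction = c("none", "pe", "ne", "hybrid"),
                       anchors = anchorState()) {
  reduction <- match.arg(reduction)
  ctx <- matcherContext(g1, g2, cfg, lex, emb)
  switch(reduction,
    none = exhaustiveMatch(ctx),
    pe = lomDrive(ctx, anchors, positive = TRUE, negative = FALSE),
    ne = lomDrive(ctx, anchors, positive = FALSE, negative = TRUE),
    hybrid = lomDrive(ctx, anchors, positive = TRUE, negative = TRUE))
}

## Exhaustive matching: every pair computed, row by row.
exhaustiveMatch <- function(ctx) {
  n1 <- length(ctx$ids1); n2 <- length(ctx$ids2)
  values <- matrix(0, n1, n2)
  for (i in seq_len(n1)) values[i, ] <- simRow(ctx, i, seq_len(n2))
  similarityMatrix(ctx$ids1, ctx$ids2, values = values)
}
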