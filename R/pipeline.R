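## High-level matching pipeline: parse, build clues, run matchers
## (optionally under a reduction driver), combine, extract, evaluate.
## These functions are also the engine behind the ontomatch command-line
## script shipped in inst/scripts/.

#' Match two ontologies end to end
#'
#' Runs the selected matcher presets over the two ontologies, combines
#' their similarity matrices with the given weights, and extracts a
#' one-to-one alignment. With \code{reduction} other than
#' \code{"none"}, every matcher runs under the corresponding
#' reduction-anchor driver and the per-matcher skip statistics are
#' reported.
#'
#' @param source,target [OntologyGraph-class] objects or file paths
#'   (passed to [parseOntology()]).
#' @param matchers Character vector of preset ids (see
#'   [matcherPreset()]).
#' @param weights Optional numeric weights for combining the matcher
#'   matrices (default: equal).
#' @param threshold Extraction threshold.
#' @param reduction \code{"none"}, \code{"pe"}, \code{"ne"}, or
#'   \code{"hybrid"}.
#' @param anchors [AnchorState-class] carrying reduction parameters.
#' @param lexicon Optional [Lexicon-class] or lexicon TSV path.
#' @param embeddings Optional [EmbeddingProvider-class] or word2vec
#'   file path.
#' @param hierarchyPredicates Passed to [parseOntology()] when sources
#'   are paths.
#' @param reference Optional reference [Alignment-class] or path; when
#'   given, the result includes the evaluation against it.
#' @param out Optional output path for the alignment file.
#' @param format Alignment output format, \code{"tsv"} or
#'   \code{"oaei-rdf"}.
#' @param seed Integer seed (the pipeline is deterministic; the seed is
#'   set for reproducibility of any downstream consumer).
#' @return List with \code{alignment}, \code{matrix} (combined
#'   [SimilarityMatrix-class]), \code{stats} (per-matcher
#'   [ReductionStats-class] or NULL), \code{report} (list with counts
#'   and benefit rate), and \code{evaluation} (when a reference was
#'   given).
#' @export
matchOntologies <- function(source, target, matchers = "M5",
                            weights = NULL, threshold = 0.8,
                            reduction = c("none", "pe", "ne", "hybrid"),
                            anchors = anchorState(), lexicon = NULL,
                            embeddings = NULL,
                            hierarchyPredicates = character(0),
                            reference = NULL, out = NULL,
                            format = c("tsv", "oaei-rdf"), seed = 1L) {
  reduction <- match.arg(reduction)
  format <- match.arg(format)
  set.seed(seed)
  if (is.character(source))
    source <- parseOntology(source, hierarchyPredicates = hierarchyPredicates)
  if (is.character(target))
    target <- parseOntology(target, hierarchyPredicates = hierarchyPredicates)
  if (is.character(lexicon)) lexicon <- readLexicon(lexicon)
  if (is.character(embeddings)) embeddings <- readEmbeddings(embeddings)

  mats <- list()
  stats <- list()
  for (m in matchers) {
    cfg <- matcherPreset(m, threshold = threshold)
    res <- runMatcher(source, target, cfg, lex = lexicon, emb = embeddings,
                      reduction = reduction, anchors = anchors)
    if (reduction == "none") {
      mats[[m]] <- res
    } else {
      mats[[m]] <- res$matrix
      stats[[m]] <- res$stats
    }
  }
  combined <- if (length(mats) == 1L) mats[[1]] else
    combineMatrices(mats, weights)
  aln <- extractAlignment(combined, threshold)
  aln@ontology1 <- source@id
  aln@ontology2 <- target@id

  n1 <- length(source@concepts); n2 <- length(target@concepts)
  codes <- statusCodes()
  st <- pairStatus(combined)
  report <- list(
    matchers = matchers,
    reduction = reduction,
    n1 = n1, n2 = n2,
    computed = sum(st == codes[["computed"]]),
    skipped_positive = sum(st == codes[["skipped_positive"]]),
    skipped_negative = sum(st == codes[["skipped_negative"]]),
    correspondences = nrow(aln@pairs))
  report$benefit_rate <-
    (report$skipped_positive + report$skipped_negative) / (n1 * n2)

  evaluation <- NULL
  if (!is.null(reference)) {
    if (is.character(reference)) reference <- readAlignment(reference)
    evaluation <- evaluateAlignment(aln, reference)
    report$p <- evaluation$p
    report$r <- evaluation$r
    report$f1 <- evaluation$f1
  }
  if (!is.null(out)) {
    writeAlignment(aln, out, format = format)
    jsonlite::write_json(report, paste0(out, ".report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(alignment = aln, matrix = combined, stats = if (length(stats)) stats,
       report = report, evaluation = evaluation)
}

#' Evaluate an alignment file against a reference file
#'
#' Reads both files ([readAlignment()]), prints precision, recall, and
#' F1, and optionally writes them as JSON.
#'
#' @param alignmentPath,referencePath Paths to alignment files
#'   (OAEI RDF or TSV).
#' @param out Optional JSON output path.
#' @return The evaluation list from [evaluateAlignment()], invisibly.
#' @export
evaluateAlignmentFiles <- function(alignmentPath, referencePath,
                                   out = NULL) {
  M <- readAlignment(alignmentPath)
  R <- readAlignment(referencePath)
  ev <- evaluateAlignment(M, R)
  cat(sprintf("precision %.4f  recall %.4f  F1 %.4f  (tp %d, fp %d, fn %d)\n",
              ev$p, ev$r, ev$f1, ev$tp, ev$fp, ev$fn))
  if (!is.null(out))
    jsonlite::write_json(ev, out, auto_unbox = TRUE, digits = NA)
  invisible(ev)
}
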