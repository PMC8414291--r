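## Alignment extraction, evaluation, and OAEI alignment-format I/O.

#' Construct an Alignment
#'
#' @param pairs data.frame with columns \code{source}, \code{target},
#'   and optionally \code{relation} (default \code{"="}) and
#'   \code{confidence} (default 1).
#' @param ontology1,ontology2 Ontology identifiers.
#' @return An [Alignment-class].
#' @export
alignment <- function(pairs = NULL, ontology1 = "onto1",
                      ontology2 = "onto2") {
  if (is.null(pairs))
    pairs <- data.frame(source = character(0), target = character(0),
                        stringsAsFactors = FALSE)
  if (is.null(pairs$relation)) pairs$relation <- rep("=", nrow(pairs))
  if (is.null(pairs$confidence)) pairs$confidence <- rep(1, nrow(pairs))
  pairs <- pairs[, c("source", "target", "relation", "confidence")]
  rownames(pairs) <- NULL
  methods::new("Alignment", ontology1 = ontology1, ontology2 = ontology2,
               pairs = pairs)
}

#' @rdname Alignment-class
#' @export
setMethod("alignmentPairs", "Alignment", function(x) x@pairs)

setMethod("show", "Alignment", function(object) {
  cat(sprintf("Alignment %s -> %s: %d correspondences\n", object@ontology1,
              object@ontology2, nrow(object@pairs)))
  if (nrow(object@pairs))
    print(utils::head(object@pairs, 5))
})

#' Extract a one-to-one alignment from a similarity matrix
#'
#' Greedy selection in descending similarity among pairs at or above the
#' threshold, enforcing one-to-one: once a source or target is used, it
#' cannot appear again. Exact ties are broken lexicographically by
#' (source, target) identifier. \code{method = "optimal"} instead
#' maximizes the total similarity over all one-to-one assignments
#' (exhaustive search, only for small matrices); on matrices with unique
#' row/column maxima both methods agree.
#'
#' @param S A [SimilarityMatrix-class]; skipped pairs count as 0.
#' @param threshold Minimum similarity in \[0, 1\].
#' @param method \code{"greedy"} (default) or \code{"optimal"}.
#' @return An [Alignment-class] with confidences equal to the selected
#'   similarities.
#' @export
extractAlignment <- function(S, threshold, method = c("greedy", "optimal")) {
  stopifnot(methods::is(S, "SimilarityMatrix"))
  method <- match.arg(method)
  if (threshold < 0 || threshold > 1)
    stop("threshold must lie in [0, 1]", call. = FALSE)
  v <- similarityValues(S)
  src <- S@sourceIds; tgt <- S@targetIds
  hits <- which(v >= threshold & v > 0, arr.ind = TRUE)
  if (nrow(hits) == 0L)
    return(alignment(NULL, ontology1 = "onto1", ontology2 = "onto2"))
  if (method == "greedy") {
    s <- v[hits]
    ord <- order(-s, src[hits[, 1]], tgt[hits[, 2]])
    hits <- hits[ord, , drop = FALSE]
    usedR <- logical(length(src)); usedC <- logical(length(tgt))
    keep <- logical(nrow(hits))
    for (k in seq_len(nrow(hits))) {
      i <- hits[k, 1]; j <- hits[k, 2]
      if (!usedR[i] && !usedC[j]) {
        keep[k] <- TRUE; usedR[i] <- TRUE; usedC[j] <- TRUE
      }
    }
    hits <- hits[keep, , drop = FALSE]
  } else {
    hits <- .optimalAssignment(v, threshold)
  }
  pairs <- data.frame(source = src[hits[, 1]], target = tgt[hits[, 2]],
                      relation = "=", confidence = v[hits],
                      stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$source, pairs$target), ]
  alignment(pairs)
}

## Exhaustive maximum-weight one-to-one assignment over pairs at or
## above the threshold. Exponential; guarded to small matrices.
.optimalAssignment <- function(v, threshold) {
  n1 <- nrow(v); n2 <- ncol(v)
  if (min(n1, n2) > 8L)
    stop("optimal extraction is exhaustive and limited to matrices with min dimension <= 8",
         call. = FALSE)
  best <- list(score = -Inf, rows = integer(0), cols = integer(0))
  recurse <- function(ri, usedC, rows, cols, score) {
    if (ri > n1) {
      if (score > best$score)
        best <<- list(score = score, rows = rows, cols = cols)
      return(invisible())
    }
    # skip this source
    recurse(ri + 1L, usedC, rows, cols, score)
    for (j in seq_len(n2)) {
      if (!usedC[j] && v[ri, j] >= threshold && v[ri, j] > 0) {
        usedC[j] <- TRUE
        recurse(ri + 1L, usedC, c(rows, ri), c(cols, j), score + v[ri, j])
        usedC[j] <- FALSE
      }
    }
  }
  recurse(1L, logical(n2), integer(0), integer(0), 0)
  cbind(row = best$rows, col = best$cols)
}

#' Evaluate an alignment against a reference
#'
#' Precision p = |M ∩ R| / |M|, recall r = |M ∩ R| / |R|, and
#' F1 = 2pr / (p + r). Correspondence identity is the (source, target,
#' relation) triple; confidences are ignored. An empty alignment or
#' reference yields 0 for the corresponding measure (with a warning).
#'
#' @param M The system [Alignment-class].
#' @param R The reference [Alignment-class].
#' @return List with \code{p}, \code{r}, \code{f1}, \code{tp},
#'   \code{fp}, \code{fn}.
#' @export
evaluateAlignment <- function(M, R) {
  stopifnot(methods::is(M, "Alignment"), methods::is(R, "Alignment"))
  keyOf <- function(a) {
    p <- a@pairs
    unique(paste(p$source, p$target, p$relation, sep = "\r"))
  }
  mk <- keyOf(M); rk <- keyOf(R)
  tp <- length(intersect(mk, rk))
  if (length(mk) == 0L || length(rk) == 0L)
    warning("empty alignment or reference; measures default to 0",
            call. = FALSE)
  p <- if (length(mk)) tp / length(mk) else 0
  r <- if (length(rk)) tp / length(rk) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(p = p, r = r, f1 = f1, tp = tp, fp = length(mk) - tp,
       fn = length(rk) - tp)
}

.ALIGN_NS <- "http://knowledgeweb.semanticweb.org/heterogeneity/alignment"

#' Write an alignment to file
#'
#' Formats: OAEI Alignment RDF/XML (\code{Cell} elements with
#' \code{entity1}, \code{entity2}, \code{relation}, \code{measure}), or
#' TSV (\code{source<TAB>target<TAB>relation<TAB>confidence}).
#' Write followed by [readAlignment()] reproduces the correspondence
#' set.
#'
#' @param a An [Alignment-class].
#' @param path Output path.
#' @param format \code{"oaei-rdf"} or \code{"tsv"}.
#' @return The path, invisibly.
#' @export
writeAlignment <- function(a, path, format = c("oaei-rdf", "tsv")) {
  stopifnot(methods::is(a, "Alignment"))
  format <- match.arg(format)
  p <- a@pairs
  if (format == "tsv") {
    ln <- sprintf("%s\t%s\t%s\t%.*g", p$source, p$target, p$relation,
                  15, p$confidence)
    writeLines(ln, path)
    return(invisible(path))
  }
  esc <- function(s) {
    s <- gsub("&", "&amp;", s, fixed = TRUE)
    s <- gsub("<", "&lt;", s, fixed = TRUE)
    gsub(">", "&gt;", s, fixed = TRUE)
  }
  cells <- vapply(seq_len(nrow(p)), function(k) paste0(
    "    <map>\n      <Cell>\n",
    sprintf("        <entity1 rdf:resource=\"%s\"/>\n", esc(p$source[k])),
    sprintf("        <entity2 rdf:resource=\"%s\"/>\n", esc(p$target[k])),
    sprintf("        <relation>%s</relation>\n", esc(p$relation[k])),
    sprintf("        <measure rdf:datatype=\"http://www.w3.org/2001/XMLSchema#float\">%.*g</measure>\n",
            15, p$confidence[k]),
    "      </Cell>\n    </map>"), character(1))
  doc <- c(
    "<?xml version=\"1.0\" encoding=\"utf-8\"?>",
    sprintf("<rdf:RDF xmlns=\"%s\"", .ALIGN_NS),
    sprintf("         xmlns:rdf=\"%s\"", .NS[["rdf"]]),
    sprintf("         xmlns:xsd=\"%s\">", .NS[["xsd"]]),
    "  <Alignment>",
    "    <xml>yes</xml>",
    "    <level>0</level>",
    "    <type>11</type>",
    sprintf("    <onto1>%s</onto1>", esc(a@ontology1)),
    sprintf("    <onto2>%s</onto2>", esc(a@ontology2)),
    cells,
    "  </Alignment>",
    "</rdf:RDF>")
  writeLines(doc, path)
  invisible(path)
}

#' Read an alignment from file
#'
#' Accepts the OAEI Alignment RDF/XML format or the package's TSV
#' format (auto-detected from the first non-blank character). Rows with
#' confidences outside \[0, 1\] or a wrong column count are rejected
#' with the offending line number.
#'
#' @param path Input path.
#' @param format \code{"auto"}, \code{"oaei-rdf"}, or \code{"tsv"}.
#' @return An [Alignment-class].
#' @export
readAlignment <- function(path, format = c("auto", "oaei-rdf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop(sprintf("alignment file '%s' does not exist", path), call. = FALSE)
  if (format == "auto") {
    head1 <- trimws(paste(readLines(path, n = 5, warn = FALSE),
                          collapse = " "))
    format <- if (startsWith(head1, "<")) "oaei-rdf" else "tsv"
  }
  if (format == "tsv") {
    ln <- readLines(path, warn = FALSE)
    keep <- nzchar(trimws(ln))
    rows <- strsplit(ln[keep], "\t", fixed = TRUE)
    lineNo <- which(keep)
    bad <- which(vapply(rows, length, integer(1)) < 2L)
    if (length(bad))
      stop(sprintf("malformed alignment line %d in '%s'", lineNo[bad[1]],
                   path), call. = FALSE)
    src <- vapply(rows, `[[`, character(1), 1L)
    tgt <- vapply(rows, `[[`, character(1), 2L)
    rel <- vapply(rows, function(r) if (length(r) >= 3L) r[[3L]] else "=",
                  character(1))
    conf <- vapply(rows, function(r)
      if (length(r) >= 4L) suppressWarnings(as.numeric(r[[4L]])) else 1,
      numeric(1))
    bad <- which(is.na(conf) | conf < 0 | conf > 1)
    if (length(bad))
      stop(sprintf("invalid confidence on line %d of '%s'", lineNo[bad[1]],
                   path), call. = FALSE)
    pairs <- data.frame(source = src, target = tgt, relation = rel,
                        confidence = conf, stringsAsFactors = FALSE)
    pairs <- pairs[!duplicated(paste(pairs$source, pairs$target)), ]
    return(alignment(pairs))
  }
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop(sprintf("cannot parse alignment file '%s': %s", path,
                 conditionMessage(e)), call. = FALSE))
  ns <- c(al = .ALIGN_NS, rdf = .NS[["rdf"]])
  cells <- xml2::xml_find_all(doc, ".//al:Cell", ns)
  grab <- function(cell, what) {
    n <- xml2::xml_find_first(cell, sprintf("./al:%s", what), ns)
    res <- xml2::xml_attr(n, "resource")
    if (!is.na(res)) res else xml2::xml_text(n)
  }
  src <- vapply(cells, grab, character(1), "entity1")
  tgt <- vapply(cells, grab, character(1), "entity2")
  rel <- vapply(cells, grab, character(1), "relation")
  conf <- suppressWarnings(as.numeric(
    vapply(cells, grab, character(1), "measure")))
  conf[is.na(conf)] <- 1
  if (any(conf < 0 | conf > 1))
    stop(sprintf("invalid confidence in alignment file '%s'", path),
         call. = FALSE)
  onto1 <- xml2::xml_text(xml2::xml_find_first(doc, ".//al:onto1", ns))
  onto2 <- xml2::xml_text(xml2::xml_find_first(doc, ".//al:onto2", ns))
  pairs <- data.frame(source = src, target = tgt, relation = rel,
                      confidence = conf, stringsAsFactors = FALSE)
  pairs <- pairs[!duplicated(paste(pairs$source, pairs$target)), ]
  alignment(pairs,
            ontology1 = if (is.na(onto1)) "onto1" else onto1,
            ontology2 = if (is.na(onto2)) "onto2" else onto2)
}

#' Build a reference alignment from lexicon cross-references
#'
#' Every cross-reference whose endpoints are concepts of the two graphs
#' becomes a correspondence with confidence 1. Duplicates collapse;
#' many-to-many entries are kept (references are not forced one-to-one).
#' Entries with unknown identifiers are dropped with a warning giving
#' their count.
#'
#' @param lex A [Lexicon-class] with cross-references.
#' @param g1,g2 [OntologyGraph-class] objects.
#' @return An [Alignment-class].
#' @export
referenceFromCrossrefs <- function(lex, g1, g2) {
  stopifnot(methods::is(lex, "Lexicon"))
  xr <- lex@crossRefs
  if (nrow(xr) == 0L)
    return(alignment(NULL, ontology1 = g1@id, ontology2 = g2@id))
  known <- xr$source %in% g1@concepts & xr$target %in% g2@concepts
  if (any(!known))
    warning(sprintf("%d cross-reference(s) with unknown identifiers dropped",
                    sum(!known)), call. = FALSE)
  xr <- xr[known, , drop = FALSE]
  xr <- xr[!duplicated(paste(xr$source, xr$target)), , drop = FALSE]
  alignment(data.frame(source = xr$source, target = xr$target,
                       relation = "=", confidence = 1,
                       stringsAsFactors = FALSE),
            ontology1 = g1@id, ontology2 = g2@id)
}
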