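## Synonym lexicon handling (local stand-in for WordNet / UBERON / UMLS
## lookups) and cross-reference loading.

#' Construct a Lexicon
#'
#' Builds a [Lexicon-class] from a term-to-synonyms map and optional
#' cross-references. The synonym map is reverse-closed: whenever
#' \code{b} is a synonym of \code{a}, \code{a} is added as a synonym of
#' \code{b}, so lookups work in both directions.
#'
#' @param synonyms Named list, term to character vector of synonyms.
#'   Terms are matched case-insensitively.
#' @param crossRefs Optional data.frame with columns \code{source},
#'   \code{target} pairing element identifiers across two ontologies.
#' @return A [Lexicon-class].
#' @export
lexicon <- function(synonyms = list(), crossRefs = NULL) {
  syn <- lapply(synonyms, function(x) unique(tolower(x)))
  names(syn) <- tolower(names(syn))
  # reverse closure
  closed <- syn
  for (a in names(syn)) {
    for (b in syn[[a]]) {
      closed[[b]] <- unique(c(closed[[b]], a))
    }
  }
  closed <- lapply(closed, function(x) x[nzchar(x)])
  if (is.null(crossRefs))
    crossRefs <- data.frame(source = character(0), target = character(0),
                            stringsAsFactors = FALSE)
  stopifnot(all(c("source", "target") %in% names(crossRefs)))
  methods::new("Lexicon", synonyms = closed,
               crossRefs = crossRefs[, c("source", "target"), drop = FALSE])
}

#' Read a synonym lexicon (and optional cross-references) from TSV
#'
#' The lexicon format is one record per line:
#' \code{term<TAB>synonym1|synonym2|...}. The cross-reference format is
#' \code{source_id<TAB>target_id}. Blank lines and lines starting with
#' \code{#} are ignored.
#'
#' @param path Path to the synonym TSV (may be NULL for cross-refs only).
#' @param crossRefPath Optional path to a cross-reference TSV.
#' @return A [Lexicon-class] with the synonym map reverse-closed.
#' @export
readLexicon <- function(path = NULL, crossRefPath = NULL) {
  syn <- list()
  if (!is.null(path)) {
    if (!file.exists(path))
      stop(sprintf("lexicon file '%s' does not exist", path), call. = FALSE)
    ln <- readLines(path, warn = FALSE)
    ln <- ln[nzchar(trimws(ln)) & !startsWith(trimws(ln), "#")]
    for (i in seq_along(ln)) {
      parts <- strsplit(ln[i], "\t", fixed = TRUE)[[1]]
      if (length(parts) != 2L)
        stop(sprintf("malformed lexicon line %d in '%s'", i, path),
             call. = FALSE)
      syns <- strsplit(parts[2], "|", fixed = TRUE)[[1]]
      syn[[parts[1]]] <- unique(c(syn[[parts[1]]], syns[nzchar(syns)]))
    }
  }
  xr <- NULL
  if (!is.null(crossRefPath)) {
    if (!file.exists(crossRefPath))
      stop(sprintf("cross-reference file '%s' does not exist", crossRefPath),
           call. = FALSE)
    ln <- readLines(crossRefPath, warn = FALSE)
    ln <- ln[nzchar(trimws(ln)) & !startsWith(trimws(ln), "#")]
    parts <- strsplit(ln, "\t", fixed = TRUE)
    bad <- which(vapply(parts, length, integer(1)) != 2L)
    if (length(bad))
      stop(sprintf("malformed cross-reference line %d in '%s'", bad[1],
                   crossRefPath), call. = FALSE)
    xr <- data.frame(source = vapply(parts, `[[`, character(1), 1L),
                     target = vapply(parts, `[[`, character(1), 2L),
                     stringsAsFactors = FALSE)
  }
  lexicon(syn, xr)
}

#' Write a Lexicon's synonym map to TSV
#'
#' @param lex A [Lexicon-class].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeLexicon <- function(lex, path) {
  stopifnot(methods::is(lex, "Lexicon"))
  syn <- lex@synonyms
  ln <- vapply(names(syn), function(a)
    paste0(a, "\t", paste(syn[[a]], collapse = "|")), character(1))
  writeLines(ln, path)
  invisible(path)
}

## Look up synonyms for a phrase: full phrase first (case-insensitive),
## then per token. Returns a character vector of synonym phrases.
lexiconLookup <- function(lex, phrase) {
  syn <- lex@synonyms
  key <- tolower(phrase)
  hit <- syn[[key]]
  if (!is.null(hit)) return(hit)
  toks <- tokenizeTerms(phrase)
  unique(unlist(lapply(toks, function(t) syn[[t]]), use.names = FALSE))
}

setMethod("show", "Lexicon", function(object) {
  cat(sprintf("Lexicon: %d terms, %d cross-references\n",
              length(object@synonyms), nrow(object@crossRefs)))
})
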