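## Shared low-level helpers: tokenization, ID-form detection, string
## similarity, deterministic hashing.

# Closed-class English stop words dropped during tokenization. Fixed,
# 25 entries; tokenization must be stable across runs and machines.
.STOPWORDS <- c(
  "a", "an", "the", "of", "in", "on", "at", "to", "for", "by", "with",
  "and", "or", "as", "is", "are", "be", "from", "that", "this", "it",
  "its", "into", "per", "via"
)

#' Tokenize a label, name, or comment
#'
#' Splits on non-alphanumeric characters, underscores, and camelCase
#' boundaries, lowercases, and drops a fixed 25-word English stop-word
#' list. Token order is preserved.
#'
#' @param text Character vector of strings to tokenize.
#' @param stopwords Character vector of tokens to drop after
#'   lowercasing; defaults to the package's fixed closed-class list.
#' @return For a single input string, a character vector of tokens; for
#'   longer inputs, a list of such vectors.
#' @examples
#' tokenizeTerms("Bone_of_Lower_Extremity")
#' tokenizeTerms("hindlimb bone")
#' @export
tokenizeTerms <- function(text, stopwords = .STOPWORDS) {
  one <- function(s) {
    if (is.na(s) || !nzchar(s)) return(character(0))
    # break camelCase before splitting on separators
    s <- gsub("([a-z0-9])([A-Z])", "\\1 \\2", s)
    s <- gsub("([A-Z])([A-Z][a-z])", "\\1 \\2", s)
    toks <- strsplit(tolower(s), "[^a-z0-9]+")[[1]]
    toks <- toks[nzchar(toks)]
    toks[!(toks %in% stopwords)]
  }
  if (length(text) == 1L) one(text) else lapply(text, one)
}

#' Test whether a local name is in ID form
#'
#' Ontologies such as anatomy thesauri use opaque identifiers (e.g.
#' \code{MA_0000216}, \code{NCI_C12269}) as local names. These carry no
#' lexical signal and are excluded from name and terminological clues.
#' A name is ID-like when, after stripping separator characters, at
#' least half of the remaining characters are digits.
#'
#' @param localName Character vector of local names.
#' @return Logical vector.
#' @examples
#' isIdLike(c("MA_0000216", "NCI_C12269", "Foot_Bone"))
#' @export
isIdLike <- function(localName) {
  vapply(localName, function(s) {
    if (is.na(s) || !nzchar(s)) return(FALSE)
    stripped <- gsub("[^A-Za-z0-9]", "", s)
    if (!nzchar(stripped)) return(FALSE)
    ndigit <- nchar(gsub("[^0-9]", "", stripped))
    ndigit / nchar(stripped) >= 0.5
  }, logical(1), USE.NAMES = FALSE)
}

#' Normalized edit similarity between two strings
#'
#' Based on the Levenshtein edit distance DE and the edit similarity
#' SE = (|s| + |t| - DE) / 2. The normalized edit distance is
#' DNE = DE / (DE + SE); this function returns \code{1 - DNE}, so that
#' identical strings score 1 and maximally different strings approach 0.
#' Two empty strings score 1.
#'
#' @param s,t Character vectors, recycled to common length.
#' @return Numeric vector of similarities in \[0, 1\].
#' @examples
#' editSimilarity("kitten", "sitting")  # DE = 3, SE = 5 -> 1 - 3/8
#' @export
editSimilarity <- function(s, t) {
  n <- max(length(s), length(t))
  s <- rep_len(as.character(s), n)
  t <- rep_len(as.character(t), n)
  de <- vapply(seq_len(n), function(i) utils::adist(s[i], t[i])[1, 1],
               numeric(1))
  se <- (nchar(s) + nchar(t) - de) / 2
  denom <- de + se
  out <- ifelse(denom <= 0, 1, 1 - de / denom)
  pmin(pmax(out, 0), 1)
}

## Cross-pair maximum of editSimilarity over two sets of strings; used
## for label-set matchers and intra-ontology equivalence detection.
maxEditSimilarity <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) return(0)
  d <- utils::adist(a, b)
  se <- (outer(nchar(a), nchar(b), "+") - d) / 2
  denom <- d + se
  sim <- ifelse(denom <= 0, 1, 1 - d / denom)
  max(sim)
}

## Deterministic 31-bit polynomial rolling hash of a string. Stable
## across platforms/sessions (no dependence on R's RNG state).
stableHash <- function(s) {
  codes <- utf8ToInt(s)
  h <- 5381
  for (cc in codes) h <- (h * 33 + cc) %% 2147483647
  as.integer(h)
}

## Run code with a local, restored RNG seed.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

## Merge weighted bags (named numeric vectors); weights sum per name.
mergeBags <- function(bags) {
  bags <- bags[vapply(bags, length, integer(1)) > 0]
  if (length(bags) == 0L) return(structure(numeric(0), names = character(0)))
  all <- unlist(bags, use.names = TRUE)
  out <- tapply(all, names(all), sum)
  structure(as.numeric(out), names = names(out))
}

## Count a token vector into a bag.
countBag <- function(tokens) {
  if (length(tokens) == 0L) return(structure(numeric(0), names = character(0)))
  tab <- table(tokens)
  structure(as.numeric(tab), names = names(tab))
}
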