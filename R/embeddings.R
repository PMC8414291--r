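## Embedding providers for the representation-learning clue dimension.

#' Create an EmbeddingProvider from a vocabulary matrix or generator
#'
#' @param vectors Numeric matrix with one row per token (rownames are
#'   tokens).
#' @param generator Optional deterministic function(token) returning a
#'   vector; consulted for tokens absent from \code{vectors}.
#' @return An [EmbeddingProvider-class].
#' @export
embeddingProvider <- function(vectors = NULL, generator = NULL) {
  if (is.null(vectors)) {
    if (is.null(generator))
      stop("need vectors and/or generator", call. = FALSE)
    probe <- generator("dimension probe token")
    vectors <- matrix(numeric(0), nrow = 0, ncol = length(probe))
  }
  storage.mode(vectors) <- "double"
  methods::new("EmbeddingProvider",
               dimension = ncol(vectors),
               vectors = vectors,
               generator = generator)
}

#' Read word vectors in plain-text word2vec format
#'
#' Each line is \code{word v1 v2 ... vd}; an optional first header line
#' \code{count dim} is detected and skipped. Out-of-vocabulary lookups
#' against the resulting provider return the zero vector.
#'
#' @param path Path to the vector file.
#' @return An [EmbeddingProvider-class].
#' @export
readEmbeddings <- function(path) {
  if (!file.exists(path))
    stop(sprintf("embedding file '%s' does not exist", path), call. = FALSE)
  ln <- readLines(path, warn = FALSE)
  ln <- ln[nzchar(trimws(ln))]
  if (length(ln) == 0L) stop("empty embedding file", call. = FALSE)
  first <- strsplit(trimws(ln[1]), "[[:space:]]+")[[1]]
  if (length(first) == 2L && !anyNA(suppressWarnings(as.numeric(first))))
    ln <- ln[-1]  # "count dim" header
  parts <- strsplit(trimws(ln), "[[:space:]]+")
  words <- vapply(parts, `[[`, character(1), 1L)
  vecs <- lapply(parts, function(p) as.numeric(p[-1]))
  d <- unique(vapply(vecs, length, integer(1)))
  if (length(d) != 1L)
    stop("inconsistent vector dimensions in embedding file", call. = FALSE)
  m <- do.call(rbind, vecs)
  rownames(m) <- words
  embeddingProvider(m)
}

## Vector for one token; zero vector when out of vocabulary and no
## generator is available. Always deterministic.
providerVector <- function(provider, token) {
  v <- provider@vectors
  if (nrow(v) && token %in% rownames(v)) return(v[token, ])
  if (!is.null(provider@generator)) return(provider@generator(token))
  numeric(provider@dimension)
}

setMethod("show", "EmbeddingProvider", function(object) {
  src <- if (is.null(object@generator)) "fixed vocabulary" else "generator"
  cat(sprintf("EmbeddingProvider: dim %d, %d stored tokens (%s)\n",
              object@dimension, nrow(object@vectors), src))
})
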