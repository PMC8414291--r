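# Shared fixtures: tiny hand-written ontologies, memoized synthetic
# pairs, and independent oracles used across test files.

.fixtures <- new.env(parent = emptyenv())

# Memoize generated pairs so several test files can share them.
synthPair <- function(...) {
  key <- paste(deparse(list(...)), collapse = "")
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- generateOntologyPair(synthParams(...))
  .fixtures[[key]]
}

# Write a Turtle string to a temp file and parse it.
parseTtl <- function(text, ...) {
  f <- tempfile(fileext = ".ttl")
  writeLines(text, f)
  parseOntology(f, ...)
}

# A three-class chain a1 <- a2 <- a3 (a1 is the root) with one label
# each, as used by several hierarchy examples.
chain3 <- function(base = "http://ex.org/a#") {
  parseTtl(sprintf('
@prefix : <%s> .
@prefix owl: <http://www.w3.org/2002/07/owl#> .
@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .
:a1 a owl:Class ; rdfs:label "alpha organ" .
:a2 a owl:Class ; rdfs:label "beta tissue" ; rdfs:subClassOf :a1 .
:a3 a owl:Class ; rdfs:label "gamma membrane" ; rdfs:subClassOf :a2 .
', base))
}

# Independent dynamic-programming Levenshtein oracle (no adist).
levDP <- function(s, t) {
  a <- strsplit(s, "")[[1]]; b <- strsplit(t, "")[[1]]
  n <- length(a); m <- length(b)
  if (n == 0) return(m)
  if (m == 0) return(n)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- numeric(m + 1); cur[1] <- i
    for (j in seq_len(m)) {
      cost <- if (a[i] == b[j]) 0 else 1
      cur[j + 1] <- min(prev[j + 1] + 1, cur[j] + 1, prev[j] + cost)
    }
    prev <- cur
  }
  prev[m + 1]
}

# Edit similarity recomputed from the DP oracle.
editSimOracle <- function(s, t) {
  de <- levDP(s, t)
  se <- (nchar(s) + nchar(t) - de) / 2
  if (de + se <= 0) return(1)
  1 - de / (de + se)
}

# Brute-force maximum-weight one-to-one assignment over all subsets of
# row-column pairings (threshold applied), independent of the package.
bruteAssignment <- function(v, threshold) {
  n1 <- nrow(v); n2 <- ncol(v)
  best <- list(score = -Inf, pairs = NULL)
  recurse <- function(i, usedC, pairs, score) {
    if (i > n1) {
      if (score > best$score) best <<- list(score = score, pairs = pairs)
      return(invisible())
    }
    recurse(i + 1, usedC, pairs, score)
    for (j in seq_len(n2)) {
      if (!usedC[j] && v[i, j] >= threshold && v[i, j] > 0)
        recurse(i + 1, replace(usedC, j, TRUE),
                rbind(pairs, c(i, j)), score + v[i, j])
    }
  }
  recurse(1, logical(n2), NULL, 0)
  best$pairs
}

# Random string from a small alphabet (lengths 0..10).
randomString <- function() {
  k <- sample(0:10, 1)
  paste(sample(letters[1:6], k, replace = TRUE), collapse = "")
}
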