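## Synthetic ontology-pair generator with known ground truth.
##
## The generator emulates the characteristics that matter for matcher
## behavior on anatomical thesauri: tree/DAG taxonomies, multi-word
## labels composed of modifiers and a head noun (subtrees share heads,
## so structural neighbors are lexically related), internal synonyms,
## ID-form local names, and label/structure perturbations between the
## two sides of a pair. Everything is a pure function of the parameter
## seed.

.SYNTH_HEADS <- c(
  "bone", "muscle", "nerve", "artery", "vein", "gland", "joint",
  "membrane", "duct", "lobe", "cortex", "node", "vessel", "tissue",
  "organ", "tract", "plexus", "follicle", "ligament", "tendon")

.SYNTH_MODIFIERS <- c(
  "left", "right", "dorsal", "ventral", "anterior", "posterior",
  "medial", "lateral", "proximal", "distal", "superior", "inferior",
  "cranial", "caudal", "deep", "superficial", "upper", "lower",
  "inner", "outer", "primary", "secondary", "accessory", "marginal",
  "central", "peripheral", "basal", "apical", "transverse", "oblique",
  "costal", "alar", "palmar", "plantar", "orbital", "nasal", "oral",
  "cardiac", "hepatic", "renal", "pulmonary", "gastric", "dermal",
  "neural", "osseous", "mucous", "serous", "cortical", "medullary",
  "terminal")

#' Parameters for the synthetic ontology-pair generator
#'
#' @param nConcepts Number of source concepts (>= 1).
#' @param shape Taxonomy shape: \code{"chain"}, \code{"tree"}, or
#'   \code{"dag"} (tree plus occasional second parents).
#' @param branching Maximum children per node for tree/DAG shapes.
#' @param labelVocabSize Size of the modifier vocabulary labels are
#'   composed from.
#' @param synonymRate Probability that a concept carries an internal
#'   synonym.
#' @param labelPerturbRate Probability that a target concept's label is
#'   perturbed (synonym substitution, token reorder, or case change).
#' @param structurePerturbRate Probability of structural edits in the
#'   target (node deletion with child re-parenting; same-depth parent
#'   swaps).
#' @param idNameFraction Fraction of target concepts whose local name is
#'   replaced by an opaque ID.
#' @param seed Integer seed; generation is a pure function of it.
#' @return A list of validated parameters (class
#'   \code{"SynthParams"}).
#' @export
synthParams <- function(nConcepts = 200L, shape = c("tree", "chain", "dag"),
                        branching = 3L, labelVocabSize = 40L,
                        synonymRate = 0.6, labelPerturbRate = 0.25,
                        structurePerturbRate = 0.05,
                        idNameFraction = 0.5, seed = 1L) {
  shape <- match.arg(shape)
  rates <- c(synonymRate, labelPerturbRate, structurePerturbRate,
             idNameFraction)
  if (any(rates < 0 | rates > 1))
    stop("rates must lie in [0, 1]", call. = FALSE)
  if (nConcepts < 1L) stop("nConcepts must be >= 1", call. = FALSE)
  if (branching < 1L) stop("branching must be >= 1", call. = FALSE)
  if (labelVocabSize < 4L) stop("labelVocabSize must be >= 4", call. = FALSE)
  out <- list(nConcepts = as.integer(nConcepts), shape = shape,
              branching = as.integer(branching),
              labelVocabSize = as.integer(min(labelVocabSize,
                                              length(.SYNTH_MODIFIERS))),
              synonymRate = synonymRate,
              labelPerturbRate = labelPerturbRate,
              structurePerturbRate = structurePerturbRate,
              idNameFraction = idNameFraction, seed = as.integer(seed))
  class(out) <- "SynthParams"
  out
}

## Deterministic alias for a vocabulary token (the token's "latinized"
## lexicon synonym).
.aliasOf <- function(token) paste0(token, "iform")

## Build an OntologyGraph from generator node tables.
.assembleGraph <- function(id, uris, localNames, labels, synonyms, edges) {
  hierarchy <- if (nrow(edges)) {
    data.frame(child = edges$child, parent = edges$parent,
               predicate = "rdfs:subClassOf", stringsAsFactors = FALSE)
  } else {
    data.frame(child = character(0), parent = character(0),
               predicate = character(0), stringsAsFactors = FALSE)
  }
  tripleRows <- function(subject, predicate, object, objectType) {
    n <- length(subject)
    data.frame(subject = subject, predicate = rep_len(predicate, n),
               object = object, objectType = rep_len(objectType, n),
               stringsAsFactors = FALSE)
  }
  typeRows <- tripleRows(uris, expandCurie("rdf:type"),
                         rep_len(expandCurie("owl:Class"), length(uris)),
                         "uri")
  # flat label/synonym triples (one row per annotation)
  labRows <- tripleRows(
    rep(uris, vapply(labels, length, integer(1))),
    expandCurie("rdfs:label"),
    unlist(labels, use.names = FALSE) %||% character(0), "literal")
  synRows <- tripleRows(
    rep(uris, vapply(synonyms, length, integer(1))),
    expandCurie("oboInOwl:hasRelatedSynonym"),
    unlist(synonyms, use.names = FALSE) %||% character(0), "literal")
  subRows <- tripleRows(hierarchy$child, expandCurie("rdfs:subClassOf"),
                        hierarchy$parent, "uri")
  triples <- rbind(typeRows, labRows, synRows, subRows)
  names(labels) <- names(synonyms) <- uris
  methods::new("OntologyGraph",
    id = id,
    concepts = uris,
    properties = character(0),
    individuals = character(0),
    triples = triples,
    localNames = structure(localNames, names = uris),
    labels = labels[vapply(labels, length, integer(1)) > 0],
    synonyms = synonyms[vapply(synonyms, length, integer(1)) > 0],
    comments = list(),
    hierarchy = hierarchy,
    disjoint = data.frame(a = character(0), b = character(0),
                          stringsAsFactors = FALSE),
    equivalents = data.frame(a = character(0), b = character(0),
                             stringsAsFactors = FALSE),
    propertyInfo = data.frame(uri = character(0), domain = character(0),
                              range = character(0),
                              stringsAsFactors = FALSE))
}

#' Generate a synthetic ontology pair with ground truth
#'
#' Builds a source taxonomy over a compositional anatomical-flavored
#' vocabulary, then derives the target by perturbing labels (synonym
#' substitution from the emitted lexicon, token reorder, case change),
#' replacing a fraction of local names with opaque IDs, and editing the
#' structure (node deletion with child re-parenting, same-depth parent
#' swaps). The reference alignment maps every surviving concept to its
#' source original; the lexicon maps vocabulary tokens to their aliases.
#'
#' @param params A \code{SynthParams} list from [synthParams()].
#' @param dir Optional directory; when given, writes \code{source.ttl},
#'   \code{target.ttl}, \code{reference.tsv}, \code{lexicon.tsv}, and
#'   \code{params.json} there.
#' @return List with components \code{source}, \code{target}
#'   ([OntologyGraph-class]), \code{reference} ([Alignment-class]),
#'   \code{lexicon} ([Lexicon-class]), and \code{params}.
#' @export
generateOntologyPair <- function(params = synthParams(), dir = NULL) {
  stopifnot(inherits(params, "SynthParams"))
  withSeed(params$seed, {
    n <- params$nConcepts
    mods <- .SYNTH_MODIFIERS[seq_len(params$labelVocabSize)]
    heads <- .SYNTH_HEADS

    ## ---- source taxonomy ---------------------------------------------
    parent <- integer(n); parent[1] <- 0L    # 0 = root
    extraParent <- integer(n)                # dag second parents
    depth <- integer(n); depth[1] <- 0L
    childCount <- integer(n)
    if (n > 1) {
      for (i in 2:n) {
        if (params$shape == "chain") {
          p <- i - 1L
        } else {
          openSlots <- which(childCount[seq_len(i - 1L)] < params$branching)
          if (length(openSlots) == 0L) openSlots <- seq_len(i - 1L)
          p <- if (length(openSlots) == 1L) openSlots else
            sample(openSlots, 1L)
        }
        parent[i] <- p
        childCount[p] <- childCount[p] + 1L
        depth[i] <- depth[p] + 1L
        if (params$shape == "dag" && i > 2L && stats::runif(1) < 0.1) {
          q <- if (i == 2L) 1L else sample(seq_len(i - 1L), 1L)
          if (q != p) extraParent[i] <- q
        }
      }
    }

    ## ---- labels ------------------------------------------------------
    headOf <- character(n)
    headOf[1] <- heads[1]
    if (n > 1) {
      for (i in 2:n) {
        headOf[i] <- if (stats::runif(1) < 0.85) headOf[parent[i]] else
          heads[sample.int(length(heads), 1L)]
      }
    }
    usedLabels <- character(0)
    labelOf <- character(n)
    for (i in seq_len(n)) {
      k <- min(1L + depth[i] %/% 2L, 3L)
      repeat {
        lab <- paste(c(sample(mods, k), headOf[i]), collapse = " ")
        if (!(lab %in% usedLabels)) break
      }
      usedLabels <- c(usedLabels, lab)
      labelOf[i] <- lab
    }

    ## ---- lexicon over the used vocabulary ----------------------------
    vocabUsed <- unique(unlist(strsplit(labelOf, " ", fixed = TRUE)))
    hasAlias <- vocabUsed[stats::runif(length(vocabUsed)) < 0.6]
    syn <- lapply(structure(hasAlias, names = hasAlias), .aliasOf)

    ## ---- internal synonyms -------------------------------------------
    ## concepts carry 0-2 internal synonyms (anatomical thesauri list
    ## several name variants per concept)
    synSrc <- vector("list", n)
    for (i in seq_len(n)) {
      variants <- character(0)
      toks0 <- strsplit(labelOf[i], " ", fixed = TRUE)[[1]]
      nsyn <- sum(stats::runif(2) < c(params$synonymRate,
                                      params$synonymRate / 2))
      cand <- which(toks0 %in% hasAlias)
      for (s in seq_len(nsyn)) {
        toks <- toks0
        if (length(cand) >= s) {
          j <- cand[s]
          toks[j] <- .aliasOf(toks[j])
          variants <- c(variants, paste(toks, collapse = " "))
        } else {
          variants <- c(variants, paste(rev(toks), collapse = " "))
        }
      }
      synSrc[[i]] <- unique(variants)
    }

    toLocal <- function(lab) {
      toks <- strsplit(lab, " ", fixed = TRUE)[[1]]
      paste(paste0(toupper(substring(toks, 1, 1)), substring(toks, 2)),
            collapse = "_")
    }
    srcBase <- "http://ontomatch.example/src#"
    tgtBase <- "http://ontomatch.example/tgt#"
    srcLocal <- vapply(labelOf, toLocal, character(1), USE.NAMES = FALSE)
    srcUris <- paste0(srcBase, srcLocal)

    srcEdges <- data.frame(
      child = srcUris[which(parent > 0L)],
      parent = srcUris[parent[parent > 0L]],
      stringsAsFactors = FALSE)
    hasExtra <- which(extraParent > 0L)
    if (length(hasExtra))
      srcEdges <- rbind(srcEdges, data.frame(
        child = srcUris[hasExtra], parent = srcUris[extraParent[hasExtra]],
        stringsAsFactors = FALSE))

    source <- .assembleGraph("source", srcUris, srcLocal,
                             as.list(labelOf), synSrc, srcEdges)

    ## ---- target: structure perturbation ------------------------------
    tparent <- parent; textra <- extraParent
    deleted <- logical(n)
    if (n > 2 && params$structurePerturbRate > 0) {
      for (i in 2:n) {
        if (stats::runif(1) < params$structurePerturbRate) deleted[i] <- TRUE
      }
      # re-parent children of deleted nodes to the nearest surviving
      # ancestor
      surviveParent <- function(i) {
        p <- tparent[i]
        while (p > 0L && deleted[p]) p <- tparent[p]
        p
      }
      for (i in seq_len(n)) {
        if (!deleted[i]) {
          tparent[i] <- surviveParent(i)
          if (textra[i] > 0L && deleted[textra[i]]) textra[i] <- 0L
        }
      }
      # same-depth parent swaps among survivors (tree/chain only: with
      # extra DAG parents depth no longer bounds reachability, and the
      # swap could close a cycle)
      alive <- which(!deleted)
      if (params$shape == "dag") alive <- integer(0)
      for (d in unique(depth[alive])) {
        atd <- alive[depth[alive] == d & tparent[alive] > 0L]
        if (length(atd) >= 2L && stats::runif(1) < params$structurePerturbRate) {
          pick <- sample(atd, 2L)
          tmp <- tparent[pick[1]]
          tparent[pick[1]] <- tparent[pick[2]]
          tparent[pick[2]] <- tmp
        }
      }
    }
    keep <- which(!deleted)
    if (length(keep) == 0L) keep <- 1L

    ## ---- target: label perturbation ----------------------------------
    tLabel <- labelOf
    for (i in keep) {
      if (stats::runif(1) >= params$labelPerturbRate) next
      toks <- strsplit(tLabel[i], " ", fixed = TRUE)[[1]]
      op <- sample(c("synonym", "reorder", "case"), 1L,
                   prob = c(0.5, 0.3, 0.2))
      if (op == "synonym") {
        cand <- which(toks %in% hasAlias)
        if (length(cand)) {
          j <- cand[sample.int(length(cand), 1L)]
          toks[j] <- .aliasOf(toks[j])
        } else toks <- rev(toks)
        tLabel[i] <- paste(toks, collapse = " ")
      } else if (op == "reorder") {
        tLabel[i] <- paste(rev(toks), collapse = " ")
      } else {
        tLabel[i] <- toupper(tLabel[i])
      }
    }

    ## ---- target: local names / IDs -----------------------------------
    tLocal <- vapply(tLabel, toLocal, character(1), USE.NAMES = FALSE)
    for (i in keep) {
      if (stats::runif(1) < params$idNameFraction)
        tLocal[i] <- sprintf("TG_%07d", i)
    }
    # guarantee uniqueness of target local names
    dup <- duplicated(tLocal)
    tLocal[dup] <- paste0(tLocal[dup], "_", which(dup))
    tgtUris <- paste0(tgtBase, tLocal)

    tEdges <- do.call(rbind, lapply(keep, function(i) {
      out <- NULL
      if (tparent[i] > 0L && !deleted[tparent[i]])
        out <- rbind(out, c(tgtUris[i], tgtUris[tparent[i]]))
      if (textra[i] > 0L && !deleted[textra[i]])
        out <- rbind(out, c(tgtUris[i], tgtUris[textra[i]]))
      out
    }))
    tEdges <- if (is.null(tEdges)) {
      data.frame(child = character(0), parent = character(0),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(child = tEdges[, 1], parent = tEdges[, 2],
                 stringsAsFactors = FALSE)
    }

    target <- .assembleGraph("target", tgtUris[keep], tLocal[keep],
                             as.list(tLabel[keep]), synSrc[keep], tEdges)

    ## ---- reference + lexicon -----------------------------------------
    refPairs <- data.frame(source = srcUris[keep], target = tgtUris[keep],
                           relation = "=", confidence = 1,
                           stringsAsFactors = FALSE)
    reference <- alignment(refPairs, ontology1 = "source",
                           ontology2 = "target")
    lex <- lexicon(syn, crossRefs = refPairs[, c("source", "target")])

    out <- list(source = source, target = target, reference = reference,
                lexicon = lex, params = params)
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      writeOntologyTurtle(source, file.path(dir, "source.ttl"))
      writeOntologyTurtle(target, file.path(dir, "target.ttl"))
      writeAlignment(reference, file.path(dir, "reference.tsv"),
                     format = "tsv")
      writeLexicon(lex, file.path(dir, "lexicon.tsv"))
      jsonlite::write_json(unclass(params), file.path(dir, "params.json"),
                           auto_unbox = TRUE)
    }
    out
  })
}

#' Deterministic toy embedding provider
#'
#' Assigns every token a reproducible unit vector derived from a seeded
#' hash of the token. Tokens connected through the supplied lexicon's
#' synonym groups share most of their direction: each group member's
#' vector is 0.95 times the group head's vector plus an orthogonal
#' residual, so head-synonym cosine is 0.95 and synonym-synonym cosine
#' is about 0.90. Unrelated tokens are near-orthogonal at moderate
#' dimension.
#'
#' @param vocab Character vector of tokens to pre-compute (the provider
#'   also generates vectors for unseen tokens on demand).
#' @param dim Embedding dimensionality (>= 2).
#' @param seed Integer seed.
#' @param lex Optional [Lexicon-class] whose synonym groups get
#'   correlated vectors.
#' @return An [EmbeddingProvider-class].
#' @export
toyEmbeddingProvider <- function(vocab = character(0), dim = 64L,
                                 seed = 1L, lex = NULL) {
  if (dim < 2L) stop("dim must be >= 2", call. = FALSE)
  dim <- as.integer(dim)
  baseVec <- function(token) {
    withSeed(stableHash(paste0("emb", seed, "|", token)) %% 2147483646L, {
      v <- stats::rnorm(dim)
      v / sqrt(sum(v^2))
    })
  }
  headOf <- function(token) {
    if (is.null(lex)) return(token)
    grp <- c(token, lex@synonyms[[tolower(token)]])
    sort(tolower(grp))[1]
  }
  gen <- function(token) {
    token <- tolower(token)
    h <- headOf(token)
    if (identical(h, token)) return(baseVec(token))
    vh <- baseVec(h)
    u <- baseVec(paste0(token, "#res"))
    u <- u - sum(u * vh) * vh
    u <- u / sqrt(sum(u^2))
    v <- 0.95 * vh + sqrt(1 - 0.95^2) * u
    v / sqrt(sum(v^2))
  }
  vectors <- if (length(vocab)) {
    m <- t(vapply(tolower(vocab), gen, numeric(dim)))
    rownames(m) <- tolower(vocab)
    m
  } else matrix(numeric(0), nrow = 0, ncol = dim)
  embeddingProvider(vectors = vectors, generator = gen)
}
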