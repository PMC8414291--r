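## Extended reduction anchors (P-AnchorE / N-AnchorE) and the LOM-PE,
## LOM-NE, LOM-Hybrid matching drivers.
##
## A P-Anchor is a computed pair with similarity strictly above ptValue;
## by hierarchy coherence it licenses skipping the cross-comparisons
## sub(a) x sup(b) and sup(a) x sub(b). An N-Anchor is a computed pair
## strictly below ntValue; by matching locality it licenses skipping the
## comparisons of a's neighbors (ball of radius nScale) against the same
## target. Both anchor kinds are extended through intra-ontology
## equivalent concepts. Anchors are only ever created from freshly
## computed similarities, never from skipped or extended entries
## (structural enforcement of the first propagation constraint).

#' Create an AnchorState with the reduction parameters
#'
#' Defaults follow the recommended operating point: ptValue 0.8,
#' ntValue 0.15, nScale 3, top-k 2, t-items 4, eqValue 0.95, with the
#' semantic-subgraph (SSG) and description-document (SDD) propagation
#' constraints enabled.
#'
#' @param ptValue,ntValue Positive / negative anchor thresholds.
#' @param topK P-AnchorsE retained per concept (1 to 4).
#' @param nScale Negative-propagation ball radius.
#' @param tItems SDD constraint: minimum distinct document tokens
#'   (strictly more than \code{tItems}) for negative propagation.
#' @param eqValue Intra-ontology name-similarity threshold for the
#'   equivalent-concept extension; values above 1 disable it.
#' @param ssg,sdd Enable the SSG / SDD constraints.
#' @return An [AnchorState-class].
#' @export
anchorState <- function(ptValue = 0.8, ntValue = 0.15, topK = 2L,
                        nScale = 3L, tItems = 4L, eqValue = 0.95,
                        ssg = TRUE, sdd = TRUE) {
  methods::new("AnchorState", ptValue = ptValue, ntValue = ntValue,
               topK = as.integer(topK), nScale = as.integer(nScale),
               tItems = as.integer(tItems), eqValue = eqValue,
               ssg = ssg, sdd = sdd,
               pa = list(), pae = list(), na = list(), nae = list())
}

setMethod("show", "AnchorState", function(object) {
  cat(sprintf(
    "AnchorState: ptValue %.2f, ntValue %.2f, top-k %d, nScale %d, t-items %d\n",
    object@ptValue, object@ntValue, object@topK, object@nScale,
    object@tItems))
  cat(sprintf("  constraints: ssg %s, sdd %s; eqValue %.2f\n",
              object@ssg, object@sdd, object@eqValue))
  cat(sprintf("  %d concepts with P-Anchors, %d with N-Anchors\n",
              length(object@pa), length(object@na)))
})

#' Select P-Anchors from one computed similarity row
#'
#' PA(a) = \{b_j : S_aj > ptValue\}, retaining the top-k entries by
#' similarity; ties are broken by target order.
#'
#' @param sims Named numeric vector of computed similarities (names are
#'   target identifiers in target order).
#' @param ptValue Anchor threshold (strict inequality).
#' @param topK Maximum number of anchors retained.
#' @return Character vector of anchor target identifiers, ordered by
#'   decreasing similarity.
#' @export
findPAnchors <- function(sims, ptValue, topK = 2L) {
  hit <- which(sims > ptValue)
  if (length(hit) == 0L) return(character(0))
  ord <- hit[order(-sims[hit], hit)]
  names(sims)[utils::head(ord, topK)]
}

## Intra-ontology equivalent-concept sets: explicit equivalence axioms
## plus pairs whose name similarity reaches eqValue. Vectorized over the
## pooled label/name strings of all concepts.
equivalenceSets <- function(g, eqValue) {
  ids <- g@concepts
  eq <- structure(vector("list", length(ids)), names = ids)
  if (nrow(g@equivalents)) {
    for (k in seq_len(nrow(g@equivalents))) {
      a <- g@equivalents$a[k]; b <- g@equivalents$b[k]
      if (a %in% ids && b %in% ids && a != b) {
        eq[[a]] <- c(eq[[a]], b)
        eq[[b]] <- c(eq[[b]], a)
      }
    }
  }
  if (eqValue <= 1) {
    strs <- lapply(structure(ids, names = ids), function(e) {
      out <- g@labels[[e]] %||% character(0)
      ln <- g@localNames[[e]]
      if (!is.null(ln) && !isIdLike(ln))
        out <- c(out, gsub("[_-]+", " ", ln))
      unique(tolower(out))
    })
    owner <- rep(seq_along(ids), vapply(strs, length, integer(1)))
    pool <- unlist(strs, use.names = FALSE)
    if (length(pool) > 1L) {
      d <- utils::adist(pool, pool)
      se <- (outer(nchar(pool), nchar(pool), "+") - d) / 2
      denom <- d + se
      sim <- ifelse(denom <= 0, 1, 1 - d / denom)
      hits <- which(sim >= eqValue, arr.ind = TRUE)
      hits <- hits[owner[hits[, 1]] != owner[hits[, 2]], , drop = FALSE]
      if (nrow(hits)) {
        for (k in seq_len(nrow(hits))) {
          a <- ids[owner[hits[k, 1]]]; b <- ids[owner[hits[k, 2]]]
          eq[[a]] <- c(eq[[a]], b)
        }
      }
    }
  }
  lapply(eq, unique)
}

#' Extend per-concept anchors through equivalent concepts
#'
#' PAE(a) = PA(a) joined with the anchors of every concept of the same
#' ontology equivalent to a (explicit equivalence axiom, or name
#' similarity at least \code{eqValue}). The same rule yields NAE from
#' N-Anchors.
#'
#' @param g The [OntologyGraph-class] the anchor owners belong to.
#' @param anchors Named list, concept to character vector of anchor
#'   targets.
#' @param eqValue Equivalence threshold; values above 1 disable the
#'   extension.
#' @param eq Optional precomputed equivalence sets (internal use).
#' @return Named list of extended anchor sets.
#' @export
extendAnchors <- function(g, anchors, eqValue = 0.95, eq = NULL) {
  if (is.null(eq)) eq <- equivalenceSets(g, eqValue)
  out <- anchors
  for (a in names(anchors)) {
    ext <- unlist(anchors[eq[[a]]], use.names = FALSE)
    out[[a]] <- unique(c(anchors[[a]], ext))
  }
  # concepts that only receive anchors through equivalents
  for (a in names(eq)) {
    if (!is.null(out[[a]])) next
    ext <- unlist(anchors[eq[[a]]], use.names = FALSE)
    if (length(ext)) out[[a]] <- unique(ext)
  }
  out
}

#' Positive reduction set of one P-AnchorE
#'
#' For an anchor (a, b), hierarchy coherence predicts that descendants
#' of a cannot match ancestors of b and vice versa:
#' PS(a|b) = sub(a) x sup(b) union sup(a) x sub(b), with transitive
#' sub/sup closures.
#'
#' @param g1,g2 Source and target [OntologyGraph-class] objects.
#' @param a,b Anchor endpoints (concepts of g1 and g2).
#' @return Two-column character matrix of (source, target) pairs.
#' @export
positiveReductionSet <- function(g1, g2, a, b) {
  if (!(a %in% g1@concepts)) stop(sprintf("unknown concept '%s'", a),
                                  call. = FALSE)
  if (!(b %in% g2@concepts)) stop(sprintf("unknown concept '%s'", b),
                                  call. = FALSE)
  idx1 <- ontologyIndex(g1); idx2 <- ontologyIndex(g2)
  subA <- closureOf(idx1, a, "in"); supA <- closureOf(idx1, a, "out")
  subB <- closureOf(idx2, b, "in"); supB <- closureOf(idx2, b, "out")
  out <- rbind(
    if (length(subA) && length(supB))
      cbind(rep(subA, each = length(supB)), rep(supB, length(subA)))
    else NULL,
    if (length(supA) && length(subB))
      cbind(rep(supA, each = length(subB)), rep(subB, length(supA)))
    else NULL)
  if (is.null(out)) matrix(character(0), ncol = 2) else out
}

#' Negative reduction set of one N-AnchorE
#'
#' For an anchor (a, b) with a low computed similarity, matching
#' locality predicts that a's neighbors do not match b either:
#' NS(a|b) = (Nb(a) minus a) x \{b\}, where Nb is the ball of radius
#' \code{nScale}. With \code{ssg}, propagation is restricted to a's
#' semantic subgraph; with \code{sdd}, it is blocked entirely unless a's
#' description document has more than \code{tItems} distinct tokens.
#'
#' @param g1 Source [OntologyGraph-class].
#' @param a,b Anchor endpoints.
#' @param nScale Ball radius.
#' @param ssg,sdd Constraint switches.
#' @param doc a's description document (a [VirtualDocument-class]);
#'   required when \code{sdd} is TRUE.
#' @param tItems SDD threshold.
#' @param ssgRadius Radius of the semantic subgraph for the SSG
#'   constraint.
#' @return Two-column character matrix of (source, target) pairs.
#' @export
negativeReductionSet <- function(g1, a, b, nScale = 3L, ssg = FALSE,
                                 sdd = FALSE, doc = NULL, tItems = 4L,
                                 ssgRadius = 2L) {
  if (!(a %in% g1@concepts)) stop(sprintf("unknown concept '%s'", a),
                                  call. = FALSE)
  if (sdd) {
    if (is.null(doc)) stop("sdd constraint requires the description document",
                           call. = FALSE)
    if (itemCount(doc) <= tItems)
      return(matrix(character(0), ncol = 2))
  }
  idx <- ontologyIndex(g1)
  nb <- setdiff(ballOf(idx, a, as.integer(nScale)), a)
  if (ssg) {
    ssgSet <- unique(c(ballOf(idx, a, as.integer(ssgRadius)),
                       siblingsOf(idx, a)))
    nb <- intersect(nb, ssgSet)
  }
  if (length(nb) == 0L) return(matrix(character(0), ncol = 2))
  cbind(nb, rep(b, length(nb)))
}

#' @rdname benefitRate
#' @export
setMethod("benefitRate", "ReductionStats", function(x) {
  if (x@n1 <= 0 || x@n2 <= 0)
    stop("benefit rate is undefined for zero-sized ontologies",
         call. = FALSE)
  (x@skippedPositive + x@skippedNegative) / (x@n1 * x@n2)
})

setMethod("show", "ReductionStats", function(object) {
  cat(sprintf("ReductionStats: %d x %d pairs\n", object@n1, object@n2))
  cat(sprintf("  computed %d, skipped %d (positive %d, negative %d)\n",
              object@computed,
              object@skippedPositive + object@skippedNegative,
              object@skippedPositive, object@skippedNegative))
  cat(sprintf("  benefit rate G = %.4f\n", benefitRate(object)))
})

## ---- shared driver machinery ----------------------------------------

## Environment holding the mutable run state of one reduction drive.
.driveState <- function(ctx, state) {
  n1 <- length(ctx$ids1); n2 <- length(ctx$ids2)
  env <- new.env(parent = emptyenv())
  env$values <- matrix(0, n1, n2, dimnames = list(ctx$ids1, ctx$ids2))
  env$status <- matrix(0L, n1, n2, dimnames = list(ctx$ids1, ctx$ids2))
  env$pa <- structure(vector("list", n1), names = ctx$ids1)
  env$na <- structure(vector("list", n1), names = ctx$ids1)
  env$paSims <- structure(vector("list", n1), names = ctx$ids1)
  env
}

## Integer index closures (memoized through ontologyIndex caches).
.closureIdx <- function(ctx, which, i, mode) {
  idx <- if (which == 1L) ctx$idx1 else ctx$idx2
  ids <- if (which == 1L) ctx$ids1 else ctx$ids2
  match(closureOf(idx, ids[i], mode), ids)
}

## Apply the positive reduction sets of source row i given its extended
## anchor list (target indices with their anchoring similarities).
## Marks uncomputed pairs as skipped_positive. PSE over the top-k
## anchors is the intersection of the per-anchor sets.
.applyPositiveSkips <- function(ctx, env, i, anchorIdx, anchorSims, topK) {
  ord <- order(-anchorSims, anchorIdx)
  keep <- utils::head(anchorIdx[ord], topK)
  if (length(keep) == 0L) return(invisible())
  n2 <- length(ctx$ids2)
  subA <- .closureIdx(ctx, 1L, i, "in")
  supA <- .closureIdx(ctx, 1L, i, "out")
  if (length(subA) == 0L && length(supA) == 0L) return(invisible())
  maskAll <- NULL
  rows <- c(subA, supA)
  for (b in keep) {
    supB <- .closureIdx(ctx, 2L, b, "out")
    subB <- .closureIdx(ctx, 2L, b, "in")
    mask <- matrix(FALSE, length(rows), n2)
    if (length(subA) && length(supB))
      mask[seq_along(subA), supB] <- TRUE
    if (length(supA) && length(subB))
      mask[length(subA) + seq_along(supA), subB] <- TRUE
    maskAll <- if (is.null(maskAll)) mask else maskAll & mask
  }
  if (!any(maskAll)) return(invisible())
  sel <- which(maskAll, arr.ind = TRUE)
  rIdx <- rows[sel[, 1]]
  flat <- cbind(rIdx, sel[, 2])
  open <- env$status[flat] == 0L
  if (any(open)) env$status[flat[open, , drop = FALSE]] <- 2L
  invisible()
}

## Apply the negative reduction sets of source row i for the anchor
## targets in bIdx (already constraint-1-clean: freshly computed).
.applyNegativeSkips <- function(ctx, env, i, bIdx, state, eq1, nbCache) {
  if (length(bIdx) == 0L) return(invisible())
  if (state@sdd && !is.null(ctx$docs1)) {
    if (itemCount(ctx$docs1[[i]]) <= state@tItems) return(invisible())
  }
  nb <- nbCache[[i]]
  if (length(nb) == 0L) return(invisible())
  open <- env$status[nb, bIdx, drop = FALSE] == 0L
  if (any(open)) {
    sel <- which(open, arr.ind = TRUE)
    flat <- cbind(nb[sel[, 1]], bIdx[sel[, 2]])
    env$status[flat] <- 3L
  }
  invisible()
}

## Neighbor index sets for negative propagation: ball of radius nScale
## minus the concept, intersected with the semantic subgraph under SSG,
## then extended with the neighbors' near-equivalents.
.negNeighborCache <- function(ctx, state, eq1) {
  ids <- ctx$ids1
  lapply(seq_along(ids), function(i) {
    e <- ids[i]
    nb <- setdiff(ballOf(ctx$idx1, e, state@nScale), e)
    if (state@ssg) {
      ssgSet <- unique(c(ballOf(ctx$idx1, e, 2L), siblingsOf(ctx$idx1, e)))
      nb <- intersect(nb, ssgSet)
    }
    nbe <- unique(c(nb, unlist(eq1[nb], use.names = FALSE)))
    nbe <- setdiff(nbe, e)
    match(nbe, ids)
  })
}

## Compute one source row over the open (status 0) columns in jIdx,
## recording values and computed status. Returns the computed column
## indices.
.computeRow <- function(ctx, env, i, jIdx) {
  jIdx <- jIdx[env$status[i, jIdx] == 0L]
  if (length(jIdx) == 0L) return(integer(0))
  env$values[i, jIdx] <- simRow(ctx, i, jIdx)
  env$status[i, jIdx] <- 1L
  jIdx
}

## Record P-anchors of row i among freshly computed columns, extend
## through equivalents, and apply positive skips.
.positiveStep <- function(ctx, env, i, computedIdx, state, eq1) {
  if (length(computedIdx) == 0L) return(invisible())
  sims <- env$values[i, computedIdx]
  hit <- computedIdx[sims > state@ptValue]
  a <- ctx$ids1[i]
  if (length(hit)) {
    env$pa[[a]] <- unique(c(env$pa[[a]], ctx$ids2[hit]))
    env$paSims[[a]] <- env$values[i, match(env$pa[[a]], ctx$ids2)]
  }
  # extended anchors: own plus those of equivalent concepts
  extTargets <- env$pa[[a]]
  extSims <- env$paSims[[a]]
  for (a2 in eq1[[a]]) {
    if (!is.null(env$pa[[a2]])) {
      extTargets <- c(extTargets, env$pa[[a2]])
      extSims <- c(extSims, env$paSims[[a2]])
    }
  }
  if (length(extTargets)) {
    dup <- !duplicated(extTargets)
    .applyPositiveSkips(ctx, env, i, match(extTargets[dup], ctx$ids2),
                        extSims[dup], state@topK)
  }
  invisible()
}

## Record N-anchors of row i among freshly computed columns and apply
## negative skips (with the equivalence-extended anchor set).
.negativeStep <- function(ctx, env, i, computedIdx, state, eq1, nbCache) {
  if (length(computedIdx) == 0L) return(invisible())
  sims <- env$values[i, computedIdx]
  hit <- computedIdx[sims < state@ntValue]
  a <- ctx$ids1[i]
  if (length(hit))
    env$na[[a]] <- unique(c(env$na[[a]], ctx$ids2[hit]))
  # NAE: add the N-anchors of equivalent concepts (all were computed)
  ext <- ctx$ids2[hit]
  for (a2 in eq1[[a]]) ext <- c(ext, env$na[[a2]])
  ext <- unique(ext)
  if (length(ext))
    .applyNegativeSkips(ctx, env, i, match(ext, ctx$ids2), state, eq1,
                        nbCache)
  invisible()
}

.finishDrive <- function(ctx, env, state, eq1) {
  n1 <- length(ctx$ids1); n2 <- length(ctx$ids2)
  st <- env$status
  stats <- methods::new("ReductionStats",
    computed = sum(st == 1L),
    skippedPositive = sum(st == 2L),
    skippedNegative = sum(st == 3L),
    n1 = n1, n2 = n2)
  pa <- env$pa[!vapply(env$pa, is.null, logical(1))]
  na <- env$na[!vapply(env$na, is.null, logical(1))]
  outState <- state
  outState@pa <- pa
  outState@na <- na
  outState@pae <- extendAnchors(ctx$g1, pa, state@eqValue, eq = eq1)
  outState@nae <- extendAnchors(ctx$g1, na, state@eqValue, eq = eq1)
  mat <- similarityMatrix(ctx$ids1, ctx$ids2, values = env$values,
                          status = env$status)
  list(matrix = mat, anchors = outState, stats = stats)
}

## Core driver. positive/negative toggle which anchor kinds are used.
## With negative (LOM-NE and LOM-Hybrid) the iteration order is by
## descending degree (ties by identifier), each row computed over its
## still-open columns. Positive-only (LOM-PE) walks the hierarchy in
## preorder, probing promising targets (children of the parent's anchor
## targets) before falling back to the full row, and finishes with a
## sweep over every pair still neither computed nor skipped.
lomDrive <- function(ctx, state, positive = TRUE, negative = TRUE) {
  env <- .driveState(ctx, state)
  eq1 <- equivalenceSets(ctx$g1, state@eqValue)
  nbCache <- if (negative) .negNeighborCache(ctx, state, eq1) else NULL
  n1 <- length(ctx$ids1); n2 <- length(ctx$ids2)

  if (negative) {
    deg <- vapply(seq_len(n1), function(i) {
      e <- ctx$ids1[i]
      length(ctx$idx1$parents[[e]]) + length(ctx$idx1$children[[e]])
    }, numeric(1))
    order1 <- order(-deg, ctx$ids1)
    for (i in order1) {
      computed <- .computeRow(ctx, env, i, seq_len(n2))
      if (positive) .positiveStep(ctx, env, i, computed, state, eq1)
      .negativeStep(ctx, env, i, computed, state, eq1, nbCache)
    }
  } else {
    # preorder over the source hierarchy, roots in identifier order
    order1 <- .preorder(ctx)
    rootTargets <- which(vapply(seq_len(n2), function(j)
      length(ctx$idx2$parents[[ctx$ids2[j]]]) == 0L, logical(1)))
    for (i in order1) {
      promising <- .promisingTargets(ctx, env, i, rootTargets)
      anchorsFound <- FALSE
      if (length(promising)) {
        computed <- .computeRow(ctx, env, i, promising)
        if (length(computed)) {
          anchorsFound <- any(env$values[i, computed] > state@ptValue)
          .positiveStep(ctx, env, i, computed, state, eq1)
        }
      }
      if (!anchorsFound) {
        computed <- .computeRow(ctx, env, i, seq_len(n2))
        .positiveStep(ctx, env, i, computed, state, eq1)
      }
    }
    # final sweep: everything still open gets computed (and can still
    # anchor skips for later rows)
    for (i in order1) {
      open <- which(env$status[i, ] == 0L)
      if (length(open)) {
        computed <- .computeRow(ctx, env, i, open)
        .positiveStep(ctx, env, i, computed, state, eq1)
      }
    }
  }
  .finishDrive(ctx, env, state, eq1)
}

## Preorder DFS over the source hierarchy; roots and children visited in
## identifier order. Concepts in no hierarchy come last.
.preorder <- function(ctx) {
  ids <- ctx$ids1
  kids <- ctx$idx1$children
  pars <- ctx$idx1$parents
  roots <- ids[vapply(ids, function(e) length(pars[[e]]) == 0L, logical(1))]
  seen <- structure(logical(length(ids)), names = ids)
  out <- integer(0)
  visit <- function(e) {
    stack <- e
    while (length(stack)) {
      cur <- stack[1]; stack <- stack[-1]
      if (seen[[cur]]) next
      seen[[cur]] <<- TRUE
      out[[length(out) + 1L]] <<- match(cur, ids)
      ch <- sort(kids[[cur]])
      stack <- c(ch, stack)
    }
  }
  for (r in sort(roots)) visit(r)
  for (e in ids) if (!seen[[e]]) out[[length(out) + 1L]] <- match(e, ids)
  out
}

## Promising targets for PE probing: the anchor targets of the concept's
## parents and their children (where a parent matched, its children are
## where the child's match is expected); for roots, the target roots.
.promisingTargets <- function(ctx, env, i, rootTargets) {
  e <- ctx$ids1[i]
  pars <- ctx$idx1$parents[[e]]
  if (length(pars) == 0L) return(rootTargets)
  anchorTargets <- unique(unlist(env$pa[pars], use.names = FALSE))
  if (length(anchorTargets) == 0L) return(integer(0))
  cand <- unique(c(anchorTargets,
                   unlist(ctx$idx2$children[anchorTargets],
                          use.names = FALSE)))
  match(cand, ctx$ids2)
}

#' Large-ontology matching with positive reduction anchors (LOM-PE)
#'
#' Walks the source hierarchy in preorder, probing each concept first
#' against the targets suggested by its parents' anchors, and uses every
#' discovered P-AnchorE to skip the hierarchy-incoherent
#' cross-comparisons in its positive reduction set. Pairs neither
#' computed nor skipped by the end of the walk are computed in a final
#' sweep, so every pair is either computed (with the exhaustive value)
#' or skipped.
#'
#' @param g1,g2 [OntologyGraph-class] objects.
#' @param cfg A [MatcherConfig-class].
#' @param state An [AnchorState-class] with the reduction parameters.
#' @param lex,emb Optional clue resources, as in [runMatcher()].
#' @return List with \code{matrix} ([SimilarityMatrix-class]),
#'   \code{anchors} (updated [AnchorState-class]), and \code{stats}
#'   ([ReductionStats-class]).
#' @export
lomPE <- function(g1, g2, cfg, state = anchorState(), lex = NULL,
                  emb = NULL) {
  ctx <- matcherContext(g1, g2, cfg, lex, emb)
  lomDrive(ctx, state, positive = TRUE, negative = FALSE)
}

#' Large-ontology matching with negative reduction anchors (LOM-NE)
#'
#' Iterates source concepts in descending degree order; every computed
#' similarity below ntValue becomes an N-AnchorE whose (constraint
#' checked) negative reduction set marks its neighbors' comparisons
#' against the same target as skipped before they are computed.
#'
#' @inheritParams lomPE
#' @return As [lomPE()].
#' @export
lomNE <- function(g1, g2, cfg, state = anchorState(), lex = NULL,
                  emb = NULL) {
  ctx <- matcherContext(g1, g2, cfg, lex, emb)
  lomDrive(ctx, state, positive = FALSE, negative = TRUE)
}

#' Hybrid large-ontology matching (LOM-Hybrid)
#'
#' The LOM-NE driver (degree-descending order) with LOM-PE bookkeeping
#' embedded: every computed similarity above ptValue also contributes
#' positive-reduction skips, and both skip kinds accumulate in one
#' status mask.
#'
#' @inheritParams lomPE
#' @return As [lomPE()].
#' @export
lomHybrid <- function(g1, g2, cfg, state = anchorState(), lex = NULL,
                      emb = NULL) {
  ctx <- matcherContext(g1, g2, cfg, lex, emb)
  lomDrive(ctx, state, positive = TRUE, negative = TRUE)
}
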