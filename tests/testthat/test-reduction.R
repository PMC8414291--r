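# Reduction anchors: anchor selection, reduction sets, and the LOM
# drivers.

# Two isomorphic labeled chains of length n with exact labels.
chainPair <- function(n = 10, seed = 1) {
  synthPair(nConcepts = n, shape = "chain", labelPerturbRate = 0,
            structurePerturbRate = 0, idNameFraction = 0, seed = seed)
}

test_that("P-anchor selection filters by threshold and keeps top-k", {
  sims <- c(b1 = 0.9, b2 = 0.85, b3 = 0.3)
  expect_equal(findPAnchors(sims, ptValue = 0.95), character(0))
  expect_equal(findPAnchors(sims, ptValue = 0.8, topK = 1), "b1")
  expect_equal(findPAnchors(sims, ptValue = 0.8, topK = 4), c("b1", "b2"))
  # strict inequality at the threshold
  expect_equal(findPAnchors(c(b1 = 0.8), ptValue = 0.8), character(0))
  # ties broken by target order
  expect_equal(findPAnchors(c(b2 = 0.9, b1 = 0.9), ptValue = 0.5, topK = 1),
               "b2")
})

test_that("anchors extend through equivalent concepts", {
  g <- parseTtl('
@prefix : <http://ex.org/e#> .
@prefix owl: <http://www.w3.org/2002/07/owl#> .
@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .
:E_001 a owl:Class ; rdfs:label "cardiac muscle" .
:E_002 a owl:Class ; rdfs:label "cardiac muscle" .
:E_003 a owl:Class ; rdfs:label "renal cortex" .
')
  b <- "http://ex.org/e#"
  anchors <- list()
  anchors[[paste0(b, "E_002")]] <- "tgt:b2"
  ext <- extendAnchors(g, anchors, eqValue = 0.95)
  # E_001 has an identical label, so it inherits E_002's anchor
  expect_true("tgt:b2" %in% ext[[paste0(b, "E_001")]])
  expect_null(ext[[paste0(b, "E_003")]])
  # an unreachable threshold disables extension entirely
  ext2 <- extendAnchors(g, anchors, eqValue = 1.01)
  expect_equal(ext2, anchors)
})

test_that("positive reduction sets are the sub/sup cross products", {
  pr <- chainPair(3)
  a <- concepts(pr$source); b <- concepts(pr$target)
  # anchor in the middle of two 3-chains skips the two cross pairs
  ps <- positiveReductionSet(pr$source, pr$target, a[2], b[2])
  expect_setequal(paste(ps[, 1], ps[, 2]),
                  c(paste(a[3], b[1]), paste(a[1], b[3])))
  # an anchor joining the two roots licenses nothing
  psr <- positiveReductionSet(pr$source, pr$target, a[1], b[1])
  expect_equal(nrow(psr), 0)
  expect_error(positiveReductionSet(pr$source, pr$target, "nope", b[1]),
               "unknown")
})

test_that("intersecting per-anchor sets never enlarges the reduction set", {
  pr <- chainPair(6)
  a <- concepts(pr$source); b <- concepts(pr$target)
  ps3 <- paste(positiveReductionSet(pr$source, pr$target, a[3], b[3])[, 1],
               positiveReductionSet(pr$source, pr$target, a[3], b[3])[, 2])
  ps4 <- paste(positiveReductionSet(pr$source, pr$target, a[3], b[4])[, 1],
               positiveReductionSet(pr$source, pr$target, a[3], b[4])[, 2])
  expect_lte(length(intersect(ps3, ps4)), length(ps3))
  expect_true(all(intersect(ps3, ps4) %in% ps3))
})

test_that("negative reduction sets are the neighbor ball times the target", {
  pr <- chainPair(3)
  a <- concepts(pr$source)
  # nScale 0: Nb is the concept itself, nothing to propagate
  expect_equal(nrow(negativeReductionSet(pr$source, a[2], "tgt:b7",
                                         nScale = 0)), 0)
  ns <- negativeReductionSet(pr$source, a[2], "tgt:b7", nScale = 1)
  expect_setequal(paste(ns[, 1], ns[, 2]),
                  paste(c(a[1], a[3]), "tgt:b7"))
  # SDD: a sparse description document blocks propagation
  smallDoc <- virtualDocument(a[2], "term", c(alpha = 1, bone = 1))
  expect_equal(nrow(negativeReductionSet(pr$source, a[2], "tgt:b7",
                                         nScale = 1, sdd = TRUE,
                                         doc = smallDoc, tItems = 4)), 0)
  richDoc <- virtualDocument(a[2], "term",
                             structure(rep(1, 6), names = letters[1:6]))
  expect_gt(nrow(negativeReductionSet(pr$source, a[2], "tgt:b7",
                                      nScale = 1, sdd = TRUE,
                                      doc = richDoc, tItems = 4)), 0)
})

test_that("an unreachable ptValue disables LOM-PE entirely", {
  pr <- chainPair(8)
  res <- lomPE(pr$source, pr$target, matcherPreset("M3"),
               anchorState(ptValue = 1.5))
  n <- length(concepts(pr$source)) * length(concepts(pr$target))
  expect_equal(res$stats@computed, n)
  expect_equal(benefitRate(res$stats), 0)
})

test_that("LOM-PE approaches the ideal computation count on exact chains", {
  pr <- chainPair(10)
  res <- lomPE(pr$source, pr$target, matcherPreset("M3"))
  n <- 10
  expect_lte(res$stats@computed, 3 * n)
  expect_gte(res$stats@skippedPositive, n^2 - 3 * n)
  # the final alignment equals the exhaustive matcher's
  ex <- runMatcher(pr$source, pr$target, matcherPreset("M3"))
  expect_identical(alignmentPairs(extractAlignment(res$matrix, 0.8)),
                   alignmentPairs(extractAlignment(ex, 0.8)))
})

test_that("ntValue 0 disables LOM-NE entirely", {
  pr <- chainPair(8)
  res <- lomNE(pr$source, pr$target, matcherPreset("M3"),
               anchorState(ntValue = 0))
  n <- length(concepts(pr$source)) * length(concepts(pr$target))
  expect_equal(res$stats@computed, n)
  expect_equal(benefitRate(res$stats), 0)
})

test_that("a low-similarity star center suppresses its leaves' comparisons", {
  g1 <- parseTtl('
@prefix : <http://ex.org/st#> .
@prefix owl: <http://www.w3.org/2002/07/owl#> .
@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .
:c a owl:Class ; rdfs:label "central node" .
:l1 a owl:Class ; rdfs:label "first arm" ; rdfs:subClassOf :c .
:l2 a owl:Class ; rdfs:label "second arm" ; rdfs:subClassOf :c .
:l3 a owl:Class ; rdfs:label "third arm" ; rdfs:subClassOf :c .
:l4 a owl:Class ; rdfs:label "fourth arm" ; rdfs:subClassOf :c .
')
  g2 <- parseTtl('
@prefix : <http://ex.org/su#> .
@prefix owl: <http://www.w3.org/2002/07/owl#> .
@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .
:x a owl:Class ; rdfs:label "alien thing" .
:y a owl:Class ; rdfs:label "strange object" ; rdfs:subClassOf :x .
')
  # the center has maximum degree: computed first; all its similarities
  # are 0 < ntValue, so every leaf x target pair is skipped
  res <- lomNE(g1, g2, matcherPreset("M3"),
               anchorState(ntValue = 0.15, nScale = 1,
                           ssg = FALSE, sdd = FALSE))
  st <- pairStatus(res$matrix)
  leafRows <- which(!grepl("#c$", res$matrix@sourceIds))
  expect_true(all(st[leafRows, ] == statusCodes()[["skipped_negative"]]))
  expect_equal(res$stats@computed, 2)  # only the center row
})

test_that("status conservation holds and G matches its definition", {
  pr <- synthPair(nConcepts = 60, seed = 3)
  res <- lomHybrid(pr$source, pr$target, matcherPreset("M5"))
  st <- pairStatus(res$matrix)
  n <- length(res$matrix@sourceIds) * length(res$matrix@targetIds)
  expect_equal(sum(st == 1L) + sum(st == 2L) + sum(st == 3L), n)
  expect_equal(sum(st == 0L), 0)
  expect_equal(benefitRate(res$stats),
               (res$stats@skippedPositive + res$stats@skippedNegative) / n)
  # skipped pairs read as similarity 0
  expect_true(all(similarityValues(res$matrix)[st > 1L] == 0))
})

test_that("disabling both anchor kinds reduces LOM-Hybrid to exhaustive matching", {
  pr <- chainPair(8)
  cfg <- matcherPreset("M5")
  res <- lomHybrid(pr$source, pr$target, cfg,
                   anchorState(ptValue = 1.5, ntValue = 0))
  ex <- runMatcher(pr$source, pr$target, cfg)
  expect_true(all(pairStatus(res$matrix) == 1L))
  expect_identical(res$matrix@values, similarityValues(ex))
})

test_that("the hybrid benefit rate dominates the single-kind drivers", {
  gh <- gp <- gn <- numeric(0)
  for (sd in 1:5) {
    pr <- synthPair(nConcepts = 60, seed = sd)
    cfg <- matcherPreset("M5")
    gh <- c(gh, benefitRate(lomHybrid(pr$source, pr$target, cfg)$stats))
    gp <- c(gp, benefitRate(lomPE(pr$source, pr$target, cfg)$stats))
    gn <- c(gn, benefitRate(lomNE(pr$source, pr$target, cfg)$stats))
  }
  expect_gte(mean(gh), max(mean(gp), mean(gn)) - 0.02)
})

test_that("benefit rate follows its definition and rejects empty inputs", {
  mk <- function(comp, sp, sn, n1, n2)
    new("ReductionStats", computed = comp, skippedPositive = sp,
        skippedNegative = sn, n1 = n1, n2 = n2)
  expect_equal(benefitRate(mk(100, 0, 0, 10, 10)), 0)
  expect_equal(benefitRate(mk(20, 50, 30, 10, 10)), 0.8)
  expect_equal(benefitRate(mk(0, 100, 0, 10, 10)), 1)
  expect_error(benefitRate(mk(0, 0, 0, 0, 10)), "zero-sized")
})

test_that("anchor bookkeeping respects its invariants", {
  pr <- synthPair(nConcepts = 60, seed = 3)
  res <- lomHybrid(pr$source, pr$target, matcherPreset("M5"))
  an <- res$anchors
  v <- res$matrix@values
  src <- res$matrix@sourceIds; tgt <- res$matrix@targetIds
  for (a in names(an@pa)) {
    # PA(a) subset of PAE(a); every PA pair was computed above ptValue
    expect_true(all(an@pa[[a]] %in% an@pae[[a]]))
    sims <- v[match(a, src), match(an@pa[[a]], tgt)]
    expect_true(all(sims > an@ptValue))
  }
  for (a in names(an@na)) {
    expect_true(all(an@na[[a]] %in% an@nae[[a]]))
    sims <- v[match(a, src), match(an@na[[a]], tgt)]
    expect_true(all(sims < an@ntValue))
  }
})
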