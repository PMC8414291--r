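# Edit similarity, TF-IDF weighting, matcher presets, matrix combination.

test_that("normalized edit similarity matches hand-worked examples", {
  expect_equal(editSimilarity("foot bone", "foot bone"), 1)
  # kitten/sitting: DE 3, SE 5, 1 - 3/8
  expect_equal(editSimilarity("kitten", "sitting"), 0.625)
  # ab/xy: DE 2, SE 1, 1 - 2/3
  expect_equal(editSimilarity("ab", "xy"), 1 / 3)
  expect_equal(editSimilarity("", ""), 1)
})

test_that("edit similarity is symmetric, bounded, and agrees with a DP oracle", {
  withr::with_seed(42, {
    for (k in 1:200) {
      s <- randomString(); t <- randomString()
      v <- editSimilarity(s, t)
      expect_gte(v, 0); expect_lte(v, 1)
      expect_equal(v, editSimilarity(t, s))
      expect_equal(v, editSimOracle(s, t))
      if (s == t) expect_equal(v, 1)
    }
    # equals 1 only for equal strings
    expect_lt(editSimilarity("abc", "abd"), 1)
  })
})

test_that("IDF follows (1/2)(1 + log2(N/n)) with a 0.5 floor", {
  mk <- function(el, toks) virtualDocument(el, "term", toks)
  docs <- list(mk("a", c(x = 1)), mk("b", c(x = 1, y = 1)),
               mk("c", c(x = 2, z = 1)), mk("d", c(x = 1, y = 1)))
  corpus <- buildCorpus(docs)
  # x in all 4 documents: IDF = 0.5; doc a is a single-token doc (w = W)
  expect_equal(unname(tfidfVector(docs[[1]], corpus)["x"]), 0.5)
  # z in 1 of 4 documents: IDF = (1/2)(1 + 2) = 1.5; tf = 1/3
  expect_equal(unname(tfidfVector(docs[[3]], corpus)["z"]), 1.5 / 3)
  # degenerate single-document corpus: sole token weight 1 * 0.5
  c1 <- buildCorpus(docs[1])
  expect_equal(unname(tfidfVector(docs[[1]], c1)["x"]), 0.5)
})

test_that("document similarity is a cosine with the expected landmarks", {
  mk <- function(el, toks) virtualDocument(el, "term", toks)
  a <- mk("a", c(x = 1)); b <- mk("b", c(x = 1, y = 1)); cc <- mk("c", c(y = 1))
  corpus <- buildCorpus(list(a, b, cc))  # df(x) = df(y) = 2: equal IDF
  expect_equal(docSimilarity(a, a, corpus), 1)
  expect_equal(docSimilarity(a, cc, corpus), 0)
  expect_equal(docSimilarity(a, b, corpus), 1 / sqrt(2))
  # symmetry and weight-scale invariance
  b2 <- mk("b", c(x = 10, y = 10))
  expect_equal(docSimilarity(b, a, corpus), docSimilarity(a, b, corpus))
  expect_equal(docSimilarity(a, b2, corpus), docSimilarity(a, b, corpus))
  # empty document
  expect_equal(docSimilarity(a, mk("e", numeric(0)), corpus), 0)
})

test_that("the name matcher yields nothing when local names are IDs", {
  g1 <- parseTtl('
@prefix : <http://ex.org/i1#> .
@prefix owl: <http://www.w3.org/2002/07/owl#> .
@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .
:MA_0000216 a owl:Class ; rdfs:label "hindlimb bone" .
:MA_0000217 a owl:Class ; rdfs:label "foot bone" .
')
  g2 <- parseTtl('
@prefix : <http://ex.org/i2#> .
@prefix owl: <http://www.w3.org/2002/07/owl#> .
@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .
:NCI_C12269 a owl:Class ; rdfs:label "Bone of Lower Extremity" .
')
  S <- runMatcher(g1, g2, matcherPreset("M1"))
  expect_true(all(similarityValues(S) == 0))
  expect_equal(nrow(alignmentPairs(extractAlignment(S, 0.5))), 0)
})

test_that("the name matcher scores word-form local names by edit similarity", {
  mkNamed <- function(base) parseTtl(sprintf('
@prefix : <%s> .
@prefix owl: <http://www.w3.org/2002/07/owl#> .
:Foot_Bone a owl:Class .
:Limb_Bone a owl:Class .
:Hindlimb a owl:Class .
', base))
  g1 <- mkNamed("http://ex.org/n1#")
  g2 <- mkNamed("http://ex.org/n2#")
  S <- runMatcher(g1, g2, matcherPreset("M1"))
  v <- similarityValues(S)
  sep <- cbind(match(paste0("http://ex.org/n1#", c("Foot_Bone", "Limb_Bone")),
                     S@sourceIds),
               match(paste0("http://ex.org/n2#", c("Foot_Bone", "Limb_Bone")),
                     S@targetIds))
  expect_equal(unname(v[sep]), c(1, 1))
  # off-diagonal pairs score the normalized edit similarity of the names
  ij <- c(match("http://ex.org/n1#Foot_Bone", S@sourceIds),
          match("http://ex.org/n2#Limb_Bone", S@targetIds))
  expect_equal(v[ij[1], ij[2]], editSimilarity("foot bone", "limb bone"))
})

test_that("a terminological matcher on identical ontologies self-matches", {
  pr <- synthPair(nConcepts = 30, labelPerturbRate = 0,
                  structurePerturbRate = 0, idNameFraction = 0,
                  synonymRate = 0.3, seed = 2)
  S <- runMatcher(pr$source, pr$source, matcherPreset("M3"))
  a <- extractAlignment(S, 0.9)
  p <- alignmentPairs(a)
  expect_equal(nrow(p), length(concepts(pr$source)))
  expect_true(all(p$source == p$target))
})

test_that("lexicon expansion changes scores only for lexicon-covered elements", {
  pr <- synthPair(nConcepts = 40, seed = 21)
  g1 <- pr$source; g2 <- pr$target
  lex <- pr$lexicon
  fields <- c("label", "synonym")
  s3 <- runMatcher(g1, g2, matcherPreset("M3"))
  s10 <- runMatcher(g1, g2, matcherPreset("M10"), lex = lex)
  covered <- function(g) vapply(concepts(g), function(e) {
    phrases <- c(elementLabels(g, e), elementSynonyms(g, e))
    toks <- unique(unlist(lapply(phrases, tokenizeTerms)))
    any(toks %in% names(lex@synonyms))
  }, logical(1))
  u1 <- !covered(g1); u2 <- !covered(g2)
  if (any(u1) && any(u2)) {
    expect_equal(similarityValues(s10)[u1, u2],
                 similarityValues(s3)[u1, u2])
  }
  expect_false(isTRUE(all.equal(similarityValues(s10),
                                similarityValues(s3))))
})

test_that("matchers fail fast when a required resource is missing", {
  g <- chain3()
  expect_error(runMatcher(g, g, matcherPreset("M10")), "lexicon")
  expect_error(runMatcher(g, g, matcherPreset("M12")), "embedding")
})

test_that("matrix combination averages with normalized weights", {
  m1 <- similarityMatrix(c("a"), c("b"), values = matrix(0.8))
  m2 <- similarityMatrix(c("a"), c("b"), values = matrix(0.4))
  # single matrix, weight 1: identity
  expect_equal(similarityValues(combineMatrices(list(m1), 1)), matrix(0.8, dimnames = list("a", "b")))
  # equal weights: (0.8 + 0.4) / 2
  comb <- combineMatrices(list(m1, m2), c(1, 1))
  expect_equal(unname(similarityValues(comb)[1, 1]), 0.6)
  # idempotent on identical inputs
  expect_equal(similarityValues(combineMatrices(list(m1, m1), c(2, 3))),
               similarityValues(m1))
  # monotone: raising an input never lowers the output
  m2b <- similarityMatrix(c("a"), c("b"), values = matrix(0.9))
  expect_gte(similarityValues(combineMatrices(list(m1, m2b), c(1, 1)))[1, 1],
             similarityValues(comb)[1, 1])
  # errors
  expect_error(combineMatrices(list(m1, m2), c(-1, 2)), "non-negative")
  m3 <- similarityMatrix(c("z"), c("b"), values = matrix(0.5))
  expect_error(combineMatrices(list(m1, m3), c(1, 1)), "mismatched")
})

test_that("reduced and exhaustive matching agree exactly on computed pairs", {
  pr <- synthPair(nConcepts = 60, seed = 3)
  cfg <- matcherPreset("M5")
  ex <- runMatcher(pr$source, pr$target, cfg)
  for (red in c("pe", "ne", "hybrid")) {
    r <- runMatcher(pr$source, pr$target, cfg, reduction = red)
    st <- pairStatus(r$matrix)
    expect_identical(r$matrix@values[st == 1L],
                     similarityValues(ex)[st == 1L])
  }
})
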