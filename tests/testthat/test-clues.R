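# Virtual-document builders for the four clue dimensions.

# Fixture: ID-form local names so labels alone feed the term documents.
cluesFixture <- function() {
  parseTtl('
@prefix : <http://ex.org/c#> .
@prefix owl: <http://www.w3.org/2002/07/owl#> .
@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .
:C_0001 a owl:Class ; rdfs:label "Foot Bone" ; rdfs:subClassOf :C_0002 .
:C_0002 a owl:Class ; rdfs:label "hindlimb bone" .
:C_0003 a owl:Class ; rdfs:label "limb bone" .
:C_0004 a owl:Class .
')
}

test_that("term documents collect label tokens with occurrence counts", {
  g <- cluesFixture()
  d <- buildTermDoc(g, "http://ex.org/c#C_0001")
  expect_equal(termWeights(d), c(bone = 1, foot = 1))
  expect_equal(itemCount(d), 2)
})

test_that("ID local names contribute no tokens; empty elements give empty docs", {
  g <- cluesFixture()
  # label only (the ID name C_0003 is mute)
  d <- buildTermDoc(g, "http://ex.org/c#C_0003")
  expect_equal(sort(names(termWeights(d))), c("bone", "limb"))
  # no label, ID name: empty document
  d0 <- buildTermDoc(g, "http://ex.org/c#C_0004")
  expect_equal(itemCount(d0), 0)
})

test_that("non-ID local names do contribute tokens", {
  g <- parseTtl('
@prefix : <http://ex.org/w#> .
@prefix owl: <http://www.w3.org/2002/07/owl#> .
@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .
:Foot_Bone a owl:Class ; rdfs:label "pedal bone" .
')
  d <- buildTermDoc(g, "http://ex.org/w#Foot_Bone")
  expect_true(all(c("foot", "bone", "pedal") %in% names(termWeights(d))))
})

test_that("an isolated concept's direct-structure doc equals its term doc", {
  g <- cluesFixture()
  e <- "http://ex.org/c#C_0003"
  expect_equal(termWeights(buildStructDoc(g, e, mode = "direct")),
               termWeights(buildTermDoc(g, e)))
})

test_that("structurally similar concepts share neighbor tokens in direct docs", {
  g1 <- parseTtl('
@prefix : <http://ex.org/s1#> .
@prefix owl: <http://www.w3.org/2002/07/owl#> .
@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .
:H_01 a owl:Class ; rdfs:label "hindlimb bone" .
:F_01 a owl:Class ; rdfs:label "foot bone" ; rdfs:subClassOf :H_01 .
')
  g2 <- parseTtl('
@prefix : <http://ex.org/s2#> .
@prefix owl: <http://www.w3.org/2002/07/owl#> .
@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .
:B_01 a owl:Class ; rdfs:label "Bone of Lower Extremity" .
:B_02 a owl:Class ; rdfs:label "Foot Bone" ; rdfs:subClassOf :B_01 .
')
  d1 <- buildStructDoc(g1, "http://ex.org/s1#H_01", mode = "direct")
  d2 <- buildStructDoc(g2, "http://ex.org/s2#B_01", mode = "direct")
  shared <- intersect(names(termWeights(d1)), names(termWeights(d2)))
  expect_true(all(c("foot", "bone") %in% shared))
})

test_that("global-structure docs decay ancestor tokens by depth", {
  g <- chain3()
  d <- buildStructDoc(g, "http://ex.org/a#a3", mode = "global", decay = 0.5)
  w <- termWeights(d)
  expect_equal(unname(w["beta"]), 0.5)    # parent a2, depth 1
  expect_equal(unname(w["alpha"]), 0.25)  # grandparent a1, depth 2
  expect_equal(unname(w["gamma"]), 1)     # own label
})

test_that("lexicon expansion adds synonym tokens, and only them", {
  g <- cluesFixture()
  lex <- lexicon(list(hindlimb = c("lower", "extremity")))
  e <- "http://ex.org/c#C_0002"
  d <- buildExtDoc(g, e, lex)
  expect_true(all(c("lower", "extremity") %in% names(termWeights(d))))
  # element whose tokens are absent from the lexicon is unchanged
  e3 <- "http://ex.org/c#C_0003"
  expect_equal(termWeights(buildExtDoc(g, e3, lex)),
               termWeights(buildTermDoc(g, e3)))
  # empty lexicon is a no-op everywhere
  expect_equal(termWeights(buildExtDoc(g, e, lexicon())),
               termWeights(buildTermDoc(g, e)))
})

test_that("the synonym map is reverse-closed", {
  lex <- lexicon(list(alpha = "beta"))
  expect_true("alpha" %in% lex@synonyms[["beta"]])
  g <- chain3()
  # element labeled "beta tissue" gains token alpha through the closure
  d <- buildExtDoc(g, "http://ex.org/a#a2", lex)
  expect_true("alpha" %in% names(termWeights(d)))
})

test_that("term-doc tokens are a subset of struct and ext doc tokens", {
  pr <- synthPair(nConcepts = 30, seed = 13)
  g <- pr$source
  lex <- pr$lexicon
  for (e in sample(concepts(g), 8)) {
    term <- names(termWeights(buildTermDoc(g, e,
                                           fields = c("label", "synonym"))))
    for (m in c("direct", "local", "global")) {
      stru <- names(termWeights(buildStructDoc(g, e, mode = m,
                                               fields = c("label", "synonym"))))
      expect_true(all(term %in% stru))
    }
    extd <- names(termWeights(buildExtDoc(g, e, lex,
                                          fields = c("label", "synonym"))))
    expect_true(all(term %in% extd))
  }
})

test_that("rps vectors are deterministic, zero for OOV, and average tokens", {
  onehot <- diag(3)
  rownames(onehot) <- c("x", "y", "z")
  prov <- embeddingProvider(vectors = onehot)
  g <- parseTtl('
@prefix : <http://ex.org/r#> .
@prefix owl: <http://www.w3.org/2002/07/owl#> .
@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .
:R_01 a owl:Class ; rdfs:label "x y" .
:R_02 a owl:Class ; rdfs:label "y x" .
:R_03 a owl:Class ; rdfs:label "x z" .
:R_04 a owl:Class ; rdfs:label "q q" .
')
  b <- "http://ex.org/r#"
  v1 <- buildRpsVector(g, paste0(b, "R_01"), prov)
  v2 <- buildRpsVector(g, paste0(b, "R_02"), prov)
  expect_identical(v1, v2)       # same token set, same vector
  v3 <- buildRpsVector(g, paste0(b, "R_03"), prov)
  # labels sharing half their tokens, orthogonal one-hots: cosine 1/2
  expect_equal(sum(v1 * v3), 0.5)
  # fully out-of-vocabulary element: zero vector
  expect_equal(buildRpsVector(g, paste0(b, "R_04"), prov), numeric(3))
})

test_that("composite documents are the alpha-weighted sum of dimensions", {
  t1 <- virtualDocument("e", "term", c(bone = 2))
  s1 <- virtualDocument("e", "struct", c(bone = 4, foot = 2))
  # identity weighting returns the term doc
  cid <- compositeDoc(list(term = t1, struct = s1), c(term = 1, struct = 0))
  expect_equal(termWeights(cid), termWeights(t1))
  # alpha (0.5, 0.5): bone gets 0.5*2 + 0.5*4 = 3
  cmix <- compositeDoc(list(term = t1, struct = s1),
                       c(term = 0.5, struct = 0.5))
  expect_equal(unname(termWeights(cmix)["bone"]), 3)
  expect_equal(unname(termWeights(cmix)["foot"]), 1)
  # disjoint vocabularies, equal alpha: union of scaled docs
  t2 <- virtualDocument("e", "term", c(alpha = 1))
  s2 <- virtualDocument("e", "struct", c(beta = 1))
  cu <- compositeDoc(list(term = t2, struct = s2),
                     c(term = 0.5, struct = 0.5))
  expect_setequal(names(termWeights(cu)), c("alpha", "beta"))
  expect_error(compositeDoc(list(term = t1), c(term = 0)), "clue weight")
})

test_that("scaling all clue weights leaves downstream cosines unchanged", {
  t1 <- virtualDocument("e1", "term", c(bone = 2, foot = 1))
  s1 <- virtualDocument("e1", "struct", c(bone = 1, limb = 3))
  t2 <- virtualDocument("e2", "term", c(bone = 1, limb = 1))
  s2 <- virtualDocument("e2", "struct", c(foot = 2))
  mk <- function(sc) {
    a <- c(term = 0.4 * sc, struct = 0.6 * sc)
    list(compositeDoc(list(term = t1, struct = s1), a),
         compositeDoc(list(term = t2, struct = s2), a))
  }
  d1 <- mk(1); dh <- mk(0.5)
  corpus <- buildCorpus(d1)
  expect_equal(docSimilarity(d1[[1]], d1[[2]], corpus),
               docSimilarity(dh[[1]], dh[[2]], corpus))
})
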