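# Parsing, hierarchy context, semantic subgraphs, tokenization.

test_that("an empty file parses to an empty graph", {
  f <- tempfile(fileext = ".ttl")
  writeLines("", f)
  g <- parseOntology(f)
  expect_length(concepts(g), 0)
  expect_equal(nrow(g@triples), 0)
})

test_that("a small Turtle fixture yields the hand-counted graph", {
  g <- chain3()
  expect_length(concepts(g), 3)
  expect_equal(nrow(hierarchyEdges(g)), 2)
  expect_length(unlist(g@labels), 3)
  expect_equal(elementLabels(g, "http://ex.org/a#a2"), "beta tissue")
})

test_that("RDF/XML and Turtle forms of the same ontology agree", {
  x <- '<?xml version="1.0"?>
<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"
  xmlns:rdfs="http://www.w3.org/2000/01/rdf-schema#"
  xmlns:owl="http://www.w3.org/2002/07/owl#">
  <owl:Class rdf:about="http://ex.org/a#a1"><rdfs:label>alpha organ</rdfs:label></owl:Class>
  <owl:Class rdf:about="http://ex.org/a#a2"><rdfs:label>beta tissue</rdfs:label>
    <rdfs:subClassOf rdf:resource="http://ex.org/a#a1"/></owl:Class>
  <owl:Class rdf:about="http://ex.org/a#a3"><rdfs:label>gamma membrane</rdfs:label>
    <rdfs:subClassOf rdf:resource="http://ex.org/a#a2"/></owl:Class>
</rdf:RDF>'
  f <- tempfile(fileext = ".owl")
  writeLines(x, f)
  gx <- parseOntology(f)
  gt <- chain3()
  expect_setequal(concepts(gx), concepts(gt))
  expect_equal(nrow(hierarchyEdges(gx)), nrow(hierarchyEdges(gt)))
  expect_equal(gx@labels[order(names(gx@labels))],
               gt@labels[order(names(gt@labels))])
})

test_that("a blank-node restriction parent resolves to the named class", {
  g <- parseTtl('
@prefix : <http://ex.org/o#> .
@prefix owl: <http://www.w3.org/2002/07/owl#> .
@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .
:partOf a owl:ObjectProperty .
:A a owl:Class ; rdfs:label "foot bone" .
:B a owl:Class ; rdfs:label "hindlimb bone" ;
   rdfs:subClassOf [ a owl:Restriction ; owl:onProperty :partOf ;
                     owl:someValuesFrom :A ] .
', hierarchyPredicates = "http://ex.org/o#partOf")
  ctx <- hierarchyContext(g, "http://ex.org/o#B")
  expect_true("http://ex.org/o#A" %in% ctx$ancestors)
})

test_that("restriction parents are ignored when the property is not hierarchical", {
  g <- parseTtl('
@prefix : <http://ex.org/o#> .
@prefix owl: <http://www.w3.org/2002/07/owl#> .
@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .
:attachedTo a owl:ObjectProperty .
:A a owl:Class ; rdfs:label "foot bone" .
:B a owl:Class ; rdfs:label "hindlimb bone" ;
   rdfs:subClassOf [ a owl:Restriction ; owl:onProperty :attachedTo ;
                     owl:someValuesFrom :A ] .
')
  expect_equal(nrow(hierarchyEdges(g)), 0)
})

test_that("hierarchy context on a chain matches hand enumeration", {
  g <- chain3()
  a1 <- "http://ex.org/a#a1"; a2 <- "http://ex.org/a#a2"
  a3 <- "http://ex.org/a#a3"
  c1 <- hierarchyContext(g, a1)
  expect_length(c1$ancestors, 0)
  expect_setequal(c1$descendants, c(a2, a3))
  c2 <- hierarchyContext(g, a2, nScale = 1)
  expect_setequal(c2$neighbors, c(a1, a2, a3))
  expect_length(c2$siblings, 0)
  expect_equal(c2$degree, 2)
  # Nb at radius 0 is the element itself
  expect_equal(hierarchyContext(g, a2, nScale = 0)$neighbors, a2)
  expect_error(hierarchyContext(g, "http://ex.org/a#nope"), "unknown")
})

test_that("two children of one parent are each other's siblings", {
  g <- parseTtl('
@prefix : <http://ex.org/o#> .
@prefix owl: <http://www.w3.org/2002/07/owl#> .
@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .
:p a owl:Class ; rdfs:label "parent organ" .
:c1 a owl:Class ; rdfs:label "left lobe" ; rdfs:subClassOf :p .
:c2 a owl:Class ; rdfs:label "right lobe" ; rdfs:subClassOf :p .
')
  expect_equal(hierarchyContext(g, "http://ex.org/o#c1")$siblings,
               "http://ex.org/o#c2")
  expect_equal(hierarchyContext(g, "http://ex.org/o#c2")$siblings,
               "http://ex.org/o#c1")
})

test_that("neighborhood balls grow monotonically with the radius", {
  pr <- synthPair(nConcepts = 40, seed = 11)
  g <- pr$source
  for (e in sample(concepts(g), 5)) {
    prev <- character(0)
    for (k in 0:4) {
      nb <- hierarchyContext(g, e, nScale = k)$neighbors
      expect_true(all(prev %in% nb))
      prev <- nb
    }
  }
})

test_that("semantic subgraph covers the ball plus siblings and is distance-symmetric", {
  g <- parseTtl('
@prefix : <http://ex.org/o#> .
@prefix owl: <http://www.w3.org/2002/07/owl#> .
@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .
:c a owl:Class ; rdfs:label "center organ" .
:l1 a owl:Class ; rdfs:label "first lobe" ; rdfs:subClassOf :c .
:l2 a owl:Class ; rdfs:label "second lobe" ; rdfs:subClassOf :c .
:l3 a owl:Class ; rdfs:label "third lobe" ; rdfs:subClassOf :c .
:l4 a owl:Class ; rdfs:label "fourth lobe" ; rdfs:subClassOf :c .
')
  b <- "http://ex.org/o#"
  # star, radius 1 from a leaf: the leaf, the center, and all siblings
  expect_setequal(semanticSubgraph(g, paste0(b, "l1"), radius = 1),
                  paste0(b, c("l1", "c", "l2", "l3", "l4")))
  # radius 0: element plus siblings
  expect_setequal(semanticSubgraph(g, paste0(b, "l1"), radius = 0),
                  paste0(b, c("l1", "l2", "l3", "l4")))
  # ball symmetry (sibling augmentation excluded): check on a chain
  gc <- chain3()
  ids <- concepts(gc)
  for (r in 0:2) {
    for (x in ids) for (y in ids) {
      inX <- y %in% hierarchyContext(gc, x, nScale = r)$neighbors
      inY <- x %in% hierarchyContext(gc, y, nScale = r)$neighbors
      expect_equal(inX, inY)
    }
  }
})

test_that("a constructed subclass cycle is rejected", {
  triples <- data.frame(
    subject = c("u:a", "u:b", "u:a", "u:b"),
    predicate = c(rep("http://www.w3.org/1999/02/22-rdf-syntax-ns#type", 2),
                  rep("http://www.w3.org/2000/01/rdf-schema#subClassOf", 2)),
    object = c(rep("http://www.w3.org/2002/07/owl#Class", 2), "u:b", "u:a"),
    objectType = "uri", stringsAsFactors = FALSE)
  expect_error(buildOntologyGraph(triples), "cycle")
})

test_that("ID-form local names are recognized", {
  expect_true(isIdLike("MA_0000216"))
  expect_true(isIdLike("NCI_C12269"))
  expect_false(isIdLike("Foot_Bone"))
  expect_false(isIdLike(""))
})

test_that("tokenization splits separators and camelCase and drops stop words", {
  expect_equal(tokenizeTerms("Bone_of_Lower_Extremity"),
               c("bone", "lower", "extremity"))
  expect_equal(tokenizeTerms(""), character(0))
  expect_equal(tokenizeTerms("hindlimb bone"), c("hindlimb", "bone"))
  expect_equal(tokenizeTerms("FootBone"), c("foot", "bone"))
})

test_that("generator output round-trips through serialization and parsing", {
  pr <- synthPair(nConcepts = 35, seed = 5)
  d <- tempfile()
  generateOntologyPair(pr$params, dir = d)
  for (side in c("source", "target")) {
    orig <- pr[[side]]
    re <- parseOntology(file.path(d, paste0(side, ".ttl")))
    expect_length(concepts(re), length(concepts(orig)))
    expect_equal(nrow(hierarchyEdges(re)), nrow(hierarchyEdges(orig)))
    expect_length(unlist(re@labels), length(unlist(orig@labels)))
    expect_length(unlist(re@synonyms), length(unlist(orig@synonyms)))
  }
})
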