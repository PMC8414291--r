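#' @describeIn OntologyGraph-class Concept identifiers of an ontology.
#' @param x An object.
#' @export
setGeneric("concepts", function(x) standardGeneric("concepts"))

#' @describeIn OntologyGraph-class Property identifiers of an ontology.
#' @export
setGeneric("ontologyProperties",
           function(x) standardGeneric("ontologyProperties"))

#' @describeIn OntologyGraph-class Ontology identifier.
#' @export
setGeneric("ontologyId", function(x) standardGeneric("ontologyId"))

#' @describeIn OntologyGraph-class Labels of one element (character
#'   vector).
#' @param element Element identifier.
#' @export
setGeneric("elementLabels",
           function(x, element) standardGeneric("elementLabels"))

#' @describeIn OntologyGraph-class Synonyms of one element.
#' @export
setGeneric("elementSynonyms",
           function(x, element) standardGeneric("elementSynonyms"))

#' @describeIn OntologyGraph-class Hierarchy edges (child/parent
#'   data.frame).
#' @export
setGeneric("hierarchyEdges", function(x) standardGeneric("hierarchyEdges"))

#' @describeIn VirtualDocument-class Token-to-weight vector of a virtual
#'   document.
#' @param x An object.
#' @export
setGeneric("termWeights", function(x) standardGeneric("termWeights"))

#' @describeIn VirtualDocument-class Number of distinct tokens.
#' @export
setGeneric("itemCount", function(x) standardGeneric("itemCount"))

#' @describeIn SimilarityMatrix-class Similarity values (numeric
#'   matrix; skipped pairs read 0).
#' @param x An object.
#' @export
setGeneric("similarityValues",
           function(x) standardGeneric("similarityValues"))

#' @describeIn SimilarityMatrix-class Per-pair status matrix (integer
#'   codes, see [statusCodes()]).
#' @export
setGeneric("pairStatus", function(x) standardGeneric("pairStatus"))

#' @describeIn Alignment-class Correspondences as a data.frame.
#' @param x An object.
#' @export
setGeneric("alignmentPairs", function(x) standardGeneric("alignmentPairs"))

#' Benefit rate of a reduction run
#'
#' G = N / (n1 * n2), where N is the size of the total reduction set
#' (skipped pairs) and n1, n2 are the concept counts of the two
#' ontologies. Larger G means fewer similarity computations.
#'
#' @param x A [ReductionStats-class] object.
#' @return Numeric scalar in \[0, 1\].
#' @export
setGeneric("benefitRate", function(x) standardGeneric("benefitRate"))
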