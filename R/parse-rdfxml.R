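## RDF/XML reader built on xml2. Handles the serialization produced by
## common OWL tools: typed node elements (owl:Class, rdf:Description),
## rdf:about / rdf:ID subjects, rdf:resource and rdf:nodeID objects,
## nested node elements (including anonymous restriction blank nodes),
## rdf:parseType="Resource", and literal property values.

parseRdfXml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop(sprintf("cannot parse RDF/XML file '%s': %s", path,
                 conditionMessage(e)), call. = FALSE))
  ns <- xml2::xml_ns(doc)
  nsmap <- as.list(ns)

  fullName <- function(node) {
    nm <- xml2::xml_name(node, ns)
    if (grepl(":", nm, fixed = TRUE)) {
      p <- sub(":.*$", "", nm)
      local <- sub("^[^:]*:", "", nm)
      uri <- nsmap[[p]]
      if (!is.null(uri)) return(paste0(uri, local))
    }
    nm
  }

  base <- xml2::xml_attr(doc, "base")
  if (is.na(base)) base <- ""
  resolveAbout <- function(node) {
    about <- xml2::xml_attr(node, "about")
    if (!is.na(about)) {
      if (!grepl("^[A-Za-z][A-Za-z0-9+.-]*:", about))
        about <- paste0(base, about)
      return(list(value = about, type = "uri"))
    }
    id <- xml2::xml_attr(node, "ID")
    if (!is.na(id)) return(list(value = paste0(base, "#", id), type = "uri"))
    nid <- xml2::xml_attr(node, "nodeID")
    if (!is.na(nid)) return(list(value = paste0("_:", nid), type = "blank"))
    NULL
  }

  triples <- list()
  emit <- function(s, p, o, otype) {
    triples[[length(triples) + 1L]] <<- list(s = s, p = p, o = o, t = otype)
  }
  bcount <- 0L
  newBlank <- function() {
    bcount <<- bcount + 1L
    sprintf("_:x%d", bcount)
  }

  rdfNS <- .NS[["rdf"]]
  processNode <- NULL

  # a property element inside a node element
  processProperty <- function(subject, prop) {
    pred <- fullName(prop)
    res <- xml2::xml_attr(prop, "resource")
    if (!is.na(res)) {
      if (!grepl("^[A-Za-z][A-Za-z0-9+.-]*:", res)) res <- paste0(base, res)
      emit(subject, pred, res, "uri")
      return(invisible())
    }
    nid <- xml2::xml_attr(prop, "nodeID")
    if (!is.na(nid)) {
      emit(subject, pred, paste0("_:", nid), "blank")
      return(invisible())
    }
    ptype <- xml2::xml_attr(prop, "parseType")
    kids <- xml2::xml_children(prop)
    if (!is.na(ptype) && ptype == "Resource") {
      b <- newBlank()
      emit(subject, pred, b, "blank")
      for (k in kids) processProperty(b, k)
      return(invisible())
    }
    if (length(kids) > 0) {
      # nested node element(s): object is the nested resource
      for (k in kids) {
        obj <- processNode(k)
        emit(subject, pred, obj$value, obj$type)
      }
      return(invisible())
    }
    txt <- xml2::xml_text(prop)
    emit(subject, pred, txt, "literal")
  }

  # a node element; returns its subject term
  processNode <- function(node) {
    subj <- resolveAbout(node)
    if (is.null(subj)) subj <- list(value = newBlank(), type = "blank")
    typeName <- fullName(node)
    if (typeName != paste0(rdfNS, "Description"))
      emit(subj$value, paste0(rdfNS, "type"), typeName, "uri")
    for (prop in xml2::xml_children(node))
      processProperty(subj$value, prop)
    subj
  }

  for (node in xml2::xml_children(doc)) processNode(node)

  if (length(triples) == 0L)
    return(data.frame(subject = character(0), predicate = character(0),
                      object = character(0), objectType = character(0),
                      stringsAsFactors = FALSE))
  data.frame(
    subject = vapply(triples, `[[`, character(1), "s"),
    predicate = vapply(triples, `[[`, character(1), "p"),
    object = vapply(triples, `[[`, character(1), "o"),
    objectType = vapply(triples, `[[`, character(1), "t"),
    stringsAsFactors = FALSE
  )
}
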