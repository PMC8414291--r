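## Turtle reader covering the dialect emitted by OWL tools and by this
## package's own serializer: @prefix directives, prefixed names, <uri>
## references, "literal" objects (with optional @lang / ^^datatype),
## 'a' for rdf:type, ';' and ',' continuation, labelled (_:x) and
## anonymous ([ ... ]) blank nodes. Produces a flat triple table with
## full URIs; blank nodes keep a stable _:bN tag.

.NS <- c(
  rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  rdfs = "http://www.w3.org/2000/01/rdf-schema#",
  owl = "http://www.w3.org/2002/07/owl#",
  xsd = "http://www.w3.org/2001/XMLSchema#",
  oboInOwl = "http://www.geneontology.org/formats/oboInOwl#"
)

## Shorten a full URI to a curie for the well-known namespaces; used
## when matching predicates against configuration.
curie <- function(uri) {
  for (p in names(.NS)) {
    ns <- .NS[[p]]
    hit <- startsWith(uri, ns)
    uri[hit] <- paste0(p, ":", substring(uri[hit], nchar(ns) + 1L))
  }
  uri
}

## Expand a curie or known predicate shorthand to a full URI.
expandCurie <- function(x, prefixes = .NS) {
  vapply(x, function(s) {
    if (grepl("^[A-Za-z][A-Za-z0-9_.-]*:", s) && !grepl("^https?:", s)) {
      p <- sub(":.*$", "", s)
      if (p %in% names(prefixes))
        return(paste0(prefixes[[p]], sub("^[^:]*:", "", s)))
    }
    s
  }, character(1), USE.NAMES = FALSE)
}

## Tokenize Turtle text. Returns character vector of tokens; literal
## tokens keep their quotes so the parser can recognize them.
.ttlTokenize <- function(text) {
  tokens <- character(0)
  lines <- integer(0)
  line <- 1L
  i <- 1L; n <- nchar(text)
  buf <- character(0)
  bufline <- 1L
  flush <- function() {
    if (length(buf)) {
      tokens[[length(tokens) + 1L]] <<- paste(buf, collapse = "")
      lines[[length(lines) + 1L]] <<- bufline
      buf <<- character(0)
    }
  }
  push <- function(tok) {
    tokens[[length(tokens) + 1L]] <<- tok
    lines[[length(lines) + 1L]] <<- line
  }
  while (i <= n) {
    ch <- substr(text, i, i)
    if (ch == "\n") line <- line + 1L
    if (ch == "#") {               # comment to end of line
      flush()
      while (i <= n && substr(text, i, i) != "\n") i <- i + 1L
    } else if (ch == "\"") {       # quoted literal (supports \" escapes)
      flush()
      j <- i + 1L
      lit <- character(0)
      while (j <= n) {
        cj <- substr(text, j, j)
        if (cj == "\\" && j < n) {
          nxt <- substr(text, j + 1L, j + 1L)
          lit <- c(lit, switch(nxt, n = "\n", t = "\t", nxt))
          j <- j + 2L
        } else if (cj == "\"") break
        else { lit <- c(lit, cj); j <- j + 1L }
      }
      if (j > n)
        stop(sprintf("unterminated literal at line %d of Turtle input", line))
      push(paste0("\"", paste(lit, collapse = ""), "\""))
      i <- j + 1L
      # attach @lang or ^^datatype to the literal token's tail silently
      if (substr(text, i, i) == "@") {
        while (i <= n && grepl("[@A-Za-z0-9-]", substr(text, i, i)))
          i <- i + 1L
      } else if (substr(text, i, i + 1L) == "^^") {
        i <- i + 2L
        if (substr(text, i, i) == "<") {
          while (i <= n && substr(text, i, i) != ">") i <- i + 1L
          i <- i + 1L
        } else {
          while (i <= n && grepl("[A-Za-z0-9_:.-]", substr(text, i, i)))
            i <- i + 1L
        }
      }
    } else if (ch == "<") {        # URI reference
      flush()
      j <- regexpr(">", substr(text, i, n), fixed = TRUE)
      if (j < 0)
        stop(sprintf("unterminated URI reference at line %d of Turtle input",
                     line))
      push(substr(text, i, i + j - 1L))
      i <- i + j
    } else if (ch %in% c(".", ";", ",", "[", "]")) {
      # '.' inside a prefixed name (rare) is not supported; our dialect
      # only uses '.' as statement terminator
      flush()
      push(ch)
      i <- i + 1L
    } else if (grepl("[[:space:]]", ch)) {
      flush(); i <- i + 1L
    } else {
      if (!length(buf)) bufline <- line
      buf <- c(buf, ch); i <- i + 1L
    }
  }
  flush()
  list(tokens = tokens, lines = unlist(lines, use.names = FALSE))
}

## Parse Turtle text into a triple data.frame.
parseTurtle <- function(text) {
  tk <- .ttlTokenize(text)
  tokens <- tk$tokens
  toklines <- tk$lines
  prefixes <- .NS
  triples <- list()
  bcount <- 0L
  pos <- 1L
  npos <- length(tokens)

  peek <- function() if (pos <= npos) tokens[[pos]] else NA_character_
  advance <- function() { t <- peek(); pos <<- pos + 1L; t }
  curLine <- function() {
    p <- min(max(pos - 1L, 1L), npos)
    if (npos == 0L) 0L else toklines[[p]]
  }

  emit <- function(s, p, o, otype) {
    triples[[length(triples) + 1L]] <<- list(s = s, p = p, o = o, t = otype)
  }

  resolveTerm <- function(tok) {
    if (startsWith(tok, "<"))
      return(list(value = substr(tok, 2L, nchar(tok) - 1L), type = "uri"))
    if (tok == "a")
      return(list(value = paste0(.NS[["rdf"]], "type"), type = "uri"))
    if (startsWith(tok, "_:"))
      return(list(value = tok, type = "blank"))
    if (startsWith(tok, "\""))
      return(list(value = substr(tok, 2L, nchar(tok) - 1L), type = "literal"))
    if (grepl("^[0-9.eE+-]+$", tok))
      return(list(value = tok, type = "literal"))
    if (grepl(":", tok, fixed = TRUE)) {
      p <- sub(":.*$", "", tok)
      pi <- match(p, names(prefixes))
      if (is.na(pi))
        stop(sprintf("undeclared prefix '%s' at line %d of Turtle input",
                     p, curLine()))
      return(list(value = paste0(prefixes[[pi]], sub("^[^:]*:", "", tok)),
                  type = "uri"))
    }
    stop(sprintf("cannot parse Turtle term '%s' at line %d", tok, curLine()))
  }

  # forward declaration for mutual recursion with parseObject
  parsePredicateObjectList <- NULL

  parseObject <- function(subject, predicate) {
    tok <- advance()
    if (identical(tok, "[")) {
      bcount <<- bcount + 1L
      bnode <- sprintf("_:b%d", bcount)
      emit(subject, predicate, bnode, "blank")
      if (!identical(peek(), "]")) parsePredicateObjectList(bnode)
      if (!identical(advance(), "]"))
        stop(sprintf("unterminated blank node at line %d of Turtle input",
                     curLine()))
    } else {
      term <- resolveTerm(tok)
      emit(subject, predicate, term$value, term$type)
    }
  }

  parsePredicateObjectList <- function(subject) {
    repeat {
      ptok <- advance()
      pterm <- resolveTerm(ptok)
      if (pterm$type != "uri")
        stop(sprintf("predicate must be a URI at line %d of Turtle input",
                     curLine()))
      repeat {
        parseObject(subject, pterm$value)
        if (identical(peek(), ",")) { advance() } else break
      }
      if (identical(peek(), ";")) {
        advance()
        # tolerate trailing ';' before '.' or ']'
        if (identical(peek(), ".") || identical(peek(), "]")) break
      } else break
    }
  }

  while (pos <= npos) {
    tok <- peek()
    if (identical(tok, "@prefix") || identical(tolower(tok), "prefix")) {
      advance()
      pname <- sub(":$", "", advance())
      uri <- advance()
      if (!startsWith(uri, "<"))
        stop(sprintf("malformed @prefix directive at line %d", curLine()))
      val <- substr(uri, 2L, nchar(uri) - 1L)
      pi <- match(pname, names(prefixes))
      if (is.na(pi)) {
        prefixes <- c(prefixes, structure(val, names = pname))
      } else prefixes[[pi]] <- val
      if (identical(peek(), ".")) advance()
    } else if (identical(tok, "@base")) {
      advance(); advance()
      if (identical(peek(), ".")) advance()
    } else {
      stok <- advance()
      if (identical(stok, "[")) {
        bcount <- bcount + 1L
        subject <- sprintf("_:b%d", bcount)
        if (!identical(peek(), "]")) parsePredicateObjectList(subject)
        if (!identical(advance(), "]"))
          stop(sprintf("unterminated blank node at line %d of Turtle input",
                       curLine()))
      } else {
        sterm <- resolveTerm(stok)
        if (sterm$type == "literal")
          stop(sprintf("subject may not be a literal (line %d)", curLine()))
        subject <- sterm$value
      }
      parsePredicateObjectList(subject)
      if (!identical(advance(), "."))
        stop(sprintf("missing '.' statement terminator at line %d of Turtle input",
                     curLine()))
    }
  }

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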