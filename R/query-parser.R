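# Boolean characteristic/parameter queries over the algorithm set.
#
# Grammar (whitespace-insensitive, keywords case-insensitive):
#   expr   := term (OR term)*
#   term   := factor (AND factor)*
#   factor := NOT factor | '(' expr ')' | atom
#   atom   := a term identifier in any accepted form, or a "quoted label"
#
# An atom names a characteristic-branch or a parameter-branch term; its
# branch decides the test: a characteristic atom holds for the algorithms
# that possess it (inferred, upward-closed), a parameter atom for the
# algorithms that use it. NOT is the closed-world complement within the
# non-deprecated algorithm set.

.tokenizeQuery <- function(text) {
  tokens <- list()
  s <- text
  pats <- c(ws = "^\\s+", lpar = "^\\(", rpar = "^\\)",
            quoted = "^\"([^\"]*)\"|^'([^']*)'",
            word = "^[^\\s()\"']+")
  while (nchar(s)) {
    matched <- FALSE
    for (kind in names(pats)) {
      m <- regexpr(pats[[kind]], s, perl = TRUE)
      if (m == 1L) {
        tok <- substr(s, 1L, attr(m, "match.length"))
        s <- substring(s, attr(m, "match.length") + 1L)
        if (kind == "ws") { matched <- TRUE; break }
        if (kind == "quoted") {
          tokens[[length(tokens) + 1L]] <-
            list(kind = "atom", value = substr(tok, 2L, nchar(tok) - 1L),
                 quoted = TRUE)
        } else if (kind == "word") {
          up <- toupper(tok)
          if (up %in% c("AND", "OR", "NOT"))
            tokens[[length(tokens) + 1L]] <- list(kind = up)
          else tokens[[length(tokens) + 1L]] <-
              list(kind = "atom", value = tok, quoted = FALSE)
        } else {
          tokens[[length(tokens) + 1L]] <- list(kind = kind)
        }
        matched <- TRUE
        break
      }
    }
    if (!matched) queryError("cannot tokenize query near: %s", s)
  }
  tokens
}

# recursive-descent parse into nested lists: list(op=, args=) / list(atom=)
.parseQuery <- function(tokens) {
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[[pos]] else NULL
  take <- function() { t <- peek(); pos <<- pos + 1L; t }

  parseExpr <- function() {
    node <- parseTerm()
    while (!is.null(peek()) && peek()$kind == "OR") {
      take()
      node <- list(op = "or", args = list(node, parseTerm()))
    }
    node
  }
  parseTerm <- function() {
    node <- parseFactor()
    while (!is.null(peek()) && peek()$kind == "AND") {
      take()
      node <- list(op = "and", args = list(node, parseFactor()))
    }
    node
  }
  parseFactor <- function() {
    t <- peek()
    if (is.null(t)) queryError("unexpected end of query")
    if (t$kind == "NOT") { take(); return(list(op = "not", args = list(parseFactor()))) }
    if (t$kind == "lpar") {
      take()
      node <- parseExpr()
      cl <- take()
      if (is.null(cl) || cl$kind != "rpar") queryError("missing ')' in query")
      return(node)
    }
    if (t$kind == "atom") { take(); return(list(atom = t$value, quoted = t$quoted)) }
    queryError("unexpected token in query")
  }

  node <- parseExpr()
  if (!is.null(peek())) queryError("trailing input after query expression")
  node
}

.resolveAtom <- function(graph, atom, quoted) {
  id <- NULL
  if (!quoted)
    id <- tryCatch(normalizeKisaoId(atom), kisao_id_error = function(e) NULL)
  if (is.null(id)) {
    hits <- searchByName(graph, atom)
    if (!length(hits)) queryError("query atom matches no term: '%s'", atom)
    if (length(hits) > 1L)
      queryError("query atom is ambiguous (%d terms match): '%s'",
                 length(hits), atom)
    id <- hits[[1]]@id
  }
  if (!id %in% graph@terms$id)
    queryError("query atom names an unknown term: '%s'", atom)
  id
}

.evalQueryNode <- function(graph, node, universe) {
  if (!is.null(node$atom)) {
    id <- .resolveAtom(graph, node$atom, node$quoted)
    branch <- termBranch(graph, id)
    idx <- .index(graph)
    if (branch == "characteristic")
      return(universe[vapply(universe, function(a)
        id %in% idx$characteristics[[a]], NA)])
    if (branch == "parameter")
      return(universe[vapply(universe, function(a)
        id %in% idx$parameters[[a]], NA)])
    queryError("query atom kisao:%s is a %s-branch term; only characteristics and parameters may be queried",
               id, branch)
  }
  argSets <- lapply(node$args, .evalQueryNode, graph = graph,
                    universe = universe)
  switch(node$op,
    and = intersect(argSets[[1]], argSets[[2]]),
    or  = union(argSets[[1]], argSets[[2]]),
    not = setdiff(universe, argSets[[1]])
  )
}

#' Algorithms matching a boolean characteristic/parameter query
#'
#' Evaluates an infix boolean expression over the non-deprecated algorithms.
#' Atoms name characteristic- or parameter-branch terms, by any identifier
#' form or by quoted label; `AND`, `OR`, `NOT` and parentheses combine them;
#' keywords are case-insensitive. A characteristic atom selects the
#' algorithms possessing that characteristic, a parameter atom the
#' algorithms using that parameter; `NOT` is the closed-world complement.
#'
#' @param graph an [OntologyGraph-class].
#' @param query the query string, e.g.
#'   `'"stochastic system behaviour" AND NOT kisao:9000105'`.
#' @return sorted character vector of algorithm ids.
#' @examples
#' g <- loadOntology(generateExampleFixture(tempfile(fileext = ".owl")))
#' algorithmsByQuery(g, '"stochastic system behaviour"')
#' @export
algorithmsByQuery <- function(graph, query) {
  if (!is.character(query) || length(query) != 1L || !nzchar(trimws(query)))
    queryError("query must be one non-empty string")
  ast <- .parseQuery(.tokenizeQuery(query))
  sort(.evalQueryNode(graph, ast, .liveAlgorithms(graph)))
}
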