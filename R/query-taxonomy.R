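# Taxonomy-level queries: listing, kind tests, search and annotations.

.termObject <- function(graph, id) {
  i <- .termRow(graph, id)
  syn <- graph@synonyms[graph@synonyms$id == id, c("text", "scope"),
                        drop = FALSE]
  syn <- syn[order(syn$scope, syn$text), , drop = FALSE]
  rownames(syn) <- NULL
  new("OntologyTerm",
      id = id,
      label = graph@terms$label[i],
      synonyms = syn,
      definition = graph@terms$definition[i],
      links = sort(graph@xrefs$link[graph@xrefs$id == id]),
      deprecated = graph@terms$deprecated[i],
      branch = graph@terms$branch[i])
}

#' List the terms of one ontology branch
#'
#' Returns every term of the algorithm, characteristic or parameter branch
#' (branch root included), sorted by id, with deprecated terms flagged.
#'
#' @param graph an [OntologyGraph-class].
#' @param branch `"algorithm"`, `"characteristic"` or `"parameter"`.
#' @return data.frame with columns `id`, `label`, `deprecated`.
#' @examples
#' g <- loadOntology(generateExampleFixture(tempfile(fileext = ".owl")))
#' listTerms(g, "algorithm")
#' @export
listTerms <- function(graph,
                      branch = c("algorithm", "characteristic", "parameter")) {
  branch <- match.arg(branch)
  t <- graph@terms[graph@terms$branch == branch,
                   c("id", "label", "deprecated"), drop = FALSE]
  t <- t[order(t$id), , drop = FALSE]
  rownames(t) <- NULL
  t
}

#' Branch kind of a term
#'
#' `termBranch()` returns which of the three KiSAO branches a term belongs
#' to (`"other"` for terms outside all three); `isAlgorithm()`,
#' `isCharacteristic()` and `isParameter()` are the boolean shorthands.
#'
#' @param graph an [OntologyGraph-class].
#' @param id a term identifier in any accepted form.
#' @return a branch kind, or a logical.
#' @name term-kind
NULL

#' @rdname term-kind
#' @export
termBranch <- function(graph, id) {
  id <- normalizeKisaoId(id)
  graph@terms$branch[.termRow(graph, id)]
}

#' @rdname term-kind
#' @export
isAlgorithm <- function(graph, id) termBranch(graph, id) == "algorithm"

#' @rdname term-kind
#' @export
isCharacteristic <- function(graph, id) termBranch(graph, id) == "characteristic"

#' @rdname term-kind
#' @export
isParameter <- function(graph, id) termBranch(graph, id) == "parameter"

#' Search for a term by identifier or by name
#'
#' `searchById()` accepts any identifier form (short id, underscore form,
#' IRI, MIRIAM URN, identifiers.org URL; prefixes case-insensitive) and
#' returns the term. `searchByName()` matches labels and synonym texts,
#' case-insensitively; with `substring = TRUE` a substring match is used
#' instead of exact equality.
#'
#' @param graph an [OntologyGraph-class].
#' @param text an identifier (`searchById`) or a name/synonym
#'   (`searchByName`).
#' @param substring logical; match substrings of labels/synonyms?
#' @return `searchById()`: one [OntologyTerm-class]; `searchByName()`: a
#'   (possibly empty) list of [OntologyTerm-class] objects sorted by id.
#' @examples
#' g <- loadOntology(generateExampleFixture(tempfile(fileext = ".owl")))
#' searchById(g, "urn:miriam:biomodels.kisao:KISAO_0000039")
#' searchByName(g, "tauL")
#' @export
searchById <- function(graph, text) {
  .termObject(graph, normalizeKisaoId(text))
}

#' @rdname searchById
#' @export
searchByName <- function(graph, text, substring = FALSE) {
  key <- tolower(text)
  hit <- function(x) {
    x <- tolower(x)
    if (substring) grepl(key, x, fixed = TRUE) else x == key
  }
  ids <- unique(c(
    graph@terms$id[!is.na(graph@terms$label) & hit(graph@terms$label)],
    graph@synonyms$id[hit(graph@synonyms$text)]
  ))
  lapply(sort(ids), .termObject, graph = graph)
}

#' @rdname searchById
#' @export
kisaoTerm <- function(graph, text) searchById(graph, text)

#' Annotation accessors
#'
#' Direct access to a term's stored annotations: name, typed synonyms
#' (optionally filtered by scope: exact, related, broad or narrow),
#' definition, literature links and deprecation flag.
#'
#' @param graph an [OntologyGraph-class].
#' @param id a term identifier.
#' @param scope optional synonym scope filter, one or more of
#'   `c("exact", "related", "broad", "narrow")`.
#' @return `termLabel()`/`termDefinition()`: character (may be `NA`);
#'   `termSynonyms()`: data.frame of `text`, `scope`; `termLinks()`:
#'   character vector; `isDeprecated()`: logical.
#' @name term-annotations
NULL

#' @rdname term-annotations
#' @export
termLabel <- function(graph, id) {
  id <- normalizeKisaoId(id)
  graph@terms$label[.termRow(graph, id)]
}

#' @rdname term-annotations
#' @export
termSynonyms <- function(graph, id, scope = NULL) {
  id <- normalizeKisaoId(id)
  .termRow(graph, id)
  syn <- graph@synonyms[graph@synonyms$id == id, c("text", "scope"),
                        drop = FALSE]
  if (!is.null(scope)) {
    scope <- match.arg(scope, SYNONYM_SCOPES, several.ok = TRUE)
    syn <- syn[syn$scope %in% scope, , drop = FALSE]
  }
  syn <- syn[order(syn$scope, syn$text), , drop = FALSE]
  rownames(syn) <- NULL
  syn
}

#' @rdname term-annotations
#' @export
termDefinition <- function(graph, id) {
  id <- normalizeKisaoId(id)
  graph@terms$definition[.termRow(graph, id)]
}

#' @rdname term-annotations
#' @export
termLinks <- function(graph, id) {
  id <- normalizeKisaoId(id)
  .termRow(graph, id)
  sort(graph@xrefs$link[graph@xrefs$id == id])
}

#' @rdname term-annotations
#' @export
isDeprecated <- function(graph, id) {
  id <- normalizeKisaoId(id)
  graph@terms$deprecated[.termRow(graph, id)]
}
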