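#' @import methods
NULL

#' OntologyGraph: an indexed in-memory ontology
#'
#' The central container of the package. It holds every class of a
#' KiSAO-shaped ontology together with its annotations, the subclass edges,
#' the asserted link axioms (has-characteristic, has-parameter, is-hybrid-of,
#' has-type), and an eagerly computed closure index (transitive
#' ancestors/descendants, inferred characteristic/parameter/hybrid sets and
#' the algorithm-branch adjacency used for hierarchy distances).
#'
#' Slots are internal; use the accessors [kisaoTerms()], [subclassEdges()],
#' [linkAxioms()], [termSynonymTable()], [branchRoots()] and the query
#' functions instead.
#'
#' @slot terms data.frame with columns `id`, `label`, `definition`,
#'   `deprecated`, `branch`.
#' @slot synonyms data.frame with columns `id`, `text`, `scope`.
#' @slot xrefs data.frame with columns `id`, `link`.
#' @slot edges data.frame of subclass axioms with columns `child`, `parent`.
#' @slot links data.frame of link axioms with columns `subject`, `relation`,
#'   `object` (`object` is a datatype name for `has_type`).
#' @slot roots named character: the three branch-root term ids.
#' @slot config the parsing configuration used (see
#'   [defaultOntologyConfig()]).
#' @slot index environment caching the closure index.
#' @exportClass OntologyGraph
setClass("OntologyGraph", representation(
  terms    = "data.frame",
  synonyms = "data.frame",
  xrefs    = "data.frame",
  edges    = "data.frame",
  links    = "data.frame",
  roots    = "character",
  config   = "list",
  index    = "environment"
))

SYNONYM_SCOPES <- c("exact", "related", "broad", "narrow")
RELATION_KINDS <- c("has_characteristic", "has_parameter", "is_hybrid_of",
                    "has_type")
BRANCH_KINDS <- c("algorithm", "characteristic", "parameter", "other")

setValidity("OntologyGraph", function(object) {
  msgs <- character()
  t <- object@terms
  need <- c("id", "label", "definition", "deprecated", "branch")
  if (!all(need %in% names(t)))
    msgs <- c(msgs, "terms must have columns id, label, definition, deprecated, branch")
  else {
    if (anyDuplicated(t$id)) msgs <- c(msgs, "duplicated term ids")
    if (!all(t$branch %in% BRANCH_KINDS)) msgs <- c(msgs, "invalid branch kind")
  }
  ids <- t$id
  e <- object@edges
  if (nrow(e)) {
    if (!all(c(e$child, e$parent) %in% ids))
      msgs <- c(msgs, "subclass edge references an unknown term")
    if (is.null(topologicalOrder(ids, e)))
      msgs <- c(msgs, "subclass edges contain a cycle")
  }
  l <- object@links
  if (nrow(l)) {
    if (!all(l$relation %in% RELATION_KINDS))
      msgs <- c(msgs, "invalid link relation")
    if (!all(l$subject %in% ids))
      msgs <- c(msgs, "link axiom subject is an unknown term")
    obj <- l$object[l$relation != "has_type"]
    if (!all(obj %in% ids))
      msgs <- c(msgs, "link axiom object is an unknown term")
  }
  if (nrow(object@synonyms) && !all(object@synonyms$scope %in% SYNONYM_SCOPES))
    msgs <- c(msgs, "invalid synonym scope")
  if (length(object@roots) != 3L ||
      !setequal(names(object@roots), c("algorithm", "characteristic", "parameter")))
    msgs <- c(msgs, "roots must name algorithm, characteristic and parameter")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn OntologyGraph compact summary of the graph.
#' @param object an `OntologyGraph`.
#' @export
setMethod("show", "OntologyGraph", function(object) {
  t <- object@terms
  cat(sprintf("OntologyGraph with %d terms (%d algorithms, %d characteristics, %d parameters, %d other)\n",
              nrow(t), sum(t$branch == "algorithm"),
              sum(t$branch == "characteristic"),
              sum(t$branch == "parameter"), sum(t$branch == "other")))
  cat(sprintf("  %d subclass edges, %d link axioms, %d deprecated terms\n",
              nrow(object@edges), nrow(object@links), sum(t$deprecated)))
  cat(sprintf("  branch roots: %s\n",
              paste(sprintf("%s=kisao:%s", names(object@roots), object@roots),
                    collapse = ", ")))
})

#' OntologyTerm: one ontology class with its annotations
#'
#' Returned by [searchById()], [searchByName()] and [kisaoTerm()].
#'
#' @slot id canonical 7-digit term id.
#' @slot label term name (`NA` when the file carries none).
#' @slot synonyms data.frame with columns `text`, `scope` (scope is one of
#'   exact, related, broad, narrow).
#' @slot definition textual definition or `NA`.
#' @slot links character vector of literature/article references.
#' @slot deprecated logical flag.
#' @slot branch one of algorithm, characteristic, parameter, other.
#' @exportClass OntologyTerm
setClass("OntologyTerm", representation(
  id         = "character",
  label      = "character",
  synonyms   = "data.frame",
  definition = "character",
  links      = "character",
  deprecated = "logical",
  branch     = "character"
))

setValidity("OntologyTerm", function(object) {
  msgs <- character()
  if (length(object@id) != 1L || !grepl("^[0-9]{7}$", object@id))
    msgs <- c(msgs, "id must be one 7-digit string")
  if (!object@branch %in% BRANCH_KINDS) msgs <- c(msgs, "invalid branch")
  if (nrow(object@synonyms) && !all(object@synonyms$scope %in% SYNONYM_SCOPES))
    msgs <- c(msgs, "invalid synonym scope")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn OntologyTerm one-screen rendering of the term.
#' @param object an `OntologyTerm`.
#' @export
setMethod("show", "OntologyTerm", function(object) {
  cat(sprintf("%s  %s  [%s%s]\n", renderKisaoId(object@id, "short"),
              ifelse(is.na(object@label), "<unlabelled>", object@label),
              object@branch,
              if (isTRUE(object@deprecated)) ", deprecated" else ""))
  if (nrow(object@synonyms))
    cat(sprintf("  synonym (%s): %s\n", object@synonyms$scope,
                object@synonyms$text), sep = "")
  if (!is.na(object@definition)) cat("  definition:", object@definition, "\n")
  for (l in object@links) cat("  link:", l, "\n")
})

# -- accessors ---------------------------------------------------------------

#' Accessors for OntologyGraph components
#'
#' @param graph an [OntologyGraph-class] object.
#' @return `kisaoTerms()`: the term table (id, label, definition, deprecated,
#'   branch); `subclassEdges()`: data.frame of (child, parent) pairs;
#'   `linkAxioms()`: data.frame of (subject, relation, object);
#'   `termSynonymTable()`: data.frame of (id, text, scope);
#'   `branchRoots()`: named character of the three branch-root ids.
#' @name graph-accessors
NULL

#' @rdname graph-accessors
#' @export
kisaoTerms <- function(graph) graph@terms

#' @rdname graph-accessors
#' @export
subclassEdges <- function(graph) graph@edges

#' @rdname graph-accessors
#' @export
linkAxioms <- function(graph) graph@links

#' @rdname graph-accessors
#' @export
termSynonymTable <- function(graph) graph@synonyms

#' @rdname graph-accessors
#' @export
branchRoots <- function(graph) graph@roots

# internal: row index of a term, failing with a classed error
.termRow <- function(graph, id) {
  i <- match(id, graph@terms$id)
  if (is.na(i)) unknownTermError("unknown term: kisao:%s", id)
  i
}

.checkBranch <- function(graph, id, branch) {
  b <- graph@terms$branch[.termRow(graph, id)]
  if (b != branch)
    branchError("kisao:%s is in the '%s' branch, expected '%s'", id, b, branch)
  invisible(b)
}
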