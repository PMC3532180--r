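# Application-level queries: characteristic-based grouping of algorithms,
# parameter lookups, hybrid links and similarity-ranked substitute search.
# Negation ("lack", query NOT) is closed-world over the inferred
# characteristic sets: a characteristic not inferable is treated as absent,
# which is the right reading for matching simulation-tool capabilities.

.liveAlgorithms <- function(graph) {
  t <- graph@terms
  sort(t$id[t$branch == "algorithm" & !t$deprecated])
}

# expand a set of filter classes to themselves plus all their descendants
.typeFilterSet <- function(graph, types) {
  types <- normalizeKisaoId(types)
  for (ty in types) .checkBranch(graph, ty, "characteristic")
  idx <- .index(graph)
  unique(c(types, unlist(idx$descendants[types], use.names = FALSE)))
}

#' Characteristics possessed by an algorithm
#'
#' The full inferred characteristic set of an algorithm (see
#' [inferredCharacteristics()]), optionally restricted to one or more
#' characteristic *types*: when `types` is given, only characteristics that
#' are one of the filter classes or their descendants are kept. An empty
#' (zero-length, non-`NULL`) filter keeps nothing.
#'
#' @param graph an [OntologyGraph-class].
#' @param algorithm an algorithm-branch term id.
#' @param types optional characteristic-type filter (characteristic-branch
#'   term ids); `NULL` means all characteristics.
#' @return sorted character vector of characteristic ids.
#' @examples
#' g <- loadOntology(generateExampleFixture(tempfile(fileext = ".owl")))
#' characteristicsOf(g, EXAMPLE_FIXTURE_IDS[["poisson_tau_leaping"]],
#'                   types = EXAMPLE_FIXTURE_IDS[["type_of_system_behaviour"]])
#' @export
characteristicsOf <- function(graph, algorithm, types = NULL) {
  chars <- inferredCharacteristics(graph, algorithm)
  if (is.null(types)) return(chars)
  if (!length(types)) return(character())
  sort(intersect(chars, .typeFilterSet(graph, types)))
}

#' Does an algorithm possess the given characteristic(s)?
#'
#' True iff every listed characteristic is in the algorithm's inferred
#' characteristic set (vacuously true for an empty list). Because inferred
#' sets are closed upward, possessing a child characteristic counts as
#' possessing the parent.
#'
#' @param graph an [OntologyGraph-class].
#' @param algorithm an algorithm-branch term id.
#' @param characteristics characteristic-branch term ids.
#' @return logical scalar.
#' @export
hasCharacteristic <- function(graph, algorithm, characteristics) {
  chars <- inferredCharacteristics(graph, algorithm)
  if (!length(characteristics)) return(TRUE)
  characteristics <- normalizeKisaoId(characteristics)
  for (ch in characteristics) .checkBranch(graph, ch, "characteristic")
  all(characteristics %in% chars)
}

#' Algorithms that possess, or lack, given characteristics
#'
#' `mode = "possess"`: every non-deprecated algorithm whose inferred
#' characteristic set contains all the listed characteristics.
#' `mode = "lack"`: every non-deprecated algorithm missing at least one of
#' them (closed-world negation). For any characteristic set the two results
#' partition the non-deprecated algorithms.
#'
#' @param graph an [OntologyGraph-class].
#' @param characteristics characteristic-branch term ids.
#' @param mode `"possess"` or `"lack"`.
#' @return sorted character vector of algorithm ids.
#' @export
algorithmsByCharacteristics <- function(graph, characteristics,
                                        mode = c("possess", "lack")) {
  mode <- match.arg(mode)
  characteristics <- if (length(characteristics))
    normalizeKisaoId(characteristics) else character()
  for (ch in characteristics) .checkBranch(graph, ch, "characteristic")
  algs <- .liveAlgorithms(graph)
  idx <- .index(graph)
  has <- vapply(algs, function(a)
    all(characteristics %in% idx$characteristics[[a]]), NA)
  if (mode == "possess") algs[has] else algs[!has]
}

#' Algorithms sharing an algorithm's characteristic profile
#'
#' Returns every non-deprecated algorithm (other than the query) whose
#' inferred characteristic set, restricted to the optional characteristic
#' types, is set-equal to the query algorithm's. With `types = NULL` the
#' full characteristic profiles are compared.
#'
#' @param graph an [OntologyGraph-class].
#' @param algorithm the query algorithm id.
#' @param types optional characteristic-type filter.
#' @return sorted character vector of algorithm ids.
#' @export
algorithmsWithSameCharacteristics <- function(graph, algorithm, types = NULL) {
  algorithm <- normalizeKisaoId(algorithm)
  target <- characteristicsOf(graph, algorithm, types)
  cands <- setdiff(.liveAlgorithms(graph), algorithm)
  cands[vapply(cands, function(a)
    setequal(characteristicsOf(graph, a, types), target), NA)]
}

#' The n algorithms most similar to a given one
#'
#' The substitute-search query: candidates are the algorithms sharing the
#' query's (type-filtered) characteristic profile
#' ([algorithmsWithSameCharacteristics()]); they are ranked by ascending
#' hierarchy distance to the query ([hierarchyDistance()]), ties broken by
#' ascending numeric id, and the first `n` are returned. The query algorithm
#' itself is never returned; fewer than `n` rows are returned when fewer
#' candidates exist; candidates in a different connected component (distance
#' `NA`) sort last.
#'
#' @param graph an [OntologyGraph-class].
#' @param algorithm the query algorithm id.
#' @param n maximum number of results (>= 0).
#' @param types optional characteristic-type filter.
#' @return data.frame with columns `id`, `label`, `distance`, ordered by
#'   ascending distance.
#' @examples
#' g <- loadOntology(generateExampleFixture(tempfile(fileext = ".owl")))
#' nMostSimilar(g, EXAMPLE_FIXTURE_IDS[["poisson_tau_leaping"]], 4,
#'              types = EXAMPLE_FIXTURE_IDS[c("type_of_system_behaviour",
#'                                          "type_of_variable")])
#' @export
nMostSimilar <- function(graph, algorithm, n, types = NULL) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0)
    usageError("n must be a single non-negative number")
  algorithm <- normalizeKisaoId(algorithm)
  .checkBranch(graph, algorithm, "algorithm")
  cands <- algorithmsWithSameCharacteristics(graph, algorithm, types)
  if (!length(cands) || n == 0)
    return(data.frame(id = character(), label = character(),
                      distance = integer()))
  dist <- .bfsDistances(graph, algorithm)[cands]
  ord <- order(is.na(dist), dist, cands)
  keep <- ord[seq_len(min(length(ord), floor(n)))]
  data.frame(id = cands[keep],
             label = graph@terms$label[match(cands[keep], graph@terms$id)],
             distance = as.integer(unname(dist[keep])))
}

#' Parameters of an algorithm, and parameter datatypes
#'
#' `algorithmParameters()` returns the inferred parameter set of an
#' algorithm (asserted on it or any ancestor). `parameterType()` returns the
#' declared datatype name of a parameter (e.g. `"double"`), or `NA` when the
#' ontology declares none.
#'
#' @param graph an [OntologyGraph-class].
#' @param algorithm an algorithm-branch term id.
#' @param parameter a parameter-branch term id.
#' @return character vector of parameter ids; or a single datatype name /
#'   `NA`.
#' @examples
#' g <- loadOntology(generateExampleFixture(tempfile(fileext = ".owl")))
#' parameterType(g, EXAMPLE_FIXTURE_IDS[["tau_leaping_epsilon"]])
#' @export
algorithmParameters <- function(graph, algorithm) {
  inferredParameters(graph, algorithm)
}

#' @rdname algorithmParameters
#' @export
parameterType <- function(graph, parameter) {
  parameter <- normalizeKisaoId(parameter)
  .checkBranch(graph, parameter, "parameter")
  ty <- .index(graph)$parameterTypes
  if (parameter %in% names(ty)) unname(ty[[parameter]]) else NA_character_
}

#' Parameters used by algorithms with given characteristics
#'
#' The union of the inferred parameter sets over all non-deprecated
#' algorithms that possess every listed characteristic — optionally
#' restricted to algorithms descending from (or equal to) `ancestor`.
#'
#' @param graph an [OntologyGraph-class].
#' @param characteristics characteristic-branch term ids.
#' @param ancestor optional algorithm-branch term id restricting the
#'   algorithm set.
#' @return sorted character vector of parameter ids.
#' @export
parametersByCharacteristics <- function(graph, characteristics,
                                        ancestor = NULL) {
  algs <- algorithmsByCharacteristics(graph, characteristics, "possess")
  if (!is.null(ancestor)) {
    ancestor <- normalizeKisaoId(ancestor)
    .checkBranch(graph, ancestor, "algorithm")
    algs <- algs[vapply(algs, function(a) isA(graph, a, ancestor), NA)]
  }
  idx <- .index(graph)
  sort(unique(c(character(),
                unlist(idx$parameters[algs], use.names = FALSE))))
}

#' Does an algorithm (or characteristic profile) use given parameters?
#'
#' With an algorithm-branch `subject`, tests whether every listed parameter
#' is in the algorithm's inferred parameter set. With a characteristic-branch
#' `subject` (one or more characteristic ids), tests membership in the union
#' of parameters over all non-deprecated algorithms possessing those
#' characteristics ([parametersByCharacteristics()]).
#'
#' @param graph an [OntologyGraph-class].
#' @param subject one algorithm id, or a vector of characteristic ids.
#' @param parameters parameter-branch term ids.
#' @return logical scalar.
#' @export
hasParameter <- function(graph, subject, parameters) {
  parameters <- if (length(parameters)) normalizeKisaoId(parameters)
                else character()
  for (p in parameters) .checkBranch(graph, p, "parameter")
  subject <- normalizeKisaoId(subject)
  branches <- vapply(subject, function(s) termBranch(graph, s), "")
  pool <- if (length(subject) == 1L && branches[[1]] == "algorithm") {
    inferredParameters(graph, subject)
  } else if (all(branches == "characteristic")) {
    parametersByCharacteristics(graph, subject)
  } else {
    branchError("subject must be one algorithm or a set of characteristics")
  }
  all(parameters %in% pool)
}

#' Hybrid-algorithm links
#'
#' An algorithm is hybrid when at least one `is_hybrid_of` axiom applies to
#' it, asserted directly or inherited from a subclass ancestor.
#' `hybridOf()` returns the union of the component algorithms.
#'
#' @param graph an [OntologyGraph-class].
#' @param algorithm an algorithm-branch term id.
#' @return `isHybrid()`: logical; `hybridOf()`: sorted character vector of
#'   algorithm ids (empty for non-hybrids).
#' @export
isHybrid <- function(graph, algorithm) {
  length(hybridOf(graph, algorithm)) > 0L
}

#' @rdname isHybrid
#' @export
hybridOf <- function(graph, algorithm) {
  algorithm <- normalizeKisaoId(algorithm)
  .checkBranch(graph, algorithm, "algorithm")
  .index(graph)$hybrids[[algorithm]]
}
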