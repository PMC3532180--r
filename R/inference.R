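# Structural reasoning over the subclass DAG: transitive closures, inherited
# existential restrictions, branch assignment and hierarchy distance. All of
# it is plain graph computation -- no tableau reasoning is attempted, which is
# sufficient for the constructs KiSAO-shaped files actually use.

# Kahn topological order over child->parent edges, parents first.
# Returns NULL when the edge set contains a cycle.
topologicalOrder <- function(ids, edges) {
  n <- length(ids)
  if (!n) return(character())
  childOf <- split(match(edges$child, ids), match(edges$parent, ids))
  indeg <- integer(n)  # number of parents still unprocessed, per node
  if (nrow(edges)) {
    cnt <- table(factor(match(edges$child, ids), levels = seq_len(n)))
    indeg <- as.integer(cnt)
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    out <- c(out, v)
    kids <- childOf[[as.character(v)]]
    for (k in kids) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(out) != n) return(NULL)
  ids[out]
}

# Transitive ancestor sets for every node, computed parents-first in
# topological order: anc(x) = union over direct parents p of {p} + anc(p).
computeAncestors <- function(ids, edges) {
  anc <- stats::setNames(vector("list", length(ids)), ids)
  anc[] <- list(character())
  if (!nrow(edges)) return(anc)
  order <- topologicalOrder(ids, edges)
  if (is.null(order))
    formatError("subclass axioms form a cycle; not a valid class hierarchy")
  parentsOf <- split(edges$parent, edges$child)
  for (id in order) {
    ps <- parentsOf[[id]]
    if (!is.null(ps))
      anc[[id]] <- unique(c(ps, unlist(anc[ps], use.names = FALSE)))
  }
  anc
}

invertClosure <- function(anc) {
  ids <- names(anc)
  desc <- stats::setNames(vector("list", length(ids)), ids)
  desc[] <- list(character())
  lens <- lengths(anc)
  if (sum(lens)) {
    flat <- data.frame(node = rep(names(anc), lens),
                       up = unlist(anc, use.names = FALSE))
    byUp <- split(flat$node, flat$up)
    desc[names(byUp)] <- byUp
  }
  desc
}

# Branch assignment: a term belongs to the branch of the unique root it is
# (or descends from); terms under no root are "other"; two roots is an error.
assignBranches <- function(ids, anc, roots) {
  branch <- rep("other", length(ids))
  names(branch) <- ids
  for (kind in names(roots)) {
    r <- roots[[kind]]
    if (!r %in% ids) next
    members <- ids[vapply(ids, function(i) i == r || r %in% anc[[i]], NA)]
    clash <- members[branch[members] != "other"]
    if (length(clash))
      formatError("term kisao:%s is reachable from two branch roots", clash[[1]])
    branch[members] <- kind
  }
  branch
}

# Inherited link objects: everything asserted on the subject or any of its
# subclass ancestors.
.inheritedObjects <- function(id, anc, linkTab) {
  sup <- c(id, anc[[id]])
  unique(linkTab$object[linkTab$subject %in% sup])
}

# Build the eager closure index. Characteristics additionally close upward
# within the characteristic branch: possessing "stochastic system behaviour"
# entails possessing "type of system behaviour". Parameters and hybrid links
# are inherited down the algorithm hierarchy but not generalized upward.
buildClosureIndex <- function(terms, edges, links) {
  ids <- terms$id
  anc <- computeAncestors(ids, edges)
  desc <- invertClosure(anc)
  branch <- stats::setNames(terms$branch, ids)
  algIds <- ids[branch == "algorithm"]
  charBranch <- ids[branch == "characteristic"]

  pick <- function(rel) links[links$relation == rel, , drop = FALSE]
  hc <- pick("has_characteristic"); hp <- pick("has_parameter")
  hy <- pick("is_hybrid_of")

  chars <- params <- hybrids <- stats::setNames(
    vector("list", length(algIds)), algIds)
  for (a in algIds) {
    cs <- .inheritedObjects(a, anc, hc)
    up <- unlist(anc[cs], use.names = FALSE)
    chars[[a]] <- sort(unique(c(cs, intersect(up, charBranch))))
    params[[a]] <- sort(.inheritedObjects(a, anc, hp))
    hybrids[[a]] <- sort(.inheritedObjects(a, anc, hy))
  }

  # undirected adjacency within the algorithm branch, for BFS distances
  ae <- edges[edges$child %in% algIds & edges$parent %in% algIds, , drop = FALSE]
  nbr <- stats::setNames(vector("list", length(algIds)), algIds)
  nbr[] <- list(character())
  if (nrow(ae)) {
    und <- rbind(data.frame(a = ae$child, b = ae$parent),
                 data.frame(a = ae$parent, b = ae$child))
    got <- lapply(split(und$b, und$a), unique)
    nbr[names(got)] <- got
  }

  typed <- pick("has_type")
  list(ancestors = anc, descendants = desc, branch = branch,
       characteristics = chars, parameters = params, hybrids = hybrids,
       algNeighbours = nbr,
       parameterTypes = stats::setNames(typed$object, typed$subject))
}

.index <- function(graph) {
  env <- graph@index
  if (is.null(env$closure))
    env$closure <- buildClosureIndex(graph@terms, graph@edges, graph@links)
  env$closure
}

#' Hierarchy queries: ancestors, descendants and subsumption
#'
#' `termAncestors()` and `termDescendants()` walk the subclass (`rdfs:subClassOf`)
#' hierarchy: with `direct = TRUE` only the immediate parents/children are
#' returned, otherwise the full transitive closure (never including the query
#' term itself). `isA(x, y)` tests whether `x` is `y` or one of its
#' descendants.
#'
#' @param graph an [OntologyGraph-class].
#' @param id,descendant,ancestor term identifiers in any accepted form.
#' @param direct logical; immediate neighbours only?
#' @return a sorted character vector of canonical term ids, or a logical for
#'   `isA()`.
#' @examples
#' g <- loadOntology(generateExampleFixture(tempfile(fileext = ".owl")))
#' termAncestors(g, "kisao:0000039")
#' isA(g, searchByName(g, "binomial tau-leaping method")[[1]]@id, "kisao:0000039")
#' @name hierarchy-queries
NULL

#' @rdname hierarchy-queries
#' @export
termAncestors <- function(graph, id, direct = FALSE) {
  id <- normalizeKisaoId(id)
  .termRow(graph, id)
  if (direct) sort(unique(graph@edges$parent[graph@edges$child == id]))
  else sort(.index(graph)$ancestors[[id]])
}

#' @rdname hierarchy-queries
#' @export
termDescendants <- function(graph, id, direct = FALSE) {
  id <- normalizeKisaoId(id)
  .termRow(graph, id)
  if (direct) sort(unique(graph@edges$child[graph@edges$parent == id]))
  else sort(.index(graph)$descendants[[id]])
}

#' @rdname hierarchy-queries
#' @export
isA <- function(graph, descendant, ancestor) {
  descendant <- normalizeKisaoId(descendant)
  ancestor <- normalizeKisaoId(ancestor)
  .termRow(graph, descendant); .termRow(graph, ancestor)
  descendant == ancestor ||
    ancestor %in% .index(graph)$ancestors[[descendant]]
}

# BFS over the undirected algorithm-branch subclass graph; returns the
# distance from `from` to every algorithm term (NA when unreachable).
.bfsDistances <- function(graph, from) {
  idx <- .index(graph)
  nbr <- idx$algNeighbours
  dist <- stats::setNames(rep(NA_integer_, length(nbr)), names(nbr))
  dist[[from]] <- 0L
  frontier <- from
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- unique(unlist(nbr[frontier], use.names = FALSE))
    nxt <- nxt[is.na(dist[nxt])]
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

#' Hierarchy distance between two algorithms
#'
#' The similarity metric used to rank substitute algorithms: the length of the
#' shortest undirected path between two classes in the subclass graph,
#' restricted to the algorithm branch (its root included). Identical terms
#' have distance 0; a child and its parent distance 1; two children of a
#' common parent (with no shorter route) distance 2. `NA` is returned when no
#' path exists.
#'
#' @param graph an [OntologyGraph-class].
#' @param a,b algorithm-branch term identifiers.
#' @return a non-negative integer, or `NA` if unreachable.
#' @export
hierarchyDistance <- function(graph, a, b) {
  a <- normalizeKisaoId(a); b <- normalizeKisaoId(b)
  .checkBranch(graph, a, "algorithm")
  .checkBranch(graph, b, "algorithm")
  if (a == b) return(0L)
  unname(.bfsDistances(graph, a)[[b]])
}

#' Inferred characteristics and parameters of an algorithm
#'
#' `inferredCharacteristics()` returns every characteristic an algorithm
#' possesses: those asserted on the algorithm itself or inherited from any
#' subclass ancestor, closed upward within the characteristic branch (an
#' algorithm with *stochastic system behaviour* also possesses *type of
#' system behaviour*). `inferredParameters()` returns the parameters asserted
#' on the algorithm or its ancestors; parameters are not generalized upward.
#'
#' @param graph an [OntologyGraph-class].
#' @param algorithm an algorithm-branch term identifier.
#' @return sorted character vector of canonical term ids.
#' @name inferred-links
NULL

#' @rdname inferred-links
#' @export
inferredCharacteristics <- function(graph, algorithm) {
  algorithm <- normalizeKisaoId(algorithm)
  .checkBranch(graph, algorithm, "algorithm")
  .index(graph)$characteristics[[algorithm]]
}

#' @rdname inferred-links
#' @export
inferredParameters <- function(graph, algorithm) {
  algorithm <- normalizeKisaoId(algorithm)
  .checkBranch(graph, algorithm, "algorithm")
  .index(graph)$parameters[[algorithm]]
}
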