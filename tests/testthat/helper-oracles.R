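# Independent oracles computed straight from fixture manifests. They share
# no code with the package's closure index: reachability is naive repeated
# edge expansion, distances come from igraph's BFS, and the query oracles
# are literal brute-force evaluations of the definitions.

oracleAncestors <- function(manifest) {
  ids <- manifest$terms$id
  e <- manifest$edges
  anc <- stats::setNames(lapply(ids, function(i)
    unique(e$parent[e$child == i])), ids)
  repeat {
    changed <- FALSE
    for (i in ids) {
      grown <- unique(c(anc[[i]], unlist(anc[anc[[i]]], use.names = FALSE)))
      if (length(grown) > length(anc[[i]])) {
        anc[[i]] <- grown
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  anc
}

oracleBranch <- function(manifest, anc) {
  ids <- manifest$terms$id
  branch <- stats::setNames(rep("other", length(ids)), ids)
  for (kind in names(manifest$roots)) {
    r <- manifest$roots[[kind]]
    hit <- vapply(ids, function(i) i == r || r %in% anc[[i]], NA)
    branch[hit] <- kind
  }
  branch
}

# fixpoint inference of characteristics: asserted on the algorithm or any
# ancestor, then closed upward within the characteristic branch
oracleCharacteristics <- function(manifest, anc, branch, alg) {
  l <- manifest$links
  sup <- c(alg, anc[[alg]])
  asserted <- l$object[l$relation == "has_characteristic" & l$subject %in% sup]
  chars <- unique(asserted)
  repeat {
    up <- unlist(anc[chars], use.names = FALSE)
    up <- up[branch[up] == "characteristic"]
    grown <- unique(c(chars, up))
    if (length(grown) == length(chars)) break
    chars <- grown
  }
  sort(chars)
}

oracleInherited <- function(manifest, anc, alg, relation) {
  l <- manifest$links
  sup <- c(alg, anc[[alg]])
  sort(unique(l$object[l$relation == relation & l$subject %in% sup]))
}

# BFS distance oracle over the undirected algorithm-branch subclass graph
oracleDistanceMatrix <- function(manifest, branch) {
  algIds <- names(branch)[branch == "algorithm"]
  e <- manifest$edges
  e <- e[e$child %in% algIds & e$parent %in% algIds, , drop = FALSE]
  ig <- igraph::graph_from_data_frame(
    e, directed = FALSE,
    vertices = data.frame(name = algIds))
  d <- igraph::distances(ig)
  d[algIds, algIds, drop = FALSE]
}

oracleLiveAlgorithms <- function(manifest, branch) {
  live <- !manifest$terms$deprecated
  sort(manifest$terms$id[branch[manifest$terms$id] == "algorithm" & live])
}

# Full oracle bundle for one manifest, computed once and cached
oracleBundle <- function(manifest) {
  anc <- oracleAncestors(manifest)
  branch <- oracleBranch(manifest, anc)
  algIds <- names(branch)[branch == "algorithm"]
  list(
    anc = anc,
    branch = branch,
    algIds = algIds,
    live = oracleLiveAlgorithms(manifest, branch),
    chars = stats::setNames(lapply(algIds, function(a)
      oracleCharacteristics(manifest, anc, branch, a)), algIds),
    params = stats::setNames(lapply(algIds, function(a)
      oracleInherited(manifest, anc, a, "has_parameter")), algIds),
    hybrids = stats::setNames(lapply(algIds, function(a)
      oracleInherited(manifest, anc, a, "is_hybrid_of")), algIds),
    dist = oracleDistanceMatrix(manifest, branch)
  )
}

oracleFilterChars <- function(chars, types, anc, branch) {
  if (is.null(types)) return(chars)
  keep <- unique(unlist(lapply(types, function(ty) {
    ids <- names(branch)
    c(ty, ids[vapply(ids, function(i) ty %in% anc[[i]], NA)])
  })))
  sort(intersect(chars, keep))
}

# brute-force n-most-similar: filter candidates by profile equality, rank by
# BFS distance then id, truncate
oracleNMostSimilar <- function(orc, alg, n, types = NULL) {
  target <- oracleFilterChars(orc$chars[[alg]], types, orc$anc, orc$branch)
  cands <- setdiff(orc$live, alg)
  cands <- cands[vapply(cands, function(a)
    setequal(oracleFilterChars(orc$chars[[a]], types, orc$anc, orc$branch),
             target), NA)]
  if (!length(cands) || n == 0)
    return(data.frame(id = character(), distance = numeric()))
  d <- orc$dist[alg, cands]
  ord <- order(is.infinite(d), d, cands)
  keep <- ord[seq_len(min(n, length(ord)))]
  data.frame(id = cands[keep], distance = unname(d[keep]))
}
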