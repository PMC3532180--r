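# KiSAO-shaped fixture generators. Two kinds:
#  * the deterministic "worked example" fixture: a minimal ontology carrying
#    the tau-leaping algorithm family, LSODE, the behaviour/variable
#    characteristics and the tau-leaping epsilon parameter;
#  * seeded random ontologies with a ground-truth manifest, used as the
#    substrate for oracle-based property testing.
# A manifest holds exactly the axiom set the serialized OWL file encodes.

newManifest <- function(terms, synonyms = NULL, xrefs = NULL,
                        edges = NULL, links = NULL,
                        roots, seed = NA_integer_) {
  empty <- function(cols) {
    df <- as.data.frame(stats::setNames(rep(list(character()), length(cols)),
                                        cols))
    df
  }
  m <- list(
    terms = terms,
    synonyms = if (is.null(synonyms)) empty(c("id", "text", "scope")) else synonyms,
    xrefs = if (is.null(xrefs)) empty(c("id", "link")) else xrefs,
    edges = if (is.null(edges)) empty(c("child", "parent")) else edges,
    links = if (is.null(links)) empty(c("subject", "relation", "object")) else links,
    roots = roots,
    seed = seed
  )
  class(m) <- "FixtureManifest"
  m
}

#' @export
print.FixtureManifest <- function(x, ...) {
  cat(sprintf(
    "FixtureManifest: %d terms, %d subclass edges, %d link axioms (seed %s)\n",
    nrow(x$terms), nrow(x$edges), nrow(x$links),
    ifelse(is.na(x$seed), "none", x$seed)))
  invisible(x)
}

.mkTerms <- function(id, label, definition = NA_character_,
                     deprecated = FALSE) {
  data.frame(id = id, label = label, definition = definition,
             deprecated = deprecated)
}

#' Term ids used by the worked-example fixture
#'
#' Terms with an established KiSAO id keep it (tau-leaping method 0000039,
#' LSODE 0000071, the three branch roots); the remaining terms carry
#' synthetic ids from the reserved 9000000+ range so they can never shadow a
#' real release id.
#'
#' @format named character vector of canonical 7-digit term ids.
#' @export
EXAMPLE_FIXTURE_IDS <- c(
  algorithm_root       = "0000000",
  characteristic_root  = "0000097",
  parameter_root       = "0000201",
  tau_leaping          = "0000039",
  lsode                = "0000071",
  poisson_tau_leaping  = "9000001",
  binomial_tau_leaping = "9000002",
  multinomial_tau_leaping = "9000003",
  implicit_tau_leaping = "9000004",
  type_of_system_behaviour = "9000101",
  stochastic_behaviour = "9000102",
  deterministic_behaviour = "9000103",
  type_of_variable     = "9000104",
  discrete_variable    = "9000105",
  continuous_variable  = "9000106",
  tau_leaping_epsilon  = "9000201"
)

#' The worked-example fixture: the tau-leaping family and LSODE
#'
#' A small, fully deterministic KiSAO-shaped ontology. The algorithm branch
#' holds the *tau-leaping method* (kisao:0000039, exact synonym `tauL`) with
#' its Poisson, binomial, multinomial and implicit subclasses, and *LSODE*
#' (kisao:0000071). Tau-leaping is linked to *stochastic system behaviour*
#' and *discrete variable* (so the variants inherit both), LSODE to
#' *deterministic system behaviour* and *continuous variable*; tau-leaping
#' has the parameter *tau-leaping epsilon*, typed `double`. Terms without an
#' established KiSAO id carry synthetic ids in the 9000000+ range; the
#' mapping is in [EXAMPLE_FIXTURE_IDS] and the returned manifest.
#'
#' @return a `FixtureManifest`; `generateExampleFixture()` additionally writes
#'   the OWL RDF/XML file and returns `path`.
#' @param path where `generateExampleFixture()` writes the OWL file.
#' @examples
#' g <- loadOntology(generateExampleFixture(tempfile(fileext = ".owl")))
#' searchById(g, "KISAO:0000039")
#' @export
exampleFixtureManifest <- function() {
  k <- EXAMPLE_FIXTURE_IDS
  terms <- .mkTerms(
    id = unname(k),
    label = c("modelling and simulation algorithm",
              "modelling and simulation algorithm characteristic",
              "modelling and simulation algorithm parameter",
              "tau-leaping method",
              "LSODE",
              "Poisson tau-leaping method",
              "binomial tau-leaping method",
              "multinomial tau-leaping method",
              "implicit tau-leaping method",
              "type of system behaviour",
              "stochastic system behaviour",
              "deterministic system behaviour",
              "type of variable",
              "discrete variable",
              "continuous variable",
              "tau-leaping epsilon"),
    definition = c(NA, NA, NA,
                   "Approximate acceleration of the stochastic simulation algorithm that fires several reactions per time leap tau.",
                   "Livermore Solver for Ordinary Differential Equations.",
                   rep(NA, 11))
  )
  synonyms <- data.frame(
    id = c(k[["tau_leaping"]], k[["lsode"]]),
    text = c("tauL", "Livermore Solver for Ordinary Differential Equations"),
    scope = c("exact", "exact")
  )
  xrefs <- data.frame(
    id = k[["tau_leaping"]],
    link = "http://identifiers.org/doi/10.1063/1.1378322"
  )
  edges <- data.frame(
    child = c(k[["tau_leaping"]], k[["lsode"]],
              k[["poisson_tau_leaping"]], k[["binomial_tau_leaping"]],
              k[["multinomial_tau_leaping"]], k[["implicit_tau_leaping"]],
              k[["type_of_system_behaviour"]], k[["type_of_variable"]],
              k[["stochastic_behaviour"]], k[["deterministic_behaviour"]],
              k[["discrete_variable"]], k[["continuous_variable"]],
              k[["tau_leaping_epsilon"]]),
    parent = c(k[["algorithm_root"]], k[["algorithm_root"]],
               rep(k[["tau_leaping"]], 4),
               rep(k[["characteristic_root"]], 2),
               rep(k[["type_of_system_behaviour"]], 2),
               rep(k[["type_of_variable"]], 2),
               k[["parameter_root"]])
  )
  links <- data.frame(
    subject = c(k[["tau_leaping"]], k[["tau_leaping"]],
                k[["lsode"]], k[["lsode"]],
                k[["tau_leaping"]], k[["tau_leaping_epsilon"]]),
    relation = c("has_characteristic", "has_characteristic",
                 "has_characteristic", "has_characteristic",
                 "has_parameter", "has_type"),
    object = c(k[["stochastic_behaviour"]], k[["discrete_variable"]],
               k[["deterministic_behaviour"]], k[["continuous_variable"]],
               k[["tau_leaping_epsilon"]], "double")
  )
  newManifest(terms, synonyms, xrefs, edges, links,
              roots = c(algorithm = k[["algorithm_root"]],
                        characteristic = k[["characteristic_root"]],
                        parameter = k[["parameter_root"]]))
}

#' @rdname exampleFixtureManifest
#' @export
generateExampleFixture <- function(path) {
  writeOntologyOwl(exampleFixtureManifest(), path)
}

#' Generate a seeded random KiSAO-shaped ontology
#'
#' Emits a random ontology with three DAG-shaped branches under the standard
#' roots, random typed link axioms, random annotations (labels, typed
#' synonyms, definitions, literature links) and a configurable fraction of
#' deprecated terms. The same seed always yields the identical manifest and,
#' via [writeOntologyOwl()], a byte-identical OWL file. The manifest is the
#' ground truth used by the test-suite oracles.
#'
#' @param nAlgorithms,nCharacteristics,nParameters branch sizes (>= 0),
#'   excluding the branch roots.
#' @param maxParents maximum number of subclass parents per term (>= 1);
#'   parents are sampled among earlier terms of the same branch, so each
#'   branch stays a rooted DAG.
#' @param linkDensity probability that any given algorithm/characteristic or
#'   algorithm/parameter pair is linked (0..1).
#' @param deprecatedFraction expected fraction of deprecated terms.
#' @param hybridFraction expected fraction of algorithms carrying
#'   `is_hybrid_of` links (each such algorithm points at two others).
#' @param seed integer RNG seed; the global RNG state is left untouched.
#' @return a `FixtureManifest`.
#' @examples
#' m <- generateRandomOntology(10, 4, 3, seed = 1)
#' g <- loadOntology(writeOntologyOwl(m, tempfile(fileext = ".owl")))
#' nrow(kisaoTerms(g))
#' @export
generateRandomOntology <- function(nAlgorithms, nCharacteristics, nParameters,
                                   maxParents = 3, linkDensity = 0.15,
                                   deprecatedFraction = 0.1,
                                   hybridFraction = 0.05, seed) {
  stopifnot(nAlgorithms >= 0, nCharacteristics >= 0, nParameters >= 0,
            maxParents >= 1, linkDensity >= 0, linkDensity <= 1,
            deprecatedFraction >= 0, deprecatedFraction <= 1)
  if (missing(seed)) usageError("a seed is required for reproducible fixtures")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  roots <- c(algorithm = "0000000", characteristic = "0000097",
             parameter = "0000201")
  mkIds <- function(n, offset) sprintf("%07d", offset + seq_len(n))
  algIds <- mkIds(nAlgorithms, 9100000L)
  chrIds <- mkIds(nCharacteristics, 9300000L)
  parIds <- mkIds(nParameters, 9500000L)

  branchEdges <- function(ids, root) {
    if (!length(ids)) return(NULL)
    do.call(rbind, lapply(seq_along(ids), function(i) {
      pool <- c(root, ids[seq_len(i - 1L)])
      k <- sample.int(min(maxParents, length(pool)), 1L)
      data.frame(child = ids[i], parent = sample(pool, k))
    }))
  }
  edges <- rbind(branchEdges(algIds, roots[["algorithm"]]),
                 branchEdges(chrIds, roots[["characteristic"]]),
                 branchEdges(parIds, roots[["parameter"]]))
  if (is.null(edges)) edges <- data.frame(child = character(),
                                          parent = character())

  ids <- c(unname(roots), algIds, chrIds, parIds)
  kind <- c("algorithm root", "characteristic root", "parameter root",
            rep("algorithm", nAlgorithms),
            rep("characteristic", nCharacteristics),
            rep("parameter", nParameters))
  terms <- .mkTerms(
    id = ids,
    label = paste("synthetic", kind, ids),
    definition = ifelse(stats::runif(length(ids)) < 0.3,
                        paste("synthetic definition of term", ids),
                        NA_character_),
    deprecated = c(rep(FALSE, 3),
                   stats::runif(length(ids) - 3) < deprecatedFraction)
  )

  synRows <- lapply(ids, function(id) {
    n <- sample(0:2, 1L, prob = c(0.5, 0.3, 0.2))
    if (!n) return(NULL)
    data.frame(id = id,
               text = paste0("syn-", id, "-", seq_len(n)),
               scope = sample(SYNONYM_SCOPES, n, replace = TRUE))
  })
  synonyms <- do.call(rbind, synRows)
  xrefs <- do.call(rbind, lapply(ids, function(id) {
    if (stats::runif(1) > 0.2) return(NULL)
    data.frame(id = id, link = paste0("http://identifiers.org/pubmed/",
                                      sample.int(1e6, 1L)))
  }))

  pairLinks <- function(subjects, objects, relation) {
    if (!length(subjects) || !length(objects)) return(NULL)
    grid <- expand.grid(subject = subjects, object = objects,
                        stringsAsFactors = FALSE)
    grid <- grid[stats::runif(nrow(grid)) < linkDensity, , drop = FALSE]
    if (!nrow(grid)) return(NULL)
    data.frame(subject = grid$subject, relation = relation,
               object = grid$object)
  }
  links <- rbind(pairLinks(algIds, chrIds, "has_characteristic"),
                 pairLinks(algIds, parIds, "has_parameter"))
  if (length(algIds) >= 3) {
    hybrids <- algIds[stats::runif(length(algIds)) < hybridFraction]
    for (h in hybrids) {
      tgt <- sample(setdiff(algIds, h), 2L)
      links <- rbind(links, data.frame(subject = h, relation = "is_hybrid_of",
                                       object = tgt))
    }
  }
  if (length(parIds)) {
    typed <- parIds[stats::runif(length(parIds)) < 0.8]
    if (length(typed))
      links <- rbind(links, data.frame(
        subject = typed, relation = "has_type",
        object = sample(c("double", "integer", "boolean"), length(typed),
                        replace = TRUE)))
  }
  if (is.null(links)) links <- data.frame(subject = character(),
                                          relation = character(),
                                          object = character())
  rownames(terms) <- rownames(edges) <- rownames(links) <- NULL
  newManifest(terms, synonyms, xrefs, edges, links, roots,
              seed = as.integer(seed))
}

#' Write a fixture manifest as TSV tables
#'
#' Dumps the ground-truth tables (`terms.tsv`, `synonyms.tsv`, `xrefs.tsv`,
#' `edges.tsv`, `links.tsv`, `meta.tsv`) into a directory, for use outside R.
#'
#' @param manifest a `FixtureManifest`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeManifestTsv <- function(manifest, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dump <- function(df, name)
    utils::write.table(df, file.path(dir, paste0(name, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "")
  dump(manifest$terms, "terms")
  dump(manifest$synonyms, "synonyms")
  dump(manifest$xrefs, "xrefs")
  dump(manifest$edges, "edges")
  dump(manifest$links, "links")
  dump(data.frame(key = c("seed", names(manifest$roots)),
                  value = c(manifest$seed, unname(manifest$roots))), "meta")
  invisible(dir)
}
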