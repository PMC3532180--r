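# Shared fixture pool. Fixtures are generated once per test run and cached
# (manifest, serialized OWL file, loaded graph, oracle bundle); sizes are a
# deterministic function of the seed, spanning small to 200-algorithm
# ontologies.

.fixtureCache <- new.env(parent = emptyenv())

fixtureSizes <- function(seed) {
  list(
    nAlgorithms = 3L + (seed * 37L) %% 198L,       # 3..200
    nCharacteristics = 2L + (seed * 17L) %% 59L,   # 2..60
    nParameters = (seed * 11L) %% 41L,             # 0..40
    maxParents = 1L + seed %% 3L,
    linkDensity = 0.05 + 0.04 * (seed %% 5L)
  )
}

poolFixture <- function(seed) {
  key <- as.character(seed)
  if (!is.null(.fixtureCache[[key]])) return(.fixtureCache[[key]])
  sz <- fixtureSizes(seed)
  manifest <- generateRandomOntology(
    sz$nAlgorithms, sz$nCharacteristics, sz$nParameters,
    maxParents = sz$maxParents, linkDensity = sz$linkDensity, seed = seed)
  owl <- tempfile(sprintf("fixture-%d-", seed), fileext = ".owl")
  writeOntologyOwl(manifest, owl)
  fx <- list(seed = seed, manifest = manifest, owl = owl,
             graph = loadOntology(owl, quiet = TRUE))
  .fixtureCache[[key]] <- fx
  fx
}

poolOracle <- function(seed) {
  key <- paste0("orc", seed)
  if (is.null(.fixtureCache[[key]]))
    .fixtureCache[[key]] <- oracleBundle(poolFixture(seed)$manifest)
  .fixtureCache[[key]]
}

exampleGraph <- function() {
  if (is.null(.fixtureCache$example)) {
    owl <- tempfile("example-", fileext = ".owl")
    generateExampleFixture(owl)
    .fixtureCache$example <- list(owl = owl, graph = loadOntology(owl),
                                manifest = exampleFixtureManifest())
  }
  .fixtureCache$example
}

# seeds used by the oracle-equivalence acceptance sweep
ORACLE_SEEDS <- 1:50

# deterministic per-seed sampler that leaves the global RNG alone
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(expr)
}
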