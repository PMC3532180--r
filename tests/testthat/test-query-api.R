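# The Table-1/Table-2 query surface, checked on the worked-example fixture
# and against brute-force manifest oracles on random fixtures.

QUERY_SEEDS <- c(6, 14, 27, 35)

test_that("listing returns each branch sorted by id with deprecation flags", {
  pg <- exampleGraph()
  algs <- listTerms(pg$graph, "algorithm")
  expect_true(all(c("tau-leaping method", "LSODE") %in% algs$label))
  expect_identical(algs$id, sort(algs$id))
  for (seed in c(6, 14)) {
    fx <- poolFixture(seed)
    orc <- poolOracle(seed)
    for (b in c("algorithm", "characteristic", "parameter")) {
      got <- listTerms(fx$graph, b)
      expect_setequal(got$id, names(orc$branch)[orc$branch == b])
      expect_identical(got$deprecated,
                       fx$manifest$terms$deprecated[match(got$id,
                                                          fx$manifest$terms$id)])
    }
  }
  empty <- loadOntology(writeOntologyOwl(
    kisaoquery:::newManifest(
      terms = data.frame(id = character(), label = character(),
                         definition = character(), deprecated = logical()),
      roots = c(algorithm = "0000000", characteristic = "0000097",
                parameter = "0000201")),
    tempfile(fileext = ".owl")), quiet = TRUE)
  expect_identical(nrow(listTerms(empty, "algorithm")), 0L)
})

test_that("term kind and its boolean shorthands follow branch assignment", {
  g <- exampleGraph()$graph
  k <- EXAMPLE_FIXTURE_IDS
  expect_identical(termBranch(g, k[["tau_leaping"]]), "algorithm")
  expect_identical(termBranch(g, k[["tau_leaping_epsilon"]]), "parameter")
  expect_true(isAlgorithm(g, k[["algorithm_root"]]))
  expect_true(isCharacteristic(g, k[["characteristic_root"]]))
  expect_true(isParameter(g, k[["parameter_root"]]))
  expect_false(isAlgorithm(g, k[["stochastic_behaviour"]]))
  expect_error(termBranch(g, "kisao:7654321"),
               class = "kisao_unknown_term_error")
})

test_that("searchById resolves every identifier form to the same term", {
  g <- exampleGraph()$graph
  for (form in c("KISAO:0000039", "kisao:0000039", "KISAO_0000039",
                 "urn:miriam:biomodels.kisao:KISAO_0000039",
                 "http://identifiers.org/biomodels.kisao/KISAO_0000039")) {
    expect_identical(searchById(g, form)@label, "tau-leaping method",
                     info = form)
  }
  expect_error(searchById(g, "kisao:1111111"),
               class = "kisao_unknown_term_error")
  expect_error(searchById(g, "junk"), class = "kisao_id_error")
})

test_that("searchByName matches labels and synonyms case-insensitively", {
  g <- exampleGraph()$graph
  hit <- searchByName(g, "tauL")
  expect_length(hit, 1L)
  expect_identical(hit[[1]]@id, "0000039")
  expect_identical(searchByName(g, "TAU-LEAPING METHOD")[[1]]@id, "0000039")
  expect_length(searchByName(g, "no such algorithm"), 0L)
  expect_gte(length(searchByName(g, "tau-leaping", substring = TRUE)), 5L)
  # every manifest label and synonym is findable on a random fixture
  fx <- poolFixture(14)
  some <- withSeed(140, sample(nrow(fx$manifest$terms),
                               min(15, nrow(fx$manifest$terms))))
  for (i in some) {
    ids <- vapply(searchByName(fx$graph, fx$manifest$terms$label[i]),
                  function(t) t@id, "")
    expect_true(fx$manifest$terms$id[i] %in% ids)
  }
  if (nrow(fx$manifest$synonyms)) {
    s <- fx$manifest$synonyms[1, ]
    ids <- vapply(searchByName(fx$graph, s$text), function(t) t@id, "")
    expect_true(s$id %in% ids)
  }
})

test_that("annotation accessors return the stored bundle, scope filters work", {
  g <- exampleGraph()$graph
  k <- EXAMPLE_FIXTURE_IDS
  syn <- termSynonyms(g, k[["tau_leaping"]])
  expect_true("tauL" %in% syn$text)
  expect_identical(termSynonyms(g, k[["tau_leaping"]], scope = "exact")$text,
                   "tauL")
  expect_identical(nrow(termSynonyms(g, k[["tau_leaping"]],
                                     scope = "narrow")), 0L)
  expect_match(termDefinition(g, k[["tau_leaping"]]), "tau")
  expect_match(termLinks(g, k[["tau_leaping"]]), "doi")
  expect_false(isDeprecated(g, k[["tau_leaping"]]))
  # bare term: empty annotations, deprecated FALSE
  expect_true(is.na(termDefinition(g, k[["discrete_variable"]])))
  expect_identical(termLinks(g, k[["discrete_variable"]]), character())
  # round-trip against a random manifest
  fx <- poolFixture(27)
  m <- fx$manifest
  some <- withSeed(270, sample(m$terms$id, 10))
  for (id in some) {
    expect_identical(termLabel(fx$graph, id),
                     m$terms$label[m$terms$id == id])
    expect_setequal(termSynonyms(fx$graph, id)$text,
                    m$synonyms$text[m$synonyms$id == id])
    expect_identical(isDeprecated(fx$graph, id),
                     m$terms$deprecated[m$terms$id == id])
  }
})

test_that("characteristicsOf honours the type filter", {
  g <- exampleGraph()$graph
  k <- EXAMPLE_FIXTURE_IDS
  expect_identical(
    characteristicsOf(g, k[["poisson_tau_leaping"]],
                      types = k[["type_of_system_behaviour"]]),
    sort(c(k[["stochastic_behaviour"]], k[["type_of_system_behaviour"]])))
  expect_identical(characteristicsOf(g, k[["poisson_tau_leaping"]],
                                     types = character()), character())
  expect_error(characteristicsOf(g, k[["poisson_tau_leaping"]],
                                 types = k[["tau_leaping"]]),
               class = "kisao_branch_error")
  # oracle comparison with a random single-type filter
  for (seed in QUERY_SEEDS) {
    fx <- poolFixture(seed); orc <- poolOracle(seed)
    chs <- names(orc$branch)[orc$branch == "characteristic"]
    picks <- withSeed(seed + 3000, list(
      alg = sample(orc$algIds, min(10, length(orc$algIds))),
      ty = sample(chs, 1)))
    for (a in picks$alg) {
      expect_setequal(characteristicsOf(fx$graph, a, types = picks$ty),
                      oracleFilterChars(orc$chars[[a]], picks$ty, orc$anc,
                                        orc$branch))
    }
  }
})

test_that("hasCharacteristic is conjunctive over inferred sets", {
  g <- exampleGraph()$graph
  k <- EXAMPLE_FIXTURE_IDS
  expect_true(hasCharacteristic(g, k[["poisson_tau_leaping"]],
                                k[["stochastic_behaviour"]]))
  expect_true(hasCharacteristic(g, k[["poisson_tau_leaping"]],
                                c(k[["stochastic_behaviour"]],
                                  k[["discrete_variable"]])))
  expect_false(hasCharacteristic(g, k[["lsode"]], k[["stochastic_behaviour"]]))
  expect_true(hasCharacteristic(g, k[["lsode"]], character()))
  fx <- poolFixture(6); orc <- poolOracle(6)
  chs <- names(orc$branch)[orc$branch == "characteristic"]
  cases <- withSeed(61, replicate(10, list(
    a = sample(orc$algIds, 1), cs = sample(chs, sample(1:3, 1))),
    simplify = FALSE))
  for (cse in cases) {
    expect_identical(hasCharacteristic(fx$graph, cse$a, cse$cs),
                     all(cse$cs %in% orc$chars[[cse$a]]))
  }
})

test_that("possess and lack partition the non-deprecated algorithms", {
  fxs <- lapply(QUERY_SEEDS, poolFixture)
  orcs <- lapply(QUERY_SEEDS, poolOracle)
  for (j in seq_along(fxs)) {
    orc <- orcs[[j]]; g <- fxs[[j]]$graph
    chs <- names(orc$branch)[orc$branch == "characteristic"]
    sets <- withSeed(QUERY_SEEDS[j] + 4000,
                     replicate(5, sample(chs, sample(1:3, 1)),
                               simplify = FALSE))
    for (cs in sets) {
      pos <- algorithmsByCharacteristics(g, cs, "possess")
      lac <- algorithmsByCharacteristics(g, cs, "lack")
      expect_length(intersect(pos, lac), 0L)
      expect_setequal(c(pos, lac), orc$live)
      # brute-force check of the possess set
      expect_setequal(pos, orc$live[vapply(orc$live, function(a)
        all(cs %in% orc$chars[[a]]), NA)])
    }
  }
})

test_that("same-characteristics means set equality of filtered profiles", {
  g <- exampleGraph()$graph
  k <- EXAMPLE_FIXTURE_IDS
  fam <- k[c("tau_leaping", "binomial_tau_leaping",
             "multinomial_tau_leaping", "implicit_tau_leaping")]
  expect_setequal(
    algorithmsWithSameCharacteristics(
      g, k[["poisson_tau_leaping"]],
      types = k[c("type_of_system_behaviour", "type_of_variable")]),
    unname(fam))
  # LSODE's full profile is unique in the fixture
  expect_length(algorithmsWithSameCharacteristics(g, k[["lsode"]]), 0L)
  for (seed in c(14, 35)) {
    fx <- poolFixture(seed); orc <- poolOracle(seed)
    picks <- withSeed(seed + 5000, sample(orc$algIds,
                                          min(8, length(orc$algIds))))
    for (a in picks) {
      want <- setdiff(orc$live, a)
      want <- want[vapply(want, function(b)
        setequal(orc$chars[[b]], orc$chars[[a]]), NA)]
      expect_setequal(algorithmsWithSameCharacteristics(fx$graph, a), want)
    }
  }
})

test_that("nMostSimilar ranks by distance with id tie-break and excludes self", {
  for (seed in QUERY_SEEDS) {
    fx <- poolFixture(seed); orc <- poolOracle(seed)
    picks <- withSeed(seed + 6000, sample(orc$algIds,
                                          min(5, length(orc$algIds))))
    for (a in picks) {
      got <- nMostSimilar(fx$graph, a, 6)
      want <- oracleNMostSimilar(orc, a, 6)
      expect_identical(got$id, want$id)
      expect_false(a %in% got$id)
      d <- got$distance
      d[is.na(d)] <- Inf
      expect_true(all(diff(d) >= 0))
      # every excluded candidate sits at >= the last included distance
      all10 <- oracleNMostSimilar(orc, a, .Machine$integer.max)
      if (nrow(all10) > nrow(got) && nrow(got))
        expect_true(all(all10$distance[-seq_len(nrow(got))] >=
                          max(d[is.finite(d)], 0)))
    }
  }
  g <- exampleGraph()$graph
  expect_identical(nrow(nMostSimilar(g, EXAMPLE_FIXTURE_IDS[["poisson_tau_leaping"]], 0)), 0L)
  expect_error(nMostSimilar(g, EXAMPLE_FIXTURE_IDS[["poisson_tau_leaping"]], -1),
               class = "kisao_usage_error")
})

test_that("boolean queries match truth-table brute force", {
  g <- exampleGraph()$graph
  k <- EXAMPLE_FIXTURE_IDS
  expect_setequal(
    algorithmsByQuery(g, sprintf("kisao:%s", k[["stochastic_behaviour"]])),
    algorithmsByCharacteristics(g, k[["stochastic_behaviour"]], "possess"))
  expect_setequal(
    algorithmsByQuery(g, sprintf("NOT kisao:%s", k[["stochastic_behaviour"]])),
    algorithmsByCharacteristics(g, k[["stochastic_behaviour"]], "lack"))
  expect_setequal(
    algorithmsByQuery(g, '"stochastic system behaviour" and "tau-leaping epsilon"'),
    intersect(
      algorithmsByCharacteristics(g, k[["stochastic_behaviour"]], "possess"),
      algorithmsByQuery(g, '"tau-leaping epsilon"')))
  # random expressions on random fixtures
  for (seed in c(6, 27)) {
    fx <- poolFixture(seed); orc <- poolOracle(seed)
    chs <- names(orc$branch)[orc$branch == "characteristic"]
    prs <- names(orc$branch)[orc$branch == "parameter"]
    atoms <- withSeed(seed + 7000, sample(c(chs, prs), 3, replace = TRUE))
    memberOf <- function(a, atom) {
      if (orc$branch[[atom]] == "characteristic") atom %in% orc$chars[[a]]
      else atom %in% orc$params[[a]]
    }
    qstr <- sprintf("(kisao:%s OR NOT kisao:%s) AND NOT (kisao:%s)",
                    atoms[1], atoms[2], atoms[3])
    want <- orc$live[vapply(orc$live, function(a)
      (memberOf(a, atoms[1]) || !memberOf(a, atoms[2])) &&
        !memberOf(a, atoms[3]), NA)]
    expect_setequal(algorithmsByQuery(fx$graph, qstr), want)
  }
  expect_error(algorithmsByQuery(g, "kisao:0000039 AND"),
               class = "kisao_query_error")
  expect_error(algorithmsByQuery(g, '"no such label"'),
               class = "kisao_query_error")
  expect_error(algorithmsByQuery(g, "kisao:0000039"),  # algorithm atom
               class = "kisao_query_error")
})

test_that("parameter queries return inferred parameters and declared types", {
  g <- exampleGraph()$graph
  k <- EXAMPLE_FIXTURE_IDS
  expect_identical(algorithmParameters(g, k[["tau_leaping"]]),
                   unname(k[["tau_leaping_epsilon"]]))
  # variants inherit the parameter from the tau-leaping method
  expect_identical(algorithmParameters(g, k[["poisson_tau_leaping"]]),
                   unname(k[["tau_leaping_epsilon"]]))
  expect_identical(algorithmParameters(g, k[["lsode"]]), character())
  expect_identical(parameterType(g, k[["tau_leaping_epsilon"]]), "double")
  # untyped parameter: absent signal, not a crash
  m <- exampleFixtureManifest()
  m$links <- m$links[m$links$relation != "has_type", ]
  g2 <- loadOntology(writeOntologyOwl(m, tempfile(fileext = ".owl")),
                     quiet = TRUE)
  expect_true(is.na(parameterType(g2, k[["tau_leaping_epsilon"]])))
  expect_error(parameterType(g, k[["tau_leaping"]]),
               class = "kisao_branch_error")
})

test_that("parametersByCharacteristics unions over matching algorithms", {
  g <- exampleGraph()$graph
  k <- EXAMPLE_FIXTURE_IDS
  expect_identical(
    parametersByCharacteristics(g, c(k[["stochastic_behaviour"]],
                                     k[["discrete_variable"]])),
    unname(k[["tau_leaping_epsilon"]]))
  expect_identical(
    parametersByCharacteristics(g, k[["deterministic_behaviour"]]),
    character())
  expect_identical(
    parametersByCharacteristics(g, k[["stochastic_behaviour"]],
                                ancestor = k[["tau_leaping"]]),
    unname(k[["tau_leaping_epsilon"]]))
  for (seed in c(14, 35)) {
    fx <- poolFixture(seed); orc <- poolOracle(seed)
    chs <- names(orc$branch)[orc$branch == "characteristic"]
    cs <- withSeed(seed + 8000, sample(chs, 2))
    matching <- orc$live[vapply(orc$live, function(a)
      all(cs %in% orc$chars[[a]]), NA)]
    want <- sort(unique(unlist(orc$params[matching], use.names = FALSE)))
    expect_setequal(parametersByCharacteristics(fx$graph, cs), want)
  }
})

test_that("hasParameter handles algorithm and characteristic-set subjects", {
  g <- exampleGraph()$graph
  k <- EXAMPLE_FIXTURE_IDS
  expect_true(hasParameter(g, k[["tau_leaping"]], k[["tau_leaping_epsilon"]]))
  expect_false(hasParameter(g, k[["lsode"]], k[["tau_leaping_epsilon"]]))
  expect_true(hasParameter(g, k[["stochastic_behaviour"]],
                           k[["tau_leaping_epsilon"]]))
  expect_false(hasParameter(g, k[["deterministic_behaviour"]],
                            k[["tau_leaping_epsilon"]]))
  expect_true(hasParameter(g, k[["lsode"]], character()))
  expect_error(hasParameter(g, k[["tau_leaping_epsilon"]],
                            k[["tau_leaping_epsilon"]]),
               class = "kisao_branch_error")
})

test_that("hybrid links are detected, inherited, and empty for non-hybrids", {
  g <- exampleGraph()$graph
  expect_false(isHybrid(g, EXAMPLE_FIXTURE_IDS[["tau_leaping"]]))
  expect_identical(hybridOf(g, EXAMPLE_FIXTURE_IDS[["tau_leaping"]]),
                   character())
  # manifest-driven: a hybrid with two targets, and inheritance to a child
  m <- exampleFixtureManifest()
  k <- EXAMPLE_FIXTURE_IDS
  m$terms <- rbind(m$terms,
                   data.frame(id = c("9000301", "9000302"),
                              label = c("synthetic hybrid method",
                                        "synthetic hybrid subtype"),
                              definition = NA, deprecated = FALSE))
  m$edges <- rbind(m$edges,
                   data.frame(child = c("9000301", "9000302"),
                              parent = c(k[["algorithm_root"]], "9000301")))
  m$links <- rbind(m$links,
                   data.frame(subject = "9000301", relation = "is_hybrid_of",
                              object = c(k[["tau_leaping"]], k[["lsode"]])))
  g2 <- loadOntology(writeOntologyOwl(m, tempfile(fileext = ".owl")),
                     quiet = TRUE)
  expect_true(isHybrid(g2, "9000301"))
  expect_setequal(hybridOf(g2, "9000301"),
                  unname(k[c("tau_leaping", "lsode")]))
  expect_setequal(hybridOf(g2, "9000302"),
                  unname(k[c("tau_leaping", "lsode")]))
  expect_error(isHybrid(g2, k[["stochastic_behaviour"]]),
               class = "kisao_branch_error")
})

test_that("consistency: hasCharacteristic matches possess-set membership", {
  fx <- poolFixture(35); orc <- poolOracle(35)
  chs <- names(orc$branch)[orc$branch == "characteristic"]
  sets <- withSeed(350, replicate(3, sample(chs, sample(1:2, 1)),
                                  simplify = FALSE))
  for (cs in sets) {
    pos <- algorithmsByCharacteristics(fx$graph, cs, "possess")
    for (a in orc$live)
      expect_identical(hasCharacteristic(fx$graph, a, cs), a %in% pos)
  }
})
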