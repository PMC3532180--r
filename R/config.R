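#' Ontology parsing configuration
#'
#' Where an ontology attaches its labels, synonyms and relation axioms is a
#' property of the release, not of OWL itself, so [loadOntology()] takes a
#' configuration naming the relevant IRIs. The defaults match KiSAO releases:
#' OBO-in-OWL annotation properties and the three KiSAO branch roots
#' (`kisao:0000000` algorithms, `kisao:0000097` characteristics,
#' `kisao:0000201` parameters).
#'
#' Configuration keys:
#' \describe{
#'   \item{base_iri}{namespace prefix of term IRIs.}
#'   \item{branch_roots}{named list/vector with entries `algorithm`,
#'     `characteristic`, `parameter`; any accepted identifier form.}
#'   \item{relations}{named list mapping the relations `has_characteristic`,
#'     `has_parameter`, `is_hybrid_of`, `has_type` to property IRIs.}
#'   \item{annotations}{named list mapping `label`, `definition`,
#'     `deprecated`, the four synonym scopes (`synonym_exact`,
#'     `synonym_related`, `synonym_broad`, `synonym_narrow`) and `link`
#'     (character vector allowed) to annotation-property IRIs.}
#' }
#'
#' @param path path to a YAML file supplying any subset of the keys above;
#'   unsupplied keys keep their defaults.
#' @return a named list with the keys described above.
#' @examples
#' cfg <- defaultOntologyConfig()
#' cfg$branch_roots
#' @export
defaultOntologyConfig <- function() {
  base <- KISAO_BASE_IRI
  obo <- "http://www.geneontology.org/formats/oboInOwl#"
  list(
    base_iri = base,
    branch_roots = c(
      algorithm      = "0000000",
      characteristic = "0000097",
      parameter      = "0000201"
    ),
    relations = c(
      has_characteristic = paste0(base, "hasCharacteristic"),
      has_parameter      = paste0(base, "hasParameter"),
      is_hybrid_of       = paste0(base, "isHybridOf"),
      has_type           = paste0(base, "hasType")
    ),
    annotations = list(
      label           = "http://www.w3.org/2000/01/rdf-schema#label",
      definition      = "http://purl.obolibrary.org/obo/IAO_0000115",
      deprecated      = "http://www.w3.org/2002/07/owl#deprecated",
      synonym_exact   = paste0(obo, "hasExactSynonym"),
      synonym_related = paste0(obo, "hasRelatedSynonym"),
      synonym_broad   = paste0(obo, "hasBroadSynonym"),
      synonym_narrow  = paste0(obo, "hasNarrowSynonym"),
      link = c("http://www.w3.org/2000/01/rdf-schema#seeAlso",
               paste0(obo, "hasDbXref"))
    )
  )
}

#' @rdname defaultOntologyConfig
#' @export
readOntologyConfig <- function(path) {
  if (!file.exists(path)) ioError("config file not found: %s", path)
  user <- yaml::read_yaml(path)
  cfg <- defaultOntologyConfig()
  for (key in intersect(names(user), names(cfg))) {
    val <- user[[key]]
    if (is.list(cfg[[key]]) || length(cfg[[key]]) > 1L) {
      val <- utils::modifyList(as.list(cfg[[key]]), as.list(val))
      if (!is.list(cfg[[key]])) val <- unlist(val)
    }
    cfg[[key]] <- val
  }
  cfg$branch_roots <- vapply(cfg$branch_roots, normalizeKisaoId, "")
  need <- c("algorithm", "characteristic", "parameter")
  if (!all(need %in% names(cfg$branch_roots)))
    formatError("config branch_roots must name %s", paste(need, collapse = ", "))
  cfg
}
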