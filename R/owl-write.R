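# Deterministic OWL 2 RDF/XML serializer for fixture manifests. Output is a
# function of the manifest alone (stable element ordering, no timestamps), so
# identical manifests yield byte-identical files -- which the fixture
# round-trip and seed-repeatability guarantees rely on.

.xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

XSD_PREFIX <- "http://www.w3.org/2001/XMLSchema#"

#' Serialize a fixture manifest as OWL 2 RDF/XML
#'
#' Writes every term, annotation, subclass axiom and link axiom of a
#' [fixture manifest][generateRandomOntology] as an RDF/XML OWL file of the
#' shape KiSAO releases use: plain `rdfs:subClassOf` resources for the
#' hierarchy and anonymous `owl:Restriction` nodes
#' (`owl:onProperty`/`owl:someValuesFrom`) for the link relations, with
#' OBO-in-OWL annotation properties.
#'
#' @param manifest a `FixtureManifest` (see [generateRandomOntology()]).
#' @param path output file path.
#' @param config parsing configuration supplying the property IRIs; defaults
#'   to [defaultOntologyConfig()].
#' @return `path`, invisibly.
#' @export
writeOntologyOwl <- function(manifest, path, config = defaultOntologyConfig()) {
  base <- config$base_iri
  rel <- config$relations
  ann <- config$annotations
  synProps <- c(exact = ann$synonym_exact, related = ann$synonym_related,
                broad = ann$synonym_broad, narrow = ann$synonym_narrow)

  qname <- function(iri) {
    # map a full property IRI onto one of the declared prefixes
    pre <- c(rdfs = "http://www.w3.org/2000/01/rdf-schema#",
             owl = "http://www.w3.org/2002/07/owl#",
             oboInOwl = "http://www.geneontology.org/formats/oboInOwl#",
             obo = "http://purl.obolibrary.org/obo/",
             kisao = base)
    for (p in names(pre)) {
      if (startsWith(iri, pre[[p]]))
        return(paste0(p, ":", substring(iri, nchar(pre[[p]]) + 1L)))
    }
    formatError("cannot serialize property outside declared namespaces: %s", iri)
  }

  out <- c(
    "<?xml version=\"1.0\"?>",
    "<rdf:RDF xmlns:rdf=\"http://www.w3.org/1999/02/22-rdf-syntax-ns#\"",
    "         xmlns:rdfs=\"http://www.w3.org/2000/01/rdf-schema#\"",
    "         xmlns:owl=\"http://www.w3.org/2002/07/owl#\"",
    "         xmlns:oboInOwl=\"http://www.geneontology.org/formats/oboInOwl#\"",
    "         xmlns:obo=\"http://purl.obolibrary.org/obo/\"",
    sprintf("         xmlns:kisao=\"%s\">", .xmlEscape(base)),
    sprintf("  <owl:Ontology rdf:about=\"%s\"/>",
            .xmlEscape(sub("#$", "", base)))
  )
  for (r in setdiff(names(rel), "has_type"))
    out <- c(out, sprintf("  <owl:ObjectProperty rdf:about=\"%s\"/>",
                          .xmlEscape(rel[[r]])))
  out <- c(out, sprintf("  <owl:DatatypeProperty rdf:about=\"%s\"/>",
                        .xmlEscape(rel[["has_type"]])))

  terms <- manifest$terms[order(manifest$terms$id), , drop = FALSE]
  for (i in seq_len(nrow(terms))) {
    id <- terms$id[i]
    out <- c(out, sprintf("  <owl:Class rdf:about=\"%s\">",
                          .xmlEscape(idToIri(id, base))))
    if (!is.na(terms$label[i]))
      out <- c(out, sprintf("    <%s>%s</%s>", qname(ann$label),
                            .xmlEscape(terms$label[i]), qname(ann$label)))
    syn <- manifest$synonyms[manifest$synonyms$id == id, , drop = FALSE]
    syn <- syn[order(syn$scope, syn$text), , drop = FALSE]
    for (j in seq_len(nrow(syn))) {
      q <- qname(synProps[[syn$scope[j]]])
      out <- c(out, sprintf("    <%s>%s</%s>", q, .xmlEscape(syn$text[j]), q))
    }
    if (!is.na(terms$definition[i]))
      out <- c(out, sprintf("    <%s>%s</%s>", qname(ann$definition[[1]]),
                            .xmlEscape(terms$definition[i]),
                            qname(ann$definition[[1]])))
    xr <- sort(manifest$xrefs$link[manifest$xrefs$id == id])
    for (l in xr) {
      q <- qname(ann$link[[1]])
      out <- c(out, sprintf("    <%s>%s</%s>", q, .xmlEscape(l), q))
    }
    if (isTRUE(terms$deprecated[i]))
      out <- c(out, paste0("    <owl:deprecated rdf:datatype=",
                           "\"http://www.w3.org/2001/XMLSchema#boolean\">",
                           "true</owl:deprecated>"))
    parents <- sort(manifest$edges$parent[manifest$edges$child == id])
    for (p in parents)
      out <- c(out, sprintf("    <rdfs:subClassOf rdf:resource=\"%s\"/>",
                            .xmlEscape(idToIri(p, base))))
    lk <- manifest$links[manifest$links$subject == id, , drop = FALSE]
    lk <- lk[order(lk$relation, lk$object), , drop = FALSE]
    for (j in seq_len(nrow(lk))) {
      objIri <- if (lk$relation[j] == "has_type")
        paste0(XSD_PREFIX, lk$object[j]) else idToIri(lk$object[j], base)
      out <- c(out,
        "    <rdfs:subClassOf>",
        "      <owl:Restriction>",
        sprintf("        <owl:onProperty rdf:resource=\"%s\"/>",
                .xmlEscape(rel[[lk$relation[j]]])),
        sprintf("        <owl:someValuesFrom rdf:resource=\"%s\"/>",
                .xmlEscape(objIri)),
        "      </owl:Restriction>",
        "    </rdfs:subClassOf>")
    }
    out <- c(out, "  </owl:Class>")
  }
  out <- c(out, "</rdf:RDF>")
  writeLines(out, path)
  invisible(path)
}
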