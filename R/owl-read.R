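# OWL 2 RDF/XML reader for KiSAO-shaped ontologies. The XML layer is xml2;
# the interpretation implemented here covers exactly the constructs such
# files use: named owl:Class nodes, plain rdfs:subClassOf resources,
# anonymous owl:Restriction nodes with owl:onProperty + owl:someValuesFrom
# (object restrictions for the link relations, XSD-datatype restrictions for
# parameter types), and OBO-style annotation properties. Anything else is
# recorded, logged with its subject IRI, and skipped -- never fatal.

RDF_NS  <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
RDFS_NS <- "http://www.w3.org/2000/01/rdf-schema#"
OWL_NS  <- "http://www.w3.org/2002/07/owl#"

# expanded "namespace-uri + local-name" of an element; `nsmap` is the
# document's xml_ns() mapping
.expandedName <- function(node, nsmap) {
  nm <- xml2::xml_name(node, nsmap)
  if (grepl(":", nm, fixed = TRUE)) {
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    uri <- unclass(nsmap)[parts[1]]
    if (!is.na(uri)) return(paste0(unname(uri), parts[2]))
  }
  nm
}

.attrResource <- function(node) xml2::xml_attr(node, "resource")

#' Load an OWL ontology into an OntologyGraph
#'
#' Reads an RDF/XML-serialized OWL 2 file (local path or URL) of the shape
#' KiSAO releases use and returns a fully indexed [OntologyGraph-class]:
#' subclass axioms `A subClassOf B` become hierarchy edges, existential
#' restrictions over the configured relation properties become link axioms
#' (`has_characteristic`, `has_parameter`, `is_hybrid_of`, and `has_type`
#' with an XSD datatype object), and annotation properties populate labels,
#' typed synonyms, definitions, literature links and deprecation flags.
#' Branch membership (algorithm / characteristic / parameter / other) is
#' computed from reachability to the configured branch roots, and the
#' transitive closure index is built eagerly.
#'
#' Restrictions over unconfigured properties and other unsupported
#' constructs are skipped with a message naming the subject IRI and recorded
#' in [skippedConstructs()]. A cyclic subclass graph, or a term reachable
#' from two branch roots, is a format error.
#'
#' @param source path or URL of an RDF/XML OWL file.
#' @param config parsing configuration; see [defaultOntologyConfig()] and
#'   [readOntologyConfig()].
#' @param quiet suppress the per-construct skip messages.
#' @return an [OntologyGraph-class].
#' @examples
#' g <- loadOntology(generateExampleFixture(tempfile(fileext = ".owl")))
#' g
#' @export
loadOntology <- function(source, config = defaultOntologyConfig(),
                         quiet = FALSE) {
  isUrl <- grepl("^https?://", source)
  if (!isUrl && !file.exists(source))
    ioError("cannot read ontology source: %s", source)
  doc <- tryCatch(xml2::read_xml(source), error = function(e)
    if (isUrl) ioError("cannot retrieve ontology from %s: %s", source,
                       conditionMessage(e))
    else formatError("not parseable as RDF/XML: %s (%s)", source,
                     conditionMessage(e)))
  nsmap <- xml2::xml_ns(doc)
  rootName <- .expandedName(xml2::xml_root(doc), nsmap)
  if (!identical(rootName, paste0(RDF_NS, "RDF")))
    formatError("not an RDF/XML document (root element is <%s>): %s",
                xml2::xml_name(xml2::xml_root(doc)), source)

  base <- config$base_iri
  relByIri <- stats::setNames(names(config$relations),
                              unname(config$relations))
  ann <- config$annotations
  annLabel <- ann$label; annDef <- ann$definition[[1]]
  annDepr <- ann$deprecated
  synByIri <- c(stats::setNames("exact", ann$synonym_exact),
                stats::setNames("related", ann$synonym_related),
                stats::setNames("broad", ann$synonym_broad),
                stats::setNames("narrow", ann$synonym_narrow))
  linkProps <- unlist(ann$link, use.names = FALSE)

  classes <- xml2::xml_find_all(
    doc, "//owl:Class[@rdf:about]",
    ns = c(owl = OWL_NS, rdf = RDF_NS))

  termRows <- list(); synRows <- list(); xrefRows <- list()
  edgeRows <- list(); linkRows <- list(); skipRows <- list()
  seen <- character()

  note <- function(subject, construct) {
    skipRows[[length(skipRows) + 1L]] <<- data.frame(subject = subject,
                                                     construct = construct)
    if (!quiet) message("skipping unsupported construct for <", subject,
                        ">: ", construct)
  }

  for (cls in classes) {
    iri <- xml2::xml_attr(cls, "about")
    id <- iriToId(iri, base)
    if (is.na(id)) { note(iri, "class outside the term namespace"); next }
    label <- NA_character_; definition <- NA_character_; deprecated <- FALSE
    for (child in xml2::xml_children(cls)) {
      prop <- .expandedName(child, nsmap)
      if (prop == paste0(RDFS_NS, "subClassOf")) {
        res <- .attrResource(child)
        if (!is.na(res)) {
          pid <- iriToId(res, base)
          if (is.na(pid)) note(iri, paste("superclass outside the term namespace:", res))
          else edgeRows[[length(edgeRows) + 1L]] <-
              data.frame(child = id, parent = pid)
          next
        }
        restr <- xml2::xml_children(child)
        if (length(restr) != 1L ||
            .expandedName(restr[[1]], nsmap) != paste0(OWL_NS, "Restriction")) {
          note(iri, "anonymous superclass that is not an owl:Restriction")
          next
        }
        onProp <- someFrom <- NA_character_
        supported <- TRUE
        for (rchild in xml2::xml_children(restr[[1]])) {
          rprop <- .expandedName(rchild, nsmap)
          if (rprop == paste0(OWL_NS, "onProperty"))
            onProp <- .attrResource(rchild)
          else if (rprop == paste0(OWL_NS, "someValuesFrom"))
            someFrom <- .attrResource(rchild)
          else supported <- FALSE
        }
        if (!supported || is.na(onProp) || is.na(someFrom)) {
          note(iri, "restriction using an unsupported filler or quantifier")
          next
        }
        relName <- if (onProp %in% names(relByIri)) relByIri[[onProp]] else NULL
        if (is.null(relName)) {
          note(iri, paste("restriction over unconfigured property:", onProp))
          next
        }
        obj <- if (relName == "has_type") {
          if (!startsWith(someFrom, XSD_PREFIX)) {
            note(iri, paste("has_type filler is not an XSD datatype:", someFrom))
            next
          }
          substring(someFrom, nchar(XSD_PREFIX) + 1L)
        } else {
          oid <- iriToId(someFrom, base)
          if (is.na(oid)) {
            note(iri, paste("restriction filler outside the term namespace:",
                            someFrom))
            next
          }
          oid
        }
        linkRows[[length(linkRows) + 1L]] <-
          data.frame(subject = id, relation = relName, object = obj)
      } else if (prop == annLabel) {
        label <- xml2::xml_text(child)
      } else if (prop == annDef) {
        definition <- xml2::xml_text(child)
      } else if (prop %in% names(synByIri)) {
        synRows[[length(synRows) + 1L]] <-
          data.frame(id = id, text = xml2::xml_text(child),
                     scope = synByIri[[prop]])
      } else if (prop %in% linkProps) {
        res <- .attrResource(child)
        val <- if (!is.na(res)) res else xml2::xml_text(child)
        xrefRows[[length(xrefRows) + 1L]] <- data.frame(id = id, link = val)
      } else if (prop == annDepr) {
        deprecated <- tolower(trimws(xml2::xml_text(child))) == "true"
      }
      # other annotations (comments etc.) are simply ignored
    }
    if (id %in% seen) {
      # merge: a class may be declared in several blocks; keep first row,
      # update annotations if the earlier one was bare
      i <- which(vapply(termRows, function(r) r$id == id, NA))[1]
      if (is.na(termRows[[i]]$label) && !is.na(label)) termRows[[i]]$label <- label
      if (is.na(termRows[[i]]$definition) && !is.na(definition))
        termRows[[i]]$definition <- definition
      termRows[[i]]$deprecated <- termRows[[i]]$deprecated || deprecated
    } else {
      seen <- c(seen, id)
      termRows[[length(termRows) + 1L]] <-
        data.frame(id = id, label = label, definition = definition,
                   deprecated = deprecated)
    }
  }

  terms <- if (length(termRows)) do.call(rbind, termRows) else
    data.frame(id = character(), label = character(),
               definition = character(), deprecated = logical())
  edges <- if (length(edgeRows)) unique(do.call(rbind, edgeRows)) else
    data.frame(child = character(), parent = character())
  links <- if (length(linkRows)) unique(do.call(rbind, linkRows)) else
    data.frame(subject = character(), relation = character(),
               object = character())
  synonyms <- if (length(synRows)) unique(do.call(rbind, synRows)) else
    data.frame(id = character(), text = character(), scope = character())
  xrefs <- if (length(xrefRows)) unique(do.call(rbind, xrefRows)) else
    data.frame(id = character(), link = character())

  # referenced-but-undeclared terms become unlabelled stubs so that every
  # edge/link endpoint resolves
  referenced <- unique(c(edges$child, edges$parent, links$subject,
                         links$object[links$relation != "has_type"]))
  missing <- setdiff(referenced, terms$id)
  if (length(missing))
    terms <- rbind(terms, data.frame(id = missing, label = NA_character_,
                                     definition = NA_character_,
                                     deprecated = FALSE))
  terms <- terms[order(terms$id), , drop = FALSE]
  rownames(terms) <- NULL

  roots <- config$branch_roots[c("algorithm", "characteristic", "parameter")]
  anc <- computeAncestors(terms$id, edges)  # also detects cycles
  terms$branch <- unname(assignBranches(terms$id, anc, roots))

  # link axioms whose subject sits in the wrong branch violate the KiSAO
  # shape; they are recorded and dropped, keeping the graph invariants true
  if (nrow(links)) {
    subjBranch <- terms$branch[match(links$subject, terms$id)]
    wantAlg <- links$relation %in% c("has_characteristic", "has_parameter",
                                     "is_hybrid_of")
    bad <- (wantAlg & subjBranch != "algorithm") |
      (links$relation == "has_type" & subjBranch != "parameter")
    if (any(bad)) {
      for (i in which(bad))
        note(idToIri(links$subject[i], base),
             paste(links$relation[i], "axiom on a", subjBranch[i],
                   "-branch subject"))
      links <- links[!bad, , drop = FALSE]
    }
  }
  rownames(edges) <- rownames(links) <- NULL

  skipped <- if (length(skipRows)) do.call(rbind, skipRows) else
    data.frame(subject = character(), construct = character())

  idx <- new.env(parent = emptyenv())
  idx$skipped <- skipped
  graph <- new("OntologyGraph", terms = terms, synonyms = synonyms,
               xrefs = xrefs, edges = edges, links = links,
               roots = roots, config = config, index = idx)
  idx$closure <- buildClosureIndex(terms, edges, links)
  graph
}

#' Constructs skipped while loading an ontology
#'
#' @param graph an [OntologyGraph-class].
#' @return data.frame with columns `subject` (IRI) and `construct`
#'   (description of what was skipped).
#' @export
skippedConstructs <- function(graph) graph@index$skipped
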