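#' KiSAO term identifiers
#'
#' A KiSAO term identifier is canonically a string of exactly seven decimal
#' digits (e.g. `"0000039"`). Four interchangeable textual renderings are in
#' common use and all are accepted by [normalizeKisaoId()]:
#'
#' * short form: `kisao:0000039`
#' * OWL class IRI: `http://www.biomodels.net/kisao/KISAO#KISAO_0000039`
#' * MIRIAM URN: `urn:miriam:biomodels.kisao:KISAO_0000039`
#' * identifiers.org URL: `http://identifiers.org/biomodels.kisao/KISAO_0000039`
#'
#' The underscore form `KISAO_0000039` and the bare canonical seven digits
#' are accepted as well. Prefix matching is case-insensitive; the digit count
#' is strict (neither six nor eight digits are accepted, so typo forms are
#' rejected rather than silently truncated).
#'
#' @param x character vector of identifiers in any accepted form.
#' @param id character vector of identifiers (normalized internally).
#' @param form one of `"short"`, `"iri"`, `"miriam_urn"`,
#'   `"identifiers_org_url"`.
#' @param baseIri IRI prefix used for the `"iri"` form; the default is the
#'   KiSAO namespace.
#' @return `normalizeKisaoId()` returns the canonical 7-digit form;
#'   `renderKisaoId()` returns the requested textual form.
#' @examples
#' normalizeKisaoId("urn:miriam:biomodels.kisao:KISAO_0000001")
#' renderKisaoId("0000001", "short")
#' @name kisao-identifiers
NULL

KISAO_BASE_IRI <- "http://www.biomodels.net/kisao/KISAO#"

.idPatterns <- c(
  "^kisao:([0-9]{7})$",
  "^kisao_([0-9]{7})$",
  "^https?://www\\.biomodels\\.net/kisao/kisao#kisao_([0-9]{7})$",
  "^urn:miriam:biomodels\\.kisao:kisao_([0-9]{7})$",
  "^https?://identifiers\\.org/biomodels\\.kisao[/:]kisao_([0-9]{7})$",
  "^([0-9]{7})$"
)

#' @rdname kisao-identifiers
#' @export
normalizeKisaoId <- function(x) {
  if (!is.character(x)) idError("identifier must be character, got %s", class(x)[1])
  x <- trimws(x)
  out <- rep(NA_character_, length(x))
  low <- tolower(x)
  for (pat in .idPatterns) {
    hit <- is.na(out) & grepl(pat, low)
    out[hit] <- sub(pat, "\\1", low[hit])
  }
  if (anyNA(out)) {
    bad <- x[is.na(out)][1]
    idError("not a recognizable KiSAO identifier: '%s'", bad)
  }
  out
}

#' @rdname kisao-identifiers
#' @export
renderKisaoId <- function(id,
                          form = c("short", "iri", "miriam_urn",
                                   "identifiers_org_url"),
                          baseIri = KISAO_BASE_IRI) {
  form <- match.arg(form)
  id <- normalizeKisaoId(id)
  switch(form,
    short = paste0("kisao:", id),
    iri = paste0(baseIri, "KISAO_", id),
    miriam_urn = paste0("urn:miriam:biomodels.kisao:KISAO_", id),
    identifiers_org_url = paste0("http://identifiers.org/biomodels.kisao/KISAO_", id)
  )
}

# Parse a full class IRI into a canonical id, or NA if it is not a term IRI
# under `baseIri`.
iriToId <- function(iri, baseIri = KISAO_BASE_IRI) {
  pat <- paste0("^", .rxEscape(baseIri), "KISAO_([0-9]{7})$")
  ifelse(grepl(pat, iri), sub(pat, "\\1", iri), NA_character_)
}

idToIri <- function(id, baseIri = KISAO_BASE_IRI) paste0(baseIri, "KISAO_", id)

.rxEscape <- function(x)
  gsub("([.\\\\|()\\[\\]{}^$*+?])", "\\\\\\1", x, perl = TRUE)
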