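# Example parsing configuration for kisaoquery::readOntologyConfig().
# Every key is optional; omitted keys keep the package defaults, which
# match KiSAO releases. Identifiers may use any accepted form.
base_iri: "http://www.biomodels.net/kisao/KISAO#"
branch_roots:
  algorithm: "kisao:0000000"
  characteristic: "kisao:0000097"
  parameter: "kisao:0000201"
relations:
  has_characteristic: "http://www.biomodels.net/kisao/KISAO#hasCharacteristic"
  has_parameter: "http://www.biomodels.net/kisao/KISAO#hasParameter"
  is_hybrid_of: "http://www.biomodels.net/kisao/KISAO#isHybridOf"
  has_type: "http://www.biomodels.net/kisao/KISAO#hasType"
annotations:
  label: "http://www.w3.org/2000/01/rdf-schema#label"
  definition: "http://purl.obolibrary.org/obo/IAO_0000115"
  deprecated: "http://www.w3.org/2002/07/owl#deprecated"
  synonym_exact: "http://www.geneontology.org/formats/oboInOwl#hasExactSynonym"
  synonym_related: "http://www.geneontology.org/formats/oboInOwl#hasRelatedSynonym"
  synonym_broad: "http://www.geneontology.org/formats/oboInOwl#hasBroadSynonym"
  synonym_narrow: "http://www.geneontology.org/formats/oboInOwl#hasNarrowSynonym"
  link:
    - "http://www.w3.org/2000/01/rdf-schema#seeAlso"
    - "http://www.geneontology.org/formats/oboInOwl#hasDbXref"
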