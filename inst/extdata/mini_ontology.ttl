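# Miniature toxic-process ontology fixture: a ~30-node synthetic stand-in
# emulating the enriched ontology structure the knowledge graph links to
# (toxic processes/diseases, adverse effects with "has context", pathway and
# gene-product attachments). It is NOT an import of TXPO/GO/KEGG/UniProt;
# identifiers live under example.org namespaces.
@prefix txo: <http://example.org/txpo/> .
@prefix go: <http://example.org/go/> .
@prefix up: <http://example.org/uniprot/> .
@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .
@prefix rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#> .

# classes
txo:ToxicProcess a rdfs:Class ; rdfs:label "toxic process" .
txo:Disease a rdfs:Class ; rdfs:label "disease" .
txo:AdverseEffect a rdfs:Class ; rdfs:label "adverse effect" .
txo:BiologicalProcess a rdfs:Class ; rdfs:label "biological process" .
txo:GoCamModel a rdfs:Class ; rdfs:label "causal activity model" .
txo:GeneProduct a rdfs:Class ; rdfs:label "gene product" .

# toxic processes and diseases
txo:cholestasis a txo:Disease , txo:ToxicProcess ;
  rdfs:label "liver cholestasis" .
txo:lipidosis a txo:ToxicProcess ;
  rdfs:label "lipidosis" .
txo:NAFLD a txo:Disease , txo:ToxicProcess ;
  rdfs:label "NAFLD" ;
  txo:is_a txo:lipidosis .

# adverse effects in the context of cholestasis
txo:increased_blood_ALP a txo:AdverseEffect ;
  rdfs:label "increased blood ALP concentration" ;
  txo:has_context txo:cholestasis .
txo:presence_of_GGT a txo:AdverseEffect ;
  rdfs:label "presence of GGT in blood" ;
  txo:has_context txo:cholestasis .
txo:hepatocellular_necrosis a txo:AdverseEffect ;
  rdfs:label "necrosis" ;
  txo:has_context txo:cholestasis .

# adverse effects specific to NAFLD
txo:increased_hepatic_triglycerides a txo:AdverseEffect ;
  rdfs:label "increased hepatic triglycerides" ;
  txo:has_context txo:NAFLD .
txo:hepatic_fat_accumulation a txo:AdverseEffect ;
  rdfs:label "hepatic fat accumulation" ;
  txo:has_context txo:NAFLD .

# adverse effects NAFLD inherits from lipidosis (NAFLD is_a lipidosis)
txo:hyperfunction_lipid_biosynthesis a txo:AdverseEffect ;
  rdfs:label "hyperfunction of lipid biosynthesis" ;
  txo:has_context txo:lipidosis .
txo:hyperfunction_cholesterol_biosynthesis a txo:AdverseEffect ;
  rdfs:label "hyperfunction of cholesterol biosynthesis" ;
  txo:has_context txo:lipidosis .

# part-of structure and pathway associations
txo:NAFLD txo:has_part txo:hyperfunction_lipid_biosynthesis .
txo:lipidosis txo:has_part txo:hyperfunction_cholesterol_biosynthesis .

go:fatty_acid_biosynthesis a txo:BiologicalProcess ;
  rdfs:label "fatty acid biosynthetic process" .
go:cholesterol_biosynthesis a txo:BiologicalProcess ;
  rdfs:label "cholesterol biosynthetic process" .
txo:hyperfunction_lipid_biosynthesis txo:pathway_association go:fatty_acid_biosynthesis .
txo:hyperfunction_cholesterol_biosynthesis txo:pathway_association go:cholesterol_biosynthesis .

txo:gocam_fa_regulation a txo:GoCamModel ;
  rdfs:label "causal model of fatty acid biosynthesis regulation" .
txo:NAFLD txo:pathway_association txo:gocam_fa_regulation .

# gene products participating in the pathways
up:ACACA a txo:GeneProduct ;
  rdfs:label "acetyl-CoA carboxylase 1" .
up:HMGCR a txo:GeneProduct ;
  rdfs:label "3-hydroxy-3-methylglutaryl-CoA reductase" .
go:fatty_acid_biosynthesis txo:has_participant up:ACACA .
go:cholesterol_biosynthesis txo:has_participant up:HMGCR .
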