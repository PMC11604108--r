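@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .
@prefix owl: <http://www.w3.org/2002/07/owl#> .
@prefix xsd: <http://www.w3.org/2001/XMLSchema#> .
@prefix obo: <http://purl.obolibrary.org/obo/> .
@prefix oboInOwl: <http://www.geneontology.org/formats/oboInOwl#> .
@prefix skos: <http://www.w3.org/2004/02/skos/core#> .

<http://example.org/ontomatch/mini.ttl> a owl:Ontology ;
    owl:versionInfo "0.1" .

obo:EX_0000001 a owl:Class ;
    rdfs:label "cardiac arrest"@en ;
    oboInOwl:hasExactSynonym "heart arrest" ;
    skos:definition "cessation of the heartbeat" .

obo:EX_0000002 a owl:Class ;
    rdfs:label "sudden cardiac arrest" ;
    rdfs:subClassOf obo:EX_0000001 .

obo:EX_0000003 a owl:Class ;
    rdfs:label "old cardiac arrest term" ;
    owl:deprecated "true"^^xsd:boolean ;
    rdfs:subClassOf [ a owl:Restriction ] .
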