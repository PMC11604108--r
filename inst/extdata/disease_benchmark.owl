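<?xml version="1.0" encoding="UTF-8"?>
<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"
         xmlns:rdfs="http://www.w3.org/2000/01/rdf-schema#"
         xmlns:owl="http://www.w3.org/2002/07/owl#"
         xmlns:oboInOwl="http://www.geneontology.org/formats/oboInOwl#"
         xmlns:skos="http://www.w3.org/2004/02/skos/core#">
  <owl:Ontology rdf:about="http://example.org/ontomatch/disease_benchmark.owl">
    <owl:versionInfo>1.0</owl:versionInfo>
  </owl:Ontology>
  <owl:Class rdf:about="http://www.ebi.ac.uk/efo/EFO_0000408">
    <rdfs:label>disease</rdfs:label>
    <skos:definition>a disposition to undergo pathological processes</skos:definition>
  </owl:Class>
  <owl:Class rdf:about="http://www.ebi.ac.uk/efo/EFO_0009690">
    <rdfs:label>respiratory system disease</rdfs:label>
    <rdfs:subClassOf rdf:resource="http://www.ebi.ac.uk/efo/EFO_0000408"/>
  </owl:Class>
  <owl:Class rdf:about="http://www.ebi.ac.uk/efo/EFO_0006505">
    <rdfs:label>chronic bronchitis</rdfs:label>
    <rdfs:subClassOf rdf:resource="http://www.ebi.ac.uk/efo/EFO_0009690"/>
  </owl:Class>
  <owl:Class rdf:about="http://www.ebi.ac.uk/efo/EFO_0000464">
    <rdfs:label>emphysema</rdfs:label>
    <rdfs:subClassOf rdf:resource="http://www.ebi.ac.uk/efo/EFO_0009690"/>
  </owl:Class>
  <owl:Class rdf:about="http://www.ebi.ac.uk/efo/EFO_0005854">
    <rdfs:label>allergic rhinitis</rdfs:label>
    <oboInOwl:hasExactSynonym>hay fever</oboInOwl:hasExactSynonym>
    <rdfs:subClassOf rdf:resource="http://www.ebi.ac.uk/efo/EFO_0009690"/>
  </owl:Class>
  <owl:Class rdf:about="http://www.ebi.ac.uk/efo/EFO_0003956">
    <rdfs:label>seasonal allergic rhinitis</rdfs:label>
    <rdfs:subClassOf rdf:resource="http://www.ebi.ac.uk/efo/EFO_0005854"/>
  </owl:Class>
  <owl:Class rdf:about="http://www.ebi.ac.uk/efo/EFO_0003086">
    <rdfs:label>kidney disease</rdfs:label>
    <rdfs:subClassOf rdf:resource="http://www.ebi.ac.uk/efo/EFO_0000408"/>
  </owl:Class>
  <owl:Class rdf:about="http://www.ebi.ac.uk/efo/EFO_1002048">
    <rdfs:label>kidney failure</rdfs:label>
    <rdfs:subClassOf rdf:resource="http://www.ebi.ac.uk/efo/EFO_0003086"/>
  </owl:Class>
  <owl:Class rdf:about="http://www.ebi.ac.uk/efo/EFO_1001226">
    <rdfs:label>uremia</rdfs:label>
    <rdfs:subClassOf rdf:resource="http://www.ebi.ac.uk/efo/EFO_1002048"/>
  </owl:Class>
  <owl:Class rdf:about="http://www.ebi.ac.uk/efo/EFO_0000319">
    <rdfs:label>cardiovascular disease</rdfs:label>
    <rdfs:subClassOf rdf:resource="http://www.ebi.ac.uk/efo/EFO_0000408"/>
  </owl:Class>
  <owl:Class rdf:about="http://www.ebi.ac.uk/efo/EFO_0000612">
    <rdfs:label>myocardial infarction</rdfs:label>
    <oboInOwl:hasExactSynonym>heart attack</oboInOwl:hasExactSynonym>
    <rdfs:subClassOf rdf:resource="http://www.ebi.ac.uk/efo/EFO_0000319"/>
  </owl:Class>
  <owl:Class rdf:about="http://www.ebi.ac.uk/efo/EFO_0000618">
    <rdfs:label>nervous system disease</rdfs:label>
    <rdfs:subClassOf rdf:resource="http://www.ebi.ac.uk/efo/EFO_0000408"/>
  </owl:Class>
  <owl:Class rdf:about="http://purl.obolibrary.org/obo/MONDO_0004975">
    <rdfs:label>Alzheimer disease</rdfs:label>
    <rdfs:subClassOf rdf:resource="http://www.ebi.ac.uk/efo/EFO_0000618"/>
  </owl:Class>
  <owl:Class rdf:about="http://www.ebi.ac.uk/efo/EFO_0000249">
    <rdfs:label>Alzheimer's disease</rdfs:label>
    <owl:deprecated>true</owl:deprecated>
  </owl:Class>
  <owl:Class rdf:about="http://www.ebi.ac.uk/efo/EFO_0003843">
    <rdfs:label>pain</rdfs:label>
  </owl:Class>
  <owl:Class rdf:about="http://purl.obolibrary.org/obo/HP_0012532">
    <rdfs:label>chronic pain</rdfs:label>
    <rdfs:subClassOf rdf:resource="http://www.ebi.ac.uk/efo/EFO_0003843"/>
  </owl:Class>
</rdf:RDF>
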