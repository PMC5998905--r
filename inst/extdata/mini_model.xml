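<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
  <model id="mini_model" fbc:strict="true">
    <listOfCompartments>
      <compartment id="c" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="A" name="metabolite A" compartment="c" constant="false"
               hasOnlySubstanceUnits="false" boundaryCondition="false"/>
      <species id="B" name="metabolite B" compartment="c" constant="false"
               hasOnlySubstanceUnits="false" boundaryCondition="false"/>
      <species id="C" name="metabolite C" compartment="c" constant="false"
               hasOnlySubstanceUnits="false" boundaryCondition="false"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="minus_thousand" value="-1000" constant="true"/>
      <parameter id="zero" value="0" constant="true"/>
      <parameter id="plus_thousand" value="1000" constant="true"/>
      <parameter id="uptake_cap" value="10" constant="true"/>
    </listOfParameters>
    <fbc:listOfGeneProducts>
      <fbc:geneProduct fbc:id="G_g1" fbc:label="g1"/>
      <fbc:geneProduct fbc:id="G_g2" fbc:label="g2"/>
      <fbc:geneProduct fbc:id="G_g3" fbc:label="g3"/>
      <fbc:geneProduct fbc:id="G_g4" fbc:label="g4"/>
    </fbc:listOfGeneProducts>
    <listOfReactions>
      <reaction id="EX_A_in" reversible="false" fast="false"
                fbc:lowerFluxBound="zero" fbc:upperFluxBound="uptake_cap">
        <listOfProducts>
          <speciesReference species="A" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="R1" reversible="false" fast="false"
                fbc:lowerFluxBound="zero" fbc:upperFluxBound="plus_thousand">
        <notes>
          <body xmlns="http://www.w3.org/1999/xhtml">
            <p>SUBSYSTEM: glycolysis</p>
          </body>
        </notes>
        <listOfReactants>
          <speciesReference species="A" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="B" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:and>
            <fbc:geneProductRef fbc:geneProduct="G_g1"/>
            <fbc:geneProductRef fbc:geneProduct="G_g2"/>
          </fbc:and>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="R2" reversible="true" fast="false"
                fbc:lowerFluxBound="minus_thousand"
                fbc:upperFluxBound="plus_thousand">
        <notes>
          <body xmlns="http://www.w3.org/1999/xhtml">
            <p>SUBSYSTEM: tca</p>
          </body>
        </notes>
        <listOfReactants>
          <speciesReference species="B" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="C" stoichiometry="2" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:or>
            <fbc:geneProductRef fbc:geneProduct="G_g3"/>
            <fbc:geneProductRef fbc:geneProduct="G_g4"/>
          </fbc:or>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="EX_C_out" reversible="false" fast="false"
                fbc:lowerFluxBound="zero" fbc:upperFluxBound="plus_thousand">
        <listOfReactants>
          <speciesReference species="C" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
    </listOfReactions>
  </model>
</sbml>
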