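<?xml version="1.0" encoding="UTF-8"?>
<!-- Synthetic COBRA-dialect SBML L2V4 fixture: a 16-compartment miniature
     model in the same dialect as published yeast genome-scale models
     (GENE_ASSOCIATION notes, kinetic-law bound parameters). Not real
     biology. -->
<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">
  <model id="synthetic_cobra_mini">
    <listOfCompartments>
      <compartment id="e" name="extracellular"/>
      <compartment id="c" name="cytoplasm"/>
      <compartment id="m" name="mitochondrion"/>
      <compartment id="n" name="nucleus"/>
      <compartment id="x" name="peroxisome"/>
      <compartment id="v" name="vacuole"/>
      <compartment id="g" name="Golgi"/>
      <compartment id="r" name="endoplasmic reticulum"/>
      <compartment id="l" name="lipid particle"/>
      <compartment id="mm" name="mitochondrial membrane"/>
      <compartment id="vm" name="vacuolar membrane"/>
      <compartment id="nm" name="nuclear membrane"/>
      <compartment id="gm" name="Golgi membrane"/>
      <compartment id="rm" name="ER membrane"/>
      <compartment id="pm" name="plasma membrane"/>
      <compartment id="b" name="boundary"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="glc_e" name="glucose" compartment="e" boundaryCondition="false"/>
      <species id="glc_c" name="glucose" compartment="c" boundaryCondition="false"/>
      <species id="g6p_c" name="glucose 6-phosphate" compartment="c" boundaryCondition="false"/>
      <species id="glucan_c" name="1,3-beta-glucan" compartment="c" boundaryCondition="false"/>
      <species id="pyr_c" name="pyruvate" compartment="c" boundaryCondition="false"/>
      <species id="pyr_m" name="pyruvate" compartment="m" boundaryCondition="false"/>
    </listOfSpecies>
    <listOfReactions>
      <reaction id="R_EX_glc" name="D-glucose exchange" reversible="true">
        <listOfReactants>
          <speciesReference species="glc_e" stoichiometry="1"/>
        </listOfReactants>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML"><ci> FLUX_VALUE </ci></math>
          <listOfParameters>
            <parameter id="LOWER_BOUND" value="-10" units="mmol_per_gDW_per_hr"/>
            <parameter id="UPPER_BOUND" value="1000" units="mmol_per_gDW_per_hr"/>
            <parameter id="OBJECTIVE_COEFFICIENT" value="0"/>
          </listOfParameters>
        </kineticLaw>
      </reaction>
      <reaction id="R_GLCt" name="glucose transport" reversible="false">
        <listOfReactants>
          <speciesReference species="glc_e" stoichiometry="1"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="glc_c" stoichiometry="1"/>
        </listOfProducts>
      </reaction>
      <reaction id="R_HEX1" name="hexokinase" reversible="false">
        <notes>
          <body xmlns="http://www.w3.org/1999/xhtml">
            <p>GENE_ASSOCIATION: YFR053C or YGL253W or YLR446W</p>
            <p>EC_NUMBER: 2.7.1.1</p>
          </body>
        </notes>
        <listOfReactants>
          <speciesReference species="glc_c" stoichiometry="1"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="g6p_c" stoichiometry="1"/>
        </listOfProducts>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML"><ci> FLUX_VALUE </ci></math>
          <listOfParameters>
            <parameter id="LOWER_BOUND" value="0"/>
            <parameter id="UPPER_BOUND" value="1000"/>
          </listOfParameters>
        </kineticLaw>
      </reaction>
      <reaction id="R_0005" name="1,3-beta-glucan synthase" reversible="false">
        <notes>
          <body xmlns="http://www.w3.org/1999/xhtml">
            <p>GENE_ASSOCIATION: (YGR032W or YLR342W)</p>
          </body>
        </notes>
        <listOfReactants>
          <speciesReference species="g6p_c" stoichiometry="1"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="glucan_c" stoichiometry="1"/>
        </listOfProducts>
      </reaction>
      <reaction id="R_PYRt2m" name="pyruvate mitochondrial transport" reversible="true">
        <listOfReactants>
          <speciesReference species="pyr_c" stoichiometry="1"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="pyr_m" stoichiometry="1"/>
        </listOfProducts>
      </reaction>
    </listOfReactions>
  </model>
</sbml>
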