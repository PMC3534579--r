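# Hand-built fixture models with known optima.

# Linear chain: uptake of A (capacity 10), A -> B (gene g_ab),
# B -> C (gene g_bc), export of C. Every flux is forced to 10 when
# C-export is maximised.
chainModel <- function() {
  mets <- data.frame(id = c("A_c", "B_c", "C_c"), compartment = "c",
                     boundary = FALSE, stringsAsFactors = FALSE)
  rxns <- data.frame(id = c("E_A", "R_AB", "R_BC", "E_C"),
                     lb = 0, ub = c(10, 1000, 1000, 1000),
                     gpr = c("", "g_ab", "g_bc", ""),
                     stringsAsFactors = FALSE)
  S <- matrix(0, 3, 4, dimnames = list(mets$id, rxns$id))
  S["A_c", "E_A"] <- 1
  S["A_c", "R_AB"] <- -1; S["B_c", "R_AB"] <- 1
  S["B_c", "R_BC"] <- -1; S["C_c", "R_BC"] <- 1
  S["C_c", "E_C"] <- -1
  MetabolicModel(S, mets, rxns)
}

# Two equal-capacity routes A -> B: R1 carries gene g1, R2 is
# gene-free, so knocking g1 down is fully compensated.
compensatedModel <- function() {
  mets <- data.frame(id = c("A_c", "B_c"), compartment = "c",
                     boundary = FALSE, stringsAsFactors = FALSE)
  rxns <- data.frame(id = c("E_A", "R1", "R2", "E_B"),
                     lb = 0, ub = c(10, 10, 10, 1000),
                     gpr = c("", "g1", "", ""),
                     stringsAsFactors = FALSE)
  S <- matrix(0, 2, 4, dimnames = list(mets$id, rxns$id))
  S["A_c", "E_A"] <- 1
  S["A_c", "R1"] <- -1; S["B_c", "R1"] <- 1
  S["A_c", "R2"] <- -1; S["B_c", "R2"] <- 1
  S["B_c", "E_B"] <- -1
  MetabolicModel(S, mets, rxns)
}

# Parallel two-branch route A -> C via B1 or B2 (each branch capacity
# 10, export capacity 10): the total is pinned at 10 but the split
# between branches is free.
parallelModel <- function() {
  mets <- data.frame(id = c("A_c", "B1_c", "B2_c", "C_c"),
                     compartment = "c", boundary = FALSE,
                     stringsAsFactors = FALSE)
  rxns <- data.frame(id = c("UP", "BR1a", "BR1b", "BR2a", "BR2b", "EX"),
                     lb = 0, ub = 10, stringsAsFactors = FALSE)
  S <- matrix(0, 4, 6, dimnames = list(mets$id, rxns$id))
  S["A_c", "UP"] <- 1
  S["A_c", "BR1a"] <- -1; S["B1_c", "BR1a"] <- 1
  S["B1_c", "BR1b"] <- -1; S["C_c", "BR1b"] <- 1
  S["A_c", "BR2a"] <- -1; S["B2_c", "BR2a"] <- 1
  S["B2_c", "BR2b"] <- -1; S["C_c", "BR2b"] <- 1
  S["C_c", "EX"] <- -1
  MetabolicModel(S, mets, rxns)
}

# A minimal SBML Level 2 document exercising the legacy conventions:
# boundary-by-compartment, notes-embedded GPR, kinetic-law bounds and
# a reaction with no bounds at all.
sbmlL2Fixture <- function() {
  paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
'<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="1">\n',
'  <model id="toyL2">\n',
'    <listOfCompartments><compartment id="c"/><compartment id="b"/></listOfCompartments>\n',
'    <listOfSpecies>\n',
'      <species id="A_b" compartment="b"/>\n',
'      <species id="A_c" compartment="c"/>\n',
'      <species id="B_c" compartment="c" boundaryCondition="false"/>\n',
'    </listOfSpecies>\n',
'    <listOfReactions>\n',
'      <reaction id="T1" reversible="false">\n',
'        <notes><body xmlns="http://www.w3.org/1999/xhtml"><p>GENE_ASSOCIATION: (g1 or g2)</p></body></notes>\n',
'        <listOfReactants><speciesReference species="A_b"/></listOfReactants>\n',
'        <listOfProducts><speciesReference species="A_c"/></listOfProducts>\n',
'        <kineticLaw><listOfParameters><parameter id="LOWER_BOUND" value="0"/><parameter id="UPPER_BOUND" value="10"/></listOfParameters></kineticLaw>\n',
'      </reaction>\n',
'      <reaction id="T2" reversible="true">\n',
'        <listOfReactants><speciesReference species="A_c"/></listOfReactants>\n',
'        <listOfProducts><speciesReference species="B_c"/></listOfProducts>\n',
'      </reaction>\n',
'    </listOfReactions>\n',
'  </model>\n',
'</sbml>\n')
}
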