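# shared fixtures and helpers, built in code at test time

f1 <- function() make_fixture("obligate_syntrophy")

f2 <- function() make_fixture("competition")

chain <- function() make_fixture("commensal_chain")

# a species with two conversion routes of different yield, the efficient one
# capacity-limited: its allocation-conditional optimum has the closed form
# z(u) = 2 * min(u, 3) + max(0, u - 3), a nontrivially concave value function
two_route_species <- function() {
  species_model("tr",
    list(metabolite("Xx", shared = TRUE), metabolite("I"), metabolite("P")),
    list(reaction("t", c(Xx = -1, I = 1), ub = 10),
         reaction("rHi", c(I = -1, P = 2), ub = 3),
         reaction("rLo", c(I = -1, P = 1)),
         reaction("bio", c(P = -1), biomass = TRUE)))
}

two_route_z <- function(u) 2 * pmin(u, 3) + pmax(0, u - 3)

# single-species community with nothing limiting beyond the model's own
# bounds: the multilevel problem must collapse to plain FBA on it
solo_community <- function(m) {
  sh <- vapply(Filter(function(x) isTRUE(x$shared), m$metabolites),
               function(x) x$id, character(1))
  build_community(list(m),
                  medium = stats::setNames(rep(Inf, length(sh)), sh),
                  accumulation = stats::setNames(rep(Inf, length(sh)), sh))
}

# minimal SBML Level 3 + fbc rendering of the scavenger species of the
# syntrophic pair, for cross-format parser checks
sbml_scavenger <- function(path, objectives = "bioB") {
  obj_lines <- vapply(objectives, function(r) sprintf(
    '          <fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="1"/>', r),
    character(1))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"',
    '      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"',
    '      level="3" version="1" fbc:required="false">',
    '  <model id="B" fbc:strict="true">',
    '    <listOfCompartments>',
    '      <compartment id="c" constant="true"/>',
    '      <compartment id="shared" constant="true"/>',
    '    </listOfCompartments>',
    '    <listOfSpecies>',
    '      <species id="Hx" compartment="shared" constant="false"/>',
    '      <species id="Hb" compartment="c" constant="false"/>',
    '      <species id="Mb" compartment="c" constant="false"/>',
    '    </listOfSpecies>',
    '    <listOfParameters>',
    '      <parameter id="lb0" value="0" constant="true"/>',
    '      <parameter id="ubinf" value="INF" constant="true"/>',
    '    </listOfParameters>',
    '    <listOfReactions>',
    '      <reaction id="tHup" reversible="false" fbc:lowerFluxBound="lb0" fbc:upperFluxBound="ubinf">',
    '        <listOfReactants><speciesReference species="Hx" stoichiometry="1" constant="true"/></listOfReactants>',
    '        <listOfProducts><speciesReference species="Hb" stoichiometry="1" constant="true"/></listOfProducts>',
    '      </reaction>',
    '      <reaction id="rB" reversible="false" fbc:lowerFluxBound="lb0" fbc:upperFluxBound="ubinf">',
    '        <listOfReactants><speciesReference species="Hb" stoichiometry="1" constant="true"/></listOfReactants>',
    '        <listOfProducts><speciesReference species="Mb" stoichiometry="1" constant="true"/></listOfProducts>',
    '      </reaction>',
    '      <reaction id="bioB" reversible="false" fbc:lowerFluxBound="lb0" fbc:upperFluxBound="ubinf">',
    '        <listOfReactants><speciesReference species="Mb" stoichiometry="1" constant="true"/></listOfReactants>',
    '      </reaction>',
    '    </listOfReactions>',
    '    <fbc:listOfObjectives fbc:activeObjective="obj">',
    '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
    '        <fbc:listOfFluxObjectives>',
    obj_lines,
    '        </fbc:listOfFluxObjectives>',
    '      </fbc:objective>',
    '    </fbc:listOfObjectives>',
    '  </model>',
    '</sbml>'), path)
  path
}

biomass_of <- function(sol, sp) sol$species[[sp]]$objective
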