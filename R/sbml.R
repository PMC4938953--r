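# SBML Level 3 export of the pathway model, for cross-checking against any
# SBML-capable kinetics tool. Writer only; one compartment, 7 species (A
# boundary, B..F, plus an empty sink), 5 reversible reactions and the
# first-order utilization of F.

.mathml_frac <- function(num, den) {
  paste0("<apply><divide/>", num, den, "</apply>")
}

.ci <- function(x) paste0("<ci> ", x, " </ci>")
.cn <- function(x) paste0("<cn> ", format(x, digits = 17), " </cn>")

# MathML for E*(kcat*S/KM - kcatr*P/KMr)/(1 + S/KM + P/KMr [+ I/KI])
.rate_mathml <- function(ids, inhibited) {
  term <- function(k, s, km) .mathml_frac(
    paste0("<apply><times/>", .ci(k), .ci(s), "</apply>"), .ci(km))
  num <- paste0("<apply><times/>", .ci(ids$E),
                "<apply><minus/>", term(ids$kcat, ids$S, ids$KM),
                term(ids$kcatr, ids$P, ids$KMr), "</apply></apply>")
  den <- paste0("<apply><plus/>", .cn(1),
                .mathml_frac(.ci(ids$S), .ci(ids$KM)),
                .mathml_frac(.ci(ids$P), .ci(ids$KMr)),
                if (inhibited) .mathml_frac(.ci(ids$I), .ci(ids$KI)) else "",
                "</apply>")
  .mathml_frac(num, den)
}

#' Export the pathway model as SBML Level 3
#'
#' Writes the five-reaction reversible Michaelis-Menten pathway, the fixed
#' boundary species A, the feedback inhibition term and the mass-action sink
#' for F as an SBML Level 3 Version 2 document with explicit kinetic laws.
#'
#' @param g A [genotype()].
#' @param env A [kinetic_env()].
#' @param path Output file path (`.xml`).
#' @return `path`, invisibly.
#' @export
export_sbml <- function(g, env = kinetic_env(), path) {
  species <- c("A", "B", "C", "D", "E_", "F")  # E_ avoids the enzyme clash
  sp_names <- c("A", "B", "C", "D", "E", "F")
  conc0 <- c(env$conc_A, rep(0, 5))
  sp_xml <- paste0(vapply(seq_along(species), function(i) sprintf(
    '      <species id="%s" name="%s" compartment="cell" initialConcentration="%.17g" hasOnlySubstanceUnits="false" boundaryCondition="%s" constant="%s"/>',
    species[i], sp_names[i], conc0[i],
    if (i == 1L) "true" else "false",
    if (i == 1L) "true" else "false"), character(1)), collapse = "\n")

  par_xml <- character(0)
  rx_xml <- character(0)
  inhib_sp <- species[env$inhib_species + 1L]
  for (i in 1:5) {
    e <- genotype_enzyme(g, i)
    pid <- function(s) sprintf("%s_r%d", s, i)
    vals <- c(E = e[["enzyme_conc"]], kcat = e[["k_cat"]], KM = e[["K_M"]],
              kcatr = e[["k_catr"]], KMr = e[["K_Mr"]])
    ids <- list(E = pid("E"), kcat = pid("kcat"), KM = pid("KM"),
                kcatr = pid("kcatr"), KMr = pid("KMr"),
                S = species[i], P = species[i + 1L],
                I = inhib_sp, KI = "KI")
    par_xml <- c(par_xml, vapply(names(vals), function(nm) sprintf(
      '      <parameter id="%s" value="%.17g" constant="true"/>',
      pid(nm), vals[[nm]]), character(1)))
    inhibited <- i == env$inhib_reaction
    modifier <- if (inhibited) sprintf(
      '        <listOfModifiers><modifierSpeciesReference species="%s"/></listOfModifiers>\n',
      inhib_sp) else ""
    rx_xml <- c(rx_xml, sprintf(
'      <reaction id="R%d" reversible="true">
        <listOfReactants><speciesReference species="%s" stoichiometry="1" constant="true"/></listOfReactants>
        <listOfProducts><speciesReference species="%s" stoichiometry="1" constant="true"/></listOfProducts>
%s        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML">
            %s
          </math>
        </kineticLaw>
      </reaction>',
      i, species[i], species[i + 1L], modifier,
      .rate_mathml(ids, inhibited)))
  }
  par_xml <- c(par_xml,
               sprintf('      <parameter id="KI" value="%.17g" constant="true"/>',
                       unclass(g)[26L]),
               sprintf('      <parameter id="k_use" value="%.17g" constant="true"/>',
                       env$k_use))
  sink_xml <- sprintf(
'      <reaction id="Rsink" reversible="false">
        <listOfReactants><speciesReference species="F" stoichiometry="1" constant="true"/></listOfReactants>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML">
            <apply><times/>%s%s</apply>
          </math>
        </kineticLaw>
      </reaction>', .ci("k_use"), .ci("F"))

  doc <- paste0(
'<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" level="3" version="2">
  <model id="linear_pathway" name="Five-enzyme linear pathway">
    <listOfCompartments>
      <compartment id="cell" size="1" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
', sp_xml, '
    </listOfSpecies>
    <listOfParameters>
', paste(par_xml, collapse = "\n"), '
    </listOfParameters>
    <listOfReactions>
', paste(rx_xml, collapse = "\n"), '
', sink_xml, '
    </listOfReactions>
  </model>
</sbml>
')
  # validate well-formedness before writing
  parsed <- xml2::read_xml(doc)
  xml2::write_xml(parsed, path)
  invisible(path)
}
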