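# Shared fixtures and independent oracles for the suite.

toy_specs_small <- function() {
  # Varied planted structures; candidate spaces stay small enough for the
  # brute-force oracle at order <= 3.
  list(
    toy_model_spec(0, c(2),    n_decoys = 2, seed = 101),
    toy_model_spec(1, c(2),    n_decoys = 3, seed = 102),
    toy_model_spec(2, c(3),    n_decoys = 2, seed = 103),
    toy_model_spec(1, c(2, 2), n_decoys = 4, seed = 104),
    toy_model_spec(0, c(3, 2), n_decoys = 3, seed = 105),
    toy_model_spec(3, c(2),    n_decoys = 5, seed = 106),
    toy_model_spec(1, c(3, 3), n_decoys = 2, seed = 107),
    toy_model_spec(2, c(2, 3), n_decoys = 3, seed = 108),
    toy_model_spec(0, integer(0), n_decoys = 4, seed = 109),
    toy_model_spec(4, c(2, 2), n_decoys = 1, seed = 110)
  )
}

toy_spec_order4 <- function() {
  toy_model_spec(1, c(4), n_decoys = 6, seed = 111)
}

family_specs <- function() {
  acc <- function(orders) toy_model_spec(0, orders, n_decoys = 1)
  list(
    toy_family_spec(3, core = toy_model_spec(1, c(2), 2), seed = 201),
    toy_family_spec(3, core = toy_model_spec(0, c(2, 2), 1),
                    accessory = acc(c(2)), seed = 202),
    toy_family_spec(4, core = toy_model_spec(1, c(3), 2),
                    accessory = acc(c(2)), seed = 203),
    toy_family_spec(3, core = toy_model_spec(2, c(2), 1),
                    accessory = acc(c(3)), seed = 204),
    toy_family_spec(3, core = toy_model_spec(1, c(2, 3), 1),
                    accessory = acc(c(2)),
                    rescue_groups = list(integer(), 1L, 2L), seed = 205)
  )
}

truth_strings <- function(truth) {
  sort(vapply(truth, function(s) paste(sort(s), collapse = "+"), character(1)))
}

# Analytic step-3/step-4 expectation, computed purely from the planted
# truths and reaction inventories (never runs FBA): a candidate common to
# all targeted members is accepted unless, for some conserved member, the
# member-present part of the candidate contains one of that member's
# planted lethal sets; it passes step 4 when all member reactions exist in
# every conserved model.
expected_solutions <- function(fam, cases) {
  truth_keys <- lapply(fam$truths, truth_strings)
  rxn_ids <- lapply(fam$models, function(m) m$reactions$reaction_id)
  out <- lapply(seq_len(nrow(cases)), function(i) {
    targeted <- cases$targeted[[i]]
    conserved <- cases$conserved[[i]]
    cand <- Reduce(intersect, truth_keys[targeted])
    if (!length(cand)) return(NULL)
    keep <- vapply(cand, function(k) {
      ids <- strsplit(k, "+", fixed = TRUE)[[1]]
      all(vapply(conserved, function(org) {
        present <- intersect(ids, rxn_ids[[org]])
        !any(vapply(fam$truths[[org]], function(s) all(s %in% present),
                    logical(1)))
      }, logical(1)))
    }, logical(1))
    cand <- cand[keep]
    if (!length(cand)) return(NULL)
    step4 <- vapply(cand, function(k) {
      ids <- strsplit(k, "+", fixed = TRUE)[[1]]
      all(vapply(conserved, function(org) all(ids %in% rxn_ids[[org]]),
                 logical(1)))
    }, logical(1))
    tibble::tibble(case_id = cases$case_id[i], reactions = cand,
                   step4_pass = unname(step4))
  })
  dplyr::arrange(dplyr::bind_rows(out), case_id, reactions)
}

# Shifted-variable LP cross-check via pracma (independent simplex
# implementation): max obj'v, S v = 0, lb <= v <= ub.
pracma_fba <- function(obj, S, lb, ub) {
  S <- as.matrix(S)
  n <- ncol(S)
  beq <- -as.vector(S %*% lb)
  res <- tryCatch(
    pracma::linprog(obj, A = diag(n), b = ub - lb, Aeq = S, beq = beq,
                    maximize = TRUE, maxiter = 2000),
    error = function(e) NULL
  )
  if (is.null(res) || is.null(res$fval)) return(NULL)
  sum(obj * (res$x + lb))
}

tiny_sbml <- function(path) {
  writeLines('<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      xmlns:groups="http://www.sbml.org/sbml/level3/version1/groups/version1"
      level="3" version="1" fbc:required="false">
  <model id="tinySBML" fbc:strict="true">
    <listOfParameters>
      <parameter id="lb_ex" value="-10" constant="true"/>
      <parameter id="lb_zero" value="0" constant="true"/>
      <parameter id="ub_def" value="1000" constant="true"/>
    </listOfParameters>
    <fbc:listOfGeneProducts>
      <fbc:geneProduct fbc:id="G_gA" fbc:label="gA"/>
      <fbc:geneProduct fbc:id="G_gB" fbc:label="gB"/>
    </fbc:listOfGeneProducts>
    <listOfSpecies>
      <species id="M_a_e" compartment="e" boundaryCondition="false" hasOnlySubstanceUnits="false" constant="false"/>
      <species id="M_a_c" compartment="c" boundaryCondition="false" hasOnlySubstanceUnits="false" constant="false"/>
      <species id="M_b_c" compartment="c" boundaryCondition="false" hasOnlySubstanceUnits="false" constant="false"/>
    </listOfSpecies>
    <listOfReactions>
      <reaction id="R_EX_a_e" reversible="true" fbc:lowerFluxBound="lb_ex" fbc:upperFluxBound="ub_def" fast="false">
        <listOfReactants>
          <speciesReference species="M_a_e" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
      <reaction id="R_At" reversible="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_def" fast="false">
        <listOfReactants>
          <speciesReference species="M_a_e" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="M_a_c" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:geneProductRef fbc:geneProduct="G_gA"/>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="R_AB" reversible="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_def" fast="false">
        <listOfReactants>
          <speciesReference species="M_a_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="M_b_c" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:and>
            <fbc:geneProductRef fbc:geneProduct="G_gA"/>
            <fbc:geneProductRef fbc:geneProduct="G_gB"/>
          </fbc:and>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="R_BIOMASS" reversible="false" fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_def" fast="false">
        <listOfReactants>
          <speciesReference species="M_b_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
    </listOfReactions>
    <groups:listOfGroups>
      <groups:group groups:id="g1" groups:kind="partonomy" groups:name="Glycolysis/Gluconeogenesis">
        <groups:listOfMembers>
          <groups:member groups:idRef="R_AB"/>
        </groups:listOfMembers>
      </groups:group>
    </groups:listOfGroups>
    <fbc:listOfObjectives fbc:activeObjective="obj">
      <fbc:objective fbc:id="obj" fbc:type="maximize">
        <fbc:listOfFluxObjectives>
          <fbc:fluxObjective fbc:reaction="R_BIOMASS" fbc:coefficient="1"/>
        </fbc:listOfFluxObjectives>
      </fbc:objective>
    </fbc:listOfObjectives>
  </model>
</sbml>', path)
  path
}
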