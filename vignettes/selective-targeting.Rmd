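---
title: "Selective multi-target screening of metabolic models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selective multi-target screening of metabolic models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selscreen)
library(dplyr)
```

## The problem

Broad-spectrum antibiotics damage the commensal microbiome along with the
pathogen. A narrow-spectrum alternative needs *selective* targets:
interventions that are fatal to the organisms one wants to eliminate and
harmless to the organisms one wants to keep. selscreen searches for such
targets at the level of metabolic reactions, using constraint-based models
of each organism's metabolism, and extends the search from single
essential reactions to *synthetic lethal sets* — minimal groups of two to
four reactions whose joint loss abolishes growth although every proper
subset is survivable. Multi-reaction targets matter because multi-target
drugs are harder to evade by single-mutation resistance, and because the
subtle metabolic differences between closely related organisms often show
up only in combination knockouts.

## The model

Each organism is a metabolic network: a stoichiometric matrix $S$
(metabolites $\times$ reactions), flux bounds $lb \le v \le ub$, and a
biomass reaction whose flux is the proxy for growth. Flux balance analysis
(FBA) predicts the growth capacity as the linear program

$$\mu^\* = \max_v \; c^\top v \quad \text{s.t.} \quad S v = 0,\;\; lb \le v \le ub,$$

with $c$ selecting the biomass reaction. Knocking out a reaction set $K$
fixes $v_j = 0$ for $j \in K$ and re-solves; the knockout is *lethal* when
the knocked-out optimum falls below a threshold fraction of the same-medium
wild-type optimum (default 1%, with an absolute floor of $10^{-6}\,h^{-1}$;
growth exactly at the threshold counts as viable). The threshold is a
convention — essentiality screens in this field commonly use a few percent
of wild type — and both parameters are exposed
(`threshold_frac`, `threshold_abs`).

Growth media enter as exchange-reaction bounds: a nutrient available at
uptake rate $u$ gives its exchange reaction the lower bound $-u$ (uptake
is negative flux by the COBRA sign convention). Four media are screened:
rich or minimal nutrient sets crossed with high or low oxygen uptake,
abbreviated R-H, R-L, M-H, M-L. Because the minimal nutrient set is a
subset of the rich one and low oxygen uptake is below high, the feasible
flux region under M-L is contained in the R-H region componentwise. Two
consequences drive the design:

* **growth is monotone** along the nesting, and
* **any knockout lethal under R-H is lethal under the other three media**,
  so lethal-set enumeration only needs to run once, under R-H — the
  organism's most resilient state. Selectivity is then judged in the
  conserved organisms' most vulnerable state, M-L.

The published compositions of the rich and minimal media behind this kind
of screen are not standardised; here they are configuration, never code.
`read_medium_config()` loads them from JSON/YAML, and the defaults used
with the synthetic models are: every nutrient exchange at
10 mmol/gDW/h, oxygen at 20 (high) or 0.1 (low) mmol/gDW/h. If a
configuration does not nest, the loader warns that the R-H-only
enumeration shortcut is unsound for it.

## The four stages

1. **Model preparation.** Models load from BiGG-style JSON or SBML L3
   FBC. Reactions are classified: exchanges (`EX_` prefix), demands
   (`DM_`), sinks (`SK_`), spontaneous (GPR equal to the spontaneous-gene
   token, BiGG's `s0001`), passive diffusion (an explicit, configurable ID
   list — there is no formal convention for these), everything else
   internal. Cross-model identity of reactions is exact ID equality: BiGG
   identifiers are shared across reconstructions by construction, and
   anything fuzzier would invent biology.
2. **Lethal-set enumeration** (`enumerate_lethal_sets()`). The candidate
   space is the gene-associated internal reactions — boundary
   pseudo-reactions cannot be drugged, spontaneous reactions have no
   enzyme to inhibit, and non-gene-associated reactions have no target.
   The search is a depth-first walk over subsets: at each viable node the
   knocked-out model is re-solved, a 1-norm-minimizing optimal flux
   distribution is computed, and only candidates carrying flux in it are
   branched on. This pruning is *complete*, not heuristic: if a further
   reaction carries zero flux in some optimal distribution of the reduced
   model, knocking it cannot abolish growth, so every lethal extension
   must intersect the support of any one optimal distribution. The
   1-norm-minimal distribution is chosen only because its support is
   small. Supersets of recorded sets are pruned, and minimality of every
   recorded set is re-verified post hoc by testing all proper subsets. An
   exhaustive mode (`prune = FALSE`) and an independent brute-force
   oracle (`brute_force_lethal_sets()`) exist solely to check the search;
   the test suite holds them equal on every fixture.
3. **Case screening** (`screen_cases()`). With $n$ organisms, every
   assignment of roles (targeted / conserved / excluded) with at least
   one target is a *case*: $3^n - 2^n$ of them ($665$ for $n = 6$). For
   each case the candidate solutions are the lethal sets common to all
   targeted organisms — exact intersection of their minimal-set
   collections, so a set minimal in one model but non-minimal in another
   does not qualify. Each candidate is then knocked out in every conserved
   model under M-L; any lethality there disqualifies it. Reactions absent
   from a conserved model are treated as a knockout no-op on it.
4. **Strict presence filter** (`strict_presence_filter()`). A solution
   whose reactions are all present in every conserved model is safe to
   interpret; one with a reaction missing from a conserved model may be a
   false positive of model scope (genomes encode more than their
   reconstructions), so such solutions are set aside. Both tables are
   kept: the step-3 table records what selectivity alone admits, the
   step-4 table what survives caution.

Downstream, `participation_table()` maps accepted solutions to subsystem
labels and counts, per pathway and order, the cases fulfillable by
attacking that pathway; `sl_only_pathways()` lists pathways never hit by a
single essential. `greedy_cover()` condenses the solution store into a
small key-reaction collection whose subsets certify many cases at once.

## Greedy coverage

Coverage of cases by a reaction collection — a case is covered when one of
its accepted solutions is a subset of the collection — is a monotone
submodular function. The natural greedy, adding one reaction at a time by
marginal coverage, fails on stores of pure synthetic lethal sets: no
single reaction completes a certificate, so the first marginal gain is
always zero. `greedy_cover()` therefore works in certificate steps: among
the uncovered solutions whose missing reactions fit the remaining budget,
it adds the one with the most newly covered cases per missing reaction
(ties: more cases, then lexicographic). Because a bad first ratio is the
known failure mode of budgeted-coverage greedies, the search restarts once
from every affordable first certificate and keeps the best run — the
classic partial-enumeration remedy. On single-essential stores this
reduces exactly to the reaction-wise greedy. The test suite checks the
result against the exhaustively computed optimum on small stores and
requires the classic $1 - 1/e$ fraction at equal budget.

## The synthetic-model generator

`generate_toy_model()` builds networks whose complete minimal-lethal-set
inventory is provable by construction, so every stage can be tested
against ground truth with zero tolerance:

* a linear glucose-assimilation chain — each chain reaction is a planted
  single essential;
* per planted synthetic lethal set of order $k$, one biomass precursor
  producible only via $k$ parallel branches of identical, ample capacity
  (1000 mmol/gDW/h against a demand of at most a few), so no proper
  subset of the branch group is limiting and exactly the full group is a
  minimal lethal set;
* decoy reactions that drain the hub into secreted waste — they can carry
  flux but never need to, so they are never essential;
* a spontaneous glucose transporter, a passive-diffusion oxygen
  transporter, boundary exchanges and a demand reaction, so every
  candidate-space exclusion rule is exercised;
* growth is required in all four media; biomass needs an
  oxygen-derived energy metabolite, which makes low-oxygen growth
  strictly smaller (0.1 vs 3.33 $h^{-1}$ in the default configuration) and
  the media ordering informative.

`generate_family()` emulates a clade: members share the core network
under identical reaction IDs and add private accessory branches (private
biomass precursors) plus, optionally, a private *rescue* bypass of a core
branch group. A rescue makes the core group non-lethal in that member
only, which plants selective solutions made purely of shared reactions —
exactly the step-4-passing geometry the screen is after — while accessory
sets plant solutions that survive step 3 but are pretermitted by step 4 in
cases conserving other members. The generator's seed controls subsystem
assignment; the topology is fully determined by the spec, which is what
makes the expected screen output computable analytically from the planted
truths (the test suite's `expected_solutions()` does this without ever
running FBA, and the pipeline must reproduce it exactly).

What the toys do *not* emulate: alternative optima webs, cofactor
coupling, reversible internal cycles, thermodynamically infeasible loops,
and the sheer size of genome-scale reconstructions. Passing the planted
recovery suite therefore validates the screening *logic*, not numerical
robustness at genome scale; the LP layer is tested separately against an
independent solver on random flux problems.

## Numerical choices

* The FBA solver is a two-phase tableau simplex with explicit
  upper-bound rows, written for this package (no LP library is part of
  the declared dependency stack). Feasibility/optimality tolerance is
  $10^{-9}$; growth below $10^{-9}$ reports as 0; infeasible knockout LPs
  count as zero growth. Dantzig pricing switches to Bland's rule after
  500 iterations, which guarantees termination on the degenerate LPs
  these networks produce. Non-finite bounds are clamped to $\pm 10^6$.
* Pruning support uses $|v_j| > 10^{-6}$ on the 1-norm-minimal optimal
  distribution; the biomass flux is fixed to the knockout optimum via a
  one-sided bound relaxed by $10^{-9}$ to avoid rounding infeasibility.
* Ties everywhere (branching order, case ordering, greedy picks,
  subsystem disagreements between models) break lexicographically, so
  reruns are byte-identical.
* Case IDs encode the role assignment in base 3 over lexicographically
  sorted organism IDs (0 excluded, 1 targeted, 2 conserved), stable
  across runs and joins.

## Problem sizes

The shipped tests and the acceptance script run on synthetic models of
roughly 15–40 reactions with candidate spaces of 4–15 reactions, ten
enumeration fixtures at orders up to 3, one order-4 fixture, five
three-to-four-member families screened end to end, and one six-member
family over all 665 cases. These sizes keep the brute-force oracle
exhaustive (every subset tested) while the structures planted in the
generators — parallel redundancy, shared cores, rescues — reproduce the
combinatorial geometry that matters for the screen's correctness.
Genome-scale reconstructions load and screen through exactly the same
code path, but order-4 enumeration over thousands of reactions is a
cluster-scale computation and the pure-R simplex is not built for it; for
such inputs the enumeration stage is the place to swap in an industrial
LP backend.

## A short example

```{r example}
fam <- generate_family(toy_family_spec(n_models = 3, seed = 11))
media <- toy_media()
scr <- run_pipeline(fam$models, media, max_order = 4)
scr
glance(scr)
tidy(scr) |> select(case_id, order, reactions, step4_pass) |> head()
```

Case `120` (organism 1 targeted, organism 2 conserved, organism 3
excluded) is solved by the shared branch pair `GRP1_B1+GRP1_B2`: lethal
for the targeted member, neutral for the conserved one because its
private bypass `P02_RSC1` reroutes the flux, and present in both models,
so it passes the strict presence filter.

```{r cover}
scr$cover_sl
```

## Known limitations

* Reaction-level only: GPR rules are parsed and used for candidate
  selection, but gene-level deletion (a gene disabling several reactions
  at once) is out of scope.
* Alternative optima are irrelevant to the decisions (only the optimal
  objective value is consumed), but reported flux vectors are one optimum
  among many and should not be over-interpreted.
* The strict presence filter trades recall for caution by design; the
  step-3 table is retained for users who want the permissive view.
* The pure-R simplex is exact but not fast; genome-scale enumeration
  needs an external LP solver and is not attempted here.
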