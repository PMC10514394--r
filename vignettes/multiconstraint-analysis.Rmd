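---
title: "Multi-constraint pathway analysis: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-constraint pathway analysis: model, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdfpath)
```

## The model

mdfpath analyzes metabolic networks under three stacked constraint layers.

**Stoichiometry.** Steady-state mass balance $S v = 0$ over the non-boundary
metabolites, with flux bounds $v_{lb} \le v \le v_{ub}$ (mmol/gDW/h). Boundary
metabolites (extracellular sinks and sources) are excluded from mass balance
and carry no concentration variable. All analyses run on a *direction-split*
model (`split_reversible()`): each reversible reaction becomes a forward and a
`_reverse` copy with negated stoichiometry and negated standard energy, so
every flux is non-negative and the total flux $\sum_i v_i$ is a linear
objective.

**Enzyme budget.** Each catalyzed reaction carries a catalytic efficiency
$k_{cat}/MW$ in $h^{-1}/kDa$. Its enzyme cost is $e_i = v_i /
(k_{cat}/MW)_i$; because $1\,kDa = 1\,g/mmol$, the cost comes out in grams of
enzyme per gram dry weight, and the proteome budget is the linear constraint
$\sum_i e_i \le E_{total}$ (default 0.13 g/gDW). Reactions without an
efficiency are exempt.

**Thermodynamics.** Each reaction with a standard transformed Gibbs energy
$\Delta_r G'^0_i$ (kJ/mol) has, at log concentrations $x_j = \ln c_j$
(natural log of mol/L, reference state 1 M, so $\Delta_r G' = \Delta_r G'^0$
exactly at unit concentrations), the driving force

$$f_i = -\Big(\Delta_r G'^0_i + RT \sum_j s_{ij} x_j\Big), \qquad RT = 2.579\ kJ/mol.$$

The max–min driving force (MDF) of a pathway is the largest $B$ such that
some concentration assignment within bounds keeps every *active* reaction at
$f_i \ge B$. The package formulates this as a mixed-integer linear program
with one binary activity indicator $z_i$ per thermodynamically constrained
reaction:

* $v_i \le v_{ub,i} \, z_i$ (an inactive reaction carries no flux),
* $f_i \ge B - M (1 - z_i)$ (only active reactions constrain $B$),
* $\sum_i z_i \ge 1$ (at least one reaction defines the min),
* $x_j \in [\ln c_{lb,j}, \ln c_{ub,j}]$ and ratio windows
  $\ln r_{lb} \le x_a - x_b \le \ln r_{ub}$ for declared cofactor pairs.

$B$ is free in sign. A negative optimum is reported as computed;
"thermodynamically infeasible" ($B < 0$) is an interpretation made by the
caller, never a solver constraint. Reactions without a $\Delta_r G'^0$
(exchanges, biomass-style sinks) are exempt from the thermodynamic layer
rather than assumed to have zero energy.

## Parameters and defaults

| Parameter | Default | Units | Why |
|---|---|---|---|
| `RT` | 2.579 | kJ/mol | the value conventionally used with transformed reaction energies at growth temperature |
| default concentration bounds | 0.5e-6 – 20e-3 | mol/L | the standard physiological window for intracellular metabolites |
| O2 / CO2 / NH4 special bounds | 0.5–200e-6 / 0.1–100e-6 / 10e-6–1e-3 | mol/L | dissolved-gas solubility and ammonium toxicity narrow these species |
| `E_total` | 0.13 | g/gDW | typical metabolic proteome budget for a fast-growing bacterium |
| `bigM` | 1000 | kJ/mol | audited at assembly: must exceed every reaction's $|\Delta_r G'^0| + RT \cdot$ span |
| `mdf_tol` | 1e-4 | kJ/mol | equality tolerance for "this reaction's maximum equals $B^*$"; far below reported 3-decimal MDFs |
| `flux_tol` | 1e-6 | mmol/gDW/h | activity threshold and pFBA objective-fixing slack |
| `stage_tol` | 0.01 | kJ/mol | separates distinct staircase levels without splitting solver noise |
| `var_tol` | 1e-3 | relative | "no variability" threshold for limiting metabolites |
| `key_tol`, `bind_tol` | 1e-6 | g/gDW | enzyme-cost invariability and budget-binding tolerances |

## The diagnostic procedure

`identify_bottlenecks()` runs five steps in a fixed order: (1) maximize $B$
at a required product flux, giving $B^*$; (2) maximize the product flux
subject to $B \ge B^*$; (3) fix that flux level and obtain a parsimonious
witness distribution by lexicographic pFBA (objective fixed within
`flux_tol`, then $\sum v$ minimized); (4) with fluxes fixed to the witness,
maximize each active reaction's own $f_i$ subject to every active reaction
keeping $f \ge B^*$; (5) reactions whose maximum equals $B^*$ within
`mdf_tol` are the bottlenecks — one is *localized*, several are
*distributed* and are coupled through shared limiting metabolites.

Fluxes are deliberately held at the step-3 witness during steps 4–5 and the
concentration-variability analysis. Alternate pFBA optima could shift the
attribution, so the witness is checked for degeneracy by flux variability at
its optimum and a warning names the affected reactions
(`warn_degenerate = TRUE`).

A limiting metabolite is one whose concentration shows no variability at the
optimum. The label is `at_lower_bound`/`at_upper_bound` when pinned at a
bound (reported preferentially), `balanced` when it appears with opposite
signs in at least two bottleneck reactions, and `constrained` in the
remaining case (pinned indirectly, e.g. through a ratio window) — a case the
classification needs to be total.

Enzyme-cost variability fixes the product flux and MDF level as constraints,
leaves fluxes otherwise free, and brackets each $e_i$. "The budget binds" is
operationalized as: the maximum attainable $\sum e_i$ over that constrained
space reaches $E_{total}$ within `bind_tol`. A key-enzyme candidate is a
reaction with an invariant cost under a binding budget; raw ranges are
always reported so users can re-threshold.

## The staircase

`sweep_mdf_curve()` evaluates the MDF on a uniform grid of required product
fluxes and bisects each detected drop until breakpoints are localized within
1e-3 mmol/gDW/h. The grid starts at the flux resolution rather than at
exactly zero: at zero demand the optimum is the degenerate free-activity
value (the single best reaction's driving force), which describes no product
pathway. Stages are grouped greedily left to right with half-open flux
ranges $(lo, hi]$, so each turning point belongs to the stage it terminates.
Refinement only sharpens breakpoints; it never moves a stage's MDF by more
than `mdf_tol`.

## Merging partial reactions

`merge_reactions()` implements the structural correction for partial
reactions catalyzed within one enzyme structure (multifunctional enzymes,
complexes, substrate channels): the merged stoichiometry is the
multiplier-weighted sum with net-zero metabolites removed. Intermediate
detection is automatic; callers may declare expected intermediates, which
are then verified to cancel exactly. Properties of the merged reaction:

* $\Delta_r G'^0$ adds exactly, and therefore the driving force adds exactly
  at *any* concentration vector — the intermediate log terms cancel
  algebraically. An explicit `dG0_override` is honored (used when a curated
  value exists), with the additivity value kept in the audit trail.
* Uncertainty combines as the root sum of squares of the weighted parts
  (independence assumption; no combination rule is standard).
* Efficiency is the minimum over the parts: the overall rate is limited by
  the kinetically weakest step.
* Genes are the union; the parts are shut; the merged reaction has status
  `"added"`; flux bounds are $ub = \min_k (ub_k/m_k)$, $lb = \max_k
  (lb_k/m_k)$, which preserves the mapping of any pre-merge solution into
  the merged network.
* Multipliers are positive integers; fractional lumping is out of scope.

Merging trades yield space for driving force: it can only remove flux
degrees of freedom (never raises the stoichiometric maximum), while at any
$B \ge 0$ a feasible pre-merge solution whose merged parts run maps to a
feasible post-merge solution (the merged force is the sum of parts, each
$\ge B$) — so low-demand MDF never decreases when the merged parts share an
exclusive intermediate. Both directions are exercised by the test suite on
seeded random networks.

## What the generators emulate — and what they do not

`gen_linear_chain()` builds source → A → B → … → sink with designed
standard energies. Two canonical parameterizations probe the two bottleneck
classes: `c(-5, 10)` makes both steps pin $B^*$ simultaneously (distributed;
at the optimum the source sits at its upper bound, the sink at its lower
bound, and the intermediate is balanced between the two steps), while
`c(-30, 30)` leaves all the strain on the second step (localized).

`gen_coupled_motif()` emulates a serine-synthesis-like situation: an
unfavorable dehydrogenase U (+15 kJ/mol) reduces a cofactor whose
reoxidation F (−20 kJ/mol) is catalyzed by the same gene product, with the
cofactor ratio confined to a narrow window (0.5–2). The downstream step D
(−4 kJ/mol) runs between metabolites with deliberately narrow concentration
windows (1e-5–2e-5 M), capping the network MDF at $4 + RT\ln 2 \approx
5.79$ kJ/mol independently of the cofactor ratio. Consequently merging U+F
(which cancels the cofactor pair) lifts the MDF from the ratio-limited value
back to the D cap, and if the ratio window is widened to the full
concentration span, merging is a no-op — the trade-off and its boundary are
both built in, not tuned in.

`gen_branched_network()` gives a two-stage staircase by construction: a
short, favorable, capacity-limited route and a long, thermodynamically poor,
high-capacity route sharing source and product.

`gen_random_model()` samples sparse networks that are feasible *by
construction*: a concentration vector is drawn inside the bounds first and
each standard energy is then drawn so the driving force at that vector is at
least 0.1 kJ/mol. This guarantees the pre-merge MDF ≥ 0.1 precondition of
the merge-monotonicity property without rejection sampling. Extra reactions
never touch the first backbone intermediate, so the first two backbone
reactions always form a valid merge candidate with an exclusive
intermediate.

None of the generators emulate genome-scale features: realistic topology
and degree distributions, currency-metabolite hubs, compartment transport,
biomass compositions, or curated parameter error structure. Passing tests
on these fixtures demonstrate that the procedures are implemented correctly
— equality with independent grid-search oracles, exact additivity, designed
bottleneck recovery — not that predictions on a particular genome-scale
reconstruction are accurate; those depend on the quality of the input model
and parameters.

## Numerical choices

The optimization back end is a dense two-phase primal simplex with Bland's
anti-cycling rule plus a depth-first branch-and-bound layer over the binary
activity indicators (active branch explored first; deterministic node
order; incumbents are verified by re-solving with binaries fixed at their
rounded values, so a linking value like $z = v/v_{ub} = 10^{-6}$ can never
be rounded away). Problems at this package's scope are tiny — tens of
variables — where a dense exact method is faster than its own overhead
would suggest and, importantly, bit-reproducible across runs. Pivot
tolerance is 1e-9; phase-1 feasibility is accepted below 1e-7;
branch-and-bound closes nodes at a 1e-9 gap.

Degenerate inputs are handled explicitly: shut reactions keep zero bounds
through every layer; metabolites of inactive reactions report their full
concentration range in variability analyses; empty bottleneck sets give
empty limiting-metabolite reports; a `bigM` too small for the concentration
spans is rejected at assembly time with the offending reaction named.

## Known limitations

* Gene association is a flat identifier set; AND/OR rule semantics are not
  evaluated (shared-enzyme detection needs identity only).
* Both split directions inherit one efficiency unless the parameter table
  provides direction-specific rows.
* No loopless-FBA correction: thermodynamically infeasible cycles are only
  excluded where the thermodynamic layer is active.
* Transport thermodynamics (membrane potential terms) are out of scope;
  exchanges are thermo-exempt.
* The dense solver is deliberately not built for genome-scale MILPs; models
  of that size should be reduced or analyzed per-subsystem.
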