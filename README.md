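# mdfpath

Thermodynamic and enzyme-constrained analysis of metabolic pathways.

Constraint-based metabolic models predict pathway usage from stoichiometry
alone; adding thermodynamic feasibility (can every step run forward at
physiological metabolite concentrations?) and a proteome budget (is the
enzyme demand affordable?) makes the predictions far more selective — and
also exposes artifacts of how reactions were written into the model. In
particular, *partial* reactions catalyzed within one enzyme structure
(multifunctional enzymes, complexes, substrate channels) expose
intermediates that never actually diffuse free in the cell, distorting both
the thermodynamic and the kinetic picture. mdfpath is for modelers who want
to run this multi-constraint analysis on small and medium networks, diagnose
*why* a pathway's driving force collapses, and correct the model structure
by merging such partial reactions into overall reactions.

## The method

For a reaction with standard transformed Gibbs energy ΔrG′° (kJ/mol) and
stoichiometric coefficients s<sub>ij</sub>, the driving force at log
concentrations x<sub>j</sub> = ln c<sub>j</sub> (mol/L) is

    f_i = −(ΔrG′°_i + RT Σ_j s_ij x_j),   RT = 2.579 kJ/mol.

The **max–min driving force (MDF)** of a pathway is the largest B such that
concentrations within bounds (default 0.5 µM – 20 mM, with tighter windows
for O2, CO2 and ammonium) keep every active reaction at f ≥ B. mdfpath
solves this as a mixed-integer linear program — binary activity indicators
z<sub>i</sub> with v<sub>i</sub> ≤ ub<sub>i</sub>·z<sub>i</sub> and
f<sub>i</sub> ≥ B − M(1−z<sub>i</sub>) — on top of mass balance S·v = 0,
flux bounds, cofactor concentration-ratio windows, and the enzyme budget
Σ v<sub>i</sub>/(kcat/MW)<sub>i</sub> ≤ E<sub>total</sub>.

On this core the package builds:

* **MDF staircase** (`sweep_mdf_curve`): MDF versus required product flux,
  with automatic stage detection and breakpoint refinement — as demand
  grows, high-driving-force routes saturate and the curve drops in plateaus.
* **Bottleneck diagnostics** (`identify_bottlenecks`): a five-step
  procedure (max MDF → max flux at that MDF → parsimonious witness →
  per-reaction driving-force maxima → equality test) classifying bottlenecks
  as *localized* (one reaction pins B) or *distributed* (several, coupled
  through shared limiting metabolites), plus limiting-metabolite
  (`concentration_variability`, `identify_limiting_metabolites`) and
  key-enzyme (`enzyme_cost_variability`) reports.
* **Microcompartment correction** (`merge_reactions`, `merge_spec`,
  `read_merge_specs`): merge partial reactions into an overall reaction —
  stoichiometries sum, channelled intermediates cancel, standard energies
  add exactly, the weakest kcat/MW is inherited, parts are shut — plus
  redundancy detection (`find_redundant_reactions`) and aerobic/anaerobic
  scenarios (`apply_scenario`).
* **Seeded generators** (`gen_linear_chain`, `gen_coupled_motif`,
  `gen_branched_network`, `gen_random_model`) of small networks with
  designed thermodynamic structure, so every stage of the analysis is
  testable without external downloads.

Models travel as BiGG-style JSON plus a TSV of per-reaction parameters
(ΔrG′°, its uncertainty, kcat/MW, genes); configurations as YAML.

## Worked example

A two-step chain with a mildly favorable step (−5 kJ/mol) followed by an
unfavorable one (+10 kJ/mol):

```r
library(mdfpath)
m <- gen_linear_chain(generator_config(), dG0_list = c(-5, 10))
identify_bottlenecks(m, product = "EX_C", min_flux = 1, enzyme_on = FALSE)
#> bottleneck_report: product EX_C, min_flux 1
#>   MDF B* = 9.37673 kJ/mol; max flux at B* = 10
#>   distributed bottleneck(s): R1, R2
#>   limiting metabolites:
#>  metabolite    conc_min    conc_max         reason
#>           A 0.010000000 0.010000000 at_upper_bound
#>           B 0.001832203 0.001832203       balanced
#>           C 0.000001000 0.000001000 at_lower_bound
```

Both steps pin the MDF at B\* = 9.377 kJ/mol — a *distributed* bottleneck:
the source A is pushed to its concentration ceiling, the product C to its
floor, and the shared intermediate B settles at the single value
(1.83 mM) that balances the two steps' driving forces. Raising either
step's force any further would push the other below B\*.

Merging a coupled enzyme pair (an unfavorable dehydrogenase U and the
cofactor-regenerating step F expressed from the same gene) removes the
cofactor-ratio limitation:

```r
motif <- gen_coupled_motif()
res <- merge_reactions(motif, motif_merge_spec())
res
#> merge_result: UF: 1 S --> 1 M2
#>   dG0 = -5 kJ/mol; shut: U, F
#> MDF before merge: 4.301 kJ/mol; after: 5.788 kJ/mol
```

The merged standard energy is the exact sum (+15 − 20 = −5 kJ/mol), the
cofactor pair cancels out of the equation, and the pathway MDF rises from
the ratio-limited 4.30 kJ/mol to the 5.79 kJ/mol cap set by the downstream
step — while the stoichiometric maximum yield stays unchanged (merging can
only remove flux degrees of freedom; the trade-off between yield space and
driving force is one-directional). `yield_percentage(8.99, 21.03)` reports
the corresponding yield as `42.7` percent.

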