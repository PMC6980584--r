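---
title: "Two-cell regulated flux balance analysis: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-cell regulated flux balance analysis: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twocellfba)
```

## The modelling problem

Filamentous, heterocyst-forming cyanobacteria split their metabolism over
two differentiated cell types. Vegetative cells run oxygenic photosynthesis
and fix carbon; heterocysts switch photosystem II off, keep their interior
essentially anoxic, and fix dinitrogen with the O2-labile nitrogenase,
which obligatorily evolves H2 (16 ATP and 8 reduced ferredoxin per N2, one
H2 per N2). The filament survives on an intercellular barter: sucrose and
glutamate move from vegetative cells to heterocysts, glutamine carries the
fixed nitrogen back. This package implements the constraint-based machinery
needed to study that barter and its consequences for photobiological
hydrogen production: single-cell flux balance analysis (FBA), a coupled
two-cell model, integration of cell-type expression data, and a set of
hydrogen-production analyses.

## Flux balance analysis and the LP layer

A metabolic model is a stoichiometric matrix $S$ ($m$ metabolites $\times$
$n$ reactions), flux bounds $v_{\min} \le v \le v_{\max}$, and an objective
$c$. FBA solves

$$\max_v \; c^\top v \quad \text{s.t.} \quad S v = b, \; v_{\min} \le v \le v_{\max},$$

with $b = 0$ unless stated. All extra couplings (photon budget, biomass
ratio, expression rows) enter as additional equality rows with explicit
slack variables, so every constraint of interest has a dual value.

The linear programs are solved by the package's own two-phase primal
simplex with bounded variables (`solve_lp()`). Numerical choices:

* pivot/feasibility tolerance $10^{-9}$; phase-1 infeasibility declared
  above $10^{-7}$ total artificial value;
* Dantzig pricing with a switch to Bland's rule after 4000 iterations of a
  phase, guaranteeing termination under degeneracy;
* at optimality the basis system is re-solved with a dense QR
  factorisation against the original data, so reported fluxes, duals and
  reduced costs do not carry accumulated pivot round-off;
* reported solutions satisfy $\lVert S v - b\rVert_\infty \le 10^{-6}$
  (stored as `residual`), and comparisons in the test-suite are made at
  $10^{-6}$ or tighter.

Degenerate alternate optima are a fact of FBA. Wherever a flux
*distribution* (not just an objective value) is reported, the package
minimises the Manhattan norm $\sum_i |v_i|$ at fixed objective
(`l1_minimal_solution()`), splitting reversible fluxes into non-negative
parts. Objective values always come from the plain FBA solve.

Infeasible cells in robustness scans are reported as `NA`, never as zero:
zero growth is an answer, infeasibility is the absence of one.

## Bound policy and the biomass reaction

`apply_bound_policy()` encodes the standard conventions, in mmol/gDCW/h:
reversible intracellular reactions $(-1000, 1000)$, irreversible ones
$(0, 1000)$, exchanges $(0, 1000)$ except a configurable set of freely
exchanged species (lower bound $-1000$) and limited nutrient uptakes
(bicarbonate, nitrate, photon; lower bound $-10$ unless overridden).
Irradiance is accepted directly as a photon uptake bound; converting
photobioreactor lux values to photon fluxes is the user's business.

`build_biomass_reaction()` turns a macromolecular composition into a drain
reaction: monomer $k$ of macromolecule $M$ with weight percent $w_M$, mole
fraction $f_k$ and molecular weight $MW_k$ (g/mmol) receives the
coefficient $(w_M/100)\, f_k / \sum_k f_k MW_k$, so consumed monomer mass
equals $(100-\text{ash})/100$ g per g of biomass (the builder's invariant,
tested at 1%). Growth-associated maintenance (GAM) is added as an ATP
hydrolysis term; non-growth maintenance (NGAM) is a separate reaction with
a hard lower bound.

## The synthetic toy network

`make_toy_model()` builds a deterministic network of about 50 reactions
and 42 metabolites in cytoplasm and periplasm. It is *not* a curated
genome-scale reconstruction; it is the smallest network that exhibits the
constraint structure the analyses exercise:

* lumped photosystems: PSII (2 photons + H2O to 0.5 O2 + 2 electrons +
  proton-motive force, gene `psbJ_toy`), PSI, an NDH electron feed from
  NADH into the photosynthetic chain, ATP synthase (3 pmf per ATP), and a
  respiratory oxidase;
* a minimal Calvin cycle (RuBisCO, phosphoribulokinase, a reversible
  transketolase lump), an oxidative pentose-phosphate branch yielding
  NADPH, and a glycolysis stub with a formate branch and a
  pyruvate:ferredoxin oxidoreductase;
* sucrose synthesis/cleavage, GS/Fd-GOGAT nitrogen assimilation, nitrate
  reduction, nitrogenase, the uptake hydrogenase (H2 to reduced
  ferredoxin) and the bidirectional NAD(P)H-linked Hox hydrogenase (two
  reversible reactions sharing the `hox_toy` gene);
* a biomass reaction over four pseudo-monomers assembled by the biomass
  builder from the measured *A. variabilis* weight percents (protein 48.3,
  carbohydrate 24.53, lipid 11.6, nucleic acid 11.37 with the DNA pool
  merged into RNA, ash 4.2).

Metabolite formulas use pseudo-elements C, N, O, P; hydrogen and charge
are not tracked. Every internal reaction except the biomass drain balances
these four elements (a test enforces it). Monomer weights are computed
from those formulas (glutamate 0.138, glycogen unit 0.152, lipid unit
0.320, nucleic-acid unit 0.217 g/mmol), which keeps the builder's mass
invariant exact; they are therefore slightly lighter than the hydrated
real molecules. GAM is 50 mmol ATP/gDCW and NGAM 0.13 mmol/gDCW/h,
cyanobacterial-model-typical values. With the default photon budget the
toy grows at realistic cyanobacterial rates (0.02-0.05 1/h).

What the toy does **not** emulate: realistic pathway redundancy and
isozyme structure (each reaction carries a single gene, so OR-expansion is
exercised by dedicated unit fixtures instead), kinetic and thermodynamic
limits, pigment and photon-wavelength physics, and the hundreds of
reactions of a genome-scale model. Tests passing on the toy therefore
demonstrate the correctness of the constraint machinery, not predictions
transferable to the real organism.

`make_expression()` produces the matching two-cell expression profiles.
Expression units are arbitrary (microarray-like); only the product
$E_j \times C$ matters. Defaults: unremarkable genes at 500; under the
`psii_bottleneck` scenario the PSII gene is measured at 56 in vegetative
cells (far below the default, making PSII limiting, and matching the scale
of the motivating microarray data); the differentiated heterocyst profile
zeroes the vegetative-only functions and doubles nitrogenase/hydrogenase
genes. All values are fixed constants; no randomness anywhere in the
generator.

## The two-cell model

`compose_two_cell()` merges two prefixed copies of the base model.
Cell-specific deletions default to nitrogenase for the vegetative copy and
PSII, RuBisCO, bicarbonate equilibration, Fd-GOGAT and nitrate reduction
for the heterocyst copy. Deletion removes the reaction *column* but keeps
all metabolite balance rows, so the dimension arithmetic of an unreduced
base with $n$ reactions and $m$ metabolites is exact:
$2n + 3 + 1$ variables (two flux copies, three shuttles, one photon slack)
and $2m + 2$ equality rows (`two_cell_dimensions()`; for $n = 983$,
$m = 921$ this gives 1970 and 1844).

The couplings are:

* three reversible, unconstrained shuttle reactions joining the two
  periplasmic pools of sucrose, glutamate and glutamine (bounds
  $\pm 1000$); an optional fixed glutamine:glutamate ratio is deliberately
  **not** imposed — the shuttles are left free and flux variability
  analysis is used to inspect them;
* the shared photon budget $v_{p,V} + v_{p,H} + s = v_{p,\max}$ with slack
  $s \in [0, v_{p,\max}]$ (default budget 20 mmol/gDCW/h, a value at which
  the toy filament is light-limited);
* biomass coupling $v_{g,H} = f \cdot v_{g,V}$ with heterocyst fraction
  $f = 0.10$ (heterocysts are about a tenth of the filament); reported
  total growth is $1.1 \times v_{g,V}$ (`total_growth()`).

Condition presets (`set_condition()`): `diazotrophic_auto` closes nitrate,
opens N2 for the heterocyst and bicarbonate (cap 10) for the vegetative
cell; `nitrate_auto` additionally opens nitrate, a strict relaxation;
`heterotrophic` closes photon and bicarbonate and feeds the vegetative
cell fructose at up to 1 mmol/gDCW/h. Bicarbonate uptake is vegetative-only
and N2 uptake heterocyst-only in every preset.

## Expression integration and shadow prices

`to_irreversible_no_or()` rewrites the model so each flux is non-negative
(reversible reactions split into forward and `_rev` copies) and each
reaction carries a single AND-conjunction of genes (rules are normalised
to disjunctive normal form; each OR-alternative becomes an `_iso<k>` copy).
The expansion provably preserves the flux space; the FBA optimum is
unchanged (tested at $10^{-6}$). A reaction with a strictly positive lower
bound and several isozymes cannot attribute that bound to one copy; the
bound is relaxed to zero with a warning (the toy has no such case).

`add_expression_constraints()` then adds, per measured gene $j$ and cell
copy, the row

$$\sum_{i \in K_j} v_i + a_j = E_j \times C, \qquad a_j \ge 0,$$

where $K_j$ contains every expanded reaction whose conjunction includes
$j$ — both directions of a split reversible reaction count, with no
cancellation exemption. $C$ (mmol/gDCW/h) converts expression units into
flux capacity. Genes that map to no reaction in a copy (e.g. nitrogenase
genes in the vegetative cell) are skipped with a warning, not an error.

$C$ is calibrated by `scan_C()`: sweep a grid (default 25 log-spaced
points over $10^{-4}\ldots1$, a range centred an order of magnitude around
typical calibrated values), compute the relative error of predicted
against observed growth, return the arg-min with ties broken towards the
smallest $C$. Predicted growth is monotone non-decreasing in $C$ (a pure
constraint relaxation), which the tests verify.

The shadow price of gene $j$ is the dual value of its row — the
sensitivity of the optimal growth to the right-hand side $E_j \times C$ —
and `gene_shadow_prices()` reports it both per rhs unit and per expression
unit (dual $\times\, C$), since either scale is meaningful and the choice
is a reporting convention. Duals are taken from the optimal basis of the
growth-maximising LP (polished by a direct solve) rather than from the
L1-minimal solution: the L1 program prices the norm, not growth, so its
duals are the wrong quantity for this sensitivity. Under the planted PSII
bottleneck the only positive shadow price is the vegetative PSII gene, the
dual matches a finite-difference perturbation at $10^{-5}$, and
complementary slackness $a_j \cdot y_j = 0$ holds row-wise.

## Hydrogen analyses

All hydrogen quantities are measured at the extracellular H2 exchange of
the studied cell (secretion), not at the enzyme level.
`h2_o2_surface()` fixes the cell's H2 and O2 exchanges on a grid and
reports the growth optimum per cell (vegetative biomass objective
throughout). Both the plain two-cell and the regulated model can be used —
fixings on an expanded model are added as net-flux equality rows over the
forward/reverse copies (`fix_net_flux()`).

`h2_range_at_suboptimal_growth()` pins growth at 90% (default) of the
model's optimum and minimises/maximises H2 secretion; each extreme is
reported as the L1-minimal distribution at its (growth, H2) fixing.
`differential_flux()` classifies reactions as up/down/unchanged between
the two states at a threshold of $10^{-6}$ mmol/gDCW/h (solver noise
floor), and computes the Hox fraction: the share of cytoplasmic H2
production carried by the Hox reactions in the maximal state.

`knockout_h2()` deletes reactions and recomputes the H2 maximum at 90% of
the *knockout model's own* optimal growth — the engineered strain is
assumed to grow at its own optimum, which is what makes an uptake-
hydrogenase deletion able to help at all: at a fixed feasible growth rate
an LP maximum can never increase when reactions are removed. On the toy,
deleting Hup leaves the H2 maximum exactly unchanged: with the
bidirectional Hox hydrogenase present, the optimum can recycle nitrogenase
H2 through the Hox reverse direction at no extra cost, so Hup deletion is
neutral rather than strictly beneficial. The package asserts the direction
(never lower), not strictness. Deleting Hox strictly lowers the maximum,
as the NAD(P)H route is the dominant H2 producer in the maximal state.

## Problem sizes and runtimes

The shipped analyses run on: the toy single cell (51 reactions, 42
metabolites), the two-cell model (100 variables, 86 rows), its expansion
(126 reaction columns) and the regulated model (about 190 variables and
150 rows). Robustness grids in the analysis scripts use 4-6 points per
axis and the C-scan 26 grid points. Every script finishes in seconds on
one CPU; the full test-suite takes well under a minute.

## Known limitations

* The simplex is dense; genome-scale models (thousands of columns) would
  need a sparse LP backend, which the LP interface deliberately isolates
  behind `solve_lp()`.
* SBML support covers the FBC subset the package writes (compartments,
  species with formulas, reactions, bounds, gene associations, one
  maximisation objective); groups, annotations and non-FBC extensions are
  ignored on read.
* Shadow prices at degenerate optima are basis-dependent; the package
  reports one valid dual vector and validates the planted-bottleneck case
  by finite differences, but uniqueness is not guaranteed by LP theory.
* The toy network's quantitative values (growth rates, H2 maxima, the Hox
  fraction) are properties of the toy, not of any real organism; only the
  qualitative orderings are meant to carry over.
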