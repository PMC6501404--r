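---
title: "Constraint-based modeling with gsmmr: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based modeling with gsmmr: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsmmr)
```

## The modeling framework

A genome-scale metabolic model is a set of mass-balanced reactions with
flux bounds, a boolean gene–protein–reaction (GPR) rule per enzymatic
reaction, and a biomass pseudo-reaction that consumes growth precursors
(amino acids, nucleotides, lipids, cofactors, and a large ATP hydrolysis
term) in fixed proportions. Flux balance analysis (FBA) assumes the cell
is at steady state — every non-boundary metabolite is produced exactly as
fast as it is consumed — and that evolution has tuned metabolism to
maximize growth. Formally it maximizes the biomass flux `Z` subject to
`S v = 0` and `a_i <= v_i <= b_i`.

Three compartment classes structure the accounting: *intracellular* and
*extracellular* metabolites are balanced; *boundary* metabolites terminate
exchange reactions and are deliberately left out of `S`, making them the
open ends through which the medium enters and products leave. An exchange
reaction is a pair `X_e <=> X_b` (or a one-sided reaction); its lower
bound is the maximal uptake rate of `X`, so applying a medium means
closing every exchange lower bound and reopening only listed components.

### Degeneracy and the flux-minimization tie-break

FBA optima are almost never unique: parallel pathways reach the same `Z`
(alternate optimal solutions). Any statement about *which* reactions carry
flux therefore needs a tie-breaking convention. `solve_fba()` re-solves a
secondary LP at the fixed optimum that minimizes the total absolute flux
(`sum |v_i|`, via the standard positive/negative split), which suppresses
futile cycles and yields a canonical, parsimonious flux vector. All
active-reaction accounting in the package uses this vector. This is a
convention, not a biological claim; counts of "active" reactions from
other conventions (any-optimum, all-optima) can differ, which is the main
reason genome-scale active-reaction tallies are hard to reproduce exactly
across implementations.

### The LP engine

The package solves its linear programs with a built-in dense two-phase
primal simplex with explicit bound handling (nonbasic variables rest at
either bound; entering a pinned `lb == ub` column is forbidden, which
would otherwise stall as a zero-length bound flip). The basis is
refactorized every pivot — robust and entirely adequate for the dense
problems up to a few hundred reactions this package targets. Pivoting
starts with Dantzig's rule and falls back to Bland's rule after a
degeneracy threshold, guaranteeing termination. The test suite
cross-checks it against `boot::simplex` and exhaustive vertex enumeration
on randomly generated programs.

Tolerances: solver feasibility `1e-9`, reporting/activity `1e-6`, both
configurable per call. Phase-1 residuals above `1e-7` report
`infeasible`; biological infeasibility (e.g. an over-constrained
measurement window) is always a reported status, never an exception.

## Essentiality

A gene knockout propagates through the GPRs: `AND` children must all
survive (complexes), one `OR` child suffices (isozymes). Reactions whose
rule evaluates false are constrained to `[0, 0]` and FBA is re-solved;
the gene is essential when the knockout optimum falls below `zero_tol`
(default `1e-6` — the literal criterion is "zero", but LP numerics
require a tolerance; on toy networks with integral yields the calls are
identical across `1e-9`–`1e-4`, which the suite asserts). Genes absent
from every GPR are reported as skipped rather than scanned. Subsystem
vulnerability attributes an essential gene to every subsystem containing
a reaction the deletion disables — membership through an intact isozyme
does not count.

## Expression integration

RPKM values are discretized with two thresholds:

* `gamma_low = 3.00` RPKM — selected as the smallest cutoff of a
  geometric grid (58 cutoffs, ratio 1.2, i.e. `1.2^k` for k = 0..57) that
  excludes at least 10% of genomic genes across all conditions
  (`select_lower_cutoff()` recomputes this from any expression table).
* `gamma_high = 850.56` RPKM — grid point `1.2^37`. No selection rule
  exists for it; it is a configurable default, not a computed quantity.

The state formula is one-sided around a single threshold in its simplest
form; the two-threshold version used here treats that as the special case
`gamma_low = gamma_high` and is what the active-reaction accounting
requires. Boundary convention: `g` exactly at a threshold is moderate
(state 0); `g = 0` is always −1. Genes missing from the table map to
state 0 — absence of measurement is not evidence of absence. Reaction
states follow `AND = min`, `OR = max`, the standard reading of
complex/isozyme semantics for graded availability.

Two application modes are exposed:

* **clamp** (default, the literal reading of the integration rule):
  state −1 reactions get bounds `[0, 0]`; state 1 reactions get their
  capacity extended to magnitude 1000 (`ub = 1000`, and `lb = -1000` iff
  the reaction was reversible). "Constrained to 1000" is read as capacity
  extension, not forced flux — forcing is what the MILP mode supplies.
  The biomass reaction is never clamped (a warning is raised instead):
  silencing the objective would make every downstream question vacuous.
* **imat** — an iMAT-style agreement maximization: binary indicators
  reward `|v| >= epsilon` for each high reaction and `|v| <= epsilon` for
  each low one, and the solver maximizes the count of satisfied
  indicators. `epsilon = 1.0` mmol/gDW/h by default, the conventional
  activity threshold at this flux scale. The search is an exact
  branch-and-bound over per-reaction choices (forward-active,
  backward-active where reversible, inactive, or miss) with LP
  feasibility pruning, fixed variable ordering and fixed choice order, so
  results are deterministic; the suite verifies it against exhaustive
  indicator enumeration on small networks.

## The synthetic-data generator

No redistributable genome-scale fixture exists at the size this package
targets, so the generator produces models and expression tables with
*known ground truth*, and the test suite's claims should be read
accordingly.

* `make_toy_core_model()` — a fixed ~27-reaction network shaped like
  bacterial central carbon metabolism (glucose transport with an isozyme
  pair, glycolysis with an AND-gated PFK/aldolase step, a pentose branch
  feeding the R5P biomass precursor, pyruvate dehydrogenase, a lumped TCA
  cycle behind a citrate-synthase gene, ethanol/acetate/butanediol
  outlets, ATP synthase, free cofactor dissipation). Stoichiometry was
  chosen so the optimum is hand-derivable: a respired glucose yields 24
  ATP, a pentose-branch glucose yields one R5P plus 3 ATP, and the
  27-ATP biomass cost balances the routes one-to-one, giving Z = U/2 at
  uptake U, exact essential set
  {gALD, gGAPD, gHEX, gPFK, gPGI, gRPI, gZWF}, and Z = U/3 with the TCA
  branch silenced.
* `make_random_model()` — segmented backbones whose essential set is
  planted *by construction* (single-gene segments are cut vertices;
  isozyme pairs are individually dispensable; AND complexes make both
  genes essential; secreted side branches are always dispensable). The
  scan-recovers-planted-set tests are exact-match over 30 seeds at 6–7
  segments.
* `make_expression_table()` — gene-level log-normal baselines
  (`sigma = 2`, spanning 0 to beyond 10^3) shared across conditions with
  small condition noise (`sigma_cond = 0.15`), a planted 2% of exact
  zeros, and the baseline log-mean calibrated by numerical integration so
  that 10% of genes fall below the pivot `1.2^5.5` in every condition —
  placing the selected lower cutoff at grid value `1.2^6` (2.99, the
  canonical 3.00 of the default thresholds). Generation is fully
  deterministic per seed (Mersenne-Twister, recorded in the spec; the
  caller's RNG stream is preserved).

What the generator does *not* emulate: realistic genome-scale topology
(hub metabolites, currency-metabolite degree distributions), elemental
mass balance, compartmentalized transport energetics, or condition
correlation structure beyond a single shared baseline. Passing tests
demonstrate correctness of the algorithms on networks with known answers,
not predictive accuracy on real reconstructions.

## Degenerate and edge inputs

Empty media close all uptakes (growth 0, reported, not an error);
measurement windows inconsistent with conservation surface as infeasible
at solve time and are never silently relaxed; dead-end metabolites and
blocked reactions are detected (not filled — gap *filling* is out of
scope); FVA at fraction 0 drops the objective constraint entirely;
duplicate reaction ids, unknown compartments, malformed equations and
unknown GPR targets are parse errors naming the offending line or id.

## Problem sizes and runtime

The default suite runs networks of 6–30 reactions, 30-seed generator
sweeps, exhaustive GPR truth tables up to 10 leaves (1024 deletion
subsets) and 5000-gene expression tables; it completes in well under a
minute on one CPU. Genome-scale inputs (~1200 reactions) are within the
solver's reach but the dense refactorizing simplex makes a full
single-gene-deletion scan there a minutes-to-hours batch job, not an
interactive call; a factorization-updating or sparse LP backend would be
the natural extension.

## Known limitations

* The dense simplex refactorizes every pivot; fine to a few hundred
  reactions, slow beyond.
* Quadratic objectives, loopless (thermodynamic) constraints and dynamic
  FBA are out of scope, as are SBML/JSON interchange (the tabular dialect
  is the single source format) and automated reconstruction.
* Active-reaction counts inherit the flux-minimization convention above;
  comparisons against counts produced under other conventions should
  expect small per-subsystem divergences, reported per-subsystem by
  `active_reaction_report()`.
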