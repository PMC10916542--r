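---
title: "Enzyme-constrained community models of synthetic consortia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enzyme-constrained community models of synthetic consortia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(consortiafba)
```

## The modeling problem

Synthetic consortia divide a biosynthetic pathway into modules carried by
different strains, with intermediates crossing between them through the
shared medium. Two design questions dominate: *which* reactions each
module should carry (pathway allocation), and *at what inoculation ratio*
the strains should be combined. Plain stoichiometric community models
cannot answer either — without a resource constraint, any allocation that
is stoichiometrically feasible looks equally good.

This package couples two constraint families on top of ordinary flux
balance analysis (FBA):

1. **Per-strain enzyme pools** ("independent"). Each sub-model keeps its
   own proteome budget: over its enzyme-annotated reactions,

   $$\sum_i v_{x i}\,\frac{MW_{x i}}{k_{cat, x i}} \;\le\; ENZ_x ,$$

   where $v_{xi}$ is a flux (mmol gDW$^{-1}$ h$^{-1}$), $MW$ a molecular
   weight (g mmol$^{-1}$, numerically kDa), $k_{cat}$ a turnover number
   (h$^{-1}$), and $ENZ_x = p_{tot} \cdot f \cdot \sigma$ the strain's
   total enzyme budget (g enzyme gDW$^{-1}$): total protein fraction
   times enzyme mass fraction times mean saturation, see `pool_budget()`.
   The cost of one reaction at flux $v$ is `enzyme_cost(v, mw, kcat)`
   $= v\,MW/k_{cat}$.

2. **Ratio-scaled interaction links** ("global"). Sub-models are
   namespaced (`glc__D_e` becomes `glc__D_e@A`) and joined only through
   shared-pool metabolites. For a community at normalized inoculation
   fractions $m_x$ (summing to 1), each link reaction has stoichiometry

   $$1.0\; \mathrm{met}_{e,x} \;\leftrightarrow\; \tfrac{1}{m_x}\,
   \mathrm{met}_{e,\mathrm{shared}},$$

   so at steady state the link fluxes of two strains across one shared
   metabolite stand in the ratio $m : n$. Links are conceptually
   reversible and stored as split irreversible pairs; directed transfer
   is imposed by bounding one half at zero.

Everything is assembled into one linear program: steady state
$S_{cul} \cdot v_{cul} = 0$ over the merged stoichiometric matrix,
irreversible bounds $0 \le v \le v_u$ (reversible reactions are split
into forward/`_reverse` siblings first), one enzyme inequality per
strain, and a product-synthesis objective.

## Interpreting the ratio scaling

The $1/m_x$ link coefficient deserves a caution that applies to any use
of this formulation. Because a strain-side unit converts into $1/m_x$
shared-side units, a strain at a *small* fraction has its transfer
*amplified* relative to its pool-limited internal flux. Consequently:

- a community optimum balances the *scaled* capacities
  $(pool_x/cost_x)/m_x$, and the best ratio allocates **more** biomass to
  the cheaper module (TOY2 peaks at 2:1 upstream:downstream);
- letting a fraction go to zero does *not* starve the community of that
  module's product — the amplification compensates. A strain is removed
  from a design by omitting (bounding to zero) its links, not by a zero
  fraction; `set_ratio()` enforces strictly positive fractions for this
  reason.

Whether sub-model fluxes should be read per gDW of that strain or per
gDW of community is not resolved by the formulation itself; this package
implements the link algebra verbatim and reports fluxes in the
community-LP units. Conclusions about allocation strategies should
therefore be read comparatively (which design wins, where the optimum
ratio sits), not as absolute per-strain rates.

## Parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| `kcat` | h$^{-1}$ | from table | turnover of the catalyzing enzyme; per-second table entries are converted ($\times 3600$) |
| `mw` | g mmol$^{-1}$ | from table | enzyme mass per catalytic site |
| `ptot`, `f`, `sigma` | g gDW$^{-1}$, –, – | user-set | organism-specific pool parameters; no constants are hard-coded |
| ratio fractions | – | normalized | raw integer ratios accepted; normalization makes sweeps comparable |
| link bound | mmol gDW$^{-1}$ h$^{-1}$ | 1000 | effectively unbounded transfer; direction via config |
| solver tolerance | – | $10^{-9}$ | feasibility and optimality; see below |

Reactions without kinetic data are handled per the `attach_enzymes()`
fallback: `exclude` removes their cost term (constraint weakened), or
`default_kcat` assigns the matched set's median kcat and mw. Exchange
and link reactions never carry cost.

## The toy communities as study conditions

All desk-scale verification runs on generated toys with round-number
parameters, chosen so every expected optimum is an exact rational:

- **TOY2** (`make_toy2()`): upstream module converts glucose to an
  intermediate at enzyme cost 0.5 g·h·gDW$^{-1}$·mmol$^{-1}$ against a
  unit pool; downstream converts intermediate to product at cost 1.0;
  shared glucose capped at 10. Closed form: product flux
  $\min(2/m,\, 1/n,\, 10)$, maximal at 2:1 where it equals 3.
- **Overflow toy** (`make_overflow_toy()`): one strain, respiration
  (26 ATP/glucose, cost 0.1) versus fermentation (12 ATP/glucose + 2
  acetate, cost 0.02), pool 1. Acetate onset is exactly at uptake
  $pool/cost_{resp} = 10$; at uptake 20 the optimum is the
  (respiration, fermentation) vertex (7.5, 12.5) secreting 25 acetate.
- **TOY3** (`make_toy3()`): two branch modules (costs 1/2 and 1/3) feed
  a condensation module (cost 1) consuming both intermediates 1:1. The
  glucose cap defaults to 20 because *both* branches draw on it (total
  uptake is twice the product flux); at cap 10 the substrate rather than
  the enzyme pools binds and several grid ratios tie. With the default,
  the 13-point grid has the unique argmax 2:3:1 at product flux 6, and
  the three-module split beats every two-module merge (best merge: 10/3).

These toys emulate the *structure* of real co-culture designs — modular
linear and branched pathways, one binding reaction per module, a shared
substrate — but not their scale (thousands of reactions), promiscuous
cofactor coupling, growth–production trade-offs, or transport
thermodynamics. A passing toy suite therefore certifies the machinery
(assembly, constraint construction, solver, sweeps), not the biological
accuracy of any particular genome-scale model, which additionally
depends on the quality of its kcat table and pool parameters.

## Numerical design

- **Solver.** The LP is solved by a dense two-phase primal simplex with
  Bland's rule (smallest eligible index enters; ratio ties break on the
  smallest basis index). Bland's rule guarantees termination and makes
  repeated solves bit-identical; variable order is the sorted reaction
  ids, so rebuilding a model reproduces the same matrix. Dense tableaus
  are entirely adequate at toy scale and keep the implementation
  dependency-free; genome-scale work would swap in a sparse solver
  behind the same `solve_fba()` interface.
- **Verification.** Every optimum is re-checked with independent
  arithmetic (`validate_solution()`): steady-state residuals, bounds,
  and enzyme rows, at tolerance $10^{-6}$ for the attached report and
  $10^{-9}$ defaults elsewhere. A tolerance of exactly 0 rejects genuine
  floating-point optima, which is why the default is nonzero.
- **Oracle.** An exact rational vertex-enumeration oracle
  (`vertex_oracle()`) solves the same polytopes by brute force over
  active-constraint subsets, with integer numerator/denominator
  arithmetic (exact below $2^{53}$). It is independent of the simplex
  path and is the reference in the regression suite; it refuses problems
  beyond 15 variables.
- **Alternate optima.** Reported flux distributions come from a
  parsimonious re-solve (`pfba()`): among solutions within relative
  $10^{-12}$ of the optimum, total flux is minimized, making
  distributions reproducible even when the optimal face is degenerate.
  Objective values are identical either way.
- **Degenerate inputs.** Infeasible sweep points are kept in the table
  with yield 0 and a status flag; vacuous enzyme constraints (a strain
  with no annotated reactions) warn rather than fail; knockouts zero
  bounds instead of deleting rows so edits stay auditable.
- **NRMSE convention.** The yield-series error is
  $\sqrt{\tfrac{1}{N}\sum_r (y_{s,r} - y_{e,r})^2} / (y_{e,\max} -
  y_{e,\min})$ — the mean inside the root follows the standard RMSE
  definition. `nrmse(c(2,2), c(1,3))` is 0.5 under this convention.

## Worked sweep

```{r toy2-sweep}
toy2 <- make_toy2()
sw <- ratio_sweep(toy2)
sw$table[, c("ratio", "status", "v_product")]
sw$argmax_label
```

```{r toy3}
sw3 <- ratio_sweep(make_toy3())
sw3$argmax_label
sw3$max
```

```{r overflow}
overflow_scan(make_overflow_toy(uptake = 20), uptake_grid = c(5, 10, 15, 20),
              substrate_exchange = "EX_glc_e_reverse")
```

```{r strategies}
compare_strategies(list(
  all_downstream = make_toy2(cost_up = 0, cost_down = 1.5),
  split_burden   = make_toy2()))
```

The strategy comparison illustrates both the method's central contrast —
the stoichiometric relaxation (`basic` rows) cannot distinguish
allocations that the enzyme-constrained model separates cleanly — and
the ratio-scaling caveat above: under the $1/m$ link algebra,
concentrating the whole burden in one module is rewarded at extreme
ratios, so the all-in-one-module strategy dominates on this grid. On the
three-strain toys, where a bounded grid and a partner constraint cap the
amplification, the split allocation wins, matching the qualitative
behavior reported for multi-module consortia.

## Known limitations

- Pure LP: no integer structure, no flux-variability or sampling
  analyses.
- Static ratios: no dynamic re-equilibration of community composition
  over a fermentation; the inoculation ratio is a fixed design
  parameter.
- One cost term per reaction: an enzyme catalyzing several reactions
  contributes one term per reaction, and isozyme alternatives must be
  aggregated upstream in the kcat table.
- The dense simplex and the exhaustive oracle are deliberately
  desk-scale; genome-scale models parse and assemble, but solving them
  efficiently requires an external LP backend.
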