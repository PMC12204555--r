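---
title: "Fixed-abundance community FBA with unequal growth rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fixed-abundance community FBA with unequal growth rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xfba)
```

## The biological problem

Free-living nitrogen-fixing bacteria face a dilemma: nitrogenase is
destroyed by oxygen, yet fixing one mole of N₂ costs 16 moles of ATP,
which aerobes can only supply through respiration. One resolution,
observed in filamentous cyanobacteria (heterocysts) and hypothesised for
free-living rhizobia, is division of labour: a small, constant fraction
of the population stops growing, protects its nitrogenase, fixes N₂, and
exports ammonia to the growing majority, which in turn replenishes the
non-growing pool by differentiation.

A flux model of such a population must hold the two sub-populations at
fixed relative abundances while letting their growth rates differ — one
of them is zero. Community FBA frameworks that weight fluxes by abundance
(cFBA, SteadyCom) assume balanced growth of all members and therefore
cannot express this. This package implements the alternative: fixed
abundances maintained by an explicit differentiation flux and a
growth-ratio constraint, on top of otherwise standard FBA.

## Formulation

Let `S` be the block stoichiometric matrix of a compartmentalised
community: one block of member-tagged reactions per member, plus a shared
extracellular pool `[u]` connected to each member by transport reactions
and to the environment by one community exchange reaction per pooled
species. With fixed abundance fractions `X_m` (strictly positive, summing
to one), mass balances are imposed on the abundance-scaled matrix

$$S_x = S \cdot X,$$

where `X` multiplies each member's columns by its abundance and leaves
the pool-exchange columns unscaled. Flux variables remain member-specific
rates (mmol per gram of member dry weight per hour); products `X_m v`
and all pool exchange fluxes are on the community basis (per gram of
community dry weight). Pins and bounds on community exchanges therefore
act on the community basis, which is how measured uptake rates are
reported.

Member abundances stay constant over time only if the two accumulation
rates keep their ratio. With `μ₁` the growing member's growth flux, `μ₁*`
its differentiation flux (same biomass stoichiometry, but the product
joins the non-growing pool), `v_PHB` the non-growing member's storage
top-up (mmol basis) and `r = X₂/X₁`, the package adds two equality rows
(community basis) to the LP:

$$v_{PHB} = \alpha\,\mu_1^*, \qquad
  \mu_1^* + \frac{MW_{PHB}}{1000} v_{PHB} = r\,\mu_1 .$$

The non-growing accumulation `μ₂ = μ₁* + MW·v_PHB/1000` is an accounting
expression, not a network column — the non-growing member has no biomass
reaction. Substituting the first row into the second yields the
differentiation coefficient

$$\mu_1^*/\mu_1 = c = \frac{r}{1 + \alpha\,MW_{PHB}/1000},\qquad 0<c\le r.$$

The objective is `μ₁`. Because `μ₂ = r μ₁` is active in every feasible
point, maximising `μ₁` also maximises total community growth
`(1+r)μ₁`; population expansion, not nitrogen export, is the biological
goal of a free-living population.

### The storage top-up coefficient α

Differentiated biomass arrives with the base PHB mass fraction
`p_base = 0.159`; non-growing cells hold `p_target = 0.50`. The top-up
per gram of differentiated biomass is

$$\alpha = \frac{1000\,(p_{target}-p_{base})/p_{target}}{MW_{PHB}}
        = 7.9303 \ \text{mmol/g}$$

with `MW_PHB = 86.0` g/mol (the hydroxybutyrate residue; 86.0, not
86.09, reproduces the published coefficient exactly and is the package
default, exposed as a parameter). A bookkeeping subtlety: this
expression normalises the extra PHB by the *pre*-top-up mass. The
realised content of the non-growing member is
`(p_base + k)/(1 + k)` with `k = α·MW/1000`, which equals `p_target`
exactly when `p_target = 0.5` — the operating point of the analysis —
and deviates for other targets. The tests assert the exact closure at
50 % and the general `(p_base+k)/(1+k)` law; `compute_alpha()` keeps the
published definition.

### Maintenance basis

ATP-maintenance bounds (defaults 1 and 2 mmol/gDW/h for growing and
non-growing cells) are applied to the member-level flux variables, i.e.
per gram of member biomass, before abundance scaling. Since the bounds
live in the member models, the community-basis convention is available
by dividing by the abundances; the member basis is the default because
maintenance is a property of a cell, not of the mixture.

## Numerical layer

The LPs these models generate are small but pathologically degenerate:
most fluxes are structurally zero and mass-balance rows are linearly
dependent. The general-purpose simplex routines available in this R
stack (`boot::simplex`, `pracma::linprog`) fail on them — artificial
variables remain basic after phase 1, or the basis factorisation goes
singular. The package therefore carries its own dense bounded-variable
two-phase simplex (`R/lp.R`) with:

* Bland's anti-cycling rule throughout (guaranteed termination);
* bound-flip handling for box constraints, so bounds never become rows;
* artificial variables pinned to zero after phase 1 (redundant rows are
  harmless);
* a terminal refinement that re-solves the basic components against the
  original system, stripping accumulated pivot error (steady-state
  residuals below 1e-9 in practice);
* feasibility and reduced-cost tolerances of 1e-9; infinite bounds are
  clamped at 1e4 (all shipped models use ±1000).

Correctness is cross-checked in the test suite against closed-form
optima, a basic-solution enumeration oracle on micro fixtures, and
hand-derived vertex values — never against the solver itself.

Degenerate optima are a modelling fact here (the robustness analysis
depends on them), so reported flux vectors always come from a secondary
minimisation of total absolute flux at the fixed optimum (parsimonious
step), making outputs reproducible, while `flux_variability()` is the
instrument for statements about alternative optima. Feasibility
boundaries (`min_exchange_for_feasibility()`) are located by an LP
minimisation of the exchange flux followed by bisection of the pinned
value, reported at 0.01 resolution; a boundary falling exactly between
two grid values is rounded to the nearest one.

## The toy diazotroph

`make_toy_cell()` builds a ~36-reaction cell whose FBA optimum has a
closed form in the spec parameters (`toy_growth_closed_form()`), and
`make_toy_community()` assembles the two-member population. The
structural features mirror the method's needs, with small-integer
stoichiometry so optima are exact rationals:

* two terminal oxidases: a proton-pumping one (2 ATP per reducing
  equivalent, 0.5 O₂) and an oxygen-scavenging one (1 ATP, 1.0 O₂ —
  four times the oxygen per ATP), so high pinned oxygen forces the
  scavenging path at a growth cost;
* a nitrogenase costing 8 ATP per ammonia (16 per N₂), and nitrite /
  nitrate reduction at 3 and 5 reducing equivalents per ammonia, giving
  the growth ordering ammonia > nitrite > dinitrogen > nitrate;
* a formate overflow valve, so substrate pinned as an equality can be
  disposed of when oxygen limits respiration (and the below-optimum
  oxygen scans show overflow excretion);
* exact maintenance (`lb = ub`), so excess ATP cannot be silently
  dissipated — this is what makes the oxidase switch observable;
* two amino-acid synthesis isozymes — an efficient one with a capacity
  cap and an uncapped wasteful one — plus a lossless degradation route.
  Inter-member amino-acid transfer is therefore free up to the cap
  (the plateau and the nonzero FVA width of the exchange) and carries a
  strictly positive marginal carbon cost beyond it (the decline).

Defaults were set once from the study conditions the package targets:
substrate (succinate-like, 4 carbons) pinned at 4.16 mmol/gDWC/h,
abundances 0.9/0.1, maintenance 1 and 2 mmol/gDW/h, `α = 7.9303`,
`MW = 86`. The biomass demand (1 substrate, 40 ATP, 1 ammonia per gram)
was chosen to put growth rates in the 0.2–0.5 h⁻¹ range typical of
rhizobia on dicarboxylic acids. Under these conditions the toy community
grows at 0.297 h⁻¹ on dinitrogen versus 0.355 h⁻¹ on ammonia, raising
the non-growing fraction from 5 % to 30 % lowers μ₁ by 28 % and
nitrogen fixation by 13 %, and the oxygen scan is unimodal with the
scavenging oxidase activating just past the optimum. These declines are
provable from the closed form for any positive parameter set (the
abundance-weighted maintenance and the top-up burden both rise with the
non-growing fraction), so the qualitative test assertions do not depend
on the particular defaults.

What the toy does *not* emulate: genome-scale redundancy (hundreds of
alternative pathways), realistic P/O ratios, proton and charge balance,
or carbon bookkeeping beyond what the scans need. Passing toy tests
therefore validates the *method* — scaling, coupling, solver, scenario
logic — not any genome-scale reconstruction; quantitative claims about
*R. etli* itself require the curated models, which are published as
supplementary workbooks and are not redistributed here (the acceptance
tests name the option hooks for local copies).

## Scenario conventions

* **Source screens** pin the carbon source as an equality at a
  carbon-matched uptake (`rate × ref_carbons / carbons` relative to the
  4.16 mmol/gDWC/h succinate reference), open exactly one nitrogen
  source, and always leave ammonia secretion open so dual C/N substrates
  can shed excess nitrogen.
* **Exchange robustness** pins the net community-basis transfer of one
  shared species between the members (negative = non-growing → growing)
  via an extra equality row; the pool exchange of that species stays
  closed so it is strictly inter-member.
* **Abundance sensitivity** rebuilds `r = f/(1−f)` and the
  differentiation coefficient per fraction; the merged network is reused
  because it is abundance-independent.
* **Oxygen scans** pin total community O₂ uptake on a grid; the
  feasibility threshold comes from LP + bisection, and oxidase
  activation calls are made degeneracy-safe by reporting the *maximum*
  flux of each oxidase over all optima (a path is "off" only when even
  its maximum is zero).
* **PCA** of flux distributions is mean-centred without unit-variance
  scaling: fluxes share units, and scaling would inflate near-zero
  reactions. Community solutions are folded onto the single-cell
  reaction index by abundance-weighted summation over members
  (`summed_member_fluxes()`), with pool transports mapped back to the
  exchange reactions they replaced. With four conditions at most three
  components carry variance; the tests assert first-component dominance
  rather than a fixed percentage, since the exact split depends on which
  degenerate optimum a solver returns.

## Known limitations

* Two-member communities are the tested regime; the construction code is
  generic over member counts, but coupling specs describe exactly one
  growing/non-growing pair.
* Exchange bounds of member models are replaced by open pool exchanges
  during community construction; medium composition must be set on the
  `EX_*[u]` reactions afterwards.
* The dense simplex targets problems up to a few hundred variables —
  ample for the shipped models, but genome-scale matrices with tens of
  thousands of reactions would need a sparse factorised solver.
* No thermodynamic or loopless constraints; flux directions are governed
  by bounds alone.

## Problem sizes in the tests

The suite solves LPs of 12–500 variables (micro fixtures through
parsimonious community solves), runs scans of 4–10 grid points and an
oxygen scan at 0.8-resolution with bisection refinement, and enumerates
basic solutions exhaustively on fixtures of up to 12 columns; the full
suite completes in about a minute on one CPU.
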