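# xfba

Constraint-based modelling of microbial communities whose members keep
**fixed relative abundances while growing at different rates** — the
situation of free-living diazotrophs such as *Rhizobium etli*, where a
small sub-population differentiates into non-growing, nitrogen-fixing
cells (the analogue of cyanobacterial heterocysts) and feeds ammonia to
the growing majority. Classical community FBA frameworks (cFBA,
SteadyCom) weight member fluxes by abundance but force all members to
grow at the same rate, which cannot represent a member whose growth rate
is zero. `xfba` removes that assumption.

## The model

For members with fixed abundance fractions `X_m` (summing to 1), the
community steady state is imposed on the abundance-scaled stoichiometry

```
S_x = S · X,      S_x v = 0,      lb ≤ v ≤ ub
```

where `X` is block-diagonal: each member's columns are multiplied by its
abundance, while the exchange columns of the shared metabolite pool `[u]`
form an identity block, so pool exchange fluxes read directly on the
community basis (mmol per gram community dry weight per hour).

Unequal growth with constant composition is enforced by three linear
coupling rows. The growing member carries two biomass fluxes — growth
`μ₁` and differentiation `μ₁*`, which converts growing into non-growing
biomass. The non-growing member accumulates mass both from
differentiation and from topping up its storage polymer
(poly-β-hydroxybutyrate, PHB) from a base mass fraction `p_base` (15.9 %)
to a target `p_target` (50 %):

```
v_PHB = α · μ₁*                      (storage top-up)
μ₂    = μ₁* + MW_PHB · v_PHB / 1000  (non-growing accumulation)
μ₂    = r · μ₁                       (fixed abundance ratio, r = X₂/X₁)
```

with `α = 1000 · (p_target − p_base)/p_target / MW_PHB` mmol PHB per gram
of differentiated biomass (`α = 7.9303` at the defaults). Substituting
gives the differentiation coefficient `μ₁*/μ₁ = r / (1 + α·MW_PHB/1000)`.
Maximising `μ₁` then also maximises the total community growth
`μ₁ + μ₂ = (1 + r) μ₁`. The LP stays linear because abundances are data,
not variables.

Around that core the package provides model I/O (TSV, JSON and the
supplementary-workbook XLSX dialect), stoichiometric-matrix assembly,
dead-end detection, biomass-reaction construction from a macromolecular
composition table, plain FBA with parsimonious flux reporting, flux
variability analysis, community construction with a shared pool, the
scenario batteries (carbon/nitrogen source screens, inter-member exchange
robustness, abundance sensitivity, oxygen/terminal-oxidase scans), PCA of
flux distributions, and an analytically solvable toy diazotroph for
testing. The LP layer is a bounded-variable two-phase simplex with
Bland's rule, built for the heavily degenerate LPs these models produce.

## Worked example

```r
library(xfba)

spec <- toy_spec()                       # analytically tractable toy cell
toy  <- make_toy_community(spec)         # growing + N-fixing members, 0.9/0.1
sol  <- solve_xfba(toy$community, toy$spec,
                   fixed = c(`EX_sub[u]` = -4.16))  # pin substrate uptake
glance(sol)
#> # A tibble: 1 × 9
#>   model    status  objective  objective_value   mu1 mu1_star    mu2 community_growth  v_phb
#>   <chr>    <chr>   <chr>                <dbl> <dbl>    <dbl>  <dbl>            <dbl>  <dbl>
#> 1 communi… optimal BIOMASS[g]           0.268 0.268   0.0177 0.0297            0.297  0.140

member_phb_content(sol)
#> # A tibble: 2 × 2
#>   member phb_fraction
#> 1 g             0.159
#> 2 nf            0.5
```

Here `mu1 = 0.2677 h⁻¹` is the growing member's community-basis growth
rate at a community substrate uptake of 4.16 mmol/gDWC/h with dinitrogen
as sole nitrogen source; `mu1_star` is the differentiation flux keeping
the 10 % non-growing fraction constant, `mu2 = r·mu1` the non-growing
accumulation, and `v_phb` the PHB top-up that raises the non-growing
members' storage content to exactly 50 % (the growing member stays at the
base 15.9 %). All five values match the toy's closed-form optimum
(`toy_community_closed_form()`) to solver precision.

Scenario batteries return tibbles and plot with `autoplot()`:

```r
ab <- abundance_sensitivity(toy$community, toy$spec,
                            fixed = c(`EX_sub[u]` = -4.16))
ab[c("fraction", "mu1", "n2_fixation")]
#> fraction  mu1     n2_fixation
#> 0.05      0.284   0.147
#> ...
#> 0.30      0.204   0.128      # growth -28 %, fixation -13 %
```

A thin command-line wrapper sits in `inst/cli/xfba`
(`xfba run config.yaml`, `xfba model validate|convert`,
`xfba fixtures make`).

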