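#' Parameters for the analytically tractable toy cell
#'
#' The toy cell is a ~30-reaction caricature of an aerobic diazotroph with
#' the structural features the community method exercises: two terminal
#' oxidases with different ATP-per-oxygen yields (the proton-pumping
#' cytochrome c path versus the oxygen-scavenging cytochrome bd path), a
#' nitrogenase with a high ATP bill, nitrite/nitrate reduction at graded
#' reducing-power costs, a formate overflow valve, a storage-polymer (PHB)
#' sink, a biomass sink and an exact ATP-maintenance flux. Stoichiometries
#' are small integers so FBA optima are exact rationals with closed forms
#' (see [toy_growth_closed_form()]).
#'
#' @param yield_cytc ATP per reducing equivalent via cytochrome c.
#' @param o2_per_red_cytc O2 per reducing equivalent via cytochrome c.
#' @param yield_cytbd ATP per reducing equivalent via cytochrome bd (must
#'   yield less ATP per O2 than the c path).
#' @param o2_per_red_cytbd O2 per reducing equivalent via cytochrome bd.
#' @param red_per_substrate Reducing equivalents per substrate catabolised.
#' @param atp_per_nh3_fixed ATP per ammonia from dinitrogen fixation
#'   (default 8, i.e. 16 per N2).
#' @param red_per_nh3_no2,red_per_nh3_no3 Reducing equivalents to reduce
#'   nitrite / nitrate to ammonia.
#' @param biomass_substrate,biomass_atp,biomass_nh3 Demand per gram of
#'   biomass (mmol substrate, ATP, ammonia).
#' @param atpm Maintenance ATP flux, enforced exactly (lb = ub).
#' @param aa_cap Member-level cap on the efficient amino-acid synthesis
#'   isozyme; beyond it a wasteful isozyme carries the flux.
#' @param big Default wide bound magnitude.
#' @param seed Optional integer; jitters the non-binding wide bounds only
#'   (never stoichiometry), so closed forms stay valid.
#' @return A `toy_spec` list.
#' @export
toy_spec <- function(yield_cytc = 2, o2_per_red_cytc = 0.5,
                     yield_cytbd = 1, o2_per_red_cytbd = 1,
                     red_per_substrate = 2, atp_per_nh3_fixed = 8,
                     red_per_nh3_no2 = 3, red_per_nh3_no3 = 5,
                     biomass_substrate = 1, biomass_atp = 40,
                     biomass_nh3 = 1, atpm = 1, aa_cap = 0.5,
                     big = 1000, seed = NULL) {
  spec <- list(yield_cytc = yield_cytc, o2_per_red_cytc = o2_per_red_cytc,
               yield_cytbd = yield_cytbd, o2_per_red_cytbd = o2_per_red_cytbd,
               red_per_substrate = red_per_substrate,
               atp_per_nh3_fixed = atp_per_nh3_fixed,
               red_per_nh3_no2 = red_per_nh3_no2,
               red_per_nh3_no3 = red_per_nh3_no3,
               biomass_substrate = biomass_substrate,
               biomass_atp = biomass_atp, biomass_nh3 = biomass_nh3,
               atpm = atpm, aa_cap = aa_cap, big = big, seed = seed)
  stopifnot(yield_cytc > 0, yield_cytbd > 0, o2_per_red_cytc > 0,
            o2_per_red_cytbd > 0, red_per_substrate > 0, atpm >= 0)
  if (o2_per_red_cytbd / yield_cytbd <= o2_per_red_cytc / yield_cytc) {
    stop("cytochrome bd must consume more O2 per ATP than cytochrome c",
         call. = FALSE)
  }
  structure(spec, class = "toy_spec")
}

#' Build the toy cell model
#'
#' Default exchange state: substrate, ammonia and oxygen open for uptake;
#' dinitrogen, nitrite, nitrate and the alternative carbon sources closed;
#' carbon dioxide and formate secretion-only; the amino-acid exchange shut
#' (it only matters between community members).
#'
#' @param spec A [toy_spec()].
#' @param atpm Override the maintenance flux (member-level, lb = ub).
#' @return A [metabolic_model()] with objective `BIOMASS`.
#' @export
make_toy_cell <- function(spec = toy_spec(), atpm = spec$atpm) {
  B <- spec$big
  ex_met <- c("sub", "glc6", "mal", "nh3", "n2", "no2", "no3", "o2", "co2",
              "for", "aa")
  mets <- tibble::tibble(id = c(paste0(ex_met, "[e]"),
                                paste0(c("sub", "red", "atp", "nh3", "n2",
                                         "no2", "no3", "o2", "co2", "for",
                                         "aa", "phb"), "[c]")))
  st <- function(...) {
    v <- c(...)
    stats::setNames(as.numeric(v), names(v))
  }
  rxn <- tibble::tibble(
    id = character(), stoichiometry = list(), lower_bound = numeric(),
    upper_bound = numeric(), subsystem = character())
  add <- function(rxn, id, stoich, lb = 0, ub = B, subsystem = NA_character_) {
    dplyr::bind_rows(rxn, tibble::tibble(
      id = id, stoichiometry = list(stoich), lower_bound = lb,
      upper_bound = ub, subsystem = subsystem))
  }
  # exchanges (positive = secretion, uptake = negative flux)
  open_uptake <- c("sub", "nh3", "o2")
  for (x in ex_met) {
    lb <- if (x %in% open_uptake) -B else 0
    ub <- if (x == "aa") 0 else B
    rxn <- add(rxn, paste0("EX_", x), st(stats::setNames(-1, paste0(x, "[e]"))),
               lb = lb, ub = ub, subsystem = "exchange")
  }
  # transports
  for (x in c("sub", "nh3", "n2", "no2", "no3", "o2", "co2", "for", "aa")) {
    rxn <- add(rxn, paste0("T_", x),
               st(stats::setNames(c(-1, 1), paste0(x, c("[e]", "[c]")))),
               lb = -B, ub = B, subsystem = "transport")
  }
  rxn <- add(rxn, "T_glc6", st(`glc6[e]` = -1, `sub[c]` = 1.5, `red[c]` = 1),
             subsystem = "transport")
  rxn <- add(rxn, "T_mal", st(`mal[e]` = -1, `red[c]` = -0.5, `sub[c]` = 1),
             subsystem = "transport")
  # core metabolism
  rxn <- add(rxn, "CAT",
             st(`sub[c]` = -1, `red[c]` = spec$red_per_substrate, `co2[c]` = 4),
             subsystem = "catabolism")
  rxn <- add(rxn, "CYTC",
             st(`red[c]` = -1, `o2[c]` = -spec$o2_per_red_cytc,
                `atp[c]` = spec$yield_cytc),
             subsystem = "oxidative phosphorylation")
  rxn <- add(rxn, "CYTBD",
             st(`red[c]` = -1, `o2[c]` = -spec$o2_per_red_cytbd,
                `atp[c]` = spec$yield_cytbd),
             subsystem = "oxidative phosphorylation")
  rxn <- add(rxn, "NIT",
             st(`n2[c]` = -1, `atp[c]` = -2 * spec$atp_per_nh3_fixed,
                `nh3[c]` = 2),
             subsystem = "nitrogen fixation")
  rxn <- add(rxn, "NO2R",
             st(`no2[c]` = -1, `red[c]` = -spec$red_per_nh3_no2, `nh3[c]` = 1),
             subsystem = "nitrogen assimilation")
  rxn <- add(rxn, "NO3R",
             st(`no3[c]` = -1, `red[c]` = -spec$red_per_nh3_no3, `nh3[c]` = 1),
             subsystem = "nitrogen assimilation")
  rxn <- add(rxn, "FERM", st(`sub[c]` = -1, `for[c]` = 4),
             subsystem = "overflow")
  rxn <- add(rxn, "PHB_SYN", st(`sub[c]` = -1, `atp[c]` = -1, `phb[c]` = 1),
             subsystem = "storage")
  rxn <- add(rxn, "DM_phb", st(`phb[c]` = -1), subsystem = "storage")
  rxn <- add(rxn, "AA_SYN_EFF",
             st(`nh3[c]` = -1, `sub[c]` = -1, `aa[c]` = 1),
             ub = spec$aa_cap, subsystem = "amino acid")
  rxn <- add(rxn, "AA_SYN_WASTE",
             st(`nh3[c]` = -1, `sub[c]` = -2, `aa[c]` = 1, `co2[c]` = 4),
             subsystem = "amino acid")
  rxn <- add(rxn, "AA_DEG", st(`aa[c]` = -1, `nh3[c]` = 1, `sub[c]` = 1),
             subsystem = "amino acid")
  rxn <- add(rxn, "ATPM", st(`atp[c]` = -1), lb = atpm, ub = atpm,
             subsystem = "maintenance")
  rxn <- add(rxn, "BIOMASS",
             st(`sub[c]` = -spec$biomass_substrate,
                `atp[c]` = -spec$biomass_atp,
                `nh3[c]` = -spec$biomass_nh3),
             subsystem = "biomass")
  model <- metabolic_model("toy_cell", metabolites = mets, reactions = rxn,
                           objective = "BIOMASS")
  if (!is.null(spec$seed)) model <- jitter_wide_bounds(model, spec$seed, B)
  model
}

# multiply non-binding wide bounds by a deterministic factor in [1, 1.25];
# stoichiometry and tight bounds are never touched
jitter_wide_bounds <- function(model, seed, big) {
  state <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(state)) assign(".Random.seed", state,
                                      envir = globalenv()), add = TRUE)
  set.seed(seed)
  n <- nrow(model$reactions)
  f <- 1 + 0.25 * stats::runif(n)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  model$reactions$lower_bound <- ifelse(lb == -big, -big * f, lb)
  model$reactions$upper_bound <- ifelse(ub == big, big * f, ub)
  model
}

#' Closed-form toy-cell growth rate
#'
#' For the toy cell on a pinned substrate uptake with ample oxygen, the FBA
#' optimum has the closed form
#' `mu = (Yc * rho * s - m) / (e_b + Yc * rho * s_b + Yc * q * n_b)`
#' where `Yc` is the cytochrome-c ATP yield per reducing equivalent, `rho`
#' the reducing equivalents per substrate, `s` the substrate uptake, `m` the
#' maintenance, `e_b`/`s_b`/`n_b` the biomass ATP/substrate/ammonia demands
#' and `q` the reducing-power cost per ammonia of the nitrogen source
#' (0 for ammonia). For dinitrogen the ATP cost enters directly:
#' `mu = (Yc * rho * s - m) / (e_b + Yc * rho * s_b + a * n_b)` with `a`
#' ATP per ammonia.
#'
#' @param spec A [toy_spec()].
#' @param substrate_rate Pinned substrate uptake, mmol/gDW/h.
#' @param n_source `"nh3"`, `"no2"`, `"no3"` or `"n2"`.
#' @param atpm Maintenance override.
#' @return The optimal growth rate in 1/h (0 when the closed form is
#'   negative; the LP is infeasible only when even zero growth cannot cover
#'   maintenance).
#' @export
toy_growth_closed_form <- function(spec, substrate_rate, n_source = "nh3",
                                   atpm = spec$atpm) {
  yc <- spec$yield_cytc
  rho <- spec$red_per_substrate
  num <- yc * rho * substrate_rate - atpm
  den <- spec$biomass_atp + yc * rho * spec$biomass_substrate
  den <- den + switch(n_source,
    nh3 = 0,
    no2 = yc * spec$red_per_nh3_no2 * spec$biomass_nh3,
    no3 = yc * spec$red_per_nh3_no3 * spec$biomass_nh3,
    n2 = spec$atp_per_nh3_fixed * spec$biomass_nh3,
    stop("unknown n_source ", sQuote(n_source), call. = FALSE))
  max(0, num / den)
}

#' Build the two-member toy community
#'
#' Growing member (`"g"`): nitrogenase shut, two biomass fluxes (growth and
#' differentiation), storage sink shut. Non-growing member (`"nf"`): no
#' biomass reactions, nitrogenase active, storage (PHB) sink active,
#' higher maintenance. All extracellular species are shared through the
#' community pool; ammonia, nitrite, nitrate and the amino acid cannot be
#' imported from outside (dinitrogen is the sole external nitrogen source),
#' and the amino-acid pool species is strictly inter-member.
#'
#' @param spec A [toy_spec()].
#' @param abundances Named abundances for tags `g` and `nf`.
#' @param coupling A [coupling_spec()]; by default built from the
#'   abundances with `alpha = compute_alpha()` defaults.
#' @param atpm_growing,atpm_non_growing Member maintenance fluxes
#'   (member-level mmol/gDW/h).
#' @return `list(community, spec)` with the [build_community()] result and
#'   the coupling spec.
#' @export
make_toy_community <- function(spec = toy_spec(),
                               abundances = c(g = 0.9, nf = 0.1),
                               coupling = NULL,
                               atpm_growing = spec$atpm,
                               atpm_non_growing = 2 * spec$atpm) {
  growing <- make_toy_cell(spec, atpm = atpm_growing)
  growing <- set_bounds(growing, "NIT", lower = 0, upper = 0)
  growing <- set_bounds(growing, "DM_phb", lower = 0, upper = 0)
  diff_rxn <- growing$reactions[growing$reactions$id == "BIOMASS", ]
  growing <- add_reaction(growing, list(
    id = "BIOMASS_DIFF", name = "differentiation biomass",
    stoichiometry = diff_rxn$stoichiometry[[1]],
    lower_bound = 0, upper_bound = spec$big, subsystem = "biomass"))

  nonGrowing <- make_toy_cell(spec, atpm = atpm_non_growing)
  nonGrowing <- remove_reactions(nonGrowing, "BIOMASS")
  nonGrowing$id <- "toy_cell_nf"

  comm <- build_community(list(g = growing, nf = nonGrowing),
                          abundance_vector(abundances))
  # external medium: dinitrogen is the only nitrogen source; the amino acid
  # never leaves or enters the community
  for (x in c("nh3", "no2", "no3", "glc6", "mal", "co2", "for")) {
    comm$model <- set_bounds(comm$model, paste0("EX_", x, "[u]"), lower = 0)
  }
  comm$model <- set_bounds(comm$model, "EX_aa[u]", lower = 0, upper = 0)

  if (is.null(coupling)) {
    coupling <- coupling_spec(
      r = abundances[["nf"]] / abundances[["g"]],
      alpha = compute_alpha(), mw_phb = 86.0,
      growth = "BIOMASS", differentiation = "BIOMASS_DIFF",
      phb_exchange = "DM_phb", growing = "g", non_growing = "nf",
      p_base = 0.159)
  }
  list(community = comm, spec = coupling)
}

#' Closed-form optimum of the coupled toy community
#'
#' With substrate pinned at `s` (community basis), dinitrogen as sole
#' nitrogen source and ample oxygen, every quantity of the coupled optimum
#' is available in closed form (see the methods vignette for the
#' derivation):
#' `mu1 = (Yc*rho*s - mbar) / ((e_b + a*n_b + Yc*rho*s_b)*(1+c) +
#' (1 + Yc*rho)*alpha*c)` with `c` the differentiation coefficient and
#' `mbar` the abundance-weighted maintenance; each mmol of PHB costs one
#' substrate (worth `Yc*rho` ATP) plus one ATP directly.
#'
#' @param spec A [toy_spec()].
#' @param abundances Named abundances (`g`, `nf`).
#' @param coupling A [coupling_spec()].
#' @param substrate_rate Pinned community substrate uptake.
#' @param atpm_growing,atpm_non_growing Member maintenance values.
#' @return List with `mu1`, `mu1_star`, `mu2`, `community_growth`, `v_phb`,
#'   `v_fix` (community-basis dinitrogen uptake).
#' @export
toy_community_closed_form <- function(spec, abundances, coupling,
                                      substrate_rate,
                                      atpm_growing = spec$atpm,
                                      atpm_non_growing = 2 * spec$atpm) {
  yrho <- spec$yield_cytc * spec$red_per_substrate
  mbar <- abundances[["g"]] * atpm_growing +
    abundances[["nf"]] * atpm_non_growing
  cc <- differentiation_coefficient(coupling)
  a <- spec$atp_per_nh3_fixed
  denom <- (spec$biomass_atp + a * spec$biomass_nh3 +
              yrho * spec$biomass_substrate) * (1 + cc) +
    (1 + yrho) * coupling$alpha * cc
  mu1 <- max(0, (yrho * substrate_rate - mbar) / denom)
  mu1s <- cc * mu1
  v_phb <- coupling$alpha * mu1s
  mu2 <- mu1s + coupling$mw_phb * v_phb / 1000
  list(mu1 = mu1, mu1_star = mu1s, mu2 = mu2,
       community_growth = mu1 + mu2, v_phb = v_phb,
       v_fix = spec$biomass_nh3 * (mu1 + mu1s) / 2)
}
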