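# Small fixtures built in code.

# Linear chain with exchanges: uptake -> A -> B -> secretion.
chain_model <- function() {
  metabolic_model(
    "chain",
    metabolites = tibble::tibble(id = c("a[e]", "a[c]", "b[c]", "b[e]")),
    reactions = tibble::tibble(
      id = c("EX_a", "T_a", "R1", "T_b", "EX_b"),
      formula = c("a[e] <=> ", "a[e] -> a[c]", "a[c] -> b[c]",
                  "b[c] -> b[e]", "b[e] -> "),
      lower_bound = c(-10, 0, 0, 0, 0),
      upper_bound = c(0, 1000, 1000, 1000, 1000)),
    objective = "EX_b")
}

# Two parallel equivalent routes from A to B (constructed degeneracy).
parallel_model <- function() {
  metabolic_model(
    "parallel",
    metabolites = tibble::tibble(id = c("a[e]", "a[c]", "b[c]", "b[e]")),
    reactions = tibble::tibble(
      id = c("EX_a", "T_a", "R1", "R2", "T_b", "EX_b"),
      formula = c("a[e] <=> ", "a[e] -> a[c]", "a[c] -> b[c]",
                  "a[c] -> b[c]", "b[c] -> b[e]", "b[e] -> "),
      lower_bound = c(-4, 0, 0, 0, 0, 0),
      upper_bound = c(0, 1000, 1000, 1000, 1000, 1000)),
    objective = "EX_b")
}

# Substrate needs 2 O2 per unit: min-O2-for-feasibility fixture.
o2_ratio_model <- function() {
  metabolic_model(
    "o2ratio",
    metabolites = tibble::tibble(id = c("s[e]", "s[c]", "o2[e]", "o2[c]",
                                        "p[c]", "p[e]")),
    reactions = tibble::tibble(
      id = c("EX_s", "T_s", "EX_o2", "T_o2", "BURN", "T_p", "EX_p"),
      formula = c("s[e] <=> ", "s[e] -> s[c]", "o2[e] <=> ",
                  "o2[e] -> o2[c]", "s[c] + 2 o2[c] -> p[c]",
                  "p[c] -> p[e]", "p[e] -> "),
      lower_bound = c(-1000, 0, -1000, 0, 0, 0, 0),
      upper_bound = c(1000, 1000, 1000, 1000, 1000, 1000, 1000)),
    objective = "EX_p")
}

# Minimal growing/non-growing pair small enough for the enumeration
# oracle (12 merged columns): lumped catabolism (sub -> 2 atp), biomass
# (atp + nh3), ammonia "fixed" at pure ATP cost in the non-growing member
# (dinitrogen left implicit), storage as a substrate sink. Shares sub and
# nh3 through the pool.
micro_member <- function(growing = TRUE) {
  base <- tibble::tibble(
    id = c("EX_sub", "EX_nh3", "CATL"),
    formula = c("sub[e] <=> ", "nh3[e] <=> ", "sub[e] -> 2 atp[c]"),
    lower_bound = c(-1000, -1000, 0),
    upper_bound = rep(1000, 3))
  if (growing) {
    rxn <- dplyr::bind_rows(base, tibble::tibble(
      id = c("BIOMASS", "BIOMASS_DIFF"),
      formula = c("1 atp[c] + 1 nh3[e] -> ", "1 atp[c] + 1 nh3[e] -> "),
      lower_bound = 0, upper_bound = 1000))
  } else {
    rxn <- dplyr::bind_rows(base, tibble::tibble(
      id = c("NITL", "DM_phb"),
      formula = c("8 atp[c] -> 1 nh3[e]", "2 atp[c] -> "),
      lower_bound = 0, upper_bound = 1000))
  }
  metabolic_model(
    if (growing) "micro_g" else "micro_nf",
    metabolites = tibble::tibble(id = c("sub[e]", "nh3[e]", "atp[c]")),
    reactions = rxn, objective = if (growing) "BIOMASS" else NULL)
}

micro_community <- function(abundances = c(g = 0.9, nf = 0.1),
                            alpha = compute_alpha(), r = NULL) {
  comm <- build_community(list(g = micro_member(TRUE),
                               nf = micro_member(FALSE)),
                          abundance_vector(abundances))
  comm$model <- set_bounds(comm$model, "EX_nh3[u]", lower = 0)
  spec <- coupling_spec(
    r = r %||% (abundances[["nf"]] / abundances[["g"]]),
    alpha = alpha, mw_phb = 86.0,
    growth = "BIOMASS", differentiation = "BIOMASS_DIFF",
    phb_exchange = "DM_phb", growing = "g", non_growing = "nf",
    p_base = 0.159)
  list(community = comm, spec = spec)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
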