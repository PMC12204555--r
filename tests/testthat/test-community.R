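test_that("abundance vectors enforce positivity and closure", {
  expect_error(abundance_vector(g = 0.9, nf = 0.2), "sum to")
  expect_error(abundance_vector(g = 1, nf = 0), "strictly positive")
  expect_error(abundance_vector(0.5, 0.5), "named")
  x <- abundance_vector(g = 0.9, nf = 0.1)
  expect_equal(sum(x), 1)
})

test_that("a single-member community reproduces the single-model optimum", {
  cell <- micro_member(TRUE)
  comm <- build_community(list(g = cell), abundance_vector(c(g = 1)))
  comm$model <- set_bounds(comm$model, "EX_sub[u]", lower = -3, upper = -3)
  comm$model$objective <- "BIOMASS[g]"
  sol <- solve_xfba(comm, spec = NULL)
  single <- solve_fba(cell, fixed = c(EX_sub = -3))
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, single$objective_value,
               tolerance = 1e-8)
})

test_that("two identical members at 0.5/0.5 with equal growth match one cell", {
  cell <- micro_member(TRUE)
  comm <- build_community(list(m1 = cell, m2 = cell),
                          abundance_vector(c(m1 = 0.5, m2 = 0.5)))
  comm$model <- set_bounds(comm$model, "EX_sub[u]", lower = -3, upper = -3)
  rxn_ids <- comm$model$reactions$id
  A <- matrix(0, 1, length(rxn_ids), dimnames = list("eq", rxn_ids))
  A[1, "BIOMASS[m1]"] <- 1
  A[1, "BIOMASS[m2]"] <- -1
  sol <- solve_xfba(comm, spec = NULL, objective = "BIOMASS[m1]",
                    extra_eq = list(A = A, b = 0))
  single <- solve_fba(cell, fixed = c(EX_sub = -3))
  b1 <- flux_of(sol, "BIOMASS[m1]")[[1]]
  b2 <- flux_of(sol, "BIOMASS[m2]")[[1]]
  expect_equal(b1, b2, tolerance = 1e-8)
  expect_equal(0.5 * b1 + 0.5 * b2, single$objective_value,
               tolerance = 1e-7)
})

test_that("community construction tags members and reroutes shared species", {
  mc <- micro_community()
  merged <- mc$community$model
  expect_true(all(c("TR_sub[g]", "TR_nh3[nf]", "EX_sub[u]", "EX_nh3[u]")
                  %in% merged$reactions$id))
  # member exchanges for shared species are gone
  expect_false(any(c("EX_sub[g]", "EX_nh3[nf]") %in% merged$reactions$id))
  memb <- merged$reactions$member
  expect_true(all(is.na(memb[grepl("\\[u\\]$", merged$reactions$id)])))
  expect_true(all(!is.na(memb[!grepl("\\[u\\]$", merged$reactions$id)])))
  expect_error(
    build_community(list(g = micro_member(TRUE)),
                    abundance_vector(c(g = 1)), shared = "ghost[e]"),
    "absent from every member")
})

test_that("abundance scaling multiplies member blocks and spares exchanges", {
  mc <- micro_community()
  S <- stoichiometric_matrix(mc$community$model)
  X <- abundance_vector(c(g = 0.9, nf = 0.1))
  Sx <- abundance_scale(S, X, mc$community$model$reactions$member)
  memb <- mc$community$model$reactions$member
  for (j in seq_len(ncol(S))) {
    f <- if (is.na(memb[j])) 1 else X[[memb[j]]]
    expect_equal(as.numeric(Sx[, j]), f * as.numeric(S[, j]),
                 info = colnames(S)[j])
  }
  expect_error(abundance_scale(S, X, rep("stranger", ncol(S))),
               "unknown member")
  # single member at abundance 1: identity
  one <- build_community(list(g = micro_member(TRUE)),
                         abundance_vector(c(g = 1)))
  S1 <- stoichiometric_matrix(one$model)
  expect_equal(as.matrix(abundance_scale(S1, abundance_vector(c(g = 1)),
                                         one$model$reactions$member)),
               as.matrix(S1))
})

test_that("a shared metabolite balances abundance-weighted member fluxes", {
  # producer at 0.1 abundance, consumer at 0.9: pool balance forces
  # 0.1 * p = 0.9 * c, checked on a two-reaction micro community
  mc <- micro_community(abundances = c(g = 0.9, nf = 0.1), alpha = 0)
  sol <- solve_xfba(mc$community, mc$spec,
                    fixed = c(`EX_sub[u]` = -3))
  p <- flux_of(sol, "TR_nh3[nf]")[[1]]   # nf exports ammonia to the pool
  cns <- -flux_of(sol, "TR_nh3[g]")[[1]] # g imports it
  expect_gt(p, 0)
  expect_equal(0.1 * p, 0.9 * cns, tolerance = 1e-8)
})

test_that("differentiation coefficient follows the closed form", {
  expect_equal(differentiation_coefficient(1 / 9, alpha = 7.9303,
                                           mw_phb = 86.0),
               (1 / 9) / (1 + 7.9303 * 86 / 1000), tolerance = 1e-12)
  expect_equal(differentiation_coefficient(1 / 9, alpha = 7.9303,
                                           mw_phb = 86.0),
               0.0661, tolerance = 1e-3)
  expect_equal(differentiation_coefficient(1 / 4, alpha = 7.9303,
                                           mw_phb = 86.0),
               0.1486, tolerance = 1e-3)
  expect_equal(differentiation_coefficient(0.37, alpha = 0, mw_phb = 86),
               0.37)
  spec <- coupling_spec(r = 1 / 9, alpha = 7.9303)
  cc <- differentiation_coefficient(spec)
  expect_true(cc > 0 && cc <= spec$r)
})

test_that("coupling identities hold as equalities in every optimum", {
  spec <- toy_spec()
  toy <- make_toy_community(spec)
  for (pin in c(-4.16, -2, -6)) {
    sol <- solve_xfba(toy$community, toy$spec,
                      fixed = c(`EX_sub[u]` = pin))
    expect_equal(sol$status, "optimal")
    mu1 <- member_aggregate(sol, "mu1")
    mu1s <- member_aggregate(sol, "mu1_star")
    mu2 <- member_aggregate(sol, "mu2")
    v_phb <- member_aggregate(sol, "v_phb")
    expect_lt(abs(v_phb - toy$spec$alpha * mu1s), 1e-8)
    expect_lt(abs(mu2 - (mu1s + toy$spec$mw_phb * v_phb / 1000)), 1e-8)
    expect_lt(abs(mu2 - toy$spec$r * mu1), 1e-8)
    cc <- differentiation_coefficient(toy$spec)
    expect_lt(abs(mu1s - cc * mu1), 1e-8)
    # aggregate steady state on the abundance-scaled system
    Sx <- abundance_scale(
      stoichiometric_matrix(toy$community$model),
      abundance_vector(c(g = 0.9, nf = 0.1)),
      toy$community$model$reactions$member)
    expect_lt(max(abs(as.numeric(Sx %*% sol$fluxes$flux))), 1e-6)
  }
})

test_that("coupled XFBA equals the hand-derived community closed form", {
  spec <- toy_spec()
  toy <- make_toy_community(spec)
  cf <- toy_community_closed_form(spec, c(g = 0.9, nf = 0.1), toy$spec,
                                  4.16)
  sol <- solve_xfba(toy$community, toy$spec, fixed = c(`EX_sub[u]` = -4.16))
  for (q in c("mu1", "mu1_star", "mu2", "community_growth", "v_phb")) {
    expect_equal(member_aggregate(sol, q), cf[[q]], tolerance = 1e-8,
                 info = q)
  }
  # and for the uncoupled (alpha = 0) variant of the analysis
  spec0 <- toy$spec; spec0$alpha <- 0
  cf0 <- toy_community_closed_form(spec, c(g = 0.9, nf = 0.1), spec0, 4.16)
  sol0 <- solve_xfba(toy$community, spec0, fixed = c(`EX_sub[u]` = -4.16))
  expect_equal(member_aggregate(sol0, "mu1"), cf0$mu1, tolerance = 1e-8)
  expect_equal(member_aggregate(sol0, "mu2"),
               spec0$r * member_aggregate(sol0, "mu1"), tolerance = 1e-9)
})

test_that("micro-community XFBA equals an independently assembled dense LP", {
  mc <- micro_community()
  comm <- mc$community; spec <- mc$spec
  sol <- solve_xfba(comm, spec, fixed = c(`EX_sub[u]` = -2), pfba = FALSE)
  expect_equal(sol$status, "optimal")

  # assemble the scaled dense system in the test, from first principles
  merged <- comm$model
  M <- dense_stoichiometry(merged)
  X <- c(g = 0.9, nf = 0.1)
  w <- ifelse(is.na(merged$reactions$member), 1,
              X[merged$reactions$member])
  Mx <- sweep(M, 2, w, `*`)
  ids <- merged$reactions$id
  extra <- matrix(0, 2, length(ids), dimnames = list(NULL, ids))
  extra[1, "DM_phb[nf]"] <- 0.1
  extra[1, "BIOMASS_DIFF[g]"] <- -spec$alpha * 0.9
  extra[2, "BIOMASS_DIFF[g]"] <- 0.9
  extra[2, "DM_phb[nf]"] <- spec$mw_phb * 0.1 / 1000
  extra[2, "BIOMASS[g]"] <- -spec$r * 0.9
  lb <- merged$reactions$lower_bound
  ub <- merged$reactions$upper_bound
  lb[ids == "EX_sub[u]"] <- ub[ids == "EX_sub[u]"] <- -2
  orc <- oracle_lp_enumerate(as.numeric(ids == "BIOMASS[g]"),
                             rbind(Mx, extra), rep(0, nrow(Mx) + 2),
                             lb, ub, maximize = TRUE)
  expect_equal(flux_of(sol, "BIOMASS[g]")[[1]], orc$objective,
               tolerance = 1e-7)
})

test_that("PHB content closes exactly at the target fraction", {
  spec <- toy_spec()
  toy <- make_toy_community(spec)
  sol <- solve_xfba(toy$community, toy$spec, fixed = c(`EX_sub[u]` = -4.16))
  ct <- member_phb_content(sol)
  expect_equal(ct$phb_fraction[ct$member == "g"], 0.159)
  # at the 50 % operating point the top-up coefficient is self-consistent:
  # the realised content equals the target exactly
  expect_equal(ct$phb_fraction[ct$member == "nf"], 0.50, tolerance = 1e-9)
  # general analytic chain: with k = alpha*mw/1000 the realised content is
  # (p_base + k)/(1 + k) for any coupling, independent of the network
  for (a in c(2, compute_alpha(0.159, 0.3, 86), 12)) {
    sp <- toy$spec; sp$alpha <- a
    s2 <- solve_xfba(toy$community, sp, fixed = c(`EX_sub[u]` = -4.16))
    ct2 <- member_phb_content(s2, sp)
    k <- a * sp$mw_phb / 1000
    expect_equal(ct2$phb_fraction[ct2$member == "nf"],
                 (sp$p_base + k) / (1 + k), tolerance = 1e-9, info = a)
  }
  # no top-up: the non-growing member inherits the base content
  sp0 <- toy$spec; sp0$alpha <- 0
  s0 <- solve_xfba(toy$community, sp0, fixed = c(`EX_sub[u]` = -4.16))
  ct0 <- member_phb_content(s0, sp0)
  expect_equal(ct0$phb_fraction[ct0$member == "nf"], sp0$p_base,
               tolerance = 1e-9)
})

test_that("maximising mu1 maximises total community growth under coupling", {
  spec <- toy_spec()
  toy <- make_toy_community(spec)
  sol <- solve_xfba(toy$community, toy$spec, fixed = c(`EX_sub[u]` = -4.16))
  best <- member_aggregate(sol, "community_growth")
  # proportionality: mu1 + mu2 = (1 + r) mu1, so no feasible point beats it
  expect_equal(best, (1 + toy$spec$r) * member_aggregate(sol, "mu1"),
               tolerance = 1e-9)
  for (frac in c(0.5, 0.9)) {
    pinned <- solve_xfba(
      toy$community, toy$spec,
      fixed = c(`EX_sub[u]` = -4.16,
                stats::setNames(frac * flux_of(sol, "BIOMASS[g]")[[1]],
                                "BIOMASS[g]")))
    expect_lt(member_aggregate(pinned, "community_growth"), best)
  }
})

test_that("coupling configuration errors are informative", {
  mc <- micro_community()
  bad <- mc$spec
  bad$growth <- "NOT_A_REACTION"
  expect_error(solve_xfba(mc$community, bad), "absent from the community")
  expect_error(coupling_spec(r = -1, alpha = 1), "r > 0")
})
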