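toy_sources <- function() {
  tibble::tibble(
    name = c("glc_nh3", "mal_nh3", "suc_nh3", "suc_no2", "suc_no3"),
    c_exchange = c("EX_glc6", "EX_mal", "EX_sub", "EX_sub", "EX_sub"),
    c_carbons = c(6, 4, 4, 4, 4),
    n_exchange = c("EX_nh3", "EX_nh3", "EX_nh3", "EX_no2", "EX_no3"))
}

test_that("the source screen matches closed forms and is order-invariant", {
  spec <- toy_spec()
  cell <- make_toy_cell(spec)
  src <- toy_sources()
  scr <- nitrogen_carbon_screen(cell, src)
  expect_equal(nrow(scr), 5)
  expect_equal(scr$status, rep("optimal", 5))
  # carbon matching: 6-carbon source at 4.16*4/6
  expect_equal(scr$c_uptake[scr$name == "glc_nh3"], 4.16 * 4 / 6,
               tolerance = 1e-9)
  # closed forms for the succinate-based runs
  expect_equal(scr$mu[scr$name == "suc_nh3"],
               toy_growth_closed_form(spec, 4.16, "nh3"), tolerance = 1e-9)
  expect_equal(scr$mu[scr$name == "suc_no2"],
               toy_growth_closed_form(spec, 4.16, "no2"), tolerance = 1e-9)
  expect_equal(scr$mu[scr$name == "suc_no3"],
               toy_growth_closed_form(spec, 4.16, "no3"), tolerance = 1e-9)
  # the reduced 6-carbon source grows fastest; oxidised N slows growth
  expect_equal(scr$name[which.max(scr$mu)], "glc_nh3")
  expect_gt(scr$mu[scr$name == "suc_nh3"], scr$mu[scr$name == "suc_no2"])
  expect_gt(scr$mu[scr$name == "suc_no2"], scr$mu[scr$name == "suc_no3"])

  # permutation invariance of the source list
  perm <- sample(nrow(src))
  scr2 <- nitrogen_carbon_screen(cell, src[perm, ])
  expect_equal(scr2[order(scr2$name), ], scr[order(scr$name), ],
               ignore_attr = TRUE)
  expect_error(
    nitrogen_carbon_screen(cell, dplyr::mutate(src, c_exchange = "EX_zz")),
    "unknown exchange")
})

test_that("a dual carbon/nitrogen source can shed excess ammonia", {
  spec <- toy_spec()
  cell <- set_bounds(make_toy_cell(spec), "EX_aa", lower = -1000,
                     upper = 1000)
  src <- tibble::tibble(name = "aa_both", c_exchange = "EX_aa",
                        c_carbons = 5, n_exchange = "EX_aa")
  scr <- nitrogen_carbon_screen(cell, src, close = c("EX_sub", "EX_nh3"))
  expect_equal(scr$status, "optimal")
  # the amino acid carries one N per 5 C; growth demand leaves a surplus
  # that must leave as ammonia
  expect_gt(scr$nh3_release, 0)
})

test_that("exchange robustness shows plateau then decline in both directions", {
  spec <- toy_spec()
  toy <- make_toy_community(spec)
  base <- solve_xfba(toy$community, toy$spec, fixed = c(`EX_sub[u]` = -4.16))
  mu0 <- member_aggregate(base, "community_growth")
  grid <- c(-0.3, -0.03, 0, 0.2, 0.4, 0.8)
  rb <- exchange_robustness(toy$community, toy$spec, "aa", grid,
                            fixed = c(`EX_sub[u]` = -4.16))
  expect_equal(nrow(rb), length(grid))
  g <- function(t) rb$community_growth[rb$exchange == t]
  # pinning at the interior optimum changes nothing
  expect_equal(g(0), mu0, tolerance = 1e-9)
  # plateau: small transfers in either direction are free
  expect_equal(g(-0.03), mu0, tolerance = 1e-7)
  expect_equal(g(0.2), mu0, tolerance = 1e-7)
  expect_equal(g(0.4), mu0, tolerance = 1e-7)
  # decline beyond the efficient-isozyme capacity, in both directions
  expect_lt(g(-0.3), mu0 - 1e-4)
  expect_lt(g(0.8), mu0 - 1e-4)
  # pinning only restricts the feasible set: the base bounds everything
  expect_true(all(rb$community_growth <= mu0 + 1e-8, na.rm = TRUE))
})

test_that("the pinned transfer has nonzero variability width at the optimum", {
  spec <- toy_spec()
  toy <- make_toy_community(spec)
  merged <- getFromNamespace("scaled_community_model", "xfba")(toy$community)
  fva <- flux_variability(
    merged, objective = "BIOMASS[g]", reactions = "TR_aa[g]",
    fixed = c(`EX_sub[u]` = -4.16),
    extra_eq = add_coupling_constraints(toy$community, toy$spec))
  expect_gt(fva$max - fva$min, 1e-3)
})

test_that("raising the non-growing share depresses growth and fixation", {
  spec <- toy_spec()
  toy <- make_toy_community(spec)
  fr <- seq(0.05, 0.30, by = 0.05)
  ab <- abundance_sensitivity(toy$community, toy$spec, fractions = fr,
                              fixed = c(`EX_sub[u]` = -4.16))
  expect_equal(ab$status, rep("optimal", length(fr)))
  expect_true(all(diff(ab$mu1) < 0))
  expect_true(all(diff(ab$n2_fixation) < 0))
  expect_true(all(diff(ab$v_phb) > 0))       # storage rises with the share
  expect_true(all(diff(ab$mu2) > 0))
  # ratios recomputed per fraction: r = f/(1-f)
  expect_equal(ab$r, fr / (1 - fr), tolerance = 1e-12)
  # the base fraction reproduces the base-case solution
  base <- solve_xfba(toy$community, toy$spec, fixed = c(`EX_sub[u]` = -4.16))
  expect_equal(ab$mu1[ab$fraction == 0.10],
               member_aggregate(base, "mu1"), tolerance = 1e-9)
  # endpoints match the hand-derived closed form
  for (f in c(0.05, 0.30)) {
    cs <- toy$spec; cs$r <- f / (1 - f)
    cf <- toy_community_closed_form(spec, c(g = 1 - f, nf = f), cs, 4.16)
    expect_equal(ab$mu1[ab$fraction == f], cf$mu1, tolerance = 1e-8)
    expect_equal(ab$n2_fixation[ab$fraction == f], cf$v_fix,
                 tolerance = 1e-8)
  }
})

test_that("the oxygen scan is unimodal with a cytochrome switch", {
  spec <- toy_spec()
  toy <- make_toy_community(spec)
  grid <- c(0.1, seq(0.8, 7.2, by = 0.8))
  ox <- oxygen_cytochrome_scan(toy$community, toy$spec, grid,
                               fixed = c(`EX_sub[u]` = -4.16))
  s <- attr(ox, "summary")
  # below the maintenance-driven threshold the pin is infeasible - recorded
  expect_equal(ox$status[ox$o2 == 0.1], "infeasible")
  # threshold from the LP + bisection equals the closed form:
  # community maintenance ATP (0.9*1 + 0.1*2) at the efficient oxidase
  thr_closed <- (0.9 * spec$atpm + 0.1 * 2 * spec$atpm) *
    spec$o2_per_red_cytc / spec$yield_cytc
  expect_lt(abs(s$feasibility_threshold - thr_closed), 0.011)
  # single interior maximum: growth rises then falls
  g <- ox$community_growth[ox$status == "optimal"]
  peak <- which.max(g)
  expect_gt(peak, 1)
  expect_lt(peak, length(g))
  expect_true(all(diff(g[seq_len(peak)]) > 0))
  expect_true(all(diff(g[peak:length(g)]) < 0))
  expect_equal(ox$o2[ox$status == "optimal"][peak], s$o2_at_max_growth)
  # oxidase sequence: no bd below the optimum, bd onset past it
  bd_total <- ox$CYTBD_g + ox$CYTBD_nf
  low <- ox$status == "optimal" & ox$o2 < s$o2_at_max_growth
  expect_true(all(abs(bd_total[low]) < 1e-8))
  expect_false(is.na(s$bd_activation_onset))
  expect_gte(s$bd_activation_onset, s$o2_at_max_growth)
  high <- ox$status == "optimal" & ox$o2 > s$bd_activation_onset
  expect_true(any(bd_total[high] > 1e-6))
})

test_that("oxygen as a relaxable upper allowance is monotone, pins are not", {
  spec <- toy_spec()
  toy <- make_toy_community(spec)
  merged <- getFromNamespace("scaled_community_model", "xfba")(toy$community)
  coup <- add_coupling_constraints(toy$community, toy$spec)
  vals <- c(-1, -2, -4, -6)   # progressively wider uptake allowance
  sc <- scan_parameter(merged, "EX_o2[u]", vals, objective = "BIOMASS[g]",
                       fixed = c(`EX_sub[u]` = -4.16), bound = "lower",
                       pfba = FALSE, extra_eq = coup)
  expect_true(all(diff(sc$objective_value) > -1e-8))
})

test_that("member fluxes fold onto the single-cell index", {
  mc <- micro_community()
  sol <- solve_xfba(mc$community, mc$spec, fixed = c(`EX_sub[u]` = -2))
  folded <- summed_member_fluxes(sol, mc$community)
  # namespace = union of member reaction ids (pool exchanges omitted)
  expect_setequal(
    folded$reaction,
    union(mc$community$members$model[[1]]$reactions$id,
          mc$community$members$model[[2]]$reactions$id))
  # a reaction carried only by the non-growing member keeps its
  # community-basis value
  expect_equal(folded$flux[folded$reaction == "NITL"],
               0.1 * flux_of(sol, "NITL[nf]")[[1]], tolerance = 1e-12)
  # transports fold back onto the original exchange ids with the summed
  # community-basis flux; total substrate uptake is the pinned 2
  expect_equal(folded$flux[folded$reaction == "EX_sub"], -2,
               tolerance = 1e-8)

  # single-member community: identity mapping up to the exchange fold
  one <- build_community(list(g = micro_member(TRUE)),
                         abundance_vector(c(g = 1)))
  one$model$objective <- "BIOMASS[g]"
  s1 <- solve_xfba(one, spec = NULL,
                   fixed = c(`EX_sub[u]` = -2))
  f1 <- summed_member_fluxes(s1, one)
  single <- solve_fba(micro_member(TRUE), fixed = c(EX_sub = -2))
  for (r in f1$reaction) {
    expect_equal(f1$flux[f1$reaction == r], flux_of(single, r)[[1]],
                 tolerance = 1e-8, info = r)
  }
})

test_that("PCA of flux vectors behaves like a covariance decomposition", {
  # hand-checkable: variance entirely along the first axis
  m <- rbind(a = c(0, 0), b = c(2, 0), c = c(4, 0))
  colnames(m) <- c("r1", "r2")
  p <- pca_flux_comparison(m)
  expect_false(p$degenerate)
  expect_equal(unname(p$explained_variance[1]), 1, tolerance = 1e-12)
  expect_equal(abs(p$loadings$PC1[p$loadings$reaction == "r1"]), 1,
               tolerance = 1e-12)

  # k observations: at most k-1 informative components, fractions sum to 1
  set.seed(11)
  m4 <- matrix(rnorm(4 * 30), 4, 30,
               dimnames = list(paste0("n", 1:4), paste0("r", 1:30)))
  p4 <- pca_flux_comparison(m4)
  expect_equal(sum(p4$explained_variance), 1, tolerance = 1e-9)
  expect_lte(sum(p4$explained_variance > 1e-10), 3)
  # loadings orthonormal
  L <- as.matrix(p4$loadings[-1])
  expect_lt(max(abs(crossprod(L) - diag(ncol(L)))), 1e-8)
  # reconstruction: scores %*% t(loadings) + centre restores the data
  rec <- as.matrix(p4$scores[-1]) %*% t(L) +
    matrix(p4$center, 4, 30, byrow = TRUE)
  expect_lt(max(abs(rec - m4)), 1e-8)

  # identical observations: degenerate, reported as such
  pd <- pca_flux_comparison(rbind(a = c(1, 2), b = c(1, 2)))
  expect_true(pd$degenerate)
  expect_error(pca_flux_comparison(list(tibble::tibble(reaction = "r",
                                                       flux = 1))),
               "at least two")
})

test_that("flux tables from different conditions align by reaction id", {
  spec <- toy_spec()
  cell <- make_toy_cell(spec)
  sols <- list(
    nh3 = tidy(solve_fba(cell, fixed = c(EX_sub = -4.16))),
    no2 = tidy(solve_fba(
      set_bounds(set_bounds(cell, "EX_nh3", lower = 0), "EX_no2",
                 lower = -1000), fixed = c(EX_sub = -4.16))))
  p <- pca_flux_comparison(sols)
  expect_equal(nrow(p$scores), 2)
  expect_equal(sum(p$explained_variance), 1, tolerance = 1e-9)
  expect_equal(unname(p$explained_variance[1]), 1, tolerance = 1e-9)
})
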