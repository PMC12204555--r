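test_that("stoichiometric matrix reconstructs reactions exactly", {
  m <- metabolic_model(
    "tiny",
    metabolites = tibble::tibble(id = c("A[c]", "B[c]")),
    reactions = tibble::tibble(id = "R1", formula = "A[c] -> B[c]"))
  S <- stoichiometric_matrix(m)
  expect_equal(dim(S), c(2L, 1L))
  expect_equal(as.numeric(S[, "R1"]), c(-1, 1))

  model <- make_toy_cell(toy_spec())
  S <- stoichiometric_matrix(model)
  expect_equal(dim(S), c(n_metabolites(model), n_reactions(model)))
  expect_identical(as.matrix(S), dense_stoichiometry(model))
  for (k in sample(n_reactions(model), 5)) {
    col <- S[, model$reactions$id[k]]
    s <- model$reactions$stoichiometry[[k]]
    expect_equal(col[names(s)], s, ignore_attr = TRUE)
  }
})

test_that("optimal fluxes satisfy steady state on the matrix", {
  model <- make_toy_cell(toy_spec())
  sol <- solve_fba(model, fixed = c(EX_sub = -4.16))
  expect_equal(sol$status, "optimal")
  resid <- as.numeric(stoichiometric_matrix(model) %*% sol$fluxes$flux)
  expect_lt(max(abs(resid)), 1e-6)
})

test_that("dead-end detection respects reversibility", {
  m <- metabolic_model(
    "de1",
    metabolites = tibble::tibble(id = c("A[c]", "B[c]")),
    reactions = tibble::tibble(id = "R1", formula = "A[c] -> B[c]"))
  expect_setequal(find_dead_ends(m), c("A[c]", "B[c]"))

  m2 <- metabolic_model(
    "de2",
    metabolites = tibble::tibble(id = c("A[e]", "B[c]", "C[e]")),
    reactions = tibble::tibble(
      id = c("EX_A", "R1", "R2", "EX_C"),
      formula = c("A[e] <=> ", "A[e] <-> B[c]", "B[c] -> C[e]", "C[e] -> ")))
  expect_length(find_dead_ends(m2), 0)

  # naive producer/consumer scans miss species touched only by reversible
  # reactions; both routes must agree that B is fine here
  expect_identical(sort(find_dead_ends(m2)), sort(oracle_dead_ends(m2)))
})

test_that("dead-end detection matches the exhaustive oracle on random networks", {
  set.seed(42)
  mets <- paste0("m", 1:12, "[c]")
  for (rep in 1:8) {
    rxn <- tibble::tibble(
      id = paste0("R", 1:20),
      stoichiometry = lapply(1:20, function(i) {
        k <- sample(2:3, 1)
        picks <- sample(mets, k)
        stats::setNames(c(-1, rep(1, k - 1)) * sample(1:2, k, TRUE), picks)
      }),
      lower_bound = ifelse(stats::runif(20) < 0.4, -1000, 0),
      upper_bound = ifelse(stats::runif(20) < 0.1, 0, 1000))
    m <- metabolic_model("rand", tibble::tibble(id = mets), rxn)
    expect_identical(sort(find_dead_ends(m)), sort(oracle_dead_ends(m)),
                     info = paste("replicate", rep))
  }
})

test_that("biomass coefficients follow the mass-to-mmol conversion", {
  one <- tibble::tibble(macromolecule = "all", fraction_pct = 100,
                        monomer_id = "x[c]", monomer_mw = 100,
                        within_fraction = 1)
  r <- build_biomass_reaction(one, product = "bio[c]")
  expect_equal(r$stoichiometry[["x[c]"]], -10)  # 1000 * 1 / 100
  expect_equal(r$stoichiometry[["bio[c]"]], 1)

  phb <- tibble::tibble(macromolecule = "phb", fraction_pct = 100,
                        monomer_id = "phb[c]", monomer_mw = 86,
                        within_fraction = 1)
  r <- build_biomass_reaction(phb)
  # 15.9 % of this coefficient is the PHB term of the full composition:
  expect_equal(-r$stoichiometry[["phb[c]"]] * 0.159, 1000 * 0.159 / 86,
               tolerance = 1e-12)
})

test_that("the shipped composition closes mass to 1 g and validates", {
  comp <- read_biomass_composition()
  expect_s3_class(comp, "biomass_composition")
  r <- build_biomass_reaction(comp, product = "biomass[c]")
  monomers <- r$stoichiometry[names(r$stoichiometry) != "biomass[c]"]
  mw <- stats::setNames(comp$monomer_mw, comp$monomer_id)
  mass <- sum(-monomers * mw[names(monomers)]) / 1000
  expect_equal(mass, 1, tolerance = 1e-3)

  # and for any random valid composition (mass closure is structural)
  set.seed(7)
  for (i in 1:5) {
    k <- sample(3:6, 1)
    fr <- stats::runif(k); fr <- 100 * fr / sum(fr)
    comp2 <- tibble::tibble(
      macromolecule = paste0("M", 1:k), fraction_pct = fr,
      monomer_id = paste0("mon", 1:k, "[c]"),
      monomer_mw = stats::runif(k, 80, 900), within_fraction = 1)
    r2 <- build_biomass_reaction(comp2, product = "bio[c]")
    mono2 <- r2$stoichiometry[names(r2$stoichiometry) != "bio[c]"]
    mw2 <- stats::setNames(comp2$monomer_mw, comp2$monomer_id)
    expect_equal(sum(-mono2 * mw2[names(mono2)]) / 1000, 1,
                 tolerance = 1e-3)
  }
})

test_that("composition validation reports the residual", {
  bad <- tibble::tibble(macromolecule = c("a", "b"),
                        fraction_pct = c(60, 30),
                        monomer_id = c("x[c]", "y[c]"),
                        monomer_mw = c(100, 100), within_fraction = c(1, 1))
  expect_error(build_biomass_reaction(bad), "sum to 90")
  bad2 <- tibble::tibble(macromolecule = "a", fraction_pct = 100,
                         monomer_id = c("x[c]", "y[c]"),
                         monomer_mw = c(100, 100),
                         within_fraction = c(0.5, 0.6))
  expect_error(build_biomass_reaction(bad2), "do not sum to 1")
})

test_that("extra-PHB coefficient alpha matches its analytic definition", {
  expect_equal(compute_alpha(0.159, 0.50, 86.0), 7.930233, tolerance = 1e-6)
  expect_equal(compute_alpha(0.25, 0.50, 100),
               1000 * ((0.50 - 0.25) / 0.50) / 100)  # = 5
  # limit: vanishing top-up as the target approaches the base content
  eps <- 10^-(3:7)
  vals <- vapply(eps, function(e) compute_alpha(0.3, 0.3 + e, 86),
                 numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_lt(vals[length(vals)], 1e-3)
  # strictly increasing in the target, strictly decreasing in the monomer mass
  targets <- seq(0.2, 0.9, by = 0.1)
  expect_true(all(diff(vapply(targets, compute_alpha, numeric(1),
                              p_base = 0.159, mw_phb = 86)) > 0))
  mws <- seq(50, 300, by = 50)
  expect_true(all(diff(vapply(mws, function(m)
    compute_alpha(0.159, 0.5, m), numeric(1))) < 0))
  expect_error(compute_alpha(0.5, 0.4, 86), "p_base < p_target")
})

test_that("carbon-matched uptakes reproduce the succinate-referenced rates", {
  expect_equal(carbon_matched_uptake(4.16, 4, 6), 2.7733, tolerance = 1e-4)
  expect_equal(carbon_matched_uptake(4.16, 4, 4), 4.16)
  expect_equal(carbon_matched_uptake(4.16, 4, 5), 3.328)
  expect_error(carbon_matched_uptake(4.16, 4, 0), "carbon counts")
})
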