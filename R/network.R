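#' Assemble the stoichiometric matrix
#'
#' Metabolites on rows, reactions on columns, signed coefficients as entries
#' (negative = consumed). Returned as a sparse `dgCMatrix` with dimnames so
#' columns reconstruct each reaction exactly.
#'
#' @param model A [metabolic_model()].
#' @return A sparse matrix of dimension `n_metabolites x n_reactions`.
#' @export
stoichiometric_matrix <- function(model) {
  met_ids <- model$metabolites$id
  rxn_ids <- model$reactions$id
  i <- integer(0); j <- integer(0); x <- numeric(0)
  for (k in seq_along(rxn_ids)) {
    s <- model$reactions$stoichiometry[[k]]
    i <- c(i, match(names(s), met_ids))
    j <- c(j, rep.int(k, length(s)))
    x <- c(x, unname(s))
  }
  Matrix::sparseMatrix(i = i, j = j, x = x,
                       dims = c(length(met_ids), length(rxn_ids)),
                       dimnames = list(met_ids, rxn_ids))
}

#' Detect dead-end metabolites
#'
#' A metabolite is a dead end when, considering reaction directionality, it
#' can never be produced or never be consumed. Reversible reactions
#' (negative lower bound) count as capable of both directions, so species
#' touched only by reversible reactions are not falsely flagged — the
#' blind spot of naive producer/consumer scans.
#'
#' @param model A [metabolic_model()].
#' @return Character vector of dead-end metabolite ids (possibly empty).
#' @export
find_dead_ends <- function(model) {
  can_produce <- stats::setNames(logical(n_metabolites(model)),
                                 model$metabolites$id)
  can_consume <- can_produce
  for (k in seq_len(n_reactions(model))) {
    s <- model$reactions$stoichiometry[[k]]
    fwd <- model$reactions$upper_bound[k] > 0
    bwd <- model$reactions$lower_bound[k] < 0
    prod_ids <- names(s)[(s > 0 & fwd) | (s < 0 & bwd)]
    cons_ids <- names(s)[(s < 0 & fwd) | (s > 0 & bwd)]
    can_produce[prod_ids] <- TRUE
    can_consume[cons_ids] <- TRUE
  }
  names(can_produce)[!(can_produce & can_consume)]
}

#' Read a biomass composition table
#'
#' TSV with columns `macromolecule`, `fraction_pct` (w/w % of dry biomass),
#' `monomer_id`, `monomer_mw` (g/mol), `within_fraction` (mass fraction of
#' the monomer within its macromolecule). A packaged synthetic composition
#' with the rhizobial macromolecule fractions (protein 50.1, DNA 3, RNA 8.5,
#' phospholipids 0.9, peptidoglycan 2.5, lipopolysaccharides 3.4,
#' polysaccharides 15.7, PHB 15.9 w/w %) and placeholder one-monomer splits
#' ships as `system.file("extdata", "biomass_composition_synthetic.tsv",
#' package = "xfba")`.
#'
#' @param path TSV file path; defaults to the packaged composition.
#' @return A `biomass_composition` tibble.
#' @export
read_biomass_composition <- function(path = NULL) {
  path <- path %||% system.file("extdata", "biomass_composition_synthetic.tsv",
                                package = "xfba")
  comp <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_biomass_composition(comp)
}

#' Validate a biomass composition
#'
#' Macromolecule fractions must sum to 100 +/- 0.1 w/w % and the monomer
#' fractions within each macromolecule to 1 +/- 0.001.
#'
#' @param comp A composition data frame (see [read_biomass_composition()]).
#' @return The composition as a classed tibble, or an error stating the
#'   residual.
#' @export
validate_biomass_composition <- function(comp) {
  comp <- tibble::as_tibble(comp)
  need <- c("macromolecule", "fraction_pct", "monomer_id", "monomer_mw",
            "within_fraction")
  missing <- setdiff(need, names(comp))
  if (length(missing) > 0) {
    stop("composition table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  macro <- dplyr::distinct(comp, .data$macromolecule, .data$fraction_pct)
  total <- sum(macro$fraction_pct)
  if (abs(total - 100) > 0.1) {
    stop(sprintf("macromolecule fractions sum to %.4f %% (residual %+.4f)",
                 total, total - 100), call. = FALSE)
  }
  within <- dplyr::summarise(dplyr::group_by(comp, .data$macromolecule),
                             s = sum(.data$within_fraction), .groups = "drop")
  bad <- within[abs(within$s - 1) > 1e-3, ]
  if (nrow(bad) > 0) {
    stop("monomer fractions of ", paste(bad$macromolecule, collapse = ", "),
         " do not sum to 1 (residual ",
         paste(sprintf("%+.4g", bad$s - 1), collapse = ", "), ")",
         call. = FALSE)
  }
  class(comp) <- c("biomass_composition", class(comp))
  comp
}

#' Build a biomass reaction from a macromolecular composition
#'
#' Each monomer enters with coefficient
#' `1000 * (fraction_pct/100) * within_fraction / monomer_mw` mmol per gram
#' of dry biomass, so the mass balance `sum(coef * mw)/1000 = 1 g` closes by
#' construction. The product side is one unit of `product` (implied unit:
#' gram biomass). Polymerisation energy is excluded unless a
#' growth-associated ATP requirement `ggr` (mmol ATP/gDW) and the ids of the
#' ATP hydrolysis species are supplied.
#'
#' @param comp A composition from [read_biomass_composition()].
#' @param id Reaction id.
#' @param product Product metabolite id.
#' @param ggr Optional growth-associated ATP demand in mmol/gDW.
#' @param atp_ids Named character vector mapping `atp`, `adp`, `pi` to
#'   metabolite ids when `ggr` is used.
#' @return A one-row reaction tibble suitable for [add_reaction()].
#' @export
build_biomass_reaction <- function(comp, id = "BIOMASS",
                                   product = "biomass[c]", ggr = NULL,
                                   atp_ids = c(atp = "atp[c]", adp = "adp[c]",
                                               pi = "pi[c]")) {
  comp <- validate_biomass_composition(comp)
  coef <- 1000 * (comp$fraction_pct / 100) * comp$within_fraction /
    comp$monomer_mw
  stoich <- tapply(-coef, comp$monomer_id, sum)
  stoich <- stats::setNames(as.numeric(stoich), names(stoich))
  stoich[product] <- 1
  if (!is.null(ggr) && ggr > 0) {
    stoich[atp_ids[["atp"]]] <- (stoich[atp_ids[["atp"]]] %|na|% 0) - ggr
    stoich[atp_ids[["adp"]]] <- (stoich[atp_ids[["adp"]]] %|na|% 0) + ggr
    stoich[atp_ids[["pi"]]] <- (stoich[atp_ids[["pi"]]] %|na|% 0) + ggr
  }
  list(id = id, name = "biomass formation", stoichiometry = stoich,
       lower_bound = 0, upper_bound = 1000, subsystem = "biomass")
}

`%|na|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a

#' Extra-PHB coupling coefficient
#'
#' The amount of storage polymer (mmol per gram of newly differentiated
#' biomass) that must be added on top of the base content to raise the PHB
#' mass fraction from `p_base` to `p_target`:
#' `alpha = 1000 * (p_target - p_base) / p_target / mw_phb`.
#' With the rhizobial defaults (`p_base = 0.159`, `p_target = 0.50`,
#' `mw_phb = 86` g/mol for the hydroxybutyrate residue) this gives 7.9302.
#'
#' @param p_base Base PHB mass fraction of growing biomass, in (0, 1).
#' @param p_target Target PHB mass fraction of non-growing biomass.
#' @param mw_phb Molar mass of the PHB monomer residue, g/mol.
#' @return alpha in mmol PHB per gram of differentiated biomass.
#' @examples
#' compute_alpha(0.159, 0.50, 86.0)
#' @export
compute_alpha <- function(p_base = 0.159, p_target = 0.50, mw_phb = 86.0) {
  stopifnot(mw_phb > 0, p_base >= 0)
  if (p_target <= p_base || p_target >= 1) {
    stop("need 0 <= p_base < p_target < 1 (got p_base = ", p_base,
         ", p_target = ", p_target, ")", call. = FALSE)
  }
  1000 * ((p_target - p_base) / p_target) / mw_phb
}

#' Carbon-matched uptake rate
#'
#' Scales a reference uptake so an alternative carbon source delivers the
#' same flux of carbon atoms: `ref_rate * ref_carbons / target_carbons`.
#' E.g. matching succinate at 4.16 mmol/gDW/h (4 C) gives glucose (6 C)
#' an uptake of 2.773.
#'
#' @param ref_rate Reference uptake rate, mmol/gDW/h (positive magnitude).
#' @param ref_carbons Carbon atoms of the reference source.
#' @param target_carbons Carbon atoms of the target source.
#' @return Matched uptake rate, mmol/gDW/h.
#' @examples
#' carbon_matched_uptake(4.16, 4, 6) # glucose
#' @export
carbon_matched_uptake <- function(ref_rate, ref_carbons, target_carbons) {
  stopifnot(ref_rate >= 0)
  if (ref_carbons < 1 || target_carbons < 1) {
    stop("carbon counts must be >= 1", call. = FALSE)
  }
  ref_rate * ref_carbons / target_carbons
}
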