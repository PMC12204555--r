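#' Abundance vector for a community
#'
#' Strictly positive member fractions summing to 1 (a zero-abundance member
#' must be removed from the community, not zeroed out).
#'
#' @param ... Named fractions, e.g. `abundance_vector(g = 0.9, nf = 0.1)`,
#'   or a single named numeric vector.
#' @return A named numeric vector of class `abundance_vector`.
#' @export
abundance_vector <- function(...) {
  x <- c(...)
  if (is.null(names(x)) || any(names(x) == "")) {
    stop("abundances must be named by member tag", call. = FALSE)
  }
  if (any(x <= 0)) {
    stop("abundances must be strictly positive; drop absent members instead",
         call. = FALSE)
  }
  if (abs(sum(x) - 1) > 1e-9) {
    stop(sprintf("abundances sum to %.12f, not 1", sum(x)), call. = FALSE)
  }
  structure(x, class = "abundance_vector")
}

member_suffix <- function(id, tag) paste0(id, "[", tag, "]")

#' Build a compartmentalised community model
#'
#' Merges member models into one network: each member's metabolites and
#' reactions are duplicated under a bracketed member tag, every shared
#' extracellular species is rerouted through a common pool compartment
#' `[u]` via per-member transport reactions, and a single community
#' exchange reaction per shared species connects the pool to the
#' environment. Every member-level boundary reaction touching a shared
#' species alone (its exchange) is replaced by the transport, so all
#' environmental traffic crosses the pool, where pins and bounds act on
#' the community basis; member-private sinks must therefore sit on
#' intracellular species, not on shared extracellular ones.
#'
#' @param members Named list of [metabolic_model()]s; names are member tags.
#' @param abundances An [abundance_vector()] over the same tags.
#' @param shared Extracellular metabolite ids (e.g. `"nh3[e]"`) to place in
#'   the pool. Default `NULL`: every extracellular species of any member.
#' @return A `community_model`: list with the merged `model`, a `members`
#'   tibble (tag, abundance, original model), the shared-species map, and
#'   the original single-model ids each transport stands for.
#' @export
build_community <- function(members, abundances, shared = NULL) {
  if (is.null(names(members)) || any(names(members) == "")) {
    stop("members must be a named list (names = member tags)", call. = FALSE)
  }
  abundances <- abundance_vector(abundances)
  if (!setequal(names(members), names(abundances))) {
    stop("member tags and abundance names differ", call. = FALSE)
  }
  for (m in members) validate_model(m)

  if (is.null(shared)) {
    shared <- unique(unlist(lapply(members, function(m) {
      m$metabolites$id[m$metabolites$compartment == "e"]
    })))
  }

  met_rows <- list(); rxn_rows <- list(); map_rows <- list()
  for (tag in names(members)) {
    m <- members[[tag]]
    rename <- stats::setNames(member_suffix(m$metabolites$id, tag),
                              m$metabolites$id)
    mets <- m$metabolites
    mets$id <- unname(rename[mets$id])
    mets$member <- tag
    met_rows[[tag]] <- mets

    rxn <- m$reactions[setdiff(names(m$reactions), "is_exchange")]
    rxn$stoichiometry <- lapply(rxn$stoichiometry, function(s) {
      stats::setNames(unname(s), unname(rename[names(s)]))
    })
    orig_id <- rxn$id
    rxn$id <- member_suffix(rxn$id, tag)
    rxn$member <- tag

    # reroute shared species: drop the member's own exchange, add transport
    present <- intersect(shared, m$metabolites$id)
    drop <- logical(nrow(rxn))
    tr <- list()
    for (sp in present) {
      base <- sub("\\[e\\]$", "", sp)
      tagged <- rename[[sp]]
      is_ex <- vapply(rxn$stoichiometry, function(s) {
        length(s) == 1L && names(s)[1L] == tagged
      }, logical(1))
      if (any(is_ex)) {
        map_rows[[length(map_rows) + 1L]] <- tibble::tibble(
          base = base, member = tag,
          transport = paste0("TR_", base, "[", tag, "]"),
          original_exchange = orig_id[is_ex][1L])
      } else {
        map_rows[[length(map_rows) + 1L]] <- tibble::tibble(
          base = base, member = tag,
          transport = paste0("TR_", base, "[", tag, "]"),
          original_exchange = NA_character_)
      }
      drop <- drop | is_ex
      tr[[sp]] <- tibble::tibble(
        id = paste0("TR_", base, "[", tag, "]"),
        name = paste0("pool transport of ", base, " (", tag, ")"),
        stoichiometry = list(stats::setNames(c(-1, 1),
                                             c(tagged, paste0(base, "[u]")))),
        lower_bound = -1000, upper_bound = 1000,
        subsystem = "community transport", member = tag)
    }
    rxn <- dplyr::bind_rows(c(list(rxn[!drop, ]), unname(tr)))
    rxn_rows[[tag]] <- rxn
  }

  in_some_member <- vapply(shared, function(sp) {
    any(vapply(members, function(m) sp %in% m$metabolites$id, logical(1)))
  }, logical(1))
  if (any(!in_some_member)) {
    stop("shared species absent from every member: ",
         paste(shared[!in_some_member], collapse = ", "), call. = FALSE)
  }

  shared_base <- unique(sub("\\[e\\]$", "", shared))
  pool_mets <- tibble::tibble(
    id = paste0(shared_base, "[u]"), name = shared_base,
    compartment = "u", formula = NA_character_, member = NA_character_)
  pool_ex <- tibble::tibble(
    id = paste0("EX_", shared_base, "[u]"),
    name = paste0("community exchange of ", shared_base),
    stoichiometry = lapply(paste0(shared_base, "[u]"), function(p) {
      stats::setNames(-1, p)
    }),
    lower_bound = -1000, upper_bound = 1000,
    subsystem = "community exchange", member = NA_character_)

  merged <- metabolic_model(
    id = paste0("community(", paste(names(members), collapse = "+"), ")"),
    metabolites = dplyr::bind_rows(c(met_rows, list(pool_mets))),
    reactions = dplyr::bind_rows(c(rxn_rows, list(pool_ex))),
    objective = NULL)

  structure(list(
    model = merged,
    members = tibble::tibble(
      tag = names(members),
      abundance = as.numeric(abundances[names(members)]),
      model = unname(members)),
    shared = shared_base,
    exchange_map = dplyr::bind_rows(map_rows)),
    class = "community_model")
}

#' @export
print.community_model <- function(x, ...) {
  cat("<community_model> ", x$model$id, "\n", sep = "")
  for (i in seq_len(nrow(x$members))) {
    cat(sprintf("  member %-6s abundance %.3f (%d reactions)\n",
                x$members$tag[i], x$members$abundance[i],
                n_reactions(x$members$model[[i]])))
  }
  cat("  shared pool species: ", length(x$shared), "\n", sep = "")
  cat("  merged: ", n_reactions(x$model), " reactions, ",
      n_metabolites(x$model), " metabolites\n", sep = "")
  invisible(x)
}

#' Abundance-scale a stoichiometric matrix
#'
#' Multiplies every member-assigned column by that member's abundance and
#' leaves pool-exchange columns untouched (the identity block), producing
#' the matrix used for all community mass balances.
#'
#' @param S Stoichiometric matrix (columns named by reaction id).
#' @param abundances An [abundance_vector()].
#' @param assignment Character vector over columns: a member tag, or `NA`
#'   for the exchange block.
#' @return The scaled matrix.
#' @export
abundance_scale <- function(S, abundances, assignment) {
  if (length(assignment) != ncol(S)) {
    stop("assignment must have one entry per column", call. = FALSE)
  }
  unknown <- setdiff(assignment[!is.na(assignment)], names(abundances))
  if (length(unknown) > 0) {
    stop("columns assigned to unknown member(s): ",
         paste(unique(unknown), collapse = ", "),
         "; every column must belong to a member or the exchange block",
         call. = FALSE)
  }
  w <- rep(1, ncol(S))
  has <- !is.na(assignment)
  w[has] <- as.numeric(abundances[assignment[has]])
  out <- S %*% Matrix::Diagonal(x = w)
  dimnames(out) <- dimnames(S)
  out
}

#' Coupling specification for a growing/non-growing pair
#'
#' Captures the constraints that keep member abundances constant although
#' growth rates differ: part of the growing member's biomass output is a
#' differentiation flux that converts growing into non-growing biomass, the
#' non-growing member tops up its storage-polymer (PHB) content, and the
#' two accumulation rates are locked to the abundance ratio.
#'
#' With `r = X2/X1` (non-growing over growing abundance), `alpha` the
#' extra-PHB coefficient ([compute_alpha()]) and `mw_phb` the monomer molar
#' mass, every optimal solution satisfies (community basis):
#' `v_PHB = alpha * mu1s`, `mu2 = mu1s + mw_phb * v_PHB / 1000`, and
#' `mu2 = r * mu1`, which imply the differentiation coefficient
#' `mu1s/mu1 = c = r / (1 + alpha * mw_phb / 1000)`.
#'
#' @param r Abundance ratio non-growing/growing, > 0.
#' @param alpha mmol extra PHB per gram of differentiated biomass, >= 0.
#' @param mw_phb PHB monomer molar mass, g/mol.
#' @param growth Reaction id of the growth biomass flux (mu1), in the
#'   untagged member namespace.
#' @param differentiation Reaction id of the differentiation biomass flux
#'   (mu1s) of the growing member.
#' @param phb_exchange Reaction id of the non-growing member's PHB
#'   accumulation flux (mmol basis).
#' @param growing,non_growing Member tags.
#' @param p_base Base PHB mass fraction of biomass (used by
#'   [member_phb_content()]).
#' @return A `coupling_spec` list.
#' @export
coupling_spec <- function(r, alpha, mw_phb = 86.0, growth = "BIOMASS",
                          differentiation = "BIOMASS_DIFF",
                          phb_exchange = "DM_phb", growing = "g",
                          non_growing = "nf", p_base = 0.159) {
  stopifnot(r > 0, alpha >= 0, mw_phb > 0)
  structure(list(r = r, alpha = alpha, mw_phb = mw_phb, growth = growth,
                 differentiation = differentiation,
                 phb_exchange = phb_exchange, growing = growing,
                 non_growing = non_growing, p_base = p_base),
            class = "coupling_spec")
}

#' Differentiation coefficient implied by a coupling spec
#'
#' `c = r / (1 + alpha * mw_phb / 1000)`, the fraction of the growing
#' member's biomass flux that differentiates; satisfies `0 < c <= r`.
#'
#' @param spec A [coupling_spec()], or the ratio `r` when `alpha` and
#'   `mw_phb` are given explicitly.
#' @param alpha,mw_phb Used when `spec` is numeric.
#' @return Scalar coefficient.
#' @examples
#' differentiation_coefficient(1 / 9, alpha = 7.9303, mw_phb = 86)
#' @export
differentiation_coefficient <- function(spec, alpha = NULL, mw_phb = NULL) {
  if (inherits(spec, "coupling_spec")) {
    r <- spec$r; alpha <- spec$alpha; mw_phb <- spec$mw_phb
  } else {
    r <- spec
    stopifnot(!is.null(alpha), !is.null(mw_phb))
  }
  r / (1 + alpha * mw_phb / 1000)
}

# tagged reaction ids of the coupling fluxes inside a merged model
coupling_ids <- function(community, spec) {
  ids <- c(growth = member_suffix(spec$growth, spec$growing),
           differentiation = member_suffix(spec$differentiation, spec$growing),
           phb = member_suffix(spec$phb_exchange, spec$non_growing))
  missing <- setdiff(ids, community$model$reactions$id)
  if (length(missing) > 0) {
    stop("coupling spec refers to reaction(s) absent from the community: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ids
}

#' Coupling constraint rows for a community
#'
#' Builds the two linear equality rows (over the merged model's reaction
#' columns, community basis) enforcing the storage-polymer top-up
#' `v_PHB = alpha * mu1s` and the abundance balance
#' `mu1s + mw_phb * v_PHB / 1000 = r * mu1`; together these make the
#' accumulation identity `mu2 = mu1s + mw_phb * v_PHB/1000` hold at the
#' ratio `mu2 = r * mu1` in every feasible solution.
#'
#' @param community A [build_community()] result.
#' @param spec A [coupling_spec()].
#' @return `list(A, b)` ready for the `extra_eq` argument of [solve_fba()].
#' @export
add_coupling_constraints <- function(community, spec) {
  ids <- coupling_ids(community, spec)
  rxn_ids <- community$model$reactions$id
  X <- stats::setNames(community$members$abundance, community$members$tag)
  x1 <- X[[spec$growing]]; x2 <- X[[spec$non_growing]]
  A <- matrix(0, nrow = 2, ncol = length(rxn_ids),
              dimnames = list(c("phb_topup", "abundance_balance"), rxn_ids))
  # Community-basis aggregates: mu1 = x1 * v(growth), mu1s = x1 * v(diff),
  # v_PHB = x2 * v(phb).
  A["phb_topup", ids[["phb"]]] <- x2
  A["phb_topup", ids[["differentiation"]]] <- -spec$alpha * x1
  A["abundance_balance", ids[["differentiation"]]] <- x1
  A["abundance_balance", ids[["phb"]]] <- spec$mw_phb * x2 / 1000
  A["abundance_balance", ids[["growth"]]] <- -spec$r * x1
  list(A = A, b = c(0, 0))
}

#' Solve the community problem with fixed abundances (XFBA)
#'
#' Runs FBA on the abundance-scaled community stoichiometry with the
#' coupling rows of [add_coupling_constraints()] attached. The LP stays
#' linear because abundances are fixed. The default objective is the
#' growing member's growth flux; since the non-growing accumulation rate is
#' locked to `r * mu1`, maximising `mu1` also maximises the total community
#' growth `mu1 + mu2`.
#'
#' Pins in `fixed` may name community exchange reactions (`EX_*[u]`,
#' community basis) or tagged member reactions (member basis).
#'
#' @param community A [build_community()] result.
#' @param spec A [coupling_spec()], or `NULL` for an uncoupled community
#'   (e.g. a single-member identity community).
#' @param fixed Named numeric pins (lb = ub).
#' @param objective Reaction id in the merged namespace; default: the
#'   tagged growth reaction of the growing member.
#' @param pfba Parsimonious flux reporting.
#' @param extra_eq Additional equality rows over the merged reaction
#'   columns, appended after the coupling rows (scenario pins).
#' @return A `flux_solution` whose `members` field carries the aggregates
#'   `mu1`, `mu1_star`, `mu2`, `community_growth`, `v_phb` (community
#'   basis) and whose `fluxes` are raw member-basis fluxes.
#' @export
solve_xfba <- function(community, spec = NULL, fixed = NULL, objective = NULL,
                       pfba = TRUE, extra_eq = NULL) {
  merged <- scaled_community_model(community)
  if (!is.null(spec)) {
    coup <- add_coupling_constraints(community, spec)
    extra_eq <- if (is.null(extra_eq)) coup else {
      list(A = rbind(coup$A, extra_eq$A), b = c(coup$b, extra_eq$b))
    }
  }
  if (is.null(objective)) {
    objective <- if (!is.null(spec)) {
      member_suffix(spec$growth, spec$growing)
    } else {
      merged$objective %||% stop("no objective given", call. = FALSE)
    }
  }
  sol <- solve_fba(merged, objective = objective, fixed = fixed, pfba = pfba,
                   extra_eq = extra_eq)
  sol$model_id <- community$model$id
  if (sol$status == "optimal" && !is.null(spec)) {
    sol <- attach_member_aggregates(sol, community, spec)
  }
  sol
}

# merged model whose stoichiometry is replaced by S_x (columns scaled by
# abundance); implemented by scaling each member reaction's coefficients,
# which is exactly S %*% diag(X) column-wise
scaled_community_model <- function(community) {
  merged <- community$model
  X <- stats::setNames(community$members$abundance, community$members$tag)
  memb <- merged$reactions$member
  merged$reactions$stoichiometry <- lapply(seq_len(nrow(merged$reactions)),
    function(k) {
      s <- merged$reactions$stoichiometry[[k]]
      if (is.na(memb[k])) s else s * X[[memb[k]]]
    })
  merged
}

attach_member_aggregates <- function(sol, community, spec) {
  ids <- coupling_ids(community, spec)
  X <- stats::setNames(community$members$abundance, community$members$tag)
  mu1 <- X[[spec$growing]] * flux_of(sol, ids[["growth"]])[[1]]
  mu1s <- X[[spec$growing]] * flux_of(sol, ids[["differentiation"]])[[1]]
  v_phb <- X[[spec$non_growing]] * flux_of(sol, ids[["phb"]])[[1]]
  mu2 <- mu1s + spec$mw_phb * v_phb / 1000
  sol$members <- tibble::tibble(
    quantity = c("mu1", "mu1_star", "mu2", "community_growth", "v_phb"),
    value = c(mu1, mu1s, mu2, mu1 + mu2, v_phb),
    units = c(rep("1/h", 4), "mmol/gDWC/h"))
  sol$coupling <- spec
  sol$objective_value <- mu1
  sol
}

#' Member aggregate value from an XFBA solution
#' @param solution A `flux_solution` from [solve_xfba()].
#' @param quantity One of `"mu1"`, `"mu1_star"`, `"mu2"`,
#'   `"community_growth"`, `"v_phb"`.
#' @return Scalar value.
#' @export
member_aggregate <- function(solution, quantity) {
  if (is.null(solution$members)) stop("solution has no member aggregates",
                                      call. = FALSE)
  i <- match(quantity, solution$members$quantity)
  if (is.na(i)) stop("unknown aggregate ", sQuote(quantity), call. = FALSE)
  solution$members$value[[i]]
}

#' PHB mass fraction of each member in an XFBA solution
#'
#' The growing member keeps the base biomass PHB fraction; the non-growing
#' member's content is the mass-weighted mix of differentiated biomass and
#' the PHB top-up:
#' `(p_base * mu1s + mw_phb * v_PHB / 1000) / mu2`. Writing
#' `k = alpha * mw_phb / 1000`, the content is `(p_base + k) / (1 + k)`;
#' with `alpha` from [compute_alpha()] this equals the target fraction
#' exactly at the default 50 % target (where normalising the top-up by the
#' pre- or post-top-up mass gives the same coefficient).
#'
#' @param solution A `flux_solution` from [solve_xfba()].
#' @param spec The [coupling_spec()] used (defaults to the one stored in
#'   the solution).
#' @return Tibble with `member` and `phb_fraction`; the non-growing entry is
#'   `NA` when `mu2 = 0`.
#' @export
member_phb_content <- function(solution, spec = NULL) {
  spec <- spec %||% solution$coupling
  if (is.null(spec)) stop("no coupling spec available", call. = FALSE)
  mu1s <- member_aggregate(solution, "mu1_star")
  mu2 <- member_aggregate(solution, "mu2")
  v_phb <- member_aggregate(solution, "v_phb")
  nf <- if (mu2 <= 0) NA_real_ else {
    (spec$p_base * mu1s + spec$mw_phb * v_phb / 1000) / mu2
  }
  tibble::tibble(member = c(spec$growing, spec$non_growing),
                 phb_fraction = c(spec$p_base, nf))
}

#' Reweight a community to new abundances
#'
#' Convenience for sensitivity analyses. The merged network is
#' abundance-independent (scaling is applied at solve time), so only the
#' abundance vector is swapped — pool bounds and any other edits to the
#' merged model are preserved — and the coupling ratio `r = X2/X1` is
#' recomputed.
#'
#' @param community A [build_community()] result.
#' @param abundances New named abundances over the same member tags.
#' @param spec A [coupling_spec()] template whose `r` is recomputed.
#' @return `list(community, spec)`.
#' @export
reweight_community <- function(community, abundances, spec) {
  abundances <- abundance_vector(abundances)
  if (!setequal(names(abundances), community$members$tag)) {
    stop("abundance names must match the member tags", call. = FALSE)
  }
  community$members$abundance <-
    as.numeric(abundances[community$members$tag])
  new_spec <- spec
  new_spec$r <- abundances[[spec$non_growing]] / abundances[[spec$growing]]
  list(community = community, spec = new_spec)
}
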