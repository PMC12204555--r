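#' Carbon/nitrogen source screen
#'
#' Reproduces the classic source-comparison experiment: each run pins the
#' carbon source at a carbon-matched uptake (same carbon-atom flux as the
#' reference source), opens exactly one nitrogen source, maximises growth
#' and records growth rate, nitrogen uptake and CO2 (plus ammonia) release.
#' When a source serves as both carbon and nitrogen source (glutamine
#' style), ammonia secretion stays open so excess nitrogen can leave.
#'
#' @param model A single-member [metabolic_model()].
#' @param sources Tibble with columns `name`, `c_exchange`, `c_carbons`,
#'   `n_exchange` (exchange reaction ids; `n_exchange` may equal
#'   `c_exchange`).
#' @param c_reference List with `rate` (reference uptake, mmol/gDW/h) and
#'   `carbons`.
#' @param nh3_exchange Ammonia exchange id (secretion is always allowed).
#' @param co2_exchange CO2 exchange id for the release readout.
#' @param close Additional exchange ids whose uptake is shut in every run
#'   (carbon or nitrogen routes not part of the screened pairs).
#' @return An `xfba_screen` tibble: one row per source pair with `mu`,
#'   `n_uptake`, `co2_release`, `nh3_release`, `status`.
#' @export
nitrogen_carbon_screen <- function(model, sources,
                                   c_reference = list(rate = 4.16,
                                                      carbons = 4),
                                   nh3_exchange = "EX_nh3",
                                   co2_exchange = "EX_co2",
                                   close = character(0)) {
  sources <- tibble::as_tibble(sources)
  need <- c("name", "c_exchange", "c_carbons", "n_exchange")
  if (!all(need %in% names(sources))) {
    stop("sources needs columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  all_ids <- model$reactions$id
  bad <- setdiff(unique(c(sources$c_exchange, sources$n_exchange,
                          nh3_exchange, co2_exchange, close)), all_ids)
  if (length(bad) > 0) {
    stop("unknown exchange reaction(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  c_exchanges <- unique(sources$c_exchange)
  n_exchanges <- unique(sources$n_exchange)
  out <- purrr::pmap(sources, function(name, c_exchange, c_carbons,
                                       n_exchange, ...) {
    uptake <- carbon_matched_uptake(c_reference$rate, c_reference$carbons,
                                    c_carbons)
    m <- model
    # close every carbon and nitrogen uptake, then open this run's pair
    for (ex in unique(c(c_exchanges, n_exchanges, close))) {
      m <- set_bounds(m, ex, lower = 0)
    }
    m <- set_bounds(m, n_exchange, lower = -1000)
    sol <- solve_fba(m, fixed = stats::setNames(-uptake, c_exchange))
    ok <- sol$status == "optimal"
    tibble::tibble(
      name = name,
      c_uptake = uptake,
      status = sol$status,
      mu = sol$objective_value,
      n_uptake = if (ok) -flux_of(sol, n_exchange)[[1]] else NA_real_,
      co2_release = if (ok) flux_of(sol, co2_exchange)[[1]] else NA_real_,
      nh3_release = if (ok) max(0, flux_of(sol, nh3_exchange)[[1]])
                    else NA_real_)
  })
  out <- dplyr::bind_rows(out)
  class(out) <- c("xfba_screen", class(out))
  out
}

# equality row pinning the community-basis pool export of `base` by the
# growing member: X_g * v(TR_base[g]) = t
transfer_pin_row <- function(community, spec, base, value) {
  tr <- paste0("TR_", base, "[", spec$growing, "]")
  rxn_ids <- community$model$reactions$id
  if (!tr %in% rxn_ids) {
    stop("no pool transport ", sQuote(tr), " in community (is ",
         sQuote(base), " shared?)", call. = FALSE)
  }
  xg <- community$members$abundance[community$members$tag == spec$growing]
  A <- matrix(0, 1, length(rxn_ids), dimnames = list("transfer_pin", rxn_ids))
  A[1, tr] <- xg
  list(A = A, b = value)
}

#' Inter-member exchange robustness scan
#'
#' Pins the net community-basis transfer of one shared metabolite between
#' the members across a grid spanning both directions and re-solves the
#' coupled problem at each point. Sign convention: negative = transfer from
#' the non-growing to the growing member. The base optimum bounds every
#' pinned optimum from above (pinning only restricts the feasible set), so
#' the expected picture is a plateau at the base growth rate for small
#' transfers and a decline (or infeasibility) at large ones.
#'
#' @param community A [build_community()] result.
#' @param spec A [coupling_spec()].
#' @param metabolite Shared species base name (e.g. `"aa"`).
#' @param grid Numeric transfer values, community basis (mmol/gDWC/h).
#' @param fixed Pins held across the scan (e.g. the substrate exchange).
#' @param nitrogenase Reaction id of the nitrogen-fixing reaction (untagged).
#' @param nh3 Base name of the shared ammonia species.
#' @return An `xfba_scan` tibble with `exchange`, `status`,
#'   `community_growth`, `n2_fixation`, `nh3_to_growing`.
#' @export
exchange_robustness <- function(community, spec, metabolite, grid,
                                fixed = NULL, nitrogenase = "NIT",
                                nh3 = "nh3") {
  nit_id <- member_suffix(nitrogenase, spec$non_growing)
  tr_nh3 <- paste0("TR_", nh3, "[", spec$growing, "]")
  X <- stats::setNames(community$members$abundance, community$members$tag)
  rows <- purrr::map(grid, function(t) {
    pin <- transfer_pin_row(community, spec, metabolite, t)
    sol <- solve_xfba(community, spec, fixed = fixed, extra_eq = pin)
    ok <- sol$status == "optimal"
    tibble::tibble(
      exchange = t, status = sol$status,
      community_growth = if (ok) member_aggregate(sol, "community_growth")
                         else NA_real_,
      n2_fixation = if (ok) X[[spec$non_growing]] * flux_of(sol, nit_id)[[1]]
                    else NA_real_,
      nh3_to_growing = if (ok) -X[[spec$growing]] * flux_of(sol, tr_nh3)[[1]]
                       else NA_real_)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("xfba_scan", class(out))
  attr(out, "reaction") <- paste0("transfer:", metabolite)
  out
}

#' Abundance sensitivity of the coupled community
#'
#' Rebuilds the community for a range of non-growing fractions `f`,
#' recomputing the abundance ratio `r = f / (1 - f)` and the
#' differentiation coefficient, and re-solves at each fraction.
#'
#' @param community A [build_community()] result (any abundances; member
#'   models are reused).
#' @param spec A [coupling_spec()] template.
#' @param fractions Non-growing member fractions in (0, 1).
#' @param fixed Pins held across the scan.
#' @param nitrogenase Untagged nitrogenase reaction id.
#' @return An `xfba_scan` tibble with per-fraction `r`, `c`, `mu1`,
#'   `mu1_star`, `mu2`, `community_growth`, `v_phb`, `n2_fixation`.
#' @export
abundance_sensitivity <- function(community, spec,
                                  fractions = seq(0.05, 0.30, by = 0.05),
                                  fixed = NULL, nitrogenase = "NIT") {
  stopifnot(all(fractions > 0 & fractions < 1))
  rows <- purrr::map(fractions, function(f) {
    ab <- stats::setNames(c(1 - f, f), c(spec$growing, spec$non_growing))
    rw <- reweight_community(community, ab, spec)
    sol <- solve_xfba(rw$community, rw$spec, fixed = fixed)
    ok <- sol$status == "optimal"
    nit_id <- member_suffix(nitrogenase, spec$non_growing)
    tibble::tibble(
      fraction = f, r = rw$spec$r,
      c = differentiation_coefficient(rw$spec),
      status = sol$status,
      mu1 = if (ok) member_aggregate(sol, "mu1") else NA_real_,
      mu1_star = if (ok) member_aggregate(sol, "mu1_star") else NA_real_,
      mu2 = if (ok) member_aggregate(sol, "mu2") else NA_real_,
      community_growth = if (ok) member_aggregate(sol, "community_growth")
                         else NA_real_,
      v_phb = if (ok) member_aggregate(sol, "v_phb") else NA_real_,
      n2_fixation = if (ok) f * flux_of(sol, nit_id)[[1]] else NA_real_)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("xfba_scan", class(out))
  attr(out, "reaction") <- "abundance"
  out
}

#' Oxygen / terminal-oxidase scan
#'
#' Pins the community oxygen uptake across a grid, re-solves the coupled
#' problem, and records growth plus the flux through each terminal oxidase
#' of each member (community basis). A summary attribute carries the
#' feasibility threshold (LP minimisation + bisection, 0.01 resolution),
#' the growth-maximising oxygen uptake, and the oxidase activation
#' boundaries of the non-growing member taken at the scan resolution from
#' degeneracy-safe flux ranges (a path is called inactive only when its
#' maximum flux over all optima is zero, active-only when the alternative's
#' maximum is zero).
#'
#' @param community A [build_community()] result.
#' @param spec A [coupling_spec()].
#' @param grid Oxygen uptake magnitudes to pin (mmol/gDWC/h).
#' @param fixed Pins held across the scan.
#' @param cytc,cytbd Untagged oxidase reaction ids.
#' @param o2_exchange Community oxygen exchange id.
#' @return An `xfba_scan` tibble (`o2`, `status`, `community_growth`,
#'   per-member oxidase fluxes) with attribute `summary`.
#' @export
oxygen_cytochrome_scan <- function(community, spec, grid, fixed = NULL,
                                   cytc = "CYTC", cytbd = "CYTBD",
                                   o2_exchange = "EX_o2[u]") {
  X <- stats::setNames(community$members$abundance, community$members$tag)
  tags <- community$members$tag
  oxid_ids <- c(outer(c(cytc, cytbd), tags, member_suffix))
  merged_scaled <- scaled_community_model(community)
  coup <- add_coupling_constraints(community, spec)

  rows <- purrr::map(grid, function(o2) {
    sol <- solve_xfba(community, spec,
                      fixed = c(fixed, stats::setNames(-o2, o2_exchange)))
    ok <- sol$status == "optimal"
    row <- tibble::tibble(o2 = o2, status = sol$status,
                          community_growth = if (ok)
                            member_aggregate(sol, "community_growth")
                          else NA_real_)
    for (tag in tags) {
      for (ox in c(cytc, cytbd)) {
        id <- member_suffix(ox, tag)
        row[[paste0(ox, "_", tag)]] <-
          if (ok) X[[tag]] * flux_of(sol, id)[[1]] else NA_real_
      }
    }
    row
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("xfba_scan", class(out))
  attr(out, "reaction") <- o2_exchange

  thr <- min_exchange_for_feasibility(merged_scaled, o2_exchange,
                                      fixed = fixed, direction = "uptake",
                                      extra_eq = coup)
  feas <- out[out$status == "optimal", ]
  o2_opt <- if (nrow(feas) > 0) feas$o2[which.max(feas$community_growth)]
            else NA_real_
  nf <- spec$non_growing
  bd_max <- oxidase_max_at_optimum(community, spec, fixed,
                                   member_suffix(cytbd, nf), feas$o2,
                                   o2_exchange)
  c_max <- oxidase_max_at_optimum(community, spec, fixed,
                                  member_suffix(cytc, nf), feas$o2,
                                  o2_exchange)
  tol <- 1e-6
  bd_on <- feas$o2[bd_max > tol]
  c_off <- feas$o2[c_max < tol & bd_max > tol]
  attr(out, "summary") <- list(
    feasibility_threshold = thr$minimum,
    o2_at_max_growth = o2_opt,
    bd_activation_onset = if (length(bd_on) > 0) min(bd_on) else NA_real_,
    bd_only_from = if (length(c_off) > 0) min(c_off) else NA_real_)
  out
}

# maximum flux of one reaction over all optimal solutions, per grid point
oxidase_max_at_optimum <- function(community, spec, fixed, reaction, o2s,
                                   o2_exchange) {
  vapply(o2s, function(o2) {
    pins <- c(fixed, stats::setNames(-o2, o2_exchange))
    fva <- try(flux_variability(
      scaled_community_model(community),
      objective = member_suffix(spec$growth, spec$growing),
      reactions = reaction, fixed = pins,
      extra_eq = add_coupling_constraints(community, spec)), silent = TRUE)
    if (inherits(fva, "try-error")) NA_real_ else fva$max[[1]]
  }, numeric(1))
}

#' Fold a community solution onto the single-cell reaction index
#'
#' Sums the community-basis (abundance-weighted) member fluxes of each
#' base reaction across members, and maps pool transports back onto the
#' member exchange reactions they replaced, so the result is directly
#' comparable with a single-cell flux distribution. Community pool
#' exchanges are omitted (their flux equals the summed transports by mass
#' balance). A tagged reaction with no single-model counterpart and
#' nonzero flux is an error.
#'
#' @param solution A `flux_solution` from [solve_xfba()].
#' @param community The [build_community()] result it came from.
#' @return Tibble `reaction`, `flux` over the single-cell namespace.
#' @export
summed_member_fluxes <- function(solution, community) {
  X <- stats::setNames(community$members$abundance, community$members$tag)
  rxn <- community$model$reactions
  map <- community$exchange_map
  acc <- list()
  bad <- character(0)
  for (k in seq_len(nrow(rxn))) {
    tag <- rxn$member[k]
    if (is.na(tag)) next  # community pool exchange
    id <- rxn$id[k]
    v <- X[[tag]] * solution$fluxes$flux[solution$fluxes$reaction == id]
    base <- sub(paste0("\\[", tag, "\\]$"), "", id)
    if (grepl("^TR_", base)) {
      hit <- map$original_exchange[map$transport == id]
      if (length(hit) == 0 || is.na(hit[1])) {
        if (abs(v) > 1e-8) bad <- c(bad, id)
        next
      }
      base <- hit[1]
    }
    acc[[base]] <- (acc[[base]] %||% 0) + v
  }
  if (length(bad) > 0) {
    stop("flux-carrying community reaction(s) with no single-model ",
         "counterpart: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  tibble::tibble(reaction = names(acc), flux = as.numeric(unlist(acc)))
}

#' Principal component analysis of flux distributions
#'
#' Compares flux vectors over a common reaction index across conditions.
#' Vectors are aligned on the union of reaction ids (absent = 0),
#' mean-centered (no unit-variance scaling: fluxes share units, and
#' scaling would inflate near-zero reactions), and decomposed with
#' [stats::prcomp()]. With k observations at most k - 1 components carry
#' variance.
#'
#' @param vectors Named list (>= 2) of flux tables (tibbles with
#'   `reaction`, `flux`) or named numeric vectors; or a numeric matrix with
#'   observations in rows.
#' @return A `pca_result`: `explained_variance` (fractions summing to 1),
#'   `scores` tibble, `loadings` tibble, `preprocessing`, `degenerate`
#'   flag, and the centering vector `center`.
#' @export
pca_flux_comparison <- function(vectors) {
  if (is.matrix(vectors)) {
    mat <- vectors
  } else {
    if (length(vectors) < 2) {
      stop("need at least two flux vectors to compare", call. = FALSE)
    }
    as_named <- lapply(vectors, function(v) {
      if (is.data.frame(v)) stats::setNames(v$flux, v$reaction) else v
    })
    ids <- unique(unlist(lapply(as_named, names)))
    mat <- do.call(rbind, lapply(as_named, function(v) {
      out <- stats::setNames(numeric(length(ids)), ids)
      out[names(v)] <- v
      out
    }))
    rownames(mat) <- names(vectors) %||%
      paste0("obs", seq_along(vectors))
  }
  if (nrow(mat) < 2) {
    stop("need at least two observations", call. = FALSE)
  }
  total_var <- sum(apply(mat, 2, stats::var))
  if (total_var < 1e-12) {
    return(structure(list(explained_variance = NULL, scores = NULL,
                          loadings = NULL, preprocessing = "mean-centered",
                          degenerate = TRUE, center = colMeans(mat)),
                     class = "pca_result"))
  }
  p <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2 / sum(p$sdev^2)
  structure(list(
    explained_variance = stats::setNames(ev, colnames(p$x)),
    scores = tibble::as_tibble(p$x, rownames = "observation"),
    loadings = tibble::as_tibble(p$rotation, rownames = "reaction"),
    preprocessing = "mean-centered",
    degenerate = FALSE,
    center = p$center),
    class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result>\n")
  if (isTRUE(x$degenerate)) {
    cat("  degenerate: all observations identical (zero variance)\n")
  } else {
    cat("  explained variance: ",
        paste(sprintf("%s %.1f%%", names(x$explained_variance),
                      100 * x$explained_variance), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}
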