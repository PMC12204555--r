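#' Solve a flux balance analysis problem
#'
#' Maximises (or minimises) the flux through an objective reaction subject
#' to steady-state mass balance `S v = 0` and the model's flux bounds.
#' Entries of `fixed` pin reactions to exact values (equality, not an upper
#' bound). When the optimum is reached and `pfba = TRUE`, a secondary
#' minimisation of total absolute flux is run with the objective pinned, so
#' reported flux distributions are reproducible even when alternative
#' optima exist (use [flux_variability()] to quantify those).
#'
#' Infeasible and iteration-limited problems are returned as a status, not
#' raised.
#'
#' @param model A [metabolic_model()].
#' @param objective Objective reaction id; defaults to `model$objective`.
#' @param fixed Named numeric vector of reaction pins (lb = ub = value).
#' @param maximize Logical.
#' @param pfba Run the parsimonious secondary minimisation.
#' @param extra_eq Optional extra equality rows as `list(A = matrix over
#'   reaction columns, b = rhs)`; used by the community solver for coupling
#'   constraints.
#' @param objective_coef Optional named vector of objective coefficients,
#'   overriding `objective`.
#' @return A `flux_solution`: list with `status`, `objective_value`,
#'   `objective`, `fluxes` (tibble `reaction`, `flux`), `model_id`.
#' @export
solve_fba <- function(model, objective = NULL, fixed = NULL, maximize = TRUE,
                      pfba = TRUE, extra_eq = NULL, objective_coef = NULL) {
  rxn <- model$reactions
  n <- nrow(rxn)
  lb <- rxn$lower_bound
  ub <- rxn$upper_bound
  if (!is.null(fixed)) {
    idx <- match(names(fixed), rxn$id)
    if (anyNA(idx)) {
      stop("fixed refers to unknown reaction(s): ",
           paste(names(fixed)[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    lb[idx] <- ub[idx] <- as.numeric(fixed)
  }
  obj <- numeric(n)
  if (!is.null(objective_coef)) {
    idx <- match(names(objective_coef), rxn$id)
    if (anyNA(idx)) {
      stop("objective_coef refers to unknown reaction(s): ",
           paste(names(objective_coef)[is.na(idx)], collapse = ", "),
           call. = FALSE)
    }
    obj[idx] <- as.numeric(objective_coef)
    objective <- paste(names(objective_coef), collapse = "+")
  } else {
    objective <- objective %||% model$objective
    if (is.null(objective)) stop("no objective given", call. = FALSE)
    i <- match(objective, rxn$id)
    if (is.na(i)) {
      stop("objective reaction ", sQuote(objective), " not in model",
           call. = FALSE)
    }
    obj[i] <- 1
  }
  S <- as.matrix(stoichiometric_matrix(model))
  A_eq <- S
  b_eq <- rep(0, nrow(S))
  if (!is.null(extra_eq)) {
    A_eq <- rbind(A_eq, extra_eq$A)
    b_eq <- c(b_eq, extra_eq$b)
  }
  res <- lp_solve(obj, A_eq = A_eq, b_eq = b_eq, lb = lb, ub = ub,
                  maximize = maximize)
  v <- res$x
  if (res$status == "optimal" && pfba) {
    vp <- pfba_minimize(obj, res$objective, A_eq, b_eq, lb, ub)
    if (!is.null(vp)) v <- vp
  }
  new_flux_solution(
    status = res$status,
    objective_value = if (res$status == "optimal") sum(obj * v) else NA_real_,
    objective = objective,
    fluxes = tibble::tibble(reaction = rxn$id,
                            flux = if (res$status == "optimal") v
                                   else NA_real_),
    model_id = model$id)
}

# secondary LP: min sum |v| with the objective pinned at its optimum
pfba_minimize <- function(obj, z, A_eq, b_eq, lb, ub) {
  n <- length(obj)
  tmax <- pmax(abs(lb), abs(ub))
  obj2 <- c(numeric(n), rep(1, n))
  A_eq2 <- cbind(rbind(A_eq, obj), matrix(0, nrow(A_eq) + 1L, n))
  b_eq2 <- c(b_eq, z)
  A_ub <- rbind(cbind(diag(n), -diag(n)),     #  v - t <= 0
                cbind(-diag(n), -diag(n)))    # -v - t <= 0
  b_ub <- rep(0, 2L * n)
  res <- lp_solve(obj2, A_eq = A_eq2, b_eq = b_eq2, A_ub = A_ub, b_ub = b_ub,
                  lb = c(lb, numeric(n)), ub = c(ub, tmax), maximize = FALSE)
  if (res$status == "optimal") res$x[seq_len(n)] else NULL
}

new_flux_solution <- function(status, objective_value, objective, fluxes,
                              model_id, members = NULL, coupling = NULL) {
  structure(list(status = status, objective_value = objective_value,
                 objective = objective, fluxes = fluxes, model_id = model_id,
                 members = members, coupling = coupling),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> ", x$model_id, "\n", sep = "")
  cat("  status:    ", x$status, "\n", sep = "")
  cat("  objective: ", x$objective, " = ",
      formatC(x$objective_value, digits = 6, format = "fg"), "\n", sep = "")
  if (!is.null(x$members)) {
    cat("  member aggregates:\n")
    print(x$members)
  }
  invisible(x)
}

#' Flux of one reaction in a solution
#' @param solution A `flux_solution`.
#' @param reaction Reaction id(s).
#' @return Named numeric vector of fluxes.
#' @export
flux_of <- function(solution, reaction) {
  i <- match(reaction, solution$fluxes$reaction)
  if (anyNA(i)) {
    stop("no such reaction(s): ", paste(reaction[is.na(i)], collapse = ", "),
         call. = FALSE)
  }
  stats::setNames(solution$fluxes$flux[i], reaction)
}

#' Flux variability analysis
#'
#' For each reaction, the minimum and maximum flux attainable while the
#' objective stays at or above `objective_fraction` of its optimum. Nonzero
#' width at fraction 1 identifies alternative optima.
#'
#' @param model A [metabolic_model()].
#' @param objective Objective reaction id; defaults to `model$objective`.
#' @param objective_fraction Fraction of the optimum to hold (default 1).
#' @param reactions Reactions to scan (default: all).
#' @param fixed Named pins forwarded to [solve_fba()].
#' @param extra_eq Extra equality rows (see [solve_fba()]).
#' @return Tibble with `reaction`, `min`, `max`.
#' @export
flux_variability <- function(model, objective = NULL, objective_fraction = 1,
                             reactions = NULL, fixed = NULL, extra_eq = NULL) {
  base <- solve_fba(model, objective = objective, fixed = fixed, pfba = FALSE,
                    extra_eq = extra_eq)
  if (base$status != "optimal") {
    stop("base problem is ", base$status, "; cannot run FVA", call. = FALSE)
  }
  rxn <- model$reactions
  reactions <- reactions %||% rxn$id
  lb <- rxn$lower_bound
  ub <- rxn$upper_bound
  if (!is.null(fixed)) {
    idx <- match(names(fixed), rxn$id)
    lb[idx] <- ub[idx] <- as.numeric(fixed)
  }
  S <- as.matrix(stoichiometric_matrix(model))
  A_eq <- S; b_eq <- rep(0, nrow(S))
  if (!is.null(extra_eq)) {
    A_eq <- rbind(A_eq, extra_eq$A); b_eq <- c(b_eq, extra_eq$b)
  }
  cvec <- numeric(nrow(rxn))
  cvec[match(base$objective, rxn$id)] <- 1
  floor_val <- objective_fraction * base$objective_value -
    1e-9 * max(1, abs(base$objective_value))
  A_ub <- matrix(-cvec, nrow = 1)
  b_ub <- -floor_val
  out <- purrr::map_dfr(reactions, function(r) {
    o <- numeric(nrow(rxn)); o[match(r, rxn$id)] <- 1
    lo <- lp_solve(o, A_eq, b_eq, A_ub, b_ub, lb, ub, maximize = FALSE)
    hi <- lp_solve(o, A_eq, b_eq, A_ub, b_ub, lb, ub, maximize = TRUE)
    tibble::tibble(reaction = r,
                   min = if (lo$status == "optimal") lo$objective else NA_real_,
                   max = if (hi$status == "optimal") hi$objective else NA_real_)
  })
  out
}

#' Minimum exchange flux needed for feasibility
#'
#' Finds the smallest uptake (or secretion) of one exchange reaction at
#' which the model remains feasible, holding any other pins. The search is
#' an LP minimisation of the exchange flux followed by a bisection of the
#' pinned value, reported at `resolution` (default 0.01).
#'
#' @param model A [metabolic_model()].
#' @param exchange Exchange reaction id.
#' @param fixed Named pins applied throughout.
#' @param direction `"uptake"` (default) or `"secretion"`; results are
#'   positive magnitudes.
#' @param resolution Reporting resolution.
#' @param extra_eq Extra equality rows (see [solve_fba()]).
#' @return A list with `status` (`"ok"` or `"infeasible"`) and `minimum`
#'   (the magnitude, 0 when the exchange is not required at all).
#' @export
min_exchange_for_feasibility <- function(model, exchange, fixed = NULL,
                                         direction = c("uptake", "secretion"),
                                         resolution = 0.01, extra_eq = NULL) {
  direction <- match.arg(direction)
  if (!exchange %in% model$reactions$id) {
    stop("no reaction ", sQuote(exchange), " in model", call. = FALSE)
  }
  sgn <- if (direction == "uptake") -1 else 1
  # LP stage: push the exchange flux as close to zero-or-opposite as possible
  probe <- solve_fba(model, objective = exchange, fixed = fixed,
                     maximize = direction == "uptake", pfba = FALSE,
                     extra_eq = extra_eq)
  if (probe$status != "optimal") {
    return(list(status = "infeasible", minimum = NA_real_))
  }
  v_star <- probe$objective_value
  need <- max(0, sgn * v_star)   # magnitude required in the stated direction
  if (need == 0) return(list(status = "ok", minimum = 0))

  feasible_at <- function(mag) {
    pins <- c(fixed, stats::setNames(sgn * mag, exchange))
    s <- solve_fba(model, objective = exchange, fixed = pins,
                   maximize = TRUE, pfba = FALSE, extra_eq = extra_eq)
    s$status == "optimal"
  }
  # the LP minimum itself is feasible up to round-off; walk outwards only
  # if numerics demand it (the pin is an equality, so overshooting can be
  # infeasible too when the network cannot absorb any excess)
  hi <- need
  tries <- 0L
  while (!feasible_at(hi)) {
    hi <- hi + resolution / 10
    tries <- tries + 1L
    if (tries > 100L) return(list(status = "infeasible", minimum = NA_real_))
  }
  lo <- max(0, need - 10 * resolution)
  if (feasible_at(lo)) {
    return(list(status = "ok", minimum = round(lo / resolution) * resolution))
  }
  while (hi - lo > resolution / 2) {
    mid <- (hi + lo) / 2
    if (feasible_at(mid)) hi <- mid else lo <- mid
  }
  list(status = "ok", minimum = round(hi / resolution) * resolution)
}

#' Scan a pinned or bounded parameter over a grid
#'
#' Re-solves the model across a grid of values applied to one reaction,
#' recording infeasible points rather than skipping them.
#'
#' @param model A [metabolic_model()].
#' @param reaction Reaction whose bound is varied.
#' @param values Numeric grid of raw flux values.
#' @param objective Objective reaction (default `model$objective`).
#' @param fixed Additional pins held across the grid.
#' @param bound `"both"` pins lb = ub = value (default); `"upper"` or
#'   `"lower"` move a single bound.
#' @param pfba Parsimonious reporting per point.
#' @param extra_eq Extra equality rows (see [solve_fba()]).
#' @return An `xfba_scan` tibble: `value`, `status`, `objective_value`, and
#'   a `solution` list column of `flux_solution`s.
#' @export
scan_parameter <- function(model, reaction, values, objective = NULL,
                           fixed = NULL, bound = c("both", "upper", "lower"),
                           pfba = TRUE, extra_eq = NULL) {
  bound <- match.arg(bound)
  if (!reaction %in% model$reactions$id) {
    stop("no reaction ", sQuote(reaction), " in model", call. = FALSE)
  }
  rows <- purrr::map(values, function(val) {
    m <- model
    if (bound == "both") {
      sol <- solve_fba(m, objective = objective,
                       fixed = c(fixed, stats::setNames(val, reaction)),
                       pfba = pfba, extra_eq = extra_eq)
    } else {
      m <- set_bounds(m, reaction,
                      lower = if (bound == "lower") val else NULL,
                      upper = if (bound == "upper") val else NULL)
      sol <- solve_fba(m, objective = objective, fixed = fixed, pfba = pfba,
                       extra_eq = extra_eq)
    }
    tibble::tibble(value = val, status = sol$status,
                   objective_value = sol$objective_value,
                   solution = list(sol))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("xfba_scan", class(out))
  attr(out, "reaction") <- reaction
  attr(out, "bound") <- bound
  out
}

#' Export a solution (with optional FVA widths) as a flux table
#'
#' @param solution A `flux_solution`.
#' @param fva Optional tibble from [flux_variability()] joined in as
#'   `fva_min`/`fva_max`.
#' @param path Optional TSV destination.
#' @return The flux tibble (invisibly when written to `path`).
#' @export
flux_table <- function(solution, fva = NULL, path = NULL) {
  out <- solution$fluxes
  if (!is.null(fva)) {
    out <- dplyr::left_join(out,
                            dplyr::rename(fva, fva_min = "min",
                                          fva_max = "max"),
                            by = "reaction")
  }
  if (!is.null(path)) {
    readr::write_tsv(out, path, progress = FALSE)
    return(invisible(out))
  }
  out
}
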