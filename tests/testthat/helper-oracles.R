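# Independent oracles, implemented without touching the package's solver.

# Brute-force LP by basic-solution enumeration: every vertex of
# {Aeq x = beq, lb <= x <= ub} has the non-"free" coordinates at a bound.
# Enumerates column subsets of size rank(Aeq) and all bound assignments of
# the remaining coordinates. Only viable for small n - use micro fixtures.
oracle_lp_enumerate <- function(obj, Aeq, beq, lb, ub, maximize = TRUE,
                                tol = 1e-8) {
  Aeq <- as.matrix(Aeq)
  n <- ncol(Aeq)
  r <- qr(Aeq)$rank
  best <- if (maximize) -Inf else Inf
  best_x <- NULL
  sets <- utils::combn(n, r)
  for (k in seq_len(ncol(sets))) {
    B <- sets[, k]
    AB <- Aeq[, B, drop = FALSE]
    if (qr(AB)$rank < r) next
    N <- setdiff(seq_len(n), B)
    grids <- if (length(N) == 0) list(numeric(0)) else {
      do.call(expand.grid, lapply(N, function(j) c(lb[j], ub[j])))
    }
    grids <- if (is.data.frame(grids)) asplit(as.matrix(grids), 1) else grids
    for (xN in grids) {
      rhs <- beq - if (length(N) > 0)
        as.numeric(Aeq[, N, drop = FALSE] %*% as.numeric(xN)) else 0
      xB <- tryCatch(qr.solve(AB, rhs), error = function(e) NULL)
      if (is.null(xB)) next
      x <- numeric(n)
      x[B] <- xB
      x[N] <- as.numeric(xN)
      if (max(abs(Aeq %*% x - beq)) > tol) next
      if (any(x < lb - tol) || any(x > ub + tol)) next
      val <- sum(obj * x)
      if ((maximize && val > best + 1e-12) ||
          (!maximize && val < best - 1e-12)) {
        best <- val
        best_x <- x
      }
    }
  }
  list(objective = best, x = best_x)
}

# Dense steady-state matrix assembled from first principles (no package
# matrix code): walks the reaction list and fills a base-R matrix.
dense_stoichiometry <- function(model) {
  mets <- model$metabolites$id
  rxns <- model$reactions$id
  M <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  for (k in seq_along(rxns)) {
    s <- model$reactions$stoichiometry[[k]]
    for (nm in names(s)) M[nm, k] <- M[nm, k] + s[[nm]]
  }
  M
}

# Exhaustive dead-end scan: for every metabolite, enumerate all (reaction,
# direction) pairs allowed by the bounds and collect producer/consumer
# evidence - written independently of find_dead_ends().
oracle_dead_ends <- function(model) {
  out <- character(0)
  for (met in model$metabolites$id) {
    produced <- FALSE
    consumed <- FALSE
    for (k in seq_len(nrow(model$reactions))) {
      s <- model$reactions$stoichiometry[[k]]
      if (!met %in% names(s)) next
      coef <- s[[met]]
      if (model$reactions$upper_bound[k] > 0) {   # forward direction usable
        if (coef > 0) produced <- TRUE
        if (coef < 0) consumed <- TRUE
      }
      if (model$reactions$lower_bound[k] < 0) {   # backward direction usable
        if (coef > 0) consumed <- TRUE
        if (coef < 0) produced <- TRUE
      }
    }
    if (!(produced && consumed)) out <- c(out, met)
  }
  out
}

# FBA via the enumeration oracle on a (small) model, applying pins and an
# optional equal-to constraint set, with abundance scaling done by plain
# column multiplication here in the test.
oracle_fba <- function(model, objective, fixed = NULL, extra_A = NULL,
                       extra_b = NULL, col_scale = NULL, maximize = TRUE) {
  M <- dense_stoichiometry(model)
  if (!is.null(col_scale)) M <- sweep(M, 2, col_scale, `*`)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  if (!is.null(fixed)) {
    idx <- match(names(fixed), model$reactions$id)
    lb[idx] <- ub[idx] <- as.numeric(fixed)
  }
  Aeq <- M
  beq <- rep(0, nrow(M))
  if (!is.null(extra_A)) {
    Aeq <- rbind(Aeq, extra_A)
    beq <- c(beq, extra_b)
  }
  obj <- as.numeric(model$reactions$id == objective)
  oracle_lp_enumerate(obj, Aeq, beq, lb, ub, maximize = maximize)
}
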