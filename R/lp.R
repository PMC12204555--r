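# Internal dense LP layer.
#
# Solves  max/min  c'v
#         s.t.     A_eq v  = b_eq
#                  A_ub v <= b_ub
#                  lb <= v <= ub
#
# The metabolic LPs here are heavily degenerate (many structurally-zero
# fluxes, linearly dependent mass-balance rows). The general-purpose
# simplex routines available in the R ecosystem used by this package's
# dependencies (boot::simplex, pracma::linprog) break down on them —
# basic artificial variables after phase 1 and singular bases during
# pivoting — so the package carries its own bounded-variable two-phase
# primal simplex with Bland's anti-cycling rule and a terminal
# basis-refinement solve. Problem sizes are small (tens to a few hundred
# variables), where a dense tableau is both fast and exact enough.

LP_BIG <- 1e4

lp_solve <- function(obj, A_eq = NULL, b_eq = NULL, A_ub = NULL, b_ub = NULL,
                     lb, ub, maximize = TRUE, tol = 1e-9) {
  n <- length(obj)
  lb <- pmax(lb, -LP_BIG)
  ub <- pmin(ub, LP_BIG)
  if (any(lb > ub)) {
    return(list(status = "infeasible", objective = NA_real_,
                x = rep(NA_real_, n)))
  }
  # shift x = v - lb so 0 <= x <= ub - lb
  A <- NULL; b <- NULL
  if (!is.null(A_eq)) {
    A <- as.matrix(A_eq)
    b <- as.numeric(b_eq) - as.numeric(A %*% lb)
  }
  u <- ub - lb
  nslack <- 0L
  if (!is.null(A_ub)) {
    A_ub <- as.matrix(A_ub)
    b2 <- as.numeric(b_ub) - as.numeric(A_ub %*% lb)
    nslack <- nrow(A_ub)
    A <- rbind(cbind(A, matrix(0, NROW(A), nslack)),
               cbind(A_ub, diag(nslack)))
    b <- c(b, b2)
    u <- c(u, rep(Inf, nslack))
  }
  if (is.null(A)) {  # box-only problem
    x <- ifelse((maximize & obj > 0) | (!maximize & obj < 0), u, 0)
    v <- x[seq_len(n)] + lb
    return(list(status = "optimal", objective = sum(obj * v), x = v))
  }
  cost <- c(if (maximize) -obj else obj, rep(0, nslack))
  res <- simplex_bounded(cost, A, b, u, tol = tol)
  if (res$status != "optimal") {
    return(list(status = res$status, objective = NA_real_,
                x = rep(NA_real_, n)))
  }
  v <- res$x[seq_len(n)] + lb
  list(status = "optimal", objective = sum(obj * v), x = v)
}

# min cost'x  s.t.  A x = b, 0 <= x <= u  (u may be Inf).
# Dense full-tableau two-phase simplex, Bland's rule throughout.
simplex_bounded <- function(cost, A, b, u, tol = 1e-9, max_iter = 50000L) {
  m <- nrow(A); n <- ncol(A)
  flip <- b < 0
  A[flip, ] <- -A[flip, , drop = FALSE]
  b[flip] <- -b[flip]

  # phase 1: artificial basis
  Nfull <- n + m
  W <- cbind(A, diag(m))           # B^-1 A_full, basis = artificials
  uu <- c(u, rep(0, m))            # artificials pinned to 0 once left
  uu[n + seq_len(m)] <- Inf        # ... but start unconstrained above
  basis <- n + seq_len(m)
  xB <- b
  at_upper <- rep(FALSE, Nfull)    # nonbasic position (lower unless TRUE)
  phase_cost <- c(rep(0, n), rep(1, m))

  run <- function(costv, W, basis, xB, at_upper, uu, allow_enter) {
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > max_iter) {
        return(list(status = "iteration_limit", W = W, basis = basis,
                    xB = xB, at_upper = at_upper))
      }
      cB <- costv[basis]
      d <- costv - as.numeric(crossprod(W, cB))
      is_basic <- rep(FALSE, Nfull); is_basic[basis] <- TRUE
      enter_lo <- !is_basic & !at_upper & d < -tol & allow_enter
      enter_hi <- !is_basic & at_upper & d > tol & allow_enter
      cand <- which(enter_lo | enter_hi)
      if (length(cand) == 0L) {
        return(list(status = "optimal", W = W, basis = basis, xB = xB,
                    at_upper = at_upper))
      }
      j <- cand[1L]                              # Bland: smallest index
      delta <- if (at_upper[j]) -1 else 1        # direction x_j moves
      w <- delta * W[, j]                        # xB changes by -w per unit t
      # max step before a basic variable hits one of its bounds
      ratio <- rep(Inf, m)
      pos <- w > tol
      neg <- w < -tol
      ratio[pos] <- pmax(0, xB[pos] / w[pos])
      ratio[neg] <- pmax(0, (xB[neg] - uu[basis[neg]]) / w[neg])
      t_basic <- if (m > 0) min(ratio) else Inf
      t <- min(t_basic, uu[j])
      if (!is.finite(t)) {
        return(list(status = "unbounded", W = W, basis = basis, xB = xB,
                    at_upper = at_upper))
      }
      xB <- xB - w * t
      if (uu[j] < t_basic - tol) {               # entering flips to its
        at_upper[j] <- !at_upper[j]              # other bound; basis fixed
        next
      }
      lim <- which(is.finite(ratio) & abs(ratio - t) <= tol * (1 + abs(t)))
      if (length(lim) == 0L) {                   # numerically a bound flip
        at_upper[j] <- !at_upper[j]
        next
      }
      r <- lim[which.min(basis[lim])]            # Bland tie-break
      leave <- basis[r]
      at_upper[leave] <- w[r] < 0                # hit upper bound if w < 0
      xj <- if (delta > 0) t else uu[j] - t      # entering variable's value
      basis[r] <- j
      piv <- W[r, j]
      W[r, ] <- W[r, ] / piv
      colj <- W[, j]
      upd <- which(abs(colj) > 1e-13)
      upd <- upd[upd != r]
      if (length(upd) > 0) {
        W[upd, ] <- W[upd, ] - outer(colj[upd], W[r, ])
      }
      xB[r] <- xj
      at_upper[j] <- FALSE                       # j is basic now
    }
  }

  p1 <- run(phase_cost, W, basis, xB, at_upper, uu,
            allow_enter = c(rep(TRUE, n), rep(FALSE, m)))
  if (p1$status != "optimal") return(list(status = p1$status, x = NULL))
  art <- p1$basis > n
  resid <- sum(abs(p1$xB[art]))
  if (resid > 1e-7) return(list(status = "infeasible", x = NULL))
  uu[n + seq_len(m)] <- 0                        # artificials locked at 0
  p1$xB[art] <- 0
  p2 <- run(c(cost, rep(0, m)), p1$W, p1$basis, p1$xB, p1$at_upper, uu,
            allow_enter = c(rep(TRUE, n), rep(FALSE, m)))
  if (p2$status != "optimal") return(list(status = p2$status, x = NULL))

  x <- numeric(Nfull)
  x[p2$at_upper] <- uu[p2$at_upper]
  x[p2$basis] <- p2$xB
  x <- x[seq_len(n)]
  # terminal refinement: re-solve the basic components exactly against the
  # original (sign-fixed) system to strip accumulated pivot error
  struct_basis <- p2$basis[p2$basis <= n]
  if (length(struct_basis) > 0) {
    nonb <- setdiff(seq_len(n), struct_basis)
    rhs <- b - if (length(nonb) > 0)
      as.numeric(A[, nonb, drop = FALSE] %*% x[nonb]) else 0
    Bmat <- A[, struct_basis, drop = FALSE]
    ref <- tryCatch(qr.solve(Bmat, rhs, tol = 1e-12), error = function(e) NULL)
    if (!is.null(ref) && max(abs(Bmat %*% ref - rhs)) < 1e-7) {
      x[struct_basis] <- ref
    }
  }
  x[abs(x) < 1e-11] <- 0
  list(status = "optimal", x = x, value = sum(cost * x))
}
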