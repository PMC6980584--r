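#' Solve a bounded linear program
#'
#' Maximises (or minimises) `obj %*% x` subject to `A %*% x == rhs` and
#' `lb <= x <= ub`, using a two-phase primal simplex with bounded variables.
#' All equality right-hand sides and finite bounds are allowed; lower bounds
#' must be finite (flux models always have finite lower bounds), upper bounds
#' may be `Inf`.
#'
#' Dual values are reported per equality row with the convention that, for a
#' maximisation, the dual of row `i` equals the sensitivity of the optimum to
#' an increase of `rhs[i]` (for non-degenerate optima).
#'
#' @param obj numeric objective coefficient vector (length n).
#' @param A constraint matrix (m x n), dense or a `Matrix` sparse matrix.
#' @param rhs right-hand-side vector (length m).
#' @param lb,ub variable bounds (length n); `lb` finite, `ub` may be `Inf`.
#' @param maximize logical; maximise (default) or minimise.
#' @param tol pivot/feasibility tolerance.
#' @param maxit iteration cap across both phases.
#' @return list with `status` ("optimal", "infeasible", "unbounded"),
#'   `objective`, `x`, `duals` (length m), `reduced_costs` (length n).
#' @export
solve_lp <- function(obj, A, rhs, lb, ub, maximize = TRUE,
                     tol = 1e-9, maxit = 50000L) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(rhs) == m, length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb))) stop("solve_lp requires finite lower bounds")
  if (any(lb > ub + 1e-12)) {
    return(list(status = "infeasible", objective = NA_real_,
                x = rep(NA_real_, n), duals = rep(NA_real_, m),
                reduced_costs = rep(NA_real_, n)))
  }
  sense <- if (maximize) 1 else -1
  cc <- sense * as.numeric(obj)

  # shift to x = lb + y, 0 <= y <= w
  w <- ub - lb
  b <- as.numeric(rhs - A %*% lb)
  rowsign <- ifelse(b < 0, -1, 1)
  As <- sweep(A, 1L, rowsign, `*`)
  bs <- b * rowsign

  res <- .simplex_bounded(cc, As, bs, w, tol = tol, maxit = maxit)
  if (res$status != "optimal") {
    return(list(status = res$status, objective = NA_real_,
                x = rep(NA_real_, n), duals = rep(NA_real_, m),
                reduced_costs = rep(NA_real_, n)))
  }

  x <- lb + res$y
  duals <- res$duals * rowsign * sense
  rc <- res$reduced_costs * sense
  list(status = "optimal",
       objective = sum(as.numeric(obj) * x),
       x = x, duals = duals, reduced_costs = rc)
}

# Two-phase bounded-variable primal simplex on
#   max cc'y  s.t.  As y = bs (bs >= 0), 0 <= y <= w.
# Full-tableau implementation with artificial columns kept so that the final
# tableau columns B^{-1} e_i yield the dual vector directly; the optimal basis
# is re-solved with base `solve()` at the end to wash out pivot round-off.
.simplex_bounded <- function(cc, As, bs, w, tol = 1e-9, maxit = 50000L) {
  m <- nrow(As); n <- ncol(As)
  Aext <- cbind(As, diag(m))
  wext <- c(w, rep(Inf, m))
  nall <- n + m
  art <- seq.int(n + 1L, nall)

  basis <- art
  vstat <- rep("L", nall)       # L: at lower, U: at upper, B: basic
  vstat[basis] <- "B"
  Tm <- Aext                     # B^{-1} Aext (B = I initially)
  xB <- bs

  run_phase <- function(cobj, allowed, basis, vstat, Tm, xB, wext, iter0) {
    iter <- iter0
    bland_after <- 4000L
    repeat {
      iter <- iter + 1L
      if (iter > maxit) stop("simplex iteration limit reached")
      y <- drop(cobj[basis] %*% Tm)
      d <- cobj - y
      atL <- vstat == "L" & allowed & d > tol
      atU <- vstat == "U" & allowed & d < -tol
      cand <- which(atL | atU)
      if (!length(cand)) {
        return(list(status = "optimal", basis = basis, vstat = vstat,
                    Tm = Tm, xB = xB, d = d, iter = iter))
      }
      q <- if (iter - iter0 > bland_after) cand[1L] else cand[which.max(abs(d[cand]))]
      from_upper <- vstat[q] == "U"
      alpha <- if (from_upper) -Tm[, q] else Tm[, q]

      # ratio test
      wB <- wext[basis]
      tlim <- rep(Inf, m)
      up <- alpha > tol
      dn <- alpha < -tol
      tlim[up] <- xB[up] / alpha[up]
      tlim[dn] <- (xB[dn] - wB[dn]) / alpha[dn]
      tlim[tlim < 0] <- 0       # degeneracy guard
      tb <- if (any(is.finite(tlim))) min(tlim) else Inf
      tself <- wext[q]
      tstar <- min(tb, tself)
      if (!is.finite(tstar)) {
        return(list(status = "unbounded", iter = iter))
      }
      if (tself <= tb) {
        # bound flip, basis unchanged
        xB <- xB - tstar * alpha
        vstat[q] <- if (from_upper) "L" else "U"
        next
      }
      r <- which(tlim <= tstar + 1e-12)
      # prefer kicking artificial variables out of the basis on ties
      r <- if (any(basis[r] > n)) r[basis[r] > n][1L] else r[1L]
      xB <- xB - tstar * alpha
      enter_val <- if (from_upper) wext[q] - tstar else tstar
      leave <- basis[r]
      vstat[leave] <- if (alpha[r] > 0) "L" else "U"
      basis[r] <- q
      vstat[q] <- "B"
      piv <- Tm[r, q]
      Tm[r, ] <- Tm[r, ] / piv
      fac <- Tm[, q]
      fac[r] <- 0
      Tm <- Tm - outer(fac, Tm[r, ])
      xB[r] <- enter_val
    }
  }

  # Phase 1: drive artificials to zero
  c1 <- c(rep(0, n), rep(-1, m))
  allowed <- rep(TRUE, nall)
  p1 <- run_phase(c1, allowed, basis, vstat, Tm, xB, wext, 0L)
  if (p1$status != "optimal") return(list(status = "infeasible"))
  artvals <- p1$xB[p1$basis > n]
  if (sum(artvals) > 1e-7) return(list(status = "infeasible"))

  # Phase 2: artificials frozen at zero
  wext2 <- wext
  wext2[art] <- 0
  allowed2 <- c(rep(TRUE, n), rep(FALSE, m))
  c2 <- c(cc, rep(0, m))
  p2 <- run_phase(c2, allowed2, p1$basis, p1$vstat, p1$Tm, p1$xB, wext2, p1$iter)
  if (p2$status != "optimal") return(list(status = p2$status))

  # reconstruct and polish against the original system
  basis <- p2$basis; vstat <- p2$vstat
  yv <- numeric(nall)
  yv[vstat == "U"] <- wext2[vstat == "U"]
  yv[basis] <- p2$xB
  struct <- seq_len(n)

  B <- Aext[, basis, drop = FALSE]
  nb <- setdiff(seq_len(nall), basis)
  polish_ok <- FALSE
  qrB <- qr(B)
  if (qrB$rank == m) {
    rhs_adj <- bs - Aext[, nb, drop = FALSE] %*% yv[nb]
    xb_exact <- qr.solve(qrB, rhs_adj)
    yv[basis] <- drop(xb_exact)
    duals <- qr.solve(qr(t(B)), c2[basis])
    polish_ok <- TRUE
  }
  if (!polish_ok) {
    duals <- drop(c2[basis] %*% p2$Tm[, art, drop = FALSE])
  }
  duals <- drop(duals)
  rc <- cc - drop(duals %*% As)

  list(status = "optimal", y = yv[struct], duals = duals,
       reduced_costs = rc)
}
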