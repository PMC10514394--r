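# Dense two-phase primal simplex and a small branch-and-bound layer.
#
# The optimization problems assembled elsewhere in the package (FBA, pFBA,
# max-min driving force and the variability analyses) are small dense LPs and
# MILPs: tens of variables, at most a few dozen binaries.  A textbook
# full-tableau simplex with Bland's anti-cycling rule is exact enough and
# deterministic, which matters for the staircase and bottleneck equality
# tests downstream.

# Solve  min/max obj'x  s.t.  mat x (dir) rhs,  lb <= x <= ub.
# dir entries are "<=", ">=" or "=".  Bounds may be +/-Inf.
# Returns list(status, x, objval); status one of
# "optimal", "infeasible", "unbounded", "error".
lp_solve <- function(obj, mat, dir, rhs, lb, ub, maximize = FALSE,
                     tol = 1e-9, max_iter = 50000L) {
  n <- length(obj)
  if (is.null(mat)) mat <- matrix(0, 0L, n)
  mat <- as.matrix(mat)
  stopifnot(ncol(mat) == n, nrow(mat) == length(rhs), length(dir) == nrow(mat))
  if (length(lb) == 1L) lb <- rep(lb, n)
  if (length(ub) == 1L) ub <- rep(ub, n)
  if (any(lb > ub + 1e-12)) {
    return(list(status = "infeasible", x = rep(NA_real_, n), objval = NA_real_))
  }
  sense <- if (maximize) -1 else 1
  cx <- sense * obj

  # --- transform to y >= 0 -------------------------------------------------
  # Each original variable maps to one column (shifted or flipped) or, if
  # free in both directions, to a pair y+ - y-.
  map_col <- integer(0)   # original index of each y column
  map_sgn <- numeric(0)   # +1 or -1
  off_x <- numeric(n)     # x = off_x + sum of sgn * y over mapped columns
  y_ub <- numeric(0)      # finite upper bounds on y (Inf allowed)
  for (j in seq_len(n)) {
    if (is.finite(lb[j])) {
      map_col <- c(map_col, j); map_sgn <- c(map_sgn, 1); off_x[j] <- lb[j]
      y_ub <- c(y_ub, ub[j] - lb[j])
    } else if (is.finite(ub[j])) {
      map_col <- c(map_col, j); map_sgn <- c(map_sgn, -1); off_x[j] <- ub[j]
      y_ub <- c(y_ub, Inf)
    } else {
      map_col <- c(map_col, j, j); map_sgn <- c(map_sgn, 1, -1)
      y_ub <- c(y_ub, Inf, Inf)
    }
  }
  ny <- length(map_col)
  Ay <- mat[, map_col, drop = FALSE] * rep(map_sgn, each = nrow(mat))
  by <- rhs - as.vector(mat %*% off_x)
  cy <- cx[map_col] * map_sgn
  c_const <- sum(cx * off_x)
  dy <- dir

  # finite upper bounds on y become explicit rows
  fin <- which(is.finite(y_ub))
  if (length(fin)) {
    Ub <- matrix(0, length(fin), ny)
    Ub[cbind(seq_along(fin), fin)] <- 1
    Ay <- rbind(Ay, Ub)
    by <- c(by, y_ub[fin])
    dy <- c(dy, rep("<=", length(fin)))
  }

  # make rhs nonnegative
  neg <- which(by < 0)
  if (length(neg)) {
    Ay[neg, ] <- -Ay[neg, , drop = FALSE]
    by[neg] <- -by[neg]
    dy[neg] <- ifelse(dy[neg] == "<=", ">=", ifelse(dy[neg] == ">=", "<=", "="))
  }
  m <- nrow(Ay)

  # --- phase setup ---------------------------------------------------------
  n_slack <- sum(dy == "<=")
  n_surp <- sum(dy == ">=")
  n_art <- sum(dy != "<=")
  ntot <- ny + n_slack + n_surp + n_art
  T <- matrix(0, m, ntot + 1L)
  T[, seq_len(ny)] <- Ay
  T[, ntot + 1L] <- by
  basis <- integer(m)
  is_art <- rep(FALSE, ntot)
  s_i <- ny; u_i <- ny + n_slack; a_i <- ny + n_slack + n_surp
  for (i in seq_len(m)) {
    if (dy[i] == "<=") {
      s_i <- s_i + 1L; T[i, s_i] <- 1; basis[i] <- s_i
    } else if (dy[i] == ">=") {
      u_i <- u_i + 1L; T[i, u_i] <- -1
      a_i <- a_i + 1L; T[i, a_i] <- 1; basis[i] <- a_i; is_art[a_i] <- TRUE
    } else {
      a_i <- a_i + 1L; T[i, a_i] <- 1; basis[i] <- a_i; is_art[a_i] <- TRUE
    }
  }

  run <- function(T, basis, cost, allowed) {
    nc <- ncol(T) - 1L
    for (iter in seq_len(max_iter)) {
      cb <- cost[basis]
      red <- cost - as.vector(cb %*% T[, seq_len(nc), drop = FALSE])
      ent <- which(allowed & red < -tol)
      if (!length(ent)) return(list(T = T, basis = basis, status = "optimal"))
      j <- ent[1L]  # Bland: smallest index
      col <- T[, j]
      pos <- which(col > tol)
      if (!length(pos)) return(list(T = T, basis = basis, status = "unbounded"))
      ratio <- T[pos, nc + 1L] / col[pos]
      best <- pos[ratio <= min(ratio) + tol]
      i <- best[which.min(basis[best])]  # Bland tie-break
      piv <- T[i, j]
      T[i, ] <- T[i, ] / piv
      for (k in seq_len(nrow(T))) {
        if (k != i && abs(T[k, j]) > 0) T[k, ] <- T[k, ] - T[k, j] * T[i, ]
      }
      basis[i] <- j
    }
    list(T = T, basis = basis, status = "error")
  }

  if (n_art > 0L) {
    cost1 <- as.numeric(is_art)
    r1 <- run(T, basis, cost1, rep(TRUE, ntot))
    if (r1$status == "error") return(list(status = "error", x = NULL, objval = NA_real_))
    T <- r1$T; basis <- r1$basis
    p1 <- sum(cost1[basis] * T[, ntot + 1L])
    if (p1 > 1e-7) {
      return(list(status = "infeasible", x = rep(NA_real_, n), objval = NA_real_))
    }
    # drive remaining basic artificials out or drop redundant rows
    drop_rows <- integer(0)
    for (i in seq_len(m)) {
      if (is_art[basis[i]]) {
        cand <- which(!is_art[seq_len(ntot)] & abs(T[i, seq_len(ntot)]) > tol)
        if (length(cand)) {
          j <- cand[1L]
          T[i, ] <- T[i, ] / T[i, j]
          for (k in seq_len(m)) {
            if (k != i && abs(T[k, j]) > 0) T[k, ] <- T[k, ] - T[k, j] * T[i, ]
          }
          basis[i] <- j
        } else {
          drop_rows <- c(drop_rows, i)
        }
      }
    }
    if (length(drop_rows)) {
      T <- T[-drop_rows, , drop = FALSE]
      basis <- basis[-drop_rows]
      m <- nrow(T)
    }
  }

  cost2 <- c(cy, rep(0, n_slack + n_surp), rep(0, n_art))
  r2 <- run(T, basis, cost2, !is_art)
  if (r2$status == "unbounded") {
    return(list(status = "unbounded", x = rep(NA_real_, n), objval = NA_real_))
  }
  if (r2$status == "error") return(list(status = "error", x = NULL, objval = NA_real_))
  T <- r2$T; basis <- r2$basis

  yv <- numeric(ntot)
  yv[basis] <- T[, ntot + 1L]
  x <- off_x
  for (k in seq_len(ny)) {
    x[map_col[k]] <- x[map_col[k]] + map_sgn[k] * yv[k]
  }
  objval <- sense * (sum(cy * yv[seq_len(ny)]) + c_const)
  list(status = "optimal", x = x, objval = objval)
}

# Branch-and-bound MILP over binary variables on top of lp_solve().
# bin_idx: indices of variables restricted to {0, 1}.
milp_solve <- function(obj, mat, dir, rhs, lb, ub, bin_idx = integer(0),
                       maximize = FALSE, int_tol = 1e-6, gap = 1e-9,
                       max_nodes = 10000L) {
  n <- length(obj)
  if (length(lb) == 1L) lb <- rep(lb, n)
  if (length(ub) == 1L) ub <- rep(ub, n)
  lb[bin_idx] <- pmax(lb[bin_idx], 0)
  ub[bin_idx] <- pmin(ub[bin_idx], 1)
  if (!length(bin_idx)) {
    return(lp_solve(obj, mat, dir, rhs, lb, ub, maximize = maximize))
  }
  best <- NULL
  best_val <- if (maximize) -Inf else Inf
  better <- function(a, b) if (maximize) a > b + gap else a < b - gap
  stack <- list(list(lb = lb, ub = ub))
  nodes <- 0L
  root_unbounded <- FALSE
  while (length(stack)) {
    nodes <- nodes + 1L
    if (nodes > max_nodes) {
      return(list(status = "error", x = NULL, objval = NA_real_))
    }
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    rel <- lp_solve(obj, mat, dir, rhs, node$lb, node$ub, maximize = maximize)
    if (rel$status == "infeasible") next
    if (rel$status == "unbounded") {
      if (nodes == 1L) root_unbounded <- TRUE
      # relaxation unbounded: branch on the first unfixed binary to resolve
      free_b <- bin_idx[node$ub[bin_idx] - node$lb[bin_idx] > 0.5]
      if (!length(free_b)) {
        return(list(status = "unbounded", x = NULL, objval = NA_real_))
      }
      j <- free_b[1L]
      for (v in c(0, 1)) {
        child <- node; child$lb[j] <- v; child$ub[j] <- v
        stack[[length(stack) + 1L]] <- child
      }
      next
    }
    if (rel$status != "optimal") return(rel)
    if (!is.null(best) && !better(rel$objval, best_val)) next
    zfrac <- abs(rel$x[bin_idx] - round(rel$x[bin_idx]))
    unfixed <- node$ub[bin_idx] - node$lb[bin_idx] > 0.5
    if (all(zfrac <= int_tol)) {
      # near-integral relaxation: verify by re-solving with the binaries
      # fixed at their rounded values (a z like v/ub = 1e-6 must not be
      # silently rounded away); branch if the fixed problem is infeasible
      if (!any(unfixed)) {
        if (is.null(best) || better(rel$objval, best_val)) {
          best <- rel$x; best_val <- rel$objval
        }
        next
      }
      zlb <- node$lb; zub <- node$ub
      zlb[bin_idx] <- zub[bin_idx] <- round(rel$x[bin_idx])
      fx <- lp_solve(obj, mat, dir, rhs, zlb, zub, maximize = maximize)
      if (fx$status == "optimal") {
        if (is.null(best) || better(fx$objval, best_val)) {
          best <- fx$x; best_val <- fx$objval
        }
        if (abs(fx$objval - rel$objval) <= gap) next
      }
      # fixing changed the optimum (or was infeasible): branch to explore
      j <- bin_idx[unfixed][which.max(zfrac[unfixed])]
      child0 <- node; child0$lb[j] <- 0; child0$ub[j] <- 0
      child1 <- node; child1$lb[j] <- 1; child1$ub[j] <- 1
      stack[[length(stack) + 1L]] <- child0
      stack[[length(stack) + 1L]] <- child1
      next
    }
    j <- bin_idx[which.max(zfrac)]
    # explore the active branch (z = 1) first: depth-first, deterministic
    child0 <- node; child0$lb[j] <- 0; child0$ub[j] <- 0
    child1 <- node; child1$lb[j] <- 1; child1$ub[j] <- 1
    stack[[length(stack) + 1L]] <- child0
    stack[[length(stack) + 1L]] <- child1
  }
  if (is.null(best)) {
    status <- if (root_unbounded) "unbounded" else "infeasible"
    return(list(status = status, x = rep(NA_real_, n), objval = NA_real_))
  }
  list(status = "optimal", x = best, objval = best_val)
}
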