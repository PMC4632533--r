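# Per-frame constrained minimisation of the cubic load-sharing cost
#   J = sum_i (F_i/Fmax_i)^3 + sum_j (L_j/Lmax_j)^3
# subject to A x = b and box bounds. The unbounded reaction columns are
# eliminated first through the left null space of their block (QR), leaving a
# smaller strictly box-bounded convex problem that is solved by an augmented
# Lagrangian with analytic gradients (inner solver: projected quasi-Newton,
# L-BFGS-B). Reactions are recovered by least squares afterwards.

#' Solver configuration
#'
#' @param constraint_tol equality residual tolerance (row-equilibrated scale).
#' @param cost_tol relative cost change declaring inner convergence.
#' @param mu0 initial augmented-Lagrangian penalty.
#' @param mu_factor penalty growth factor when the residual stalls.
#' @param max_outer maximum outer (multiplier) iterations.
#' @param inner_maxit L-BFGS-B iteration cap per inner solve.
#' @param row_equilibrate divide each equality row by its norm (conditioning).
#' @return list of solver settings.
#' @export
solver_control <- function(constraint_tol = 1e-7, cost_tol = 1e-8, mu0 = 10,
                           mu_factor = 10, max_outer = 40, inner_maxit = 300,
                           row_equilibrate = TRUE) {
  list(constraint_tol = constraint_tol, cost_tol = cost_tol, mu0 = mu0,
       mu_factor = mu_factor, max_outer = max_outer, inner_maxit = inner_maxit,
       row_equilibrate = row_equilibrate)
}

#' Solve one frame system
#'
#' Minimises the cubic load-sharing cost over the frame's equations of motion
#' and box bounds. Infeasible frames (equality residual above tolerance after
#' the multiplier iterations) are flagged, not fabricated.
#'
#' @param sys an `fb_system` from [assemble_system()] (or any object with the
#'   same fields).
#' @param control see [solver_control()].
#' @param warm optional solution vector of the previous frame (same layout)
#'   used as the starting point.
#' @return object of class `"fb_solution"`: `x` (full unknown vector, named),
#'   `J` (cost), `feasible`, `residual` (max abs equality violation, original
#'   row scale), `iterations` (outer iterations), plus `forces` (bounded
#'   columns, named) and `reactions` (list of 3-vectors per reaction group).
#' @export
solve_frame <- function(sys, control = solver_control(), warm = NULL) {
  A <- sys$A; b <- sys$b
  nB <- which(is.finite(sys$upper))
  nR <- which(!is.finite(sys$upper))
  if (any(sys$lower[nB] != 0)) stop("bounded columns must have zero lower bounds")
  ub <- sys$upper[nB]
  if (any(ub <= 0)) stop("bounded columns must have positive upper bounds")
  cost_cols <- sys$cost[nB]

  AB <- A[, nB, drop = FALSE]
  outer_it <- 0L

  # eliminate free (reaction) columns via the left null space of their block
  if (length(nR)) {
    AR <- A[, nR, drop = FALSE]
    qa <- qr(AR)
    r <- qa$rank
    m <- nrow(A)
    if (r < m) {
      Qf <- qr.Q(qa, complete = TRUE)
      Nb <- Qf[, (r + 1):m, drop = FALSE]
      Ared <- t(Nb) %*% AB
      bred <- as.numeric(t(Nb) %*% b)
    } else {
      Ared <- matrix(0, 0, length(nB)); bred <- numeric(0)
    }
  } else {
    Ared <- AB; bred <- b
  }

  # scale variables to z = x/ub in [0,1]; cost becomes sum(z^3) on cost cols
  Az <- sweep(Ared, 2, ub, `*`)
  if (nrow(Az) > 0 && control$row_equilibrate) {
    rn <- pmax(sqrt(rowSums(Az^2)), 1e-12)
    Az <- Az / rn
    bz <- bred / rn
  } else {
    bz <- bred
  }
  w <- as.numeric(cost_cols)
  z0 <- if (!is.null(warm)) pmin(1, pmax(0, warm[nB] / ub)) else rep(0.5, length(nB))

  if (nrow(Az) == 0) {
    z <- rep(0, length(nB))  # unconstrained in the bounded block: cost minimum
    feas_red <- TRUE
  } else {
    lambda <- rep(0, nrow(Az))
    mu <- control$mu0
    z <- z0
    res_prev <- Inf
    feas_red <- FALSE
    tAz <- t(Az)
    for (outer_it in seq_len(control$max_outer)) {
      fn <- function(zz) {
        r_ <- as.numeric(Az %*% zz) - bz
        sum(w * zz^3) + sum(lambda * r_) + 0.5 * mu * sum(r_^2)
      }
      gr <- function(zz) {
        r_ <- as.numeric(Az %*% zz) - bz
        3 * w * zz^2 + as.numeric(tAz %*% (lambda + mu * r_))
      }
      opt <- stats::optim(z, fn, gr, method = "L-BFGS-B", lower = 0, upper = 1,
                          control = list(maxit = control$inner_maxit,
                                         factr = 1e4))
      z <- opt$par
      r_ <- as.numeric(Az %*% z) - bz
      rmax <- max(abs(r_))
      if (rmax <= control$constraint_tol) { feas_red <- TRUE; break }
      lambda <- lambda + mu * r_
      if (rmax > 0.25 * res_prev) mu <- min(mu * control$mu_factor, 1e14)
      res_prev <- rmax
    }
    # polish: minimum-norm correction on the inactive set drives the equality
    # residual to machine precision without moving the active bounds
    for (pol in 1:3) {
      free <- z > 1e-9 & z < 1 - 1e-9
      r_ <- as.numeric(Az %*% z) - bz
      if (max(abs(r_)) < 1e-12 || !any(free)) break
      dz <- tryCatch(qr.coef(qr(Az[, free, drop = FALSE]), -r_),
                     error = function(e) NULL)
      if (is.null(dz)) break
      dz[is.na(dz)] <- 0
      znew <- z
      znew[free] <- pmin(1, pmax(0, z[free] + dz))
      if (max(abs(as.numeric(Az %*% znew) - bz)) < max(abs(r_))) z <- znew else break
    }
    r_ <- as.numeric(Az %*% z) - bz
    if (max(abs(r_)) <= control$constraint_tol) feas_red <- TRUE
  }

  xB <- z * ub
  x <- numeric(ncol(A))
  x[nB] <- xB
  if (length(nR)) {
    rhs <- b - as.numeric(AB %*% xB)
    xR <- qr.coef(qa, rhs)
    xR[is.na(xR)] <- 0
    x[nR] <- xR
  }
  resid_full <- as.numeric(A %*% x) - b
  # residual is judged against the working force scale: right-hand side
  # magnitude or a milli-fraction of the force bounds, whichever is larger
  scale <- max(1, max(abs(b)), 1e-3 * max(ub))
  residual <- max(abs(resid_full))
  feasible <- feas_red && residual <= 1e3 * control$constraint_tol * scale
  J <- sum((xB[cost_cols] / ub[cost_cols])^3)
  names(x) <- sys$cols$name

  reactions <- list()
  if (!is.null(sys$reaction_groups)) {
    for (g in sys$reaction_groups) {
      reactions[[g]] <- unname(x[paste0(g, c("x", "y", "z"))])
    }
  }
  structure(list(x = x, J = J, feasible = feasible, residual = residual,
                 iterations = outer_it,
                 forces = setNames(xB, sys$cols$name[nB]),
                 reactions = reactions),
            class = "fb_solution")
}

#' @export
print.fb_solution <- function(x, ...) {
  cat(sprintf("Frame solution: J = %.6g, %s (residual %.2e, %d outer iterations)\n",
              x$J, if (x$feasible) "feasible" else "INFEASIBLE",
              x$residual, x$iterations))
  invisible(x)
}
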