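# Constrained minimisation of the cubic load-sharing cost.

bounded_sys <- function(A, b, ub) {
  n <- ncol(A)
  structure(list(A = A, b = b, lower = rep(0, n), upper = ub,
                 cols = data.frame(type = rep("muscle", n),
                                   name = paste0("u", seq_len(n)),
                                   stringsAsFactors = FALSE),
                 cost = rep(TRUE, n), case = NA_integer_,
                 reaction_groups = NULL, rows = NULL,
                 counts = c(equations = nrow(A), unknowns = n)),
            class = "fb_system")
}

test_that("a fully determined single-muscle system is solved exactly", {
  # one equation: 0.05 m arm, 10 N m required, Fmax 1000 N -> F = 200 N
  sys <- bounded_sys(matrix(0.05, 1, 1), 10, 1000)
  sol <- solve_frame(sys)
  expect_true(sol$feasible)
  expect_equal(unname(sol$forces[1]), 200, tolerance = 1e-6)
  expect_equal(sol$J, (200 / 1000)^3, tolerance = 1e-9)
  expect_equal(sol$J, 0.008, tolerance = 1e-9)
})

test_that("identical parallel muscles share the load equally (convexity)", {
  sys <- bounded_sys(matrix(c(1, 1), 1, 2), 800, c(1000, 1000))
  sol <- solve_frame(sys)
  expect_true(sol$feasible)
  expect_equal(unname(sol$forces), c(400, 400), tolerance = 1e-4)
})

test_that("solutions match an exhaustive grid search on small systems", {
  for (seed in c(2, 7, 13)) {
    fs <- make_feasible_system(seed, n_eq = 3, n_unknowns = 6)
    sol <- solve_frame(fs$system)
    expect_true(sol$feasible)

    # oracle: grid over the 3-dimensional affine feasible set
    A <- fs$system$A; ub <- fs$system$upper
    Z <- null_basis(A)
    expect_equal(ncol(Z), 3)
    gr <- seq(-max(ub), max(ub), length.out = 41)
    best <- Inf; best_t <- c(0, 0, 0)
    for (t1 in gr) for (t2 in gr) for (t3 in gr) {
      x <- fs$witness + as.numeric(Z %*% c(t1, t2, t3))
      if (all(x >= 0) && all(x <= ub)) {
        v <- sum((x / ub)^3)
        if (v < best) { best <- v; best_t <- c(t1, t2, t3) }
      }
    }
    # refine around the coarse winner with a local solve on the null space
    obj <- function(t) {
      x <- fs$witness + as.numeric(Z %*% t)
      if (any(x < 0) || any(x > ub)) return(1e6)
      sum((x / ub)^3)
    }
    oracle <- best
    for (st in list(best_t, c(0, 0, 0))) {
      o <- stats::optim(st, obj, control = list(maxit = 10000, reltol = 1e-14))
      oracle <- min(oracle, o$value)
    }
    expect_equal(sol$J, oracle, tolerance = 1e-3)
  }
})

test_that("a constructed interior witness bounds the optimum from above", {
  fs <- make_feasible_system(4, n_eq = 3, n_unknowns = 8)
  wit <- fs$witness
  expect_lt(max(abs(fs$system$A %*% wit - fs$system$b)), 1e-12)
  J_wit <- sum((wit / fs$system$upper)^3)
  sol <- solve_frame(fs$system)
  expect_true(sol$feasible)
  expect_lte(sol$J, J_wit + 1e-9)
  expect_lt(sol$residual, 1e-5)
})

test_that("pinching the bounds onto the witness forces that exact solution", {
  fs <- make_feasible_system(5, n_eq = 3, n_unknowns = 6)
  sys <- fs$system
  sys$upper <- fs$witness * (1 + 1e-9)
  sol <- solve_frame(sys)
  expect_true(sol$feasible)
  expect_equal(unname(sol$forces), unname(fs$witness), tolerance = 1e-5)
})

test_that("warm starts accelerate but do not change the converged cost", {
  fs <- make_feasible_system(6, n_eq = 4, n_unknowns = 9)
  cold <- solve_frame(fs$system)
  warm <- solve_frame(fs$system, warm = cold$x * (1 + 0.05))
  expect_true(warm$feasible)
  expect_equal(warm$J, cold$J, tolerance = 1e-6)
})

test_that("solutions are invariant under a change of length units", {
  # scaling all moment rows (mm instead of m) must not move the solution
  fs <- make_feasible_system(8, n_eq = 3, n_unknowns = 6)
  sol <- solve_frame(fs$system)
  sys_mm <- fs$system
  sys_mm$A <- sys_mm$A * 1000
  sys_mm$b <- sys_mm$b * 1000
  sol_mm <- solve_frame(sys_mm)
  expect_equal(sol_mm$J, sol$J, tolerance = 1e-6)
  expect_equal(unname(sol_mm$forces), unname(sol$forces), tolerance = 1e-3)
})

test_that("infeasible systems are flagged, not fabricated", {
  # two contradictory equations on one bounded variable
  sys <- bounded_sys(matrix(c(1, 1), 2, 1), c(10, 20), 100)
  sol <- solve_frame(sys)
  expect_false(sol$feasible)
  expect_gt(sol$residual, 1)
  # demanding more than the bound allows
  sys2 <- bounded_sys(matrix(1, 1, 1), 500, 100)
  sol2 <- solve_frame(sys2)
  expect_false(sol2$feasible)
})

test_that("free reaction columns are recovered by least squares", {
  # one muscle + one free reaction pair: the reaction absorbs the force row
  A <- rbind(c(0.05, 0), c(1, -1))
  sys <- structure(list(
    A = A, b = c(10, 50), lower = c(0, -Inf), upper = c(1000, Inf),
    cols = data.frame(type = c("muscle", "reaction"), name = c("m1", "R1x"),
                      stringsAsFactors = FALSE),
    cost = c(TRUE, FALSE), case = NA_integer_,
    reaction_groups = NULL, rows = NULL,
    counts = c(equations = 2, unknowns = 2)), class = "fb_system")
  sol <- solve_frame(sys)
  expect_true(sol$feasible)
  expect_equal(unname(sol$forces["m1"]), 200, tolerance = 1e-5)
  expect_equal(unname(sol$x["R1x"]), 150, tolerance = 1e-4)
})
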