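# Inertial parameters, inter-segmental load recursion, equation assembly.

test_that("inertial parameters scale like mass and length squared", {
  L <- c(foot = 0.18, shank = 0.43, thigh = 0.43)
  p1 <- inertial_params(80, L)
  p2 <- inertial_params(160, L)
  for (seg in c("foot", "shank", "thigh", "pelvis")) {
    expect_equal(p2[[seg]]$m, 2 * p1[[seg]]$m)
  }
  expect_equal(p1$patella$m, 0)
  expect_lte(p1$foot$m + p1$shank$m + p1$thigh$m + p1$pelvis$m, 80 + 1e-9)
  p3 <- inertial_params(80, L * 2)
  expect_equal(p3$shank$Y_local, 4 * p1$shank$Y_local, tolerance = 1e-12)
  # tensors are positive semi-definite
  expect_true(all(eigen(p1$thigh$Y_local)$values >= 0))
  expect_error(inertial_params(-1, L), "positive")
  expect_error(inertial_params(80, c(foot = 0.18)), "shank")
})

test_that("static standing reproduces textbook statics in the load recursion", {
  ctx <- fx_context(fx_static(0))
  tr <- ctx$trial
  i <- 3
  W <- sum(vapply(c("foot", "shank", "thigh", "pelvis"),
                  function(s) ctx$states[[s]]$m, numeric(1))) * 9.81
  expect_equal(tr$ground$force[i, 2], W, tolerance = 1e-6)
  # -S3 = sum(m_k (a - g)) - GRF over foot+shank+thigh: hip carries the rest
  m123 <- sum(vapply(c("foot", "shank", "thigh"), function(s) ctx$states[[s]]$m,
                     numeric(1)))
  S3 <- ctx$loads$S$S3[i, ]
  expect_equal(S3[2], W - m123 * 9.81, tolerance = 1e-6)
  expect_equal(S3[c(1, 3)], c(0, 0), tolerance = 1e-6)
})

test_that("zero gravity with zero ground reaction yields vanishing loads", {
  ctx <- fx_context(fx_static(0))
  n <- ctx$trial$n
  ground0 <- list(force = matrix(0, n, 3), cop = ctx$trial$ground$cop,
                  free_moment = matrix(0, n, 3))
  l0 <- intersegmental_loads(ctx$states, ground0, gravity = c(0, 0, 0))
  for (k in 1:3) {
    expect_equal(max(abs(l0$S[[k + 1]][3, ])), 0, tolerance = 1e-9)
    expect_equal(max(abs(l0$W[[k + 1]][3, ])), 0, tolerance = 1e-9)
  }
})

test_that("flight-phase loads are purely inertial (weightless limb)", {
  tr <- fx_jump()
  ctx <- fx_context(tr)
  toff <- attr(tr, "takeoff_time")
  flight <- which(tr$time > toff + 0.03 & tr$time < max(tr$time) - 0.03)
  # in free fall a = g, so S^k = 0 at every chain level
  for (k in 1:3) {
    expect_lt(max(abs(ctx$loads$S[[k + 1]][flight, ])), 1e-6)
  }
})

test_that("assembled systems have the published dimensions for the full layout", {
  an_full <- make_full_layout_anatomy(fx_spec())
  expect_length(an_full$muscles, 163)
  expect_length(an_full$ligaments, 14)
  ctx <- fx_context(fx_static(20), an_full)
  fr <- fx_frame(ctx, 2, case = NULL)
  paths <- fr$paths
  dims <- list()
  for (cs in 1:4) {
    sys <- assemble_system(cs, paths, an_full, ctx$states, ctx$loads,
                           ctx$trial$ground, 2, fr$pq, muscle_force_bounds(an_full))
    dims[[cs]] <- dim(sys$A)
  }
  expect_equal(dims[[1]], c(18L, 186L))
  expect_equal(dims[[2]], c(22L, 190L))
  expect_equal(dims[[3]], c(22L, 190L))
  expect_equal(dims[[4]], c(22L, 193L))
})

test_that("toy systems have consistent block structure and bounds", {
  ctx <- fx_context()
  fr <- fx_frame(ctx, 100, case = 4)
  sys <- fr$sys
  M <- length(ctx$anatomy$muscles); N <- length(ctx$anatomy$ligaments)
  expect_equal(ncol(sys$A), M + 1 + N + 15)
  expect_equal(nrow(sys$A), 22)
  expect_true(all(sys$lower[sys$cols$type != "reaction"] == 0))
  expect_true(all(is.infinite(sys$upper[sys$cols$type == "reaction"])))
  expect_true(all(is.finite(sys$upper[sys$cols$type == "muscle"])))
  # cost covers muscles and ligaments only
  expect_equal(sum(sys$cost), M + N)
  # the rho row ties the patellar tendon to the quadriceps tension
  rho_row <- sys$A[22, ]
  expect_equal(unname(rho_row[M + 1]), -1)
  qn <- vapply(Filter(function(m) m$group == "quadriceps", ctx$anatomy$muscles),
               function(m) m$name, character(1))
  expect_true(all(rho_row[match(qn, sys$cols$name)] > 0))
  expect_true(all(rho_row[setdiff(seq_len(M), match(qn, sys$cols$name))] == 0))
})

test_that("collapsing the case-4 compartments satisfies the case-3 force rows", {
  ctx <- fx_context()
  i <- 60
  fr4 <- fx_frame(ctx, i, case = 4)
  fr3 <- fx_frame(ctx, i, case = 3)
  sol4 <- solve_frame(fr4$sys)
  expect_true(sol4$feasible)
  x3 <- rep(0, ncol(fr3$sys$A))
  names(x3) <- fr3$sys$cols$name
  shared <- intersect(names(sol4$x), names(x3))
  x3[shared] <- sol4$x[shared]
  collapsed <- sol4$reactions$R2_med + sol4$reactions$R2_lat
  x3[paste0("R2", c("x", "y", "z"))] <- collapsed
  resid3 <- as.numeric(fr3$sys$A %*% x3) - fr3$sys$b
  expect_lt(max(abs(resid3[1:9])), 1e-6)  # force rows hold exactly
})

test_that("the reaction-only system reproduces classical inverse dynamics", {
  ctx <- fx_context()
  i <- 50
  fr3 <- fx_frame(ctx, i, case = 3)
  sys <- fr3$sys
  rcols <- which(sys$cols$type == "reaction")
  # with all muscle/ligament columns at zero, force rows give the reactions
  Ar <- sys$A[1:9, rcols]
  xr <- solve(Ar[, 1:9], sys$b[1:9])  # R1, R2, R3 blocks in order
  # R^k then equals the inter-segmental resultants S^k of the recursion
  expect_equal(xr[1:3], ctx$loads$S$S1[i, ], tolerance = 1e-9)
  expect_equal(xr[4:6], ctx$loads$S$S2[i, ], tolerance = 1e-9)
  expect_equal(xr[7:9], ctx$loads$S$S3[i, ], tolerance = 1e-9)
})

test_that("feasible solutions reproduce the Newton-Euler right-hand side", {
  ctx <- fx_context()
  fr <- fx_frame(ctx, 40, case = 2)
  sol <- solve_frame(fr$sys)
  expect_true(sol$feasible)
  expect_lt(max(abs(fr$sys$A %*% sol$x - fr$sys$b)), 1e-4)
  # summing the three segment force rows: internal reactions cancel, leaving
  # muscle/patellar/ligament actions against the whole-chain resultant
  rows <- 1:9
  lhs <- as.numeric(fr$sys$A[rows, ] %*% sol$x)
  expect_equal(lhs, fr$sys$b[rows], tolerance = 1e-4)
})

test_that("frame systems serialize to a readable text dump", {
  ctx <- fx_context()
  fr <- fx_frame(ctx, 10, case = 1)
  f <- withr::local_tempfile(fileext = ".txt")
  write_system(fr$sys, f)
  lines <- readLines(f)
  expect_match(lines[1], "case 1")
  expect_true(any(startsWith(lines, "A ")))
  expect_true(any(startsWith(lines, "bound ")))
})

test_that("the compression-only switch restricts the case-4 compartments", {
  an <- fx_anatomy()
  st <- fx_static(30)
  cfg <- fb_config(compression_only = TRUE)
  fit <- freebody(st, an, case = 4, config = cfg, frames = 2:3)
  expect_equal(fit$solved_fraction, 100)
  # axial (tibial y) components of both compartments are compressive
  expect_true(all(fit$reactions$R2_med[, 2] >= -1e-6))
  expect_true(all(fit$reactions$R2_lat[, 2] >= -1e-6))
  # and the total contact magnitude stays close to the unconstrained case
  fit0 <- freebody(st, an, case = 4, frames = 2:3)
  expect_equal(fit$contact_forces$total_tfj, fit0$contact_forces$total_tfj,
               tolerance = 0.2)
})
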