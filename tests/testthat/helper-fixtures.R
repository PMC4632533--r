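# Shared fixtures, built once per test run. Everything is generated in code
# (synthetic study conditions, seed fixed through synth_spec defaults).

.fx <- new.env(parent = emptyenv())

fx_spec <- function() synth_spec()

fx_anatomy <- function() {
  if (is.null(.fx$anatomy)) .fx$anatomy <- make_toy_anatomy(fx_spec())
  .fx$anatomy
}

fx_jump <- function() {
  if (is.null(.fx$jump)) .fx$jump <- make_jump_trial(fx_spec())
  .fx$jump
}

fx_static <- function(theta_deg = 30) {
  key <- paste0("static", theta_deg)
  if (is.null(.fx[[key]])) .fx[[key]] <- make_static_trial(fx_spec(), theta_deg = theta_deg)
  .fx[[key]]
}

fx_fit <- function(case) {
  key <- paste0("fit", case)
  if (is.null(.fx[[key]])) .fx[[key]] <- freebody(fx_jump(), fx_anatomy(), case = case)
  .fx[[key]]
}

# Per-frame modelling context assembled through the public API: poses, states,
# loads, element paths, patellar state and (optionally) the frame system.
fx_context <- function(trial = fx_jump(), anatomy = fx_anatomy()) {
  key <- paste0("ctx_", length(anatomy$muscles), "_", trial$n, "_",
                digest_cheap(sum(trial$ground$force) + sum(trial$markers[[1]])))
  if (!is.null(.fx[[key]])) return(.fx[[key]])
  cal <- attr(trial, "calibration")
  sub <- attr(trial, "subject")
  frames <- build_segment_frames(cal)
  poses <- fit_pose_series(trial, frames)
  inertia <- inertial_params(sub$mass, sub$segment_lengths, pelvis_com = sub$pelvis_com)
  states <- segment_states(poses, inertia, trial$rate)
  loads <- intersegmental_loads(states, trial$ground)
  ctx <- list(trial = trial, anatomy = anatomy, frames = frames, poses = poses,
              inertia = inertia, states = states, loads = loads,
              q_s0 = matrix_to_quat(frames$shank$R0),
              q_t0 = matrix_to_quat(frames$thigh$R0))
  .fx[[key]] <- ctx
  ctx
}

digest_cheap <- function(x) sprintf("%.6f", sum(as.numeric(x)))

# Element paths + patellar state + frame system at one frame of a context.
fx_frame <- function(ctx, i, case = NULL) {
  an <- ctx$anatomy
  pose_at <- function(seg) list(q = ctx$poses[[seg]]$q[i, ], o = ctx$poses[[seg]]$o[i, ])
  tib <- pose_at("shank"); fem <- pose_at("thigh")
  th <- knee_flexion_angle(tib$q, fem$q, ctx$q_s0, ctx$q_t0)
  if (th < 0 && th > -2) th <- 0
  pat <- suppressWarnings(patella_pose(th, tib, fem, an))
  pf <- list(foot = pose_at("foot"), shank = tib, thigh = fem,
             pelvis = pose_at("pelvis"), patella = pat)
  cyls <- list()
  for (cy in an$cylinders) cyls[[cy$id]] <- posed_cylinder(cy, pf[[cy$segment]])
  paths <- list()
  for (m in an$muscles) paths[[m$name]] <- element_path(m, pf, cyls)
  for (l in an$ligaments) paths[[l$name]] <- element_path(l, pf, cyls)
  pt_el <- list(name = "patellar_tendon",
                attachments = list(
                  list(segment = "patella", point = an$patellar_tendon$patella_point),
                  list(segment = "shank", point = an$landmarks$tibial_tuberosity$point)),
                via_points = list(), cylinder = NA_character_)
  paths$patellar_tendon <- element_path(pt_el, pf, cyls)
  pq <- pq_state(an, paths, pat, tib, fem)
  out <- list(theta = th, poses_frame = pf, paths = paths, pq = pq, i = i)
  if (!is.null(case)) {
    out$sys <- assemble_system(case, paths, an, ctx$states, ctx$loads,
                               ctx$trial$ground, i, pq, muscle_force_bounds(an))
  }
  out
}

# Orthonormal basis of the null space of a matrix (for grid oracles).
null_basis <- function(A) {
  s <- svd(A, nv = ncol(A))
  r <- sum(s$d > 1e-10 * s$d[1])
  if (r == ncol(A)) matrix(0, ncol(A), 0) else s$v[, (r + 1):ncol(A), drop = FALSE]
}

deriv_central_vec <- function(v, rate) {
  as.numeric(segbody:::deriv_central(matrix(v, ncol = 1), rate))
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  quat_to_matrix(q / sqrt(sum(q^2)))
}

cross3 <- segbody:::cross3

# Discretised shortest-path oracle for single-cylinder wrapping: the path in
# the cross-sectional plane is searched over a dense grid of entry/exit
# contact points on the circle (tangency is not assumed; chords that would cut
# the circle are excluded), and the axial coordinate rides along at constant
# slope, which is optimal by the Minkowski inequality.
wrap_oracle <- function(p1, p2, cyl, n_grid = 721) {
  zc <- cyl$axis_direction / sqrt(sum(cyl$axis_direction^2))
  ref <- if (abs(zc[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  xc <- cross3(ref, zc); xc <- xc / sqrt(sum(xc^2))
  B <- cbind(xc, cross3(zc, xc), zc)
  q1 <- as.numeric(t(B) %*% (p1 - cyl$axis_point))
  q2 <- as.numeric(t(B) %*% (p2 - cyl$axis_point))
  r1 <- q1[1:2]; r2 <- q2[1:2]; R <- cyl$radius
  dz <- q2[3] - q1[3]
  v <- r2 - r1
  tpar <- max(0, min(1, -sum(r1 * v) / sum(v^2)))
  if (sqrt(sum((r1 + tpar * v)^2)) >= R - 1e-12) return(sqrt(sum((p2 - p1)^2)))
  th <- seq(0, 2 * pi, length.out = n_grid)[-n_grid]
  Tm <- cbind(R * cos(th), R * sin(th))
  seg_clear <- function(a) {
    vv <- sweep(Tm, 2, a)
    tt <- pmin(1, pmax(0, -(a[1] * vv[, 1] + a[2] * vv[, 2]) / rowSums(vv^2)))
    px <- a[1] + tt * vv[, 1]; py <- a[2] + tt * vv[, 2]
    sqrt(px^2 + py^2) >= R - 1e-9
  }
  d1 <- sqrt(rowSums(sweep(Tm, 2, r1)^2))
  d2 <- sqrt(rowSums(sweep(Tm, 2, r2)^2))
  ok1 <- seg_clear(r1); ok2 <- seg_clear(r2)
  side <- cyl$wrap_side
  best <- Inf
  d2ok <- ifelse(ok2, d2, Inf)
  for (i in which(ok1)) {
    darc <- (side * (th - th[i])) %% (2 * pi)
    best <- min(best, d1[i] + min(R * darc + d2ok))
  }
  sqrt(best^2 + dz^2)
}
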