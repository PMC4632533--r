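# Frame construction, absolute-orientation fitting, differentiation, filtering.

test_that("calibration frames follow the stated axis conventions", {
  cal <- make_calibration_trial(fx_spec())
  fr <- build_segment_frames(cal)

  # pelvis origin is the mid-point of the ASIS markers
  mid_asis <- (colMeans(cal$markers$RASIS) + colMeans(cal$markers$LASIS)) / 2
  expect_equal(fr$pelvis$origin0, mid_asis, tolerance = 1e-12)

  # shank: y runs from the ankle (distal) to the knee (proximal)
  ankle <- (colMeans(cal$markers$FAM) + colMeans(cal$markers$TAM)) / 2
  knee <- (colMeans(cal$markers$FLE) + colMeans(cal$markers$FME)) / 2
  expect_equal(fr$shank$R0[, 2], (knee - ankle) / sqrt(sum((knee - ankle)^2)),
               tolerance = 1e-12)
  expect_equal(fr$shank$origin0, knee, tolerance = 1e-12)

  # all frames orthonormal, right-handed
  for (seg in c("foot", "shank", "thigh", "pelvis")) {
    R <- fr[[seg]]$R0
    expect_equal(t(R) %*% R, diag(3), tolerance = 1e-12)
    expect_equal(det(R), 1, tolerance = 1e-12)
  }
})

test_that("rigidly rotating the calibration rotates the frames and keeps local coordinates", {
  set.seed(11)
  cal <- make_calibration_trial(fx_spec())
  R <- random_rotation()
  cal2 <- cal
  cal2$markers <- lapply(cal$markers, function(m) t(R %*% t(m)))
  fr <- build_segment_frames(cal)
  fr2 <- build_segment_frames(cal2)
  for (seg in c("foot", "shank", "thigh", "pelvis")) {
    expect_equal(fr2[[seg]]$R0, R %*% fr[[seg]]$R0, tolerance = 1e-9)
    expect_equal(fr2[[seg]]$local, fr[[seg]]$local, tolerance = 1e-9)
  }
})

test_that("degenerate (collinear) landmark geometry is rejected", {
  cal <- make_calibration_trial(fx_spec())
  bad <- cal
  # malleoli coincide: the intermediate z axis vanishes
  bad$markers$FAM <- bad$markers$TAM
  expect_error(build_segment_frames(bad), "degenerate")
})

test_that("the absolute-orientation fit recovers exact rigid transforms", {
  set.seed(21)
  local <- matrix(stats::rnorm(15), 5, 3)
  f0 <- fit_pose(local, local)
  expect_equal(f0$R, diag(3), tolerance = 1e-10)
  expect_equal(f0$origin, c(0, 0, 0), tolerance = 1e-10)
  expect_lt(f0$rms, 1e-12)

  for (rep in 1:5) {
    R <- random_rotation()
    t0 <- stats::rnorm(3)
    obs <- t(R %*% t(local)) + matrix(t0, 5, 3, byrow = TRUE)
    f <- fit_pose(local, obs)
    expect_equal(f$R, R, tolerance = 1e-10)
    expect_equal(f$origin, t0, tolerance = 1e-10)
    expect_lt(f$rms, 1e-10)
  }

  expect_error(fit_pose(local[1:2, ], local[1:2, ]), "3 markers")
  line <- cbind(1:4, 2 * (1:4), -(1:4))
  expect_error(fit_pose(line, line), "collinear")
})

test_that("fit residuals under isotropic noise match the degrees-of-freedom ratio", {
  # 4 markers, 12 coordinates, 6 rigid dof: expected RMS = sigma * sqrt(1/2)
  set.seed(31)
  sigma <- 1e-3
  local <- rbind(c(0.1, 0, 0), c(0, 0.1, 0.02), c(-0.1, 0.05, -0.03), c(0.02, -0.08, 0.06))
  rms <- replicate(800, {
    R <- random_rotation()
    obs <- t(R %*% t(local)) + matrix(stats::rnorm(12, sd = sigma), 4, 3)
    fit_pose(local, obs)$rms
  })
  expect_equal(sqrt(mean(rms^2)), sigma * sqrt(1 - 6 / 12), tolerance = 0.08)
  # rotation error vanishes as the noise does
  R <- random_rotation()
  obs <- t(R %*% t(local)) + matrix(stats::rnorm(12, sd = 1e-9), 4, 3)
  expect_equal(fit_pose(local, obs)$R, R, tolerance = 1e-6)
})

test_that("pose fitting is equivariant under pre-rotation of the observations", {
  set.seed(41)
  local <- matrix(stats::rnorm(15, sd = 0.1), 5, 3)
  R1 <- random_rotation(); t1 <- stats::rnorm(3)
  obs <- t(R1 %*% t(local)) + matrix(t1, 5, 3, byrow = TRUE)
  Rpre <- random_rotation()
  obs2 <- t(Rpre %*% t(obs))
  f1 <- fit_pose(local, obs)
  f2 <- fit_pose(local, obs2)
  expect_equal(f2$R, Rpre %*% f1$R, tolerance = 1e-9)
  expect_equal(f2$origin, as.numeric(Rpre %*% f1$origin), tolerance = 1e-9)
})

test_that("quaternion differentiation reproduces analytic kinematics", {
  rate <- 2000
  n <- 200
  tt <- (0:(n - 1)) / rate

  # constant pose: everything zero
  pose_c <- list(q = matrix(rep(c(1, 0, 0, 0), n), n, 4, byrow = TRUE),
                 o = matrix(rep(c(0.1, 0.2, 0.3), n), n, 3, byrow = TRUE))
  d <- differentiate_poses(pose_c, rate)
  expect_equal(max(abs(d$omega)), 0, tolerance = 1e-12)
  expect_equal(max(abs(d$alpha)), 0, tolerance = 1e-12)
  expect_equal(max(abs(accel_central(pose_c$o, rate))), 0, tolerance = 1e-9)

  # uniform rotation about z at omega rad/s
  w <- 3.2
  Q <- t(vapply(tt, function(t) quat_from_axis_angle(c(0, 0, 1), w * t), numeric(4)))
  pose_r <- list(q = quat_hemispherize(Q), o = matrix(0, n, 3))
  dr <- differentiate_poses(pose_r, rate)
  interior <- 3:(n - 2)
  expect_lt(max(abs(dr$omega[interior, 3] - w)), 1e-6)
  expect_lt(max(abs(dr$omega[interior, 1:2])), 1e-6)
  expect_lt(max(abs(dr$alpha[interior, ])), 1e-3)

  # pure translation x(t) = a t^2 / 2
  a <- 4.9
  pose_t <- list(q = matrix(rep(c(1, 0, 0, 0), n), n, 4, byrow = TRUE),
                 o = cbind(a * tt^2 / 2, 0 * tt, 0 * tt))
  acc <- accel_central(pose_t$o, rate)
  expect_equal(acc[interior, 1], rep(a, length(interior)), tolerance = 1e-6)

  # sign flips must be rejected
  Qbad <- Q; Qbad[10, ] <- -Qbad[10, ]
  expect_error(differentiate_poses(list(q = Qbad, o = matrix(0, n, 3)), rate),
               "hemispherize")
})

test_that("free-fall segments satisfy a = g through the marker pipeline", {
  tr <- fx_jump()
  ctx <- fx_context(tr)
  toff <- attr(tr, "takeoff_time")
  flight <- which(tr$time > toff + 0.03 & tr$time < max(tr$time) - 0.03)
  for (seg in c("foot", "shank", "thigh")) {
    acc <- ctx$states[[seg]]$a[flight, , drop = FALSE]
    g <- matrix(c(0, -9.81, 0), length(flight), 3, byrow = TRUE)
    expect_equal(acc, g, tolerance = 1e-6)
  }
})

test_that("the zero-phase low-pass behaves like a low-pass", {
  rate <- 1000
  tt <- (0:4095) / rate
  # DC unchanged
  expect_equal(lowpass(rep(2.5, 512), 10, rate), rep(2.5, 512), tolerance = 1e-6)

  x <- sin(2 * pi * 1 * tt) + sin(2 * pi * 50 * tt)
  y <- lowpass(x, 10, rate)
  amp <- function(v, f) {
    sp <- abs(stats::fft(v))[1:(length(v) / 2)]
    sp[round(f * length(v) / rate) + 1]
  }
  expect_gt(amp(y, 1) / amp(x, 1), 0.95)                       # passband kept
  expect_lt(amp(y, 50) / amp(x, 50), 10^(-40 / 20))            # > 40 dB down

  set.seed(5)
  wn <- stats::rnorm(2048)
  expect_lt(stats::var(lowpass(wn, 20, rate)), stats::var(wn)) # variance shrinks

  expect_error(lowpass(x, 600, rate), "Nyquist")
})

test_that("trial CSV dialect and TRC round-trip through the readers", {
  tr <- make_static_trial(fx_spec(), theta_deg = 10, duration = 0.05)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trial_csv(tr, f)
  tr2 <- read_trial_csv(f)
  expect_equal(tr2$rate, tr$rate)
  expect_equal(tr2$markers$FCC, unname(tr$markers$FCC), tolerance = 1e-12)
  expect_equal(tr2$ground$force, unname(tr$ground$force), tolerance = 1e-12)

  # left-side mirroring flips z of positions and forces
  tr3 <- read_trial_csv(f, side = "left")
  expect_equal(tr3$markers$FCC[, 3], -tr2$markers$FCC[, 3])
  expect_equal(tr3$ground$force[, 1:2], tr2$ground$force[, 1:2])

  # minimal TRC written by hand
  trc <- withr::local_tempfile(fileext = ".trc")
  m <- tr$markers$FCC
  lines <- c(
    "PathFileType\t4\t(X/Y/Z)\ttest.trc",
    "DataRate\tCameraRate\tNumFrames\tNumMarkers\tUnits\tOrigDataRate\tOrigDataStartFrame\tOrigNumFrames",
    sprintf("%g\t%g\t%d\t1\tmm\t%g\t1\t%d", tr$rate, tr$rate, tr$n, tr$rate, tr$n),
    "Frame#\tTime\tFCC\t\t",
    "\t\tX1\tY1\tZ1",
    sprintf("%d\t%.6f\t%.4f\t%.4f\t%.4f", seq_len(tr$n), tr$time,
            m[, 1] * 1000, m[, 2] * 1000, m[, 3] * 1000)
  )
  writeLines(lines, trc)
  tr4 <- read_trc(trc)
  expect_equal(tr4$rate, tr$rate)
  expect_equal(tr4$markers$FCC, unname(m), tolerance = 1e-6)
})
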