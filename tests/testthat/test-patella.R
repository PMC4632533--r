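# Patellar posture regression, patellar pose, and the P/Q tendon force ratio.

test_that("regression polynomials return the published intercepts at zero flexion", {
  ang <- eval_patella_polynomials(0)
  expect_equal(unname(ang["pt_sagittal"]), 20.4)
  expect_equal(unname(ang["pt_coronal"]), 10.9)
  expect_equal(unname(ang["patellar_flexion"]), 5.59)
  expect_equal(unname(ang["patellar_tilt"]), 1.63)
  expect_equal(unname(ang["patellar_rotation"]), 1.43)
})

test_that("polynomial evaluation agrees with an independent Horner scheme", {
  coefs <- patella_coefficients()
  horner <- function(b, x) ((((b[5] * x + b[4]) * x + b[3]) * x + b[2]) * x + b[1])
  for (th in c(10, 45, 100)) {
    ang <- suppressWarnings(eval_patella_polynomials(th))
    for (v in rownames(coefs)) {
      expect_equal(unname(ang[v]), horner(unname(coefs[v, ]), th), tolerance = 1e-12)
    }
  }
  # printed worked value: 20.4 - 0.260 * 100 = -5.6 degrees
  expect_equal(unname(suppressWarnings(eval_patella_polynomials(100))["pt_sagittal"]),
               -5.6, tolerance = 1e-12)
  expect_warning(eval_patella_polynomials(150), "outside")
  expect_warning(eval_patella_polynomials(-10), "outside")
})

test_that("the packaged coefficient file matches the built-in table", {
  f <- system.file("extdata", "patella_coefficients_v1.csv", package = "segbody")
  expect_equal(unname(patella_coefficients(f)), unname(patella_coefficients()))
})

test_that("patellar pose places the origin along the tendon from the tuberosity", {
  an <- fx_anatomy()
  idp <- list(q = c(1, 0, 0, 0), o = c(0, 0, 0))
  p0 <- patella_pose(0, idp, idp, an)
  tub <- an$landmarks$tibial_tuberosity$point
  dir <- patellar_tendon_direction(20.4, 10.9)
  expect_equal(p0$o, tub + an$patellar_tendon$length * dir, tolerance = 1e-12)

  # doubling the tendon length doubles the displacement, orientation unchanged
  an2 <- an; an2$patellar_tendon$length <- 2 * an$patellar_tendon$length
  p2 <- patella_pose(0, idp, idp, an2)
  expect_equal(p2$o - tub, 2 * (p0$o - tub), tolerance = 1e-12)
  expect_equal(p2$q, p0$q, tolerance = 1e-12)

  # common rotation of tibia and femur rotates the patellar pose identically
  set.seed(3)
  R <- random_rotation()
  rp <- list(q = matrix_to_quat(R), o = c(0, 0, 0))
  pr <- patella_pose(25, rp, rp, an)
  pi_ <- patella_pose(25, idp, idp, an)
  expect_equal(pr$o, as.numeric(R %*% pi_$o), tolerance = 1e-9)
  expect_equal(quat_to_matrix(pr$q), R %*% quat_to_matrix(pi_$q), tolerance = 1e-9)

  # with all orientation coefficients zeroed the patella keeps the femoral frame
  cz <- patella_coefficients()
  cz[c("patellar_flexion", "patellar_tilt", "patellar_rotation"), ] <- 0
  pz <- patella_pose(30, idp, rp, an, coefficients = cz)
  expect_equal(quat_to_matrix(pz$q), R, tolerance = 1e-9)
})

test_that("P/Q follows the lever law on constructed sagittal geometry", {
  base_geom <- function(arm_q = 0.02, arm_p = 0.02) {
    list(quad_point = c(arm_q, 0.05, 0), quad_dir = c(0, 1, 0),
         pt_point = c(arm_p, -0.05, 0), pt_dir = c(0, -1, 0),
         pivot = c(0, 0, 0), R_femur = diag(3), femur_origin = c(0, 0, 0))
  }
  # symmetric geometry: equal arms, opposite pulls -> P/Q = 1
  expect_equal(pq_ratio(base_geom())$ratio, 1, tolerance = 1e-12)
  # doubling the quadriceps arm doubles the ratio
  expect_equal(pq_ratio(base_geom(arm_q = 0.04))$ratio, 2, tolerance = 1e-12)
  # scale invariance: scaling all geometry leaves the ratio unchanged
  g <- base_geom(arm_q = 0.031, arm_p = 0.017)
  gs <- g
  for (f in c("quad_point", "pt_point", "pivot")) gs[[f]] <- 3.7 * gs[[f]]
  expect_equal(pq_ratio(gs)$ratio, pq_ratio(g)$ratio, tolerance = 1e-12)
  # degenerate: patellar tendon through the pivot
  g0 <- base_geom(arm_p = 0)
  expect_error(pq_ratio(g0), "degenerate")
})

test_that("P/Q decreases monotonically as the quadriceps arm shrinks with flexion", {
  # planar pulley: the quadriceps line rotates onto the pivot as theta grows,
  # its arm shrinking, while the patellar tendon arm is fixed
  ratio_at <- function(theta_deg) {
    a <- theta_deg * pi / 180
    g <- list(quad_point = c(0.03 * cos(a), 0.05, 0), quad_dir = c(0, 1, 0),
              pt_point = c(0.025, -0.05, 0), pt_dir = c(0, -1, 0),
              pivot = c(0, 0, 0), R_femur = diag(3), femur_origin = c(0, 0, 0))
    pq_ratio(g)$ratio
  }
  sweep <- vapply(seq(0, 80, by = 10), ratio_at, numeric(1))
  expect_true(all(diff(sweep) < 0))
})

test_that("the toy anatomy yields a smooth physiological P/Q profile in flexion", {
  ctx <- fx_context()
  tr <- ctx$trial
  idx <- which(tr$time > 0.2 & tr$time < 0.55)[seq(1, 60, by = 10)]
  th <- numeric(0); pq <- numeric(0)
  for (i in idx) {
    f <- fx_frame(ctx, i)
    th <- c(th, f$theta); pq <- c(pq, f$pq$ratio)
  }
  ord <- order(th)
  expect_true(all(pq > 0.5) && all(pq < 3))
  expect_true(all(diff(pq[ord]) < 0))  # decreasing with flexion
})

test_that("the effective patellar tendon bound scales with P/Q and the quadriceps bounds", {
  an <- fx_anatomy()
  fm <- muscle_force_bounds(an)
  qn <- c("vastus_medialis", "vastus_intermedius", "vastus_lateralis", "rectus_femoris")
  expect_equal(patellar_tendon_bound(1.5, fm, an), 1.5 * sum(fm[qn]))
  expect_equal(patellar_tendon_bound(0, fm, an), 0)
})

test_that("knee flexion is zero at calibration and recovers imposed angles", {
  q0s <- matrix_to_quat(random_rotation())
  q0t <- matrix_to_quat(random_rotation())
  expect_equal(knee_flexion_angle(q0s, q0t, q0s, q0t), 0, tolerance = 1e-9)
  for (th in c(12, 47, 83)) {
    qs <- matrix_to_quat(quat_to_matrix(q0t) %*%
                           matrix(c(cos(-th * pi / 180), -sin(-th * pi / 180), 0,
                                    sin(-th * pi / 180), cos(-th * pi / 180), 0,
                                    0, 0, 1), 3, byrow = TRUE) %*%
                           t(quat_to_matrix(q0t)) %*% quat_to_matrix(q0s))
    expect_equal(knee_flexion_angle(qs, q0t, q0s, q0t), th, tolerance = 1e-6)
  }
})
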