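# Element paths, cylinder wrapping, moment arms and action-reaction closure.

make_cyl <- function(axis_point = c(0, 0, 0), axis_direction = c(0, 0, 1),
                     radius = 0.03, wrap_side = 1) {
  list(axis_point = axis_point, axis_direction = axis_direction,
       radius = radius, wrap_side = wrap_side, segment = "thigh")
}

test_that("chords that miss the cylinder stay straight; wraps are shortest paths", {
  cyl <- make_cyl(radius = 0.03, wrap_side = 1)

  w0 <- cylinder_wrap(c(0.2, 0.1, 0), c(0.2, -0.1, 0.05), cyl)
  expect_false(w0$wrapped)
  expect_equal(w0$length, sqrt(0.2^2 + 0.05^2), tolerance = 1e-12)

  # chord through the cylinder: tangent-arc-tangent, against the brute-force oracle
  set.seed(9)
  for (rep in 1:4) {
    p1 <- c(0.15, 0.02 * stats::runif(1, -1, 1), 0.05 * stats::runif(1, -1, 1))
    p2 <- c(-0.18, 0.02 * stats::runif(1, -1, 1), 0.05 * stats::runif(1, -1, 1))
    w <- cylinder_wrap(p1, p2, cyl)
    expect_true(w$wrapped)
    expect_equal(w$length, wrap_oracle(p1, p2, cyl), tolerance = 1e-4)
    # wrapped length is never shorter than the chord
    expect_gte(w$length, sqrt(sum((p2 - p1)^2)) - 1e-12)
  }
})

test_that("diametrically opposed endpoints give the closed-form wrapped length", {
  r <- 0.03
  cyl <- make_cyl(radius = r, wrap_side = 1)
  d <- 0.2
  w <- cylinder_wrap(c(d, 0, 0), c(-d, 0, 0), cyl)
  expect_true(w$wrapped)
  tangent <- sqrt(d^2 - r^2)
  beta <- acos(r / d)          # tangent-point half-angle
  arc <- r * (pi - 2 * beta)   # wrapped angle between the tangent points
  expect_equal(w$length, 2 * tangent + arc, tolerance = 1e-9)
})

test_that("wrapping is symmetric under translation along the cylinder axis", {
  cyl <- make_cyl(radius = 0.025, wrap_side = -1)
  p1 <- c(0.12, 0.06, -0.02); p2 <- c(-0.1, 0.03, 0.04)
  w <- cylinder_wrap(p1, p2, cyl)
  s <- c(0, 0, 0.37)
  w2 <- cylinder_wrap(p1 + s, p2 + s, cyl)
  expect_equal(w2$length, w$length, tolerance = 1e-12)
  expect_equal(w2$points, w$points + matrix(s, nrow(w$points), 3, byrow = TRUE),
               tolerance = 1e-9)
})

test_that("grazing paths approach the straight length continuously", {
  r <- 0.03
  cyl <- make_cyl(radius = r, wrap_side = 1)
  # chord passing at distance r*(1 - eps) below tangency
  for (eps in c(1e-4, 1e-6)) {
    y <- r * (1 - eps)
    w <- cylinder_wrap(c(0.3, y, 0), c(-0.3, y, 0), cyl)
    expect_true(w$wrapped)
    expect_equal(w$length, 0.6, tolerance = 1e-4)
  }
  expect_error(cylinder_wrap(c(0.01, 0, 0), c(-0.2, 0, 0), cyl), "inside")
})

test_that("paths through via points respect order and the triangle inequality", {
  an <- fx_anatomy()
  ctx <- fx_context()
  f <- fx_frame(ctx, 3)
  # straight element: two points, length = distance
  sol <- f$paths$soleus
  expect_equal(nrow(sol$points), 2)
  expect_equal(sol$length, sqrt(sum((sol$points[2, ] - sol$points[1, ])^2)))
  # via-point element: longer than the straight chord
  ta <- f$paths$tibialis_anterior
  expect_equal(nrow(ta$points), 3)
  chord <- sqrt(sum((ta$points[3, ] - ta$points[1, ])^2))
  expect_gte(ta$length, chord)
})

test_that("every element satisfies action-reaction closure at posed frames", {
  ctx <- fx_context()
  for (i in c(3, 90, 130)) {
    f <- fx_frame(ctx, i)
    for (p in f$paths) {
      cl <- path_closure(p, ref_point = c(0.3, 0.5, 0))
      expect_lt(max(abs(cl$force)), 1e-9)
      expect_lt(max(abs(cl$moment)), 2e-5)  # wrap contact applied on the axis
    }
  }
})

test_that("attachment moment arms are exact cross products", {
  path <- structure(list(
    points = rbind(c(0, 1, 0), c(1, 1, 0)),
    length = 1,
    records = list(list(segment = "shank", point = c(0, 1, 0), f = c(1, 0, 0))),
    name = "probe"), class = "fb_path")
  # unit force along +x applied at (0,1,0) about the origin: moment (0,0,-1)
  m <- attachment_moment_arms(path, "shank", c(0, 0, 0))
  expect_equal(m$moment, c(0, 0, -1))
  expect_equal(m$force, c(1, 0, 0))
  # force through the reference point has zero moment
  m0 <- attachment_moment_arms(path, "shank", c(0, 1, 0))
  expect_equal(m0$moment, c(0, 0, 0))
})

test_that("sagittal moment arms match the tendon-excursion derivative", {
  # hinge: shank rotates about the knee z-axis; for a knee-spanning element
  # d(length)/d(theta) equals minus the moment arm about the hinge axis
  an <- fx_anatomy()
  knee <- c(0, 0.5, 0)
  pose_th <- function(th) {
    Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, byrow = TRUE)
    list(foot = list(q = c(1, 0, 0, 0), o = c(0, 0, 0)),
         shank = list(q = matrix_to_quat(Rz), o = knee),
         thigh = list(q = c(1, 0, 0, 0), o = c(0, 0.93, 0)),
         pelvis = list(q = c(1, 0, 0, 0), o = c(0, 1.1, 0)),
         patella = list(q = c(1, 0, 0, 0), o = c(0.05, 0.45, 0)))
  }
  ham <- Filter(function(m) m$name == "hamstring_medialis", an$muscles)[[1]]
  arm_z <- function(th) {
    p <- element_path(ham, pose_th(th), list())
    attachment_moment_arms(p, "shank", knee)$moment[3]
  }
  len <- function(th) element_path(ham, pose_th(th), list())$length
  h <- 1e-5
  for (th in c(0.1, 0.4)) {
    dl <- (len(th + h) - len(th - h)) / (2 * h)
    expect_equal(-dl, arm_z(th), tolerance = 1e-5)
  }
})

test_that("effective arms equal the free-body summation on a planar chain", {
  # three-segment planar chain with an explicit free-body oracle
  ankle <- c(0, 0.1, 0); knee <- c(0.05, 0.5, 0); hip <- c(-0.02, 0.93, 0)
  poses <- list(foot = list(q = c(1, 0, 0, 0), o = ankle),
                shank = list(q = c(1, 0, 0, 0), o = knee),
                thigh = list(q = c(1, 0, 0, 0), o = hip),
                pelvis = list(q = c(1, 0, 0, 0), o = c(0, 1.1, 0)))
  # biarticular element: thigh origin to foot insertion (does not touch the shank)
  el <- list(name = "biarticular",
             attachments = list(list(segment = "thigh", point = c(-0.04, -0.42, 0) ),
                                list(segment = "foot", point = c(-0.06, -0.05, 0))),
             via_points = list(), cylinder = NA_character_)
  path <- element_path(el, poses, list())

  # free-body oracle: unit tension; reactions transmitted at ankle and knee
  # equal the net force applied below each cut (telescoped polyline edges)
  f_foot <- Reduce(`+`, lapply(Filter(function(r) r$segment == "foot", path$records),
                               function(r) r$f))
  # shank: no attachments; loads arrive as +R at the ankle (from the foot) and
  # leave as -R at the knee; moment about the knee:
  oracle_shank <- cross3(ankle - knee, f_foot)
  v_shank <- effective_moment_arm(path, "shank", knee,
                                  distal_point = ankle, distal_segments = "foot")
  expect_equal(v_shank, oracle_shank, tolerance = 1e-12)
  expect_false(all(v_shank == 0))  # intermediate segment feels the reactions

  # thigh: origin attachment + knee reaction (everything below the knee)
  org <- Filter(function(r) r$segment == "thigh", path$records)[[1]]
  oracle_thigh <- cross3(org$point - hip, org$f) + cross3(knee - hip, f_foot)
  v_thigh <- effective_moment_arm(path, "thigh", hip,
                                  distal_point = knee,
                                  distal_segments = c("foot", "shank"))
  expect_equal(v_thigh, oracle_thigh, tolerance = 1e-12)

  # monoarticular element about its spanned joint with contact at the centre:
  # the effective arm reduces to the attachment arm exactly
  mono <- list(name = "mono",
               attachments = list(list(segment = "shank", point = c(-0.03, -0.15, 0)),
                                  list(segment = "foot", point = c(-0.05, -0.04, 0))),
               via_points = list(), cylinder = NA_character_)
  pm <- element_path(mono, poses, list())
  att <- attachment_moment_arms(pm, "foot", ankle)
  v_foot <- effective_moment_arm(pm, "foot", ankle)  # foot has no distal joint
  expect_equal(v_foot, att$moment, tolerance = 1e-12)

  # whole-limb closure including reactions: the induced reactions cancel in
  # pairs, so summing all segment force records gives zero
  expect_equal(path_closure(path)$force, c(0, 0, 0), tolerance = 1e-12)
})
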