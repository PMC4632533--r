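# Patellar posture model: the pose of the patella is a function of the
# tibiofemoral flexion angle theta only. Patellar tendon orientation
# (sagittal/coronal plane angles in the tibial frame) and the three patellar
# Euler angles (flexion z, tilt y', rotation x'' relative to the femoral
# frame) are quartic regression polynomials in theta (degrees in, degrees
# out). The patellar/quadriceps tendon force ratio (P/Q) follows from the
# sagittal-plane moment equilibrium of the massless patella.

# Regression coefficients: rows are variables, columns b0..b4 of
# value = b0 + b1*theta + b2*theta^2 + b3*theta^3 + b4*theta^4 (theta in deg).
PATELLA_COEFFICIENTS <- matrix(c(
  20.4, -2.60e-1, 0,        0,        0,
  10.9, -2.33e-1, 1.89e-3, -5.69e-6,  0,
  5.59,  6.60e-1, 0,        0,        0,
  1.63,  6.67e-2, 1.44e-4, -5.37e-6,  0,
  1.43,  1.06e-1, -3.45e-3, 5.47e-5, -2.38e-7
), nrow = 5, byrow = TRUE,
  dimnames = list(c("pt_sagittal", "pt_coronal", "patellar_flexion",
                    "patellar_tilt", "patellar_rotation"),
                  paste0("b", 0:4)))

#' Patellar regression coefficients
#'
#' Returns the coefficient table of the patellar posture model, either the
#' packaged defaults or a table loaded from a versioned CSV (columns
#' `variable, b0..b4`) for subject-specific overrides.
#'
#' @param path optional CSV file overriding the packaged coefficients.
#' @return 5 x 5 numeric matrix, rows `pt_sagittal`, `pt_coronal`,
#'   `patellar_flexion`, `patellar_tilt`, `patellar_rotation`.
#' @export
patella_coefficients <- function(path = NULL) {
  if (is.null(path)) return(PATELLA_COEFFICIENTS)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- rownames(PATELLA_COEFFICIENTS)
  if (!all(need %in% df$variable)) {
    stop("coefficient file must define variables: ", paste(need, collapse = ", "))
  }
  m <- as.matrix(df[match(need, df$variable), paste0("b", 0:4)])
  rownames(m) <- need
  m
}

#' Evaluate the patellar posture polynomials
#'
#' @param theta knee (tibiofemoral) flexion angle, degrees. Values outside the
#'   calibrated range trigger a warning.
#' @param coefficients coefficient matrix, see [patella_coefficients()].
#' @param range calibrated flexion range (degrees).
#' @return named numeric vector (degrees): `pt_sagittal`, `pt_coronal`,
#'   `patellar_flexion`, `patellar_tilt`, `patellar_rotation`.
#' @export
eval_patella_polynomials <- function(theta, coefficients = patella_coefficients(),
                                     range = c(0, 120)) {
  if (theta < range[1] - 1e-9 || theta > range[2] + 1e-9) {
    warning(sprintf("knee flexion %.1f deg is outside the calibrated range [%g, %g]",
                    theta, range[1], range[2]))
  }
  powers <- theta^(0:4)
  setNames(as.numeric(coefficients %*% powers), rownames(coefficients))
}

rot_z <- function(a) matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, byrow = TRUE)
rot_y <- function(a) matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)), 3, byrow = TRUE)
rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)), 3, byrow = TRUE)

#' Patellar tendon direction in the tibial frame
#'
#' Unit vector from the tibial tuberosity towards the inferior patellar pole:
#' the tibial +y axis tilted posteriorly by the sagittal plane angle (about z)
#' and laterally by the coronal plane angle (about x).
#'
#' @param sagittal,coronal tendon plane angles, degrees.
#' @return unit 3-vector in the tibial local frame.
#' @export
patellar_tendon_direction <- function(sagittal, coronal) {
  as.numeric(rot_x(coronal * pi / 180) %*% rot_z(sagittal * pi / 180) %*% c(0, 1, 0))
}

#' Knee flexion angle from segment poses
#'
#' Flexion is the z-axis Euler rotation (flexion-abduction-rotation sequence)
#' of the tibia relative to the femur, measured from the calibration pose and
#' signed so that flexion (crouching) is positive. Degrees.
#'
#' @param q_shank,q_thigh frame quaternions of shank and thigh.
#' @param q_shank0,q_thigh0 calibration quaternions (defaults: identity).
#' @return knee flexion, degrees.
#' @export
knee_flexion_angle <- function(q_shank, q_thigh,
                               q_shank0 = c(1, 0, 0, 0), q_thigh0 = c(1, 0, 0, 0)) {
  C <- t(quat_to_matrix(q_thigh)) %*% quat_to_matrix(q_shank)
  C0 <- t(quat_to_matrix(q_thigh0)) %*% quat_to_matrix(q_shank0)
  D <- C %*% t(C0)
  -atan2(D[2, 1], D[1, 1]) * 180 / pi
}

#' Pose of the patella from the knee flexion angle
#'
#' The patellar origin (the point where the patellar tendon meets the patella)
#' is placed at the tibial tuberosity plus the tendon vector: tendon length
#' oriented by the sagittal/coronal plane angles in the tibial frame, mapped
#' to global coordinates. The orientation composes the femoral frame with the
#' intrinsic z-y'-x'' Euler triplet (patellar flexion, tilt, rotation).
#'
#' @param theta knee flexion angle, degrees.
#' @param tibia_pose,femur_pose lists with `q` (unit quaternion) and `o`
#'   (global origin) for the frame considered.
#' @param anatomy an `fb_anatomy` (tuberosity landmark and tendon length).
#' @param coefficients regression coefficients.
#' @return list `q`, `o`: the patellar pose (local-to-global).
#' @export
patella_pose <- function(theta, tibia_pose, femur_pose, anatomy,
                         coefficients = patella_coefficients()) {
  ang <- eval_patella_polynomials(theta, coefficients)
  tub <- anatomy$landmarks$tibial_tuberosity
  if (tub$segment != "shank") stop("tibial_tuberosity landmark must live on the shank")
  R_tib <- quat_to_matrix(tibia_pose$q)
  tub_g <- tibia_pose$o + as.numeric(R_tib %*% tub$point)
  dir_g <- as.numeric(R_tib %*% patellar_tendon_direction(ang["pt_sagittal"],
                                                          ang["pt_coronal"]))
  origin_pt <- tub_g + anatomy$patellar_tendon$length * dir_g
  R_fem <- quat_to_matrix(femur_pose$q)
  # patellar flexion follows the flexing tibia: negative z rotation in the
  # convention where knee flexion is a -z Euler rotation of tibia on femur
  R_pat <- R_fem %*% rot_z(-ang["patellar_flexion"] * pi / 180) %*%
    rot_y(ang["patellar_tilt"] * pi / 180) %*%
    rot_x(ang["patellar_rotation"] * pi / 180)
  o <- origin_pt - as.numeric(R_pat %*% anatomy$patellar_tendon$patella_point)
  list(q = matrix_to_quat(R_pat), o = o)
}

cross2 <- function(a, b) a[1] * b[2] - a[2] * b[1]

#' Patellar/quadriceps tendon force ratio from sagittal moment balance
#'
#' Both tendon lines of action are projected onto the femoral sagittal plane;
#' the ratio P/Q is the signed quotient of their moment arms about the
#' patellofemoral contact pivot, the value for which the massless patella is
#' in moment equilibrium. The equilibrium contact point (the pivot shifted
#' minimally so that the net tendon moment vanishes) is also returned.
#'
#' @param geom list with global-frame fields: `quad_point`, `quad_dir` (point
#'   and unit direction of the quadriceps tendon pull on the patella),
#'   `pt_point`, `pt_dir` (patellar tendon pull on the patella), `pivot`
#'   (nominal patellofemoral contact), `R_femur`, `femur_origin` (femoral
#'   frame used to define the sagittal plane).
#' @return list of class `"fb_pq"`: `ratio` (P/Q, dimensionless, >= 0),
#'   `contact` (equilibrium contact point, global frame).
#' @export
pq_ratio <- function(geom) {
  to2 <- function(p) { v <- t(geom$R_femur) %*% (p - geom$femur_origin); c(v[1], v[2]) }
  dir2 <- function(u) { v <- t(geom$R_femur) %*% u; c(v[1], v[2]) }
  qp <- to2(geom$quad_point); qd <- dir2(geom$quad_dir)
  pp <- to2(geom$pt_point); pd <- dir2(geom$pt_dir)
  pv <- to2(geom$pivot)
  nq <- sqrt(sum(qd^2)); np <- sqrt(sum(pd^2))
  if (nq < 1e-9 || np < 1e-9) stop("degenerate geometry: tendon line normal to sagittal plane")
  qd <- qd / nq; pd <- pd / np
  m_q <- cross2(qp - pv, qd)
  m_p <- cross2(pp - pv, pd)
  if (abs(m_p) < 1e-12) stop("degenerate geometry: patellar tendon has no sagittal moment arm")
  ratio <- abs(m_q) / abs(m_p)
  # net tendon moment about the nominal pivot; the contact point shifts onto
  # the line of action of the resultant so the patella stays in equilibrium
  f <- qd + ratio * pd
  g <- m_q + ratio * m_p
  delta2 <- if (sum(f^2) > 1e-12) (g / sum(f^2)) * c(f[2], -f[1]) else c(0, 0)
  contact <- geom$pivot + delta2[1] * geom$R_femur[, 1] + delta2[2] * geom$R_femur[, 2]
  structure(list(ratio = ratio, contact = contact), class = "fb_pq")
}

#' Patellar mechanics of one frame
#'
#' Builds the sagittal-plane geometry from the posed anatomy and evaluates the
#' P/Q ratio: the quadriceps pull is the mean unit direction of the final path
#' edge of each quadriceps element at its patellar insertion, the patellar
#' tendon pulls from the patellar origin towards the tibial tuberosity, and
#' the nominal pivot is the patellofemoral joint centre carried by the
#' patella.
#'
#' @param anatomy an `fb_anatomy`.
#' @param paths list of element paths for the frame (see [element_path()]),
#'   named by muscle.
#' @param pat_pose,tibia_pose,femur_pose single-frame poses.
#' @return list: `ratio`, `contact` (global), `rho` named vector over muscles
#'   (P/Q for quadriceps elements, 0 otherwise).
#' @export
pq_state <- function(anatomy, paths, pat_pose, tibia_pose, femur_pose) {
  R_pat <- quat_to_matrix(pat_pose$q)
  quads <- Filter(function(m) m$group == "quadriceps", anatomy$muscles)
  if (length(quads) == 0) stop("anatomy has no quadriceps elements; P/Q undefined")
  ins_pts <- NULL; dirs <- NULL
  for (m in quads) {
    pl <- paths[[m$name]]$points
    np <- nrow(pl)
    ins_pts <- rbind(ins_pts, pl[np, ])
    dirs <- rbind(dirs, (pl[np - 1, ] - pl[np, ]) / sqrt(sum((pl[np - 1, ] - pl[np, ])^2)))
  }
  quad_point <- colMeans(ins_pts)
  quad_dir <- colMeans(dirs); quad_dir <- quad_dir / sqrt(sum(quad_dir^2))
  pt_origin <- pat_pose$o + as.numeric(R_pat %*% anatomy$patellar_tendon$patella_point)
  tub <- anatomy$landmarks$tibial_tuberosity
  tub_g <- tibia_pose$o + as.numeric(quat_to_matrix(tibia_pose$q) %*% tub$point)
  pt_dir <- (tub_g - pt_origin) / sqrt(sum((tub_g - pt_origin)^2))
  pfj <- anatomy$joint_centres$patellofemoral
  pivot <- if (pfj$segment == "patella") {
    pat_pose$o + as.numeric(R_pat %*% pfj$point)
  } else {
    femur_pose$o + as.numeric(quat_to_matrix(femur_pose$q) %*% pfj$point)
  }
  pq <- pq_ratio(list(quad_point = quad_point, quad_dir = quad_dir,
                      pt_point = pt_origin, pt_dir = pt_dir, pivot = pivot,
                      R_femur = quat_to_matrix(femur_pose$q),
                      femur_origin = femur_pose$o))
  rho <- setNames(vapply(anatomy$muscles,
                         function(m) if (m$group == "quadriceps") pq$ratio else 0,
                         numeric(1)),
                  vapply(anatomy$muscles, function(m) m$name, character(1)))
  list(ratio = pq$ratio, contact = pq$contact, rho = rho)
}

#' Effective patellar tendon force bound
#'
#' In the formulation without an explicit patella the tendon force is not an
#' independent unknown; its effective upper bound is the flexion-dependent
#' P/Q ratio times the summed bounds of the quadriceps elements.
#'
#' @param rho P/Q ratio at the frame.
#' @param fmax named vector of muscle force bounds.
#' @param anatomy an `fb_anatomy`.
#' @return scalar bound, N.
#' @export
patellar_tendon_bound <- function(rho, fmax, anatomy) {
  qn <- vapply(Filter(function(m) m$group == "quadriceps", anatomy$muscles),
               function(m) m$name, character(1))
  rho * sum(fmax[qn])
}
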