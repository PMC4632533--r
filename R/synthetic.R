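# Synthetic study conditions: a planar-dominant five-segment toy anatomy and
# dynamically consistent countermovement-jump trials generated by forward
# kinematics, with the ground reaction computed from whole-body Newton-Euler
# balance at the same discrete differentiation used downstream, so the
# distal-to-proximal load recursion closes to machine precision. None of this
# is measured data: it exists so the full pipeline is testable end to end.

#' Specification of a synthetic subject and jump
#'
#' Defaults describe an athletic male subject captured at 200 Hz performing a
#' moderate countermovement jump: ~70 deg crouch reached in 0.4 s, a 300 ms
#' push-off and a short flight. Marker noise defaults to zero (the generator's
#' purpose is dynamic consistency; noise is opt-in).
#'
#' @param seed integer seed for the (optional) marker noise.
#' @param mass body mass, kg.
#' @param rate capture rate, Hz.
#' @param shank_length,thigh_length joint-to-joint lengths, m.
#' @param crouch_angle peak knee flexion of the countermovement, degrees.
#' @param takeoff_angle knee flexion at take-off, degrees (the leg leaves the
#'   ground before full extension, still extending).
#' @param stand_time,crouch_duration,push_duration,flight_duration phase
#'   durations, s.
#' @param marker_noise_sd isotropic marker noise after ground-reaction
#'   computation, m.
#' @return list of class `"fb_synth_spec"`.
#' @export
synth_spec <- function(seed = 1, mass = 83.7, rate = 200,
                       shank_length = 0.43, thigh_length = 0.43,
                       crouch_angle = 70, takeoff_angle = 15, stand_time = 0.15,
                       crouch_duration = 0.40, push_duration = 0.30,
                       flight_duration = 0.25, marker_noise_sd = 0) {
  structure(list(seed = seed, mass = mass, rate = rate,
                 shank_length = shank_length, thigh_length = thigh_length,
                 crouch_angle = crouch_angle, takeoff_angle = takeoff_angle,
                 stand_time = stand_time,
                 crouch_duration = crouch_duration, push_duration = push_duration,
                 flight_duration = flight_duration,
                 marker_noise_sd = marker_noise_sd), class = "fb_synth_spec")
}

# Calibration-pose world geometry of the toy subject: marker positions, joint
# centres, segment frames and the world-frame positions of every muscle /
# ligament / cylinder feature. Everything except deliberate transverse
# offsets lives in the single sagittal plane through the hip.
toy_subject <- function(spec = synth_spec()) {
  mid_asis <- c(0.04, 0.16 + spec$shank_length + spec$thigh_length, 0)
  markers <- list(
    RASIS = mid_asis + c(0, 0, 0.12), LASIS = mid_asis + c(0, 0, -0.12),
    RPSIS = mid_asis + c(-0.18, 0.02, 0.05), LPSIS = mid_asis + c(-0.18, 0.02, -0.05)
  )
  z_int_p <- unit3(markers$RASIS - markers$LASIS, "pelvis z")
  x_int_p <- mid_asis - (markers$RPSIS + markers$LPSIS) / 2
  y_p <- unit3(cross3(z_int_p, x_int_p), "pelvis y")
  x_p <- unit3(cross3(y_p, z_int_p), "pelvis x")
  R_pelvis <- unname(cbind(x_p, y_p, cross3(x_p, y_p)))
  W <- sqrt(sum((markers$RASIS - markers$LASIS)^2))
  hip <- hip_centre_regression(mid_asis, R_pelvis, W)

  knee <- hip - c(0, spec$thigh_length, 0)
  ankle <- knee - c(0, spec$shank_length, 0)
  zs <- hip[3]

  markers <- c(markers, list(
    FAM = ankle + c(0, 0, 0.04), TAM = ankle + c(0, 0, -0.04),
    C1 = knee + c(0.02, -0.12, 0.035), C2 = knee + c(-0.025, -0.22, -0.03),
    C3 = knee + c(0.03, -0.30, -0.015),
    FLE = knee + c(0, 0, 0.05), FME = knee + c(0, 0, -0.05),
    T1 = hip + c(0.03, -0.18, 0.045), T2 = hip + c(-0.03, -0.28, -0.04),
    T3 = hip + c(0.02, -0.33, 0.05),
    FM2 = ankle + c(0.16, -0.07, 0), FCC = ankle + c(-0.05, -0.06, 0.005),
    FMT = ankle + c(0.12, -0.05, 0.035), TF = ankle + c(0.06, -0.02, -0.02)
  ))

  # segment frames at calibration (same construction as the pipeline)
  R_foot <- axes_from_y_zint(ankle - markers$FM2, markers$FAM - markers$TAM, "foot")
  R_shank <- axes_from_y_zint(knee - ankle, markers$FAM - markers$TAM, "shank")
  R_thigh <- axes_from_y_zint(hip - knee, markers$FLE - markers$FME, "thigh")
  frames <- list(
    foot = list(R = R_foot, o = ankle),
    shank = list(R = R_shank, o = knee),
    thigh = list(R = R_thigh, o = hip),
    pelvis = list(R = R_pelvis, o = mid_asis)
  )
  list(spec = spec, markers = markers, frames = frames,
       joints = list(ankle = ankle, knee = knee, hip = hip),
       mid_asis = mid_asis, plane_z = zs,
       segment_lengths = c(foot = sqrt(sum((ankle - markers$FM2)^2)),
                           shank = spec$shank_length, thigh = spec$thigh_length),
       pelvis_com_world = hip + c(0.06, 0.25, 0))
}

to_local <- function(frames, segment, p_world) {
  as.numeric(t(frames[[segment]]$R) %*% (p_world - frames[[segment]]$o))
}

#' Toy anatomical dataset
#'
#' A planar-dominant five-segment anatomy with 12 muscle elements (a
#' quadriceps group of three vasti plus rectus femoris, soleus, tibialis
#' anterior, two gastrocnemius and two hamstring elements, gluteal and
#' iliopsoas elements), 4 ligaments with physiological bounds, a patellar
#' tendon and one femoral-condyle wrapping cylinder. Transverse (z) offsets on
#' paired elements provide out-of-plane moment authority in both senses, so
#' every joint rotation sense has an actuator.
#'
#' @param spec a [synth_spec()].
#' @return an `fb_anatomy`.
#' @export
make_toy_anatomy <- function(spec = synth_spec()) {
  su <- toy_subject(spec)
  fr <- su$frames
  A <- su$joints$ankle; K <- su$joints$knee; H <- su$joints$hip
  att <- function(segment, p_world) list(segment = segment, point = to_local(fr, segment, p_world))

  # patella world pose at calibration (theta = 0): tendon leaves the
  # tuberosity along the regression direction in the tibial frame
  tub_w <- K + c(0.055, -0.07, 0)
  ang0 <- eval_patella_polynomials(0)
  dir_w <- as.numeric(fr$shank$R %*% patellar_tendon_direction(ang0["pt_sagittal"],
                                                               ang0["pt_coronal"]))
  pt_len <- 0.05
  att_pat <- function(p_local) list(segment = "patella", point = p_local)

  mus <- function(name, origin, insertion, pcsa, group = "other",
                  via = list(), cylinder = NA_character_) {
    list(name = name, attachments = list(origin, insertion), via_points = via,
         cylinder = cylinder, pcsa = pcsa, group = group)
  }
  muscles <- list(
    mus("soleus", att("shank", K + c(-0.035, -0.15, 0)),
        att("foot", A + c(-0.05, -0.05, 0)), 0.0058),
    mus("tibialis_anterior", att("shank", K + c(0.03, -0.20, 0)),
        att("foot", A + c(0.10, -0.05, 0)), 0.0019,
        via = list(att("shank", A + c(0.035, 0.03, 0)))),
    mus("gastrocnemius_medialis", att("thigh", K + c(-0.03, 0.05, -0.03)),
        att("foot", A + c(-0.05, -0.05, 0.015)), 0.0021),
    mus("gastrocnemius_lateralis", att("thigh", K + c(-0.03, 0.05, 0.03)),
        att("foot", A + c(-0.05, -0.05, -0.015)), 0.0021),
    mus("vastus_medialis", att("thigh", K + c(0.02, 0.18, -0.03)),
        att_pat(c(0.015, 0.032, -0.006)), 0.0044, group = "quadriceps",
        cylinder = "fem_condyle"),
    mus("vastus_intermedius", att("thigh", K + c(0.02, 0.18, 0)),
        att_pat(c(0.015, 0.032, 0)), 0.0040, group = "quadriceps",
        cylinder = "fem_condyle"),
    mus("vastus_lateralis", att("thigh", K + c(0.02, 0.18, 0.03)),
        att_pat(c(0.015, 0.032, 0.006)), 0.0059, group = "quadriceps",
        cylinder = "fem_condyle"),
    mus("rectus_femoris", att("pelvis", H + c(0.035, 0.03, 0)),
        att_pat(c(0.015, 0.036, 0)), 0.0028, group = "quadriceps",
        cylinder = "fem_condyle"),
    mus("hamstring_medialis", att("pelvis", H + c(-0.05, 0.02, -0.02)),
        att("shank", K + c(0.015, -0.07, -0.035)), 0.0023),
    mus("hamstring_lateralis", att("pelvis", H + c(-0.05, 0.02, 0.02)),
        att("shank", K + c(-0.035, -0.055, 0.035)), 0.0023),
    mus("gluteus", att("pelvis", H + c(-0.09, 0.06, 0.04)),
        att("thigh", H + c(-0.03, -0.13, 0.055)), 0.0087),
    mus("iliopsoas", att("pelvis", H + c(0.03, 0.06, -0.015)),
        att("thigh", H + c(0.015, -0.07, -0.03)), 0.0040,
        via = list(att("pelvis", H + c(0.035, 0.005, -0.02))))
  )
  ligaments <- list(
    list(name = "anterior_cruciate", upper_bound = 2000,
         attachments = list(att("thigh", K + c(-0.005, 0.02, 0)),
                            att("shank", K + c(0.015, -0.025, 0)))),
    list(name = "medial_collateral", upper_bound = 3000,
         attachments = list(att("thigh", K + c(0, 0.03, -0.045)),
                            att("shank", K + c(0.005, -0.07, -0.04)))),
    list(name = "lateral_collateral", upper_bound = 2000,
         attachments = list(att("thigh", K + c(0, 0.03, 0.045)),
                            att("shank", K + c(0.005, -0.07, 0.04)))),
    list(name = "iliofemoral_anterior", upper_bound = 850,
         attachments = list(att("pelvis", H + c(0.03, 0.02, 0.015)),
                            att("thigh", H + c(0.015, -0.045, 0.02))))
  )
  cylinders <- list(list(
    id = "fem_condyle", segment = "thigh",
    axis_point = to_local(fr, "thigh", K + c(0, 0.005, 0)),
    axis_direction = c(0, 0, 1), radius = 0.032, wrap_side = -1
  ))
  segments <- data.frame(
    name = c("foot", "shank", "thigh", "pelvis", "patella"),
    ref_length = c(su$segment_lengths["foot"], spec$shank_length,
                   spec$thigh_length, 0.24, 0.04),
    massless = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  joint_centres <- list(
    ankle = list(segment = "foot", point = c(0, 0, 0)),
    tibiofemoral = list(segment = "shank", point = c(0, 0, 0)),
    hip = list(segment = "thigh", point = c(0, 0, 0)),
    patellofemoral = list(segment = "patella", point = c(-0.030, 0.010, 0))
  )
  landmarks <- list(
    tibial_tuberosity = list(segment = "shank", point = to_local(fr, "shank", tub_w))
  )
  fb_anatomy(segments, muscles, ligaments, cylinders, joint_centres, landmarks,
             patellar_tendon = list(length = pt_len, patella_point = c(0, 0, 0)))
}

#' Synthetic full-scale anatomical layout
#'
#' A synthetic stand-in reproducing only the dimensions of the full cadaveric
#' dataset (163 muscle elements, the 14 ligaments with their published force
#' bounds): toy elements are replicated with small deterministic offsets until
#' the element count is reached. Intended solely for structural checks of the
#' equation assembly; it is not anatomical data.
#'
#' @param spec a [synth_spec()].
#' @param n_muscles,n_ligaments element counts of the full layout.
#' @return an `fb_anatomy` with `M = n_muscles`, `N = n_ligaments`.
#' @export
make_full_layout_anatomy <- function(spec = synth_spec(), n_muscles = 163,
                                     n_ligaments = 14) {
  base <- make_toy_anatomy(spec)
  tmpl <- base$muscles
  muscles <- vector("list", n_muscles)
  for (i in seq_len(n_muscles)) {
    m <- tmpl[[((i - 1) %% length(tmpl)) + 1]]
    d <- 1e-3 * (((i - 1) %/% length(tmpl)) + 1)
    m$name <- sprintf("%s_el%03d", m$name, i)
    m$attachments <- lapply(m$attachments, function(a) {
      a$point <- a$point + c(d, 0, -d); a
    })
    muscles[[i]] <- m
  }
  lig_tab <- table5_ligament_bounds()
  lig_tmpl <- list(hip = base$ligaments[[4]], knee = base$ligaments[[1]],
                   ankle = list(name = "", upper_bound = 1, attachments = list(
                     list(segment = "shank", point = c(0, -spec$shank_length + 0.03, -0.03)),
                     list(segment = "foot", point = c(-0.02, -0.03, 0.02)))))
  ligaments <- lapply(seq_len(min(n_ligaments, nrow(lig_tab))), function(j) {
    l <- lig_tmpl[[lig_tab$joint[j]]]
    d <- 2e-3 * j
    l$name <- lig_tab$ligament[j]
    l$upper_bound <- lig_tab$upper_bound[j]
    l$attachments <- lapply(l$attachments, function(a) { a$point <- a$point + c(0, 0, d); a })
    l
  })
  base$muscles <- muscles
  base$ligaments <- ligaments
  validate_anatomy(base)
  base
}

#' Published ligament force upper bounds
#'
#' The 14 lower-limb ligaments of the model with their force upper bounds (N)
#' and the joint they span.
#'
#' @return data.frame: `ligament`, `joint`, `upper_bound`.
#' @export
table5_ligament_bounds <- function() {
  data.frame(
    ligament = c("iliofemoral_anterior", "iliofemoral_lateral", "pubofemoral",
                 "ischiofemoral", "anterior_cruciate", "posterior_cruciate",
                 "medial_collateral", "lateral_collateral", "oblique_popliteal",
                 "posterior_tibiotalar", "tibiocalcaneal", "tibionavicular",
                 "posterior_talofibular", "calcaneofibular"),
    joint = c("hip", "hip", "hip", "hip", "knee", "knee", "knee", "knee", "knee",
              "ankle", "ankle", "ankle", "ankle", "ankle"),
    upper_bound = c(850, 850, 450, 450, 2000, 4000, 3000, 2000, 1000,
                    850, 850, 850, 850, 850),
    stringsAsFactors = FALSE
  )
}

min_jerk <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5

# Knee flexion profile (radians) of the countermovement jump at time t.
jump_theta <- function(t, spec) {
  th <- spec$crouch_angle * pi / 180
  tho <- spec$takeoff_angle * pi / 180
  t1 <- spec$stand_time
  t2 <- t1 + spec$crouch_duration
  t3 <- t2 + spec$push_duration
  if (t <= t1) return(0)
  if (t <= t2) return(th * min_jerk((t - t1) / spec$crouch_duration))
  if (t <= t3) return(tho + (th - tho) * (1 - ((t - t2) / spec$push_duration)^2))
  tho
}

# Split the knee flexion angle between shank and thigh so the whole-body
# centre of mass stays above the (fixed) foot: alpha sin(a T) = beta
# sin((1-a) T), with alpha/beta the mass-weighted horizontal excursions of
# the chain above the knee and above the hip. A balanced squat keeps the
# centre of pressure inside the base of support.
balance_split <- function(su, theta) {
  fr <- DE_LEVA_MALE
  m_s <- fr$mass_frac[fr$segment == "shank"]; c_s <- fr$com_frac[fr$segment == "shank"]
  m_t <- fr$mass_frac[fr$segment == "thigh"]; c_t <- fr$com_frac[fr$segment == "thigh"]
  m_p <- 1 - sum(fr$mass_frac)
  Ls <- su$spec$shank_length; Lt <- su$spec$thigh_length
  alpha <- (m_s * (1 - c_s) + m_t + m_p) * Ls
  beta <- (m_t * (1 - c_t) + m_p) * Lt
  if (abs(theta) < 1e-3) return(beta / (alpha + beta))
  stats::uniroot(function(a) alpha * sin(a * theta) - beta * sin((1 - a) * theta),
                 c(0.05, 0.95), tol = 1e-12)$root
}

# Build the pose (R, o) of every segment at contact-phase knee flexion Theta.
contact_pose <- function(su, theta) {
  a <- balance_split(su, theta)
  phi_s <- -a * theta
  phi_t <- (1 - a) * theta
  A0 <- su$joints$ankle; K0 <- su$joints$knee; H0 <- su$joints$hip
  Rs <- rot_z(phi_s); Rt <- rot_z(phi_t)
  knee <- A0 + as.numeric(Rs %*% (K0 - A0))
  hip <- knee + as.numeric(Rt %*% (H0 - K0))
  list(
    foot = list(R = su$frames$foot$R, o = A0),
    shank = list(R = Rs %*% su$frames$shank$R, o = knee),
    thigh = list(R = Rt %*% su$frames$thigh$R, o = hip),
    pelvis = list(R = su$frames$pelvis$R, o = hip + (su$mid_asis - H0))
  )
}

#' Generate a synthetic movement trial
#'
#' Forward kinematics from a knee-flexion profile (hip and ankle angles are
#' distributed from it; the foot stays flat during contact), with an optional
#' ballistic flight phase in which the configuration is frozen and the whole
#' body translates under gravity. Ground reaction force is the whole-body
#' Newton-Euler resultant computed from the same central-difference
#' accelerations used downstream; the centre of pressure and vertical free
#' moment are solved from the whole-body moment balance about the ankle, so
#' the generated trial satisfies the model's own equations before noise. The
#' independently accumulated inter-segmental loads are attached as attribute
#' `"oracle"`.
#'
#' @param spec a [synth_spec()].
#' @param theta_fun knee flexion profile (rad) as a function of time; default
#'   is the countermovement-jump profile of the spec.
#' @param flight logical: append the ballistic flight phase.
#' @param duration trial length, s (default: jump phases plus flight).
#' @return an `fb_trial` with attributes `oracle` (`S0..S3`, `W1..W3`),
#'   `takeoff_time`, `subject` (lengths, mass, pelvis com), `calibration`
#'   (a matching static calibration trial).
#' @export
make_jump_trial <- function(spec = synth_spec(), theta_fun = NULL, flight = TRUE,
                            duration = NULL) {
  su <- toy_subject(spec)
  if (is.null(theta_fun)) theta_fun <- function(t) jump_theta(t, spec)
  t_take <- spec$stand_time + spec$crouch_duration + spec$push_duration
  if (is.null(duration)) {
    duration <- if (flight) t_take + spec$flight_duration else t_take
  }
  n <- floor(duration * spec$rate) + 1
  time <- (seq_len(n) - 1) / spec$rate
  segs <- c("foot", "shank", "thigh", "pelvis")

  # inertial model shared with the pipeline
  pelvis_com_local <- to_local(su$frames, "pelvis", su$pelvis_com_world)
  inertia <- inertial_params(spec$mass, su$segment_lengths,
                             pelvis_com = pelvis_com_local)

  poses <- lapply(segs, function(s) list(q = matrix(0, n, 4), o = matrix(0, n, 3)))
  names(poses) <- segs
  contact <- if (flight) time <= t_take + 1e-9 else rep(TRUE, n)
  for (i in seq_len(n)) {
    if (contact[i]) {
      cp <- contact_pose(su, theta_fun(time[i]))
      for (s in segs) {
        poses[[s]]$q[i, ] <- matrix_to_quat(cp[[s]]$R)
        poses[[s]]$o[i, ] <- cp[[s]]$o
      }
    }
  }
  if (any(!contact)) {
    i_take <- max(which(contact))
    # whole-body CoM velocity at take-off from the contact trajectory
    com_tot <- Reduce(`+`, lapply(segs, function(s) {
      inertia[[s]]$m * track_point(poses[[s]], inertia[[s]]$com_local)
    })) / sum(vapply(segs, function(s) inertia[[s]]$m, numeric(1)))
    v0 <- (com_tot[i_take, ] - com_tot[i_take - 1, ]) * spec$rate
    for (i in which(!contact)) {
      dtf <- time[i] - time[i_take]
      shift <- v0 * dtf + 0.5 * GRAVITY * dtf^2
      for (s in segs) {
        poses[[s]]$q[i, ] <- poses[[s]]$q[i_take, ]
        poses[[s]]$o[i, ] <- poses[[s]]$o[i_take, ] + shift
      }
    }
  }
  for (s in segs) poses[[s]]$q <- quat_hemispherize(poses[[s]]$q)

  # discrete kinematics (same differentiation scheme as the pipeline)
  kin <- lapply(segs, function(s) {
    de <- differentiate_poses(poses[[s]], spec$rate)
    com <- track_point(poses[[s]], inertia[[s]]$com_local)
    list(com = com, a = accel_central(com, spec$rate),
         omega = de$omega, alpha = de$alpha, m = inertia[[s]]$m,
         Y = function(i) {
           R <- quat_to_matrix(poses[[s]]$q[i, ])
           R %*% inertia[[s]]$Y_local %*% t(R)
         })
  })
  names(kin) <- segs

  grf <- matrix(0, n, 3); cop <- matrix(0, n, 3); freem <- matrix(0, n, 3)
  w_thresh <- 0.02 * spec$mass * 9.81
  last_cop <- c(su$joints$ankle[1] + 0.05, 0, su$plane_z)
  for (i in seq_len(n)) {
    F <- Reduce(`+`, lapply(kin, function(k) k$m * (k$a[i, ] - GRAVITY)))
    grf[i, ] <- F
    ankle_i <- poses$foot$o[i, ]
    Mreq <- Reduce(`+`, lapply(kin, function(k) {
      cross3(k$com[i, ] - ankle_i, k$m * (k$a[i, ] - GRAVITY)) +
        as.numeric(k$Y(i) %*% k$alpha[i, ]) +
        cross3(k$omega[i, ], as.numeric(k$Y(i) %*% k$omega[i, ]))
    }))
    if (abs(F[2]) > w_thresh) {
      rx <- (Mreq[3] + ankle_i[2] * F[1]) / F[2]
      rz <- (-ankle_i[2] * F[3] - Mreq[1]) / F[2]
      cop[i, ] <- ankle_i + c(rx, -ankle_i[2], rz)
      freem[i, 2] <- Mreq[2] - (rz * F[1] - rx * F[3])
      last_cop <- cop[i, ]
    } else {
      cop[i, ] <- last_cop
      freem[i, ] <- c(0, 0, 0)
    }
  }

  # independent load accumulation (closed form, distal chains)
  chain <- c("foot", "shank", "thigh")
  oracle <- list(S = list(S0 = grf), W = list(W0 = freem))
  for (k in 1:3) {
    Sk <- matrix(0, n, 3); Wk <- matrix(0, n, 3)
    ok <- poses[[chain[k]]]$o
    for (i in seq_len(n)) {
      acc_f <- c(0, 0, 0); acc_m <- c(0, 0, 0)
      for (j in 1:k) {
        kj <- kin[[chain[j]]]
        mag <- kj$m * (kj$a[i, ] - GRAVITY)
        acc_f <- acc_f + mag
        acc_m <- acc_m + cross3(kj$com[i, ] - ok[i, ], mag) +
          as.numeric(kj$Y(i) %*% kj$alpha[i, ]) +
          cross3(kj$omega[i, ], as.numeric(kj$Y(i) %*% kj$omega[i, ]))
      }
      Sk[i, ] <- grf[i, ] - acc_f
      Wk[i, ] <- cross3(cop[i, ] - ok[i, ], grf[i, ]) + freem[i, ] - acc_m
    }
    oracle$S[[paste0("S", k)]] <- Sk
    oracle$W[[paste0("W", k)]] <- Wk
  }

  # marker local coordinates from calibration, then forward kinematics
  seg_of_marker <- list()
  for (s in names(SEGMENT_MARKERS)) for (lab in SEGMENT_MARKERS[[s]]) seg_of_marker[[lab]] <- s
  markers <- list()
  set.seed(spec$seed)
  for (lab in names(su$markers)) {
    s <- seg_of_marker[[lab]]
    loc <- to_local(su$frames, s, su$markers[[lab]])
    traj <- track_point(poses[[s]], loc)
    if (spec$marker_noise_sd > 0) {
      traj <- traj + matrix(stats::rnorm(3 * n, sd = spec$marker_noise_sd), n, 3)
    }
    markers[[lab]] <- traj
  }

  trial <- fb_trial(markers, spec$rate,
                    ground = list(force = grf, cop = cop, free_moment = freem),
                    time = time)
  attr(trial, "oracle") <- oracle
  attr(trial, "takeoff_time") <- if (flight) t_take else NA_real_
  attr(trial, "subject") <- list(mass = spec$mass,
                                 segment_lengths = su$segment_lengths,
                                 pelvis_com = pelvis_com_local)
  attr(trial, "calibration") <- make_calibration_trial(spec)
  trial
}

#' Static posture trial
#'
#' A held posture at constant knee flexion (degrees): every kinematic term is
#' zero, the ground reaction equals body weight and the centre of pressure
#' sits below the whole-body centre of mass.
#'
#' @param spec a [synth_spec()].
#' @param theta_deg held knee flexion, degrees.
#' @param duration hold time, s.
#' @return an `fb_trial` (same attributes as [make_jump_trial()]).
#' @export
make_static_trial <- function(spec = synth_spec(), theta_deg = 0, duration = 0.25) {
  make_jump_trial(spec, theta_fun = function(t) theta_deg * pi / 180,
                  flight = FALSE, duration = duration)
}

#' Calibration trial of the synthetic subject
#'
#' Markers of the anatomical standing position, held still.
#'
#' @param spec a [synth_spec()].
#' @param n_frames number of frames.
#' @return an `fb_trial` without ground reaction.
#' @export
make_calibration_trial <- function(spec = synth_spec(), n_frames = 10) {
  su <- toy_subject(spec)
  markers <- lapply(su$markers, function(p) {
    matrix(p, n_frames, 3, byrow = TRUE)
  })
  fb_trial(markers, spec$rate)
}

#' Random small feasible frame system
#'
#' A random equality system with a known interior witness (`b = A x_true`),
#' for solver oracles: the witness satisfies the system exactly and bounds
#' enclose it.
#'
#' @param seed integer seed.
#' @param n_eq,n_unknowns dimensions (kept small for grid-search oracles).
#' @return list `system` (an `fb_system`-shaped object, all columns bounded
#'   and in the cost) and `witness`.
#' @export
make_feasible_system <- function(seed = 1, n_eq = 3, n_unknowns = 6) {
  set.seed(seed)
  A <- matrix(stats::runif(n_eq * n_unknowns, -1, 1), n_eq, n_unknowns)
  ub <- stats::runif(n_unknowns, 1, 5)
  x_true <- ub * stats::runif(n_unknowns, 0.25, 0.75)
  b <- as.numeric(A %*% x_true)
  sys <- structure(list(
    A = A, b = b, lower = rep(0, n_unknowns), upper = ub,
    cols = data.frame(type = rep("muscle", n_unknowns),
                      name = paste0("u", seq_len(n_unknowns)),
                      stringsAsFactors = FALSE),
    cost = rep(TRUE, n_unknowns), case = NA_integer_,
    reaction_groups = NULL, rows = NULL,
    counts = c(equations = n_eq, unknowns = n_unknowns)
  ), class = "fb_system")
  list(system = sys, witness = x_true)
}

#' Take-off detection
#'
#' The take-off instant is the first time the vertical ground reaction force
#' drops to (effectively) zero after having carried load.
#'
#' @param trial an `fb_trial` with ground reaction.
#' @param threshold force threshold, N.
#' @return take-off time, s (NA when the trial never leaves the ground).
#' @export
detect_takeoff <- function(trial, threshold = 5) {
  fy <- trial$ground$force[, 2]
  loaded <- which(fy > threshold)
  if (!length(loaded)) return(NA_real_)
  after <- which(fy <= threshold & seq_along(fy) > min(loaded))
  if (!length(after)) return(NA_real_)
  trial$time[min(after)]
}
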