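# Segment inertia, recursive inter-segmental loads, and assembly of the
# per-frame indeterminate equations of motion for the four model cases:
#   case 1: 18 equations (3 force + 3 moment rows per segment for foot, shank,
#           thigh); moments use effective arms; no explicit patella; the
#           patellar tendon is not an independent unknown (quadriceps tension
#           is routed through the patella with the P/Q ratio).
#   case 2: patella added: patellar tendon force and patellofemoral reaction
#           unknowns, 3 patellar force-equilibrium rows and the P/Q row;
#           muscle/ligament moments still via effective arms (hybrid form).
#   case 3: as case 2 but fully segment-based: moment rows use attachment
#           arms and the joint reactions appear explicitly with their own
#           moment arms.
#   case 4: as case 3 with the tibiofemoral reaction split into medial and
#           lateral compartment contacts offset along the tibial z-axis.
# Unknown layout: [F_1..F_M, (F_pt), L_1..L_N, reactions]; full-anatomy
# dimensions (M = 163, N = 14) are 186 / 190 / 190 / 193 unknowns.

# Segment inertial fractions (adjusted male anthropometry): mass as a
# fraction of body mass; centre of mass as a fraction of segment length from
# the proximal joint; radii of gyration (sagittal, transverse, longitudinal)
# as fractions of segment length.
DE_LEVA_MALE <- data.frame(
  segment = c("foot", "shank", "thigh"),
  mass_frac = c(0.0137, 0.0433, 0.1416),
  com_frac = c(0.4415, 0.4459, 0.4095),
  r_sag = c(0.257, 0.251, 0.329),
  r_trans = c(0.245, 0.246, 0.329),
  r_long = c(0.124, 0.102, 0.149),
  stringsAsFactors = FALSE
)

#' Segment inertial parameters
#'
#' Applies the anthropometric fractions: per-segment mass, centre of mass
#' position along the local y-axis (measured from the proximal joint) and a
#' diagonal local inertia tensor from the radii of gyration. The pelvis is the
#' remainder body (pelvis plus head-arms-trunk) with a configurable lumped
#' centre of mass and radius of gyration; the patella is massless.
#'
#' @param subject_mass body mass, kg.
#' @param segment_lengths named vector (m) with `foot`, `shank`, `thigh`.
#' @param pelvis_com lumped pelvis+HAT centre of mass in the pelvis frame (m).
#' @param pelvis_gyradius lumped radius of gyration (m) for all three axes.
#' @return list of class `"fb_inertia"`: per segment `m` (kg), `com_local`
#'   (m), `Y_local` (kg m^2).
#' @export
inertial_params <- function(subject_mass, segment_lengths,
                            pelvis_com = c(-0.02, 0.25, 0),
                            pelvis_gyradius = 0.30) {
  if (subject_mass <= 0) stop("subject mass must be positive")
  need <- c("foot", "shank", "thigh")
  if (!all(need %in% names(segment_lengths))) {
    stop("segment_lengths must name foot, shank and thigh")
  }
  if (any(segment_lengths[need] <= 0)) stop("segment lengths must be positive")
  out <- list()
  for (i in seq_len(nrow(DE_LEVA_MALE))) {
    r <- DE_LEVA_MALE[i, ]
    L <- segment_lengths[[r$segment]]
    m <- subject_mass * r$mass_frac
    out[[r$segment]] <- list(
      m = m,
      com_local = c(0, -r$com_frac * L, 0),
      Y_local = m * diag(c((r$r_trans * L)^2, (r$r_long * L)^2, (r$r_sag * L)^2))
    )
  }
  m_pelvis <- subject_mass * (1 - sum(DE_LEVA_MALE$mass_frac))
  out$pelvis <- list(m = m_pelvis, com_local = pelvis_com,
                     Y_local = m_pelvis * diag(rep(pelvis_gyradius^2, 3)))
  out$patella <- list(m = 0, com_local = c(0, 0, 0), Y_local = diag(0, 3))
  structure(out, class = "fb_inertia", subject_mass = subject_mass)
}

# Per-frame rigid-body state of one segment.
segment_state_frame <- function(pose_i, omega, alpha, inert, rate = NULL) {
  R <- quat_to_matrix(pose_i$q)
  list(R = R, o = pose_i$o,
       com = pose_i$o + as.numeric(R %*% inert$com_local),
       m = inert$m,
       Y = R %*% inert$Y_local %*% t(R),
       omega = omega, alpha = alpha)
}

#' Per-frame segment states for the equations of motion
#'
#' Combines fitted poses with inertial parameters: centre-of-mass
#' trajectories and their accelerations (central differences), angular
#' velocity/acceleration from the quaternion series, and the globally
#' resolved inertia tensors.
#'
#' @param poses an `fb_poses` object.
#' @param inertia an `fb_inertia` object.
#' @param rate sampling rate, Hz.
#' @param segments segments to process.
#' @return list of class `"fb_states"`: per segment `o`, `com`, `a` (n x 3
#'   CoM acceleration), `omega`, `alpha`, `m`, and per-frame rotation/inertia
#'   accessors `R(i)`, `Y(i)`.
#' @export
segment_states <- function(poses, inertia, rate,
                           segments = c("foot", "shank", "thigh", "pelvis")) {
  out <- list()
  for (seg in segments) {
    p <- poses[[seg]]
    de <- differentiate_poses(p, rate)
    inert <- inertia[[seg]]
    com <- track_point(p, inert$com_local)
    Rl <- lapply(seq_len(nrow(p$q)), function(i) quat_to_matrix(p$q[i, ]))
    out[[seg]] <- list(
      o = p$o, q = p$q, com = com, a = accel_central(com, rate),
      omega = de$omega, alpha = de$alpha, m = inert$m,
      R = function(i) NULL, Y_local = inert$Y_local, Rlist = Rl
    )
    out[[seg]]$R <- local({
      Rl_ <- Rl
      function(i) Rl_[[i]]
    })
    out[[seg]]$Y <- local({
      Rl_ <- Rl; Yl <- inert$Y_local
      function(i) Rl_[[i]] %*% Yl %*% t(Rl_[[i]])
    })
  }
  structure(out, class = "fb_states", n = nrow(poses[[segments[1]]]$q), rate = rate)
}

#' Recursive inter-segmental loads
#'
#' Newton-Euler resultants at the proximal end of foot, shank and thigh,
#' working from distal to proximal: `-S^k = m^k (a^k - g) - S^(k-1)` with
#' `S^0` the ground reaction force, and the matching moment recursion about
#' each segment's proximal joint centre with `W^0` the free moment of the
#' ground action (whose force acts at the centre of pressure).
#'
#' @param states an `fb_states` object (foot, shank, thigh present).
#' @param ground list `force`, `cop`, `free_moment` (n x 3 each).
#' @param gravity gravity vector (m s^-2).
#' @return list of class `"fb_loads"`: `S` and `W`, each a list of n x 3
#'   matrices for `S0..S3` / `W0..W3` (`S0`/`W0` echo the ground action).
#' @export
intersegmental_loads <- function(states, ground, gravity = GRAVITY) {
  chain <- c("foot", "shank", "thigh")
  n <- nrow(states$foot$o)
  S <- list(S0 = ground$force)
  W <- list(W0 = ground$free_moment)
  for (k in 1:3) {
    seg <- chain[k]
    st <- states[[seg]]
    Sk <- matrix(0, n, 3); Wk <- matrix(0, n, 3)
    Sprev <- S[[k]]; Wprev <- W[[k]]
    for (i in seq_len(n)) {
      mag <- st$m * (st$a[i, ] - gravity)
      Sk[i, ] <- Sprev[i, ] - mag
      chat <- st$com[i, ] - st$o[i, ]
      dist_pt <- if (k == 1) ground$cop[i, ] else states[[chain[k - 1]]]$o[i, ]
      dhat <- dist_pt - st$o[i, ]
      Yg <- st$Y(i)
      rot <- as.numeric(Yg %*% st$alpha[i, ]) +
        cross3(st$omega[i, ], as.numeric(Yg %*% st$omega[i, ]))
      Wk[i, ] <- Wprev[i, ] + cross3(dhat, Sprev[i, ]) -
        cross3(chat, mag) - rot
    }
    S[[paste0("S", k)]] <- Sk
    W[[paste0("W", k)]] <- Wk
  }
  structure(list(S = S, W = W), class = "fb_loads")
}

# Route a quadriceps element through the patella for the case-1 formulation:
# the patellar tendon creates an equal and opposite effect on the tibial and
# femoral segments and is not an independent unknown. Per 1 N of quadriceps
# tension the tibia receives rho * (tendon pull) at the tuberosity and the
# femur receives the net tendon force on the (massless) patella at the
# patellofemoral contact point.
fold_patella_case1 <- function(path, pt_path, rho, contact_point) {
  recs <- list()
  pat_force <- c(0, 0, 0)
  for (rec in path$records) {
    if (identical(rec$segment, "patella")) {
      pat_force <- pat_force + rec$f
    } else {
      recs[[length(recs) + 1]] <- rec
    }
  }
  for (rec in pt_path$records) {
    if (identical(rec$segment, "patella")) {
      pat_force <- pat_force + rho * rec$f
    } else {
      rec$f <- rho * rec$f
      recs[[length(recs) + 1]] <- rec
    }
  }
  recs[[length(recs) + 1]] <- list(segment = "thigh", point = contact_point, f = pat_force)
  structure(list(points = path$points, length = path$length, records = recs,
                 name = path$name), class = "fb_path")
}

CHAIN <- c("foot", "shank", "thigh")

#' Assemble the indeterminate equations of motion of one frame
#'
#' Populates the matrix `A`, right-hand side `b` and variable bounds of the
#' requested case. Force rows balance each segment; moment rows are referenced
#' to each segment's proximal joint centre and use effective moment arms
#' (cases 1-2) or attachment arms plus explicit reaction arms through
#' skew-symmetric offset matrices (cases 3-4); cases 2-4 add the patellar
#' force equilibrium rows and the row tying the patellar tendon force to the
#' P/Q ratio of the quadriceps tension. Muscles are bounded by `[0, Fmax]`,
#' ligaments by `[0, Lmax]`; reactions are unbounded.
#'
#' @param case 1, 2, 3 or 4.
#' @param paths named list of `fb_path` objects for every muscle (and the
#'   patellar tendon under `patellar_tendon`) and ligament, at this frame.
#' @param anatomy an `fb_anatomy`.
#' @param states an `fb_states` object.
#' @param loads an `fb_loads` object from [intersegmental_loads()].
#' @param ground ground reaction list (`force`, `cop`, `free_moment`).
#' @param frame frame index.
#' @param pq patellar state for the frame (list `ratio`, `contact`, `rho`),
#'   required for every case (case 1 uses it to route the quadriceps).
#' @param fmax,lmax named bound vectors (N).
#' @param condyle_half_distance case-4 half inter-condyle distance (m),
#'   contacts at +/- this offset along the tibial z-axis.
#' @param compression_only case 4 only: express the compartment reactions in
#'   the tibial frame and restrict their axial (+y) component to compression
#'   (non-negative, capped at `compression_cap`). Default off: reactions are
#'   unbounded in sign.
#' @param compression_cap force ceiling (N) for the compression-only axial
#'   component.
#' @param gravity gravity vector.
#' @return object of class `"fb_system"`: `A`, `b`, `lower`, `upper`, `cols`
#'   (data.frame: type, name), `cost` (logical: column enters the cost),
#'   `case`, `reaction_groups`, `rows` (labels), `contacts`.
#' @export
assemble_system <- function(case, paths, anatomy, states, loads, ground, frame,
                            pq, fmax, lmax = NULL,
                            condyle_half_distance = 0.02,
                            compression_only = FALSE, compression_cap = 2e4,
                            gravity = GRAVITY) {
  stopifnot(case %in% 1:4)
  if (is.null(pq)) stop("patellar state (pq) is required")
  i <- frame
  mus_names <- vapply(anatomy$muscles, function(m) m$name, character(1))
  lig_names <- vapply(anatomy$ligaments, function(l) l$name, character(1))
  M <- length(mus_names); N <- length(lig_names)
  if (is.null(lmax)) lmax <- ligament_force_bounds(anatomy)

  # contact points (global): joint centres carried by the distal segment
  o_foot <- states$foot$o[i, ]; o_shank <- states$shank$o[i, ]
  o_thigh <- states$thigh$o[i, ]
  z_tib <- states$shank$R(i)[, 3]
  contacts <- list(
    ankle = o_foot, knee = o_shank, hip = o_thigh,
    knee_med = o_shank - condyle_half_distance * z_tib,
    knee_lat = o_shank + condyle_half_distance * z_tib,
    pfj = pq$contact
  )

  # case-1 patellar routing
  eff_paths <- paths
  if (case == 1) {
    pt_path <- paths$patellar_tendon
    if (is.null(pt_path)) stop("paths must include 'patellar_tendon'")
    for (m in anatomy$muscles) {
      if (m$group == "quadriceps") {
        eff_paths[[m$name]] <- fold_patella_case1(paths[[m$name]], pt_path,
                                                  pq$ratio, contacts$pfj)
      }
    }
  }

  has_pt <- case >= 2
  col_type <- c(rep("muscle", M), if (has_pt) "pt",
                rep("ligament", N))
  col_name <- c(mus_names, if (has_pt) "patellar_tendon", lig_names)
  reaction_groups <- if (case == 4) {
    c("R1", "R2_med", "R2_lat", "R3", "Rpat")
  } else if (case >= 2) {
    c("R1", "R2", "R3", "Rpat")
  } else {
    c("R1", "R2", "R3")
  }
  for (g in reaction_groups) {
    col_type <- c(col_type, rep("reaction", 3))
    col_name <- c(col_name, paste0(g, c("x", "y", "z")))
  }
  ncols <- length(col_type)
  n_el <- M + has_pt + N

  nrows <- if (case == 1) 18L else 22L
  A <- matrix(0, nrows, ncols)
  b <- numeric(nrows)
  row_labels <- c(t(outer(paste0("force_", CHAIN), c("x", "y", "z"), paste0)),
                  t(outer(paste0("moment_", CHAIN), c("x", "y", "z"), paste0)))
  if (case >= 2) row_labels <- c(row_labels, paste0("patella_force_", c("x", "y", "z")),
                                 "pq_ratio")

  el_paths <- c(lapply(mus_names, function(nm) eff_paths[[nm]]),
                if (has_pt) list(paths$patellar_tendon),
                lapply(lig_names, function(nm) paths[[nm]]))
  for (p in el_paths) if (is.null(p)) stop("missing path for an element")

  # --- force rows (9): segment k rows 3k-2..3k
  for (k in 1:3) {
    seg <- CHAIN[k]
    st <- states[[seg]]
    rows <- (3 * (k - 1) + 1):(3 * k)
    for (j in seq_len(n_el)) {
      A[rows, j] <- attachment_moment_arms(el_paths[[j]], seg, contacts$ankle)$force
    }
    b[rows] <- st$m * (st$a[i, ] - gravity) - if (k == 1) loads$S$S0[i, ] else c(0, 0, 0)
  }
  rblock <- function(group) {
    j0 <- n_el + 3 * (match(group, reaction_groups) - 1)
    (j0 + 1):(j0 + 3)
  }
  put_I <- function(rows, group, sgn) {
    A[rows, rblock(group)] <<- A[rows, rblock(group)] + sgn * diag(3)
  }
  put_I(1:3, "R1", -1)
  if (case == 4) {
    put_I(4:6, "R1", 1); put_I(4:6, "R2_med", -1); put_I(4:6, "R2_lat", -1)
    put_I(7:9, "R2_med", 1); put_I(7:9, "R2_lat", 1); put_I(7:9, "R3", -1)
    put_I(7:9, "Rpat", 1)
  } else {
    put_I(4:6, "R1", 1); put_I(4:6, "R2", -1)
    put_I(7:9, "R2", 1); put_I(7:9, "R3", -1)
    if (case >= 2) put_I(7:9, "Rpat", 1)
  }

  # --- moment rows (9): rows 9 + (3k-2..3k), about each proximal joint centre
  refs <- list(foot = contacts$ankle, shank = contacts$knee, thigh = contacts$hip)
  for (k in 1:3) {
    seg <- CHAIN[k]
    st <- states[[seg]]
    rows <- 9 + (3 * (k - 1) + 1):(3 * k)
    if (case <= 2) {
      distal_pt <- if (k == 1) NULL else states[[CHAIN[k - 1]]]$o[i, ]
      distal_segs <- if (k == 1) character(0) else CHAIN[seq_len(k - 1)]
      for (j in seq_len(n_el)) {
        A[rows, j] <- effective_moment_arm(el_paths[[j]], seg, refs[[seg]],
                                           distal_pt, distal_segs)
      }
      if (case == 2 && k == 3) {
        A[rows, rblock("Rpat")] <- skew3(contacts$pfj - refs$thigh)
      }
    } else {
      for (j in seq_len(n_el)) {
        A[rows, j] <- attachment_moment_arms(el_paths[[j]], seg, refs[[seg]])$moment
      }
      if (k == 2) {
        A[rows, rblock("R1")] <- skew3(contacts$ankle - refs$shank)
        if (case == 4) {
          A[rows, rblock("R2_med")] <- -skew3(contacts$knee_med - refs$shank)
          A[rows, rblock("R2_lat")] <- -skew3(contacts$knee_lat - refs$shank)
        }
      }
      if (k == 3) {
        if (case == 4) {
          A[rows, rblock("R2_med")] <- skew3(contacts$knee_med - refs$thigh)
          A[rows, rblock("R2_lat")] <- skew3(contacts$knee_lat - refs$thigh)
        } else {
          A[rows, rblock("R2")] <- skew3(contacts$knee - refs$thigh)
        }
        A[rows, rblock("Rpat")] <- skew3(contacts$pfj - refs$thigh)
      }
    }
    chat <- st$com[i, ] - st$o[i, ]
    Yg <- st$Y(i)
    rot <- as.numeric(Yg %*% st$alpha[i, ]) +
      cross3(st$omega[i, ], as.numeric(Yg %*% st$omega[i, ]))
    rhs <- st$m * cross3(chat, st$a[i, ] - gravity) + rot
    if (k == 1) {
      dhat <- ground$cop[i, ] - st$o[i, ]
      rhs <- rhs - cross3(dhat, loads$S$S0[i, ]) - loads$W$W0[i, ]
    } else if (case <= 2) {
      dhat <- states[[CHAIN[k - 1]]]$o[i, ] - st$o[i, ]
      rhs <- rhs - cross3(dhat, loads$S[[paste0("S", k - 1)]][i, ])
    }
    b[rows] <- rhs
  }

  # --- patellar rows (cases 2-4)
  if (case >= 2) {
    rows <- 19:21
    for (j in seq_len(n_el)) {
      A[rows, j] <- attachment_moment_arms(el_paths[[j]], "patella", contacts$pfj)$force
    }
    A[rows, rblock("Rpat")] <- -diag(3)
    b[rows] <- c(0, 0, 0)
    # P/Q ratio row: sum(rho_i F_i) - F_pt = 0
    A[22, seq_len(M)] <- pq$rho[mus_names]
    A[22, M + 1] <- -1
    b[22] <- 0
  }

  lower <- rep(0, ncols)
  upper <- numeric(ncols)
  upper[col_type == "muscle"] <- fmax[mus_names]
  if (has_pt) upper[col_type == "pt"] <- patellar_tendon_bound(pq$ratio, fmax, anatomy)
  if (N > 0) upper[col_type == "ligament"] <- lmax[lig_names]
  lower[col_type == "reaction"] <- -Inf
  upper[col_type == "reaction"] <- Inf

  reaction_basis <- NULL
  if (case == 4 && compression_only) {
    # compartment reactions expressed in the tibial frame; the axial (+y)
    # component transmits compression only
    B <- states$shank$R(i)
    reaction_basis <- list(R2_med = B, R2_lat = B)
    for (g in c("R2_med", "R2_lat")) {
      cols_g <- rblock(g)
      A[, cols_g] <- A[, cols_g] %*% B
      ycol <- cols_g[2]
      lower[ycol] <- 0
      upper[ycol] <- compression_cap
    }
  }

  structure(list(
    A = A, b = b, lower = lower, upper = upper,
    cols = data.frame(type = col_type, name = col_name, stringsAsFactors = FALSE),
    cost = col_type %in% c("muscle", "ligament"),
    case = case, reaction_groups = reaction_groups,
    reaction_basis = reaction_basis,
    rows = row_labels, contacts = contacts,
    counts = c(equations = nrows, unknowns = ncols)
  ), class = "fb_system")
}

#' @export
print.fb_system <- function(x, ...) {
  cat(sprintf("Equations of motion, case %d: %d scalar equations, %d unknowns\n",
              x$case, nrow(x$A), ncol(x$A)))
  if (x$case >= 2) {
    cat("  (18 segment rows + 3 patellar force rows + 1 P/Q row)\n")
  }
  tab <- table(x$cols$type)
  cat("  columns:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Dump a frame system as plain text
#'
#' Writes the matrix, right-hand side and bounds in a coordinate (row, col,
#' value) text format for debugging.
#'
#' @param sys an `fb_system`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_system <- function(sys, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%% segbody frame system, case %d, %d x %d",
                     sys$case, nrow(sys$A), ncol(sys$A)), con)
  nz <- which(sys$A != 0, arr.ind = TRUE)
  writeLines(sprintf("A %d %d %.17g", nz[, 1], nz[, 2], sys$A[nz]), con)
  writeLines(sprintf("b %d %.17g", seq_along(sys$b), sys$b), con)
  writeLines(sprintf("bound %d %.17g %.17g", seq_along(sys$lower), sys$lower, sys$upper), con)
  invisible(path)
}
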