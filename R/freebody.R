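# Front door: fit the segment-based musculoskeletal model to one movement
# trial. freebody() runs the whole chain -- calibration frames, per-frame
# absolute-orientation fits, quaternion kinematics, patellar model, muscle
# path geometry, equations of motion, per-frame constrained optimisation --
# and returns a classed object with the usual accessor methods.

#' Pipeline configuration
#'
#' @param cutoff low-pass cutoff for markers and ground reaction, Hz
#'   (`NA` = no filtering; synthetic trials are already smooth).
#' @param filter_order Butterworth order of the zero-phase filter.
#' @param sigma_max maximum muscle stress, N m^-2.
#' @param pcsa_multiplier PCSA scaling for the muscle force bounds.
#' @param condyle_half_distance case-4 half inter-condyle distance, m.
#' @param contact_force_threshold vertical GRF (N) above which a frame counts
#'   as ground contact (peak forces are taken over contact frames).
#' @param solver see [solver_control()].
#' @param theta_clamp small negative knee flexion angles (degrees) up to this
#'   magnitude are clamped to zero before the patellar model.
#' @param compression_only case-4 switch: tibiofemoral compartment reactions
#'   restricted to compression along the tibial axis (see
#'   [assemble_system()]).
#' @return list of settings.
#' @export
fb_config <- function(cutoff = NA, filter_order = 4, sigma_max = 3.139e5,
                      pcsa_multiplier = 2, condyle_half_distance = 0.02,
                      contact_force_threshold = 5, solver = solver_control(),
                      theta_clamp = 2, compression_only = FALSE) {
  list(cutoff = cutoff, filter_order = filter_order, sigma_max = sigma_max,
       pcsa_multiplier = pcsa_multiplier,
       condyle_half_distance = condyle_half_distance,
       contact_force_threshold = contact_force_threshold,
       solver = solver, theta_clamp = theta_clamp,
       compression_only = compression_only)
}

filter_trial <- function(trial, cutoff, order) {
  trial$markers <- lapply(trial$markers, lowpass, cutoff = cutoff,
                          rate = trial$rate, order = order)
  if (!is.null(trial$ground)) {
    trial$ground$force <- lowpass(trial$ground$force, cutoff, trial$rate, order)
    trial$ground$cop <- lowpass(trial$ground$cop, cutoff, trial$rate, order)
    trial$ground$free_moment <- lowpass(trial$ground$free_moment, cutoff,
                                        trial$rate, order)
  }
  trial
}

#' Fit the segment-based lower-limb model to a movement trial
#'
#' Estimates per-frame muscle, ligament and joint contact forces from marker
#' trajectories and ground reaction forces by minimising the cubic
#' load-sharing cost over the simultaneous, fully segment-based equations of
#' motion of the chosen case (1-4).
#'
#' @param trial an `fb_trial` with ground reaction (movement trial).
#' @param anatomy an `fb_anatomy`, already scaled to the subject (see
#'   [scale_anatomy()]).
#' @param case model case: 1 (no explicit patella), 2 (patella, hybrid moment
#'   rows), 3 (fully explicit joint reactions), 4 (medial/lateral tibiofemoral
#'   split).
#' @param calibration calibration trial; defaults to the `"calibration"`
#'   attribute of `trial`.
#' @param subject list with `mass` (kg) and optional `segment_lengths`,
#'   `pelvis_com`; defaults to the `"subject"` attribute of `trial`.
#' @param config see [fb_config()].
#' @param frames subset of frame indices to solve (default: all).
#' @return an object of class `"freebody"`; see [summary.freebody()],
#'   [coef.freebody()], [plot.freebody()], [residuals.freebody()].
#' @export
freebody <- function(trial, anatomy, case = 4, calibration = NULL,
                     subject = NULL, config = fb_config(), frames = NULL) {
  stopifnot(inherits(trial, "fb_trial"), inherits(anatomy, "fb_anatomy"),
            case %in% 1:4)
  if (is.null(calibration)) calibration <- attr(trial, "calibration")
  if (is.null(calibration)) stop("a calibration trial is required")
  if (is.null(subject)) subject <- attr(trial, "subject")
  if (is.null(subject$mass)) stop("subject mass is required")
  if (is.null(trial$ground)) stop("the movement trial has no ground reaction data")
  if (!is.na(config$cutoff)) {
    trial <- filter_trial(trial, config$cutoff, config$filter_order)
  }

  cal_frames <- build_segment_frames(calibration)
  poses <- fit_pose_series(trial, cal_frames)

  lengths <- subject$segment_lengths
  if (is.null(lengths)) {
    j0 <- cal_frames$joints0
    fm2 <- colMeans(calibration$markers$FM2)
    lengths <- c(foot = sqrt(sum((j0$ankle - fm2)^2)),
                 shank = sqrt(sum((j0$tibiofemoral - j0$ankle)^2)),
                 thigh = sqrt(sum((j0$hip - j0$tibiofemoral)^2)))
  }
  inertia <- if (is.null(subject$pelvis_com)) {
    inertial_params(subject$mass, lengths)
  } else {
    inertial_params(subject$mass, lengths, pelvis_com = subject$pelvis_com)
  }
  states <- segment_states(poses, inertia, trial$rate)
  loads <- intersegmental_loads(states, trial$ground)

  q_s0 <- matrix_to_quat(cal_frames$shank$R0)
  q_t0 <- matrix_to_quat(cal_frames$thigh$R0)
  fmax <- muscle_force_bounds(anatomy, config$sigma_max, config$pcsa_multiplier)
  lmax <- ligament_force_bounds(anatomy)
  mus_names <- names(fmax)

  pt_element <- list(
    name = "patellar_tendon",
    attachments = list(
      list(segment = "patella", point = anatomy$patellar_tendon$patella_point),
      list(segment = "shank", point = anatomy$landmarks$tibial_tuberosity$point)
    ),
    via_points = list(), cylinder = NA_character_
  )

  if (is.null(frames)) frames <- seq_len(trial$n)
  nf <- length(frames)
  n_el_names <- c(mus_names, "patellar_tendon",
                  vapply(anatomy$ligaments, function(l) l$name, character(1)))
  forces <- matrix(NA_real_, nf, length(n_el_names),
                   dimnames = list(NULL, n_el_names))
  theta <- numeric(nf); J <- rep(NA_real_, nf); resid <- rep(NA_real_, nf)
  feasible <- rep(FALSE, nf)
  reactions <- list()
  warm <- NULL
  sys1 <- NULL

  for (fi in seq_len(nf)) {
    i <- frames[fi]
    pose_at <- function(seg) list(q = poses[[seg]]$q[i, ], o = poses[[seg]]$o[i, ])
    tibia <- pose_at("shank"); femur <- pose_at("thigh")
    th <- knee_flexion_angle(tibia$q, femur$q, q_s0, q_t0)
    if (th < 0 && th > -config$theta_clamp) th <- 0
    theta[fi] <- th
    pat <- suppressWarnings(patella_pose(th, tibia, femur, anatomy))
    poses_frame <- list(foot = pose_at("foot"), shank = tibia, thigh = femur,
                        pelvis = pose_at("pelvis"), patella = pat)
    cyls <- list()
    for (cy in anatomy$cylinders) {
      cyls[[cy$id]] <- posed_cylinder(cy, poses_frame[[cy$segment]])
    }
    paths <- list()
    for (m in anatomy$muscles) paths[[m$name]] <- element_path(m, poses_frame, cyls)
    for (l in anatomy$ligaments) paths[[l$name]] <- element_path(l, poses_frame, cyls)
    paths$patellar_tendon <- element_path(pt_element, poses_frame, cyls)
    pq <- pq_state(anatomy, paths, pat, tibia, femur)

    sys <- assemble_system(case, paths, anatomy, states, loads, trial$ground,
                           i, pq, fmax, lmax,
                           condyle_half_distance = config$condyle_half_distance,
                           compression_only = isTRUE(config$compression_only))
    if (fi == 1) sys1 <- sys
    sol <- solve_frame(sys, config$solver, warm = warm)
    resid[fi] <- sol$residual
    if (sol$feasible) {
      feasible[fi] <- TRUE
      warm <- sol$x
      keep <- intersect(names(sol$forces), colnames(forces))
      forces[fi, keep] <- sol$forces[keep]
      if (case == 1) forces[fi, "patellar_tendon"] <-
          pq$ratio * sum(sol$forces[intersect(names(sol$forces), quad_names(anatomy))])
      J[fi] <- sol$J
      for (g in names(sol$reactions)) {
        if (is.null(reactions[[g]])) reactions[[g]] <- matrix(NA_real_, nf, 3)
        reactions[[g]][fi, ] <- sol$reactions[[g]]
      }
    }
  }

  solved_fraction <- 100 * mean(feasible)
  if (solved_fraction < 50) {
    stop(sprintf("optimization failed on %.1f%% of frames (solved %.1f%%)",
                 100 - solved_fraction, solved_fraction))
  }

  bw <- subject$mass * 9.81
  mag <- function(m) sqrt(rowSums(m^2))
  contact <- list(ankle = mag(reactions$R1), hip = mag(reactions$R3))
  if (case == 4) {
    contact$medial_tfj <- mag(reactions$R2_med)
    contact$lateral_tfj <- mag(reactions$R2_lat)
    contact$total_tfj <- mag(reactions$R2_med + reactions$R2_lat)
  } else {
    contact$total_tfj <- mag(reactions$R2)
  }
  if (case >= 2) contact$pfj <- mag(reactions$Rpat)

  time <- trial$time[frames]
  on_ground <- trial$ground$force[frames, 2] > config$contact_force_threshold
  pk <- vapply(contact, function(s) {
    v <- s[on_ground & feasible]
    if (length(v)) max(v, na.rm = TRUE) else NA_real_
  }, numeric(1))

  structure(list(
    case = case, time = time, theta = theta, forces = forces,
    reactions = reactions, contact_forces = contact,
    peaks = list(N = pk, BW = pk / bw),
    J = J, residual = resid, feasible = feasible,
    solved_fraction = solved_fraction, body_weight = bw,
    subject_mass = subject$mass, fmax = fmax, lmax = lmax,
    takeoff_time = detect_takeoff(trial),
    system = sys1, config = config,
    n_muscles = length(mus_names), n_ligaments = length(anatomy$ligaments)
  ), class = "freebody")
}

quad_names <- function(anatomy) {
  vapply(Filter(function(m) m$group == "quadriceps", anatomy$muscles),
         function(m) m$name, character(1))
}

#' @export
print.freebody <- function(x, ...) {
  cat(sprintf("Segment-based lower-limb force estimate (case %d)\n", x$case))
  cat(sprintf("  %d frames, solved %.1f%%, %d muscle elements, %d ligaments\n",
              length(x$time), x$solved_fraction, x$n_muscles, x$n_ligaments))
  cat("  peak joint contact forces (body weight):\n")
  bwp <- x$peaks$BW
  for (nm in names(bwp)) cat(sprintf("    %-12s %6.2f BW\n", nm, bwp[nm]))
  invisible(x)
}

#' Summary of a fitted model
#'
#' @param object a `freebody` fit.
#' @param ... unused.
#' @return list of class `"summary.freebody"`: peak contact forces (N and
#'   body weight), peak muscle forces and their utilisation (fraction of
#'   Fmax), solved fraction and take-off time.
#' @export
summary.freebody <- function(object, ...) {
  pk_mus <- apply(object$forces, 2, max, na.rm = TRUE)
  util <- pk_mus[names(object$fmax)] / object$fmax
  out <- list(case = object$case, peaks = object$peaks,
              solved_fraction = object$solved_fraction,
              peak_muscle_forces = pk_mus, utilisation = util,
              takeoff_time = object$takeoff_time,
              mean_residual = mean(object$residual[object$feasible]))
  class(out) <- "summary.freebody"
  out
}

#' @export
print.summary.freebody <- function(x, ...) {
  cat(sprintf("Case %d: solved %.1f%% of frames, mean equality residual %.2e\n",
              x$case, x$solved_fraction, x$mean_residual))
  if (!is.na(x$takeoff_time)) cat(sprintf("Take-off at %.3f s\n", x$takeoff_time))
  cat("\nPeak joint contact forces:\n")
  m <- rbind(N = x$peaks$N, BW = x$peaks$BW)
  print(round(m, 2))
  cat("\nPeak muscle forces (N, top 6 by utilisation):\n")
  ord <- order(x$utilisation, decreasing = TRUE)
  show <- utils::head(ord, 6)
  df <- data.frame(force_N = round(x$peak_muscle_forces[names(x$utilisation)[show]], 1),
                   utilisation = round(x$utilisation[show], 3))
  print(df)
  invisible(x)
}

#' Peak joint contact forces of a fit
#'
#' @param object a `freebody` fit.
#' @param units `"BW"` (body weight) or `"N"`.
#' @param ... unused.
#' @return named numeric vector of peak joint contact forces.
#' @export
coef.freebody <- function(object, units = c("BW", "N"), ...) {
  units <- match.arg(units)
  object$peaks[[units]]
}

#' Constraint residuals of a fit
#'
#' @param object a `freebody` fit.
#' @param ... unused.
#' @return per-frame maximum absolute equality residual (N / N m scale).
#' @export
residuals.freebody <- function(object, ...) object$residual

#' Plot joint contact forces and muscle forces over time
#'
#' @param x a `freebody` fit.
#' @param which `"contact"`, `"muscles"` or `"both"`.
#' @param ... passed to `matplot`.
#' @export
plot.freebody <- function(x, which = c("both", "contact", "muscles"), ...) {
  which <- match.arg(which)
  two <- which == "both"
  if (two) {
    op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
    on.exit(graphics::par(op))
  }
  if (which %in% c("both", "contact")) {
    cf <- do.call(cbind, x$contact_forces)
    graphics::matplot(x$time, cf / x$body_weight, type = "l", lty = 1,
                      xlab = "time (s)", ylab = "contact force (BW)",
                      main = sprintf("Joint contact forces, case %d", x$case), ...)
    graphics::legend("topleft", colnames(cf), col = seq_len(ncol(cf)), lty = 1,
                     cex = 0.7, bty = "n")
    if (!is.na(x$takeoff_time)) graphics::abline(v = x$takeoff_time, lty = 3)
  }
  if (which %in% c("both", "muscles")) {
    graphics::matplot(x$time, x$forces, type = "l", lty = 1,
                      xlab = "time (s)", ylab = "element force (N)",
                      main = "Muscle / ligament forces", ...)
    if (!is.na(x$takeoff_time)) graphics::abline(v = x$takeoff_time, lty = 3)
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# Run configuration (structured text file) and end-to-end pipeline

#' Default run configuration
#'
#' @return named list mirroring the YAML run-configuration file.
#' @export
default_run_config <- function() {
  list(case = 4, anatomy = "", calibration = "", trial = "", side = "right",
       cutoff = NA, sigma_max = 3.139e5, pcsa_multiplier = 2,
       condyle_half_distance = 0.02, subject_mass = NA,
       out_dir = "segbody_out", seed = 1)
}

#' Read / write a run configuration
#'
#' YAML key-value file; missing keys take the defaults of
#' [default_run_config()].
#'
#' @param path YAML file.
#' @return named configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- utils::modifyList(default_run_config(), yaml::read_yaml(path))
  if (!cfg$case %in% 1:4) stop("case must be 1, 2, 3 or 4")
  if (cfg$condyle_half_distance <= 0) stop("condyle_half_distance must be positive")
  cfg
}

#' @rdname read_run_config
#' @param cfg configuration list.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

config_hash <- function(cfg) {
  cfg <- cfg[setdiff(names(cfg), "out_dir")]
  s <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  r <- as.integer(charToRaw(s))
  h <- 0
  for (v in r) h <- (h * 31 + v) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full pipeline from a configuration
#'
#' Loads the anatomy and trials named in the configuration (synthetic inputs
#' when paths are `"synthetic"`), fits the model and writes tidy per-frame
#' forces (`forces.csv`), a JSON summary (`summary.json`: peaks, solved
#' fraction, configuration hash) and a log to the output directory.
#'
#' @param cfg configuration list (see [read_run_config()]) or path to one.
#' @return the `freebody` fit, invisibly.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  set.seed(cfg$seed)
  synth <- identical(cfg$anatomy, "synthetic") || identical(cfg$trial, "synthetic")
  if (synth) {
    spec <- synth_spec(seed = cfg$seed)
    anatomy <- make_toy_anatomy(spec)
    trial <- make_jump_trial(spec)
    calibration <- attr(trial, "calibration")
    subject <- attr(trial, "subject")
  } else {
    anatomy <- load_anatomy(cfg$anatomy)
    trial <- if (grepl("\\.trc$", cfg$trial, ignore.case = TRUE)) {
      read_force_csv(read_trc(cfg$trial, cfg$side), cfg$force, cfg$side)
    } else {
      read_trial_csv(cfg$trial, cfg$side)
    }
    calibration <- if (grepl("\\.trc$", cfg$calibration, ignore.case = TRUE)) {
      read_trc(cfg$calibration, cfg$side)
    } else {
      read_trial_csv(cfg$calibration, cfg$side)
    }
    subject <- list(mass = cfg$subject_mass)
  }
  config <- fb_config(cutoff = cfg$cutoff, sigma_max = cfg$sigma_max,
                      pcsa_multiplier = cfg$pcsa_multiplier,
                      condyle_half_distance = cfg$condyle_half_distance)
  fit <- freebody(trial, anatomy, case = cfg$case, calibration = calibration,
                  subject = subject, config = config)

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  tidy <- data.frame(
    frame = rep(seq_along(fit$time), ncol(fit$forces)),
    time = rep(fit$time, ncol(fit$forces)),
    element = rep(colnames(fit$forces), each = nrow(fit$forces)),
    force_N = as.vector(fit$forces)
  )
  utils::write.csv(tidy, file.path(cfg$out_dir, "forces.csv"), row.names = FALSE)
  smry <- list(case = fit$case, solved_fraction = fit$solved_fraction,
               peaks_N = as.list(fit$peaks$N), peaks_BW = as.list(fit$peaks$BW),
               takeoff_time = fit$takeoff_time, config_hash = config_hash(cfg))
  jsonlite::write_json(smry, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c(
    sprintf("segbody %s", as.character(utils::packageVersion("segbody"))),
    sprintf("config hash: %s", config_hash(cfg)),
    sprintf("case %d, solved %.1f%% of frames", fit$case, fit$solved_fraction),
    sprintf("peaks (BW): %s",
            paste(sprintf("%s=%.2f", names(fit$peaks$BW), fit$peaks$BW), collapse = ", "))
  ), file.path(cfg$out_dir, "run.log"))
  invisible(fit)
}
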