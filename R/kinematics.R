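# Segment kinematics from marker trajectories: segment-fixed frame
# construction at the calibration pose, per-frame absolute-orientation fits,
# and quaternion-based differentiation to angular velocity/acceleration.
#
# Global frame convention: x anterior, y superior, z medial-to-lateral for a
# right-side trial (left-side trials are mirrored in z on input). All
# positions in metres, angles in radians unless stated.

GRAVITY <- c(0, -9.81, 0)

# Marker labels expected per segment (calibration / movement trials).
SEGMENT_MARKERS <- list(
  foot = c("FCC", "FMT", "FM2", "TF"),
  shank = c("FAM", "TAM", "C1", "C2", "C3"),
  thigh = c("FLE", "FME", "T1", "T2", "T3"),
  pelvis = c("RASIS", "LASIS", "RPSIS", "LPSIS")
)

#' Construct a marker trial
#'
#' @param markers named list; each entry an n x 3 matrix of marker positions
#'   in the global frame (m), rows = frames.
#' @param rate sampling rate, Hz.
#' @param ground optional ground reaction: list with `force` (n x 3, N),
#'   `cop` (n x 3 centre of pressure, m) and `free_moment` (n x 3, N m;
#'   vertical free moment in the y component).
#' @param time optional time vector (defaults to `(0:(n-1))/rate`).
#' @return object of class `"fb_trial"`.
#' @export
fb_trial <- function(markers, rate, ground = NULL, time = NULL) {
  n <- nrow(markers[[1]])
  if (rate <= 0) stop("sample rate must be positive")
  for (lab in names(markers)) {
    if (nrow(markers[[lab]]) != n) stop("marker ", lab, " has inconsistent frame count")
  }
  if (!is.null(ground)) {
    if (nrow(ground$force) != n) stop("ground reaction is not synchronized with markers")
    if (any(!is.finite(ground$force))) stop("non-finite ground reaction force")
    if (is.null(ground$free_moment)) ground$free_moment <- matrix(0, n, 3)
  }
  if (is.null(time)) time <- (seq_len(n) - 1) / rate
  structure(list(markers = markers, rate = rate, ground = ground,
                 time = time, n = n), class = "fb_trial")
}

#' @export
print.fb_trial <- function(x, ...) {
  cat("Marker trial:", x$n, "frames @", x$rate, "Hz,",
      length(x$markers), "markers",
      if (!is.null(x$ground)) "(with ground reaction)" else "(no ground reaction)", "\n")
  invisible(x)
}

marker_at <- function(trial, label, frame) {
  m <- trial$markers[[label]]
  if (is.null(m)) stop("required marker missing from trial: ", label)
  m[frame, ]
}

#' Hip joint centre from pelvis geometry
#'
#' Regression offset from the mid-point of the anterior superior iliac spines,
#' expressed in the pelvis frame as fractions of the inter-ASIS width
#' (posterior, inferior, lateral). Right side.
#'
#' @param mid_asis mid-ASIS point (global, m).
#' @param R_pelvis pelvis rotation matrix (local to global).
#' @param asis_width inter-ASIS distance (m).
#' @param coef regression fractions along pelvis (x, y, z).
#' @return hip joint centre in global coordinates.
#' @export
hip_centre_regression <- function(mid_asis, R_pelvis, asis_width,
                                  coef = c(-0.19, -0.30, 0.36)) {
  as.numeric(mid_asis + R_pelvis %*% (coef * asis_width))
}

unit3 <- function(v, what = "vector") {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("degenerate frame: ", what, " has zero length (collinear landmarks?)")
  v / n
}

# Orthonormal frame from a primary y axis and an intermediate z axis:
# x = y x z_int (normalised), permanent z = x x y.
axes_from_y_zint <- function(y, z_int, segment) {
  y <- unit3(y, paste0(segment, " y-axis"))
  x <- unit3(cross3(y, z_int), paste0(segment, " x-axis"))
  z <- cross3(x, y)
  unname(cbind(x, y, z))
}

#' Build segment-fixed frames from a calibration trial
#'
#' Constructs the local coordinate system of each segment from the marker
#' positions of a standing calibration (anatomical position): the y-axis runs
#' from the distal to the proximal joint, an intermediate medial-to-lateral
#' z-axis is taken from anatomical landmarks, x completes the frame and the
#' permanent z is re-orthogonalised. The origin is the proximal joint centre,
#' except the pelvis whose origin is the mid-point of the ASIS markers. Marker
#' positions are re-expressed in each local frame for later pose fitting.
#'
#' @param calibration an `fb_trial` of the subject standing still.
#' @param segments which segments to construct.
#' @param frame calibration frame index used (marker positions are averaged
#'   over all frames when `frame = NULL`).
#' @return list of class `"fb_frames"`: per segment `R0` (local-to-global at
#'   calibration), `origin0` (global), `local` (named list of marker local
#'   coordinates); plus `joints0`, the calibration joint centres in global
#'   coordinates (ankle, tibiofemoral, hip).
#' @export
build_segment_frames <- function(calibration,
                                 segments = c("foot", "shank", "thigh", "pelvis"),
                                 frame = NULL) {
  pos <- function(label) {
    m <- calibration$markers[[label]]
    if (is.null(m)) stop("calibration is missing required marker ", label)
    if (is.null(frame)) colMeans(m) else m[frame, ]
  }
  ankle <- (pos("FAM") + pos("TAM")) / 2
  knee <- (pos("FLE") + pos("FME")) / 2
  mid_asis <- (pos("RASIS") + pos("LASIS")) / 2
  mid_psis <- (pos("RPSIS") + pos("LPSIS")) / 2

  # pelvis frame first: the hip centre regression is expressed in it
  z_int_p <- unit3(pos("RASIS") - pos("LASIS"), "pelvis z")
  x_int_p <- mid_asis - mid_psis
  y_p <- unit3(cross3(z_int_p, x_int_p), "pelvis y")
  x_p <- unit3(cross3(y_p, z_int_p), "pelvis x")
  R_pelvis <- unname(cbind(x_p, y_p, cross3(x_p, y_p)))
  asis_w <- sqrt(sum((pos("RASIS") - pos("LASIS"))^2))
  hip <- hip_centre_regression(mid_asis, R_pelvis, asis_w)

  defs <- list(
    foot = list(R = function() axes_from_y_zint(ankle - pos("FM2"),
                                                pos("FAM") - pos("TAM"), "foot"),
                origin = ankle),
    shank = list(R = function() axes_from_y_zint(knee - ankle,
                                                 pos("FAM") - pos("TAM"), "shank"),
                 origin = knee),
    thigh = list(R = function() axes_from_y_zint(hip - knee,
                                                 pos("FLE") - pos("FME"), "thigh"),
                 origin = hip),
    pelvis = list(R = function() R_pelvis, origin = mid_asis)
  )
  out <- list()
  for (seg in segments) {
    d <- defs[[seg]]
    if (is.null(d)) stop("no frame definition for segment ", seg)
    R0 <- d$R()
    labs <- intersect(SEGMENT_MARKERS[[seg]], names(calibration$markers))
    if (length(labs) < 3) stop("segment ", seg, " has fewer than 3 markers in calibration")
    local <- lapply(labs, function(lab) as.numeric(t(R0) %*% (pos(lab) - d$origin)))
    names(local) <- labs
    out[[seg]] <- list(R0 = R0, origin0 = d$origin, local = local)
  }
  out$joints0 <- list(ankle = ankle, tibiofemoral = knee, hip = hip)
  class(out) <- "fb_frames"
  out
}

#' Absolute orientation by the quaternion method
#'
#' Least-squares rigid transform (rotation + translation) between two
#' corresponding point sets, via the eigen-decomposition of the 4x4
#' quaternion matrix built from the cross-covariance of the centred points.
#' Minimises the sum of squared marker residuals.
#'
#' @param local p x 3 matrix of segment-local marker coordinates.
#' @param observed p x 3 matrix of observed global positions (same order).
#' @return list: `q` (unit quaternion local-to-global), `R` (3 x 3 rotation),
#'   `origin` (global position of the local origin), `rms` residual (m).
#' @export
fit_pose <- function(local, observed) {
  if (nrow(local) < 3) stop("pose fit needs at least 3 markers")
  if (nrow(local) != nrow(observed)) stop("point sets differ in size")
  a <- scale(local, scale = FALSE)
  b <- scale(observed, scale = FALSE)
  if (svd(a)$d[2] < 1e-10) stop("pose fit markers are collinear")
  M <- t(a) %*% b
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy, Szx - Sxz, Sxy - Syx,
    Syz - Szy, Sxx - Syy - Szz, Sxy + Syx, Szx + Sxz,
    Szx - Sxz, Sxy + Syx, -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx, Szx + Sxz, Syz + Szy, -Sxx - Syy + Szz
  ), nrow = 4, byrow = TRUE)
  e <- eigen(N, symmetric = TRUE)
  q <- e$vectors[, 1]
  if (q[1] < 0) q <- -q
  R <- quat_to_matrix(q)
  origin <- as.numeric(colMeans(observed) - R %*% colMeans(local))
  res <- observed - (t(R %*% t(local)) + matrix(origin, nrow(local), 3, byrow = TRUE))
  list(q = q, R = R, origin = origin, rms = sqrt(mean(rowSums(res^2))))
}

#' Fit segment poses for every frame of a trial
#'
#' Applies [fit_pose()] per frame and segment using the calibration local
#' coordinates. Markers missing (NA) in a frame are dropped provided at least
#' three remain; otherwise the frame is flagged unusable.
#'
#' @param trial an `fb_trial`.
#' @param frames an `fb_frames` calibration object.
#' @param segments segments to track.
#' @return named list per segment with `q` (n x 4, sign-continuous), `o`
#'   (n x 3 origin track), `rms` (n), `ok` (logical n); class `"fb_poses"`.
#' @export
fit_pose_series <- function(trial, frames,
                            segments = c("foot", "shank", "thigh", "pelvis")) {
  out <- list()
  for (seg in segments) {
    fr <- frames[[seg]]
    labs <- intersect(names(fr$local), names(trial$markers))
    if (length(labs) < 3) stop("segment ", seg, " has fewer than 3 tracked markers")
    L <- do.call(rbind, fr$local[labs])
    n <- trial$n
    Q <- matrix(NA_real_, n, 4); O <- matrix(NA_real_, n, 3)
    rms <- rep(NA_real_, n); ok <- rep(FALSE, n)
    for (i in seq_len(n)) {
      obs <- do.call(rbind, lapply(labs, function(lab) trial$markers[[lab]][i, ]))
      keep <- stats::complete.cases(obs)
      if (sum(keep) >= 3) {
        f <- fit_pose(L[keep, , drop = FALSE], obs[keep, , drop = FALSE])
        Q[i, ] <- f$q; O[i, ] <- f$origin; rms[i] <- f$rms; ok[i] <- TRUE
      }
    }
    if (!all(ok)) warning(sum(!ok), " frame(s) of segment ", seg,
                          " had <3 markers and were flagged")
    out[[seg]] <- list(q = quat_hemispherize(Q), o = O, rms = rms, ok = ok)
  }
  structure(out, class = "fb_poses", rate = trial$rate, n = trial$n)
}

#' Second central difference of a trajectory
#'
#' Acceleration of an n x 3 trajectory at the sampling rate; the end points
#' copy their interior neighbour.
#'
#' @param x n x 3 matrix of positions (m).
#' @param rate sampling rate, Hz.
#' @return n x 3 matrix of accelerations (m s^-2).
#' @export
accel_central <- function(x, rate) {
  n <- nrow(x)
  a <- matrix(0, n, 3)
  if (n >= 3) {
    a[2:(n - 1), ] <- (x[1:(n - 2), ] - 2 * x[2:(n - 1), ] + x[3:n, ]) * rate^2
    a[1, ] <- a[2, ]; a[n, ] <- a[n - 1, ]
  }
  a
}

# First central difference (one-sided at the ends).
deriv_central <- function(x, rate) {
  n <- nrow(x)
  d <- matrix(0, n, ncol(x))
  if (n >= 3) {
    d[2:(n - 1), ] <- (x[3:n, ] - x[1:(n - 2), ]) * rate / 2
    d[1, ] <- (x[2, ] - x[1, ]) * rate
    d[n, ] <- (x[n, ] - x[n - 1, ]) * rate
  } else if (n == 2) {
    d[1, ] <- d[2, ] <- (x[2, ] - x[1, ]) * rate
  }
  d
}

#' Differentiate segment poses
#'
#' Quaternion-based kinematics: the angular velocity is the vector part of
#' `2 * qdot x q*` (global frame), with the quaternion series hemispherised
#' first; angular acceleration and linear accelerations are central
#' differences at the sampling rate (one-sided at the end points).
#'
#' @param pose one segment's pose series (`q` n x 4, `o` n x 3).
#' @param rate sampling rate, Hz.
#' @return list: `omega`, `alpha` (n x 3, rad/s and rad/s^2, global frame).
#' @export
differentiate_poses <- function(pose, rate) {
  if (nrow(pose$q) < 5) stop("need at least 5 frames to differentiate")
  Q <- pose$q
  dots <- rowSums(Q[-1, , drop = FALSE] * Q[-nrow(Q), , drop = FALSE])
  if (any(dots < 0)) stop("quaternion series has uncorrected sign flips; hemispherize first")
  Qd <- deriv_central(Q, rate)
  omega <- t(vapply(seq_len(nrow(Q)), function(i) {
    2 * quat_mul(Qd[i, ], quat_conj(Q[i, ]))[2:4]
  }, numeric(3)))
  alpha <- deriv_central(omega, rate)
  list(omega = omega, alpha = alpha)
}

#' Global trajectory of a segment-fixed point
#'
#' @param pose one segment's pose series.
#' @param p_local fixed point in the segment frame.
#' @return n x 3 global trajectory.
#' @export
track_point <- function(pose, p_local) {
  n <- nrow(pose$q)
  t(vapply(seq_len(n), function(i) {
    pose$o[i, ] + as.numeric(quat_to_matrix(pose$q[i, ]) %*% p_local)
  }, numeric(3)))
}

#' Zero-phase low-pass filter
#'
#' Butterworth filter applied forward and backward (zero phase lag). Stands in
#' for the generalised cross-validated quintic-spline smoothing used on the
#' original trial data; the filter order and cutoff are configuration.
#'
#' @param x numeric vector or matrix (columns filtered independently).
#' @param cutoff cutoff frequency, Hz (must be below the Nyquist frequency).
#' @param rate sampling rate, Hz.
#' @param order Butterworth order before the forward-backward pass.
#' @return filtered series, same shape as `x`.
#' @export
lowpass <- function(x, cutoff, rate, order = 4) {
  if (cutoff >= rate / 2) stop("cutoff must be below the Nyquist frequency")
  if (cutoff <= 0) stop("cutoff must be positive")
  bf <- signal::butter(order, 2 * cutoff / rate, type = "low")
  filt1 <- function(v) {
    # centre the series and pad by odd reflection: the mean passes exactly and
    # the forward-backward edge transients are absorbed by the padding
    n <- length(v)
    mu <- mean(v)
    v0 <- v - mu
    pad <- min(n - 1, ceiling(3 * rate / cutoff))
    vp <- c(2 * v0[1] - v0[(pad + 1):2], v0, 2 * v0[n] - v0[(n - 1):(n - pad)])
    as.numeric(signal::filtfilt(bf, vp))[(pad + 1):(pad + n)] + mu
  }
  if (is.matrix(x)) apply(x, 2, filt1) else filt1(x)
}
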