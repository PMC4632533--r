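# Muscle and ligament path geometry at a posed frame: straight lines, via
# points (frictionless eyelets), and shortest-path wrapping around a cylinder
# (tangent line - geodesic helix - tangent line). Each path yields "action
# records": (segment, application point, force per 1 N tension) for every
# body the element touches. Unit tension applied through the records sums to
# zero force over all touched bodies (action-reaction closure).

#' Shortest path of a taut element around a cylinder
#'
#' If the straight chord between the two endpoints misses the cylinder the
#' straight segment is returned. Otherwise the path is the tangent line from
#' `p1` to the cylinder, the geodesic (helical) arc on the surface on the
#' configured wrap side, and the tangent line to `p2`; the axial coordinate is
#' distributed linearly along the unwrapped arc length, which makes the path
#' the global shortest on that side.
#'
#' @param p1,p2 endpoints, global frame (m). Must lie outside the cylinder.
#' @param cyl posed cylinder: list with `axis_point`, `axis_direction` (unit),
#'   `radius`, `wrap_side` (+1 counter-clockwise about the axis, -1 clockwise),
#'   all in the global frame.
#' @param arc_points number of points used to discretise the wrapped arc in
#'   the returned polyline (the length is computed in closed form).
#' @return list: `points` (polyline, k x 3), `length` (m), `wrapped` (logical),
#'   and when wrapped `t1`, `t2` (tangent points).
#' @export
cylinder_wrap <- function(p1, p2, cyl, arc_points = 24) {
  zc <- cyl$axis_direction / sqrt(sum(cyl$axis_direction^2))
  ref <- if (abs(zc[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  xc <- cross3(ref, zc); xc <- xc / sqrt(sum(xc^2))
  yc <- cross3(zc, xc)
  B <- cbind(xc, yc, zc)
  q1 <- as.numeric(t(B) %*% (p1 - cyl$axis_point))
  q2 <- as.numeric(t(B) %*% (p2 - cyl$axis_point))
  r1 <- q1[1:2]; r2 <- q2[1:2]
  R <- cyl$radius
  d1 <- sqrt(sum(r1^2)); d2 <- sqrt(sum(r2^2))
  if (d1 < R - 1e-9 || d2 < R - 1e-9) stop("path endpoint lies inside the wrapping cylinder")

  straight <- function() {
    list(points = rbind(p1, p2), length = sqrt(sum((p2 - p1)^2)), wrapped = FALSE)
  }
  # does the 2D chord cross the circle?
  v <- r2 - r1
  vv <- sum(v^2)
  if (vv < 1e-18) return(straight())
  tpar <- max(0, min(1, -sum(r1 * v) / vv))
  dmin <- sqrt(sum((r1 + tpar * v)^2))
  if (dmin >= R - 1e-9) return(straight())

  side <- cyl$wrap_side
  tangent_angle <- function(r, arriving) {
    d <- sqrt(sum(r^2))
    alpha <- atan2(r[2], r[1])
    beta <- acos(pmin(1, R / d))
    cand <- c(alpha + beta, alpha - beta)
    for (tt in cand) {
      Tp <- R * c(cos(tt), sin(tt))
      leg <- if (arriving) Tp - r else r - Tp   # direction of travel at T
      s <- cross2(Tp, leg)                      # >0: travelling CCW past T
      if (sign(s) == side) return(tt)
    }
    cand[1]
  }
  t1 <- tangent_angle(r1, arriving = TRUE)
  t2 <- tangent_angle(r2, arriving = FALSE)
  dwrap <- (side * (t2 - t1)) %% (2 * pi)
  T1 <- R * c(cos(t1), sin(t1)); T2 <- R * c(cos(t2), sin(t2))
  s1 <- sqrt(sum((T1 - r1)^2))
  sa <- R * dwrap
  s2 <- sqrt(sum((r2 - T2)^2))
  stot <- s1 + sa + s2
  dz <- q2[3] - q1[3]
  zT1 <- q1[3] + dz * s1 / stot
  zT2 <- q1[3] + dz * (s1 + sa) / stot
  len <- sqrt(stot^2 + dz^2)

  ts <- seq(0, dwrap, length.out = max(2, arc_points))
  arc <- t(vapply(ts, function(a) {
    ang <- t1 + side * a
    c(R * cos(ang), R * sin(ang), zT1 + (zT2 - zT1) * (a / dwrap))
  }, numeric(3)))
  to_global <- function(q) as.numeric(B %*% q) + cyl$axis_point
  pts <- rbind(p1, t(apply(arc, 1, to_global)), p2)
  list(points = pts, length = len, wrapped = TRUE,
       t1 = to_global(c(T1, zT1)), t2 = to_global(c(T2, zT2)))
}

# A cylinder carried by its segment, expressed in the global frame.
posed_cylinder <- function(cyl, pose) {
  Rm <- quat_to_matrix(pose$q)
  list(axis_point = pose$o + as.numeric(Rm %*% cyl$axis_point),
       axis_direction = as.numeric(Rm %*% cyl$axis_direction),
       radius = cyl$radius, wrap_side = cyl$wrap_side, segment = cyl$segment)
}

#' Path and action records of one element at a posed frame
#'
#' Maps the element's attachment and via points into the global frame through
#' the segment poses, inserts cylinder wrapping on flagged elements, and
#' derives the per-segment action records for unit tension: endpoints pull
#' along the adjacent edge, via points (frictionless eyelets, equal tension
#' throughout) receive the vector sum of the adjacent edge directions, and a
#' wrapped cylinder receives the net rope load applied on the cylinder axis at
#' the arc mid-point.
#'
#' @param element a muscle or ligament record from an `fb_anatomy`.
#' @param poses named list of single-frame poses (`q`, `o`) per segment.
#' @param cylinders list of posed cylinders named by id (see
#'   [posed_cylinder()]); only consulted when the element references one.
#' @return list of class `"fb_path"`: `points` (polyline, global), `length`,
#'   `records` (list of `segment`, `point`, `f` with `f` the force per 1 N),
#'   `name`.
#' @export
element_path <- function(element, poses, cylinders = list()) {
  nodes <- c(list(element$attachments[[1]]), element$via_points,
             element$attachments[-1])
  pts <- t(vapply(nodes, function(nd) {
    pose <- poses[[nd$segment]]
    if (is.null(pose)) stop("no pose for segment ", nd$segment, " (element ", element$name, ")")
    pose$o + as.numeric(quat_to_matrix(pose$q) %*% nd$point)
  }, numeric(3)))
  segs <- vapply(nodes, function(nd) nd$segment, character(1))

  wrap_rec <- NULL
  cyl_id <- if (is.null(element$cylinder)) NA else element$cylinder
  if (!is.na(cyl_id)) {
    cyl <- cylinders[[cyl_id]]
    if (is.null(cyl)) stop("posed cylinder '", cyl_id, "' not supplied")
    # wrap each edge; in practice a single edge crosses the cylinder
    new_pts <- pts[1, , drop = FALSE]; new_segs <- segs[1]
    for (i in seq_len(nrow(pts) - 1)) {
      w <- cylinder_wrap(pts[i, ], pts[i + 1, ], cyl)
      if (w$wrapped) {
        inner <- w$points[-c(1, nrow(w$points)), , drop = FALSE]
        new_pts <- rbind(new_pts, inner)
        new_segs <- c(new_segs, rep(NA_character_, nrow(inner)))
        u_in <- (w$points[1, ] - w$t1); u_in <- u_in / sqrt(sum(u_in^2))
        u_out <- (w$points[nrow(w$points), ] - w$t2); u_out <- u_out / sqrt(sum(u_out^2))
        mid <- (w$t1 + w$t2) / 2
        ax <- cyl$axis_direction
        mid_axis <- cyl$axis_point + sum((mid - cyl$axis_point) * ax) * ax
        wrap_rec <- list(segment = cyl$segment, point = mid_axis, f = u_in + u_out)
      }
      new_pts <- rbind(new_pts, pts[i + 1, ])
      new_segs <- c(new_segs, segs[i + 1])
    }
    pts <- new_pts; segs <- new_segs
  }

  k <- nrow(pts)
  edge <- function(i, j) {
    u <- pts[j, ] - pts[i, ]
    u / sqrt(sum(u^2))
  }
  records <- list()
  node_idx <- which(!is.na(segs))
  for (ii in seq_along(node_idx)) {
    i <- node_idx[ii]
    # pull along the adjacent polyline edges (for a node next to a wrapped
    # arc that is the tangent edge, not the node-to-node chord)
    f <- c(0, 0, 0)
    if (ii > 1) f <- f + edge(i, i - 1)
    if (ii < length(node_idx)) f <- f + edge(i, i + 1)
    records[[length(records) + 1]] <- list(segment = segs[i], point = pts[i, ], f = f)
  }
  if (!is.null(wrap_rec)) records[[length(records) + 1]] <- wrap_rec

  len <- sum(sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-k, , drop = FALSE])^2)))
  structure(list(points = pts, length = len, records = records,
                 name = element$name), class = "fb_path")
}

#' Attachment moment arms of a path on one segment
#'
#' Sum of cross products of application-point offsets (from the segment's
#' reference point, by convention its proximal joint centre) with the unit
#' force directions: the direct rotational effect of 1 N of tension, without
#' induced joint reactions.
#'
#' @param path an `fb_path`.
#' @param segment segment name.
#' @param ref_point reference point for moments (global frame).
#' @return list `force` (net force on the segment per 1 N) and `moment`
#'   (N m per N).
#' @export
attachment_moment_arms <- function(path, segment, ref_point) {
  f <- c(0, 0, 0); m <- c(0, 0, 0)
  for (rec in path$records) {
    if (identical(rec$segment, segment)) {
      f <- f + rec$f
      m <- m + cross3(rec$point - ref_point, rec$f)
    }
  }
  list(force = f, moment = m)
}

#' Effective moment arm of an element on a segment
#'
#' The overall rotational effect of 1 N of tension on the segment, including
#' the joint reaction forces the tension induces: the attachment moments plus
#' the moment of the reaction transmitted across the segment's distal joint.
#' The transmitted reaction per unit tension equals the net force the element
#' applies to all bodies distal of that joint (for a polyline this telescopes
#' to the edge crossing the joint). Moments are referenced to the segment's
#' proximal joint centre, where the proximal reaction has zero arm.
#'
#' @param path an `fb_path`.
#' @param segment segment name (`"foot"`, `"shank"`, `"thigh"`).
#' @param ref_point the segment's proximal joint centre (global).
#' @param distal_point contact point of the segment's distal joint (global);
#'   `NULL` for the foot, which has no distal joint in the chain.
#' @param distal_segments names of the bodies distal of that joint.
#' @return 3-vector `v` (N m per N).
#' @export
effective_moment_arm <- function(path, segment, ref_point,
                                 distal_point = NULL, distal_segments = character(0)) {
  att <- attachment_moment_arms(path, segment, ref_point)
  v <- att$moment
  if (!is.null(distal_point) && length(distal_segments)) {
    f_distal <- c(0, 0, 0)
    for (rec in path$records) {
      if (rec$segment %in% distal_segments) f_distal <- f_distal + rec$f
    }
    v <- v + cross3(distal_point - ref_point, f_distal)
  }
  v
}

#' Net force and moment of a path over all touched bodies
#'
#' Diagnostic for the action-reaction closure invariant: both should vanish
#' for any element, wrapped or not.
#'
#' @param path an `fb_path`.
#' @param ref_point moment reference (any point; the total is point-free when
#'   the total force is zero).
#' @return list `force`, `moment`.
#' @export
path_closure <- function(path, ref_point = c(0, 0, 0)) {
  f <- c(0, 0, 0); m <- c(0, 0, 0)
  for (rec in path$records) {
    f <- f + rec$f
    m <- m + cross3(rec$point - ref_point, rec$f)
  }
  list(force = f, moment = m)
}
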