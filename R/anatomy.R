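# Anatomical dataset: segments, muscle/ligament elements, wrapping cylinders,
# joint centres and landmarks, all in segment-local coordinates (metres, SI).
# The container mirrors the structure of cadaveric lower-limb datasets
# (origin/insertion/via-point tables per segment with PCSA per element).

SEGMENT_NAMES <- c("foot", "shank", "thigh", "pelvis", "patella")

#' Construct an anatomical dataset
#'
#' Builds and validates the container holding the musculoskeletal geometry:
#' rigid segments, muscle elements (origin, via points, insertion, PCSA),
#' ligaments with force upper bounds, wrapping cylinders, joint centres and
#' named landmarks. All coordinates are segment-local, in metres.
#'
#' @param segments data.frame with columns `name` (one of foot, shank, thigh,
#'   pelvis, patella), `ref_length` (joint-to-joint reference length, m) and
#'   `massless` (logical; the patella is massless).
#' @param muscles list of muscle elements. Each element is a list with fields
#'   `name`, `attachments` (ordered list of `list(segment, point)` from origin
#'   to insertion), `via_points` (possibly empty ordered list of
#'   `list(segment, point)`), `cylinder` (id of a wrapping cylinder or `NA`),
#'   `pcsa` (m^2) and `group` (`"quadriceps"` or `"other"`).
#' @param ligaments list of ligament elements: `name`, `attachments` (as for
#'   muscles), `upper_bound` (N).
#' @param cylinders list of wrapping cylinders: `id`, `segment`, `axis_point`
#'   (local, m), `axis_direction` (unit), `radius` (m), `wrap_side` (+1/-1,
#'   chirality of the wrap about the axis).
#' @param joint_centres named list (`ankle`, `tibiofemoral`, `patellofemoral`,
#'   `hip`), each `list(segment, point)` with the point expressed in the local
#'   frame of the distal segment of the joint.
#' @param landmarks named list of `list(segment, point)`; must contain
#'   `tibial_tuberosity` (patellar tendon insertion).
#' @param patellar_tendon list with `length` (m) and `patella_point` (local
#'   point on the patella where the tendon meets it; the patellar frame origin
#'   by convention).
#' @return object of class `"fb_anatomy"`.
#' @seealso [load_anatomy()], [scale_anatomy()], [muscle_force_bounds()]
#' @export
fb_anatomy <- function(segments, muscles, ligaments = list(), cylinders = list(),
                       joint_centres, landmarks = list(),
                       patellar_tendon = list(length = 0.05,
                                              patella_point = c(0, 0, 0))) {
  ds <- structure(list(
    segments = segments,
    muscles = muscles,
    ligaments = ligaments,
    cylinders = cylinders,
    joint_centres = joint_centres,
    landmarks = landmarks,
    patellar_tendon = patellar_tendon
  ), class = "fb_anatomy")
  validate_anatomy(ds)
  ds
}

#' Validate an anatomical dataset
#'
#' Checks referential integrity (every attachment, via point, cylinder and
#' joint centre references an existing segment), positivity of PCSA, ligament
#' bounds and cylinder radii, unit axis directions, and presence of the joint
#' centres required by the equations of motion.
#'
#' @param ds an `fb_anatomy` object.
#' @return `ds`, invisibly. Errors name the offending record.
#' @export
validate_anatomy <- function(ds) {
  segs <- ds$segments$name
  if (!all(segs %in% SEGMENT_NAMES)) {
    stop("unknown segment name(s): ", paste(setdiff(segs, SEGMENT_NAMES), collapse = ", "))
  }
  if (any(duplicated(segs))) stop("duplicated segment names")
  if (any(!is.finite(ds$segments$ref_length)) || any(ds$segments$ref_length <= 0)) {
    stop("segment reference lengths must be positive and finite")
  }
  if ("patella" %in% segs && !isTRUE(ds$segments$massless[segs == "patella"])) {
    stop("the patella segment must be flagged massless")
  }
  chk_point <- function(rec, what, owner) {
    if (!rec$segment %in% segs) {
      stop(sprintf("%s of '%s' references unknown segment '%s'", what, owner, rec$segment))
    }
    if (length(rec$point) != 3 || any(!is.finite(rec$point))) {
      stop(sprintf("%s of '%s' has a non-finite local point", what, owner))
    }
  }
  if (length(ds$muscles) == 0) stop("at least one muscle element is required")
  cyl_ids <- vapply(ds$cylinders, function(cy) cy$id, character(1))
  for (m in ds$muscles) {
    if (length(m$attachments) < 2) stop(sprintf("muscle '%s' needs >= 2 attachments", m$name))
    for (a in m$attachments) chk_point(a, "attachment", m$name)
    for (v in m$via_points) chk_point(v, "via point", m$name)
    if (!is.finite(m$pcsa) || m$pcsa <= 0) stop(sprintf("muscle '%s' has non-positive pcsa", m$name))
    if (!is.na(m$cylinder) && !(m$cylinder %in% cyl_ids)) {
      stop(sprintf("muscle '%s' references unknown cylinder '%s'", m$name, m$cylinder))
    }
    if (!m$group %in% c("quadriceps", "other")) {
      stop(sprintf("muscle '%s' has unknown group '%s'", m$name, m$group))
    }
  }
  for (l in ds$ligaments) {
    if (length(l$attachments) < 2) stop(sprintf("ligament '%s' needs >= 2 attachments", l$name))
    for (a in l$attachments) chk_point(a, "attachment", l$name)
    if (!is.finite(l$upper_bound) || l$upper_bound <= 0) {
      stop(sprintf("ligament '%s' must have a positive upper bound", l$name))
    }
  }
  for (cy in ds$cylinders) {
    if (!cy$segment %in% segs) stop(sprintf("cylinder '%s' references unknown segment '%s'",
                                            cy$id, cy$segment))
    if (cy$radius <= 0) stop(sprintf("cylinder '%s' has non-positive radius", cy$id))
    if (abs(sqrt(sum(cy$axis_direction^2)) - 1) > 1e-6) {
      stop(sprintf("cylinder '%s' axis direction is not unit length", cy$id))
    }
    if (!cy$wrap_side %in% c(-1, 1)) stop(sprintf("cylinder '%s' wrap_side must be +1/-1", cy$id))
  }
  need <- c("ankle", "tibiofemoral", "patellofemoral", "hip")
  missing <- setdiff(need, names(ds$joint_centres))
  if (length(missing)) stop("missing joint centre(s): ", paste(missing, collapse = ", "))
  for (jn in names(ds$joint_centres)) chk_point(ds$joint_centres[[jn]], "joint centre", jn)
  for (ln in names(ds$landmarks)) chk_point(ds$landmarks[[ln]], "landmark", ln)
  if (!"tibial_tuberosity" %in% names(ds$landmarks)) {
    stop("landmarks must include 'tibial_tuberosity'")
  }
  if (!is.finite(ds$patellar_tendon$length) || ds$patellar_tendon$length <= 0) {
    stop("patellar tendon length must be positive")
  }
  invisible(ds)
}

#' @export
print.fb_anatomy <- function(x, ...) {
  cat("Anatomical dataset:",
      length(x$muscles), "muscle elements,",
      length(x$ligaments), "ligaments,",
      length(x$cylinders), "wrapping cylinder(s)\n")
  cat("Segments:", paste(sprintf("%s (%.3f m)", x$segments$name, x$segments$ref_length),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Scale an anatomical dataset to a subject
#'
#' Scales every segment-local coordinate (attachments, via points, cylinder
#' axis points, joint centres, landmarks) componentwise by per-segment scale
#' factors, linearly within the Cartesian frame. The longitudinal (y) factor
#' is subject length / reference length; transverse (x, z) factors default to
#' the y factor and may be overridden per segment. Cylinder radii are scaled
#' by the mean transverse factor of their segment; the patellar tendon length
#' by the shank longitudinal factor. PCSA is not geometric in this schema and
#' is left untouched.
#'
#' @param ds an `fb_anatomy` object.
#' @param subject list with `segment_lengths` (named vector of subject
#'   joint-to-joint lengths, m; segments not named keep factor 1) and optional
#'   `transverse_scale` (named vector of transverse factors per segment).
#' @return a new, validated `fb_anatomy` with updated reference lengths.
#' @export
scale_anatomy <- function(ds, subject) {
  segs <- ds$segments$name
  sy <- setNames(rep(1, length(segs)), segs)
  if (!is.null(subject$segment_lengths)) {
    for (s in names(subject$segment_lengths)) {
      if (!s %in% segs) stop("unknown segment in subject lengths: ", s)
      if (!is.finite(subject$segment_lengths[[s]]) || subject$segment_lengths[[s]] <= 0) {
        stop("non-positive subject length for segment ", s)
      }
      sy[s] <- subject$segment_lengths[[s]] / ds$segments$ref_length[segs == s]
    }
  }
  st <- sy
  if (!is.null(subject$transverse_scale)) {
    for (s in names(subject$transverse_scale)) {
      if (!s %in% segs) stop("unknown segment in transverse scale: ", s)
      st[s] <- subject$transverse_scale[[s]]
    }
  }
  if (any(sy <= 0) || any(st <= 0)) stop("scale factors must be positive")
  fac <- function(seg) unname(c(st[seg], sy[seg], st[seg]))
  scale_pt <- function(rec) { rec$point <- rec$point * fac(rec$segment); rec }

  ds$muscles <- lapply(ds$muscles, function(m) {
    m$attachments <- lapply(m$attachments, scale_pt)
    m$via_points <- lapply(m$via_points, scale_pt)
    m
  })
  ds$ligaments <- lapply(ds$ligaments, function(l) {
    l$attachments <- lapply(l$attachments, scale_pt)
    l
  })
  ds$cylinders <- lapply(ds$cylinders, function(cy) {
    cy$axis_point <- cy$axis_point * fac(cy$segment)
    cy$radius <- cy$radius * st[cy$segment]
    cy
  })
  ds$joint_centres <- lapply(ds$joint_centres, scale_pt)
  ds$landmarks <- lapply(ds$landmarks, scale_pt)
  ds$patellar_tendon$length <- ds$patellar_tendon$length * sy["shank"]
  ds$patellar_tendon$patella_point <- ds$patellar_tendon$patella_point * fac("patella")
  ds$segments$ref_length <- ds$segments$ref_length * sy[segs]
  validate_anatomy(ds)
  ds
}

#' Muscle force upper bounds from PCSA
#'
#' `Fmax_i = pcsa_i * pcsa_multiplier * sigma_max`. The default maximum muscle
#' stress is 3.139e5 N m^-2 and the default PCSA multiplier is 2 (cadaveric
#' cross-sections doubled for a young athletic population); both are
#' configuration, not constants of the method.
#'
#' @param ds an `fb_anatomy` object.
#' @param sigma_max maximum muscle stress, N m^-2.
#' @param pcsa_multiplier dimensionless PCSA scaling.
#' @return named numeric vector of upper bounds (N), one per muscle element.
#' @export
muscle_force_bounds <- function(ds, sigma_max = 3.139e5, pcsa_multiplier = 2) {
  if (!is.finite(sigma_max) || sigma_max <= 0) stop("sigma_max must be positive")
  if (!is.finite(pcsa_multiplier) || pcsa_multiplier <= 0) stop("pcsa_multiplier must be positive")
  setNames(vapply(ds$muscles, function(m) m$pcsa * pcsa_multiplier * sigma_max, numeric(1)),
           vapply(ds$muscles, function(m) m$name, character(1)))
}

#' Ligament force upper bounds
#' @param ds an `fb_anatomy` object.
#' @return named numeric vector of ligament upper bounds (N).
#' @export
ligament_force_bounds <- function(ds) {
  setNames(vapply(ds$ligaments, function(l) l$upper_bound, numeric(1)),
           vapply(ds$ligaments, function(l) l$name, character(1)))
}
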