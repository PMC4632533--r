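# Anatomy file schema, version 1.
#
# A dataset on disk is either a directory of CSV tables or one JSON document
# of identical structure. The CSV directory contains:
#   segments.csv  : name, ref_length, massless
#   muscles.csv   : name, pcsa, group, cylinder,
#                   origin_segment, origin_x/y/z,
#                   insertion_segment, insertion_x/y/z
#   viapoints.csv : muscle, order, segment, x, y, z
#   ligaments.csv : name, upper_bound, origin_segment, origin_x/y/z,
#                   insertion_segment, insertion_x/y/z
#   cylinders.csv : id, segment, axis_x/y/z, dir_x/y/z, radius, wrap_side
#   joints.csv    : joint, segment, x, y, z
#   landmarks.csv : name, segment, x, y, z
#   meta.csv      : key, value (schema_version, patellar_tendon_length,
#                   patellar_tendon_x/y/z)
# Every file starts with the versioned header line "# segbody-anatomy v1".
# All coordinates are segment-local and in metres.

ANATOMY_SCHEMA_HEADER <- "# segbody-anatomy v1"

read_schema_csv <- function(path) {
  first <- readLines(path, n = 1)
  if (!identical(first, ANATOMY_SCHEMA_HEADER)) {
    stop("file ", basename(path), " is missing the anatomy schema header '",
         ANATOMY_SCHEMA_HEADER, "'")
  }
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

write_schema_csv <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(ANATOMY_SCHEMA_HEADER, con)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   con, row.names = FALSE, quote = FALSE)
}

#' Load an anatomical dataset from disk
#'
#' Accepts either a directory of CSV tables (see the schema documented in
#' `anatomy_io.R`) or a single JSON document of identical structure. The
#' loaded dataset is validated for referential integrity.
#'
#' @param path directory containing the CSV tables, or a `.json` file.
#' @return an `fb_anatomy` object.
#' @export
load_anatomy <- function(path) {
  if (dir.exists(path)) {
    load_anatomy_csv(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE) && file.exists(path)) {
    load_anatomy_json(path)
  } else {
    stop("anatomy path not found (expect a CSV directory or .json file): ", path)
  }
}

load_anatomy_csv <- function(dir) {
  need <- c("segments.csv", "muscles.csv", "viapoints.csv", "ligaments.csv",
            "cylinders.csv", "joints.csv", "landmarks.csv", "meta.csv")
  for (f in need) {
    if (!file.exists(file.path(dir, f))) stop("anatomy directory is missing ", f)
  }
  segments <- read_schema_csv(file.path(dir, "segments.csv"))
  segments$massless <- as.logical(segments$massless)
  mus <- read_schema_csv(file.path(dir, "muscles.csv"))
  vps <- read_schema_csv(file.path(dir, "viapoints.csv"))
  lig <- read_schema_csv(file.path(dir, "ligaments.csv"))
  cyl <- read_schema_csv(file.path(dir, "cylinders.csv"))
  jnt <- read_schema_csv(file.path(dir, "joints.csv"))
  lmk <- read_schema_csv(file.path(dir, "landmarks.csv"))
  meta <- read_schema_csv(file.path(dir, "meta.csv"))
  meta_val <- function(key) {
    i <- match(key, meta$key)
    if (is.na(i)) stop("meta.csv is missing key ", key)
    meta$value[i]
  }
  if (meta_val("schema_version") != "1") stop("unsupported anatomy schema version")

  muscles <- lapply(seq_len(nrow(mus)), function(i) {
    r <- mus[i, ]
    v <- vps[vps$muscle == r$name, , drop = FALSE]
    v <- v[order(v$order), , drop = FALSE]
    list(
      name = r$name,
      attachments = list(
        list(segment = r$origin_segment, point = c(r$origin_x, r$origin_y, r$origin_z)),
        list(segment = r$insertion_segment,
             point = c(r$insertion_x, r$insertion_y, r$insertion_z))
      ),
      via_points = lapply(seq_len(nrow(v)), function(j) {
        list(segment = v$segment[j], point = c(v$x[j], v$y[j], v$z[j]))
      }),
      cylinder = if (is.na(r$cylinder) || r$cylinder == "") NA_character_ else r$cylinder,
      pcsa = r$pcsa,
      group = r$group
    )
  })
  orphan <- setdiff(unique(vps$muscle), mus$name)
  if (length(orphan)) stop("viapoints.csv references unknown muscle(s): ",
                           paste(orphan, collapse = ", "))
  ligaments <- lapply(seq_len(nrow(lig)), function(i) {
    r <- lig[i, ]
    list(name = r$name,
         attachments = list(
           list(segment = r$origin_segment, point = c(r$origin_x, r$origin_y, r$origin_z)),
           list(segment = r$insertion_segment,
                point = c(r$insertion_x, r$insertion_y, r$insertion_z))
         ),
         upper_bound = r$upper_bound)
  })
  cylinders <- lapply(seq_len(nrow(cyl)), function(i) {
    r <- cyl[i, ]
    list(id = r$id, segment = r$segment,
         axis_point = c(r$axis_x, r$axis_y, r$axis_z),
         axis_direction = c(r$dir_x, r$dir_y, r$dir_z),
         radius = r$radius, wrap_side = r$wrap_side)
  })
  joint_centres <- setNames(lapply(seq_len(nrow(jnt)), function(i) {
    list(segment = jnt$segment[i], point = c(jnt$x[i], jnt$y[i], jnt$z[i]))
  }), jnt$joint)
  landmarks <- setNames(lapply(seq_len(nrow(lmk)), function(i) {
    list(segment = lmk$segment[i], point = c(lmk$x[i], lmk$y[i], lmk$z[i]))
  }), lmk$name)

  fb_anatomy(segments, muscles, ligaments, cylinders, joint_centres, landmarks,
             patellar_tendon = list(
               length = as.numeric(meta_val("patellar_tendon_length")),
               patella_point = c(as.numeric(meta_val("patellar_tendon_x")),
                                 as.numeric(meta_val("patellar_tendon_y")),
                                 as.numeric(meta_val("patellar_tendon_z")))))
}

load_anatomy_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(as.character(x$schema_version), "1")) {
    stop("unsupported anatomy schema version in ", path)
  }
  relist_pt <- function(p) list(segment = p$segment,
                                point = as.numeric(unlist(p$point)))
  segments <- do.call(rbind, lapply(x$segments, function(s) {
    data.frame(name = s$name, ref_length = s$ref_length,
               massless = isTRUE(s$massless), stringsAsFactors = FALSE)
  }))
  muscles <- lapply(x$muscles, function(m) {
    list(name = m$name,
         attachments = lapply(m$attachments, relist_pt),
         via_points = if (is.null(m$via_points)) list() else lapply(m$via_points, relist_pt),
         cylinder = if (is.null(m$cylinder) || is.na(m$cylinder)) NA_character_
                    else as.character(m$cylinder),
         pcsa = as.numeric(m$pcsa), group = m$group)
  })
  ligaments <- lapply(x$ligaments, function(l) {
    list(name = l$name, attachments = lapply(l$attachments, relist_pt),
         upper_bound = as.numeric(l$upper_bound))
  })
  cylinders <- lapply(x$cylinders, function(cy) {
    list(id = cy$id, segment = cy$segment,
         axis_point = as.numeric(unlist(cy$axis_point)),
         axis_direction = as.numeric(unlist(cy$axis_direction)),
         radius = as.numeric(cy$radius), wrap_side = as.numeric(cy$wrap_side))
  })
  fb_anatomy(segments, muscles, ligaments, cylinders,
             joint_centres = lapply(x$joint_centres, relist_pt),
             landmarks = lapply(x$landmarks, relist_pt),
             patellar_tendon = list(
               length = as.numeric(x$patellar_tendon$length),
               patella_point = as.numeric(unlist(x$patellar_tendon$patella_point))))
}

#' Write an anatomical dataset to disk
#'
#' Inverse of [load_anatomy()]: writes the CSV-directory form when `path` has
#' no `.json` extension, otherwise one JSON document. Round-trips exactly.
#'
#' @param ds an `fb_anatomy` object.
#' @param path target directory (CSV form) or `.json` file path.
#' @return `path`, invisibly.
#' @export
write_anatomy <- function(ds, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- list(
      schema_version = "1",
      segments = ds$segments,
      muscles = ds$muscles,
      ligaments = ds$ligaments,
      cylinders = ds$cylinders,
      joint_centres = ds$joint_centres,
      landmarks = ds$landmarks,
      patellar_tendon = ds$patellar_tendon
    )
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
    return(invisible(path))
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_schema_csv(ds$segments, file.path(path, "segments.csv"))

  att_cols <- function(el) {
    o <- el$attachments[[1]]; ins <- el$attachments[[length(el$attachments)]]
    c(origin_segment = o$segment, origin_x = o$point[1], origin_y = o$point[2],
      origin_z = o$point[3], insertion_segment = ins$segment,
      insertion_x = ins$point[1], insertion_y = ins$point[2], insertion_z = ins$point[3])
  }
  mus <- do.call(rbind, lapply(ds$muscles, function(m) {
    data.frame(name = m$name, pcsa = m$pcsa, group = m$group,
               cylinder = ifelse(is.na(m$cylinder), "", m$cylinder),
               t(att_cols(m)), stringsAsFactors = FALSE)
  }))
  num_cols <- c("pcsa", grep("_[xyz]$", names(mus), value = TRUE))
  for (cc in num_cols) mus[[cc]] <- as.numeric(mus[[cc]])
  write_schema_csv(mus, file.path(path, "muscles.csv"))

  vrows <- list()
  for (m in ds$muscles) {
    if (length(m$via_points)) {
      for (j in seq_along(m$via_points)) {
        v <- m$via_points[[j]]
        vrows[[length(vrows) + 1]] <- data.frame(
          muscle = m$name, order = j, segment = v$segment,
          x = v$point[1], y = v$point[2], z = v$point[3], stringsAsFactors = FALSE)
      }
    }
  }
  vps <- if (length(vrows)) do.call(rbind, vrows) else
    data.frame(muscle = character(), order = integer(), segment = character(),
               x = numeric(), y = numeric(), z = numeric())
  write_schema_csv(vps, file.path(path, "viapoints.csv"))

  lig <- if (length(ds$ligaments)) do.call(rbind, lapply(ds$ligaments, function(l) {
    d <- data.frame(name = l$name, upper_bound = l$upper_bound, t(att_cols(l)),
                    stringsAsFactors = FALSE)
    for (cc in grep("_[xyz]$", names(d), value = TRUE)) d[[cc]] <- as.numeric(d[[cc]])
    d
  })) else data.frame(name = character(), upper_bound = numeric(),
                      origin_segment = character(), origin_x = numeric(),
                      origin_y = numeric(), origin_z = numeric(),
                      insertion_segment = character(), insertion_x = numeric(),
                      insertion_y = numeric(), insertion_z = numeric())
  write_schema_csv(lig, file.path(path, "ligaments.csv"))

  cyl <- if (length(ds$cylinders)) do.call(rbind, lapply(ds$cylinders, function(cy) {
    data.frame(id = cy$id, segment = cy$segment,
               axis_x = cy$axis_point[1], axis_y = cy$axis_point[2], axis_z = cy$axis_point[3],
               dir_x = cy$axis_direction[1], dir_y = cy$axis_direction[2],
               dir_z = cy$axis_direction[3], radius = cy$radius, wrap_side = cy$wrap_side,
               stringsAsFactors = FALSE)
  })) else data.frame(id = character(), segment = character(), axis_x = numeric(),
                      axis_y = numeric(), axis_z = numeric(), dir_x = numeric(),
                      dir_y = numeric(), dir_z = numeric(), radius = numeric(),
                      wrap_side = numeric())
  write_schema_csv(cyl, file.path(path, "cylinders.csv"))

  jnt <- do.call(rbind, lapply(names(ds$joint_centres), function(jn) {
    j <- ds$joint_centres[[jn]]
    data.frame(joint = jn, segment = j$segment, x = j$point[1], y = j$point[2],
               z = j$point[3], stringsAsFactors = FALSE)
  }))
  write_schema_csv(jnt, file.path(path, "joints.csv"))

  lmk <- do.call(rbind, lapply(names(ds$landmarks), function(ln) {
    l <- ds$landmarks[[ln]]
    data.frame(name = ln, segment = l$segment, x = l$point[1], y = l$point[2],
               z = l$point[3], stringsAsFactors = FALSE)
  }))
  write_schema_csv(lmk, file.path(path, "landmarks.csv"))

  meta <- data.frame(
    key = c("schema_version", "patellar_tendon_length", "patellar_tendon_x",
            "patellar_tendon_y", "patellar_tendon_z"),
    value = c("1", sprintf("%.17g", ds$patellar_tendon$length),
              sprintf("%.17g", ds$patellar_tendon$patella_point)),
    stringsAsFactors = FALSE)
  write_schema_csv(meta, file.path(path, "meta.csv"))
  invisible(path)
}
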