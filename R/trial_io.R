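# Trial file formats. The documented CSV dialect (one column per marker
# coordinate, labels as column prefixes) is the generator's native output;
# TRC (text) marker files with a separate force CSV are also accepted.
# Left-side trials are mirrored in z on input so the right-side conventions
# apply throughout.

TRIAL_SCHEMA_HEADER <- "# segbody-trial v1"

#' Write a trial in the documented CSV dialect
#'
#' Columns: `time`, `<LABEL>_X/_Y/_Z` per marker (m) and, when ground reaction
#' is present, `GRF_X/_Y/_Z` (N), `COP_X/_Y/_Z` (m), `FREEMOM_X/_Y/_Z` (N m).
#' The first line is a versioned header comment carrying the sample rate.
#'
#' @param trial an `fb_trial`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(trial, path) {
  df <- data.frame(time = trial$time)
  for (lab in names(trial$markers)) {
    m <- trial$markers[[lab]]
    df[[paste0(lab, "_X")]] <- m[, 1]
    df[[paste0(lab, "_Y")]] <- m[, 2]
    df[[paste0(lab, "_Z")]] <- m[, 3]
  }
  if (!is.null(trial$ground)) {
    for (i in 1:3) df[[paste0("GRF_", c("X", "Y", "Z")[i])]] <- trial$ground$force[, i]
    for (i in 1:3) df[[paste0("COP_", c("X", "Y", "Z")[i])]] <- trial$ground$cop[, i]
    for (i in 1:3) df[[paste0("FREEMOM_", c("X", "Y", "Z")[i])]] <- trial$ground$free_moment[, i]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%s rate=%.10g", TRIAL_SCHEMA_HEADER, trial$rate), con)
  utils::write.csv(format(df, digits = 17, trim = TRUE), con,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trial from the documented CSV dialect
#'
#' @param path CSV file written by [write_trial_csv()] (or conforming to the
#'   dialect).
#' @param side `"right"` or `"left"`; left-side trials are mirrored in z.
#' @return an `fb_trial`.
#' @export
read_trial_csv <- function(path, side = "right") {
  first <- readLines(path, n = 1)
  if (!startsWith(first, TRIAL_SCHEMA_HEADER)) {
    stop("file is missing the trial schema header '", TRIAL_SCHEMA_HEADER, "'")
  }
  rate <- as.numeric(sub(".*rate=", "", first))
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!is.finite(rate)) rate <- 1 / stats::median(diff(df$time))
  zf <- if (identical(side, "left")) -1 else 1
  xcols <- grep("_X$", names(df), value = TRUE)
  labs <- sub("_X$", "", setdiff(xcols, c("GRF_X", "COP_X", "FREEMOM_X")))
  markers <- lapply(labs, function(lab) {
    cbind(df[[paste0(lab, "_X")]], df[[paste0(lab, "_Y")]], zf * df[[paste0(lab, "_Z")]])
  })
  names(markers) <- labs
  ground <- NULL
  if ("GRF_X" %in% names(df)) {
    ground <- list(
      force = cbind(df$GRF_X, df$GRF_Y, zf * df$GRF_Z),
      cop = cbind(df$COP_X, df$COP_Y, zf * df$COP_Z),
      free_moment = cbind(zf * df$FREEMOM_X, zf * df$FREEMOM_Y, df$FREEMOM_Z)
    )
  }
  fb_trial(markers, rate, ground = ground, time = df$time)
}

#' Read a TRC marker file
#'
#' Minimal reader for the tab-separated TRC motion-capture format: the data
#' rate, units and marker labels are taken from the standard header rows.
#' Millimetre files are converted to metres.
#'
#' @param path TRC file.
#' @param side `"right"` or `"left"` (left mirrored in z).
#' @return an `fb_trial` without ground reaction (see [read_force_csv()]).
#' @export
read_trc <- function(path, side = "right") {
  lines <- readLines(path)
  if (length(lines) < 6) stop("not a TRC file: ", path)
  hdr <- strsplit(lines[2], "\t")[[1]]
  val <- strsplit(lines[3], "\t")[[1]]
  rate <- as.numeric(val[match("DataRate", hdr)])
  units <- val[match("Units", hdr)]
  lab_row <- strsplit(lines[4], "\t")[[1]]
  labs <- lab_row[-(1:2)]
  labs <- labs[labs != ""]
  dat <- utils::read.table(text = lines[-(1:5)], sep = "\t", header = FALSE,
                           fill = TRUE, blank.lines.skip = TRUE)
  time <- dat[[2]]
  scale <- if (identical(tolower(units), "mm")) 1e-3 else 1
  zf <- if (identical(side, "left")) -1 else 1
  markers <- list()
  for (i in seq_along(labs)) {
    cols <- 2 + (3 * (i - 1) + 1):(3 * i)
    markers[[labs[i]]] <- cbind(dat[[cols[1]]], dat[[cols[2]]],
                                zf * dat[[cols[3]]]) * scale
  }
  fb_trial(markers, rate, time = time)
}

#' Read a ground-reaction CSV and attach it to a trial
#'
#' The force file carries `time, GRF_X..Z, COP_X..Z, FREEMOM_X..Z` columns
#' (the trial dialect without markers). Samples are linearly interpolated onto
#' the trial's time base.
#'
#' @param trial an `fb_trial` (e.g. from [read_trc()]).
#' @param path force CSV.
#' @param side `"right"` or `"left"`.
#' @return the trial with ground reaction attached.
#' @export
read_force_csv <- function(trial, path, side = "right") {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  zf <- if (identical(side, "left")) -1 else 1
  interp <- function(col, flip = FALSE) {
    y <- stats::approx(df$time, df[[col]], xout = trial$time, rule = 2)$y
    if (flip) zf * y else y
  }
  trial$ground <- list(
    force = cbind(interp("GRF_X"), interp("GRF_Y"), interp("GRF_Z", TRUE)),
    cop = cbind(interp("COP_X"), interp("COP_Y"), interp("COP_Z", TRUE)),
    free_moment = cbind(interp("FREEMOM_X", TRUE), interp("FREEMOM_Y", TRUE),
                        interp("FREEMOM_Z"))
  )
  trial
}
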