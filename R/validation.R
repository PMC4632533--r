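# Waveform comparison: Geers' magnitude/phase error decomposition between a
# measured and a calculated curve, and composite (take-off aligned) mean
# curves across trials.

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Geers' metric between two sampled curves
#'
#' Decomposes the discrepancy between a measured curve m(t) and a calculated
#' curve c(t) over a window `[t1, t2]` into a magnitude error
#' `M = sqrt(Vcc/Vmm) - 1` (insensitive to phase) and a phase error
#' `P = (1/pi) * acos(Vmc / sqrt(Vmm*Vcc))` (insensitive to magnitude), where
#' `Vmm`, `Vcc`, `Vmc` are the mean squared/cross energy integrals over the
#' window, computed by trapezoidal integration after linear resampling onto a
#' common grid.
#'
#' @param measured,calculated lists with `t` (time) and `y` (value), or
#'   two-column matrices/data.frames (time, value).
#' @param window comparison window `c(t1, t2)`; defaults to the overlap of the
#'   two curves.
#' @param n_grid number of resampling points.
#' @return object of class `"fb_geers"`: `M`, `P`, `Vmm`, `Vcc`, `Vmc`,
#'   `window`.
#' @export
geers <- function(measured, calculated, window = NULL, n_grid = 512) {
  as_curve <- function(x) {
    if (is.list(x) && !is.null(x$t)) list(t = as.numeric(x$t), y = as.numeric(x$y))
    else list(t = as.numeric(x[, 1]), y = as.numeric(x[, 2]))
  }
  m <- as_curve(measured); cc <- as_curve(calculated)
  if (is.null(window)) {
    window <- c(max(min(m$t), min(cc$t)), min(max(m$t), max(cc$t)))
  }
  if (window[2] <= window[1]) stop("comparison window is empty (disjoint time supports?)")
  tt <- seq(window[1], window[2], length.out = n_grid)
  mi <- stats::approx(m$t, m$y, xout = tt)$y
  ci <- stats::approx(cc$t, cc$y, xout = tt)$y
  dt <- window[2] - window[1]
  Vmm <- trapz(tt, mi^2) / dt
  Vcc <- trapz(tt, ci^2) / dt
  Vmc <- trapz(tt, mi * ci) / dt
  if (Vmm <= 0 || Vcc <= 0) stop("Geers metric undefined: a curve has zero energy in the window")
  M <- sqrt(Vcc / Vmm) - 1
  P <- acos(max(-1, min(1, Vmc / sqrt(Vmm * Vcc)))) / pi
  structure(list(M = M, P = P, Vmm = Vmm, Vcc = Vcc, Vmc = Vmc, window = window),
            class = "fb_geers")
}

#' @export
print.fb_geers <- function(x, ...) {
  cat(sprintf("Geers metric: M = %+.4f (magnitude), P = %.4f (phase) over [%g, %g]\n",
              x$M, x$P, x$window[1], x$window[2]))
  invisible(x)
}

#' Composite curve aligned at take-off
#'
#' Re-indexes each trial's force series to time-to-event (t - t_takeoff),
#' resamples onto a common grid spanning the overlap of all trials and
#' averages. Optionally normalises each trial by a per-trial maximum (e.g.
#' maximum force capability) before averaging.
#'
#' @param trials list of curves (`t`, `y`).
#' @param event_times numeric vector, one take-off time per trial.
#' @param normalize per-trial divisors (same length), or `NULL`.
#' @param n_grid grid size.
#' @return list `t` (time relative to the event) and `y` (mean curve).
#' @export
composite_curve <- function(trials, event_times, normalize = NULL, n_grid = 256) {
  if (length(trials) < 1) stop("at least one trial required")
  if (length(event_times) != length(trials)) stop("one event time per trial required")
  shifted <- Map(function(tr, ev) list(t = tr$t - ev, y = tr$y), trials, event_times)
  lo <- max(vapply(shifted, function(s) min(s$t), numeric(1)))
  hi <- min(vapply(shifted, function(s) max(s$t), numeric(1)))
  if (hi <= lo) stop("trials have disjoint time supports after alignment")
  tt <- seq(lo, hi, length.out = n_grid)
  ys <- vapply(seq_along(shifted), function(i) {
    y <- stats::approx(shifted[[i]]$t, shifted[[i]]$y, xout = tt)$y
    if (!is.null(normalize)) y <- y / normalize[i]
    y
  }, numeric(n_grid))
  list(t = tt, y = rowMeans(ys))
}
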