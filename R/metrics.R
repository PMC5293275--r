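# Published observables computed from simulation traces: cell-body and
# nucleus lengths, lateral nucleus deformation ratios, speeds, direction
# angles, trough counting and the pass/block classification. All metrics are
# pure functions of their inputs.

#' Cell-body length along the migration direction
#'
#' The longest separation between front and rear parts of the membrane,
#' implemented as the range of node positions projected on the migration
#' direction (the unprojected diameter is available via
#' \code{projected = FALSE}). The nucleus length N(t) is the same measure on
#' the nucleus curve.
#'
#' @param curve a [boundary_curve()] or M x 2 position matrix.
#' @param dir unit migration direction.
#' @param projected if FALSE, return the maximum pairwise distance instead.
#' @return length in cm.
#' @export
body_length <- function(curve, dir = c(0, 1), projected = TRUE) {
  X <- if (inherits(curve, "boundary_curve")) curve$X else as.matrix(curve)
  if (projected) {
    d <- dir / sqrt(sum(dir^2))
    pr <- X %*% d
    max(pr) - min(pr)
  } else {
    max(stats::dist(X))
  }
}

#' Lateral deformation ratio of the nucleus from live marker state
#'
#' W/E marker distances to the advected nucleus-center marker, normalized by
#' their initial values; their mean is the lateral deformation ratio (1 = no
#' deformation, < 1 = inward/lateral compression).
#'
#' @param cell a [glioma_cell()] whose \code{markers$Xnc} has been advected.
#' @return list with \code{Lperp}, \code{W}, \code{E}.
#' @export
deformation_ratio <- function(cell) {
  mk <- cell$markers
  if (is.null(mk) || is.null(mk$refW)) stop("markers not initialized")
  XW <- cell$nucleus$X[mk$iW, ]
  XE <- cell$nucleus$X[mk$iE, ]
  W <- sqrt(sum((XW - mk$Xnc)^2)) / mk$refW
  E <- sqrt(sum((XE - mk$Xnc)^2)) / mk$refE
  list(Lperp = (W + E) / 2, W = W, E = E)
}

#' Nucleus deformation ratio at a trace time
#'
#' @param trace a trace data frame from [run_simulation()].
#' @param t time (s); the nearest recorded sample is used.
#' @return list with \code{Lperp}, \code{W}, \code{E}.
#' @export
nucleus_deformation <- function(trace, t) {
  if (!all(c("Lperp", "LperpW", "LperpE") %in% names(trace)))
    stop("trace does not carry deformation markers")
  i <- which.min(abs(trace$t - t))
  list(Lperp = trace$Lperp[i], W = trace$LperpW[i], E = trace$LperpE[i])
}

#' Average migration speed over a time window
#'
#' Membrane-centroid displacement over the window divided by its duration,
#' in um/h.
#'
#' @param trace trace data frame with \code{t}, \code{cx}, \code{cy}.
#' @param window length-2 c(t0, t1) in seconds; default the whole trace.
#' @return speed in um/h.
#' @export
average_speed <- function(trace, window = range(trace$t)) {
  stopifnot(window[2] > window[1])
  i0 <- which.min(abs(trace$t - window[1]))
  i1 <- which.min(abs(trace$t - window[2]))
  if (i0 == i1) stop("window lies within a single trace sample")
  disp <- sqrt((trace$cx[i1] - trace$cx[i0])^2 +
                 (trace$cy[i1] - trace$cy[i0])^2)
  disp / (trace$t[i1] - trace$t[i0]) * 3.6e7   # cm/s -> um/h
}

#' Binned speed time series
#'
#' Centroid speed per time bin, for stop-and-go (saltatory) migration plots.
#'
#' @param trace trace data frame.
#' @param bin bin width (s).
#' @return data frame with \code{t} (bin midpoints) and \code{speed} (um/h).
#' @export
speed_series <- function(trace, bin) {
  edges <- seq(min(trace$t), max(trace$t), by = bin)
  if (length(edges) < 2) stop("trace shorter than one bin")
  out <- data.frame(t = numeric(0), speed = numeric(0))
  for (i in 1:(length(edges) - 1)) {
    sp <- try(average_speed(trace, c(edges[i], edges[i + 1])), silent = TRUE)
    if (!inherits(sp, "try-error"))
      out <- rbind(out, data.frame(t = (edges[i] + edges[i + 1]) / 2,
                                   speed = sp))
  }
  out
}

#' Classify the gap-passing outcome of a run
#'
#' Three-way classification against the line through the intercellular gap:
#' \emph{passed} when the entire nucleus has crossed the gap line before
#' T_end (the first such time is the passing time); \emph{in_process} when
#' the membrane front has entered the gap but the nucleus has not fully
#' crossed; \emph{non_invasive} otherwise.
#'
#' @param trace trace data frame with \code{nucleus_min_y} and
#'   \code{membrane_max_y}.
#' @param gap_line_y y-coordinate of the gap line (cm).
#' @param T_end classification horizon (s); default the end of the trace.
#' @return list with \code{status} and \code{passing_time} (s, only present
#'   when passed).
#' @export
classify_passing <- function(trace, gap_line_y, T_end = max(trace$t)) {
  tr <- trace[trace$t <= T_end, , drop = FALSE]
  crossed <- tr$nucleus_min_y > gap_line_y
  if (any(crossed)) {
    return(list(status = "passed", passing_time = tr$t[which(crossed)[1]]))
  }
  entered <- any(tr$membrane_max_y > gap_line_y)
  list(status = if (entered) "in_process" else "non_invasive",
       passing_time = NULL)
}

#' Count troughs of a deformation series
#'
#' Number of local minima below \code{baseline} whose times are separated by
#' at least \code{min_separation}. Large inward nucleus deformations recur
#' each time the cell squeezes through a gap; this counts those events.
#'
#' @param series numeric values (e.g. the lateral deformation ratio).
#' @param baseline threshold below which a minimum counts.
#' @param min_separation minimum spacing between counted troughs, in the
#'   units of \code{t}.
#' @param t timestamps; defaults to the sample index.
#' @return list with \code{count} and \code{times}.
#' @export
count_troughs <- function(series, baseline = 0.9, min_separation = 1800,
                          t = seq_along(series)) {
  n <- length(series)
  stopifnot(n >= 3, length(t) == n)
  is_min <- c(FALSE, series[2:(n - 1)] < series[1:(n - 2)] &
                series[2:(n - 1)] <= series[3:n], FALSE)
  cand <- which(is_min & series < baseline)
  times <- numeric(0)
  last <- -Inf
  for (i in cand) {
    if (t[i] - last >= min_separation) {
      times <- c(times, t[i])
      last <- t[i]
    }
  }
  list(count = length(times), times = times)
}

#' Signed direction angle from vertical
#'
#' Angle of a displacement from the +y axis in degrees; positive toward +x
#' (north-east), negative toward -x (north-west).
#'
#' @param dx,dy displacement components (vectorized).
#' @return angle in degrees.
#' @export
direction_angle <- function(dx, dy) {
  atan2(dx, dy) * 180 / pi
}

#' Direction-angle time series of a trace
#'
#' Windowed centroid displacements converted to angles from vertical; when a
#' window's displacement is below \code{min_disp} the previous angle is
#' carried forward (the angle is undefined for a stationary cell).
#'
#' @param trace trace data frame.
#' @param window window length (s).
#' @param min_disp minimum displacement (cm) for a defined angle.
#' @return data frame with \code{t} and \code{angle} (degrees).
#' @export
direction_angle_series <- function(trace, window, min_disp) {
  edges <- seq(min(trace$t), max(trace$t), by = window)
  ang <- NA_real_
  out <- data.frame(t = numeric(0), angle = numeric(0))
  for (i in seq_len(length(edges) - 1)) {
    i0 <- which.min(abs(trace$t - edges[i]))
    i1 <- which.min(abs(trace$t - edges[i + 1]))
    dx <- trace$cx[i1] - trace$cx[i0]
    dy <- trace$cy[i1] - trace$cy[i0]
    if (sqrt(dx^2 + dy^2) >= min_disp) ang <- direction_angle(dx, dy)
    out <- rbind(out, data.frame(t = edges[i + 1], angle = ang))
  }
  out
}
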