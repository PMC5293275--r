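# The elongation/retraction migration cycle and the chemotaxis-dependent
# active force. The cycle is a two-state machine driven by the smoothed rate
# of change of the cell-body length: elongation ends when L'(t) decays to the
# retention rate delta_ret+ (> 0), retraction ends when L'(t) recovers to
# delta_ret- (< 0); either switch is forced after max_phase_duration.

#' Create a migration-cycle state machine
#'
#' @param delta_ret_plus positive retention rate (cm/s): elongation switches
#'   to retraction when the smoothed L' falls to this value.
#' @param delta_ret_minus negative retention rate (cm/s): retraction switches
#'   back when the smoothed L' rises to this value.
#' @param max_phase_duration fallback phase length (s); a switch is forced
#'   when a phase exceeds it.
#' @param smooth_window number of samples in the moving-average window used
#'   to estimate L' (raw node-resolution lengths are noisy).
#' @param t0 start time (s).
#' @return an object of class \code{migration_cycle}.
#' @export
migration_cycle <- function(delta_ret_plus, delta_ret_minus,
                            max_phase_duration, smooth_window = 5, t0 = 0) {
  stopifnot(delta_ret_plus > 0, delta_ret_minus < 0, max_phase_duration > 0,
            smooth_window >= 3)
  structure(list(
    phase = "elongation",
    delta_ret_plus = delta_ret_plus,
    delta_ret_minus = delta_ret_minus,
    max_phase_duration = max_phase_duration,
    smooth_window = as.integer(smooth_window),
    phase_start = t0,
    t_hist = numeric(0), L_hist = numeric(0),
    Lp = NA_real_,
    switches = data.frame(t = numeric(0), from = character(0),
                          to = character(0)),
    switched = FALSE
  ), class = "migration_cycle")
}

#' Retention strip width
#' @param cycle a [migration_cycle()].
#' @return omega_ret = delta_ret+ - delta_ret- (cm/s).
#' @export
retention_width <- function(cycle) {
  cycle$delta_ret_plus - cycle$delta_ret_minus
}

# Smoothed L'(t): centered finite difference of the moving-average of L over
# the last 2 * window samples.
.smoothed_rate <- function(tv, Lv, w) {
  n <- length(Lv)
  if (n < 2 * w) return(NA_real_)
  m1 <- mean(Lv[(n - w + 1):n]);       t1 <- mean(tv[(n - w + 1):n])
  m0 <- mean(Lv[(n - 2 * w + 1):(n - w)]); t0 <- mean(tv[(n - 2 * w + 1):(n - w)])
  if (t1 == t0) return(NA_real_)
  (m1 - m0) / (t1 - t0)
}

#' Update the migration phase from a new cell-length sample
#'
#' Appends (t, L) to the history, re-estimates the smoothed rate L', and
#' switches phase when the rate crosses the relevant retention rate (or the
#' phase times out). Phases alternate strictly. The caller must refreeze
#' anchors (see [freeze_anchors()]) whenever \code{$switched} is TRUE.
#'
#' @param cycle a [migration_cycle()].
#' @param L_now current cell-body length (cm).
#' @param t current time (s).
#' @return the updated cycle; \code{$switched} flags a phase change at this
#'   sample and \code{$Lp} holds the smoothed rate.
#' @export
update_phase <- function(cycle, L_now, t) {
  keep <- 4L * cycle$smooth_window
  cycle$t_hist <- c(utils::tail(cycle$t_hist, keep - 1L), t)
  cycle$L_hist <- c(utils::tail(cycle$L_hist, keep - 1L), L_now)
  cycle$Lp <- .smoothed_rate(cycle$t_hist, cycle$L_hist, cycle$smooth_window)
  cycle$switched <- FALSE
  aged <- (t - cycle$phase_start) >= cycle$max_phase_duration
  # the rate estimate must be based on samples from the current phase
  settled <- !is.na(cycle$Lp) &&
    (cycle$t_hist[max(1L, length(cycle$t_hist) - 2L * cycle$smooth_window + 1L)]
     >= cycle$phase_start)
  trigger <- if (cycle$phase == "elongation") {
    settled && cycle$Lp <= cycle$delta_ret_plus
  } else {
    settled && cycle$Lp >= cycle$delta_ret_minus
  }
  if (trigger || aged) {
    from <- cycle$phase
    cycle$phase <- if (from == "elongation") "retraction" else "elongation"
    cycle$switches <- rbind(cycle$switches,
                            data.frame(t = t, from = from, to = cycle$phase))
    cycle$phase_start <- t
    cycle$switched <- TRUE
  }
  cycle
}

#' Migration direction from the chemoattractant gradient
#'
#' Unit vector along the disk-average of grad C over B(x, Rsc). When the
#' sensing radius is under-resolved (Rsc < 2h) the average degenerates to the
#' bilinearly interpolated gradient at x. If the averaged gradient magnitude
#' is below 1e-14 the previous direction is retained.
#'
#' @param chem a [chem_field()].
#' @param x length-2 position (cm).
#' @param Rsc chemotactic sensing radius (cm).
#' @param prev previous unit direction (returned in the degenerate case).
#' @return unit length-2 vector.
#' @export
migration_direction <- function(chem, x, Rsc, prev = c(0, 1)) {
  g <- chem_gradient(chem)
  h <- chem$h
  if (Rsc < 2 * h) {
    gx <- interp_bilinear(g$dx, rbind(x), h, origin = h / 2, periodic = FALSE)
    gy <- interp_bilinear(g$dy, rbind(x), h, origin = h / 2, periodic = FALSE)
    v <- c(gx, gy)
  } else {
    co <- ((1:chem$N) - 0.5) * h
    DX <- outer(co - x[1], rep(1, chem$N))
    DY <- outer(rep(1, chem$N), co - x[2])
    inside <- DX^2 + DY^2 <= Rsc^2
    v <- c(mean(g$dx[inside]), mean(g$dy[inside]))
  }
  nv <- sqrt(sum(v^2))
  if (!is.finite(nv) || nv < 1e-14) return(prev)
  v / nv
}

#' Chemotactic force strength and active force constant
#'
#' |F_C| = |grad C| / (1 + lambda_s |grad C|^2), a saturating response that
#' is bounded by 1/(2 sqrt(lambda_s)) however steep the gradient, and
#' c_a = chi (alpha + |F_C|).
#'
#' @param gradC length-2 gradient of the chemoattractant at the cell.
#' @param lambda_s chemotactic saturation parameter (> 0); published value 20.
#' @param chi basal active force strength; published value 0.7.
#' @param alpha_sig basal signaling strength; published value 0.15.
#' @return list with \code{Fc} (the strength |F_C|) and \code{ca}.
#' @export
chemotactic_force_strength <- function(gradC, lambda_s = 20, chi = 0.7,
                                       alpha_sig = 0.15) {
  stopifnot(lambda_s > 0)
  g <- sqrt(sum(gradC^2))
  Fc <- g / (1 + lambda_s * g^2)
  list(Fc = Fc, ca = chi * (alpha_sig + Fc))
}

#' Active migration force on the glioma membrane
#'
#' During elongation each front node carries the force density c_a d; during
#' retraction the active force is zero (the cell pulls on its frozen front
#' anchors instead).
#'
#' @param cell a [glioma_cell()] with front nodes selected.
#' @param phase "elongation" or "retraction".
#' @param ca active force constant.
#' @param dir unit migration direction.
#' @return M x 2 force density matrix over the membrane nodes.
#' @export
active_force <- function(cell, phase, ca, dir) {
  M <- nrow(cell$membrane$X)
  Fa <- matrix(0, M, 2)
  if (phase == "elongation" && length(cell$front_nodes)) {
    Fa[cell$front_nodes, 1] <- ca * dir[1]
    Fa[cell$front_nodes, 2] <- ca * dir[2]
  }
  Fa
}

#' Total boundary force density on the glioma membrane
#'
#' Sum of the elastic term, the phase-appropriate tether term (rear anchors
#' during elongation, front anchors during retraction) and the active term.
#' The nucleus contributes elastic force only (with the live myosin-modulated
#' stiffness) and is assembled separately by the runner.
#'
#' @param cell a [glioma_cell()] with anchors frozen for the current phase.
#' @param phase "elongation" or "retraction".
#' @param ca active force constant.
#' @param dir unit migration direction.
#' @return M x 2 force density matrix.
#' @export
glioma_membrane_force <- function(cell, phase, ca, dir) {
  Fm <- elastic_force(cell$membrane)
  if (phase == "elongation" && length(cell$rear_nodes) && !is.null(cell$Zr)) {
    Fm[cell$rear_nodes, ] <- Fm[cell$rear_nodes, , drop = FALSE] +
      tether_force(cell$membrane$X[cell$rear_nodes, , drop = FALSE],
                   cell$Zr, cell$ct)
  } else if (phase == "retraction" && length(cell$front_nodes) &&
             !is.null(cell$Zf)) {
    Fm[cell$front_nodes, ] <- Fm[cell$front_nodes, , drop = FALSE] +
      tether_force(cell$membrane$X[cell$front_nodes, , drop = FALSE],
                   cell$Zf, cell$ct)
  }
  Fm + active_force(cell, phase, ca, dir)
}
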