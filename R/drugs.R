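# Pulsed anti-invasion drug schedules. Both drugs follow
#   dX/dt = sum_j I [t_j <= t < t_j + pulse] - mu X,
# an injection that is on for the first pulse interval of each dosing cycle
# tau (t_j = j tau, j = 0..N-1) and first-order decay otherwise. The ODE is
# advanced exactly on each piecewise-constant sub-interval.
#
# "blebbistatin" caps bound myosin II (degradation term -alpha B mb);
# "inhibitor" attenuates the actin-myosin association rate (factor e^{-D}).

#' Create a drug schedule state
#'
#' @param type "blebbistatin" or "inhibitor".
#' @param I injection strength (uM/s for blebbistatin; 1/s exponent scale for
#'   the association inhibitor). Published blebbistatin base value 5e-2.
#' @param tau_hours dosing interval (h); must be at least the pulse length.
#' @param n_inj number of injections in the schedule.
#' @param mu decay rate (1/s); published value 5.13e-4 for both drugs.
#' @param conc initial concentration; the blebbistatin kinetics were studied
#'   from an initial 150 uM bolus.
#' @param pulse_hours pulse (injection-on) length per cycle in hours;
#'   default 1/3 h.
#' @param alpha_bleb bound-myosin degradation rate by blebbistatin
#'   (1/(s uM)); published value 1e-4. Ignored for type "inhibitor".
#' @return an object of class \code{drug_state}.
#' @export
drug_state <- function(type = c("blebbistatin", "inhibitor"), I = 0,
                       tau_hours = 2, n_inj = 0L, mu = 5.13e-4, conc = 0,
                       pulse_hours = 1 / 3, alpha_bleb = 1e-4) {
  type <- match.arg(type)
  stopifnot(I >= 0, conc >= 0, mu > 0, tau_hours >= pulse_hours,
            pulse_hours > 0, n_inj >= 0)
  structure(list(type = type, I = I, tau = tau_hours * 3600,
                 pulse = pulse_hours * 3600, n_inj = as.integer(n_inj),
                 mu = mu, conc = conc, alpha_bleb = alpha_bleb),
            class = "drug_state")
}

# Is the injection on at time t (start-inclusive)?
.injection_on <- function(ds, t) {
  if (ds$n_inj == 0L || ds$I == 0) return(FALSE)
  j <- floor(t / ds$tau)
  j >= 0 && j < ds$n_inj && (t - j * ds$tau) < ds$pulse
}

# Next time > t at which the on/off indicator can change.
.next_toggle <- function(ds, t) {
  if (ds$n_inj == 0L || ds$I == 0) return(Inf)
  j <- floor(t / ds$tau)
  if (j >= ds$n_inj) return(Inf)
  edge_on <- j * ds$tau + ds$pulse
  edge_next <- (j + 1) * ds$tau
  if (t < edge_on) edge_on else edge_next
}

#' Advance a drug schedule one time step
#'
#' Exact piecewise linear-ODE update over [t, t + dt], splitting at pulse
#' edges: with the injection on, X relaxes toward the plateau I/mu; off, it
#' decays as exp(-mu dt). Beyond the last scheduled injection only decay
#' remains.
#'
#' @param ds a [drug_state()].
#' @param t current time (s).
#' @param dt step (s).
#' @return the state with \code{conc} advanced.
#' @export
drug_step <- function(ds, t, dt) {
  stopifnot(dt > 0)
  tend <- t + dt
  x <- ds$conc
  while (t < tend - 1e-12 * max(1, tend)) {
    tnext <- min(tend, .next_toggle(ds, t))
    dlt <- tnext - t
    if (.injection_on(ds, t)) {
      plat <- ds$I / ds$mu
      x <- plat + (x - plat) * exp(-ds$mu * dlt)
    } else {
      x <- x * exp(-ds$mu * dlt)
    }
    t <- tnext
  }
  ds$conc <- x
  ds
}

#' Aggregate drug effects for the myosin kinetics
#'
#' Sums blebbistatin concentrations (B) and association-inhibitor
#' concentrations (D) over a list of [drug_state()]s.
#'
#' @param drugs list of [drug_state()] objects (possibly empty).
#' @return list with \code{B}, \code{D} and \code{alpha_bleb}.
#' @export
drug_effects <- function(drugs) {
  B <- 0; D <- 0; ab <- 1e-4
  for (d in drugs) {
    if (d$type == "blebbistatin") { B <- B + d$conc; ab <- d$alpha_bleb }
    else D <- D + d$conc
  }
  list(B = B, D = D, alpha_bleb = ab)
}
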