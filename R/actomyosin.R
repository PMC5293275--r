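# Acto-myosin kinetics: confinement pressure sensed along the membrane sets
# the available actin concentration, bound myosin II follows mass-action
# binding kinetics, and a Hill-type stiffening rate converts bound myosin to
# the live nucleus stiffness. All updates use exact exponential integration
# of the (coefficient-frozen) linear ODE, so no solver tolerance enters.

#' Create a myosin kinetics state
#'
#' @param mT total myosin II concentration (uM); published value 1.
#' @param k1 association rate (1/(uM s)); published value 0.002.
#' @param k_1 dissociation rate (1/s); published value 1e-4.
#' @param kp myosin-pressure sensitivity (uM s^2/(g cm)); published values
#'   0.9 (wild type) and 0.045 (MYOII knockdown).
#' @param Rs pressure sensing radius (cm); published value 4.69 um.
#' @param mb initial bound myosin (uM); default the steady state at zero
#'   pressure, i.e. 0.
#' @param pressure_scale calibration constant multiplying the sensed pressure
#'   before the kp conversion (the pressure gauge fixes only the mean; this
#'   exposes the overall scale as configuration).
#' @return an object of class \code{myosin_state}.
#' @export
myosin_state <- function(mT = 1, k1 = 0.002, k_1 = 1e-4, kp = 0.9,
                         Rs = 4.69e-4, mb = 0, pressure_scale = 1) {
  stopifnot(k1 > 0, k_1 > 0, mT > 0, mb >= 0, mb <= mT)
  structure(list(mT = mT, k1 = k1, k_1 = k_1, kp = kp, Rs = Rs, mb = mb,
                 pressure_scale = pressure_scale),
            class = "myosin_state")
}

#' Membrane-averaged sensing pressure
#'
#' Each membrane point senses the average of the fluid pressure over the
#' surrounding disk of radius Rs; the cell-level sensing pressure p^s is the
#' mean of those disk averages over the membrane nodes. Reported in the
#' zero-mean pressure gauge of the projection.
#'
#' @param st a [fluid_state()] that has taken at least one step.
#' @param curve the membrane [boundary_curve()].
#' @param Rs sensing radius (cm).
#' @param kern_hat optional cached [disk_kernel_hat()] for radius Rs.
#' @return p^s in g/(cm s^2).
#' @export
sensing_pressure <- function(st, curve, Rs, kern_hat = NULL) {
  p <- pressure_field(st)
  if (is.null(kern_hat)) kern_hat <- disk_kernel_hat(st$N, st$L, Rs)
  pb <- disk_average_field(p, kern_hat)
  mean(interp_bilinear(pb, curve$X, st$h, origin = 0, periodic = TRUE))
}

#' Actin filament concentration from sensed pressure
#'
#' [a] = max(0, kp * p^s): the linear pressure-to-actin conversion, clamped
#' at zero because the zero-mean gauge can make the sensed pressure slightly
#' negative in unconfined positions.
#'
#' @param ps sensing pressure (g/(cm s^2)).
#' @param kp myosin-pressure sensitivity.
#' @param pressure_scale calibration constant (see [myosin_state()]).
#' @return actin concentration (uM).
#' @export
actin_concentration <- function(ps, kp, pressure_scale = 1) {
  max(0, kp * pressure_scale * ps)
}

#' Steady-state bound myosin concentration
#'
#' mb_s = mT a / (a + 1/K) with K = k1 / k_1, the fixed point of the binding
#' kinetics at constant actin concentration.
#'
#' @param a actin concentration (uM), non-negative.
#' @param ms a [myosin_state()].
#' @return steady-state bound myosin (uM).
#' @export
steady_state_mb <- function(a, ms) {
  stopifnot(a >= 0)
  K <- ms$k1 / ms$k_1
  ms$mT * a / (a + 1 / K)
}

#' Advance the bound-myosin kinetics one step
#'
#' d[mb]/dt = k1 e^{-D} mT a - (k1 e^{-D} a + k_1) mb - alpha B mb, where B
#' is the blebbistatin concentration (capping bound myosin at rate alpha B)
#' and D the association-inhibitor concentration (attenuating the
#' association rate by e^{-D}). With B = D = 0 this is the base mass-action
#' equation. Coefficients are frozen over dt and the linear ODE is solved
#' exactly; the result is clamped to [0, mT].
#'
#' @param ms a [myosin_state()].
#' @param a actin concentration (uM), non-negative.
#' @param dt time step (s).
#' @param B blebbistatin concentration (uM).
#' @param alpha_bleb degradation rate of bound myosin by blebbistatin
#'   (1/(s uM)); published value 1e-4.
#' @param D association-inhibitor concentration (dimensionless exponent).
#' @return the state with \code{mb} advanced.
#' @export
step_myosin <- function(ms, a, dt, B = 0, alpha_bleb = 1e-4, D = 0) {
  stopifnot(dt > 0, a >= 0, B >= 0, D >= 0)
  k1e <- ms$k1 * exp(-D)
  loss <- k1e * a + ms$k_1 + alpha_bleb * B
  gain <- k1e * ms$mT * a
  mb_inf <- gain / loss
  ms$mb <- mb_inf + (ms$mb - mb_inf) * exp(-loss * dt)
  ms$mb <- min(max(ms$mb, 0), ms$mT)
  ms
}

#' Nucleus stiffening parameters
#'
#' @param ce_n_b basal nucleus elastic stiffness (g cm/s^2); published value
#'   3.8e-5.
#' @param ks,ks_min Hill amplitudes of the stiffening rate; published values
#'   5 and 0.1.
#' @param Kmb reciprocal critical threshold (1/uM); published value 1.8.
#' @param n Hill coefficient; published value 10.
#' @param fold scenario multiplier on the basal stiffness.
#' @return an object of class \code{stiffening_params}.
#' @export
stiffening_params <- function(ce_n_b = 3.8e-5, ks = 5, ks_min = 0.1,
                              Kmb = 1.8, n = 10, fold = 1) {
  stopifnot(ks > 0, ks_min > 0, Kmb > 0, n > 0, fold > 0)
  structure(list(ce_n_b = ce_n_b, ks = ks, ks_min = ks_min, Kmb = Kmb,
                 n = n, fold = fold),
            class = "stiffening_params")
}

#' Myosin-dependent stiffening rate of the nucleus
#'
#' r(mb) = ks (1/mb)^n / (Kmb^n + (1/mb)^n) + ks_min, evaluated in the
#' overflow-safe form ks / (1 + (Kmb mb)^n) + ks_min. Monotone decreasing in
#' mb, from ks + ks_min (unbound myosin, stiff nucleus) down to ks_min
#' (saturated bound myosin, soft nucleus), with half maximum at
#' 1/mb = Kmb.
#'
#' @param mb bound myosin (uM), >= 0 (mb = 0 gives the limit ks + ks_min).
#' @param params a [stiffening_params()].
#' @return dimensionless rate, vectorized over mb.
#' @export
stiffening_rate <- function(mb, params) {
  stopifnot(all(mb >= 0))
  params$ks / (1 + (params$Kmb * mb)^params$n) + params$ks_min
}

#' Live nucleus stiffness
#'
#' c_e^Gn = fold * ce_n_b * r(mb); pushed into the nucleus curve before each
#' elastic-force evaluation.
#'
#' @param r stiffening rate from [stiffening_rate()].
#' @param params a [stiffening_params()].
#' @return stiffness (g cm/s^2).
#' @export
nucleus_stiffness <- function(r, params) {
  stopifnot(all(r >= 0))
  params$fold * params$ce_n_b * r
}
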