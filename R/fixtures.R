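# Reduced-scale test fixtures. These are scaled-mode configurations: the
# grid, stiffnesses, kinetic rates and phase clocks are rescaled together so
# that a full elongation-retraction cycle — and the wild-type vs
# myosin-knockdown contrast on the two-cell gap — are observable in a short
# run, while every mechanism (spectral fluid solve, IB coupling, pressure
# sensing, Hill stiffening, chemotaxis, phase machine) is exercised
# unchanged. The methods vignette documents the similarity argument; the
# published parameter set remains the default of [scenario_config()].

#' Named test fixtures
#'
#' \describe{
#'   \item{taylor_green}{solver-validation parameters (periodic vortex with
#'     a closed-form viscous decay).}
#'   \item{ode_only}{kinetics harness: a prescribed square-wave sensing
#'     pressure bypassing the fluid.}
#'   \item{mini_two_gap}{scaled two-cell-gap scenario, wild-type myosin
#'     sensitivity, 64^2 grid.}
#'   \item{mini_two_gap_kd}{the same geometry with the 20-fold lower
#'     myosin-pressure sensitivity of the knockdown.}
#'   \item{mini_two_gap_128}{the wild-type scenario on a 128^2 grid.}
#'   \item{mini_two_gap_kd_128}{the knockdown scenario on a 128^2 grid.}
#'   \item{mini_quiescent}{the gap geometry with no chemoattractant source
#'     and no active force: a force-balanced configuration for drift and
#'     area-conservation checks.}
#'   \item{mini_astro_pair}{scaled astrocyte-pair geometry; accepts
#'     \code{d} (gap, cm) and \code{fold} (nucleus stiffness multiplier).}
#' }
#'
#' @param name fixture name.
#' @param ... fixture-specific overrides (e.g. \code{d}, \code{fold}, or any
#'   [scenario_config()] section).
#' @return a [scenario_config()] (or a plain parameter list for
#'   \code{taylor_green} / \code{ode_only}).
#' @export
fixture_generator <- function(name, ...) {
  known <- c("taylor_green", "ode_only", "mini_two_gap", "mini_two_gap_kd",
             "mini_two_gap_128", "mini_two_gap_kd_128", "mini_quiescent",
             "mini_astro_pair")
  if (!name %in% known)
    stop("unknown fixture '", name, "'; available: ",
         paste(known, collapse = ", "))
  dots <- list(...)
  if (name == "taylor_green") {
    return(list(kind = "taylor_green", N = 64L, L = 2 * pi, rho = 1,
                mu = 0.01, k = 1, dt = 1e-3, nsteps = 100L))
  }
  if (name == "ode_only") {
    # square-wave sensing pressure: high plateaus on [150,450] and
    # [650,850] minutes, mirroring the kinetics study's forcing
    amp <- if (!is.null(dots$amplitude)) dots$amplitude else 1
    return(list(kind = "ode_only",
                ps_fun = function(t) {
                  tm <- t / 60
                  amp * as.numeric((tm >= 150 & tm < 450) |
                                     (tm >= 650 & tm < 850))
                }))
  }
  base <- .mini_base()
  cfg <- switch(name,
    mini_two_gap = base,
    mini_two_gap_kd = .merge_cfg(base, list(name = "mini_two_gap_kd",
                                            glioma = list(kp = 0.045))),
    mini_two_gap_128 = .merge_cfg(base, list(name = "mini_two_gap_128",
                                             domain = list(N = 128L))),
    mini_two_gap_kd_128 = .merge_cfg(base, list(
      name = "mini_two_gap_kd_128", domain = list(N = 128L),
      glioma = list(kp = 0.045))),
    mini_quiescent = .merge_cfg(base, list(
      name = "mini_quiescent",
      chem = list(lam_in = 0),
      motility = list(chi = 0, alpha_sig = 0))),
    mini_astro_pair = .merge_cfg(base, list(
      name = "mini_astro_pair",
      normals = list(layout = "astrocyte_pair",
                     d = if (!is.null(dots$d)) dots$d else 8e-4),
      glioma = list(fold = if (!is.null(dots$fold)) dots$fold else 1)))
  )
  dots$d <- NULL; dots$fold <- NULL; dots$amplitude <- NULL
  if (length(dots)) cfg <- .merge_cfg(cfg, dots)
  class(cfg) <- "scenario_config"
  cfg
}

# The scaled two-cell-gap base configuration (64^2 grid). Geometry: a pair
# of tethered normal cells of radius 16 um separated by an 8 um gap at
# y = 50 um; a 10 um glioma cell with a 6 um nucleus (12 um nuclear
# diameter > gap) starts below and is attracted to a source at the top.
.mini_base <- function() {
  cfg <- scenario_config(
    name = "mini_two_gap",
    domain = list(L = 0.01, N = 64L),
    time = list(dt = 0.05, T_end = 500, record_stride = 5L),
    fluid = list(rho = 1, mu = 0.15, advect = FALSE),
    glioma = list(center = c(0.005, 0.0031), radius = 10e-4,
                  nucleus_radius = 5e-4, ce_m = 2e-5, ce_n_b = 2e-5,
                  ct = 1000, kp = 0.9, fold = 1),
    normals = list(layout = "two_gap", radius = 16e-4, gap = 6e-4,
                   gap_y = 0.005, ce = 2e-6, ct = 2000),
    chem = list(source = c(0.005, 0.009), stride = 2L),
    myosin = list(k1 = 0.1, k_1 = 0.005, pressure_scale = 45, stride = 2L),
    motility = list(chi = 1.5, delta_ret_plus = 3e-6, delta_ret_minus = -3e-6,
                    max_phase_duration = 15, smooth_window = 4,
                    dir_stride = 5L),
    numerics = list(substep_safety = 0.5)
  )
  cfg
}

#' Taylor-Green vortex field
#'
#' u = (sin kx cos ky, -cos kx sin ky): divergence-free, and under pure
#' (advection-free) viscous evolution its amplitude decays exactly as
#' exp(-2 nu k^2 t). For this flow the nonlinear term is a pure gradient, so
#' the projection removes it and the decay law holds with advection too.
#'
#' @param st a [fluid_state()] with L = 2 pi / k * integer.
#' @param k integer wavenumber.
#' @return the state with the vortex installed.
#' @export
taylor_green <- function(st, k = 1) {
  co <- (0:(st$N - 1)) * st$h
  X <- matrix(co, st$N, st$N)
  Y <- matrix(co, st$N, st$N, byrow = TRUE)
  st$ux <- sin(k * X) * cos(k * Y)
  st$uy <- -cos(k * X) * sin(k * Y)
  st
}
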