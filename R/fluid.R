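# Spectral (FFT) solver for the 2D incompressible Navier-Stokes equations on a
# periodic box, used as the carrier fluid of the immersed-boundary model.
#
# Discretization: Fourier collocation in space; per step the body force and the
# explicit skew-symmetric advection term are applied, the velocity is projected
# onto its divergence-free part (the projection multiplier is the pressure, in
# the zero-mean gauge), and the viscous term is integrated exactly with the
# spectral integrating factor exp(-nu k^2 dt). The scheme is unconditionally
# stable in the viscous term; advection carries the usual CFL restriction.

#' Create a fluid state on a periodic grid
#'
#' Velocity, pressure and grid metadata for the spectral immersed-boundary
#' fluid solver. All quantities are CGS: the published configuration is a
#' 0.1 mm x 0.1 mm box stored as \code{L = 0.01} cm with density
#' 1.35 g/cm^3 and viscosity 2.7 g/(cm s).
#'
#' Fields are stored as N x N matrices with \code{A[i, j]} the value at
#' \code{x = (i-1) h}, \code{y = (j-1) h}.
#'
#' @param N grid points per side.
#' @param L box side length (cm).
#' @param rho fluid density (g/cm^3).
#' @param mu dynamic viscosity (g/(cm s)).
#' @param dt configured time step (s), used by [stability_dt()] as the cap.
#' @return an object of class \code{fluid_state}.
#' @export
fluid_state <- function(N, L, rho, mu, dt = 0.004) {
  stopifnot(N >= 4, N %% 2 == 0, L > 0, rho > 0, mu > 0, dt > 0)
  z <- matrix(0, N, N)
  st <- list(
    N = N, L = L, h = L / N, rho = rho, mu = mu, dt = dt,
    ux = z, uy = z, p = z, t = 0, nstep = 0L,
    wave = .wavegrid(N, L)
  )
  class(st) <- "fluid_state"
  st
}

# Spectral wavenumber grids. The Nyquist column is kept for the Laplacian
# (even powers) but zeroed for first derivatives, the standard real-field
# convention.
.wavegrid <- function(N, L) {
  m <- c(0:(N / 2), -((N / 2) - 1):-1)       # integer frequencies, length N
  k <- 2 * pi * m / L
  kd <- k
  kd[N / 2 + 1] <- 0                          # drop Nyquist in odd derivatives
  KX <- matrix(kd, N, N)                      # varies along rows (x index)
  KY <- matrix(kd, N, N, byrow = TRUE)
  K2 <- matrix(k, N, N)^2 + matrix(k, N, N, byrow = TRUE)^2
  # projection/pressure use the derivative-consistent symbol KX^2 + KY^2
  # (Nyquist-free), so the discrete divergence of the result is exactly zero
  K2P <- KX^2 + KY^2
  K2Pinv <- ifelse(K2P > 0, 1 / K2P, 0)
  list(KX = KX, KY = KY, K2 = K2, K2Pinv = K2Pinv)
}

.fft2 <- function(a) stats::fft(a)
.ifft2 <- function(ah) stats::fft(ah, inverse = TRUE) / length(ah)

.re_check <- function(ah, what, tol = 1e-10) {
  a <- .ifft2(ah)
  mx <- max(abs(Re(a)), 1)
  if (max(abs(Im(a))) > tol * mx)
    warning(sprintf("spectral round-trip of %s has imaginary part %.3e",
                    what, max(abs(Im(a)))))
  Re(a)
}

# Skew-symmetric advection term 0.5 * (u . grad u + div(u u)), evaluated with
# spectral derivatives. Returns the two components in physical space.
.advection <- function(st) {
  w <- st$wave
  uxh <- .fft2(st$ux); uyh <- .fft2(st$uy)
  dudx <- Re(.ifft2(1i * w$KX * uxh)); dudy <- Re(.ifft2(1i * w$KY * uxh))
  dvdx <- Re(.ifft2(1i * w$KX * uyh)); dvdy <- Re(.ifft2(1i * w$KY * uyh))
  uu <- st$ux * st$ux; uv <- st$ux * st$uy; vv <- st$uy * st$uy
  divx <- Re(.ifft2(1i * w$KX * .fft2(uu) + 1i * w$KY * .fft2(uv)))
  divy <- Re(.ifft2(1i * w$KX * .fft2(uv) + 1i * w$KY * .fft2(vv)))
  list(x = 0.5 * (st$ux * dudx + st$uy * dudy + divx),
       y = 0.5 * (st$ux * dvdx + st$uy * dvdy + divy))
}

#' Advance the fluid one time step under a body force
#'
#' One projection step: explicit force and (optionally) skew-symmetric
#' advection, exact spectral pressure projection, exact viscous decay. The
#' returned velocity is discretely divergence-free and the pressure is the
#' zero-mean projection multiplier.
#'
#' By default the spatial-mean (k = 0) component of the force is removed so
#' the periodic box carries no net momentum drift (momentum gauge); set
#' \code{drop_mean_force = FALSE} to keep it, in which case the mean velocity
#' obeys d<u>/dt = <f>/rho exactly.
#'
#' @param st a [fluid_state()].
#' @param fx,fy body-force density components (g/(cm^2 s^2)) on the grid.
#' @param dt time step (s); defaults to the configured step.
#' @param advect include the nonlinear advection term.
#' @param drop_mean_force remove the k = 0 force mode (default TRUE).
#' @return the advanced \code{fluid_state}.
#' @export
navier_stokes_step <- function(st, fx = NULL, fy = NULL, dt = st$dt,
                               advect = TRUE, drop_mean_force = TRUE) {
  stopifnot(inherits(st, "fluid_state"), dt > 0)
  N <- st$N
  if (is.null(fx)) fx <- matrix(0, N, N)
  if (is.null(fy)) fy <- matrix(0, N, N)
  if (!all(is.finite(fx)) || !all(is.finite(fy)))
    stop(sprintf("non-finite body force at step %d", st$nstep + 1L))
  if (!all(is.finite(st$ux)) || !all(is.finite(st$uy)))
    stop(sprintf("non-finite velocity at step %d", st$nstep + 1L))
  cfl <- stability_dt(st)
  if (dt > cfl * (1 + 1e-9))
    stop(sprintf("dt = %g exceeds stability bound %g at step %d",
                 dt, cfl, st$nstep + 1L))
  w <- st$wave
  fxh <- .fft2(fx); fyh <- .fft2(fy)
  if (drop_mean_force) { fxh[1, 1] <- 0; fyh[1, 1] <- 0 }
  rx <- fxh / st$rho; ry <- fyh / st$rho
  if (advect && (any(st$ux != 0) || any(st$uy != 0))) {
    adv <- .advection(st)
    rx <- rx - .fft2(adv$x); ry <- ry - .fft2(adv$y)
  }
  # pressure: laplacian(p) = div(f - rho adv); dt-independent, zero-mean
  ph <- -1i * st$rho * (w$KX * rx + w$KY * ry) * w$K2Pinv
  # Leray projection of the right-hand side, then exact integration of each
  # viscous mode: du/dt = -nu k^2 u + P r has the closed-form update
  # u(t+dt) = E u + (1-E)/(nu k^2) P r with E = exp(-nu k^2 dt). This is
  # exact for frozen forces, reduces to forward Euler for nu k^2 dt -> 0 and
  # to the Stokes balance u = P f/(mu k^2) in the overdamped limit.
  kr <- (w$KX * rx + w$KY * ry) * w$K2Pinv
  rx <- rx - w$KX * kr
  ry <- ry - w$KY * kr
  nu <- st$mu / st$rho
  nk2 <- nu * w$K2
  E <- exp(-nk2 * dt)
  G <- ifelse(nk2 > 1e-300, (1 - E) / nk2, dt)
  G[1, 1] <- dt                                # k = 0: pure acceleration
  uxh <- E * .fft2(st$ux) + G * rx
  uyh <- E * .fft2(st$uy) + G * ry
  st$ux <- .re_check(uxh, "ux"); st$uy <- .re_check(uyh, "uy")
  st$p <- .re_check(ph, "p")
  st$t <- st$t + dt
  st$nstep <- st$nstep + 1L
  st
}

#' Pressure field of the most recent projection
#'
#' Zero-mean (gauge-fixed) pressure consistent with the last
#' [navier_stokes_step()]. Errors if no step has been taken.
#'
#' @param st a [fluid_state()].
#' @return N x N pressure matrix (g/(cm s^2)).
#' @export
pressure_field <- function(st) {
  stopifnot(inherits(st, "fluid_state"))
  if (st$nstep == 0L)
    stop("pressure_field() called before the first navier_stokes_step()")
  st$p
}

#' Stable time step for the coupled explicit scheme
#'
#' Returns the configured dt capped by the advective CFL bound and by
#' heuristic relaxation-rate bounds for the explicitly coupled elastic and
#' tether forces. For a curve of stiffness c and node spacing ds the fastest
#' elastic relaxation rate in Stokes flow scales as c/(mu ds); a tether of
#' stiffness ct relaxes at about ct ds/mu. The returned dt is monotone
#' non-increasing in every stiffness.
#'
#' @param st a [fluid_state()].
#' @param stiffness optional list with elements \code{ce} (vector of elastic
#'   stiffnesses, g cm/s^2), \code{ct} (tether stiffnesses, g/(cm s^2)) and
#'   \code{ds} (node spacings, cm).
#' @param safety safety factor applied to the stiffness bounds.
#' @return time step in seconds, never larger than the configured dt.
#' @export
stability_dt <- function(st, stiffness = NULL, safety = 0.5) {
  stopifnot(inherits(st, "fluid_state"))
  dt <- st$dt
  umax <- max(abs(st$ux), abs(st$uy))
  if (umax > 0) dt <- min(dt, st$h / umax)
  if (!is.null(stiffness)) {
    ds <- if (!is.null(stiffness$ds)) min(stiffness$ds) else st$h / 2
    if (length(stiffness$ce) && max(stiffness$ce) > 0)
      dt <- min(dt, safety * st$mu * ds / max(stiffness$ce))
    if (length(stiffness$ct) && max(stiffness$ct) > 0)
      dt <- min(dt, safety * st$mu / (max(stiffness$ct) * ds))
  }
  dt
}

#' Discrete (spectral) divergence of the velocity field
#'
#' Diagnostic used by the solver's divergence-free post-condition.
#'
#' @param st a [fluid_state()].
#' @return maximum absolute divergence over the grid (1/s).
#' @export
max_divergence <- function(st) {
  w <- st$wave
  d <- Re(.ifft2(1i * (w$KX * .fft2(st$ux) + w$KY * .fft2(st$uy))))
  max(abs(d))
}

#' Total kinetic energy of the fluid
#' @param st a [fluid_state()].
#' @return energy, 0.5 rho h^2 sum(|u|^2) (g cm^2/s^2 per unit depth).
#' @export
kinetic_energy <- function(st) {
  0.5 * st$rho * st$h^2 * sum(st$ux^2 + st$uy^2)
}
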