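# Discrete delta-function coupling between the Eulerian grid and Lagrangian
# curves: force spreading, velocity interpolation (exact adjoints), and the
# disk-average smoothing used by pressure sensing and gradient sensing.

#' Regularized delta function (Peskin 4-point kernel)
#'
#' One-dimensional smoothed delta with support on 4 grid cells,
#' delta_h(r) = phi(r/h)/h, where phi is the standard immersed-boundary
#' 4-point kernel. It satisfies, exactly, the zeroth moment (partition of
#' unity), the even/odd sum condition (each equal 1/2) and the first moment
#' condition; the 2D kernel is the tensor product of 1D kernels.
#'
#' @param r offset from a grid point (cm), any numeric vector.
#' @param h grid spacing (cm).
#' @return kernel weights (1/cm).
#' @export
ib_delta <- function(r, h = 1) {
  x <- abs(r / h)
  w <- numeric(length(x))
  i1 <- x < 1
  i2 <- x >= 1 & x < 2
  w[i1] <- (3 - 2 * x[i1] + sqrt(1 + 4 * x[i1] - 4 * x[i1]^2)) / 8
  w[i2] <- (5 - 2 * x[i2] - sqrt(-7 + 12 * x[i2] - 4 * x[i2]^2)) / 8
  w / h
}

# 4-point stencil data for points at positions P (n x 2) on a periodic N-grid
# with spacing h and nodes at (i-1) h. Returns, for each of the 16 stencil
# offsets, linear grid indices and tensor-product weights phi_x phi_y.
.stencil <- function(P, N, h) {
  gx <- P[, 1] / h
  gy <- P[, 2] / h
  jx <- floor(gx); jy <- floor(gy)
  offs <- -1:2
  wx <- lapply(offs, function(q) ib_delta(gx - (jx + q)))   # phi values (h=1)
  wy <- lapply(offs, function(q) ib_delta(gy - (jy + q)))
  ix <- lapply(offs, function(q) ((jx + q) %% N) + 1L)
  iy <- lapply(offs, function(q) ((jy + q) %% N) + 1L)
  list(wx = wx, wy = wy, ix = ix, iy = iy, n = nrow(P))
}

#' Spread Lagrangian force densities onto the fluid grid
#'
#' f(x) = sum_k F_k delta_h2(x - X_k) ds, the discrete layer integral. The
#' total force is conserved exactly: h^2 sum(f) = sum(F) ds.
#'
#' @param Fnode M x 2 force densities at curve nodes.
#' @param X M x 2 node positions (cm); wrapped periodically.
#' @param N,h grid size and spacing.
#' @param ds arclength weight per node (cm).
#' @return list with components \code{fx}, \code{fy} (N x N matrices).
#' @export
spread_forces <- function(Fnode, X, N, h, ds) {
  Fnode <- as.matrix(Fnode)
  if (!all(is.finite(Fnode))) {
    bad <- which(!is.finite(rowSums(Fnode)))[1]
    stop(sprintf("non-finite force density at node %d", bad))
  }
  st <- .stencil(as.matrix(X), N, h)
  fx <- matrix(0, N, N); fy <- matrix(0, N, N)
  scale <- ds / h^2
  for (a in 1:4) for (b in 1:4) {
    w <- st$wx[[a]] * st$wy[[b]] * scale
    idx <- st$ix[[a]] + (st$iy[[b]] - 1L) * N
    sx <- rowsum(Fnode[, 1] * w, idx)
    sy <- rowsum(Fnode[, 2] * w, idx)
    ii <- as.integer(rownames(sx))
    fx[ii] <- fx[ii] + sx
    fy[ii] <- fy[ii] + sy
  }
  list(fx = fx, fy = fy)
}

#' Interpolate grid velocity at Lagrangian points
#'
#' U_k = h^2 sum_x u(x) delta_h2(x - X_k): the exact adjoint of
#' [spread_forces()] (the h^2 and ds weights cancel in the adjoint identity
#' sum F . U ds = h^2 sum f . u).
#'
#' @param ux,uy velocity components (N x N matrices).
#' @param X n x 2 points (cm).
#' @param N,h grid size and spacing.
#' @return n x 2 matrix of velocities.
#' @export
interpolate_velocity <- function(ux, uy, X, N, h) {
  st <- .stencil(as.matrix(X), N, h)
  Ux <- numeric(st$n); Uy <- numeric(st$n)
  for (a in 1:4) for (b in 1:4) {
    w <- st$wx[[a]] * st$wy[[b]]
    idx <- st$ix[[a]] + (st$iy[[b]] - 1L) * N
    Ux <- Ux + w * ux[idx]
    Uy <- Uy + w * uy[idx]
  }
  cbind(Ux, Uy, deparse.level = 0)
}

#' Spectral disk-average convolution kernel
#'
#' FFT of the normalized indicator of a disk of radius R on the periodic
#' grid. Convolving a field with it gives, at every grid point, the average
#' of the field over the surrounding disk — the smoothing used by the
#' membrane pressure sensor.
#'
#' @param N,L grid size and box length.
#' @param R disk radius (cm).
#' @return complex N x N matrix (cache and reuse across steps).
#' @export
disk_kernel_hat <- function(N, L, R) {
  h <- L / N
  co <- (0:(N - 1)) * h
  dx <- pmin(co, L - co)                     # periodic distance to origin
  D2 <- outer(dx^2, dx^2, "+")
  mask <- (D2 <= R^2) * 1
  if (sum(mask) == 0) mask[1, 1] <- 1        # radius below grid: point sample
  stats::fft(mask / sum(mask))
}

#' Disk-average a grid field
#'
#' @param field N x N matrix.
#' @param kern_hat kernel from [disk_kernel_hat()].
#' @return N x N matrix of disk averages.
#' @export
disk_average_field <- function(field, kern_hat) {
  Re(stats::fft(stats::fft(field) * kern_hat, inverse = TRUE)) / length(field)
}

#' Bilinear interpolation of a grid field at arbitrary points
#'
#' @param field N x N matrix with \code{field[i, j]} at
#'   \code{x = (i-1) h + origin}, \code{y = (j-1) h + origin}.
#' @param P n x 2 points (cm).
#' @param h grid spacing; \code{origin} first-node coordinate (0 for the
#'   periodic fluid grid, h/2 for the cell-centered chemoattractant grid).
#' @param periodic wrap indices (fluid) or clamp to the box (chemoattractant).
#' @return numeric vector of length n.
#' @export
interp_bilinear <- function(field, P, h, origin = 0, periodic = TRUE) {
  N <- nrow(field)
  P <- matrix(as.numeric(P), ncol = 2)
  gx <- (P[, 1] - origin) / h
  gy <- (P[, 2] - origin) / h
  j0x <- floor(gx); j0y <- floor(gy)
  tx <- gx - j0x; ty <- gy - j0y
  wrap <- function(j) {
    if (periodic) (j %% N) + 1L
    else pmin(pmax(j, 0L), N - 1L) + 1L
  }
  i1 <- wrap(j0x); i2 <- wrap(j0x + 1)
  j1 <- wrap(j0y); j2 <- wrap(j0y + 1)
  field[cbind(i1, j1)] * (1 - tx) * (1 - ty) +
    field[cbind(i2, j1)] * tx * (1 - ty) +
    field[cbind(i1, j2)] * (1 - tx) * ty +
    field[cbind(i2, j2)] * tx * ty
}
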