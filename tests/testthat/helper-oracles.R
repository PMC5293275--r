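# Independent oracles used across the suite.

# Finite-difference gradient of the discrete stretching energy: the oracle
# for the elastic force density (F = -grad E / ds).
fd_elastic_force <- function(curve, eps = 1e-6) {
  X0 <- curve$X
  G <- matrix(0, nrow(X0), 2)
  for (k in seq_len(nrow(X0))) for (d in 1:2) {
    cp <- curve; cm <- curve
    cp$X[k, d] <- cp$X[k, d] + eps
    cm$X[k, d] <- cm$X[k, d] - eps
    G[k, d] <- (elastic_energy(cp) - elastic_energy(cm)) / (2 * eps)
  }
  -G / curve$ds
}

# Direct O(n^2) DCT-II, the oracle for the FFT-based transform.
dct2_direct <- function(A) {
  n <- nrow(A)
  B <- outer(0:(n - 1), 0:(n - 1),
             function(k, m) cos(pi * k * (m + 0.5) / n))
  B %*% A %*% t(B)
}

# A smooth random closed curve (Fourier perturbation of a circle).
random_closed_curve <- function(M = 40, seed = 1, c = 1) {
  set.seed(seed)
  th <- 2 * pi * (0:(M - 1)) / M
  r <- 1 + 0.2 * sin(2 * th + runif(1, 0, 2 * pi)) +
    0.1 * cos(3 * th + runif(1, 0, 2 * pi))
  boundary_curve(cbind(r * cos(th), r * sin(th)), ds = 2 * pi / M, c = c)
}

# Brute-force disk quadrature of the averaged chemo gradient (midpoint rule).
quadrature_direction <- function(chem, x, Rsc, npts = 100) {
  g <- chem_gradient(chem)
  s <- seq(-Rsc, Rsc, length.out = npts)
  pts <- as.matrix(expand.grid(x[1] + s, x[2] + s))
  keep <- (pts[, 1] - x[1])^2 + (pts[, 2] - x[2])^2 <= Rsc^2
  pts <- pts[keep, ]
  gx <- interp_bilinear(g$dx, pts, chem$h, origin = chem$h / 2, periodic = FALSE)
  gy <- interp_bilinear(g$dy, pts, chem$h, origin = chem$h / 2, periodic = FALSE)
  v <- c(mean(gx), mean(gy))
  v / sqrt(sum(v^2))
}
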