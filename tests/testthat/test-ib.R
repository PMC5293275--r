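# Immersed-boundary structures: delta kernel, spreading/interpolation,
# elastic and tether forces, curve geometry.

test_that("delta kernel satisfies symmetry and moment conditions", {
  r <- seq(-2.5, 2.5, by = 0.01)
  expect_equal(ib_delta(r), ib_delta(-r))
  set.seed(42)
  x <- runif(1000, 0, 50)
  for (xx in x[1:50]) {
    j <- floor(xx) + (-3:4)
    expect_lt(abs(sum(ib_delta(xx - j)) - 1), 1e-14)
    expect_lt(abs(sum((j - xx) * ib_delta(xx - j))), 1e-13)
  }
  # even/odd grid sums are each 1/2 (the 4-point kernel postulate)
  xx <- 0.3
  j <- floor(xx) + (-3:4)
  w <- ib_delta(xx - j)
  expect_lt(abs(sum(w[j %% 2 == 0]) - 0.5), 1e-14)
})

test_that("spreading conserves total force exactly", {
  set.seed(3)
  N <- 32; h <- 0.25; M <- 25
  X <- cbind(runif(M, 0, N * h), runif(M, 0, N * h))
  Fn <- matrix(rnorm(2 * M), M)
  ds <- 0.1
  sf <- spread_forces(Fn, X, N, h, ds)
  expect_equal(h^2 * sum(sf$fx), sum(Fn[, 1]) * ds, tolerance = 1e-12)
  expect_equal(h^2 * sum(sf$fy), sum(Fn[, 2]) * ds, tolerance = 1e-12)
  z <- spread_forces(matrix(0, M, 2), X, N, h, ds)
  expect_equal(max(abs(z$fx)), 0)
})

test_that("spread and interpolate are exact adjoints", {
  set.seed(11)
  N <- 48; h <- 0.11
  for (rep in 1:5) {
    M <- sample(10:60, 1)
    X <- cbind(runif(M, 0, N * h), runif(M, 0, N * h))
    Fn <- matrix(rnorm(2 * M), M)
    ds <- runif(1, 0.01, 0.3)
    u <- matrix(rnorm(N * N), N); v <- matrix(rnorm(N * N), N)
    sf <- spread_forces(Fn, X, N, h, ds)
    U <- interpolate_velocity(u, v, X, N, h)
    lhs <- sum((Fn[, 1] * U[, 1] + Fn[, 2] * U[, 2]) * ds)
    rhs <- h^2 * sum(sf$fx * u + sf$fy * v)
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("interpolation reproduces uniform and linear fields", {
  N <- 32; h <- 0.5
  u <- matrix(1, N, N); v <- matrix(0, N, N)
  X <- cbind(runif(10, 2, 10), runif(10, 2, 10))
  U <- interpolate_velocity(u, v, X, N, h)
  expect_equal(U[, 1], rep(1, 10), tolerance = 1e-12)
  expect_equal(U[, 2], rep(0, 10), tolerance = 1e-12)
  co <- (0:(N - 1)) * h
  ulin <- matrix(co, N, N)             # u = x
  Ul <- interpolate_velocity(ulin, v, X, N, h)
  expect_equal(Ul[, 1], X[, 1], tolerance = 1e-12)  # exact by moments
})

test_that("non-finite force densities abort with the node index", {
  X <- cbind(1:10, 1:10)
  Fn <- matrix(0, 10, 2); Fn[4, 1] <- Inf
  expect_error(spread_forces(Fn, X, 32, 0.5, 0.1), "node 4")
})

test_that("elastic force of a circle is radially symmetric with zero sum", {
  cv <- circle_curve(c(0, 0), 1, M = 64, c = 2)
  Fe <- elastic_force(cv)
  mag <- sqrt(rowSums(Fe^2))
  expect_lt(diff(range(mag)) / mean(mag), 1e-10)
  inward <- rowSums(Fe * cv$X)
  expect_true(all(inward < 0))                     # pre-tension contracts
  expect_lt(max(abs(colSums(Fe) * cv$ds)), 1e-12 * max(mag))
})

test_that("elastic force matches the finite-difference energy gradient", {
  for (seed in 1:3) {
    cv <- random_closed_curve(M = 30, seed = seed, c = 1.7)
    Fe <- elastic_force(cv)
    Ffd <- fd_elastic_force(cv)
    expect_lt(max(abs(Fe - Ffd)) / max(abs(Fe)), 1e-6)
  }
})

test_that("coincident nodes raise an error", {
  cv <- circle_curve(c(0, 0), 1, M = 16, c = 1)
  cv$X[2, ] <- cv$X[1, ]
  expect_error(elastic_force(cv), "degenerate")
})

test_that("tether force is linear with the published normal-cell stiffness", {
  X <- matrix(c(0, 0), 1, 2)
  Z <- matrix(c(1, 0), 1, 2)
  expect_equal(as.numeric(tether_force(X, Z, 400)), c(400, 0))
  expect_equal(tether_force(X, 2 * Z, 400), 2 * tether_force(X, Z, 400))
  expect_equal(max(abs(tether_force(Z, Z, 400))), 0)
  expect_error(tether_force(matrix(0, 2, 2), Z, 400), "differ in length")
})

test_that("enclosed area: circle, glioma radius, translation invariance", {
  cv <- circle_curve(c(0, 0), 1, M = 2000, c = 0)
  expect_equal(enclosed_area(cv), pi, tolerance = 1e-4)
  gl <- circle_curve(c(0.005, 0.005), 5e-4, M = 400, c = 0)
  expect_equal(enclosed_area(gl), pi * (5e-4)^2, tolerance = 1e-4)
  cv2 <- cv; cv2$X <- sweep(cv2$X, 2, c(3.2, -1.4), "+")
  expect_equal(enclosed_area(cv2), enclosed_area(cv), tolerance = 1e-12)
})

test_that("resampling restores uniform spacing and preserves area", {
  # nodes clustered on one side of a circle: the node spacing is stretched
  # 2x on the far side while the shape is unchanged
  th <- 2 * pi * stats::pbeta((0:99) / 100, 1.6, 1)
  cv <- boundary_curve(cbind(cos(th), sin(th)), ds = 2 * pi / 100, c = 1)
  a0 <- enclosed_area(cv)
  rs <- resample_curve(cv, target_ds = cv$ds)
  seg <- sqrt(rowSums((rs$X[c(2:nrow(rs$X), 1), ] - rs$X)^2))
  expect_lt(diff(range(seg)) / mean(seg), 0.01)
  expect_lt(abs(enclosed_area(rs) - a0) / a0, 1e-3)
  # an already-uniform curve is unchanged
  cu <- circle_curve(c(0, 0), 1, M = 50, c = 0)
  ru <- resample_curve(cu)
  expect_equal(nrow(ru$X), 50)
  expect_lt(max(abs(ru$X - cu$X)), 1e-10)
})

test_that("curve orientation is normalized and nucleus containment enforced", {
  th <- 2 * pi * (0:19) / 20
  Xcw <- cbind(cos(-th), sin(-th))      # clockwise input
  cv <- boundary_curve(Xcw, ds = 0.3, c = 1)
  expect_gt(gliomaIB:::.shoelace_signed(cv$X), 0)
  expect_error(
    glioma_cell(c(0, 0), 1, nucleus_radius = 1.2, ce_m = 1, ce_n_b = 1,
                ct = 1, target_ds = 0.2),
    "nucleus")
})
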