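# Trace observables.

synthetic_trace <- function(n = 50, dt = 60) {
  t <- dt * (1:n)
  data.frame(t = t, cx = 0.005, cy = 0.002 + 1e-7 * t,
             nucleus_min_y = 0.002 + 1e-7 * t,
             membrane_max_y = 0.003 + 1e-7 * t,
             Lperp = 1 - 0.05 * sin(t / 500)^2,
             LperpW = 1, LperpE = 1)
}

test_that("body length: circle diameter, ellipse major axis, brute force", {
  cv <- circle_curve(c(0, 0), 2, M = 200, c = 0)
  expect_equal(body_length(cv, c(0, 1)), 4, tolerance = 1e-3)
  expect_equal(body_length(cv, c(1, 1)), 4, tolerance = 1e-3)
  th <- 2 * pi * (0:199) / 200
  ell <- boundary_curve(cbind(1.2 * cos(th), 3 * sin(th)), ds = 0.05, c = 0)
  expect_equal(body_length(ell, c(0, 1)), 6, tolerance = 1e-3)
  set.seed(6)
  X <- matrix(rnorm(40), 20)
  X <- X[order(atan2(X[, 2] - mean(X[, 2]), X[, 1] - mean(X[, 1]))), ]
  d <- c(0.6, 0.8)
  brute <- max(outer(X %*% d, X %*% d, "-"))
  expect_equal(body_length(X, d), brute, tolerance = 1e-12)
})

test_that("deformation ratio is 1 at rest, invariant to rigid translation", {
  cell <- glioma_cell(c(0, 0), 1, 0.5, ce_m = 1, ce_n_b = 1, ct = 1,
                      target_ds = 0.05)
  expect_equal(deformation_ratio(cell)$Lperp, 1, tolerance = 1e-12)
  cell$nucleus$X <- sweep(cell$nucleus$X, 2, c(0.3, -0.1), "+")
  cell$markers$Xnc <- cell$markers$Xnc + c(0.3, -0.1)
  expect_equal(deformation_ratio(cell)$Lperp, 1, tolerance = 1e-12)
  # uniform 50% lateral compression about the center
  cell2 <- glioma_cell(c(0, 0), 1, 0.5, ce_m = 1, ce_n_b = 1, ct = 1,
                       target_ds = 0.05)
  cell2$nucleus$X[, 1] <- cell2$nucleus$X[, 1] * 0.5
  # W/E markers sit on discrete nodes near (but not exactly at) the poles
  expect_equal(deformation_ratio(cell2)$Lperp, 0.5, tolerance = 5e-3)
})

test_that("average speed: zero when stationary, exact on synthetic motion", {
  tr <- synthetic_trace()
  tr0 <- tr; tr0$cy <- 0.002
  expect_equal(average_speed(tr0), 0)
  # cy advances 1e-7 cm/s = 3.6 um/h
  expect_equal(average_speed(tr), 3.6, tolerance = 1e-9)
  # hand-computed piecewise trajectory
  tr2 <- data.frame(t = c(0, 1800, 3600), cx = c(0, 0, 0),
                    cy = c(0, 10e-4, 10e-4))
  expect_equal(average_speed(tr2, c(0, 3600)), 10, tolerance = 1e-12)
  expect_equal(average_speed(tr2, c(1800, 3600)), 0)
})

test_that("passing classification distinguishes the three outcomes", {
  tr <- synthetic_trace()
  # never reaches the gap
  low <- tr; low$membrane_max_y <- 0.0031; low$nucleus_min_y <- 0.002
  expect_equal(classify_passing(low, 0.005)$status, "non_invasive")
  # membrane enters, nucleus does not cross
  mid <- tr; mid$membrane_max_y <- 0.006; mid$nucleus_min_y <- 0.004
  expect_equal(classify_passing(mid, 0.005)$status, "in_process")
  # nucleus fully crosses at a known time
  hi <- tr
  hi$membrane_max_y <- 0.007
  hi$nucleus_min_y <- 0.004 + (hi$t >= 1500) * 0.002
  out <- classify_passing(hi, 0.005)
  expect_equal(out$status, "passed")
  expect_equal(out$passing_time, min(hi$t[hi$t >= 1500]))
  # horizon cuts off the crossing
  expect_equal(classify_passing(hi, 0.005, T_end = 1200)$status, "in_process")
})

test_that("trough counting: constant, sinusoid, prescribed dips", {
  expect_equal(count_troughs(rep(1, 100))$count, 0)
  t <- seq(0, 3 * 3600, by = 60)
  s <- 1 - 0.3 * pmax(0, sin(2 * pi * t / 3600))   # 3 dips below 0.9
  out <- count_troughs(s, baseline = 0.9, min_separation = 1800, t = t)
  expect_equal(out$count, 3)
  # dips at prescribed times recovered
  s2 <- rep(1, length(t))
  for (tc in c(3600, 7200)) s2 <- s2 - 0.5 * exp(-((t - tc) / 300)^2)
  out2 <- count_troughs(s2, baseline = 0.9, min_separation = 1800, t = t)
  expect_equal(out2$count, 2)
  expect_equal(out2$times, c(3600, 7200), tolerance = 60)
})

test_that("direction angle sign convention (NE positive, NW negative)", {
  expect_equal(direction_angle(0, 1), 0)
  expect_equal(direction_angle(1, 1), 45)
  expect_equal(direction_angle(-1, 1), -45)
})

test_that("metrics are pure: re-running on a saved trace is bit-identical", {
  tr <- synthetic_trace()
  a <- classify_passing(tr, 0.005)
  b <- classify_passing(tr, 0.005)
  expect_identical(a, b)
  expect_identical(average_speed(tr), average_speed(tr))
})
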