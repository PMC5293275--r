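# Migration cycle, direction sensing and active force.

test_that("migration direction follows a uniform gradient exactly", {
  ch <- chem_field(32, 0.01)
  co <- ((1:32) - 0.5) * ch$h
  ch$C <- matrix(co, 32, 32, byrow = TRUE)   # C = a*y
  d <- migration_direction(ch, c(0.005, 0.005), Rsc = 0.4e-4)
  expect_equal(d, c(0, 1), tolerance = 1e-10)
})

test_that("a flat field retains the previous direction", {
  ch <- chem_field(32, 0.01)
  ch$C <- matrix(1, 32, 32)
  prev <- c(sqrt(0.5), sqrt(0.5))
  expect_equal(migration_direction(ch, c(0.005, 0.005), 0.4e-4, prev = prev),
               prev)
})

test_that("disk-averaged direction matches brute-force quadrature", {
  ch <- chem_field(64, 0.01)
  ch <- place_source(ch, c(0.0075, 0.0085))
  for (i in 1:200) ch <- step_chem(ch, 2)
  x <- c(0.004, 0.004)
  Rsc <- 6 * ch$h                            # resolved disk -> quadrature path
  d <- migration_direction(ch, x, Rsc)
  dq <- quadrature_direction(ch, x, Rsc)
  ang <- acos(min(1, sum(d * dq))) * 180 / pi
  expect_lt(ang, 1)
})

test_that("chemotactic force strength has the published values and bound", {
  cf0 <- chemotactic_force_strength(c(0, 0))
  expect_equal(cf0$Fc, 0)
  expect_equal(cf0$ca, 0.7 * 0.15)           # = 0.105, the basal drive
  gmax <- 1 / sqrt(20)
  cfm <- chemotactic_force_strength(c(gmax, 0))
  expect_equal(cfm$Fc, 1 / (2 * sqrt(20)))   # global maximum ~ 0.1118
  set.seed(8)
  for (i in 1:100) {
    g <- rnorm(2) * 10^runif(1, -3, 4)
    expect_lte(chemotactic_force_strength(g)$Fc, 1 / (2 * sqrt(20)) + 1e-15)
  }
  big <- chemotactic_force_strength(c(1e8, 0))
  expect_lt(big$Fc, 1e-6)                    # bounded as |grad C| -> infinity
})

test_that("active force acts on front nodes during elongation only", {
  cell <- glioma_cell(c(0, 0), 1, 0.5, ce_m = 1, ce_n_b = 1, ct = 1,
                      target_ds = 0.1)
  cell <- select_front_rear(cell, c(0, 1))
  Fa <- active_force(cell, "retraction", ca = 0.105, dir = c(0, 1))
  expect_equal(max(abs(Fa)), 0)
  Fa <- active_force(cell, "elongation", ca = 0.105, dir = c(0, 1))
  expect_equal(unique(Fa[cell$front_nodes, 2]), 0.105)
  others <- setdiff(seq_len(nrow(Fa)), cell$front_nodes)
  expect_equal(max(abs(Fa[others, ])), 0)
  # linear in chi through ca
  expect_equal(active_force(cell, "elongation", 0.21, c(0, 1)),
               2 * Fa)
})

test_that("front and rear arcs are disjoint and face opposite ways", {
  cell <- glioma_cell(c(0, 0), 1, 0.5, ce_m = 1, ce_n_b = 1, ct = 1,
                      target_ds = 0.05, front_halfwidth = 60)
  cell <- select_front_rear(cell, c(0, 1))
  expect_length(intersect(cell$front_nodes, cell$rear_nodes), 0)
  expect_true(all(cell$membrane$X[cell$front_nodes, 2] > 0))
  expect_true(all(cell$membrane$X[cell$rear_nodes, 2] < 0))
})

test_that("phase switches at the retention-rate crossing of a known ramp", {
  # L'(t) = 4 delta+ * exp(-t/20): crosses delta+ at t = 20 log 4
  dp <- 2e-6
  cyc <- migration_cycle(dp, -dp, max_phase_duration = 1e6,
                         smooth_window = 5)
  dt <- 0.5
  t <- 0; L <- 0.002
  tcross <- NA
  for (i in 1:400) {
    t <- t + dt
    L <- L + 4 * dp * exp(-t / 20) * dt
    cyc <- update_phase(cyc, L, t)
    if (cyc$switched) { tcross <- t; break }
  }
  expect_equal(tcross, 20 * log(4), tolerance = 0.15)
  expect_equal(cyc$phase, "retraction")
})

test_that("no switch while L' stays above the retention rate", {
  dp <- 2e-6
  cyc <- migration_cycle(dp, -dp, max_phase_duration = 1e6, smooth_window = 5)
  t <- 0; L <- 0.002
  for (i in 1:100) {
    t <- t + 0.5
    L <- L + 2 * dp * 0.5          # constant L' = 2 delta+
    cyc <- update_phase(cyc, L, t)
  }
  expect_equal(cyc$phase, "elongation")
  expect_equal(nrow(cyc$switches), 0)
})

test_that("phases alternate strictly and time out at max duration", {
  cyc <- migration_cycle(1e-6, -1e-6, max_phase_duration = 5,
                         smooth_window = 3)
  t <- 0
  for (i in 1:200) {
    t <- t + 0.5
    cyc <- update_phase(cyc, 0.002, t)   # flat L: only timeouts fire
  }
  sw <- cyc$switches
  expect_gt(nrow(sw), 3)
  expect_true(all(sw$from != sw$to))
  expect_true(all(sw$from[-1] == sw$to[-nrow(sw)]))  # strict alternation
})

test_that("membrane force decomposes into its independent terms", {
  cell <- glioma_cell(c(0, 0), 1, 0.5, ce_m = 1.3, ce_n_b = 1, ct = 7,
                      target_ds = 0.1)
  cell <- select_front_rear(cell, c(0, 1))
  cell <- freeze_anchors(cell, "elongation")
  # displace so tether forces are non-trivial
  cell$membrane$X <- cell$membrane$X + 0.05 * matrix(
    sin(1:(2 * nrow(cell$membrane$X))), ncol = 2)
  Ftot <- glioma_membrane_force(cell, "elongation", ca = 0.3, dir = c(0, 1))
  Fe <- elastic_force(cell$membrane)
  Ft <- matrix(0, nrow(Fe), 2)
  Ft[cell$rear_nodes, ] <- tether_force(
    cell$membrane$X[cell$rear_nodes, , drop = FALSE], cell$Zr, cell$ct)
  Fa <- active_force(cell, "elongation", 0.3, c(0, 1))
  expect_equal(Ftot, Fe + Ft + Fa, tolerance = 1e-12)
})
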