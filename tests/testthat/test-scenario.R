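# Scenario construction, orchestration, determinism and sweeps. Runs here
# use short horizons of the reduced-scale fixtures; the full mechanism check
# lives in test-acceptance.R.

test_that("configuration merging and published defaults", {
  cfg <- scenario_config()
  expect_equal(cfg$domain$L, 0.01)
  expect_equal(cfg$domain$N, 512L)
  expect_equal(cfg$time$dt, 0.004)
  expect_equal(cfg$fluid$rho, 1.35)
  expect_equal(cfg$fluid$mu, 2.7)
  expect_equal(cfg$glioma$radius, 5e-4)
  expect_equal(cfg$glioma$ce_m, 3.8e-5)
  expect_equal(cfg$glioma$ct, 1500)
  expect_equal(cfg$normals$radius, 8e-4)
  expect_equal(cfg$normals$ce, 0.0023)
  expect_equal(cfg$normals$ct, 400)
  expect_equal(cfg$motility$chi, 0.7)
  expect_equal(cfg$motility$lambda_s, 20)
  expect_equal(cfg$myosin$Rs, 4.69e-4)
  expect_equal(cfg$chem$lam_in, 0.82)
  ov <- scenario_config(glioma = list(kp = 0.045), domain = list(N = 64L))
  expect_equal(ov$glioma$kp, 0.045)
  expect_equal(ov$domain$N, 64L)
  expect_equal(ov$glioma$radius, 5e-4)   # untouched defaults survive
})

test_that("layout generators produce the documented geometries", {
  cfg <- fixture_generator("mini_two_gap")
  ctrs <- normal_layout(cfg)
  expect_equal(nrow(ctrs), 2)
  gap <- (ctrs[2, 1] - ctrs[1, 1]) - 2 * cfg$normals$radius
  expect_equal(gap, cfg$normals$gap)
  expect_lt(gap, 2 * cfg$glioma$nucleus_radius)  # narrower than the nucleus
  cfg$normals$layout <- "astrocyte_pair"; cfg$normals$d <- 4e-4
  ctrs <- normal_layout(cfg)
  expect_equal((ctrs[2, 1] - ctrs[1, 1]) - 2 * cfg$normals$radius, 4e-4)
  for (th in c(11.3, 16.7, 21.8)) {
    cfg$normals$layout <- "turning_angle"; cfg$normals$theta <- th
    ctrs <- normal_layout(cfg)
    expect_equal(nrow(ctrs), 6)
    # the two gap-connecting vectors subtend 2*theta
    gaps <- cbind((ctrs[c(1, 3, 5), 1] + ctrs[c(2, 4, 6), 1]) / 2,
                  ctrs[c(1, 3, 5), 2])
    v1 <- gaps[2, ] - gaps[1, ]; v2 <- gaps[3, ] - gaps[2, ]
    ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
    expect_equal(ang, 2 * th, tolerance = 1e-6)
  }
  expect_error(normal_layout(scenario_config(normals = list(layout = "nope"))),
               "unknown layout")
})

test_that("geometry validation rejects overlap and out-of-domain cells", {
  cfg <- fixture_generator("mini_two_gap",
                           glioma = list(center = c(0.005, 0.0045)))
  expect_error(build_scenario(cfg), "overlaps glioma")
  cfg2 <- fixture_generator("mini_two_gap",
                            glioma = list(center = c(0.0005, 0.0031)))
  expect_error(build_scenario(cfg2), "outside domain|overlaps")
})

test_that("build produces a quiescent, well-initialized state", {
  sim <- build_scenario(fixture_generator("mini_two_gap"))
  expect_equal(max(abs(sim$fluid$ux)), 0)
  expect_equal(max(abs(sim$chem$C)), 0)
  expect_equal(sim$myosin$mb, 0)                 # steady state at zero p
  expect_equal(sim$cycle$phase, "elongation")
  expect_false(is.null(sim$glioma$Zr))
  expect_gt(length(sim$glioma$front_nodes), 0)
  # node spacing about h/2
  ds <- sim$glioma$membrane$ds
  expect_lt(abs(ds - sim$fluid$h / 2) / (sim$fluid$h / 2), 0.1)
})

test_that("identical configurations give identical runs (determinism)", {
  cfg <- fixture_generator("mini_two_gap")
  r1 <- run_simulation(build_scenario(cfg), T_end = 5)
  r2 <- run_simulation(build_scenario(cfg), T_end = 5)
  expect_identical(r1$trace, r2$trace)
})

test_that("restart from the returned state continues bit-exactly", {
  cfg <- fixture_generator("mini_two_gap")
  full <- run_simulation(build_scenario(cfg), T_end = 6)
  part <- run_simulation(build_scenario(cfg), T_end = 3)
  rest <- run_simulation(part$sim, T_end = 6)
  n <- nrow(full$trace)
  expect_equal(rest$sim$glioma$membrane$X, full$sim$glioma$membrane$X,
               tolerance = 1e-14)
  lastf <- full$trace[n, ]; rownames(lastf) <- NULL
  lastr <- rest$trace[nrow(rest$trace), ]; rownames(lastr) <- NULL
  expect_identical(lastf, lastr)
})

test_that("no chemoattractant and no active force give no directed drift", {
  cfg <- fixture_generator("mini_quiescent")
  res <- run_simulation(build_scenario(cfg), T_end = 60)
  tr <- res$trace
  h <- cfg$domain$L / cfg$domain$N
  disp <- sqrt((tail(tr$cx, 1) - tr$cx[1])^2 + (tail(tr$cy, 1) - tr$cy[1])^2)
  expect_lt(disp, h)
})

test_that("sweeps cover the axis grid and record failures without stopping", {
  cfg <- fixture_generator("mini_two_gap")
  res <- run_sweep(cfg, axes = list(`glioma.kp` = c(0.9, 0.045),
                                    `glioma.fold` = 1),
                   T_end = 2)
  expect_equal(nrow(res), 2)
  expect_true(all(res$status == "non_invasive"))   # nothing moves in 2 s
  # an invalid geometry on one axis point is recorded, not fatal
  res2 <- run_sweep(cfg, axes = list(`normals.gap` = c(6e-4, -30e-4)),
                    T_end = 2)
  expect_equal(sum(is.na(res2$status)), 1)
  expect_match(res2$error[is.na(res2$status)], "overlap")
})

test_that("fixture registry lists known names and rejects unknown ones", {
  expect_error(fixture_generator("nope"), "available")
  ode <- fixture_generator("ode_only")
  expect_equal(ode$ps_fun(200 * 60), 1)   # high plateau
  expect_equal(ode$ps_fun(500 * 60), 0)   # low phase
  tg <- fixture_generator("taylor_green")
  expect_equal(tg$kind, "taylor_green")
})

test_that("instability is reported with step diagnostics, not silence", {
  # absurd stiffness with substepping disabled must be caught
  cfg <- fixture_generator("mini_two_gap",
                           glioma = list(ce_m = 10),
                           numerics = list(substep_safety = 1e9))
  sim <- build_scenario(cfg)
  expect_error(run_simulation(sim, T_end = 10),
               "non-finite|instability|stability")
})
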