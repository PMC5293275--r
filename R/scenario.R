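# Scenario construction and the coupled time loop. A scenario couples, per
# step: boundary forces -> spreading -> fluid solve -> interpolation /
# advection -> chemoattractant step -> pressure sensing and myosin kinetics
# -> drug kinetics -> phase update -> metrics. The model is fully
# deterministic: identical configurations give identical outputs.

#' Build a scenario configuration
#'
#' Returns the full configuration list with the published parameter set as
#' defaults (0.1 mm box, 512^2 grid, dt = 0.004 s, CGS cell mechanics,
#' wild-type myosin sensitivity) and any overrides merged in recursively.
#'
#' @param ... named overrides, e.g. \code{glioma = list(kp = 0.045)},
#'   \code{domain = list(N = 64)}.
#' @return a nested configuration list of class \code{scenario_config}.
#' @export
scenario_config <- function(...) {
  cfg <- list(
    name = "custom",
    domain = list(L = 0.01, N = 512L),
    time = list(dt = 0.004, T_end = 3 * 3600, record_stride = 25L),
    fluid = list(rho = 1.35, mu = 2.7, advect = TRUE, drop_mean_force = TRUE),
    glioma = list(center = c(0.005, 0.0026), radius = 5e-4,
                  nucleus_radius = 3e-4, ce_m = 3.8e-5, ce_n_b = 3.8e-5,
                  ct = 1500, kp = 0.9, fold = 1, front_halfwidth = 60),
    normals = list(layout = "two_gap", radius = 8e-4, ce = 0.0023, ct = 400,
                   gap = 4e-4, gap_y = 0.005, centers = NULL,
                   theta = 11.3, d = 4e-4),
    chem = list(DC = 2.15e-6, lam_in = 0.82, muC = 1e-6,
                source = c(0.005, 0.009), source_radius = NULL, stride = 1L),
    myosin = list(mT = 1, k1 = 0.002, k_1 = 1e-4, Rs = 4.69e-4,
                  pressure_scale = 1, stride = 5L),
    stiffening = list(ks = 5, ks_min = 0.1, Kmb = 1.8, n = 10),
    motility = list(chi = 0.7, alpha_sig = 0.15, lambda_s = 20, Rsc = 0.4e-4,
                    delta_ret_plus = 2e-6, delta_ret_minus = -2e-6,
                    max_phase_duration = 120, smooth_window = 5,
                    dir_stride = 10L),
    drugs = list(),
    numerics = list(ds_factor = 0.5, substep_safety = 0.5)
  )
  ov <- list(...)
  cfg <- .merge_cfg(cfg, ov)
  class(cfg) <- "scenario_config"
  cfg
}

.merge_cfg <- function(base, ov) {
  for (nm in names(ov)) {
    if (is.list(ov[[nm]]) && is.list(base[[nm]]) && !is.null(names(ov[[nm]])))
      base[[nm]] <- .merge_cfg(base[[nm]], ov[[nm]])
    else base[[nm]] <- ov[[nm]]
  }
  base
}

# ---- normal-cell layout generators ----

#' Normal-cell center layouts
#'
#' Generates the center coordinates of the tethered normal cells for the
#' scenario geometries: \code{two_gap} (a pair straddling a vertical gap),
#' \code{multilayer} (staggered rows), \code{zigzag} (rows whose gaps
#' alternate sides), \code{turning_angle} (six cells in three rows with gap
#' columns tilted by +/- theta), \code{astrocyte_pair} (a pair at
#' separation d) and \code{explicit} (centers given directly).
#'
#' @param cfg a [scenario_config()]; uses \code{cfg$normals} and the domain.
#' @return matrix of centers (cm).
#' @export
normal_layout <- function(cfg) {
  nc <- cfg$normals
  L <- cfg$domain$L
  r <- nc$radius
  switch(nc$layout,
    explicit = {
      if (is.null(nc$centers)) stop("layout 'explicit' needs normals$centers")
      as.matrix(nc$centers)
    },
    two_gap = {
      off <- r + nc$gap / 2
      rbind(c(L / 2 - off, nc$gap_y), c(L / 2 + off, nc$gap_y))
    },
    astrocyte_pair = {
      off <- r + nc$d / 2
      rbind(c(L / 2 - off, nc$gap_y), c(L / 2 + off, nc$gap_y))
    },
    multilayer = {
      dy <- 2 * r + nc$gap
      rows <- seq(nc$gap_y, L - r, by = dy)
      ctrs <- NULL
      for (k in seq_along(rows)) {
        xshift <- if (k %% 2 == 0) r + nc$gap / 2 else 0
        xs <- seq(r * 0.6 + xshift, L - r * 0.6, by = 2 * r + nc$gap)
        ctrs <- rbind(ctrs, cbind(xs, rows[k]))
      }
      ctrs
    },
    zigzag = {
      dy <- 2 * r + nc$gap
      rows <- seq(nc$gap_y, L - r, by = dy)
      ctrs <- NULL
      for (k in seq_along(rows)) {
        sh <- if (k %% 2 == 0) nc$gap else -nc$gap
        off <- r + nc$gap / 2
        ctrs <- rbind(ctrs,
                      rbind(c(L / 2 - off + sh, rows[k]),
                            c(L / 2 + off + sh, rows[k])))
      }
      ctrs
    },
    turning_angle = {
      # three rows of two cells; successive gap positions offset so the two
      # inter-row connecting vectors subtend the turning angle theta
      dy <- 2 * r + nc$gap
      y0 <- nc$gap_y
      sh <- dy * tan(nc$theta * pi / 180)
      off <- r + nc$gap / 2
      gx <- c(L / 2, L / 2 + sh, L / 2)
      ctrs <- NULL
      for (k in 1:3)
        ctrs <- rbind(ctrs,
                      rbind(c(gx[k] - off, y0 + (k - 1) * dy),
                            c(gx[k] + off, y0 + (k - 1) * dy)))
      ctrs
    },
    stop(sprintf("unknown layout '%s'", nc$layout))
  )
}

# ---- scenario assembly ----

#' Initialize a simulation from a configuration
#'
#' Builds the fluid at rest, samples all cell curves at about h/2 node
#' spacing, installs the chemoattractant source, selects the initial
#' front/rear arcs from the initial direction (toward the source), freezes
#' the elongation anchors and starts the myosin kinetics at the zero-pressure
#' steady state. Validates that every cell lies inside the domain and that
#' no two cells overlap.
#'
#' @param cfg a [scenario_config()].
#' @return an object of class \code{ib_simulation}.
#' @export
build_scenario <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  L <- cfg$domain$L; N <- as.integer(cfg$domain$N)
  h <- L / N
  ds <- cfg$numerics$ds_factor * h
  fl <- fluid_state(N, L, cfg$fluid$rho, cfg$fluid$mu, dt = cfg$time$dt)
  ch <- chem_field(N, L, cfg$chem$DC, cfg$chem$lam_in, cfg$chem$muC)
  ch <- place_source(ch, cfg$chem$source, cfg$chem$source_radius)

  gl <- glioma_cell(cfg$glioma$center, cfg$glioma$radius,
                    cfg$glioma$nucleus_radius, cfg$glioma$ce_m,
                    cfg$glioma$ce_n_b, cfg$glioma$ct, target_ds = ds,
                    fold = cfg$glioma$fold,
                    front_halfwidth = cfg$glioma$front_halfwidth)
  ctrs <- normal_layout(cfg)
  normals <- lapply(seq_len(nrow(ctrs)), function(i)
    normal_cell(ctrs[i, ], cfg$normals$radius, cfg$normals$ce,
                cfg$normals$ct, target_ds = ds))
  .validate_geometry(cfg, ctrs)

  dir0 <- cfg$chem$source - cfg$glioma$center
  dir0 <- dir0 / sqrt(sum(dir0^2))
  gl <- select_front_rear(gl, dir0)
  gl <- freeze_anchors(gl, "elongation")

  ms <- myosin_state(cfg$myosin$mT, cfg$myosin$k1, cfg$myosin$k_1,
                     cfg$glioma$kp, cfg$myosin$Rs, mb = 0,
                     pressure_scale = cfg$myosin$pressure_scale)
  sp <- stiffening_params(cfg$glioma$ce_n_b, cfg$stiffening$ks,
                          cfg$stiffening$ks_min, cfg$stiffening$Kmb,
                          cfg$stiffening$n, cfg$glioma$fold)
  gl$ce_n <- nucleus_stiffness(stiffening_rate(ms$mb, sp), sp)
  drugs <- lapply(cfg$drugs, function(d) do.call(drug_state, d))
  cyc <- migration_cycle(cfg$motility$delta_ret_plus,
                         cfg$motility$delta_ret_minus,
                         cfg$motility$max_phase_duration,
                         cfg$motility$smooth_window)

  sim <- list(cfg = cfg, fluid = fl, chem = ch, glioma = gl,
              normals = normals, myosin = ms, stiff = sp, drugs = drugs,
              cycle = cyc, dir = dir0, ps = 0, ca = 0, Fc = 0,
              rs_kernel = disk_kernel_hat(N, L, cfg$myosin$Rs),
              gap_line_y = cfg$normals$gap_y, t = 0, step = 0L)
  class(sim) <- "ib_simulation"
  sim
}

.validate_geometry <- function(cfg, ctrs) {
  L <- cfg$domain$L
  rG <- cfg$glioma$radius; rN <- cfg$normals$radius
  bad <- character(0)
  cg <- cfg$glioma$center
  if (any(cg - rG < 0) || any(cg + rG > L))
    bad <- c(bad, "glioma outside domain")
  for (i in seq_len(nrow(ctrs))) {
    if (any(ctrs[i, ] - rN < 0) || any(ctrs[i, ] + rN > L))
      bad <- c(bad, sprintf("normal cell %d outside domain", i))
    if (sqrt(sum((ctrs[i, ] - cg)^2)) < rG + rN)
      bad <- c(bad, sprintf("normal cell %d overlaps glioma", i))
    if (i < nrow(ctrs)) for (j in (i + 1):nrow(ctrs)) {
      if (sqrt(sum((ctrs[i, ] - ctrs[j, ])^2)) < 2 * rN - 1e-12)
        bad <- c(bad, sprintf("normal cells %d and %d overlap", i, j))
    }
  }
  if (length(bad)) stop("invalid geometry: ", paste(bad, collapse = "; "))
  invisible(TRUE)
}

# Assemble the force density on every Lagrangian node (glioma membrane,
# nucleus, normal membranes), returning stacked positions, forces and
# per-node ds weights.
.assemble_forces <- function(sim) {
  gl <- sim$glioma
  Fm <- glioma_membrane_force(gl, sim$cycle$phase, sim$ca, sim$dir)
  Fn <- elastic_force(gl$nucleus, c = gl$ce_n)
  Xs <- list(gl$membrane$X, gl$nucleus$X)
  Fs <- list(Fm, Fn)
  dss <- list(rep(gl$membrane$ds, nrow(Fm)), rep(gl$nucleus$ds, nrow(Fn)))
  for (ncell in sim$normals) {
    Fe <- elastic_force(ncell$membrane) +
      tether_force(ncell$membrane$X, ncell$ZN, ncell$ct)
    Xs <- c(Xs, list(ncell$membrane$X))
    Fs <- c(Fs, list(Fe))
    dss <- c(dss, list(rep(ncell$membrane$ds, nrow(Fe))))
  }
  list(X = do.call(rbind, Xs), F = do.call(rbind, Fs),
       ds = unlist(dss),
       sizes = vapply(Xs, nrow, integer(1)))
}

# Advect all curves and the nucleus-center marker with the current velocity.
.advect_structures <- function(sim, dt) {
  gl <- sim$glioma
  Xall <- rbind(gl$membrane$X, gl$nucleus$X,
                do.call(rbind, lapply(sim$normals, function(x) x$membrane$X)),
                matrix(gl$markers$Xnc, 1, 2))
  U <- interpolate_velocity(sim$fluid$ux, sim$fluid$uy, Xall,
                            sim$fluid$N, sim$fluid$h)
  Xall <- Xall + dt * U
  i <- nrow(gl$membrane$X)
  gl$membrane$X <- Xall[1:i, , drop = FALSE]
  j <- i + nrow(gl$nucleus$X)
  gl$nucleus$X <- Xall[(i + 1):j, , drop = FALSE]
  for (k in seq_along(sim$normals)) {
    m <- nrow(sim$normals[[k]]$membrane$X)
    sim$normals[[k]]$membrane$X <- Xall[(j + 1):(j + m), , drop = FALSE]
    j <- j + m
  }
  gl$markers$Xnc <- as.numeric(Xall[j + 1, ])
  sim$glioma <- gl
  sim
}

#' Run the coupled simulation
#'
#' Executes the fixed step ordering (forces, spreading, fluid solve,
#' advection, chemoattractant, sensing/kinetics, drugs, phase update,
#' metrics) until \code{T_end}, sub-stepping the fluid-structure update when
#' the stability bound requires it. Aborts with step diagnostics if any
#' field becomes non-finite.
#'
#' @param sim an [build_scenario()] simulation (or a previous result's
#'   \code{$sim}, for restart).
#' @param T_end horizon in seconds; default from the configuration.
#' @param verbose print progress every ~10 percent.
#' @return list of class \code{ib_result} with \code{trace} (data frame) and
#'   \code{sim} (final state, restartable).
#' @export
run_simulation <- function(sim, T_end = sim$cfg$time$T_end, verbose = FALSE) {
  stopifnot(inherits(sim, "ib_simulation"))
  cfg <- sim$cfg
  dt <- cfg$time$dt
  stiff_summary <- list(
    ce = c(cfg$glioma$ce_m,
           cfg$glioma$fold * cfg$glioma$ce_n_b *
             (cfg$stiffening$ks + cfg$stiffening$ks_min),
           cfg$normals$ce),
    ct = c(cfg$glioma$ct, cfg$normals$ct),
    ds = sim$glioma$membrane$ds)
  dts <- stability_dt(sim$fluid, stiff_summary,
                      safety = cfg$numerics$substep_safety)
  nsub <- max(1L, as.integer(ceiling(dt / dts - 1e-9)))
  dt_sub <- dt / nsub
  nsteps <- as.integer(ceiling((T_end - sim$t) / dt - 1e-9))
  rows <- vector("list", nsteps %/% cfg$time$record_stride + 2L)
  nrow_rec <- 0L

  for (istep in seq_len(nsteps)) {
    sim$step <- sim$step + 1L
    # migration direction + chemotactic drive
    if (sim$step %% cfg$motility$dir_stride == 1L || cfg$motility$dir_stride == 1L) {
      ctr <- colMeans(sim$glioma$membrane$X)
      sim$dir <- migration_direction(sim$chem, ctr, cfg$motility$Rsc,
                                     prev = sim$dir)
      g <- chem_gradient(sim$chem)
      gc <- c(interp_bilinear(g$dx, rbind(ctr), sim$chem$h, sim$chem$h / 2,
                              periodic = FALSE),
              interp_bilinear(g$dy, rbind(ctr), sim$chem$h, sim$chem$h / 2,
                              periodic = FALSE))
      cf <- chemotactic_force_strength(gc, cfg$motility$lambda_s,
                                       cfg$motility$chi, cfg$motility$alpha_sig)
      sim$Fc <- cf$Fc; sim$ca <- cf$ca
    }
    # fluid-structure sub-steps
    for (isub in seq_len(nsub)) {
      asm <- .assemble_forces(sim)
      sf <- spread_forces(asm$F, asm$X, sim$fluid$N, sim$fluid$h, asm$ds)
      sim$fluid <- navier_stokes_step(sim$fluid, sf$fx, sf$fy, dt_sub,
                                      advect = cfg$fluid$advect,
                                      drop_mean_force = cfg$fluid$drop_mean_force)
      sim <- .advect_structures(sim, dt_sub)
    }
    # chemoattractant
    if (sim$step %% cfg$chem$stride == 0L)
      sim$chem <- step_chem(sim$chem, dt * cfg$chem$stride)
    # pressure sensing, myosin kinetics, drug kinetics, nucleus stiffness
    if (sim$step %% cfg$myosin$stride == 0L) {
      dt_kin <- dt * cfg$myosin$stride
      sim$ps <- sensing_pressure(sim$fluid, sim$glioma$membrane,
                                 cfg$myosin$Rs, sim$rs_kernel)
      a <- actin_concentration(sim$ps, sim$myosin$kp,
                               sim$myosin$pressure_scale)
      for (k in seq_along(sim$drugs))
        sim$drugs[[k]] <- drug_step(sim$drugs[[k]], sim$t, dt_kin)
      eff <- drug_effects(sim$drugs)
      sim$myosin <- step_myosin(sim$myosin, a, dt_kin, B = eff$B,
                                alpha_bleb = eff$alpha_bleb, D = eff$D)
      r <- stiffening_rate(sim$myosin$mb, sim$stiff)
      sim$glioma$ce_n <- nucleus_stiffness(r, sim$stiff)
    }
    sim$t <- sim$t + dt
    # phase machine on the projected cell-body length
    Lb <- body_length(sim$glioma$membrane, sim$dir)
    sim$cycle <- update_phase(sim$cycle, Lb, sim$t)
    if (sim$cycle$switched) {
      sim$glioma <- select_front_rear(sim$glioma, sim$dir)
      sim$glioma <- freeze_anchors(sim$glioma, sim$cycle$phase)
    }
    # metrics
    if (sim$step %% cfg$time$record_stride == 0L || istep == nsteps) {
      if (!all(is.finite(sim$glioma$membrane$X)))
        stop(sprintf("instability: non-finite membrane at step %d (t = %g s)",
                     sim$step, sim$t))
      defo <- deformation_ratio(sim$glioma)
      ctr <- colMeans(sim$glioma$membrane$X)
      r <- stiffening_rate(sim$myosin$mb, sim$stiff)
      eff <- drug_effects(sim$drugs)
      nrow_rec <- nrow_rec + 1L
      rows[[nrow_rec]] <- data.frame(
        t = sim$t, phase = sim$cycle$phase,
        L = Lb, Lp = sim$cycle$Lp,
        Nlen = body_length(sim$glioma$nucleus, sim$dir),
        cx = ctr[1], cy = ctr[2],
        nucleus_min_y = min(sim$glioma$nucleus$X[, 2]),
        nucleus_max_y = max(sim$glioma$nucleus$X[, 2]),
        membrane_max_y = max(sim$glioma$membrane$X[, 2]),
        Lperp = defo$Lperp, LperpW = defo$W, LperpE = defo$E,
        ps = sim$ps, mb = sim$myosin$mb, r = r, ce_n = sim$glioma$ce_n,
        ca = sim$ca, Fc = sim$Fc, dirx = sim$dir[1], diry = sim$dir[2],
        B = eff$B, D = eff$D,
        area_mem = enclosed_area(sim$glioma$membrane),
        area_nuc = enclosed_area(sim$glioma$nucleus))
      if (verbose && nrow_rec %% max(1, length(rows) %/% 10) == 0)
        message(sprintf("t = %.1f s  phase = %s  mb = %.3f", sim$t,
                        sim$cycle$phase, sim$myosin$mb))
    }
  }
  out <- list(trace = do.call(rbind, rows[seq_len(nrow_rec)]), sim = sim)
  class(out) <- "ib_result"
  out
}

#' Run a parameter sweep
#'
#' Cartesian product over named configuration axes (dot-separated paths into
#' the configuration, e.g. \code{"glioma.kp"}); each point is built, run and
#' classified against the gap line. Individual failures are recorded and the
#' sweep continues.
#'
#' @param base a [scenario_config()].
#' @param axes named list of value vectors, names are config paths.
#' @param T_end horizon (s); default from the base configuration.
#' @param verbose print progress per run.
#' @return data frame with one row per grid point: the axis values,
#'   \code{status}, \code{passing_time} (NA unless passed) and \code{error}.
#' @export
run_sweep <- function(base, axes, T_end = base$time$T_end, verbose = FALSE) {
  grid <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
  if (verbose) message(sprintf("sweep: %d runs", nrow(grid)))
  res <- grid
  res$status <- NA_character_
  res$passing_time <- NA_real_
  res$error <- NA_character_
  for (i in seq_len(nrow(grid))) {
    cfg <- base
    for (ax in names(axes)) cfg <- .set_path(cfg, ax, grid[i, ax])
    class(cfg) <- "scenario_config"
    out <- tryCatch({
      rr <- run_simulation(build_scenario(cfg), T_end = T_end)
      classify_passing(rr$trace, cfg$normals$gap_y, T_end)
    }, error = function(e) list(status = NA_character_,
                                passing_time = NULL, err = conditionMessage(e)))
    res$status[i] <- out$status
    if (!is.null(out$passing_time)) res$passing_time[i] <- out$passing_time
    if (!is.null(out$err)) res$error[i] <- out$err
    if (verbose) message(sprintf("  run %d/%d: %s", i, nrow(grid),
                                 res$status[i]))
  }
  res
}

.set_path <- function(cfg, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (length(parts) == 1) cfg[[parts]] <- value
  else cfg[[parts[1]]] <- .set_path(cfg[[parts[1]]],
                                    paste(parts[-1], collapse = "."), value)
  cfg
}
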