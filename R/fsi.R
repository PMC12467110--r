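#' Default run configuration
#'
#' Nested configuration for [run_simulation()]. Physical defaults: 800 Pa
#' inlet driving pressure against 0 Pa outlet, air density 1.1455 kg/m^3,
#' kinematic viscosity 6.6e-5 m^2/s (a reduced-Reynolds-number gas),
#' acoustic substep ratio 16, ten-point anechoic buffers, 0.2 mm contact
#' gap and the two-layer tissue of [default_materials()]. The desk-scale
#' grid (48 x 72 over a 2.8 x 10 cm box) and a 4 mm prephonatory gap keep
#' the glottal channel resolved by several cells at this resolution.
#'
#' @return nested list of defaults.
#' @export
default_run_config <- function() {
  list(
    experiment = "phonosim-run",
    geometry = modify_defaults(larynx_config(),
                               list(folds = list(gap = 0.004))),
    grid = list(nx = 48L, ny = 72L),
    flow = list(dt = 5e-6, n_steps = 100L, rho = 1.1455, nu = 6.6e-5,
                nu_multiplier = 1, cfl_max = 1.0, poisson_tol = 1e-8,
                inlet_pressure = 800, outlet_pressure = 0,
                pressure_ramp_time = 1e-3, max_velocity = 400),
    acoustics = list(enabled = TRUE, substep_ratio = 16L, gamma = 1.4,
                     p_ambient = 101325, buffer_points = 10L,
                     buffer_sigma = NULL),
    solid = list(materials = list(
                   cover = list(E = 1.33, Eprime = 26.70, G = 6.68,
                                eta = 0.9, etaprime = 0.0, vsg = 0.43,
                                rho = 1040),
                   body = list(E = 4.76, Eprime = 95.24, G = 23.81,
                               eta = 0.9, etaprime = 0.0, vsg = 0,
                               rho = 1040)),
                 rayleigh = c(0, 1e-5), newmark = c(0.3025, 0.6),
                 contact_gap = 2e-4, load_relax = 0.2, vel_relax = 0.2,
                 include_viscous_traction = FALSE),
    motion = list(mode = "coupled", amplitude = 0.0015, frequency = 154),
    output = list(record_every = 1L, snapshot_every = 0L,
                  snapshot_dir = NULL)
  )
}

materials_from_config <- function(mc) {
  lapply(mc, function(m)
    material_layer(m$E, m$Eprime, m$G, m$eta, m$etaprime,
                   vsg = if (is.null(m$vsg)) 0 else m$vsg, rho = m$rho))
}

# medial x-profile of a wet polyline at the requested y stations
medial_profile <- function(pts, ys, side) {
  n <- nrow(pts)
  out <- rep(if (side == "left") -Inf else Inf, length(ys))
  for (k in seq_len(n - 1L)) {
    y1 <- pts[k, 2]; y2 <- pts[k + 1L, 2]
    lo <- min(y1, y2); hi <- max(y1, y2)
    hit <- which(ys >= lo & ys <= hi)
    if (length(hit) == 0L) next
    if (abs(y2 - y1) < 1e-14) {
      xv <- rep(max(pts[k, 1], pts[k + 1L, 1]), length(hit))
      if (side == "right") xv <- rep(min(pts[k, 1], pts[k + 1L, 1]),
                                     length(hit))
    } else {
      s <- (ys[hit] - y1) / (y2 - y1)
      xv <- pts[k, 1] + s * (pts[k + 1L, 1] - pts[k, 1])
    }
    if (side == "left") out[hit] <- pmax(out[hit], xv) else
      out[hit] <- pmin(out[hit], xv)
  }
  out
}

# minimum glottal gap (m) between the deformed wet polylines
glottal_gap <- function(wetL, wetR, n_stations = 41L) {
  yr <- range(wetL[, 2])
  ys <- seq(yr[1] + 1e-6, yr[2] - 1e-6, length.out = n_stations)
  xL <- medial_profile(wetL, ys, "left")
  xR <- medial_profile(wetR, ys, "right")
  g <- xR - xL
  ok <- is.finite(g)
  list(gap = max(min(g[ok]), 0), y = ys[ok][which.min(g[ok])])
}

# bilinear sample of a cell field at points
sample_field <- function(field, grid, x, y) {
  i0 <- pmin(pmax(findInterval(x, grid$xc), 1L), grid$nx - 1L)
  j0 <- pmin(pmax(findInterval(y, grid$yc), 1L), grid$ny - 1L)
  tx <- pmin(pmax((x - grid$xc[i0]) / (grid$xc[i0 + 1L] - grid$xc[i0]), 0), 1)
  ty <- pmin(pmax((y - grid$yc[j0]) / (grid$yc[j0 + 1L] - grid$yc[j0]), 0), 1)
  f00 <- field[cbind(i0, j0)]; f10 <- field[cbind(i0 + 1L, j0)]
  f01 <- field[cbind(i0, j0 + 1L)]; f11 <- field[cbind(i0 + 1L, j0 + 1L)]
  (1 - tx) * (1 - ty) * f00 + tx * (1 - ty) * f10 +
    (1 - tx) * ty * f01 + tx * ty * f11
}

#' Integrate fluid pressure traction onto the wet fold surface
#'
#' Per segment of the wet polyline the total pressure (incompressible plus
#' perturbed) is sampled at the midpoint and the force
#' `-(P + p') n ds depth` (n = outward solid normal) is split between the
#' segment end nodes. Viscous traction is omitted by default, consistent
#' with pressure loading dominating the fold drive.
#'
#' @param wet deformed wet-node coordinates (ordered polyline).
#' @param p_total total pressure field on the grid (Pa).
#' @param grid [cartesian_grid()].
#' @param side `"left"` or `"right"` fold (sets the outward normal sense).
#' @param depth anterior-posterior depth (m).
#' @param offset sampling offset along the outward normal (m); one cell by
#'   default, keeping the bilinear stencil on fluid values.
#' @return matrix of nodal forces (n x 2, N).
#' @export
fold_traction <- function(wet, p_total, grid, side, depth,
                          offset = max(grid$dx[1], grid$dy[1])) {
  n <- nrow(wet)
  f <- matrix(0, n, 2L)
  seg <- wet[-1, , drop = FALSE] - wet[-n, , drop = FALSE]
  len <- sqrt(rowSums(seg^2))
  mid <- (wet[-1, , drop = FALSE] + wet[-n, , drop = FALSE]) / 2
  # outward normal from the traversal orientation: the wet polyline runs
  # wall -> tip along the inferior face, up the medial face, tip -> wall
  # along the superior face; that is counter-clockwise around the left
  # fold (outward normal (dy, -dx)) and clockwise around the right fold
  # (outward normal (-dy, dx))
  nrm <- if (side == "left") cbind(seg[, 2], -seg[, 1]) / len else
    cbind(-seg[, 2], seg[, 1]) / len
  p <- sample_field(p_total, grid, mid[, 1] + offset * nrm[, 1],
                    mid[, 2] + offset * nrm[, 2])
  fs <- -p * nrm * len * depth
  f[-n, ] <- f[-n, ] + fs / 2
  f[-1, ] <- f[-1, ] + fs / 2
  f
}

# nearest-surface-vertex velocity lookup used as the moving-wall BC
wall_velocity_fun <- function(verts, vels, comp) {
  force(verts); force(vels); force(comp)
  function(x, y) {
    out <- numeric(length(x))
    for (k in seq_along(x)) {
      d2 <- (verts[, 1] - x[k])^2 + (verts[, 2] - y[k])^2
      out[k] <- vels[which.min(d2), comp]
    }
    out
  }
}

prune_solver_cache <- function(max_entries = 40L) {
  if (length(ls(.phs_cache)) > max_entries) clear_solver_cache()
}

build_interface <- function(setup, dL, dR) {
  fix <- setup$fixture
  wetL0 <- fix$solid$left$nodes[fix$solid$left$fsi, , drop = FALSE]
  wetR0 <- fix$solid$right$nodes[fix$solid$right$fsi, , drop = FALSE]
  wetL <- wetL0 + dL
  wetR <- wetR0 + dR
  xdom <- fix$domain$x[2]
  pad <- 1e-4
  loopL <- rbind(c(-xdom - pad, wetL[1, 2]), wetL,
                 c(-xdom - pad, wetL[nrow(wetL), 2]))
  loopR <- rbind(c(xdom + pad, wetR[1, 2]), wetR,
                 c(xdom + pad, wetR[nrow(wetR), 2]))
  ch <- setup$channel_deformed
  nv <- nrow(ch$vertices)
  verts <- rbind(ch$vertices, loopL, loopR)
  loops <- c(ch$loops,
             list(nv + seq_len(nrow(loopL)),
                  nv + nrow(loopL) + seq_len(nrow(loopR))))
  list(surface = surface(verts, loops = loops,
                         tags = c(ch$tags, "fsi", "fsi")),
       wetL = wetL, wetR = wetR,
       n_channel = nv)
}

#' Run a phonation simulation on the idealized fixture
#'
#' Time-marches the explicit three-step coupling: (1) incompressible
#' solve on the current deformed interface with the solid velocities as
#' moving-wall conditions, (2) LPCE acoustic substeps on the same shape
#' driven by the stored pressure time-derivative, (3) solid Newmark step
#' under the total (incompressible + perturbed) pressure traction, then
#' interface update and contact enforcement. The physics path contains no
#' random numbers, so runs are bit-reproducible; the per-step record and
#' the effective config (with hash) are returned.
#'
#' Motion modes: `"coupled"` (full FSI), `"kinematic"` (prescribed
#' sinusoidal medial fold motion, solid solver bypassed) and `"static"`
#' (rigid folds).
#'
#' @param config nested list merged over [default_run_config()].
#' @param resume path to a checkpoint written by [save_checkpoint()]; the
#'   run continues to `flow$n_steps` total steps.
#' @param checkpoint_path optional path; if given, a checkpoint is written
#'   at the end of the run.
#' @return object of class `phs_run`: `record` ([cycle_record()]),
#'   `displacement_snapshots` (stacked wet-surface displacements by step),
#'   final states and the effective `config`.
#' @export
run_simulation <- function(config = list(), resume = NULL,
                           checkpoint_path = NULL) {
  cfg <- validate_config(config)
  setup <- simulation_setup(cfg)
  if (is.null(resume)) {
    st <- initial_coupled_state(setup)
  } else {
    st <- readRDS(resume)
    if (!identical(st$config_hash, physics_hash(cfg)))
      stop("checkpoint was written with a different configuration")
  }
  n_total <- cfg$flow$n_steps
  rec_every <- cfg$output$record_every
  rows <- vector("list", n_total)
  snaps <- vector("list", n_total)
  while (st$step < n_total) {
    st <- coupled_step(st, setup)
    if (st$step %% rec_every == 0L) {
      rows[[st$step]] <- st$diag
      snaps[[st$step]] <- st$wet_disp
    }
    if (cfg$output$snapshot_every > 0L &&
        st$step %% cfg$output$snapshot_every == 0L &&
        !is.null(cfg$output$snapshot_dir)) {
      write_vtk_rectilinear(setup$grid,
        list(u = st$flow$u, v = st$flow$v, p = st$flow$p, pp = st$ac$pp),
        file.path(cfg$output$snapshot_dir,
                  sprintf("%s_%06d.vtk", cfg$experiment, st$step)))
    }
    prune_solver_cache()
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  snaps <- snaps[!vapply(snaps, is.null, logical(1))]
  df <- do.call(rbind, rows)
  record <- cycle_record(df$t, Ag = df$Ag, Q = df$Q, p_probe = df$p_probe,
                         p_sub = df$p_sub, p_sup = df$p_sup,
                         p_sgs_up = df$p_sgs_up, p_sgs_down = df$p_sgs_down)
  if (!is.null(checkpoint_path)) save_checkpoint(st, checkpoint_path)
  structure(list(record = record,
                 displacement_snapshots = if (length(snaps))
                   do.call(cbind, snaps) else NULL,
                 state = st, config = cfg,
                 config_hash = attr(cfg, "hash")),
            class = "phs_run")
}

# static per-run context (grids, meshes, operators) -- rebuilt from config,
# never checkpointed
simulation_setup <- function(cfg) {
  fixture <- make_idealized_larynx(cfg$geometry)
  channel <- fixture$channel
  if (cfg$geometry$sgs$severity > 0) {
    y_sup <- cfg$geometry$folds$y0 + cfg$geometry$folds$thickness
    spec <- sgs_spec(severity = cfg$geometry$sgs$severity,
                     L = cfg$geometry$sgs$length,
                     location = y_sup - cfg$geometry$sgs$location,
                     rotation_deg = cfg$geometry$sgs$rotation_deg)
    channel <- apply_sgs(channel, spec)
  }
  grid <- uniform_grid(fixture$domain$x, fixture$domain$y,
                       cfg$grid$nx, cfg$grid$ny)
  # smoothstep ramp of the driving pressure avoids an impulsive start
  ramp <- cfg$flow$pressure_ramp_time
  p_in <- cfg$flow$inlet_pressure
  inlet_p <- if (ramp > 0) {
    function(x, y, t) {
      s <- pmin(t / ramp, 1)
      rep(p_in * s^2 * (3 - 2 * s), length.out = length(x))
    }
  } else p_in
  bc <- list(
    xlo = flow_bc("wall"), xhi = flow_bc("wall"),
    ylo = flow_bc("pressure", p = inlet_p),
    yhi = flow_bc("pressure", p = cfg$flow$outlet_pressure))
  sysL <- sysR <- NULL
  if (cfg$motion$mode == "coupled") {
    mats <- materials_from_config(cfg$solid$materials)
    sysL <- assemble_system(fixture$solid$left, mats,
                            thickness = cfg$geometry$folds$depth_z)
    sysR <- assemble_system(fixture$solid$right, mats,
                            thickness = cfg$geometry$folds$depth_z)
  }
  czone <- NULL
  if (cfg$acoustics$enabled) {
    c0 <- sqrt(cfg$acoustics$gamma * cfg$acoustics$p_ambient / cfg$flow$rho)
    smax <- cfg$acoustics$buffer_sigma %||%
      (8 * c0 / (cfg$acoustics$buffer_points * grid$dy[1]))
    czone <- buffer_zone(grid$ny, cfg$acoustics$buffer_points,
                         c("lo", "hi"), smax)
  }
  list(cfg = cfg, fixture = fixture, channel_deformed = channel,
       grid = grid, bc = bc, sysL = sysL, sysR = sysR, buffer_y = czone)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# hash of the physics-relevant configuration (run length and output
# cadence excluded, so a checkpointed run may be extended)
physics_hash <- function(cfg) {
  cfg$flow$n_steps <- NULL
  cfg$output <- NULL
  attributes(cfg) <- list(names = names(cfg))
  object_hash(cfg)
}

initial_coupled_state <- function(setup) {
  cfg <- setup$cfg
  ndofL <- 2L * nrow(setup$fixture$solid$left$nodes)
  ndofR <- 2L * nrow(setup$fixture$solid$right$nodes)
  st <- list(step = 0L,
             flow = flow_state(setup$grid, rho = cfg$flow$rho,
                               nu = cfg$flow$nu * cfg$flow$nu_multiplier),
             ac = if (cfg$acoustics$enabled)
               acoustic_state_2d(setup$grid, cfg$acoustics$gamma,
                                 cfg$flow$rho) else NULL,
             solidL = solid_state(ndofL), solidR = solid_state(ndofR),
             P_prev = NULL,
             config_hash = physics_hash(cfg))
  st
}

# prescribed medial displacement of the wet nodes in kinematic mode
kinematic_disp <- function(setup, t) {
  cfg <- setup$cfg
  A <- cfg$motion$amplitude; f <- cfg$motion$frequency
  s <- A * (0.5 - 0.5 * cos(2 * pi * f * t))     # starts closed-ward at 0
  v <- A * pi * f * sin(2 * pi * f * t)
  list(dx = s, vx = v)
}

#' Advance the coupled fluid-structure-acoustic state by one flow step
#'
#' @param st coupled state from [run_simulation()] internals.
#' @param setup simulation context (internal).
#' @return updated state with per-step diagnostics in `st$diag`.
#' @export
coupled_step <- function(st, setup) {
  cfg <- setup$cfg
  dt <- cfg$flow$dt
  fix <- setup$fixture
  meshL <- fix$solid$left; meshR <- fix$solid$right
  # current interface displacement/velocity of the wet nodes
  if (cfg$motion$mode == "kinematic") {
    kin <- kinematic_disp(setup, st$flow$t)
    nL <- length(meshL$fsi); nR <- length(meshR$fsi)
    dL <- cbind(rep(kin$dx, nL), 0); dR <- cbind(rep(-kin$dx, nR), 0)
    vL <- cbind(rep(kin$vx, nL), 0); vR <- cbind(rep(-kin$vx, nR), 0)
    # clamp at the contact gap
    gapfix <- contact_clamp_kinematic(fix, dL, dR, cfg$solid$contact_gap)
    dL <- gapfix$dL; dR <- gapfix$dR
  } else if (cfg$motion$mode == "static") {
    dL <- dR <- vL <- vR <- NULL
  } else {
    dL <- cbind(st$solidL$d[2L * meshL$fsi - 1L], st$solidL$d[2L * meshL$fsi])
    dR <- cbind(st$solidR$d[2L * meshR$fsi - 1L], st$solidR$d[2L * meshR$fsi])
    vL <- cbind(st$solidL$v[2L * meshL$fsi - 1L], st$solidL$v[2L * meshL$fsi])
    vR <- cbind(st$solidR$v[2L * meshR$fsi - 1L], st$solidR$v[2L * meshR$fsi])
    # interface-velocity relaxation: together with the load filter this
    # keeps the explicit added-mass feedback of the confined 2D geometry
    # below unit gain (first-order low-pass on the moving-wall condition)
    av <- cfg$solid$vel_relax
    if (av < 1) {
      if (is.null(st$vel_filt))
        st$vel_filt <- list(left = vL * 0, right = vR * 0)
      vL <- av * vL + (1 - av) * st$vel_filt$left
      vR <- av * vR + (1 - av) * st$vel_filt$right
      st$vel_filt <- list(left = vL, right = vR)
    }
  }
  if (is.null(dL)) {
    nL <- length(meshL$fsi); nR <- length(meshR$fsi)
    dL <- matrix(0, nL, 2L); dR <- matrix(0, nR, 2L)
    vL <- matrix(0, nL, 2L); vR <- matrix(0, nR, 2L)
  }
  iface <- build_interface(setup, dL, dR)
  verts <- iface$surface$vertices
  nv_ch <- iface$n_channel
  vels <- matrix(0, nrow(verts), 2L)
  # loop vertices: channel static; fold loops carry the solid velocities
  # (base padding vertices stay at rest)
  nL <- nrow(iface$wetL); nR <- nrow(iface$wetR)
  vels[nv_ch + 1L + seq_len(nL), ] <- vL
  vels[nv_ch + nL + 3L + seq_len(nR), ] <- vR
  prob <- flow_problem(setup$grid, setup$bc, cfl_max = cfg$flow$cfl_max,
                       poisson_tol = cfg$flow$poisson_tol)
  prob <- update_immersed(prob, iface$surface,
                          wall_u = wall_velocity_fun(verts, vels, 1L),
                          wall_v = wall_velocity_fun(verts, vels, 2L))
  P_old <- st$flow$p
  flow <- advance_flow(st$flow, prob, dt)
  if (max(abs(flow$u), abs(flow$v)) > cfg$flow$max_velocity)
    stop(sprintf(paste0("instability detected at step %d: max velocity ",
                        "%.1f m/s exceeds bound %.1f"),
                 st$step + 1L, max(abs(flow$u), abs(flow$v)),
                 cfg$flow$max_velocity))

  # acoustic substeps on the same deformed shape
  ac <- st$ac
  if (cfg$acoustics$enabled) {
    nsub <- cfg$acoustics$substep_ratio
    dt_ac <- dt / nsub
    dPdt <- (flow$p - P_old) / dt
    dPdt[prob$flags != 0L] <- 0
    forcing <- lpce_forcing(V = flow$v, U = flow$u,
                            P = flow$p + cfg$acoustics$p_ambient,
                            dPdt = dPdt)
    bc_ac <- list(xlo = "wall", xhi = "wall", ylo = "open", yhi = "open")
    segkey <- sprintf("acseg_%s", prob$id)
    seg <- cache_get(segkey)
    if (is.null(seg)) seg <- cache_set(segkey, build_ac_segments(prob$flags))
    for (k in seq_len(nsub))
      ac <- rk4_step_2d(ac, forcing, dt_ac, prob, bc_ac,
                        zone_y = setup$buffer_y, seg = seg)
  }

  # solid update under the total pressure traction; perturbed pressure is
  # ghost-mirrored so near-surface sampling sees fluid values
  depth <- cfg$geometry$folds$depth_z
  p_total <- flow$p + if (cfg$acoustics$enabled)
    ghost_cell_update(ac$pp, prob$gs, 0, "neumann") else 0
  if (cfg$motion$mode == "coupled") {
    fL <- fold_traction(iface$wetL, p_total, setup$grid, "left", depth)
    fR <- fold_traction(iface$wetR, p_total, setup$grid, "right", depth)
    loadL <- numeric(2L * nrow(meshL$nodes))
    loadL[2L * meshL$fsi - 1L] <- fL[, 1]; loadL[2L * meshL$fsi] <- fL[, 2]
    loadR <- numeric(2L * nrow(meshR$nodes))
    loadR[2L * meshR$fsi - 1L] <- fR[, 1]; loadR[2L * meshR$fsi] <- fR[, 2]
    # temporal load relaxation filters the odd-even added-mass feedback
    # of the explicit coupling
    th <- cfg$solid$load_relax
    if (!is.null(st$last_load)) {
      loadL <- th * loadL + (1 - th) * st$last_load$left
      loadR <- th * loadR + (1 - th) * st$last_load$right
    }
    st$solidL <- step_dynamics(st$solidL, setup$sysL, loadL, dt,
                               cfg$solid$rayleigh, cfg$solid$newmark)
    st$solidR <- step_dynamics(st$solidR, setup$sysR, loadR, dt,
                               cfg$solid$rayleigh, cfg$solid$newmark)
    st$solidL <- enforce_contact(st$solidL, meshL, cfg$solid$contact_gap)
    st$solidR <- enforce_contact(st$solidR, meshR, cfg$solid$contact_gap)
    st$last_load <- list(left = loadL, right = loadR)
  }

  st$flow <- flow
  st$ac <- ac
  st$P_prev <- P_old
  st$step <- st$step + 1L

  # diagnostics / record row
  gg <- glottal_gap(iface$wetL, iface$wetR)
  y_exit <- fix$config$folds$y0 + fix$config$folds$thickness
  j_exit <- findInterval(y_exit, setup$grid$yf)
  j_exit <- min(max(j_exit, 1L), setup$grid$ny + 1L)
  fluid_row <- prob$flags[, min(j_exit, setup$grid$ny)] == 0L
  Q <- sum(flow$vf[fluid_row, j_exit] * setup$grid$dx[fluid_row]) * depth
  mk <- fix$markers
  tap <- function(nm, field) {
    r <- mk[mk$name == nm, ]
    sample_field(field, setup$grid, r$x, r$y)
  }
  pp_field <- if (cfg$acoustics$enabled) ac$pp else
    matrix(0, setup$grid$nx, setup$grid$ny)
  st$diag <- data.frame(
    t = flow$t,
    Ag = gg$gap * depth * 1e4,                    # m^2 -> cm^2
    Q = Q * 1e6,                                  # m^3/s -> mL/s
    p_probe = tap("probe", pp_field),
    p_sub = tap("p_sub", flow$p),
    p_sup = tap("p_sup", flow$p),
    p_sgs_up = tap("p_sgs_up", flow$p),
    p_sgs_down = tap("p_sgs_down", flow$p),
    div_max = attr(flow, "div_max"))
  st$wet_disp <- c(as.vector(t(dL)), as.vector(t(dR)))
  st
}

# clamp prescribed kinematic motion at the contact gap
contact_clamp_kinematic <- function(fix, dL, dR, gap) {
  wetL <- fix$solid$left$nodes[fix$solid$left$fsi, 1] + dL[, 1]
  wetR <- fix$solid$right$nodes[fix$solid$right$fsi, 1] + dR[, 1]
  limL <- -gap / 2; limR <- gap / 2
  overL <- wetL > limL
  overR <- wetR < limR
  dL[overL, 1] <- limL - fix$solid$left$nodes[fix$solid$left$fsi, 1][overL]
  dR[overR, 1] <- limR - fix$solid$right$nodes[fix$solid$right$fsi, 1][overR]
  list(dL = dL, dR = dR)
}

#' Write a checkpoint of the full coupled state
#'
#' All prognostic fields (flow including the Adams-Bashforth history,
#' acoustic state, solid displacement/velocity/acceleration, step counter
#' and config hash) are serialized, so a resumed run reproduces the
#' uninterrupted trajectory exactly.
#'
#' @param st coupled state (from `phs_run$state`).
#' @param path RDS output path.
#' @return `path` invisibly.
#' @export
save_checkpoint <- function(st, path) {
  st$diag <- NULL
  saveRDS(st, path)
  invisible(path)
}

#' Severity-sweep experiment on the fixture
#'
#' Runs the configured simulation at each stenosis severity and reports
#' per-case steady flow/pressure summaries plus deltas against the first
#' (baseline) case: mean and peak flow, mean glottal area, flow
#' resistances across the stenosis and the glottis, the glottal-to-stenosis
#' area ratio and the percentage change in trans-glottal pressure drop.
#' Failures are isolated per case.
#'
#' @param base_config configuration overrides shared by all cases.
#' @param severities vector of severities (the clinical sweep is
#'   `c(0, 0.5, 0.75, 0.9, 0.96)`).
#' @param steady_fraction final fraction of each record used as the
#'   steady averaging window.
#' @return tibble (one row per severity) of class `phs_sweep`; failed
#'   cases carry `NA` metrics and the error message.
#' @export
run_experiment_matrix <- function(base_config = list(),
                                  severities = c(0, 0.5, 0.75, 0.9, 0.96),
                                  steady_fraction = 0.25) {
  rows <- lapply(severities, function(sv) {
    cfg <- utils::modifyList(base_config,
                             list(geometry = list(sgs = list(severity = sv))))
    res <- tryCatch(run_simulation(cfg), error = function(e) e)
    if (inherits(res, "error"))
      return(tibble::tibble(severity = sv, error = conditionMessage(res),
                            Q_mean = NA_real_, Q_peak = NA_real_,
                            Ag_mean = NA_real_, fr_sgs = NA_real_,
                            fr_vf = NA_real_, fr_total = NA_real_,
                            area_ratio = NA_real_, dp_vf = NA_real_))
    rec <- res$record
    n <- nrow(rec)
    w <- rec[seq.int(max(1L, floor((1 - steady_fraction) * n)), n), ]
    Qm3 <- w$Q * 1e-6
    ref_area_cm2 <- res$config$geometry$channel$width *
      res$config$geometry$folds$depth_z * 1e4
    tibble::tibble(
      severity = sv, error = NA_character_,
      Q_mean = mean(w$Q), Q_peak = max(w$Q), Ag_mean = mean(w$Ag),
      fr_sgs = flow_resistance(w, Qm3, "sgs"),
      fr_vf = flow_resistance(w, Qm3, "vf"),
      fr_total = flow_resistance(w, Qm3, "total"),
      area_ratio = area_ratio(w$Ag, sv, ref_area_cm2),
      dp_vf = mean(w$p_sub - w$p_sup))
  })
  out <- do.call(rbind, rows)
  base_dp <- out$dp_vf[1]
  out$dpvf_change <- vapply(out$dp_vf, function(d)
    if (is.na(d) || is.na(base_dp) || base_dp == 0) NA_real_ else
      pressure_drop_change(base_dp, d), numeric(1))
  out$dQ_mean_pct <- (out$Q_mean - out$Q_mean[1]) / out$Q_mean[1] * 100
  class(out) <- c("phs_sweep", class(out))
  out
}
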