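#' Incompressible flow state
#'
#' Cell-centred collocated velocity/pressure fields plus the face-normal
#' velocities used for mass fluxes (momentum interpolation keeps the two
#' consistent and suppresses pressure checkerboarding).
#'
#' @param grid [cartesian_grid()].
#' @param rho density (kg/m^3); default 1.1455 (air at the reduced Reynolds
#'   number used throughout).
#' @param nu kinematic viscosity (m^2/s); default 6.6e-5.
#' @param u0,v0,p0 initial fields: scalars or `nx x ny` matrices.
#' @return object of class `phs_flow_state`.
#' @export
flow_state <- function(grid, rho = 1.1455, nu = 6.6e-5,
                       u0 = 0, v0 = 0, p0 = 0) {
  nx <- grid$nx; ny <- grid$ny
  mk <- function(z) if (is.matrix(z)) z else matrix(z, nx, ny)
  u <- mk(u0); v <- mk(v0); p <- mk(p0)
  structure(list(u = u, v = v, p = p,
                 uf = matrix(0, nx + 1L, ny), vf = matrix(0, nx, ny + 1L),
                 t = 0, rho = rho, nu = nu,
                 conv_prev = NULL),
            class = "phs_flow_state")
}

#' Boundary-condition description for one domain side
#'
#' @param type `"wall"` (Dirichlet velocity, zero normal pressure gradient)
#'   or `"pressure"` (Dirichlet pressure, zero-gradient velocity).
#' @param u,v velocity at the boundary face: scalar or `function(x, y, t)`.
#' @param p boundary pressure (Pa), `"pressure"` type only.
#' @return list consumed by [flow_problem()].
#' @export
flow_bc <- function(type = c("wall", "pressure"), u = 0, v = 0, p = 0) {
  type <- match.arg(type)
  list(type = type, u = u, v = v, p = p)
}

#' Assemble a flow problem: grid, boundary conditions, immersed surface
#'
#' Precomputes cell flags, ghost-cell stencils and face metadata. Call
#' [update_immersed()] whenever the immersed surface moves.
#'
#' @param grid [cartesian_grid()].
#' @param bc named list of [flow_bc()]s for sides `xlo`, `xhi`, `ylo`, `yhi`.
#' @param surface optional immersed `phs_surface`.
#' @param cfl_max advective CFL bound checked every step.
#' @param poisson_tol relative residual tolerance for the projection solve.
#' @return object of class `phs_flow_problem`.
#' @export
flow_problem <- function(grid, bc, surface = NULL, cfl_max = 1.0,
                         poisson_tol = 1e-8) {
  stopifnot(all(c("xlo", "xhi", "ylo", "yhi") %in% names(bc)))
  prob <- structure(list(grid = grid, bc = bc, surface = surface,
                         cfl_max = cfl_max, poisson_tol = poisson_tol,
                         wall_u = 0, wall_v = 0,
                         revision = 0L),
                    class = "phs_flow_problem")
  update_immersed(prob, surface)
}

#' Replace the immersed surface (moving-boundary bookkeeping)
#'
#' Reclassifies cells, rebuilds ghost stencils and bumps the operator
#' revision so cached factorizations are refreshed.
#'
#' @param prob [flow_problem()].
#' @param surface new immersed surface (or `NULL`).
#' @param wall_u,wall_v wall velocity at the surface: scalar or
#'   `function(x, y)` evaluated at body-intercept points.
#' @return updated problem.
#' @export
update_immersed <- function(prob, surface, wall_u = 0, wall_v = 0) {
  prob$surface <- surface
  flags <- classify_cells(prob$grid, surface)
  prob$flags <- flags
  prob$gs <- if (is.null(surface)) list(n = 0L, n_fallback = 0L) else
    build_ghost_stencils(prob$grid, flags, surface)
  prob$wall_u <- wall_u; prob$wall_v <- wall_v
  prob$id <- sprintf("fp%s", object_hash(list(dim(flags), which(flags != 0L),
                                              vapply(prob$bc, `[[`, "", "type"))))
  prob
}

# ---- internal finite-volume operators -------------------------------------

# boundary face value of a scalar/function bc entry
bc_eval <- function(val, x, y, t) {
  if (is.function(val)) val(x, y, t) else rep(val, length.out = length(x))
}

# face-interpolation of a cell field to interior faces (distance weighted)
interp_xfaces <- function(q, grid) {
  nx <- grid$nx
  a <- grid$dx[-1] / (grid$dx[-nx] + grid$dx[-1])   # weight on left cell
  q[-nx, , drop = FALSE] * a + q[-1, , drop = FALSE] * (1 - a)
}
interp_yfaces <- function(q, grid) {
  ny <- grid$ny
  a <- grid$dy[-1] / (grid$dy[-ny] + grid$dy[-1])
  sweep(q[, -ny, drop = FALSE], 2, a, `*`) +
    sweep(q[, -1, drop = FALSE], 2, 1 - a, `*`)
}

# pressure interpolated to all faces, honouring side types
face_pressure <- function(p, prob, t) {
  grid <- prob$grid; bc <- prob$bc
  nx <- grid$nx; ny <- grid$ny
  pfx <- matrix(0, nx + 1L, ny)
  pfx[2:nx, ] <- interp_xfaces(p, grid)
  pfx[1, ] <- if (bc$xlo$type == "pressure")
    bc_eval(bc$xlo$p, grid$xf[1], grid$yc, t) else p[1, ]
  pfx[nx + 1L, ] <- if (bc$xhi$type == "pressure")
    bc_eval(bc$xhi$p, grid$xf[nx + 1L], grid$yc, t) else p[nx, ]
  pfy <- matrix(0, nx, ny + 1L)
  pfy[, 2:ny] <- interp_yfaces(p, grid)
  pfy[, 1] <- if (bc$ylo$type == "pressure")
    bc_eval(bc$ylo$p, grid$xc, grid$yf[1], t) else p[, 1]
  pfy[, ny + 1L] <- if (bc$yhi$type == "pressure")
    bc_eval(bc$yhi$p, grid$xc, grid$yf[ny + 1L], t) else p[, ny]
  list(x = pfx, y = pfy)
}

# cell-centred gradient from face values
cell_grad <- function(pf, grid) {
  gx <- (pf$x[-1, , drop = FALSE] - pf$x[-(grid$nx + 1L), , drop = FALSE]) /
    grid$dx
  gy <- sweep(pf$y[, -1, drop = FALSE] - pf$y[, -(grid$ny + 1L), drop = FALSE],
              2, grid$dy, `/`)
  list(x = gx, y = gy)
}

# convective divergence of q transported by (uf, vf)
convective <- function(q, comp, uf, vf, prob, t) {
  grid <- prob$grid; bc <- prob$bc
  nx <- grid$nx; ny <- grid$ny
  qfx <- matrix(0, nx + 1L, ny)
  qfx[2:nx, ] <- interp_xfaces(q, grid)
  qfx[1, ] <- if (bc$xlo$type == "wall")
    bc_eval(bc$xlo[[comp]], grid$xf[1], grid$yc, t) else q[1, ]
  qfx[nx + 1L, ] <- if (bc$xhi$type == "wall")
    bc_eval(bc$xhi[[comp]], grid$xf[nx + 1L], grid$yc, t) else q[nx, ]
  qfy <- matrix(0, nx, ny + 1L)
  qfy[, 2:ny] <- interp_yfaces(q, grid)
  qfy[, 1] <- if (bc$ylo$type == "wall")
    bc_eval(bc$ylo[[comp]], grid$xc, grid$yf[1], t) else q[, 1]
  qfy[, ny + 1L] <- if (bc$yhi$type == "wall")
    bc_eval(bc$yhi[[comp]], grid$xc, grid$yf[ny + 1L], t) else q[, ny]
  Fx <- uf * qfx; Fy <- vf * qfy
  (Fx[-1, ] - Fx[-(nx + 1L), ]) / grid$dx +
    sweep(Fy[, -1] - Fy[, -(ny + 1L)], 2, grid$dy, `/`)
}

# explicit Laplacian of a velocity component, Dirichlet at wall sides,
# zero-gradient at pressure sides; immersed cells carry mirrored ghost
# values so the interior stencil applies unchanged
velocity_laplacian <- function(q, comp, prob, t) {
  grid <- prob$grid; bc <- prob$bc
  nx <- grid$nx; ny <- grid$ny
  hx <- diff(grid$xc); hy <- diff(grid$yc)
  gfx <- matrix(0, nx + 1L, ny)        # dq/dx at x-faces
  gfx[2:nx, ] <- (q[-1, ] - q[-nx, ]) / hx
  if (bc$xlo$type == "wall")
    gfx[1, ] <- (q[1, ] - bc_eval(bc$xlo[[comp]], grid$xf[1], grid$yc, t)) /
      (grid$dx[1] / 2)
  if (bc$xhi$type == "wall")
    gfx[nx + 1L, ] <- (bc_eval(bc$xhi[[comp]], grid$xf[nx + 1L], grid$yc, t) -
                       q[nx, ]) / (grid$dx[nx] / 2)
  gfy <- matrix(0, nx, ny + 1L)
  gfy[, 2:ny] <- sweep(q[, -1] - q[, -ny], 2, hy, `/`)
  if (bc$ylo$type == "wall")
    gfy[, 1] <- (q[, 1] - bc_eval(bc$ylo[[comp]], grid$xc, grid$yf[1], t)) /
      (grid$dy[1] / 2)
  if (bc$yhi$type == "wall")
    gfy[, ny + 1L] <- (bc_eval(bc$yhi[[comp]], grid$xc, grid$yf[ny + 1L], t) -
                       q[, ny]) / (grid$dy[ny] / 2)
  (gfx[-1, ] - gfx[-(nx + 1L), ]) / grid$dx +
    sweep(gfy[, -1] - gfy[, -(ny + 1L)], 2, grid$dy, `/`)
}

# sparse Helmholtz operator (I - 0.5 nu dt L) for the Crank-Nicolson solve;
# identity rows on non-fluid cells. Returns an LU factorization plus the
# diagonal boundary bookkeeping needed for the RHS.
cn_matrix <- function(prob, dt, nu) {
  grid <- prob$grid; bc <- prob$bc; flags <- prob$flags
  nx <- grid$nx; ny <- grid$ny
  hx <- diff(grid$xc); hy <- diff(grid$yc)
  n <- nx * ny
  idx <- function(i, j) i + (j - 1L) * nx
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  # accumulate in lists to avoid quadratic concatenation
  rows <- vector("list", ny)
  for (j in seq_len(ny)) {
    iL <- integer(5L * nx); jL <- integer(5L * nx); vL <- numeric(5L * nx)
    k <- 0L
    for (i in seq_len(nx)) {
      me <- idx(i, j)
      if (flags[i, j] != 0L) {
        k <- k + 1L; iL[k] <- me; jL[k] <- me; vL[k] <- 1
        next
      }
      diag <- 1
      add <- function(col, coef) {
        k <<- k + 1L; iL[k] <<- me; jL[k] <<- col; vL[k] <<- coef
      }
      cfl_ <- 0.5 * nu * dt
      # west
      if (i > 1L) {
        c_ <- cfl_ / (hx[i - 1L] * grid$dx[i])
        add(idx(i - 1L, j), -c_); diag <- diag + c_
      } else if (bc$xlo$type == "wall") {
        diag <- diag + cfl_ / ((grid$dx[1] / 2) * grid$dx[1])
      }
      # east
      if (i < nx) {
        c_ <- cfl_ / (hx[i] * grid$dx[i])
        add(idx(i + 1L, j), -c_); diag <- diag + c_
      } else if (bc$xhi$type == "wall") {
        diag <- diag + cfl_ / ((grid$dx[nx] / 2) * grid$dx[nx])
      }
      # south
      if (j > 1L) {
        c_ <- cfl_ / (hy[j - 1L] * grid$dy[j])
        add(idx(i, j - 1L), -c_); diag <- diag + c_
      } else if (bc$ylo$type == "wall") {
        diag <- diag + cfl_ / ((grid$dy[1] / 2) * grid$dy[1])
      }
      # north
      if (j < ny) {
        c_ <- cfl_ / (hy[j] * grid$dy[j])
        add(idx(i, j + 1L), -c_); diag <- diag + c_
      } else if (bc$yhi$type == "wall") {
        diag <- diag + cfl_ / ((grid$dy[ny] / 2) * grid$dy[ny])
      }
      add(me, diag)
    }
    rows[[j]] <- list(i = iL[seq_len(k)], j = jL[seq_len(k)], v = vL[seq_len(k)])
  }
  ii <- unlist(lapply(rows, `[[`, "i"))
  jj <- unlist(lapply(rows, `[[`, "j"))
  vv <- unlist(lapply(rows, `[[`, "v"))
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(n, n))
  Matrix::lu(A)
}

# boundary Dirichlet contribution to the CN right-hand side (implicit half)
cn_bc_rhs <- function(comp, prob, dt, nu, t) {
  grid <- prob$grid; bc <- prob$bc
  nx <- grid$nx; ny <- grid$ny
  r <- matrix(0, nx, ny)
  cfl_ <- 0.5 * nu * dt
  if (bc$xlo$type == "wall")
    r[1, ] <- r[1, ] + cfl_ * bc_eval(bc$xlo[[comp]], grid$xf[1], grid$yc, t) /
      ((grid$dx[1] / 2) * grid$dx[1])
  if (bc$xhi$type == "wall")
    r[nx, ] <- r[nx, ] + cfl_ *
      bc_eval(bc$xhi[[comp]], grid$xf[nx + 1L], grid$yc, t) /
      ((grid$dx[nx] / 2) * grid$dx[nx])
  if (bc$ylo$type == "wall")
    r[, 1] <- r[, 1] + cfl_ * bc_eval(bc$ylo[[comp]], grid$xc, grid$yf[1], t) /
      ((grid$dy[1] / 2) * grid$dy[1])
  if (bc$yhi$type == "wall")
    r[, ny] <- r[, ny] + cfl_ *
      bc_eval(bc$yhi[[comp]], grid$xc, grid$yf[ny + 1L], t) /
      ((grid$dy[ny] / 2) * grid$dy[ny])
  r
}

# pressure-correction Poisson operator on fluid cells:
# dirichlet (phi = 0) at "pressure" domain faces, Neumann elsewhere
poisson_matrix <- function(grid, flags, dirichlet_sides) {
  nx <- grid$nx; ny <- grid$ny
  hx <- diff(grid$xc); hy <- diff(grid$yc)
  fluid <- which(flags == 0L)
  map <- integer(nx * ny); map[fluid] <- seq_along(fluid)
  nf <- length(fluid)
  iL <- integer(5L * nf); jL <- integer(5L * nf); vL <- numeric(5L * nf)
  k <- 0L
  add <- function(r, c_, val) {
    k <<- k + 1L; iL[k] <<- r; jL[k] <<- c_; vL[k] <<- val
  }
  any_dir <- FALSE
  for (m in seq_len(nf)) {
    cell <- fluid[m]
    i <- ((cell - 1L) %% nx) + 1L
    j <- ((cell - 1L) %/% nx) + 1L
    diag <- 0
    # west
    if (i > 1L && flags[i - 1L, j] == 0L) {
      c_ <- 1 / (hx[i - 1L] * grid$dx[i])
      add(m, map[cell - 1L], c_); diag <- diag - c_
    } else if (i == 1L && "xlo" %in% dirichlet_sides) {
      diag <- diag - 1 / ((grid$dx[1] / 2) * grid$dx[i]); any_dir <- TRUE
    }
    # east
    if (i < nx && flags[i + 1L, j] == 0L) {
      c_ <- 1 / (hx[i] * grid$dx[i])
      add(m, map[cell + 1L], c_); diag <- diag - c_
    } else if (i == nx && "xhi" %in% dirichlet_sides) {
      diag <- diag - 1 / ((grid$dx[nx] / 2) * grid$dx[i]); any_dir <- TRUE
    }
    # south
    if (j > 1L && flags[i, j - 1L] == 0L) {
      c_ <- 1 / (hy[j - 1L] * grid$dy[j])
      add(m, map[cell - nx], c_); diag <- diag - c_
    } else if (j == 1L && "ylo" %in% dirichlet_sides) {
      diag <- diag - 1 / ((grid$dy[1] / 2) * grid$dy[j]); any_dir <- TRUE
    }
    # north
    if (j < ny && flags[i, j + 1L] == 0L) {
      c_ <- 1 / (hy[j] * grid$dy[j])
      add(m, map[cell + nx], c_); diag <- diag - c_
    } else if (j == ny && "yhi" %in% dirichlet_sides) {
      diag <- diag - 1 / ((grid$dy[ny] / 2) * grid$dy[j]); any_dir <- TRUE
    }
    add(m, m, diag)
  }
  A <- Matrix::sparseMatrix(i = iL[seq_len(k)], j = jL[seq_len(k)],
                            x = vL[seq_len(k)], dims = c(nf, nf))
  list(A = A, fluid = fluid, map = map, any_dirichlet = any_dir)
}

#' Solve the pressure(-correction) Poisson equation
#'
#' Homogeneous Neumann at walls and the immersed-boundary faces, Dirichlet
#' (value 0) at the listed pressure sides. With no Dirichlet face the
#' system is singular: set `gauge_pin = TRUE` to pin the solution at one
#' fluid cell (the right-hand side is mean-corrected for compatibility).
#'
#' @param rhs `nx x ny` right-hand side (defined on fluid cells).
#' @param grid [cartesian_grid()].
#' @param flags cell classification; `NULL` means all fluid.
#' @param dirichlet_sides character subset of
#'   `c("xlo", "xhi", "ylo", "yhi")`.
#' @param gauge_pin pin one cell when the system is all-Neumann.
#' @param tol relative residual tolerance; exceeded -> error with the
#'   residual reported.
#' @return `nx x ny` solution field (NA on non-fluid cells).
#' @export
solve_poisson <- function(rhs, grid, flags = NULL,
                          dirichlet_sides = character(),
                          gauge_pin = FALSE, tol = 1e-8) {
  if (is.null(flags)) flags <- matrix(0L, grid$nx, grid$ny)
  pm <- poisson_matrix(grid, flags, dirichlet_sides)
  b <- as.numeric(rhs)[pm$fluid]
  A <- pm$A
  if (!pm$any_dirichlet) {
    if (!gauge_pin)
      stop(paste("Poisson system is singular (all-Neumann):",
                 "add a Dirichlet pressure side or set gauge_pin = TRUE",
                 "to fix the gauge"))
    b <- b - mean(b)
    A[1, ] <- 0; A[1, 1] <- 1; b[1] <- 0
  }
  x <- as.numeric(Matrix::solve(A, b))
  res <- sqrt(sum((as.numeric(A %*% x) - b)^2))
  scale <- max(sqrt(sum(b^2)), 1e-300)
  if (res / scale > tol)
    stop(sprintf("Poisson solve did not converge: relative residual %.3e",
                 res / scale))
  out <- matrix(NA_real_, grid$nx, grid$ny)
  out[pm$fluid] <- x
  out
}

#' Discrete divergence of the face velocities
#' @param uf,vf face-normal velocities.
#' @param grid [cartesian_grid()].
#' @return `nx x ny` divergence field.
#' @export
face_divergence <- function(uf, vf, grid) {
  (uf[-1, , drop = FALSE] - uf[-(grid$nx + 1L), , drop = FALSE]) / grid$dx +
    sweep(vf[, -1, drop = FALSE] - vf[, -(grid$ny + 1L), drop = FALSE],
          2, grid$dy, `/`)
}

#' Advance the incompressible solution by one fractional step
#'
#' Van Kan scheme: (i) intermediate velocity with second-order
#' Adams-Bashforth convection and Crank-Nicolson diffusion (bootstrapped
#' with forward Euler on the first step), (ii) pressure-correction Poisson
#' solve on momentum-interpolated face velocities, (iii) velocity and
#' pressure update. Ghost cells enforce the (possibly moving) immersed-wall
#' velocity before the operators are applied.
#'
#' @param state [flow_state()].
#' @param prob [flow_problem()].
#' @param dt time step (s); checked against the advective CFL bound.
#' @return updated state; the maximum fluid-cell divergence after
#'   projection is attached as attribute `"div_max"`.
#' @export
advance_flow <- function(state, prob, dt) {
  grid <- prob$grid; bc <- prob$bc
  nx <- grid$nx; ny <- grid$ny
  t <- state$t; rho <- state$rho; nu <- state$nu
  fluid <- prob$flags == 0L
  if (!all(is.finite(state$u[fluid])) || !all(is.finite(state$v[fluid])))
    stop("non-finite velocity field")
  # immersed-wall values on ghost cells
  u <- ghost_cell_update(state$u, prob$gs, prob$wall_u, "dirichlet")
  v <- ghost_cell_update(state$v, prob$gs, prob$wall_v, "dirichlet")
  p <- ghost_cell_update(state$p, prob$gs, 0, "neumann")
  state$u <- u; state$v <- v; state$p <- p

  # CFL audit on current face velocities
  cfl <- dt * max(max(abs(state$uf)) / min(grid$dx),
                  max(abs(state$vf)) / min(grid$dy))
  if (cfl > prob$cfl_max)
    stop(sprintf("CFL violation: %.3f > %.3f", cfl, prob$cfl_max))

  Nu <- convective(u, "u", state$uf, state$vf, prob, t)
  Nv <- convective(v, "v", state$uf, state$vf, prob, t)
  if (is.null(state$conv_prev)) {
    Nhu <- Nu; Nhv <- Nv
  } else {
    Nhu <- 1.5 * Nu - 0.5 * state$conv_prev$u
    Nhv <- 1.5 * Nv - 0.5 * state$conv_prev$v
  }
  pf <- face_pressure(p, prob, t)
  gp <- cell_grad(pf, grid)
  Lu <- velocity_laplacian(u, "u", prob, t)
  Lv <- velocity_laplacian(v, "v", prob, t)

  rhs_u <- u + dt * (-Nhu - gp$x / rho + 0.5 * nu * Lu) +
    cn_bc_rhs("u", prob, dt, nu, t + dt)
  rhs_v <- v + dt * (-Nhv - gp$y / rho + 0.5 * nu * Lv) +
    cn_bc_rhs("v", prob, dt, nu, t + dt)
  nonfluid <- !fluid
  rhs_u[nonfluid] <- u[nonfluid]
  rhs_v[nonfluid] <- v[nonfluid]

  key <- sprintf("cn_%s_%.17g_%.17g", prob$id, dt, nu)
  fac <- cache_get(key)
  if (is.null(fac)) fac <- cache_set(key, cn_matrix(prob, dt, nu))
  us <- matrix(as.numeric(Matrix::solve(fac, as.numeric(rhs_u))), nx, ny)
  vs <- matrix(as.numeric(Matrix::solve(fac, as.numeric(rhs_v))), nx, ny)

  # momentum-interpolated face velocities (Rhie-Chow with the old
  # pressure) across fluid-fluid faces; immersed faces carry the wall
  # normal velocity directly (no-penetration without lagged feedback)
  hx <- diff(grid$xc); hy <- diff(grid$yc)
  ffx_i <- fluid[-nx, , drop = FALSE] & fluid[-1, , drop = FALSE]
  ffy_i <- fluid[, -ny, drop = FALSE] & fluid[, -1, drop = FALSE]
  ufs <- matrix(0, nx + 1L, ny)
  ufs[2:nx, ] <- interp_xfaces(us, grid) +
    ifelse(ffx_i,
           dt / rho * (interp_xfaces(gp$x, grid) -
                       (p[-1, ] - p[-nx, ]) / hx),
           0)
  if (any(!ffx_i)) {
    ib <- which(!ffx_i, arr.ind = TRUE)
    wx <- grid$xf[ib[, 1] + 1L]; wy <- grid$yc[ib[, 2]]
    wv <- if (is.function(prob$wall_u)) prob$wall_u(wx, wy) else
      rep(prob$wall_u, nrow(ib))
    ufs[cbind(ib[, 1] + 1L, ib[, 2])] <- wv
  }
  ufs[1, ] <- if (bc$xlo$type == "wall")
    bc_eval(bc$xlo$u, grid$xf[1], grid$yc, t + dt) else us[1, ]
  ufs[nx + 1L, ] <- if (bc$xhi$type == "wall")
    bc_eval(bc$xhi$u, grid$xf[nx + 1L], grid$yc, t + dt) else us[nx, ]
  vfs <- matrix(0, nx, ny + 1L)
  vfs[, 2:ny] <- interp_yfaces(vs, grid) +
    ifelse(ffy_i,
           dt / rho * (interp_yfaces(gp$y, grid) -
                       sweep(p[, -1] - p[, -ny], 2, hy, `/`)),
           0)
  if (any(!ffy_i)) {
    ib <- which(!ffy_i, arr.ind = TRUE)
    wx <- grid$xc[ib[, 1]]; wy <- grid$yf[ib[, 2] + 1L]
    wv <- if (is.function(prob$wall_v)) prob$wall_v(wx, wy) else
      rep(prob$wall_v, nrow(ib))
    vfs[cbind(ib[, 1], ib[, 2] + 1L)] <- wv
  }
  vfs[, 1] <- if (bc$ylo$type == "wall")
    bc_eval(bc$ylo$v, grid$xc, grid$yf[1], t + dt) else vs[, 1]
  vfs[, ny + 1L] <- if (bc$yhi$type == "wall")
    bc_eval(bc$yhi$v, grid$xc, grid$yf[ny + 1L], t + dt) else vs[, ny]

  # projection
  dirichlet_sides <- names(bc)[vapply(bc, function(b) b$type == "pressure",
                                      logical(1))]
  pkey <- sprintf("poisson_%s_%s", prob$id,
                  paste(dirichlet_sides, collapse = ""))
  pp <- cache_get(pkey)
  if (is.null(pp)) {
    pm <- poisson_matrix(grid, prob$flags, dirichlet_sides)
    if (!pm$any_dirichlet) {
      pm$A[1, ] <- 0; pm$A[1, 1] <- 1
      pm$pinned <- TRUE
    } else pm$pinned <- FALSE
    pm$fac <- Matrix::lu(pm$A)
    pp <- cache_set(pkey, pm)
  }
  div <- face_divergence(ufs, vfs, grid)
  b <- (rho / dt) * as.numeric(div)[pp$fluid]
  if (pp$pinned) { b <- b - mean(b); b[1] <- 0 }
  phi_v <- as.numeric(Matrix::solve(pp$fac, b))
  phi <- matrix(0, nx, ny)
  phi[pp$fluid] <- phi_v

  # face-velocity correction: only across fluid-fluid interior faces and
  # Dirichlet pressure boundary faces
  corr_x <- matrix(0, nx + 1L, ny)
  ffx <- fluid[-nx, , drop = FALSE] & fluid[-1, , drop = FALSE]
  corr_x[2:nx, ][ffx] <- ((phi[-1, ] - phi[-nx, ]) / hx)[ffx]
  if (bc$xlo$type == "pressure")
    corr_x[1, fluid[1, ]] <- (phi[1, fluid[1, ]] - 0) / (grid$dx[1] / 2)
  if (bc$xhi$type == "pressure")
    corr_x[nx + 1L, fluid[nx, ]] <- (0 - phi[nx, fluid[nx, ]]) /
      (grid$dx[nx] / 2)
  corr_y <- matrix(0, nx, ny + 1L)
  ffy <- fluid[, -ny, drop = FALSE] & fluid[, -1, drop = FALSE]
  corr_y[, 2:ny][ffy] <- (sweep(phi[, -1] - phi[, -ny], 2, hy, `/`))[ffy]
  if (bc$ylo$type == "pressure")
    corr_y[fluid[, 1], 1] <- (phi[fluid[, 1], 1] - 0) / (grid$dy[1] / 2)
  if (bc$yhi$type == "pressure")
    corr_y[fluid[, ny], ny + 1L] <- (0 - phi[fluid[, ny], ny]) /
      (grid$dy[ny] / 2)
  uf1 <- ufs - dt / rho * corr_x
  vf1 <- vfs - dt / rho * corr_y

  # cell-centred correction from face-interpolated phi (Neumann at walls
  # and immersed faces, zero at pressure sides)
  phifx <- matrix(0, nx + 1L, ny)
  phifx[2:nx, ] <- interp_xfaces(phi, grid)
  phifx[1, ] <- if (bc$xlo$type == "pressure") 0 else phi[1, ]
  phifx[nx + 1L, ] <- if (bc$xhi$type == "pressure") 0 else phi[nx, ]
  phify <- matrix(0, nx, ny + 1L)
  phify[, 2:ny] <- interp_yfaces(phi, grid)
  phify[, 1] <- if (bc$ylo$type == "pressure") 0 else phi[, 1]
  phify[, ny + 1L] <- if (bc$yhi$type == "pressure") 0 else phi[, ny]
  gphi <- cell_grad(list(x = phifx, y = phify), grid)
  u1 <- us - dt / rho * gphi$x
  v1 <- vs - dt / rho * gphi$y
  p1 <- p + phi

  st <- state
  st$u <- u1; st$v <- v1; st$p <- p1
  st$uf <- uf1; st$vf <- vf1
  st$t <- t + dt
  st$conv_prev <- list(u = Nu, v = Nv)
  div1 <- face_divergence(uf1, vf1, grid)
  attr(st, "div_max") <- max(abs(div1[fluid]))
  st
}
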