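test_that("pressure Poisson solver converges at second order", {
  errs <- vapply(c(16L, 32L, 64L), function(n) {
    g <- uniform_grid(c(0, 1), c(0, 1), n, n)
    X <- outer(g$xc, rep(1, n)); Y <- outer(rep(1, n), g$yc)
    phi <- sin(pi * X) * sin(pi * Y)
    sol <- solve_poisson(-2 * pi^2 * phi, g,
                         dirichlet_sides = c("xlo", "xhi", "ylo", "yhi"))
    max(abs(sol - phi))
  }, numeric(1))
  orders <- log2(errs[-3] / errs[-1])
  expect_true(all(orders >= 1.9))
})

test_that("tiny Poisson systems match a hand-built direct solve", {
  # 1D two-cell problem: cells at x = 0.25, 0.75, Dirichlet phi = 0 at
  # x = 0, Neumann at x = 1 and both y faces. By hand:
  #  cell1: (phi2-phi1)/0.5/0.5 - (phi1-0)/0.25/0.5 = r1
  #  cell2: -(phi2-phi1)/0.5/0.5 = r2
  g <- uniform_grid(c(0, 1), c(0, 1), 2L, 1L)
  r <- c(1, -2)
  A <- matrix(c(-4 - 8, 4, 4, -4), 2, 2, byrow = TRUE)
  expected <- solve(A, r)
  sol <- solve_poisson(matrix(r, 2, 1), g, dirichlet_sides = "xlo")
  expect_equal(as.numeric(sol), expected, tolerance = 1e-12)
})

test_that("all-Neumann systems need a gauge and give a constant for zero rhs", {
  g <- uniform_grid(c(0, 1), c(0, 1), 8, 8)
  expect_error(solve_poisson(matrix(0, 8, 8), g), "gauge")
  sol <- solve_poisson(matrix(0, 8, 8), g, gauge_pin = TRUE)
  expect_equal(max(abs(sol)), 0)
})

test_that("a quiescent state with balanced boundaries stays quiescent", {
  g <- uniform_grid(c(0, 1), c(0, 1), 16, 16)
  bc <- list(xlo = flow_bc("pressure", p = 0), xhi = flow_bc("pressure", p = 0),
             ylo = flow_bc("wall"), yhi = flow_bc("wall"))
  st <- flow_state(g, rho = 1, nu = 0.01)
  prob <- flow_problem(g, bc)
  for (k in 1:5) st <- advance_flow(st, prob, 0.01)
  expect_lt(max(abs(st$u)), 1e-12)
  expect_lt(max(abs(st$v)), 1e-12)
})

test_that("pressure-driven channel flow converges to the Poiseuille profile", {
  H <- 1; L <- 2; ny <- 64L; nx <- 16L
  g <- uniform_grid(c(0, L), c(0, H), nx, ny)
  rho <- 1; nu <- 0.1; dp <- 1
  bc <- list(xlo = flow_bc("pressure", p = dp),
             xhi = flow_bc("pressure", p = 0),
             ylo = flow_bc("wall"), yhi = flow_bc("wall"))
  prob <- flow_problem(g, bc)
  uex <- dp / (2 * rho * nu * L) * g$yc * (H - g$yc)
  st <- flow_state(g, rho = rho, nu = nu,
                   u0 = matrix(rep(0.9 * uex, each = nx), nx, ny))
  dt <- 0.01
  for (k in 1:600) st <- advance_flow(st, prob, dt)
  err <- max(abs(sweep(st$u, 2, uex, "-"))) / max(uex)
  expect_lt(err, 0.01)
  # divergence-free after projection
  expect_lt(attr(st, "div_max"), 1e-8)
  # global mass conservation: inflow equals outflow at steady state
  qin <- sum(st$uf[1, ]) * g$dy[1]
  qout <- sum(st$uf[nx + 1L, ]) * g$dy[1]
  expect_lt(abs(qin - qout) / abs(qin), 1e-6)
})

test_that("Taylor-Green vortex kinetic energy decays at the viscous rate", {
  nu <- 0.01; n <- 64L
  g <- uniform_grid(c(0, 2 * pi), c(0, 2 * pi), n, n)
  uex <- function(x, y, t) sin(x) * cos(y) * exp(-2 * nu * t)
  vex <- function(x, y, t) -cos(x) * sin(y) * exp(-2 * nu * t)
  bcf <- flow_bc("wall", u = uex, v = vex)
  prob <- flow_problem(g, list(xlo = bcf, xhi = bcf, ylo = bcf, yhi = bcf))
  X <- outer(g$xc, rep(1, n)); Y <- outer(rep(1, n), g$yc)
  st <- flow_state(g, rho = 1, nu = nu, u0 = uex(X, Y, 0), v0 = vex(X, Y, 0),
                   p0 = 0.25 * (cos(2 * X) + cos(2 * Y)))
  st$uf[2:n, ] <- uex(outer(g$xf[2:n], rep(1, n)),
                      outer(rep(1, n - 1), g$yc), 0)
  st$uf[1, ] <- uex(rep(g$xf[1], n), g$yc, 0)
  st$uf[n + 1L, ] <- uex(rep(g$xf[n + 1L], n), g$yc, 0)
  st$vf[, 2:n] <- vex(outer(g$xc, rep(1, n - 1)),
                      outer(rep(1, n), g$yf[2:n]), 0)
  st$vf[, 1] <- vex(g$xc, rep(g$yf[1], n), 0)
  st$vf[, n + 1L] <- vex(g$xc, rep(g$yf[n + 1L], n), 0)
  E0 <- sum(st$u^2 + st$v^2)
  Tend <- 2 * pi                      # one eddy turnover at U = 1
  dt <- 0.5 * g$dx[1]                 # CFL 0.5
  nsteps <- ceiling(Tend / dt); dt <- Tend / nsteps
  for (k in seq_len(nsteps)) st <- advance_flow(st, prob, dt)
  decay <- sum(st$u^2 + st$v^2) / E0
  expect_equal(decay, exp(-4 * nu * Tend), tolerance = 0.01)
})

test_that("CFL violations are detected, not silently integrated", {
  g <- uniform_grid(c(0, 1), c(0, 1), 16, 16)
  bc <- list(xlo = flow_bc("wall"), xhi = flow_bc("wall"),
             ylo = flow_bc("wall"), yhi = flow_bc("wall"))
  prob <- flow_problem(g, bc, cfl_max = 0.5)
  st <- flow_state(g, rho = 1, nu = 0.01)
  st$uf[] <- 10
  expect_error(advance_flow(st, prob, 0.01), "CFL")
})

test_that("no-penetration holds on a static immersed wall", {
  pp <- make_strip_channel_problem()
  st <- pp$state
  for (k in 1:500) st <- advance_flow(st, pp$prob, 0.002)
  # wall-normal velocity at the immersed faces is identically the wall value
  fl <- pp$prob$flags
  ffx <- (fl[-nrow(fl), ] == 0L) & (fl[-1, ] == 0L)
  ib_faces <- which(!ffx, arr.ind = TRUE)
  uf_ib <- st$uf[cbind(ib_faces[, 1] + 1L, ib_faces[, 2])]
  expect_lt(max(abs(uf_ib)), 1e-3 * max(abs(st$v)))
  # and the through-flow matches a plane Poiseuille estimate in order
  expect_gt(max(st$v[fl == 0L]), 0.5)
  expect_lt(max(st$v[fl == 0L]), 1.0)
})
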