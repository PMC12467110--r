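test_that("compact derivative is exact for constants and linears", {
  x <- seq(0, 1, length.out = 32)
  h <- x[2] - x[1]
  expect_equal(compact_deriv(rep(3.5, 32), h), rep(0, 32))
  expect_equal(compact_deriv(2 - 4 * x, h), rep(-4, 32), tolerance = 1e-12)
  expect_error(compact_deriv(1:5, 0.1), "8 samples")
})

test_that("compact derivative reaches sixth order in the interior", {
  errs <- vapply(c(32L, 64L, 128L), function(n) {
    x <- seq(0, 2 * pi, length.out = n)
    d <- compact_deriv(sin(3 * x), x[2] - x[1])
    i <- (n %/% 4):(n - n %/% 4)     # interior, clear of closure influence
    max(abs(d[i] - 3 * cos(3 * x[i])))
  }, numeric(1))
  orders <- log2(errs[-3] / errs[-1])
  expect_true(all(orders >= 5.5))
})

test_that("LPCE tendencies match the governing operators term by term", {
  n <- 64
  x <- seq(0, 1, length.out = n)
  h <- x[2] - x[1]
  # quiescent base, Gaussian p': pressure tendency 0, momentum -grad p/rho
  ac <- acoustic_state_1d(x, v = 0, p = exp(-(x - 0.5)^2 / 0.01),
                          gamma = 1.4, rho0 = 1.2)
  rhs <- lpce_rhs(ac, lpce_forcing(P = 1e5))
  expect_equal(rhs$p, rep(0, n))
  expect_equal(rhs$v, -compact_deriv(ac$p, h) / 1.2)
  # everything zero -> zero tendencies
  ac0 <- acoustic_state_1d(x)
  rhs0 <- lpce_rhs(ac0, lpce_forcing(P = 1e5))
  expect_equal(rhs0$v, rep(0, n))
  expect_equal(rhs0$p, rep(0, n))
})

test_that("LPCE matches a symbolic evaluation on polynomial fields", {
  # V = 2 + x, P = 1e5 + 10 x, v' = 3 x^2, p' = 5 x, dP/dt = 7:
  #  dv/dt = -d(v'V)/dx - (1/rho) dp'/dx = -(6x(2+x) + 3x^2) - 5/rho
  #  dp/dt = -V dp'/dx - gamma P dv'/dx - v' dP/dx - dPdt
  n <- 128
  x <- seq(0, 1, length.out = n)
  rho <- 1.2; gam <- 1.4
  ac <- acoustic_state_1d(x, v = 3 * x^2, p = 5 * x, gamma = gam, rho0 = rho)
  fl <- lpce_forcing(V = 2 + x, P = 1e5 + 10 * x, dPdt = 7)
  rhs <- lpce_rhs(ac, fl)
  v_exact <- -(6 * x * (2 + x) + 3 * x^2) - 5 / rho
  p_exact <- -(2 + x) * 5 - gam * (1e5 + 10 * x) * 6 * x - 3 * x^2 * 10 - 7
  i <- 10:(n - 10)    # interior: closure truncation excluded
  expect_equal(rhs$v[i], v_exact[i], tolerance = 1e-7)
  expect_equal(rhs$p[i], p_exact[i], tolerance = 1e-4)
})

test_that("RK4 time integration is fourth-order accurate", {
  # standing wave in a closed duct; halving dt scales the error by ~16
  Ld <- 0.35; n <- 64
  x <- seq(0, Ld, length.out = n)
  flow <- lpce_forcing(P = air$P0)
  run <- function(dt, nst) {
    ac <- acoustic_state_1d(x, v = 0, p = cos(pi * x / Ld),
                            gamma = air$gamma, rho0 = air$rho)
    for (k in seq_len(nst)) ac <- rk4_step(ac, flow, dt,
                                           bc = list(lo = "wall", hi = "wall"))
    ac$p
  }
  dt0 <- 0.2 * (x[2] - x[1]) / air$c0
  ref <- run(dt0 / 8, 64L)
  e1 <- max(abs(run(dt0, 8L) - ref))
  e2 <- max(abs(run(dt0 / 2, 16L) - ref))
  expect_gt(log2(e1 / e2), 3.7)
})

test_that("an acoustic pulse travels at the speed of sound", {
  n <- 256
  x <- seq(0, 1, length.out = n)
  h <- x[2] - x[1]
  p0 <- exp(-(x - 0.3)^2 / (2 * (10 * h)^2))
  ac <- acoustic_state_1d(x, v = p0 / (air$rho * air$c0), p = p0,
                          gamma = air$gamma, rho0 = air$rho)
  flow <- lpce_forcing(P = air$P0)
  dt <- 0.5 * h / air$c0
  peakpos <- function(p) {
    k <- which.max(p)
    y0 <- p[k - 1]; y1 <- p[k]; y2 <- p[k + 1]
    x[k] + 0.5 * (y0 - y2) / (y0 - 2 * y1 + y2) * h
  }
  x0 <- peakpos(ac$p)
  for (k in 1:100) ac <- rk4_step(ac, flow, dt,
                                  bc = list(lo = "wall", hi = "wall"))
  speed <- (peakpos(ac$p) - x0) / (100 * dt)
  expect_equal(speed, air$c0, tolerance = 0.005)
})

test_that("closed-duct standing wave oscillates at c/(2L)", {
  Ld <- 0.35; n <- 64
  x <- seq(0, Ld, length.out = n)
  ac <- acoustic_state_1d(x, v = 0, p = cos(pi * x / Ld),
                          gamma = air$gamma, rho0 = air$rho)
  flow <- lpce_forcing(P = air$P0)
  dt <- 0.4 * (x[2] - x[1]) / air$c0
  ps <- numeric(4000)
  for (k in seq_along(ps)) {
    ac <- rk4_step(ac, flow, dt, bc = list(lo = "wall", hi = "wall"))
    ps[k] <- ac$p[2]
  }
  f <- fundamental_frequency(ps, 1 / dt)
  expect_equal(f, air$c0 / (2 * Ld), tolerance = 0.01)
  # hard wall: normal perturbed velocity stays negligible
  expect_lt(abs(ac$v[1]), 1e-6 * max(abs(ac$v)))
})

test_that("acoustic energy is conserved in a closed hard-wall domain", {
  Ld <- 0.35; n <- 64
  x <- seq(0, Ld, length.out = n)
  ac <- acoustic_state_1d(x, v = 0, p = cos(pi * x / Ld),
                          gamma = air$gamma, rho0 = air$rho)
  flow <- lpce_forcing(P = air$P0)
  dt <- 0.4 * (x[2] - x[1]) / air$c0
  E0 <- acoustic_energy(ac, air$P0)
  for (k in 1:1000) ac <- rk4_step(ac, flow, dt,
                                   bc = list(lo = "wall", hi = "wall"))
  expect_equal(acoustic_energy(ac, air$P0), E0, tolerance = 0.005)
})

test_that("acoustic CFL violations are rejected", {
  x <- seq(0, 0.1, length.out = 32)
  ac <- acoustic_state_1d(x)
  expect_error(rk4_step(ac, lpce_forcing(P = air$P0), dt = 1e-3), "CFL")
})

test_that("anechoic buffer absorbs an outgoing pulse", {
  n <- 256
  x <- seq(0, 1, length.out = n)
  h <- x[2] - x[1]
  zone <- buffer_zone(n, 10L, "hi", sigma_max = 8 * air$c0 / (10 * h))
  # structural properties
  expect_error(buffer_zone(n, 0L, "hi", 1), "width")
  expect_true(all(diff(zone$sigma[(n - 9L):n]) >= 0))  # monotone ramp
  # zero field is a fixed point
  ac0 <- acoustic_state_1d(x)
  ac0b <- apply_buffer(ac0, zone, 1e-5)
  expect_equal(ac0b$p, ac0$p)
  # a pulse entirely outside the buffer is untouched
  p0 <- exp(-(x - 0.3)^2 / (2 * (6 * h)^2))
  acp <- acoustic_state_1d(x, p = p0)
  expect_equal(apply_buffer(acp, zone, 1e-5)$p, p0)
  # reflection measurement: right-going unit pulse into buffer + wall
  p1 <- exp(-(x - 0.6)^2 / (2 * (8 * h)^2))
  ac <- acoustic_state_1d(x, v = p1 / (air$rho * air$c0), p = p1,
                          gamma = air$gamma, rho0 = air$rho)
  flow <- lpce_forcing(P = air$P0)
  dt <- 0.4 * h / air$c0
  nst <- ceiling(0.7 / air$c0 / dt)
  for (k in seq_len(nst))
    ac <- rk4_step(ac, flow, dt, bc = list(lo = "wall", hi = "wall"),
                   zone = zone)
  expect_lt(max(abs(ac$p[1:220])), 0.01)
})
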