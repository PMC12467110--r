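test_that("rigid motions carry no strain energy", {
  mesh <- solid_mesh(rbind(c(0, 0), c(1, 0), c(0, 1)), matrix(1:3, 1),
                     layer = "body")
  mats <- list(body = material_layer(10, 10, 10 / 2.6, 0.3, 0.3))
  sys <- assemble_system(mesh, mats)
  d_tr <- rep(c(0.3, -0.2), 3)
  th <- 1e-6
  d_rot <- as.vector(t(cbind(-th * mesh$nodes[, 2], th * mesh$nodes[, 1])))
  d_def <- as.vector(t(cbind(0.01 * mesh$nodes[, 1], 0)))
  Edef <- strain_energy(sys, d_def)
  expect_lt(strain_energy(sys, d_tr), 1e-10 * Edef)
  expect_lt(strain_energy(sys, d_rot) / (0.5 * 1e4 * th^2), 1e-10)
})

test_that("single-element patch test reproduces the constitutive law", {
  mesh <- solid_mesh(rbind(c(0, 0), c(1, 0), c(0, 1)), matrix(1:3, 1),
                     layer = "cover")
  # spatially constant transverse modulus so the element law is exact
  cover <- material_layer(1.33, 26.70, 6.68, 0.9, 0.0, vsg = 0)
  sys <- assemble_system(mesh, list(cover = cover))
  ex <- 0.01; ey <- -0.004; gxy <- 0.003
  d <- as.vector(t(cbind(ex * mesh$nodes[, 1] + gxy * mesh$nodes[, 2],
                         ey * mesh$nodes[, 2])))
  C <- phonosim:::elasticity_2d(cover)
  eps <- c(ex, ey, gxy)
  E_expected <- 0.5 * sum(eps * (C %*% eps)) * 0.5   # element area 1/2
  expect_equal(strain_energy(sys, d), E_expected, tolerance = 1e-12)
})

test_that("cover VSG varies the transverse modulus; VSG = 0 keeps it constant", {
  mesh <- make_beam_mesh(0.01, 0.004, nx = 4L, ny = 4L, layer = "cover")
  m_novsg <- list(cover = material_layer(1.33, 26.7, 6.68, 0.9, 0, vsg = 0))
  m_vsg <- list(cover = material_layer(1.33, 26.7, 6.68, 0.9, 0, vsg = 0.43))
  K0 <- assemble_system(mesh, m_novsg)$K
  K1 <- assemble_system(mesh, m_vsg)$K
  # the graded assembly is stiffer (modulus grows away from the anchor)
  expect_gt(sum(Matrix::diag(K1)), sum(Matrix::diag(K0)))
  # regression guard: vsg = 0 twice is bit-identical
  expect_identical(as.numeric(K0), as.numeric(assemble_system(mesh, m_novsg)$K))
})

test_that("inadmissible elastic constants are rejected by name", {
  expect_error(material_layer(1, 1, 1, 0.999, 0.9), "positive definite")
  expect_error(material_layer(1, 26, -2, 0.9, 0), "positive definite")
})

test_that("stiffness is symmetric and mass positive definite", {
  mesh <- make_beam_mesh(0.02, 0.005, nx = 6L, ny = 3L)
  sys <- assemble_system(mesh, list(body = default_materials()$body))
  expect_lt(max(abs(sys$K - Matrix::t(sys$K))), 1e-8 * max(abs(sys$K)))
  ev <- eigen(as.matrix(sys$M), symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))
})

test_that("isotropic-limit element stiffness matches the textbook formula", {
  # independent oracle: plane-strain CST stiffness assembled by hand
  nodes <- rbind(c(0, 0), c(2, 0.3), c(0.5, 1.4))
  mesh <- solid_mesh(nodes, matrix(1:3, 1), layer = "body")
  E <- 40; nu <- 0.3   # kPa
  mats <- list(body = material_layer(E, E, E / (2 * (1 + nu)), nu, nu))
  K <- as.matrix(assemble_system(mesh, mats)$K)
  Epa <- E * 1e3
  D <- Epa / ((1 + nu) * (1 - 2 * nu)) *
    matrix(c(1 - nu, nu, 0, nu, 1 - nu, 0, 0, 0, (1 - 2 * nu) / 2), 3, 3)
  b <- c(nodes[2, 2] - nodes[3, 2], nodes[3, 2] - nodes[1, 2],
         nodes[1, 2] - nodes[2, 2])
  cc <- c(nodes[3, 1] - nodes[2, 1], nodes[1, 1] - nodes[3, 1],
          nodes[2, 1] - nodes[1, 1])
  A <- 0.5 * ((nodes[2, 1] - nodes[1, 1]) * (nodes[3, 2] - nodes[1, 2]) -
              (nodes[3, 1] - nodes[1, 1]) * (nodes[2, 2] - nodes[1, 2]))
  B <- matrix(0, 3, 6)
  B[1, c(1, 3, 5)] <- b; B[2, c(2, 4, 6)] <- cc
  B[3, c(1, 3, 5)] <- cc; B[3, c(2, 4, 6)] <- b
  B <- B / (2 * A)
  K_ref <- A * t(B) %*% D %*% B
  expect_equal(K, unname(K_ref), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("slender isotropic cantilever matches Euler-Bernoulli within 2%", {
  L <- 0.2; h <- 0.01; E <- 100; P <- 1e-3
  mesh <- make_beam_mesh(L, h, nx = 240L, ny = 16L)
  sys <- assemble_system(mesh, list(body = material_layer(E, E, E / 2, 0, 0)))
  load <- numeric(sys$n_dof)
  tip <- mesh$fsi
  load[2 * tip] <- P / length(tip)
  d <- static_solve(sys, load)
  defl <- P * L^3 / (3 * E * 1e3 * h^3 / 12)
  expect_equal(mean(d[2 * tip]), defl, tolerance = 0.02)
})

test_that("Newmark reproduces the damped single-mass oscillator", {
  m <- 0.02; k <- 500; c_ <- 0.4; F0 <- 1
  sys <- structure(list(K = Matrix::Matrix(k, sparse = TRUE),
                        M = Matrix::Matrix(m, sparse = TRUE),
                        free = 1L, n_dof = 1L, uid = "sdof_test"),
                   class = "phs_fem_system")
  wn <- sqrt(k / m); zeta <- c_ / (2 * sqrt(k * m)); Tn <- 2 * pi / wn
  dt <- Tn / 200
  st <- solid_state(1L)
  for (i in seq_len(round(10 * Tn / dt)))
    st <- step_dynamics(st, sys, F0, dt, rayleigh = c(0, c_ / k))
  wd <- wn * sqrt(1 - zeta^2)
  x_exact <- F0 / k * (1 - exp(-zeta * wn * st$t) *
                       (cos(wd * st$t) + zeta * wn / wd * sin(wd * st$t)))
  expect_equal(st$d, x_exact, tolerance = 0.001)
  # zero load, zero state stays zero
  st0 <- solid_state(1L)
  st0 <- step_dynamics(st0, sys, 0, dt)
  expect_equal(st0$d, 0); expect_equal(st0$v, 0)
})

test_that("undamped free vibration conserves mechanical energy", {
  mesh <- make_beam_mesh(0.05, 0.01, nx = 10L, ny = 3L)
  sys <- assemble_system(mesh, list(body = material_layer(5, 5, 2.5, 0, 0)))
  st <- solid_state(sys$n_dof)
  load <- numeric(sys$n_dof)
  load[2 * mesh$fsi] <- 1e-4
  st$d <- static_solve(sys, load)
  energy <- function(s) strain_energy(sys, s$d) +
    0.5 * sum(s$v * as.numeric(sys$M %*% s$v))
  E0 <- energy(st)
  for (i in 1:100)
    st <- step_dynamics(st, sys, numeric(sys$n_dof), 1e-4, rayleigh = c(0, 0))
  expect_equal(energy(st), E0, tolerance = 1e-3)
})

test_that("contact projects penetrating nodes onto the offset plane", {
  fix <- make_idealized_larynx()
  meshL <- fix$solid$left
  st <- solid_state(2L * nrow(meshL$nodes))
  # all nodes outside the gap: untouched
  st1 <- enforce_contact(st, meshL, plane_gap = 2e-4)
  expect_equal(st1$d, st$d)
  expect_equal(attr(st1, "n_contact"), 0L)
  # node pushed to the midplane: projected back, normal velocity zeroed
  st$d[2 * meshL$fsi - 1L] <- -meshL$nodes[meshL$fsi, 1]   # onto x = 0
  st$v[2 * meshL$fsi - 1L] <- 2
  st2 <- enforce_contact(st, meshL, plane_gap = 2e-4)
  x_def <- meshL$nodes[meshL$fsi, 1] + st2$d[2 * meshL$fsi - 1L]
  expect_equal(max(x_def), -1e-4)
  expect_equal(max(abs(st2$v[2 * meshL$fsi - 1L])), 0)
  expect_gt(attr(st2, "n_contact"), 0L)
})

test_that("prescribed closing motion floors the gap at exactly the contact gap", {
  fix <- make_idealized_larynx()
  gaps <- vapply(seq(0, 1, length.out = 41), function(s) {
    # sinusoidal closing drive, amplitude larger than the half gap
    dx <- 0.004 * sin(pi * s)
    nL <- length(fix$solid$left$fsi); nR <- length(fix$solid$right$fsi)
    cl <- phonosim:::contact_clamp_kinematic(
      fix, cbind(rep(dx, nL), 0), cbind(rep(-dx, nR), 0), gap = 2e-4)
    wetL <- fix$solid$left$nodes[fix$solid$left$fsi, 1] + cl$dL[, 1]
    wetR <- fix$solid$right$nodes[fix$solid$right$fsi, 1] + cl$dR[, 1]
    min(wetR) - max(wetL)
  }, numeric(1))
  expect_equal(min(gaps), 2e-4)
})
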