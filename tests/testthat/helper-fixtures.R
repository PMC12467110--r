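# Shared fixture builders for the test suite. Everything is generated in
# code; no binary data.

# closed triangulated tube along y with end caps: circular cross-section
# of radius r, axis x = z = 0
make_capped_cylinder <- function(r = 0.005, y0 = 0, y1 = 0.06,
                                 n_ring = 64L, n_axial = 40L) {
  th <- seq(0, 2 * pi, length.out = n_ring + 1L)[-(n_ring + 1L)]
  ys <- seq(y0, y1, length.out = n_axial)
  verts <- do.call(rbind, lapply(ys, function(y)
    cbind(r * cos(th), y, r * sin(th))))
  idx <- function(i, k) (k - 1L) * n_ring + i       # i on ring, k axial
  tri <- list()
  for (k in seq_len(n_axial - 1L)) {
    i2 <- c(seq_len(n_ring - 1L) + 1L, 1L)
    tri[[k]] <- rbind(cbind(idx(seq_len(n_ring), k), idx(i2, k),
                            idx(i2, k + 1L)),
                      cbind(idx(seq_len(n_ring), k), idx(i2, k + 1L),
                            idx(seq_len(n_ring), k + 1L)))
  }
  apex_lo <- nrow(verts) + 1L
  apex_hi <- nrow(verts) + 2L
  verts <- rbind(verts, c(0, y0, 0), c(0, y1, 0))
  i2 <- c(seq_len(n_ring - 1L) + 1L, 1L)
  caps <- rbind(cbind(idx(i2, 1L), idx(seq_len(n_ring), 1L), apex_lo),
                cbind(idx(seq_len(n_ring), n_axial), idx(i2, n_axial),
                      apex_hi))
  surface(verts, triangles = do.call(rbind, c(tri, list(caps))))
}

# exact ZOH discretization of a damped second-order resonator driven by u;
# independent ground truth for the transfer-function tests
resonator_response <- function(u, fs, fr, zeta) {
  w0 <- 2 * pi * fr
  A <- matrix(c(0, -w0^2, 1, -2 * zeta * w0), 2, 2)
  ev <- eigen(A)
  Ad <- Re(ev$vectors %*% diag(exp(ev$values / fs)) %*% solve(ev$vectors))
  Bd <- Re(ev$vectors %*% diag((exp(ev$values / fs) - 1) / ev$values) %*%
           solve(ev$vectors)) %*% c(0, 1)
  n <- length(u)
  p <- numeric(n)
  x <- c(0, 0)
  for (k in 2:n) {
    x <- Ad %*% x + Bd * u[k - 1L]
    p[k] <- x[1]
  }
  p
}

# two-strip immersed channel in a unit box, pressure-driven along y
make_strip_channel_problem <- function(n = 32L, nu = 0.05, dp = 1) {
  g <- uniform_grid(c(0, 1), c(0, 1), n, n)
  sL <- rbind(c(-0.1, -0.2), c(0.22, -0.2), c(0.22, 1.2), c(-0.1, 1.2))
  sR <- rbind(c(0.78, -0.2), c(1.1, -0.2), c(1.1, 1.2), c(0.78, 1.2))
  s <- surface(rbind(sL, sR), loops = list(1:4, 5:8))
  bc <- list(xlo = flow_bc("wall"), xhi = flow_bc("wall"),
             ylo = flow_bc("pressure", p = dp),
             yhi = flow_bc("pressure", p = 0))
  prob <- update_immersed(flow_problem(g, bc), s)
  list(grid = g, prob = prob, state = flow_state(g, rho = 1, nu = nu))
}

air <- list(rho = 1.1455, gamma = 1.4, P0 = 101325)
air$c0 <- sqrt(air$gamma * air$P0 / air$rho)
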