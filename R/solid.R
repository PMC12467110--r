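#' Plane-strain solid mesh for the vocal-fold tissue
#'
#' Linear-triangle finite-element mesh with per-element layer labels
#' (body/cover), fixed (zero-displacement) node set and an ordered wet
#' (fluid-structure interface) node set.
#'
#' @param nodes n x 2 coordinates (m).
#' @param tri m x 3 element connectivity.
#' @param layer character vector of per-element layer labels.
#' @param fixed integer vector of constrained node ids.
#' @param fsi integer vector of wet-surface node ids, ordered along the
#'   interface polyline.
#' @param side optional "left"/"right" marker used by the contact model.
#' @return object of class `phs_solid_mesh`.
#' @export
solid_mesh <- function(nodes, tri, layer, fixed = integer(), fsi = integer(),
                       side = NULL) {
  nodes <- as.matrix(nodes); storage.mode(nodes) <- "double"
  tri <- as.matrix(tri); storage.mode(tri) <- "integer"
  if (ncol(nodes) != 2L) stop("nodes must be n x 2")
  if (ncol(tri) != 3L) stop("tri must be m x 3")
  if (length(layer) != nrow(tri)) stop("one layer label per element")
  a <- tri_areas(nodes, tri)
  if (any(a <= 0)) stop("non-positive element area: check node ordering")
  structure(list(nodes = nodes, tri = tri, layer = layer,
                 fixed = as.integer(fixed), fsi = as.integer(fsi),
                 side = side),
            class = "phs_solid_mesh")
}

tri_areas <- function(nodes, tri) {
  x <- matrix(nodes[tri, 1], ncol = 3)
  y <- matrix(nodes[tri, 2], ncol = 3)
  0.5 * ((x[, 2] - x[, 1]) * (y[, 3] - y[, 1]) -
         (x[, 3] - x[, 1]) * (y[, 2] - y[, 1]))
}

#' Transversely isotropic material layer
#'
#' Engineering constants of one vocal-fold tissue layer. The fiber
#' (longitudinal) axis is anterior-posterior, i.e. out of plane for the 2D
#' plane-strain reference model. Moduli are in kPa as is conventional for
#' laryngeal tissue; they are converted to Pa during assembly.
#'
#' Defaults (cover: E 1.33, E' 26.70, G 6.68, eta 0.9, eta' 0.0,
#' VSG 0.43 kPa/mm; body: 4.76, 95.24, 23.81, 0.9, 0.0) are the two-layer
#' canine-larynx values used throughout the package; tissue density
#' 1040 kg/m^3.
#'
#' @param E transverse Young's modulus (kPa).
#' @param Eprime longitudinal Young's modulus (kPa).
#' @param G longitudinal shear modulus (kPa).
#' @param eta transverse Poisson ratio.
#' @param etaprime longitudinal Poisson ratio.
#' @param vsg vertical stiffness gradient of the transverse modulus
#'   (kPa/mm along the inferior-superior axis; cover layer only).
#' @param rho tissue density (kg/m^3).
#' @return object of class `phs_material`.
#' @export
material_layer <- function(E, Eprime, G, eta, etaprime, vsg = 0,
                           rho = 1040) {
  m <- structure(list(E = E, Eprime = Eprime, G = G, eta = eta,
                      etaprime = etaprime, vsg = vsg, rho = rho),
                 class = "phs_material")
  elasticity_2d(m)  # validates positive definiteness
  m
}

#' Default two-layer material set
#' @return named list with `cover` and `body` [material_layer()]s.
#' @export
default_materials <- function() {
  list(cover = material_layer(1.33, 26.70, 6.68, 0.9, 0.0, vsg = 0.43),
       body = material_layer(4.76, 95.24, 23.81, 0.9, 0.0))
}

# Plane-strain constitutive matrix (Pa) for a transversely isotropic
# material with the fiber axis out of plane. E_override (kPa) lets the
# vertical stiffness gradient vary the cover transverse modulus per element.
elasticity_2d <- function(mat, E_override = NULL) {
  E <- if (is.null(E_override)) mat$E else E_override
  E <- E * 1e3; Ep <- mat$Eprime * 1e3; G <- mat$G * 1e3
  eta <- mat$eta; etap <- mat$etaprime
  # 3D compliance, fiber axis = 3
  S <- matrix(0, 6, 6)
  S[1, 1] <- S[2, 2] <- 1 / E
  S[3, 3] <- 1 / Ep
  S[1, 2] <- S[2, 1] <- -eta / E
  S[1, 3] <- S[3, 1] <- S[2, 3] <- S[3, 2] <- -etap / Ep
  S[4, 4] <- S[5, 5] <- 1 / G
  S[6, 6] <- 2 * (1 + eta) / E
  ev <- eigen(S[1:3, 1:3], symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0) || G <= 0)
    stop(sprintf(paste0("elasticity tensor not positive definite for ",
                        "E=%g, E'=%g, G=%g kPa, eta=%g, eta'=%g"),
                 E / 1e3, Ep / 1e3, G / 1e3, eta, etap))
  C3 <- solve(S)
  C3[c(1, 2, 6), c(1, 2, 6)]   # plane strain: (e_xx, e_yy, g_xy) retained
}

#' Assemble stiffness and mass operators
#'
#' Constant-strain triangles, consistent mass. The cover layer's transverse
#' modulus varies linearly along the inferior-superior (y) coordinate at
#' slope `vsg` (kPa/mm), evaluated at element centroids and anchored at the
#' inferior bound of the cover layer.
#'
#' @param mesh [solid_mesh()].
#' @param layers named list of [material_layer()]s keyed by the mesh layer
#'   labels (see [default_materials()]).
#' @param thickness out-of-plane depth (m) scaling both operators.
#' @return object of class `phs_fem_system`: sparse `K`, `M`, the free-DOF
#'   index, and bookkeeping for time stepping.
#' @export
assemble_system <- function(mesh, layers = default_materials(),
                            thickness = 1) {
  stopifnot(inherits(mesh, "phs_solid_mesh"))
  nn <- nrow(mesh$nodes); ne <- nrow(mesh$tri)
  areas <- tri_areas(mesh$nodes, mesh$tri)
  cy <- (mesh$nodes[mesh$tri[, 1], 2] + mesh$nodes[mesh$tri[, 2], 2] +
         mesh$nodes[mesh$tri[, 3], 2]) / 3
  # VSG anchor: inferior-most node of each varying layer
  y_ref <- vapply(names(layers), function(nm) {
    el <- mesh$layer == nm
    if (!any(el)) return(NA_real_)
    min(mesh$nodes[unique(as.vector(mesh$tri[el, ])), 2])
  }, numeric(1))
  iK <- integer(36L * ne); jK <- integer(36L * ne); vK <- numeric(36L * ne)
  iM <- integer(18L * ne); jM <- integer(18L * ne); vM <- numeric(18L * ne)
  Mref <- matrix(c(2, 1, 1, 1, 2, 1, 1, 1, 2) / 12, 3, 3)
  for (e in seq_len(ne)) {
    en <- mesh$tri[e, ]
    xy <- mesh$nodes[en, ]
    mat <- layers[[mesh$layer[e]]]
    if (is.null(mat)) stop(sprintf("no material for layer '%s'", mesh$layer[e]))
    Eov <- NULL
    if (!is.null(mat$vsg) && mat$vsg != 0) {
      dy_mm <- (cy[e] - y_ref[[mesh$layer[e]]]) * 1e3
      Eov <- mat$E + mat$vsg * dy_mm
    }
    C <- elasticity_2d(mat, Eov)
    b <- c(xy[2, 2] - xy[3, 2], xy[3, 2] - xy[1, 2], xy[1, 2] - xy[2, 2])
    c_ <- c(xy[3, 1] - xy[2, 1], xy[1, 1] - xy[3, 1], xy[2, 1] - xy[1, 1])
    A <- areas[e]
    B <- matrix(0, 3, 6)
    B[1, c(1, 3, 5)] <- b
    B[2, c(2, 4, 6)] <- c_
    B[3, c(1, 3, 5)] <- c_
    B[3, c(2, 4, 6)] <- b
    B <- B / (2 * A)
    Ke <- thickness * A * t(B) %*% C %*% B
    dof <- as.vector(rbind(2L * en - 1L, 2L * en))
    sK <- 36L * (e - 1L)
    iK[sK + 1:36] <- rep(dof, each = 6L)
    jK[sK + 1:36] <- rep(dof, times = 6L)
    vK[sK + 1:36] <- as.vector(Ke)
    Me <- thickness * mat$rho * A * Mref
    sM <- 18L * (e - 1L)
    # consistent mass couples like-direction DOFs only
    iM[sM + 1:18] <- c(rep(2L * en - 1L, each = 3L), rep(2L * en, each = 3L))
    jM[sM + 1:18] <- c(rep(2L * en - 1L, times = 3L), rep(2L * en, times = 3L))
    vM[sM + 1:18] <- c(as.vector(t(Me)), as.vector(t(Me)))
  }
  nd <- 2L * nn
  K <- Matrix::sparseMatrix(i = iK, j = jK, x = vK, dims = c(nd, nd))
  M <- Matrix::sparseMatrix(i = iM, j = jM, x = vM, dims = c(nd, nd))
  fixed_dof <- as.vector(rbind(2L * mesh$fixed - 1L, 2L * mesh$fixed))
  free <- setdiff(seq_len(nd), fixed_dof)
  structure(list(K = K, M = M, free = free, n_dof = nd, mesh = mesh,
                 thickness = thickness,
                 uid = sprintf("%d_%.10e_%.10e", nd, sum(K@x), sum(M@x))),
            class = "phs_fem_system")
}

#' Solid dynamic state
#' @param n_dof number of displacement degrees of freedom.
#' @param t time (s).
#' @return list with displacement `d`, velocity `v`, acceleration `a`, `t`.
#' @export
solid_state <- function(n_dof, t = 0) {
  list(d = numeric(n_dof), v = numeric(n_dof), a = numeric(n_dof), t = t)
}

#' One implicit Newmark step of the tissue dynamics
#'
#' Average-acceleration Newmark (beta = 1/4, gamma = 1/2, unconditionally
#' stable, energy-conserving for undamped linear systems) with optional
#' Rayleigh damping `C = alpha M + beta_r K`. Fixed-surface constraints are
#' enforced exactly by elimination.
#'
#' @param state solid state (see [solid_state()]).
#' @param system [assemble_system()] result.
#' @param load external nodal force vector (N), full DOF length.
#' @param dt time step (s).
#' @param rayleigh `c(alpha, beta)` damping coefficients (1/s, s).
#' @param newmark `c(beta, gamma)` integrator parameters; the default
#'   average acceleration (1/4, 1/2) is energy-conserving, while
#'   `gamma > 1/2` (with `beta = (gamma + 1/2)^2 / 4`) adds the
#'   high-frequency algorithmic dissipation used in coupled runs.
#' @return updated state.
#' @export
step_dynamics <- function(state, system, load, dt,
                          rayleigh = c(0, 1e-5),
                          newmark = c(0.25, 0.5)) {
  fr <- system$free
  K <- system$K[fr, fr, drop = FALSE]; M <- system$M[fr, fr, drop = FALSE]
  C <- rayleigh[1] * M + rayleigh[2] * K
  beta <- newmark[1]; gamma <- newmark[2]
  key <- sprintf("newmark_%s_%.17g_%.17g_%.17g_%.17g_%.17g",
                 system$uid %||% as.character(length(fr)), dt,
                 rayleigh[1], rayleigh[2], beta, gamma)
  A <- cache_get(key)
  if (is.null(A)) {
    Aeff <- M / (beta * dt^2) + gamma / (beta * dt) * C + K
    A <- if (length(fr) == 1L) list(scalar = as.numeric(Aeff)) else
      Matrix::lu(Aeff)
    cache_set(key, A)
  }
  d0 <- state$d[fr]; v0 <- state$v[fr]; a0 <- state$a[fr]
  rhs <- load[fr] +
    M %*% (d0 / (beta * dt^2) + v0 / (beta * dt) + (1 / (2 * beta) - 1) * a0) +
    C %*% (gamma / (beta * dt) * d0 + (gamma / beta - 1) * v0 +
           dt * (gamma / (2 * beta) - 1) * a0)
  d1 <- if (is.list(A)) as.numeric(rhs) / A$scalar else
    as.numeric(Matrix::solve(A, rhs))
  a1 <- (d1 - d0) / (beta * dt^2) - v0 / (beta * dt) - (1 / (2 * beta) - 1) * a0
  v1 <- v0 + dt * ((1 - gamma) * a0 + gamma * a1)
  st <- state
  st$d[fr] <- d1; st$v[fr] <- v1; st$a[fr] <- a1
  st$t <- state$t + dt
  st
}

#' Static linear solve K d = f
#' @inheritParams step_dynamics
#' @return displacement vector (full DOF length, zeros on fixed DOFs).
#' @export
static_solve <- function(system, load) {
  fr <- system$free
  d <- numeric(system$n_dof)
  d[fr] <- as.numeric(Matrix::solve(system$K[fr, fr, drop = FALSE], load[fr]))
  d
}

#' Strain energy of a displacement field
#' @inheritParams step_dynamics
#' @param d displacement vector.
#' @return scalar 0.5 d' K d.
#' @export
strain_energy <- function(system, d) {
  0.5 * sum(d * as.numeric(system$K %*% d))
}

#' Rigid-plane contact between the vocal folds
#'
#' Any wet-surface node whose deformed medial coordinate crosses its side's
#' offset plane (midplane +/- gap/2) is projected back onto the plane and
#' its medial (normal) velocity zeroed, so the inter-fold gap never falls
#' below `plane_gap`. The artificial gap defaults to 0.2 mm, split
#' symmetrically about the midplane.
#'
#' @param state solid state.
#' @param mesh [solid_mesh()] with a `side` marker.
#' @param plane_gap minimum total gap (m).
#' @param midplane_x medial plane x-coordinate (m).
#' @return updated state; the number of constrained nodes is attached as
#'   attribute `"n_contact"`.
#' @export
enforce_contact <- function(state, mesh, plane_gap = 2e-4, midplane_x = 0) {
  stopifnot(!is.null(mesh$side))
  lim <- if (mesh$side == "left") midplane_x - plane_gap / 2 else
    midplane_x + plane_gap / 2
  idx <- mesh$fsi
  xdof <- 2L * idx - 1L
  x <- mesh$nodes[idx, 1] + state$d[xdof]
  viol <- if (mesh$side == "left") x > lim else x < lim
  if (any(viol)) {
    state$d[xdof[viol]] <- lim - mesh$nodes[idx[viol], 1]
    state$v[xdof[viol]] <- 0
  }
  attr(state, "n_contact") <- sum(viol)
  state
}

#' Structured cantilever/beam mesh (for verification studies)
#'
#' @param L,h beam length and height (m); `nx`, `ny` element counts.
#' @param layer label applied to all elements.
#' @return [solid_mesh()] fixed at x = 0, wet surface along the free end.
#' @export
make_beam_mesh <- function(L, h, nx = 40L, ny = 4L, layer = "body") {
  xs <- seq(0, L, length.out = nx + 1L)
  ys <- seq(-h / 2, h / 2, length.out = ny + 1L)
  nodes <- as.matrix(expand.grid(x = xs, y = ys))
  idx <- function(i, j) i + (j - 1L) * (nx + 1L)
  tri <- matrix(NA_integer_, 2L * nx * ny, 3L)
  k <- 0L
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    n1 <- idx(i, j); n2 <- idx(i + 1L, j)
    n3 <- idx(i + 1L, j + 1L); n4 <- idx(i, j + 1L)
    tri[k + 1L, ] <- c(n1, n2, n3); tri[k + 2L, ] <- c(n1, n3, n4)
    k <- k + 2L
  }
  solid_mesh(nodes, tri, layer = rep(layer, nrow(tri)),
             fixed = idx(1L, seq_len(ny + 1L)),
             fsi = idx(nx + 1L, seq_len(ny + 1L)))
}
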