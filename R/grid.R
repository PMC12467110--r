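#' Non-uniform collocated Cartesian grid (2D)
#'
#' Cell-centred grid used by both the incompressible and acoustic solvers.
#' Fields are stored as `nx x ny` matrices indexed `[i, j]` with `i` along
#' x and `j` along y.
#'
#' @param x_nodes,y_nodes strictly increasing face coordinates (m); the
#'   grid has `length(x_nodes) - 1` by `length(y_nodes) - 1` cells.
#' @return object of class `phs_grid` with face coordinates (`xf`, `yf`),
#'   centres (`xc`, `yc`) and spacings (`dx`, `dy`).
#' @export
cartesian_grid <- function(x_nodes, y_nodes) {
  if (any(diff(x_nodes) <= 0) || any(diff(y_nodes) <= 0))
    stop("node coordinates must be strictly increasing")
  xf <- as.numeric(x_nodes); yf <- as.numeric(y_nodes)
  structure(list(
    xf = xf, yf = yf,
    xc = (xf[-1] + xf[-length(xf)]) / 2,
    yc = (yf[-1] + yf[-length(yf)]) / 2,
    dx = diff(xf), dy = diff(yf),
    nx = length(xf) - 1L, ny = length(yf) - 1L),
    class = "phs_grid")
}

#' Uniform grid helper
#' @param xlim,ylim domain extents; `nx`, `ny` cell counts.
#' @return [cartesian_grid()].
#' @export
uniform_grid <- function(xlim, ylim, nx, ny) {
  cartesian_grid(seq(xlim[1], xlim[2], length.out = nx + 1L),
                 seq(ylim[1], ylim[2], length.out = ny + 1L))
}

#' Classify grid cells against an immersed surface
#'
#' Flags each cell centre as fluid or solid by ray-parity point-in-polygon
#' tests against the closed immersed loops; solid cells with at least one
#' fluid face neighbour are designated ghost cells. Deterministic for a
#' given surface and grid.
#'
#' @param grid [cartesian_grid()].
#' @param s `phs_surface` (2D closed loops) or `NULL` for an empty domain.
#' @return integer `nx x ny` matrix: 0 fluid, 1 solid, 2 ghost.
#' @export
classify_cells <- function(grid, s = NULL) {
  nx <- grid$nx; ny <- grid$ny
  flags <- matrix(0L, nx, ny)
  if (is.null(s)) return(flags)
  stopifnot(inherits(s, "phs_surface"))
  if (s$dim != 2L) stop("cell classification implemented for 2D surfaces")
  pts <- cbind(rep(grid$xc, ny), rep(grid$yc, each = nx))
  solid <- matrix(points_inside(s, pts), nx, ny)
  flags[solid] <- 1L
  # ghost: solid with a fluid 4-neighbour
  fl <- !solid
  nb <- matrix(FALSE, nx, ny)
  nb[-1, ] <- nb[-1, ] | fl[-nx, ]
  nb[-nx, ] <- nb[-nx, ] | fl[-1, ]
  nb[, -1] <- nb[, -1] | fl[, -ny]
  nb[, -ny] <- nb[, -ny] | fl[, -1]
  flags[solid & nb] <- 2L
  flags
}

#' Precompute ghost-cell mirror geometry
#'
#' For every ghost cell: the body-intercept point (closest point on the
#' immersed surface, so the ghost-image segment is normal to it), the image
#' point mirrored into the fluid, and the bilinear interpolation stencil at
#' the image point. Ghosts whose stencil contains non-fluid cells are
#' counted in `n_fallback`; their interpolation replaces the missing donors
#' with the boundary condition at the body intercept (see
#' [ghost_cell_update()]).
#'
#' @param grid [cartesian_grid()].
#' @param flags classification from [classify_cells()].
#' @param s immersed `phs_surface`.
#' @return list describing the ghost stencils, used by [ghost_cell_update()].
#' @export
build_ghost_stencils <- function(grid, flags, s) {
  gi <- which(flags == 2L, arr.ind = TRUE)
  ng <- nrow(gi)
  if (ng == 0L)
    return(list(n = 0L, n_fallback = 0L))
  gc_xy <- cbind(grid$xc[gi[, 1]], grid$yc[gi[, 2]])
  cp <- closest_surface_point(s, gc_xy)
  bi <- cp$point
  im <- 2 * bi - gc_xy                       # image point in the fluid
  # bilinear stencil: cell centres surrounding the image point
  i0 <- pmin(pmax(findInterval(im[, 1], grid$xc), 1L), grid$nx - 1L)
  j0 <- pmin(pmax(findInterval(im[, 2], grid$yc), 1L), grid$ny - 1L)
  # no clamping: an image point beyond the outermost cell centre is
  # handled by (linear-exact) bilinear extrapolation from the edge stencil
  tx <- (im[, 1] - grid$xc[i0]) / (grid$xc[i0 + 1L] - grid$xc[i0])
  ty <- (im[, 2] - grid$yc[j0]) / (grid$yc[j0 + 1L] - grid$yc[j0])
  w <- cbind((1 - tx) * (1 - ty), tx * (1 - ty), (1 - tx) * ty, tx * ty)
  cells <- cbind(i0 + (j0 - 1L) * grid$nx,
                 i0 + 1L + (j0 - 1L) * grid$nx,
                 i0 + j0 * grid$nx,
                 i0 + 1L + j0 * grid$nx)
  fluid_ok <- matrix(flags[cells] == 0L, ng, 4L)
  # donor coordinates of the stencil corners
  dx_ <- cbind(grid$xc[i0], grid$xc[i0 + 1L], grid$xc[i0], grid$xc[i0 + 1L])
  dy_ <- cbind(grid$yc[j0], grid$yc[j0], grid$yc[j0 + 1L], grid$yc[j0 + 1L])
  nvec <- im - bi                            # points into the fluid
  nn <- sqrt(rowSums(nvec^2)); nn[nn == 0] <- 1
  nvec <- nvec / nn
  n_fallback <- sum(!apply(fluid_ok, 1L, all))
  list(n = ng, idx = gi, cells = cells, w = w, fluid_ok = fluid_ok,
       donor_x = dx_, donor_y = dy_, normal = nvec,
       bi = bi, im = im, gc = gc_xy,
       n_fallback = n_fallback)
}

#' Update ghost-cell values so the wall condition holds at the surface
#'
#' The body intercept lies midway between the ghost centre and the image
#' point, so a Dirichlet condition gives `g = 2 w_BI - f_image` (mirror)
#' and a homogeneous Neumann condition gives `g = f_image`; both are
#' second-order along the surface normal, with bilinear (linear-exact)
#' interpolation at the image point. When part of the bilinear stencil is
#' not fluid, the missing donor rows are replaced by the boundary
#' condition imposed at the body intercept (value for Dirichlet, zero
#' normal gradient for Neumann) and the small bilinear system is solved
#' directly, which preserves linear exactness.
#'
#' @param field `nx x ny` field matrix.
#' @param gs stencils from [build_ghost_stencils()].
#' @param wall value at the body intercept: scalar, or function `(x, y)`
#'   evaluated at the intercept points (Dirichlet only).
#' @param type `"dirichlet"` or `"neumann"`.
#' @return field with ghost cells overwritten.
#' @export
ghost_cell_update <- function(field, gs, wall = 0,
                              type = c("dirichlet", "neumann")) {
  type <- match.arg(type)
  if (gs$n == 0L) return(field)
  fvals <- matrix(field[gs$cells], gs$n, 4L)
  fim <- rowSums(fvals * gs$w)
  wv <- if (is.function(wall)) wall(gs$bi[, 1], gs$bi[, 2]) else
    rep(wall, length.out = gs$n)
  fb <- which(!apply(gs$fluid_ok, 1L, all))
  for (k in fb) {
    ok <- gs$fluid_ok[k, ]
    xb <- gs$bi[k, 1]; yb <- gs$bi[k, 2]
    xi <- gs$im[k, 1]; yi <- gs$im[k, 2]
    # distinct constraints: the fluid donors plus one condition at the
    # body intercept (value for Dirichlet, zero normal gradient otherwise)
    xs <- gs$donor_x[k, ok]; ys <- gs$donor_y[k, ok]
    bs <- fvals[k, ok]
    if (type == "dirichlet") {
      crow <- function(basis) switch(basis,
        bilinear = c(1, xb, yb, xb * yb), linear = c(1, xb, yb))
      cval <- wv[k]
    } else {
      nx_ <- gs$normal[k, 1]; ny_ <- gs$normal[k, 2]
      crow <- function(basis) switch(basis,
        bilinear = c(0, nx_, ny_, nx_ * yb + ny_ * xb), linear = c(0, nx_, ny_))
      cval <- 0
    }
    m <- length(bs) + 1L
    fim[k] <- if (m >= 4L) {
      A <- rbind(cbind(1, xs, ys, xs * ys), crow("bilinear"))
      cf <- tryCatch(solve(A, c(bs, cval)), error = function(e) rep(NA, 4))
      if (anyNA(cf)) mean(bs) else sum(cf * c(1, xi, yi, xi * yi))
    } else if (m == 3L) {
      A <- rbind(cbind(1, xs, ys), crow("linear"))
      cf <- tryCatch(solve(A, c(bs, cval)), error = function(e) rep(NA, 3))
      if (anyNA(cf)) mean(bs) else sum(cf * c(1, xi, yi))
    } else if (m == 2L) {
      # one donor + the intercept: linear along the connecting line
      if (type == "dirichlet") {
        d1 <- sqrt((xs - xb)^2 + (ys - yb)^2)
        di <- sqrt((xi - xb)^2 + (yi - yb)^2)
        if (d1 > 1e-14) cval + (bs - cval) * di / d1 else cval
      } else bs
    } else {
      if (type == "dirichlet") cval else 0
    }
  }
  gvals <- if (type == "dirichlet") 2 * wv - fim else fim
  field[gs$idx] <- gvals
  field
}
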