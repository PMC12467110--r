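#' Immersed-boundary surfaces
#'
#' A `phs_surface` holds the Lagrangian interface geometry immersed in the
#' Cartesian flow/acoustic grid. In 2D it is a set of closed polylines
#' (loops); in 3D a consistently oriented triangulated surface. Coordinates
#' are SI metres.
#'
#' @param vertices numeric matrix, one row per vertex (2 or 3 columns).
#' @param loops list of integer vectors; each vector lists vertex indices of
#'   one closed loop in order (the closing edge is implicit). 2D only.
#' @param triangles integer matrix (m x 3) of vertex indices. 3D only.
#' @param tags character vector of per-loop (2D) or per-triangle (3D) region
#'   labels, e.g. `"wall"`, `"inlet"`, `"outlet"`, `"fsi"`, `"fixed"`.
#' @return An object of class `phs_surface`.
#' @export
surface <- function(vertices, loops = NULL, triangles = NULL, tags = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dim <- ncol(vertices)
  if (!dim %in% c(2L, 3L)) stop("vertices must have 2 or 3 columns")
  if (dim == 2L) {
    if (is.null(loops)) stop("2D surface requires `loops`")
    loops <- lapply(loops, as.integer)
    for (lp in loops) {
      if (length(lp) < 3L) stop("each loop needs at least 3 vertices")
      if (any(lp < 1L | lp > nrow(vertices))) stop("loop index out of range")
    }
    if (is.null(tags)) tags <- rep("wall", length(loops))
    if (length(tags) != length(loops)) stop("one tag per loop required")
    s <- structure(list(vertices = vertices, loops = loops, tags = tags,
                        dim = 2L), class = "phs_surface")
  } else {
    if (is.null(triangles)) stop("3D surface requires `triangles`")
    triangles <- as.matrix(triangles)
    storage.mode(triangles) <- "integer"
    if (ncol(triangles) != 3L) stop("triangles must have 3 columns")
    if (any(triangles < 1L | triangles > nrow(vertices)))
      stop("triangle index out of range")
    if (is.null(tags)) tags <- rep("wall", nrow(triangles))
    if (length(tags) != nrow(triangles)) stop("one tag per triangle required")
    s <- structure(list(vertices = vertices, triangles = triangles,
                        tags = tags, dim = 3L), class = "phs_surface")
  }
  s
}

#' @export
print.phs_surface <- function(x, ...) {
  if (x$dim == 2L) {
    cat(sprintf("<phs_surface 2D: %d vertices, %d loop(s), tags: %s>\n",
                nrow(x$vertices), length(x$loops),
                paste(unique(x$tags), collapse = ", ")))
  } else {
    cat(sprintf("<phs_surface 3D: %d vertices, %d triangles, tags: %s>\n",
                nrow(x$vertices), nrow(x$triangles),
                paste(unique(x$tags), collapse = ", ")))
  }
  invisible(x)
}

#' Closed polygon surface from ordered 2D vertices
#'
#' @param xy numeric matrix (n x 2) of vertices in order around the loop.
#' @param tag region label for the loop.
#' @return `phs_surface` with one loop.
#' @export
polygon_surface <- function(xy, tag = "wall") {
  surface(xy, loops = list(seq_len(nrow(xy))), tags = tag)
}

#' Regular polygon approximation of a circle
#'
#' @param r radius (m); `n` vertex count; `center` length-2 centre.
#' @return n x 2 vertex matrix (counter-clockwise, not closed).
#' @export
circle_polygon <- function(r, n = 256L, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

#' Signed polygon area (shoelace formula)
#'
#' Positive for counter-clockwise vertex order.
#'
#' @param xy n x 2 vertex matrix (closing edge implicit).
#' @return signed area.
#' @export
polygon_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  0.5 * sum(x * yn - xn * y)
}

# Edge list (from, to) row indices for one loop
loop_edges <- function(loop) {
  cbind(loop, c(loop[-1], loop[1]))
}

#' Validate surface closure and element quality
#'
#' Checks that loops are closed with no degenerate (shorter than `eps`)
#' segments in 2D, or that every edge is shared by exactly two triangles and
#' no triangle area is below `eps` in 3D.
#'
#' @param s `phs_surface`.
#' @param eps degeneracy threshold (m for segment length, m^2 for area).
#' @return `TRUE` invisibly; stops with a message on violation.
#' @export
validate_surface <- function(s, eps = 1e-12) {
  stopifnot(inherits(s, "phs_surface"))
  if (any(!is.finite(s$vertices))) stop("non-finite vertex coordinates")
  if (s$dim == 2L) {
    for (lp in s$loops) {
      e <- loop_edges(lp)
      len <- sqrt(rowSums((s$vertices[e[, 2], , drop = FALSE] -
                           s$vertices[e[, 1], , drop = FALSE])^2))
      if (any(len <= eps)) stop("degenerate polyline segment")
    }
  } else {
    tri <- s$triangles
    a <- s$vertices[tri[, 1], ]; b <- s$vertices[tri[, 2], ]
    cc <- s$vertices[tri[, 3], ]
    u <- b - a; v <- cc - a
    nrm <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                 u[, 3] * v[, 1] - u[, 1] * v[, 3],
                 u[, 1] * v[, 2] - u[, 2] * v[, 1])
    area <- 0.5 * sqrt(rowSums(nrm^2))
    if (any(area <= eps)) stop("degenerate triangle")
    # each undirected edge must appear exactly twice for a closed surface
    ed <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
    key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
    cnt <- table(key)
    if (any(cnt != 2L)) stop("surface not closed: edge not shared by exactly 2 triangles")
  }
  invisible(TRUE)
}

#' Point-in-surface test for 2D loops (even-odd ray parity per loop)
#'
#' A point is "inside" if it lies inside any loop. Loops are treated as
#' independent solid regions so overlapping components union cleanly.
#'
#' @param s `phs_surface` (2D).
#' @param pts n x 2 matrix of query points.
#' @return logical vector, `TRUE` for points inside the solid.
#' @export
points_inside <- function(s, pts) {
  stopifnot(s$dim == 2L)
  pts <- as.matrix(pts)
  inside <- rep(FALSE, nrow(pts))
  for (lp in s$loops) {
    P <- s$vertices[lp, , drop = FALSE]
    n <- nrow(P)
    xi <- P[, 1]; yi <- P[, 2]
    xj <- c(xi[n], xi[-n]); yj <- c(yi[n], yi[-n])
    inl <- rep(FALSE, nrow(pts))
    for (k in seq_len(n)) {
      crosses <- ((yi[k] > pts[, 2]) != (yj[k] > pts[, 2]))
      if (any(crosses)) {
        xint <- (xj[k] - xi[k]) * (pts[crosses, 2] - yi[k]) /
          (yj[k] - yi[k]) + xi[k]
        flip <- pts[crosses, 1] < xint
        inl[crosses] <- xor(inl[crosses], flip)
      }
    }
    inside <- inside | inl
  }
  inside
}

#' Closest point on a 2D surface to each query point
#'
#' Used by the ghost-cell method to construct the body-intercept point and
#' the surface normal for each ghost cell.
#'
#' @param s `phs_surface` (2D).
#' @param pts n x 2 query points.
#' @return list with `point` (n x 2 closest surface points), `dist`
#'   (distances) and `seg_loop`/`seg_idx` bookkeeping.
#' @export
closest_surface_point <- function(s, pts) {
  stopifnot(s$dim == 2L)
  pts <- as.matrix(pts)
  np <- nrow(pts)
  best_d2 <- rep(Inf, np)
  best_pt <- matrix(NA_real_, np, 2)
  for (lp in s$loops) {
    e <- loop_edges(lp)
    A <- s$vertices[e[, 1], , drop = FALSE]
    B <- s$vertices[e[, 2], , drop = FALSE]
    AB <- B - A
    len2 <- rowSums(AB^2)
    for (k in seq_len(nrow(e))) {
      ap <- cbind(pts[, 1] - A[k, 1], pts[, 2] - A[k, 2])
      tpar <- (ap[, 1] * AB[k, 1] + ap[, 2] * AB[k, 2]) / len2[k]
      tpar <- pmin(1, pmax(0, tpar))
      qx <- A[k, 1] + tpar * AB[k, 1]
      qy <- A[k, 2] + tpar * AB[k, 2]
      d2 <- (pts[, 1] - qx)^2 + (pts[, 2] - qy)^2
      upd <- d2 < best_d2
      if (any(upd)) {
        best_d2[upd] <- d2[upd]
        best_pt[upd, 1] <- qx[upd]
        best_pt[upd, 2] <- qy[upd]
      }
    }
  }
  list(point = best_pt, dist = sqrt(best_d2))
}

#' Translate / transform surface vertices
#'
#' @param s `phs_surface`.
#' @param f function mapping an n x d vertex matrix to a new n x d matrix.
#' @return surface with transformed vertices.
#' @export
transform_surface <- function(s, f) {
  s$vertices <- f(s$vertices)
  s
}
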