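#' Subglottic stenosis specification
#'
#' Parameters of the idealized cosine constriction applied to the subglottal
#' tract. The severity is the fraction of cross-sectional area removed at
#' the narrowest plane; `a` is the fractional reduction of the hydraulic
#' diameter. For a circular (or affinely circular) section the two are
#' related by `severity = 1 - (1 - a)^2`.
#'
#' Defaults follow the clinically motivated choices used throughout the
#' package: narrowest section 3.13 cm below the superior vocal-fold surface,
#' stenosis length 1.0 cm, tract rotation 22 degrees about the z-axis.
#'
#' @param severity fraction of area removed, in [0, 1). Exactly one of
#'   `severity` or `a` must be given.
#' @param a hydraulic-diameter reduction fraction, in [0, 1).
#' @param L axial length of the stenosis window (m).
#' @param location axial coordinate (in the rotated frame, m) of the
#'   narrowest section. For anatomical geometries this is 3.13 cm inferior
#'   to the superior vocal-fold surface.
#' @param rotation_deg rotation applied about the z-axis before the
#'   deformation (and inverted after), aligning the subglottal tract with
#'   the axial (y) axis.
#' @return object of class `phs_sgs_spec`.
#' @export
sgs_spec <- function(severity = NULL, a = NULL, L = 0.01,
                     location = 0.0313, rotation_deg = 22) {
  if (is.null(severity) && is.null(a))
    stop("give either `severity` or `a`")
  if (!is.null(severity) && !is.null(a)) {
    if (abs(a_to_severity(a) - severity) > 1e-8)
      stop("`severity` and `a` are inconsistent")
  }
  if (is.null(a)) a <- severity_to_a(severity)
  if (is.null(severity)) severity <- a_to_severity(a)
  if (a < 0 || a >= 1) stop("`a` must lie in [0, 1)")
  if (L <= 0) stop("`L` must be positive")
  structure(list(severity = severity, a = a, L = L, location = location,
                 rotation_deg = rotation_deg), class = "phs_sgs_spec")
}

#' Map stenosis severity to the hydraulic-diameter reduction `a`
#'
#' For a circular cross-section the cosine deformation scales both
#' transverse coordinates by `(1 - a)` at the narrowest plane, so the area
#' shrinks by the factor `(1 - a)^2` and
#' `a = 1 - sqrt(1 - severity)`. The printed clinical severities 50/75/90/96
#' per cent map to a = 0.2929, 0.5, 0.6838, 0.8 (4 d.p.).
#'
#' @param severity fraction of cross-sectional area removed, in [0, 1).
#' @return the hydraulic-diameter reduction fraction `a`.
#' @seealso [a_to_severity()], [sgs_calibrate_a()] for the polygon-area
#'   numerical route.
#' @export
severity_to_a <- function(severity) {
  if (any(severity < 0 | severity >= 1)) stop("severity must lie in [0, 1)")
  1 - sqrt(1 - severity)
}

#' Inverse of [severity_to_a()]
#' @param a hydraulic-diameter reduction fraction in [0, 1).
#' @return severity (area-reduction fraction).
#' @export
a_to_severity <- function(a) {
  if (any(a < 0 | a >= 1)) stop("`a` must lie in [0, 1)")
  1 - (1 - a)^2
}

#' Calibrate `a` against the deformed polygon area (numerical route)
#'
#' Discretizes a circular cross-section as a fine polygon at the narrowest
#' stenosis plane, applies the radial cosine scaling, and bisects on `a`
#' until the shoelace area of the deformed polygon equals
#' `(1 - severity)` times the original. This is the normative definition of
#' the severity-to-`a` map for arbitrary cross-sections; for circles it
#' agrees with the closed form in [severity_to_a()].
#'
#' @param severity target area-reduction fraction in [0, 1).
#' @param n_poly number of polygon vertices.
#' @param tol bisection tolerance on `a`.
#' @return calibrated `a`.
#' @export
sgs_calibrate_a <- function(severity, n_poly = 4096L, tol = 1e-12) {
  if (severity < 0 || severity >= 1) stop("severity must lie in [0, 1)")
  if (severity == 0) return(0)
  poly <- circle_polygon(1, n = n_poly)
  area0 <- abs(polygon_area(poly))
  target <- (1 - severity) * area0
  # narrowest plane: both coordinates scaled by (1 - a)
  f <- function(a) abs(polygon_area(poly * (1 - a))) - target
  lo <- 0; hi <- 1 - 1e-12
  while (hi - lo > tol) {
    mid <- 0.5 * (lo + hi)
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  0.5 * (lo + hi)
}

rotation_matrix_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

#' Apply the cosine subglottic-stenosis deformation to a surface
#'
#' Nodes with rotated axial coordinate inside the stenosis window
#' `[location - L/2, location + L/2]` are scaled toward the tract axis:
#' with `yc` the distance from the lower (inferior) window bound,
#' `x_s = x - x * (a/2) * (1 - cos(2*pi*yc/L))` (and identically for `z` in
#' 3D). The axial coordinate is unchanged; the taper is C1-smooth at both
#' window ends. The tract is rotated by `rotation_deg` about the z-axis
#' before the deformation and rotated back afterwards.
#'
#' @param s `phs_surface` (2D polylines or 3D triangulation). Transverse
#'   coordinates are measured from the tract axis (x = 0, and z = 0 in 3D)
#'   in the rotated frame.
#' @param spec `phs_sgs_spec`.
#' @return deformed surface.
#' @export
apply_sgs <- function(s, spec) {
  stopifnot(inherits(s, "phs_surface"), inherits(spec, "phs_sgs_spec"))
  if (spec$a >= 1) stop("`a` must be < 1")
  if (spec$a == 0) return(s)
  lo <- spec$location - spec$L / 2
  hi <- spec$location + spec$L / 2
  V <- s$vertices
  R <- rotation_matrix_z(spec$rotation_deg)
  xy <- V[, 1:2, drop = FALSE] %*% t(R)  # rotate by +rotation_deg
  yr <- xy[, 2]
  rng <- range(yr)
  if (lo < rng[1] - 1e-12 || hi > rng[2] + 1e-12)
    stop("stenosis window lies outside the axial extent of the surface")
  inwin <- yr >= lo & yr <= hi
  if (any(inwin)) {
    yc <- yr[inwin] - lo
    scale <- 1 - spec$a / 2 * (1 - cos(2 * pi * yc / spec$L))
    xy[inwin, 1] <- xy[inwin, 1] * scale
    if (ncol(V) == 3L) V[inwin, 3] <- V[inwin, 3] * scale
  }
  V[, 1:2] <- xy %*% R  # rotate back
  s$vertices <- V
  s
}
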