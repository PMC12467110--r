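#' Idealized two-layer larynx fixture (2D)
#'
#' Builds a straight subglottal-glottal-supraglottal channel with a pair of
#' two-layer (body/cover) vocal folds protruding from the lateral walls,
#' leaving a configurable initial medial gap. The channel walls are returned
#' as immersed wall-region polygons (so a stenosis deformation can bend
#' them), the folds as closed wet polygons plus matching plane-strain
#' finite-element meshes. Deterministic: the same config always yields
#' bit-identical geometry.
#'
#' Coordinates: x is medial-lateral, y is inferior-superior (flow axis,
#' inlet at y = 0). All lengths in metres.
#'
#' @param config nested list; see [larynx_config()] for the defaults. Any
#'   subset of keys may be overridden.
#' @return object of class `phs_larynx`: list with `channel` (wall-region
#'   surface, 2 loops), `folds` (wet fold surface, 2 loops tagged "fsi"),
#'   `solid` (list of `left`/`right` [solid_mesh()]s), `markers`
#'   (data.frame of named boundary locations: inlet, outlet, taps, probe),
#'   `domain` (x/y extents for the flow grid) and the effective `config`.
#' @export
make_idealized_larynx <- function(config = list()) {
  cfg <- modify_defaults(larynx_config(), config)
  ch <- cfg$channel; fo <- cfg$folds
  if (ch$length <= 0 || ch$width <= 0 || ch$wall_pad <= 0 ||
      fo$thickness <= 0 || fo$gap <= 0 || fo$depth_z <= 0)
    stop("fixture dimensions must be positive")
  if (fo$gap >= ch$width) stop("initial gap must be smaller than channel width")
  W <- ch$width; Lc <- ch$length
  xw <- W / 2                       # channel half-width (wall position)
  xdom <- xw + ch$wall_pad
  y0 <- fo$y0; Tf <- fo$thickness
  if (y0 <= 0 || y0 + Tf >= Lc) stop("folds must lie inside the channel")
  D <- xw - fo$gap / 2              # maximum medial protrusion

  # channel wall-region polygons; inner curve densely sampled so the
  # stenosis deformation is resolved. The strips extend past the inlet and
  # outlet planes so near-boundary ghost cells mirror across the lateral
  # wall, not across an artificial end cap.
  nyw <- ch$n_wall
  ext <- 0.1 * Lc
  yy <- seq(-ext, Lc + ext, length.out = nyw)
  pad <- 1e-4
  left_loop <- rbind(c(-xdom - pad, -ext), cbind(rep(-xw, nyw), yy),
                     c(-xdom - pad, Lc + ext))
  right_loop <- rbind(c(xdom + pad, -ext), cbind(rep(xw, nyw), yy),
                      c(xdom + pad, Lc + ext))
  nv <- nrow(left_loop)
  channel <- surface(rbind(left_loop, right_loop),
                     loops = list(seq_len(nv), nv + seq_len(nv)),
                     tags = c("wall", "wall"))

  solidL <- fold_mesh(cfg, side = "left")
  solidR <- fold_mesh(cfg, side = "right")

  # wet fold polygons for the immersed-boundary solver: the fsi polyline
  # closed along the wall (base slightly into the wall region so the union
  # with the wall polygon is watertight)
  fold_loop <- function(m) {
    wet <- m$nodes[m$fsi, , drop = FALSE]
    base_x <- if (m$side == "left") -xdom else xdom
    rbind(c(base_x, wet[1, 2]), wet, c(base_x, wet[nrow(wet), 2]))
  }
  fl <- fold_loop(solidL); fr <- fold_loop(solidR)
  folds <- surface(rbind(fl, fr),
                   loops = list(seq_len(nrow(fl)), nrow(fl) + seq_len(nrow(fr))),
                   tags = c("fsi", "fsi"))

  y_sup <- y0 + Tf                  # superior fold surface
  markers <- data.frame(
    name = c("inlet", "outlet", "p_sub", "p_sup", "p_sgs_up", "p_sgs_down",
             "probe"),
    x = rep(0, 7),
    y = c(0, Lc,
          y0 - 0.004, y_sup + 0.004,
          max(y_sup - cfg$sgs$location - cfg$sgs$length / 2 - 0.004, 0.002),
          y_sup - cfg$sgs$location + cfg$sgs$length / 2 + 0.004,
          Lc - 0.005),
    stringsAsFactors = FALSE)

  structure(list(channel = channel, folds = folds,
                 solid = list(left = solidL, right = solidR),
                 markers = markers,
                 domain = list(x = c(-xdom, xdom), y = c(0, Lc)),
                 config = cfg),
            class = "phs_larynx")
}

#' Default fixture configuration
#'
#' Channel and fold dimensions loosely follow adult human laryngeal scale:
#' a 10 cm airway segment, 2 cm wide, folds 1 cm thick (inferior-superior)
#' starting 5 cm above the inlet, 1 mm initial glottal gap, 1 cm
#' anterior-posterior depth used to convert 2D gaps to areas.
#'
#' @return nested list of defaults.
#' @export
larynx_config <- function() {
  list(
    channel = list(length = 0.10, width = 0.02, wall_pad = 0.004,
                   n_wall = 201L),
    folds = list(y0 = 0.05, thickness = 0.01, gap = 0.001,
                 depth_z = 0.01, n_xi = 6L, n_eta = 12L,
                 cover_frac = 0.3, shape_end = 0.15,
                 plateau = c(0.4, 0.6)),
    sgs = list(severity = 0, length = 0.01, location = 0.0313,
               rotation_deg = 0)
  )
}

# Medial-surface profile shape in [0, 1]: trapezoid with plateau and
# non-zero end thickness (keeps the structured fold mesh non-degenerate).
fold_shape <- function(eta, plateau = c(0.4, 0.6), s_end = 0.15) {
  s <- numeric(length(eta))
  lo <- plateau[1]; hi <- plateau[2]
  r <- eta < lo
  s[r] <- s_end + (1 - s_end) * eta[r] / lo
  s[eta >= lo & eta <= hi] <- 1
  f <- eta > hi
  s[f] <- s_end + (1 - s_end) * (1 - eta[f]) / (1 - hi)
  s
}

# Structured triangulated fold block; left fold attaches to x = -W/2.
fold_mesh <- function(cfg, side = c("left", "right")) {
  side <- match.arg(side)
  ch <- cfg$channel; fo <- cfg$folds
  xw <- ch$width / 2
  D <- xw - fo$gap / 2
  nxi <- fo$n_xi; neta <- fo$n_eta
  xi <- seq(0, 1, length.out = nxi + 1L)
  eta <- seq(0, 1, length.out = neta + 1L)
  prof <- fold_shape(eta, fo$plateau, fo$shape_end)  # protrusion fraction
  sgn <- if (side == "left") 1 else -1
  wall_x <- if (side == "left") -xw else xw
  nodes <- matrix(NA_real_, (nxi + 1L) * (neta + 1L), 2L)
  idx <- function(i, j) i + (j - 1L) * (nxi + 1L)   # i over xi, j over eta
  for (j in seq_len(neta + 1L)) {
    xm <- wall_x + sgn * D * prof[j]               # medial surface at eta_j
    nodes[idx(seq_len(nxi + 1L), j), 1] <- wall_x + xi * (xm - wall_x)
    nodes[idx(seq_len(nxi + 1L), j), 2] <- fo$y0 + fo$thickness * eta[j]
  }
  tri <- matrix(NA_integer_, 2L * nxi * neta, 3L)
  k <- 0L
  for (j in seq_len(neta)) {
    for (i in seq_len(nxi)) {
      n1 <- idx(i, j); n2 <- idx(i + 1L, j)
      n3 <- idx(i + 1L, j + 1L); n4 <- idx(i, j + 1L)
      # split so triangle orientation is CCW for the left fold
      tri[k + 1L, ] <- c(n1, n2, n3)
      tri[k + 2L, ] <- c(n1, n3, n4)
      k <- k + 2L
    }
  }
  # flip orientation for the mirrored fold so areas stay positive
  if (side == "right") tri <- tri[, c(1, 3, 2)]
  cent_xi <- (xi[-1] + xi[-length(xi)]) / 2
  layer <- character(nrow(tri))
  k <- 0L
  for (j in seq_len(neta)) {
    for (i in seq_len(nxi)) {
      lab <- if (cent_xi[i] > 1 - fo$cover_frac) "cover" else "body"
      layer[k + 1L] <- lab; layer[k + 2L] <- lab
      k <- k + 2L
    }
  }
  fixed <- idx(1L, seq_len(neta + 1L))
  # wet boundary: inferior edge (wall -> tip), medial column, superior edge
  fsi <- c(idx(seq(2L, nxi + 1L), 1L),
           idx(nxi + 1L, seq(2L, neta + 1L)),
           idx(rev(seq(2L, nxi)), neta + 1L))
  solid_mesh(nodes, tri, layer = layer, fixed = fixed, fsi = fsi,
             side = side)
}

# shallow-recursive override of defaults; unknown keys rejected
modify_defaults <- function(defaults, override, path = "") {
  if (length(override) == 0) return(defaults)
  for (nm in names(override)) {
    if (!nm %in% names(defaults))
      stop(sprintf("unknown config key '%s%s'", path, nm))
    if (is.list(defaults[[nm]]) && is.list(override[[nm]])) {
      defaults[[nm]] <- modify_defaults(defaults[[nm]], override[[nm]],
                                        paste0(path, nm, "."))
    } else {
      defaults[[nm]] <- override[[nm]]
    }
  }
  defaults
}
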