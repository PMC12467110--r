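#' Read an STL surface mesh (ASCII or binary)
#'
#' Auto-detects the flavour. Coordinates are multiplied by `unit` to bring
#' user meshes to SI metres (e.g. `unit = 1e-3` for millimetre STL).
#'
#' @param path file path.
#' @param unit scale factor applied to coordinates.
#' @param merge_tol vertex-welding tolerance (in scaled units) used to
#'   rebuild shared connectivity from the facet soup.
#' @return 3D `phs_surface`.
#' @export
read_stl <- function(path, unit = 1, merge_tol = 1e-9) {
  con <- file(path, "rb")
  head <- readBin(con, "raw", 80L)
  ntri_bin <- tryCatch(readBin(con, "integer", 1L, size = 4L,
                               endian = "little"), error = function(e) NA)
  close(con)
  sz <- file.size(path)
  is_binary <- length(ntri_bin) == 1L && !is.na(ntri_bin) &&
    sz == 84 + 50 * as.numeric(ntri_bin)
  if (is_binary) {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", 84L)
    v <- matrix(NA_real_, 3L * ntri_bin, 3L)
    for (k in seq_len(ntri_bin)) {
      vals <- readBin(con, "numeric", 12L, size = 4L, endian = "little")
      v[(3L * k - 2L):(3L * k), ] <- matrix(vals[4:12], 3, 3, byrow = TRUE)
      readBin(con, "raw", 2L)
    }
  } else {
    txt <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
    if (length(vl) == 0L || length(vl) %% 3L != 0L)
      stop(sprintf("malformed ASCII STL '%s': %d vertex lines", path,
                   length(vl)))
    v <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p)
      as.numeric(p[2:4])))
  }
  v <- v * unit
  key <- apply(round(v / merge_tol), 1L, paste, collapse = "_")
  uid <- !duplicated(key)
  verts <- v[uid, , drop = FALSE]
  map <- match(key, key[uid])
  tri <- matrix(map, ncol = 3L, byrow = TRUE)
  surface(verts, triangles = tri)
}

#' Write an STL surface mesh
#'
#' @param s 3D `phs_surface`.
#' @param path output path.
#' @param ascii write ASCII (default) or little-endian binary.
#' @param unit divide coordinates by this factor on output.
#' @return `path` invisibly.
#' @export
write_stl <- function(s, path, ascii = TRUE, unit = 1) {
  stopifnot(inherits(s, "phs_surface"), s$dim == 3L)
  V <- s$vertices / unit
  tri <- s$triangles
  a <- V[tri[, 1], , drop = FALSE]
  b <- V[tri[, 2], , drop = FALSE]
  cc <- V[tri[, 3], , drop = FALSE]
  u <- b - a; w <- cc - a
  nrm <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
               u[, 3] * w[, 1] - u[, 1] * w[, 3],
               u[, 1] * w[, 2] - u[, 2] * w[, 1])
  nl <- sqrt(rowSums(nrm^2)); nl[nl == 0] <- 1
  nrm <- nrm / nl
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid phonosim", con)
    for (k in seq_len(nrow(tri))) {
      writeLines(c(
        sprintf("  facet normal %.9e %.9e %.9e", nrm[k, 1], nrm[k, 2],
                nrm[k, 3]),
        "    outer loop",
        sprintf("      vertex %.9e %.9e %.9e", a[k, 1], a[k, 2], a[k, 3]),
        sprintf("      vertex %.9e %.9e %.9e", b[k, 1], b[k, 2], b[k, 3]),
        sprintf("      vertex %.9e %.9e %.9e", cc[k, 1], cc[k, 2], cc[k, 3]),
        "    endloop",
        "  endfacet"), con)
    }
    writeLines("endsolid phonosim", con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80L), con)
    writeBin(as.integer(nrow(tri)), con, size = 4L, endian = "little")
    for (k in seq_len(nrow(tri))) {
      writeBin(as.numeric(c(nrm[k, ], a[k, ], b[k, ], cc[k, ])), con,
               size = 4L, endian = "little")
      writeBin(raw(2L), con)
    }
  }
  invisible(path)
}

#' Write a 2D polyline surface as legacy VTK polydata
#'
#' @param s 2D `phs_surface`.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_vtk_polydata <- function(s, path) {
  stopifnot(inherits(s, "phs_surface"), s$dim == 2L)
  con <- file(path, "w")
  on.exit(close(con))
  nv <- nrow(s$vertices)
  writeLines(c("# vtk DataFile Version 3.0", "phonosim polylines", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d double", nv)), con)
  writeLines(sprintf("%.12e %.12e 0.0", s$vertices[, 1], s$vertices[, 2]),
             con)
  sizes <- vapply(s$loops, length, integer(1)) + 1L
  writeLines(sprintf("LINES %d %d", length(s$loops),
                     sum(sizes) + length(s$loops)), con)
  for (k in seq_along(s$loops)) {
    lp <- s$loops[[k]]
    writeLines(paste(c(length(lp) + 1L, lp - 1L, lp[1] - 1L),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Read legacy VTK polydata polylines back into a surface
#' @param path VTK file written by [write_vtk_polydata()].
#' @return 2D `phs_surface`.
#' @export
read_vtk_polydata <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot open '%s'", path))
  txt <- readLines(path, warn = FALSE)
  ip <- grep("^POINTS", txt)
  if (length(ip) != 1L) stop(sprintf("parse error in '%s': no POINTS", path))
  nv <- as.integer(strsplit(txt[ip], "\\s+")[[1]][2])
  pts <- do.call(rbind, lapply(txt[(ip + 1L):(ip + nv)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  il <- grep("^LINES", txt)
  if (length(il) != 1L) stop(sprintf("parse error in '%s': no LINES", path))
  nl <- as.integer(strsplit(txt[il], "\\s+")[[1]][2])
  loops <- lapply(txt[(il + 1L):(il + nl)], function(l) {
    v <- as.integer(strsplit(trimws(l), "\\s+")[[1]])
    idx <- v[-1] + 1L
    if (idx[1] == idx[length(idx)]) idx <- idx[-length(idx)]
    idx
  })
  surface(pts[, 1:2, drop = FALSE], loops = loops)
}

#' Write cell-centred fields as a legacy VTK rectilinear grid
#'
#' @param grid [cartesian_grid()].
#' @param fields named list of `nx x ny` matrices.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_vtk_rectilinear <- function(grid, fields, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "phonosim fields", "ASCII",
               "DATASET RECTILINEAR_GRID",
               sprintf("DIMENSIONS %d %d 1", grid$nx, grid$ny),
               sprintf("X_COORDINATES %d double", grid$nx)), con)
  writeLines(paste(sprintf("%.9e", grid$xc), collapse = " "), con)
  writeLines(sprintf("Y_COORDINATES %d double", grid$ny), con)
  writeLines(paste(sprintf("%.9e", grid$yc), collapse = " "), con)
  writeLines(c("Z_COORDINATES 1 double", "0.0",
               sprintf("POINT_DATA %d", grid$nx * grid$ny)), con)
  for (nm in names(fields)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.9e", as.numeric(fields[[nm]])), con)
  }
  invisible(path)
}

#' Write a time-series record to CSV with a unit header line
#'
#' The first line is a `#`-prefixed unit annotation, followed by a regular
#' CSV table.
#'
#' @param record data.frame (e.g. [cycle_record()]).
#' @param path output path.
#' @param units named character vector of units per column.
#' @return `path` invisibly.
#' @export
write_series_csv <- function(record, path,
                             units = c(t = "s", Ag = "cm^2", Q = "mL/s",
                                       p_probe = "Pa", p_sub = "Pa",
                                       p_sup = "Pa", p_sgs_up = "Pa",
                                       p_sgs_down = "Pa")) {
  con <- file(path, "w")
  on.exit(close(con))
  ann <- vapply(names(record), function(nm)
    sprintf("%s:%s", nm, if (nm %in% names(units)) units[[nm]] else "1"),
    character(1))
  writeLines(paste0("# units ", paste(ann, collapse = ",")), con)
  utils::write.csv(as.data.frame(record), con, row.names = FALSE)
  invisible(path)
}

#' Read a time-series CSV written by [write_series_csv()]
#' @param path file path.
#' @return [cycle_record()] when the standard columns are present,
#'   otherwise a tibble; declared units attached as attribute `"units"`.
#' @export
read_series_csv <- function(path) {
  first <- readLines(path, n = 1L)
  units <- NULL
  if (startsWith(first, "# units ")) {
    kv <- strsplit(sub("^# units ", "", first), ",")[[1]]
    sp <- strsplit(kv, ":")
    units <- stats::setNames(vapply(sp, `[`, "", 2L),
                             vapply(sp, `[`, "", 1L))
  }
  df <- utils::read.csv(path, comment.char = "#")
  out <- if (all(c("t", "Ag") %in% names(df))) {
    do.call(cycle_record, df[intersect(names(df),
      c("t", "Ag", "Q", "p_probe", "p_sub", "p_sup", "p_sgs_up",
        "p_sgs_down"))])
  } else tibble::as_tibble(df)
  attr(out, "units") <- units
  out
}

#' Read a YAML run configuration
#'
#' Unknown keys are rejected against [default_run_config()]; missing keys
#' take their defaults. The effective configuration (with its md5 hash) is
#' what every solver output records for provenance.
#'
#' @param path YAML file.
#' @return validated config list with attribute `"hash"`.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  validate_config(if (is.null(user)) list() else user)
}

#' Validate and complete a run configuration
#' @param config partial nested list.
#' @return full config with attribute `"hash"`.
#' @export
validate_config <- function(config = list()) {
  cfg <- modify_defaults(default_run_config(), config)
  attr(cfg, "hash") <- object_hash(cfg)
  cfg
}
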