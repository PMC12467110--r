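# Internal helpers: factorization cache, batched tridiagonal solver, hashing.

.phs_cache <- new.env(parent = emptyenv())

cache_get <- function(key) {
  if (exists(key, envir = .phs_cache, inherits = FALSE))
    get(key, envir = .phs_cache, inherits = FALSE)
  else NULL
}

cache_set <- function(key, value) {
  assign(key, value, envir = .phs_cache)
  value
}

#' Clear cached operator factorizations
#'
#' Solver operators (Poisson, Crank-Nicolson, Newmark) are factorized once
#' and reused across time steps; call this to reclaim memory between
#' unrelated runs.
#' @return invisibly, the number of entries dropped.
#' @export
clear_solver_cache <- function() {
  n <- length(ls(.phs_cache))
  rm(list = ls(.phs_cache), envir = .phs_cache)
  invisible(n)
}

# md5 of an R object via canonical JSON (config provenance stamping)
object_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(f))
}

rms <- function(x) sqrt(mean(x^2))
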