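#' Snapshot proper orthogonal decomposition of surface vibration
#'
#' Singular-value decomposition of the mean-subtracted snapshot matrix of
#' wet-surface displacements. Spatial modes are orthonormal (unweighted
#' Euclidean inner product); mode energies are the squared singular values
#' normalized to sum to one.
#'
#' @param snapshots numeric matrix, one column per time sample, rows are
#'   the stacked surface displacement components (consistent node ordering
#'   across cases that will be compared).
#' @param times optional sample times (s).
#' @param n_modes number of modes to retain (default: all).
#' @return object of class `phs_pod`: `modes` (columns orthonormal),
#'   `energies`, temporal `coeffs` (mode x time), the temporal `mean`
#'   vector and `times`.
#' @export
compute_pod <- function(snapshots, times = NULL, n_modes = NULL) {
  X <- as.matrix(snapshots)
  if (ncol(X) < 2L) stop("need at least 2 snapshots")
  mu <- rowMeans(X)
  X0 <- X - mu
  if (max(abs(X0)) == 0) stop("zero-variance snapshots: POD undefined")
  sv <- svd(X0)
  energies <- sv$d^2 / sum(sv$d^2)
  k <- if (is.null(n_modes)) length(sv$d) else min(n_modes, length(sv$d))
  structure(list(modes = sv$u[, seq_len(k), drop = FALSE],
                 energies = energies[seq_len(k)],
                 energies_all = energies,
                 coeffs = (diag(sv$d, nrow = length(sv$d)) %*%
                           t(sv$v))[seq_len(k), , drop = FALSE],
                 mean = mu, times = times),
            class = "phs_pod")
}

#' @export
print.phs_pod <- function(x, ...) {
  cat(sprintf("<phs_pod: %d modes, leading energies %s>\n",
              ncol(x$modes),
              paste(sprintf("%.1f%%", 100 * utils::head(x$energies, 3)),
                    collapse = ", ")))
  invisible(x)
}

#' Mode-energy table of a POD (one row per mode)
#' @param x `phs_pod`.
#' @return tibble with mode index, energy fraction and cumulative energy.
#' @export
pod_energies <- function(x) {
  tibble::tibble(mode = seq_along(x$energies), energy = x$energies,
                 cumulative = cumsum(x$energies))
}

#' Similarity between two mode shapes
#'
#' Absolute normalized inner product: 1 for identical (up to sign) modes,
#' 0 for orthogonal modes.
#'
#' @param mode_a,mode_b numeric vectors on the same node ordering.
#' @return value in [0, 1].
#' @export
mode_similarity <- function(mode_a, mode_b) {
  na <- sqrt(sum(mode_a^2)); nb <- sqrt(sum(mode_b^2))
  if (na == 0 || nb == 0) stop("zero-norm mode")
  if (length(mode_a) != length(mode_b)) stop("mode dimensions differ")
  abs(sum(mode_a * mode_b)) / (na * nb)
}

#' Extreme displacement states of one POD mode
#'
#' The two peak-displacement states over a vibration cycle: the mean shape
#' plus/minus the mode scaled by the peak absolute temporal coefficient.
#'
#' @param mode spatial mode vector.
#' @param amplitude_series temporal coefficients of the mode.
#' @param mean mean shape vector (default zero).
#' @return list with `plus` and `minus` state vectors.
#' @export
extreme_states <- function(mode, amplitude_series, mean = 0) {
  a <- max(abs(amplitude_series))
  list(plus = mean + a * mode, minus = mean - a * mode)
}
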