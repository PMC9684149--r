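#' Instantaneous spike phases on a time grid
#'
#' Linear phase interpolation between consecutive spikes: for
#' `t_m <= t < t_{m+1}`, `phi(t) = 2 pi (t - t_m) / (t_{m+1} - t_m)`.  The
#' phase is defined only between a neuron's first and last spike in the
#' window; outside, the validity mask is `FALSE`.  Neurons with fewer than
#' two spikes are fully masked (with a warning).
#'
#' @param trains a [spike_trains()] object.
#' @param grid evaluation times (defaults to the observation window at
#'   1e-3 spacing, i.e. every 10th integration sample of the default
#'   protocol).
#' @return An object of class `"phase_series"`: list with `t`, `phi`
#'   (time-by-neuron matrix, `NA` where undefined), and `valid` (logical
#'   matrix).
#' @export
phases_from_spikes <- function(trains, grid = NULL) {
  if (is.null(grid))
    grid <- seq(trains$window[1], trains$window[2], by = 1e-3)
  if (any(grid < trains$window[1] - 1e-12) ||
      any(grid > trains$window[2] + 1e-12))
    stop("grid must lie inside the observation window")
  n <- trains$n
  phi <- matrix(NA_real_, length(grid), n)
  few <- 0L
  for (i in seq_len(n)) {
    sp <- trains$spikes[[i]]
    if (length(sp) < 2) { few <- few + 1L; next }
    j <- findInterval(grid, sp)
    ok <- j >= 1 & j < length(sp)
    phi[ok, i] <- 2 * pi * (grid[ok] - sp[j[ok]]) / (sp[j[ok] + 1] - sp[j[ok]])
  }
  if (few > 0)
    warning(few, " neuron(s) with < 2 spikes are fully phase-masked")
  structure(list(t = grid, phi = phi, valid = !is.na(phi)),
            class = "phase_series")
}

#' Pairwise-cosine order parameter S
#'
#' The global order parameter
#' `S = 2 / (N (N - 1)) * sum_{i<j} cos^2((phi_i - phi_j) / 2)`,
#' computed directly over all unordered pairs of valid phases.  `S = 1`
#' for an in-phase population; for large uniformly random populations `S`
#' approaches 1/2 (the exact finite-N minimum is
#' `1/2 - 1/(2 (N - 1))`).  `NA` entries are excluded pairwise; fewer than
#' two valid phases yield `NA`.
#'
#' @param phi numeric vector of phases (radians), possibly with `NA`.
#' @return Instantaneous `S` in `[1/2 - 1/(2(N-1)), 1]`.
#' @export
order_S <- function(phi) {
  phi <- phi[!is.na(phi)]
  n <- length(phi)
  if (n < 2) return(NA_real_)
  d <- outer(phi, phi, "-")
  sum(cos(d[upper.tri(d)] / 2)^2) * 2 / (n * (n - 1))
}

#' Kuramoto order parameter R
#'
#' Modulus of the population-mean unit phasor,
#' `R e^{i theta} = mean(e^{i phi_j})`; the mean phase `theta` is
#' discarded.  `R = 1` for complete synchrony, near 0 for asynchrony.
#' `NA` phases are excluded; at least one valid phase is required.
#'
#' @param phi numeric vector of phases (radians), possibly with `NA`.
#' @return Instantaneous `R` in \[0, 1\].
#' @export
order_R <- function(phi) {
  phi <- phi[!is.na(phi)]
  if (length(phi) < 1) return(NA_real_)
  sqrt(sum(cos(phi))^2 + sum(sin(phi))^2) / length(phi)
}

# Vectorized per-time-point order parameters over a phase matrix.  S(t) is
# obtained from R(t) through the exact pair-sum identity
# S = 1/2 + (m R^2 - 1) / (2 (m - 1)) over the m valid phases — the same
# double-angle reduction of the cos^2 pair sum that the test suite verifies
# against the direct pairwise order_S().
.order_series <- function(phi_mat) {
  valid <- !is.na(phi_mat)
  m <- rowSums(valid)
  C <- rowSums(cos(phi_mat), na.rm = TRUE)
  S2 <- rowSums(sin(phi_mat), na.rm = TRUE)
  R <- ifelse(m >= 1, sqrt(C^2 + S2^2) / pmax(m, 1), NA_real_)
  S <- ifelse(m >= 2, 0.5 + (m * R^2 - 1) / (2 * (m - 1)), NA_real_)
  list(S = S, R = R, n_valid = m)
}

#' Time-averaged synchronization summary
#'
#' Averages the instantaneous order parameters over the observation grid
#' and attaches the generalized susceptibilities — the relative RMS
#' temporal fluctuations `kappa_X = sqrt(<X^2> - <X>^2) / <X>` — for both
#' `S` and `R`.  Tiny negative variances from round-off are floored at
#' zero, so a constant series has exactly `kappa = 0`.
#'
#' @param S_t,R_t numeric series of instantaneous order parameters
#'   (`NA`s dropped).
#' @param n_valid optional series of contributing-neuron counts.
#' @return An object of class `"sync_summary"`: list with `S`, `R`,
#'   `kappa_S`, `kappa_R`, `n_valid` (minimum over the grid).
#' @export
summarize_sync <- function(S_t, R_t, n_valid = NULL) {
  kap <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(NA_real_)
    mu <- mean(x)
    if (mu == 0) return(NA_real_)  # flagged: relative fluctuation undefined
    sqrt(max(mean(x^2) - mu^2, 0)) / mu
  }
  if (!any(!is.na(S_t)) || !any(!is.na(R_t)))
    stop("empty order-parameter series")
  structure(list(S = mean(S_t, na.rm = TRUE), R = mean(R_t, na.rm = TRUE),
                 kappa_S = kap(S_t), kappa_R = kap(R_t),
                 n_valid = if (is.null(n_valid)) NA_integer_
                           else min(n_valid)),
            class = "sync_summary")
}

#' @export
print.sync_summary <- function(x, ...) {
  cat(sprintf("S = %.4f  R = %.4f  kappa_S = %.4f  kappa_R = %.4f  (n_valid >= %s)\n",
              x$S, x$R, x$kappa_S, x$kappa_R, x$n_valid))
  invisible(x)
}

#' Synchronization summary straight from spike trains
#'
#' The full metric pipeline: phase assignment on the evaluation grid,
#' instantaneous `S(t)` and `R(t)` over the valid neurons at each time
#' point, then time averaging and susceptibilities.
#'
#' @param trains a [spike_trains()] object.
#' @param grid evaluation grid (see [phases_from_spikes()]).
#' @return A `"sync_summary"`.
#' @export
sync_from_spikes <- function(trains, grid = NULL) {
  ph <- suppressWarnings(phases_from_spikes(trains, grid))
  os <- .order_series(ph$phi)
  summarize_sync(os$S, os$R, os$n_valid)
}

#' Local field potential configuration and synthesis
#'
#' The LFP at a virtual electrode is the distance-weighted sum of all
#' membrane potentials, `LFP(t) = sum_e V_e(t) Shape(r_e)`, with the shape
#' function equal to 1 inside the cutoff radius and decaying as
#' `(cutoff / r)^m` beyond it.  The electrode defaults to the centroid of
#' the supplied coordinates; cutoff and decay exponent default to one
#' lattice spacing and 2 (both configurable — the upstream literature
#' leaves them free).
#'
#' @param coords two-column matrix of node coordinates
#'   (see [node_coordinates()]).
#' @param electrode length-2 electrode position (default: centroid).
#' @param cutoff cutoff distance `> 0` below which the weight is 1 (also
#'   regularizes a zero-distance singularity).
#' @param m decay exponent `>= 0`; `m = 0` gives the plain sum.
#' @return `lfp_config()` returns an `"lfp_config"`; `lfp()` returns the
#'   LFP series (one value per trace row).
#' @export
lfp_config <- function(coords, electrode = NULL, cutoff = 1, m = 2) {
  stopifnot(is.matrix(coords), ncol(coords) == 2, cutoff > 0, m >= 0)
  if (is.null(electrode)) electrode <- colMeans(coords)
  r <- sqrt((coords[, 1] - electrode[1])^2 +
              (coords[, 2] - electrode[2])^2)
  w <- ifelse(r < cutoff, 1, (cutoff / r)^m)
  structure(list(coords = coords, electrode = electrode, cutoff = cutoff,
                 m = m, weights = w),
            class = "lfp_config")
}

#' @rdname lfp_config
#' @param traces time-by-neuron voltage matrix (from [run_network()] with
#'   `record_every > 0`).
#' @param cfg an `"lfp_config"`.
#' @export
lfp <- function(traces, cfg) {
  stopifnot(inherits(cfg, "lfp_config"), ncol(traces) == length(cfg$weights))
  as.vector(traces %*% cfg$weights)
}
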