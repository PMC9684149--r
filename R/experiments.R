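#' Coupling-strength sweep specification
#'
#' Describes one synchronization-transition experiment: a topology, a
#' drive mode, a grid of coupling strengths, the scan direction(s), and
#' the trial count.  The reference protocol repeats each experiment 10
#' times with fresh random initial conditions and averages; scans use a
#' grid step of 1e-4 in sleep mode and 1e-3 in wake mode.
#'
#' `topology` is either a fixed adjacency matrix or a zero-argument
#' function returning one.  A function is re-invoked for every trial under
#' a trial-specific seed, so random topologies (long-range additions,
#' Watts-Strogatz) test structural rather than instance-specific effects;
#' pass a prebuilt matrix for fixed-graph sweeps.
#'
#' @param topology adjacency matrix or generator function.
#' @param drive a [drive_mode()].
#' @param g_grid increasing numeric vector of coupling strengths.
#' @param direction `"forward"`, `"backward"`, or `"both"`.
#' @param trials trials per grid point (default 10).
#' @param base_seed integer seed from which all trial seeds derive.
#' @param cfg a [sim_config()] template (its `g` field is overridden).
#' @param params an [hb_params()] object.
#' @return A `"sweep_spec"` object.
#' @export
sweep_spec <- function(topology, drive, g_grid,
                       direction = c("forward", "backward", "both"),
                       trials = 10, base_seed = 1,
                       cfg = sim_config(), params = hb_params()) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(g_grid), length(g_grid) >= 1,
            !is.unsorted(g_grid, strictly = TRUE), all(g_grid >= 0),
            trials >= 1)
  if (!is.function(topology)) topology <- as_adjacency(unclass(topology))
  structure(list(topology = topology, drive = drive,
                 g_grid = as.numeric(g_grid), direction = direction,
                 trials = as.integer(trials),
                 base_seed = as.integer(base_seed), cfg = cfg,
                 params = params),
            class = "sweep_spec")
}

# deterministic per-(trial, grid-point, direction) seed, kept < 2^31
.trial_seed <- function(base_seed, trial, gi, dir_code) {
  (base_seed * 7919 + trial * 104729 + gi * 1299709 +
     dir_code * 15485863) %% 2147483629L
}

#' Run a coupling sweep
#'
#' Forward scans simulate each grid point independently with fresh random
#' initial membrane potentials; backward scans start each trial from a
#' fresh run at the largest coupling and then continue adiabatically
#' downward, handing the final state of each run to the next (smaller)
#' coupling.  Trials that abort (non-finite state) are recorded with `NA`
#' metrics and a warning, never dropped silently.
#'
#' @param spec a [sweep_spec()].
#' @param grid metric evaluation grid spacing, h (default 1e-3).
#' @param quiet suppress progress output.
#' @return A `"sweep_result"`: list with `rows` (one data.frame row per
#'   trial x grid point x direction: `g, direction, trial, seed, S, R,
#'   kappa_S, kappa_R, n_valid`), `summary` (per `g` x direction mean and
#'   sd of the metrics), `label` (forward-scan transition classification,
#'   see [classify_transition()]), and the spec.
#' @export
run_sweep <- function(spec, grid = 1e-3, quiet = TRUE) {
  dirs <- if (spec$direction == "both") c("forward", "backward")
          else spec$direction
  rows <- list()
  for (dir in dirs) {
    dir_code <- if (dir == "forward") 0L else 1L
    g_seq <- if (dir == "forward") spec$g_grid else rev(spec$g_grid)
    for (trial in seq_len(spec$trials)) {
      carried <- NULL  # backward-scan adiabatic state
      topo_seed <- .trial_seed(spec$base_seed, trial, 0L, dir_code)
      adj <- if (is.function(spec$topology)) {
        set.seed(topo_seed)
        spec$topology()
      } else spec$topology
      for (gi in seq_along(g_seq)) {
        g <- g_seq[gi]
        cfg <- spec$cfg
        cfg$g <- g
        seed <- .trial_seed(spec$base_seed, trial, gi, dir_code)
        set.seed(seed)
        init <- if (dir == "backward") carried else NULL
        tr <- tryCatch(
          suppressWarnings(run_network(adj, cfg, spec$params, spec$drive,
                                       init = init)),
          error = function(e) e)
        if (inherits(tr, "error")) {
          warning(sprintf("trial aborted at g = %g (%s): %s", g, dir,
                          conditionMessage(tr)))
          rows[[length(rows) + 1]] <- data.frame(
            g = g, direction = dir, trial = trial, seed = seed,
            S = NA_real_, R = NA_real_, kappa_S = NA_real_,
            kappa_R = NA_real_, n_valid = NA_integer_)
          carried <- NULL
          next
        }
        sm <- tryCatch(
          sync_from_spikes(tr, seq(tr$window[1], tr$window[2], by = grid)),
          error = function(e) NULL)
        rows[[length(rows) + 1]] <- data.frame(
          g = g, direction = dir, trial = trial, seed = seed,
          S = if (is.null(sm)) NA_real_ else sm$S,
          R = if (is.null(sm)) NA_real_ else sm$R,
          kappa_S = if (is.null(sm)) NA_real_ else sm$kappa_S,
          kappa_R = if (is.null(sm)) NA_real_ else sm$kappa_R,
          n_valid = if (is.null(sm)) NA_integer_ else sm$n_valid)
        if (dir == "backward") carried <- tr$final_state
        if (!quiet)
          message(sprintf("%s g=%g trial %d: S=%.3f", dir, g, trial,
                          rows[[length(rows)]]$S))
      }
    }
  }
  rows <- do.call(rbind, rows)
  agg <- stats::aggregate(rows[c("S", "R", "kappa_S", "kappa_R")],
                          by = rows[c("g", "direction")],
                          function(x) mean(x, na.rm = TRUE))
  sdv <- stats::aggregate(rows[c("S", "R")], by = rows[c("g", "direction")],
                          function(x) stats::sd(x, na.rm = TRUE))
  names(sdv)[3:4] <- c("S_sd", "R_sd")
  summary <- merge(agg, sdv, by = c("g", "direction"))
  summary <- summary[order(summary$direction, summary$g), ]
  rownames(summary) <- NULL
  fwd <- summary[summary$direction == "forward", ]
  label <- if (nrow(fwd) >= 5) classify_transition(fwd$S, fwd$g)
           else NA_character_
  structure(list(rows = rows, summary = summary, label = label,
                 spec = spec),
            class = "sweep_result")
}

#' Classify a synchronization transition curve
#'
#' Operational labels for the mean `S`-versus-`g` curve of a forward scan:
#' \describe{
#'   \item{explosive}{some adjacent-grid jump in mean `S` exceeds
#'     `jump_thr`;}
#'   \item{frustrated}{the curve has an interior dip deeper than `dip_thr`
#'     below an earlier local maximum (synchrony rises, collapses,
#'     recovers);}
#'   \item{frustrated+explosive}{both of the above;}
#'   \item{continuous}{neither, the curve is monotone nondecreasing within
#'     `mono_tol` and ends above `sync_level`;}
#'   \item{none}{anything else.}
#' }
#' The thresholds are artifact choices, recorded in the result so labels
#' are auditable.
#'
#' @param S mean order-parameter curve.
#' @param g matching coupling grid (only used for validation).
#' @param jump_thr explosive jump threshold.
#' @param dip_thr frustration dip depth threshold.
#' @param mono_tol monotonicity tolerance for the continuous label.
#' @param sync_level terminal synchrony level for the continuous label.
#' @return A character label with attribute `thresholds`.
#' @export
classify_transition <- function(S, g = seq_along(S), jump_thr = 0.25,
                                dip_thr = 0.1, mono_tol = 0.02,
                                sync_level = 0.9) {
  stopifnot(length(S) == length(g))
  if (length(S) < 5) stop("need at least 5 grid points to classify")
  ok <- !is.na(S)
  S <- S[ok]; g <- g[ok]
  jumps <- diff(S)
  explosive <- any(jumps > jump_thr)
  run_max <- cummax(S)
  frustrated <- any(run_max[-length(S)] - S[-1] > dip_thr)
  label <- if (explosive && frustrated) "frustrated+explosive"
    else if (explosive) "explosive"
    else if (frustrated) "frustrated"
    else if (all(jumps > -mono_tol) && S[length(S)] > sync_level)
      "continuous"
    else "none"
  structure(label, thresholds = c(jump_thr = jump_thr, dip_thr = dip_thr,
                                  mono_tol = mono_tol,
                                  sync_level = sync_level))
}

#' Hysteresis loop area
#'
#' Signed trapezoidal area between the backward and forward mean-`S`
#' curves on a common coupling grid; positive when the backward
#' (adiabatically continued) branch stays more synchronized, the
#' signature of bistability.
#'
#' @param forward,backward data.frames with columns `g` and `S` (e.g.
#'   subsets of a [run_sweep()] summary), on identical grids.
#' @return The signed area.
#' @export
hysteresis_area <- function(forward, backward) {
  if (!isTRUE(all.equal(sort(forward$g), sort(backward$g))))
    stop("forward and backward scans must share the coupling grid")
  f <- forward[order(forward$g), ]
  b <- backward[order(backward$g), ]
  d <- b$S - f$S
  sum(diff(f$g) * (d[-1] + d[-length(d)]) / 2)
}

#' Raster export
#'
#' Flattens spike trains into a plotting-ready table of (neuron, time)
#' rows, ordered by neuron then time.
#'
#' @param trains a [spike_trains()] object.
#' @return A data.frame with columns `neuron` and `time`.
#' @export
export_raster <- function(trains) {
  data.frame(neuron = rep(seq_along(trains$spikes),
                          lengths(trains$spikes)),
             time = as.numeric(unlist(trains$spikes)))
}

#' Append sweep rows to a results CSV
#'
#' Writes the per-trial rows with identifying columns in a stable column
#' order, creating the file (with header) if needed.
#'
#' @param result a `"sweep_result"`.
#' @param file CSV path.
#' @param topology_label,drive_label identifying strings.
#' @return `file`, invisibly.
#' @export
append_sweep_csv <- function(result, file, topology_label = "",
                             drive_label = result$spec$drive$mode) {
  rows <- result$rows
  out <- data.frame(topology = topology_label, drive = drive_label,
                    rows[c("g", "direction", "trial", "S", "R", "kappa_S",
                           "kappa_R", "n_valid", "seed")])
  utils::write.table(out, file, sep = ",", row.names = FALSE,
                     col.names = !file.exists(file), append = file.exists(file))
  invisible(file)
}
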