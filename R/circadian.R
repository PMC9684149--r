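#' Free dCLOCK concentration
#'
#' The transcriptionally active dCLOCK is whatever is not bound by PER:
#' `max(dclock - per, 0)`.
#'
#' @param dclock,per concentrations, nM (vectorized).
#' @return Free dCLOCK concentration, nM.
#' @examples
#' dclock_free(1.0, 0.4)  # 0.6
#' dclock_free(0.4, 1.0)  # 0, never negative
#' @export
dclock_free <- function(dclock, per) {
  pmax(dclock - per, 0)
}

#' Sleep/wake drive mode
#'
#' Selects how the external drive current of each neuron is produced.  The
#' synchronization experiments clamp the drive to a constant so the
#' population stays in one state: `"sleep"` corresponds to zero drive (the
#' sleep regime covers drives in \[0, 0.3\]) and `"wake"` to a strong drive
#' of 2.5 (the wake regime needs > 2.2).  The `"oscillator"` mode derives
#' the drive from the running dCLOCK/PER oscillator instead, letting the
#' network cycle through sleep and wake.
#'
#' @param mode `"sleep"`, `"wake"` or `"oscillator"`.
#' @param level optional numeric override of the constant drive level
#'   (ignored in oscillator mode).
#' @return An object of class `"drive_mode"`.
#' @export
drive_mode <- function(mode = c("sleep", "wake", "oscillator"),
                       level = NULL) {
  mode <- match.arg(mode)
  if (is.null(level))
    level <- switch(mode, sleep = 0, wake = 2.5, oscillator = NA_real_)
  stopifnot(is.numeric(level), length(level) == 1)
  structure(list(mode = mode, constant_level = level),
            class = "drive_mode")
}

#' Circadian oscillator state with delay history
#'
#' The oscillator state carries the two concentrations plus a record of past
#' free-dCLOCK values on the integration grid, so the delayed feedback terms
#' can be evaluated.  A fresh state uses constant history: the initial
#' free-dCLOCK value is assumed for all earlier times.
#'
#' @param dclock,per initial concentrations, nM (nonnegative).
#' @param params a [circadian_params()] object.
#' @param dt history grid spacing, h.
#' @param t0 time of the state, h.
#' @return An object of class `"circadian_state"` with fields `dclock`,
#'   `per`, `t`, `dt`, and `history` (free-dCLOCK values at times
#'   `t0 - (n-1) dt, ..., t0`).
#' @export
circadian_state <- function(dclock = 0.5, per = 0.5,
                            params = circadian_params(), dt = 1e-3,
                            t0 = 0) {
  stopifnot(dclock >= 0, per >= 0, dt > 0)
  n_hist <- ceiling(max(params$tau_1, params$tau_2) / dt) + 2L
  structure(list(dclock = dclock, per = per, t = t0, dt = dt,
                 history = rep(dclock_free(dclock, per), n_hist)),
            class = "circadian_state")
}

# delayed free-dCLOCK at time `t_query`, linearly interpolated on the
# history grid; times before the recorded history take the oldest value
# (constant-history initialization), times beyond state$t are an error.
.circ_hist_lookup <- function(state, t_query) {
  if (t_query > state$t + 1e-9)
    stop("requested delay time lies in the future of the recorded history")
  n <- length(state$history)
  x <- (t_query - state$t) / state$dt + n  # fractional index, grid end = n
  if (x <= 1) return(state$history[[1]])
  j <- floor(x)
  if (j >= n) return(state$history[[n]])
  f <- x - j
  state$history[[j]] * (1 - f) + state$history[[j + 1]] * f
}

#' Circadian derivatives with delayed feedback
#'
#' `d[dCLOCK]/dt = v_sc R_sc - k_dc [dCLOCK]` with the repression ratio
#' `R_sc = K_2 / (K_2 + [dCLOCK_free])` evaluated at `t - tau_2`, and
#' `d[PER]/dt = v_sp R_sp - k_dp [PER]` with the activation ratio
#' `R_sp = [dCLOCK_free] / (K_1 + [dCLOCK_free])` evaluated at `t - tau_1`.
#' The delayed values come from the state's history buffer; requesting a
#' delay older than the buffer signals an error.
#'
#' @param state a [circadian_state()].
#' @param params a [circadian_params()] object.
#' @param t evaluation time, h (defaults to the state's own time).
#' @return A list `d_dclock`, `d_per`, and the ratios `R_sc`, `R_sp`.
#' @export
circadian_deriv <- function(state, params = circadian_params(),
                            t = state$t) {
  need <- max(params$tau_1, params$tau_2) / state$dt + 1
  if (length(state$history) < need)
    stop("delay exceeds the recorded history buffer")
  df2 <- .circ_hist_lookup(state, t - params$tau_2)
  df1 <- .circ_hist_lookup(state, t - params$tau_1)
  R_sc <- params$K_2 / (params$K_2 + df2)
  R_sp <- df1 / (params$K_1 + df1)
  list(d_dclock = params$v_sc * R_sc - params$k_dc * state$dclock,
       d_per = params$v_sp * R_sp - params$k_dp * state$per,
       R_sc = R_sc, R_sp = R_sp)
}

#' External drive current
#'
#' In the constant modes the drive is a scalar injected current independent
#' of the membrane potential (0 in sleep, 2.5 in wake by default).  In
#' oscillator mode it is the synaptic-form difference of the dCLOCK and PER
#' currents, `(g_dclock [dCLOCK] - g_per [PER]) (E_syn - V)`.
#'
#' @param mode a [drive_mode()].
#' @param V membrane potential(s), mV.
#' @param state a [circadian_state()] (oscillator mode only).
#' @param params a [circadian_params()] object.
#' @return Drive current(s), same length as `V`.
#' @export
external_current <- function(mode, V, state = NULL,
                             params = circadian_params()) {
  if (mode$mode != "oscillator")
    return(rep(mode$constant_level, length(V)))
  stopifnot(!is.null(state))
  (params$g_dclock * state$dclock - params$g_per * state$per) *
    (params$E_syn - V)
}

#' Integrate the circadian oscillator
#'
#' Fixed-step RK4 integration of the delayed dCLOCK/PER system, with the
#' delayed terms interpolated from the accumulated free-dCLOCK history
#' (constant history before the start).  This standalone integrator serves
#' sleep-wake-cycle demonstrations and tests; inside network simulations
#' the oscillator is advanced by the compiled core with the same scheme.
#'
#' @param params a [circadian_params()] object.
#' @param t_end end time, h.
#' @param dt time step, h (the oscillator is slow; 1e-3 h is ample).
#' @param state initial [circadian_state()] (fresh constant-history state
#'   by default).
#' @param keep_every record every `keep_every`-th step.
#' @return A data.frame with columns `t`, `dclock`, `per`, `dclock_free`.
#' @export
simulate_circadian <- function(params = circadian_params(), t_end = 240,
                               dt = 1e-3, state = NULL, keep_every = 10L) {
  if (is.null(state))
    state <- circadian_state(params = params, dt = dt)
  stopifnot(abs(state$dt - dt) < 1e-12)
  n_steps <- round(t_end / dt)
  n_keep <- floor(n_steps / keep_every) + 1L
  out <- matrix(NA_real_, n_keep, 3)
  i_keep <- 1L
  dc <- state$dclock; pe <- state$per
  # grow the history in a preallocated buffer; state$history keeps the tail
  hist <- c(state$history, numeric(n_steps))
  n0 <- length(state$history)
  lookup <- function(idx_frac) {
    if (idx_frac <= 1) return(hist[[1]])
    j <- floor(idx_frac)
    f <- idx_frac - j
    hist[[j]] * (1 - f) + hist[[min(j + 1, length(hist))]] * f
  }
  rhs <- function(dc, pe, step_frac) {
    # fractional grid index of (t - tau) relative to hist, grid end = n0+step
    i2 <- n0 + step_frac - params$tau_2 / dt
    i1 <- n0 + step_frac - params$tau_1 / dt
    df2 <- lookup(i2); df1 <- lookup(i1)
    c(params$v_sc * params$K_2 / (params$K_2 + df2) - params$k_dc * dc,
      params$v_sp * df1 / (params$K_1 + df1) - params$k_dp * pe)
  }
  for (s in seq_len(n_steps)) {
    if ((s - 1L) %% keep_every == 0L) {
      out[i_keep, ] <- c((s - 1L) * dt, dc, pe); i_keep <- i_keep + 1L
    }
    k1 <- rhs(dc, pe, s - 1)
    k2 <- rhs(dc + dt / 2 * k1[1], pe + dt / 2 * k1[2], s - 0.5)
    k3 <- rhs(dc + dt / 2 * k2[1], pe + dt / 2 * k2[2], s - 0.5)
    k4 <- rhs(dc + dt * k3[1], pe + dt * k3[2], s)
    dc <- max(dc + dt / 6 * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1]), 0)
    pe <- max(pe + dt / 6 * (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2]), 0)
    hist[[n0 + s]] <- max(dc - pe, 0)
  }
  if (i_keep <= n_keep) out[i_keep, ] <- c(n_steps * dt, dc, pe)
  out <- out[seq_len(min(i_keep, n_keep)), , drop = FALSE]
  data.frame(t = out[, 1], dclock = out[, 2], per = out[, 3],
             dclock_free = pmax(out[, 2] - out[, 3], 0))
}
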