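#' Simulation configuration
#'
#' Integration protocol for network simulations: classical fixed-step RK4
#' with step `dt = 1e-4` (hour-based time unit), a 48 h transient that is
#' discarded, a 12 h observation window, spike detection at an upward
#' crossing of -20 mV, and membrane potentials initialized uniformly in
#' \[-10, 80\] mV.
#'
#' @param dt integration step.
#' @param g gap-junction coupling strength.
#' @param t_transient discarded transient length.
#' @param t_observe observation window length.
#' @param spike_threshold spike detection threshold, mV.
#' @param v_init_range range of the uniform initial membrane potentials.
#' @param record_every if > 0, keep every such-th voltage sample during the
#'   observation window (0 = record nothing).
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(dt = 1e-4, g = 0, t_transient = 48, t_observe = 12,
                       spike_threshold = -20, v_init_range = c(-10, 80),
                       record_every = 0L) {
  stopifnot(dt > 0, g >= 0, t_transient >= 0, t_observe > 0,
            length(v_init_range) == 2, v_init_range[1] <= v_init_range[2],
            record_every >= 0)
  structure(list(dt = dt, g = g, t_transient = t_transient,
                 t_observe = t_observe, spike_threshold = spike_threshold,
                 v_init_range = v_init_range,
                 record_every = as.integer(record_every)),
            class = "sim_config")
}

#' Gap-junction coupling currents
#'
#' The electrical-synapse current received by each neuron:
#' `I_gj[i] = g * sum_j a_ij (V[j] - V[i])`.  Pairwise antisymmetry makes
#' the currents sum to zero over the whole network.
#'
#' @param V vector of membrane potentials.
#' @param adj adjacency matrix (same dimension).
#' @param g coupling strength, `g >= 0`.
#' @return Vector of coupling currents.
#' @export
coupling_current <- function(V, adj, g) {
  m <- unclass(adj)
  if (length(V) != nrow(m)) stop("length(V) must match the adjacency size")
  stopifnot(g >= 0)
  g * (as.vector(m %*% V) - rowSums(m) * V)
}

#' Network state
#'
#' Snapshot of all dynamic variables at one instant.
#'
#' @param t time, h.
#' @param V membrane potentials, mV.
#' @param gating a [gating_state()] with vector fields.
#' @param circadian optional [circadian_state()].
#' @return An object of class `"network_state"`.
#' @export
network_state <- function(t, V, gating, circadian = NULL) {
  stopifnot(length(gating$a_K) == length(V))
  structure(list(t = t, V = V, gating = gating, circadian = circadian),
            class = "network_state")
}

#' Advance a network state by one RK4 step
#'
#' Pure-R reference implementation of the integrator's elementary step:
#' classical RK4 on all membrane and gating variables, with the coupling
#' and drive currents re-evaluated at every internal stage.  The compiled
#' integrator used by [run_network()] performs the identical update; this
#' function exists for clarity and as the cross-check target in the test
#' suite.  Constant-drive modes only (the delayed circadian variables need
#' the integrator's history machinery).
#'
#' @param state a [network_state()].
#' @param cfg a [sim_config()].
#' @param adj adjacency matrix.
#' @param params an [hb_params()] object.
#' @param drive a [drive_mode()] (`"sleep"` or `"wake"`).
#' @return The updated [network_state()].
#' @export
rk4_step <- function(state, cfg, adj, params = hb_params(),
                     drive = drive_mode("sleep")) {
  if (drive$mode == "oscillator")
    stop("rk4_step() supports constant-drive modes only; use run_network()")
  I_ext <- drive$constant_level
  dt <- cfg$dt
  f <- function(V, gt) {
    I_gj <- coupling_current(V, adj, cfg$g)
    hb_derivs(V, gt, I_gj, I_ext, params)
  }
  g0 <- state$gating
  k1 <- f(state$V, g0)
  adv <- function(h, k) gating_state(g0$a_K + h * k$da_K,
                                     g0$a_pNa + h * k$da_pNa,
                                     g0$a_KCa + h * k$da_KCa)
  k2 <- f(state$V + dt / 2 * k1$dV, adv(dt / 2, k1))
  k3 <- f(state$V + dt / 2 * k2$dV, adv(dt / 2, k2))
  k4 <- f(state$V + dt * k3$dV, adv(dt, k3))
  comb <- function(a, b, c, d) (a + 2 * b + 2 * c + d) * dt / 6
  network_state(
    t = state$t + dt,
    V = state$V + comb(k1$dV, k2$dV, k3$dV, k4$dV),
    gating = gating_state(
      g0$a_K + comb(k1$da_K, k2$da_K, k3$da_K, k4$da_K),
      g0$a_pNa + comb(k1$da_pNa, k2$da_pNa, k3$da_pNa, k4$da_pNa),
      g0$a_KCa + comb(k1$da_KCa, k2$da_KCa, k3$da_KCa, k4$da_KCa)))
}

#' Simulate a coupled network
#'
#' Integrates the gap-junction-coupled Huber-Braun network with the
#' compiled fixed-step RK4 core, discards the transient, and detects
#' spikes in the observation window as upward crossings of the threshold
#' (crossing times linearly interpolated between the bracketing samples to
#' reduce phase quantization).
#'
#' Membrane potentials are initialized uniformly in `cfg$v_init_range`
#' using the current R RNG state (seed with [set.seed()] for
#' reproducibility); `a_K` and `a_pNa` start at their voltage steady state
#' and `a_KCa` at 0, so that only the membrane potential is randomized.
#' The discarded transient makes the gating convention immaterial to the
#' reported statistics.  Alternatively, `init` supplies a complete
#' [network_state()] explicitly — the mechanism behind adiabatic
#' forward/backward continuation in hysteresis scans.
#'
#' @param adj adjacency matrix.
#' @param cfg a [sim_config()].
#' @param params an [hb_params()] object.
#' @param drive a [drive_mode()].
#' @param circ_params a [circadian_params()] object (oscillator mode).
#' @param init optional initial [network_state()] overriding the random
#'   initialization.
#' @return An object of class `"spike_trains"`: a list with fields
#'   `spikes` (per-neuron numeric vectors of spike times), `window`
#'   (observation bounds), `n` neurons, `final_state` (a
#'   [network_state()]), and, when `cfg$record_every > 0`, `trace_t` and
#'   `traces` (time-by-neuron voltage matrix).  A warning is issued when
#'   any neuron spikes fewer than twice in the window (its phase is then
#'   undefined).
#' @export
run_network <- function(adj, cfg = sim_config(), params = hb_params(),
                        drive = drive_mode("sleep"),
                        circ_params = circadian_params(), init = NULL) {
  csr <- .adj_csr(adj)
  n <- nrow(adj)
  if (is.null(init)) {
    V0 <- stats::runif(n, cfg$v_init_range[1], cfg$v_init_range[2])
    gt <- gating_steady_state(V0, params)
    dclock0 <- 0.5; per0 <- 0.5
  } else {
    stopifnot(length(init$V) == n)
    V0 <- init$V; gt <- init$gating
    dclock0 <- if (!is.null(init$circadian)) init$circadian$dclock else 0.5
    per0 <- if (!is.null(init$circadian)) init$circadian$per else 0.5
  }
  mode_code <- if (drive$mode == "oscillator") 1L else 0L
  res <- .hb_simulate_cpp(csr$indptr, csr$indices, .hb_param_vec(params),
                          cfg$g, cfg$dt, cfg$t_transient, cfg$t_observe,
                          V0, gt$a_K, gt$a_pNa, gt$a_KCa,
                          cfg$spike_threshold, mode_code,
                          if (mode_code == 0L) drive$constant_level else 0,
                          .circ_param_vec(circ_params), dclock0, per0,
                          cfg$record_every)
  n_spk <- lengths(res$spikes)
  if (any(n_spk < 2))
    warning(sum(n_spk < 2), " neuron(s) spiked fewer than twice in the ",
            "observation window; their phase is undefined")
  final_circ <- NULL
  if (mode_code == 1L) {
    final_circ <- circadian_state(res$final_dclock, res$final_per,
                                  circ_params, dt = cfg$dt,
                                  t0 = res$window[2])
  }
  out <- list(spikes = res$spikes, window = res$window, n = n,
              final_state = network_state(
                t = res$window[2], V = res$final_V,
                gating = gating_state(res$final_a_K, res$final_a_pNa,
                                      res$final_a_KCa),
                circadian = final_circ))
  if (cfg$record_every > 0) {
    out$trace_t <- res$trace_t
    out$traces <- res$traces
  }
  structure(out, class = "spike_trains")
}

#' Spike-train container and serialization
#'
#' `spike_trains()` builds the container from a list of per-neuron spike
#' times (each strictly increasing, inside the window).
#' `write_spike_trains()` stores them as plain text: a header line
#' `# window <t0> <t1>` followed by `neuron time` pairs;
#' `read_spike_trains()` round-trips the format.
#'
#' @param spikes list of numeric vectors of spike times.
#' @param window length-2 observation window.
#' @param file path.
#' @return A `"spike_trains"` object.
#' @export
spike_trains <- function(spikes, window) {
  stopifnot(is.list(spikes), length(window) == 2, window[1] < window[2])
  for (sp in spikes) {
    if (length(sp) && (any(diff(sp) <= 0) || any(sp < window[1]) ||
                       any(sp > window[2])))
      stop("spike times must be strictly increasing inside the window")
  }
  structure(list(spikes = spikes, window = as.numeric(window),
                 n = length(spikes)),
            class = "spike_trains")
}

#' @rdname spike_trains
#' @export
write_spike_trains <- function(x, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# window %.17g %.17g", x$window[1], x$window[2]), con)
  idx <- rep(seq_along(x$spikes), lengths(x$spikes))
  if (length(idx))
    utils::write.table(
      data.frame(neuron = idx,
                 time = sprintf("%.17g", unlist(x$spikes))),
      con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname spike_trains
#' @param n number of neurons (inferred from the data when omitted).
#' @export
read_spike_trains <- function(file, n = NULL) {
  header <- readLines(file, n = 1)
  window <- as.numeric(strsplit(trimws(sub("# window", "", header)),
                                "\\s+")[[1]])
  tab <- tryCatch(utils::read.table(file, skip = 1),
                  error = function(e) data.frame(V1 = integer(),
                                                 V2 = numeric()))
  if (is.null(n)) n <- if (nrow(tab)) max(tab[[1]]) else 0L
  spikes <- split(tab[[2]], factor(tab[[1]], levels = seq_len(n)))
  spikes <- lapply(spikes, function(v) as.numeric(v))
  names(spikes) <- NULL
  spike_trains(spikes, window)
}

#' @export
print.spike_trains <- function(x, ...) {
  cat(sprintf(
    "spike_trains: %d neurons, window [%.4g, %.4g] h, %d spikes total\n",
    x$n, x$window[1], x$window[2], sum(lengths(x$spikes))))
  invisible(x)
}
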