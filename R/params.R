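#' Huber-Braun neuron parameters
#'
#' Constructs the full biophysical parameter set of the Huber-Braun
#' thermoreceptor neuron used throughout the package, shared by every neuron
#' in a network.  All quantities live in the model's internal number system:
#' voltages in mV, conductances in mS/cm^2, time in the model's hour-based
#' unit (the unit in which the gating time constants are tabulated).
#'
#' The default capacitance deserves a note.  The published parameter table
#' lists the gating time constants of the original millisecond-based
#' Huber-Braun model rescaled into the hour-based unit (2 ms -> 0.000875,
#' 10 ms -> 0.00425, 20 ms -> 0.00875, i.e. a factor of 4.375e-4 per ms).
#' The membrane capacitance must be expressed in the same unit system for
#' the membrane and gating timescales to keep their original ratio; the
#' original C = 1 uF/cm^2 therefore becomes 4.375e-4, the default here.
#' Larger values (e.g. 1) make the membrane orders of magnitude slower than
#' the gating variables and the model stops spiking altogether; see the
#' package vignette for the full reasoning.
#'
#' The slow depolarizing and slow repolarizing currents have no tabulated
#' reversal potentials; following the original model's convention the
#' persistent-Na current reverses at `V_Na` and the Ca-gated K current at
#' `V_K`.  Both are overridable.
#'
#' Temperature scaling factors `rho` and `phi` are fixed at 1 (reference
#' temperature); they are retained as parameters so the scaling structure of
#' the original model stays visible.
#'
#' @param C membrane capacitance (see Details; default 4.375e-4).
#' @param g_l,g_Na,g_K,g_pNa,g_KCa conductances, mS/cm^2.
#' @param V_l,V_Na,V_K reversal potentials, mV.
#' @param V_pNa,V_KCa reversal potentials of the slow currents, mV
#'   (defaults `V_Na` and `V_K`).
#' @param V_0Na,V_0K,V_0pNa half-activation potentials, mV.
#' @param s_Na,s_K,s_pNa activation slopes, 1/mV.
#' @param tau_K,tau_pNa,tau_KCa gating time constants (hour-based unit).
#' @param eta coupling constant of the slow-current feedback, cm^2/uA.
#' @param xi relaxation factor of the Ca-gated K activation (dimensionless).
#' @param alpha,beta scaling factors of the spike-generating and
#'   subthreshold current pairs.
#' @param rho,phi temperature scaling factors (fixed at 1 by default).
#'
#' @return An object of class `"hb_params"`: a named list of the above.
#' @examples
#' p <- hb_params()
#' p$g_K
#' @seealso [circadian_params()], [write_params()], [read_params()]
#' @export
hb_params <- function(C = 4.375e-4,
                      g_l = 0.4, g_Na = 1.3, g_K = 1.75,
                      g_pNa = 0.22, g_KCa = 0.35,
                      V_l = -60, V_Na = 50, V_K = -90,
                      V_pNa = V_Na, V_KCa = V_K,
                      V_0Na = -25, V_0K = -25, V_0pNa = -40,
                      s_Na = 0.25, s_K = 0.25, s_pNa = 0.09,
                      tau_K = 0.000875, tau_pNa = 0.00425, tau_KCa = 0.00875,
                      eta = 0.012, xi = 0.17,
                      alpha = 4, beta = 4,
                      rho = 1, phi = 1) {
  p <- list(C = C, g_l = g_l, g_Na = g_Na, g_K = g_K, g_pNa = g_pNa,
            g_KCa = g_KCa, V_l = V_l, V_Na = V_Na, V_K = V_K,
            V_pNa = V_pNa, V_KCa = V_KCa, V_0Na = V_0Na, V_0K = V_0K,
            V_0pNa = V_0pNa, s_Na = s_Na, s_K = s_K, s_pNa = s_pNa,
            tau_K = tau_K, tau_pNa = tau_pNa, tau_KCa = tau_KCa,
            eta = eta, xi = xi, alpha = alpha, beta = beta,
            rho = rho, phi = phi)
  validate_hb_params(p)
  structure(p, class = "hb_params")
}

validate_hb_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  stopifnot(vapply(p, num1, logical(1)))
  cond <- c("g_l", "g_Na", "g_K", "g_pNa", "g_KCa")
  if (any(unlist(p[cond]) < 0)) stop("conductances must be >= 0")
  taus <- c("tau_K", "tau_pNa", "tau_KCa")
  if (any(unlist(p[taus]) <= 0)) stop("time constants must be > 0")
  if (p$C <= 0) stop("capacitance must be > 0")
  invisible(p)
}

#' Drosophila circadian oscillator parameters
#'
#' Parameters of the simplified dCLOCK/PER delay model that generates the
#' sleep-wake drive current.  Concentrations in nM, rates per hour, delays
#' in hours (these are genuine circadian hours, the slow subsystem).
#'
#' @param v_sc,v_sp synthesis rates of dCLOCK and PER, nM/h.
#' @param k_dc,k_dp degradation rates, 1/h.
#' @param K_1,K_2 Michaelis constants of the PER and dCLOCK feedback, nM.
#' @param tau_1,tau_2 transcription-to-protein delays, h.
#' @param g_dclock,g_per synaptic conductances of the derived drive current.
#' @param E_syn synaptic reversal potential, mV.
#' @return An object of class `"circadian_params"`.
#' @export
circadian_params <- function(v_sc = 0.25, v_sp = 0.5,
                             k_dc = 0.5, k_dp = 0.5,
                             K_1 = 0.3, K_2 = 0.1,
                             tau_1 = 10, tau_2 = 10,
                             g_dclock = 0.05, g_per = 0.05,
                             E_syn = 50) {
  p <- list(v_sc = v_sc, v_sp = v_sp, k_dc = k_dc, k_dp = k_dp,
            K_1 = K_1, K_2 = K_2, tau_1 = tau_1, tau_2 = tau_2,
            g_dclock = g_dclock, g_per = g_per, E_syn = E_syn)
  stopifnot(vapply(p, function(x) is.numeric(x) && length(x) == 1,
                   logical(1)),
            p$K_1 > 0, p$K_2 > 0, p$tau_1 >= 0, p$tau_2 >= 0)
  structure(p, class = "circadian_params")
}

# fixed field order shared with the C++ core
.hb_param_fields <- c("C", "g_l", "g_Na", "g_K", "g_pNa", "g_KCa",
                      "V_l", "V_Na", "V_K", "V_pNa", "V_KCa",
                      "V_0Na", "V_0K", "V_0pNa", "s_Na", "s_K", "s_pNa",
                      "tau_K", "tau_pNa", "tau_KCa",
                      "eta", "xi", "alpha", "beta", "rho", "phi")

.circ_param_fields <- c("v_sc", "v_sp", "k_dc", "k_dp", "K_1", "K_2",
                        "tau_1", "tau_2", "g_dclock", "g_per", "E_syn")

.hb_param_vec <- function(p) unlist(p[.hb_param_fields], use.names = FALSE)
.circ_param_vec <- function(p) unlist(p[.circ_param_fields],
                                      use.names = FALSE)

#' Read and write parameter sets as flat YAML
#'
#' Parameter sets are serialized as a flat key-value YAML mapping.  Missing
#' keys fall back to the defaults, so a file containing only overrides is
#' valid.
#'
#' @param p an [hb_params()] or [circadian_params()] object.
#' @param file path of the YAML file.
#' @return `read_params()` returns an `"hb_params"` object,
#'   `read_circadian_params()` a `"circadian_params"` object;
#'   `write_params()` returns `file` invisibly.
#' @export
write_params <- function(p, file) {
  yaml::write_yaml(unclass(p), file)
  invisible(file)
}

#' @rdname write_params
#' @export
read_params <- function(file) {
  vals <- yaml::read_yaml(file)
  known <- intersect(names(vals), .hb_param_fields)
  do.call(hb_params, vals[known])
}

#' @rdname write_params
#' @export
read_circadian_params <- function(file) {
  vals <- yaml::read_yaml(file)
  known <- intersect(names(vals), .circ_param_fields)
  do.call(circadian_params, vals[known])
}
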