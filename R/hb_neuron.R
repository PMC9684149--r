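#' Steady-state activation sigmoid
#'
#' The Boltzmann activation curve `1 / (1 + exp(-s (V - V0)))` used by every
#' gating variable of the Huber-Braun neuron.  The fast Na activation is
#' purely algebraic (always at this steady state); the slow gates relax
#' toward it.
#'
#' @param V membrane potential, mV (vectorized).
#' @param s activation slope, 1/mV.
#' @param V0 half-activation potential, mV.
#' @return Activation value(s) in (0, 1), strictly increasing in `V`.
#' @examples
#' steady_activation(-25, 0.25, -25)  # 0.5 at the half-activation point
#' @export
steady_activation <- function(V, s, V0) {
  1 / (1 + exp(-s * (V - V0)))
}

#' Gating state of a Huber-Braun neuron
#'
#' Bundles the three dynamic activation variables.  `a_K` and `a_pNa` are
#' sigmoid-driven and stay in \[0, 1\]; `a_KCa` is driven by the slow
#' depolarizing current and is only required to be nonnegative at rest.
#'
#' @param a_K activation of the fast repolarizing K current.
#' @param a_pNa activation of the slow depolarizing (persistent Na) current.
#' @param a_KCa activation of the slow repolarizing (Ca-gated K) current.
#' @return An object of class `"gating_state"` (a named list; each field may
#'   be a vector for a population).
#' @export
gating_state <- function(a_K, a_pNa, a_KCa) {
  stopifnot(is.numeric(a_K), is.numeric(a_pNa), is.numeric(a_KCa),
            length(a_K) == length(a_pNa), length(a_K) == length(a_KCa))
  structure(list(a_K = a_K, a_pNa = a_pNa, a_KCa = a_KCa),
            class = "gating_state")
}

#' Gating variables at their voltage steady state
#'
#' `a_K` and `a_pNa` at the sigmoid steady state for potential `V`, with
#' `a_KCa = 0` (its rest value in the absence of slow depolarizing
#' current).  This is the default initialization of [run_network()].
#'
#' @param V membrane potential(s), mV.
#' @param params an [hb_params()] object.
#' @return A [gating_state()].
#' @export
gating_steady_state <- function(V, params = hb_params()) {
  gating_state(a_K = steady_activation(V, params$s_K, params$V_0K),
               a_pNa = steady_activation(V, params$s_pNa, params$V_0pNa),
               a_KCa = rep(0, length(V)))
}

#' Ionic currents of the Huber-Braun neuron
#'
#' The five membrane currents at potential `V` and gating state `g`:
#' leak `I_l = g_l (V - V_l)` and the four gated currents
#' `I_j = rho g_j a_j (V - V_j)`.  The fast Na current uses the
#' instantaneous activation [steady_activation()]; the others use the
#' supplied gating state.  Currents are positive outward, so each current
#' vanishes at its reversal potential.
#'
#' @param V membrane potential(s), mV.
#' @param gating a [gating_state()].
#' @param params an [hb_params()] object.
#' @return A named list of currents `I_l`, `I_Na`, `I_K`, `I_pNa`, `I_KCa`
#'   (uA/cm^2-scale numbers), each the length of `V`.
#' @export
ionic_currents <- function(V, gating, params = hb_params()) {
  p <- params
  a_Na <- steady_activation(V, p$s_Na, p$V_0Na)
  list(I_l = p$g_l * (V - p$V_l),
       I_Na = p$rho * p$g_Na * a_Na * (V - p$V_Na),
       I_K = p$rho * p$g_K * gating$a_K * (V - p$V_K),
       I_pNa = p$rho * p$g_pNa * gating$a_pNa * (V - p$V_pNa),
       I_KCa = p$rho * p$g_KCa * gating$a_KCa * (V - p$V_KCa))
}

#' Time derivatives of the gating variables
#'
#' `a_K` and `a_pNa` relax toward their voltage sigmoids with time
#' constants `tau_K` and `tau_pNa`; `a_KCa` is charged by the slow
#' depolarizing current and decays with relaxation factor `xi`:
#' `da_KCa/dt = (-eta I_pNa - xi a_KCa) / tau_KCa`.  All three derivatives
#' carry the temperature factor `phi` (1 at reference temperature).
#'
#' @param V membrane potential(s), mV.
#' @param gating a [gating_state()].
#' @param I_pNa the slow depolarizing current (from [ionic_currents()]).
#' @param params an [hb_params()] object.
#' @return A named list `da_K`, `da_pNa`, `da_KCa`.
#' @export
gating_derivs <- function(V, gating, I_pNa, params = hb_params()) {
  p <- params
  list(da_K = p$phi * (steady_activation(V, p$s_K, p$V_0K) - gating$a_K) /
         p$tau_K,
       da_pNa = p$phi *
         (steady_activation(V, p$s_pNa, p$V_0pNa) - gating$a_pNa) /
         p$tau_pNa,
       da_KCa = p$phi * (-p$eta * I_pNa - p$xi * gating$a_KCa) / p$tau_KCa)
}

#' Membrane potential derivative
#'
#' The membrane equation of the Huber-Braun neuron:
#' `C dV/dt = -I_l - alpha (I_Na + I_K) - beta (I_pNa + I_KCa)
#'  + I_gj + I_ext`,
#' where `alpha` scales the spike-generating current pair and `beta` the
#' subthreshold pair, `I_gj` is the summed gap-junction current and `I_ext`
#' the external drive.
#'
#' @param V membrane potential(s), mV.
#' @param gating a [gating_state()].
#' @param I_gj gap-junction input current(s) (default 0).
#' @param I_ext external drive current(s) (default 0).
#' @param params an [hb_params()] object.
#' @return `dV/dt` in mV per time unit.
#' @export
membrane_deriv <- function(V, gating, I_gj = 0, I_ext = 0,
                           params = hb_params()) {
  p <- params
  I <- ionic_currents(V, gating, p)
  (-I$I_l - p$alpha * (I$I_Na + I$I_K) - p$beta * (I$I_pNa + I$I_KCa) +
     I_gj + I_ext) / p$C
}

#' Full single-population right-hand side
#'
#' Convenience wrapper returning all four state derivatives at once; the
#' reference R implementation against which the compiled network integrator
#' is cross-checked.
#'
#' @inheritParams membrane_deriv
#' @return A list `dV`, `da_K`, `da_pNa`, `da_KCa`.
#' @keywords internal
hb_derivs <- function(V, gating, I_gj = 0, I_ext = 0, params = hb_params()) {
  I <- ionic_currents(V, gating, params)
  gd <- gating_derivs(V, gating, I$I_pNa, params)
  list(dV = membrane_deriv(V, gating, I_gj, I_ext, params),
       da_K = gd$da_K, da_pNa = gd$da_pNa, da_KCa = gd$da_KCa)
}
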