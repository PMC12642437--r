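# Activity-based (non-spiking) neuron kinetics.
#
# Each population is described by its membrane potential V (mV); the
# rhythmogenic populations (RG, PF, MN) additionally carry the slow
# inactivation h of a persistent sodium current.  Units: mV, ms, nS, pF
# (so currents are in pA).

#' Piecewise-linear population output function
#'
#' Translates a membrane potential into the integrated population activity
#' in \[0, 1\]: zero at or below `Vth`, one at or above `Vmax`, linear in
#' between.  Thresholds are closed (f(Vth) = 0, f(Vmax) = 1 exactly).
#'
#' @param V membrane potential (mV); vectorized
#' @param Vth,Vmax lower and upper threshold potentials (mV), `Vth < Vmax`
#' @return activity in \[0, 1\]
#' @export
#' @examples
#' output_f(c(-60, -25, 10), Vth = -50, Vmax = 0)
output_f <- function(V, Vth = -50, Vmax = 0) {
  stopifnot(Vth < Vmax)
  pmin(1, pmax(0, (V - Vth) / (Vmax - Vth)))
}

#' Persistent-sodium channel activation
#'
#' Instantaneous sigmoid activation of the persistent sodium channel,
#' midpoint -40 mV, slope 6 mV.
#'
#' @param V membrane potential (mV); vectorized
#' @return activation in (0, 1), strictly increasing in V
#' @export
m_NaP <- function(V) 1 / (1 + exp(-(V + 40) / 6))

#' Steady-state slow inactivation of the persistent sodium channel
#'
#' Sigmoid with midpoint -45 mV and slope -4 mV (decreasing in V).
#'
#' @param V membrane potential (mV); vectorized
#' @return steady inactivation in (0, 1)
#' @export
h_inf <- function(V) 1 / (1 + exp((V + 45) / 4))

#' Time constant of the slow inactivation
#'
#' `320 + 320 / cosh((V + 35) / 15)` ms: peaks at 640 ms at -35 mV and
#' tends to 320 ms far from it.  This slow variable sets the burst and
#' interburst durations of the rhythm generator.
#'
#' @param V membrane potential (mV); vectorized
#' @return time constant (ms) in (320, 640]
#' @export
tau_h <- function(V) 320 + 320 / cosh((V + 35) / 15)

#' Synaptic currents of every population
#'
#' Conductance-based excitatory and inhibitory synaptic currents.  The
#' excitatory drive collects weighted presynaptic activity, the supraspinal
#' tonic drive `gamma * d`, and the afferent feedback `s`; the inhibitory
#' drive collects weighted presynaptic activity only.  Weights are stored
#' non-negative; the sign of their effect lives in the current expression.
#'
#' @param V membrane potentials, one per registered population
#' @param conn connectivity from [build_connectivity()]: matrices `A`
#'   (excitatory) and `B` (inhibitory), rows = targets, cols = sources,
#'   and vector `gamma`
#' @param net network constants (list with `gSynE`, `gSynI`, `ESynE`,
#'   `ESynI` per population, `Vth`, `Vmax`)
#' @param drive scalar supraspinal drive d
#' @param s afferent feedback per population (non-negative), default 0
#' @return list with components `ISynE` and `ISynI` (pA, per population)
#' @export
synaptic_currents <- function(V, conn, net, drive, s = 0) {
  if (any(s < 0)) stop("afferent feedback s must be non-negative")
  f <- output_f(V, net$Vth, net$Vmax)
  excit <- drop(conn$A %*% f) + conn$gamma * drive + s
  inhib <- drop(conn$B %*% f)
  list(ISynE = net$gSynE * (V - net$ESynE) * excit,
       ISynI = net$gSynI * (V - net$ESynI) * inhib)
}

#' Membrane and slow-variable derivatives of the whole network
#'
#' For RG/PF/MN populations: `C dV/dt = -INaP - ILeak - ISynE - ISynI`
#' with `INaP = gNaP * m_NaP(V) * h * (V - ENa)` and
#' `dh/dt = (h_inf(V) - h) / tau_h(V)`.  IN/CIN populations have no
#' persistent sodium current.
#'
#' @param V membrane potentials per population
#' @param h slow inactivation, one entry per h-carrying population
#'   (ordering of [h_index()])
#' @param params network parameter bundle (component `network` of
#'   [default_params()]): constants plus per-population `gNaP`, `gLeak`,
#'   `ELeak`, `ESynI`
#' @param conn connectivity from [build_connectivity()]
#' @param drive scalar supraspinal drive
#' @param s afferent feedback per population, default all zero
#' @return list with `dV` (mV/ms per population) and `dh` (1/ms per h slot)
#' @export
membrane_derivative <- function(V, h, params, conn, drive, s = 0) {
  np <- length(params$ELeak)
  if (length(V) != np) stop("V has length ", length(V), ", expected ", np)
  hi <- params$h_index
  if (length(h) != length(hi)) stop("h has wrong length")
  hfull <- numeric(np)
  hfull[hi] <- h
  syn <- synaptic_currents(V, conn, params, drive, s)
  INaP <- params$gNaP * m_NaP(V) * hfull * (V - params$ENa)  # gNaP = 0 off h pops
  ILeak <- params$gLeak * (V - params$ELeak)
  dV <- (-INaP - ILeak - syn$ISynE - syn$ISynI) / params$C
  dh <- (h_inf(V[hi]) - h) / tau_h(V[hi])
  list(dV = dV, dh = dh)
}
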