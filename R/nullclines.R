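# Frozen-variable nullcline analysis of the rhythm-generator dynamics.
#
# For one h-carrying population (typically left RG-F or right RG-E) the
# (V, h) plane is analyzed with every other state variable frozen at its
# recorded value: the h-nullcline is the static sigmoid h_inf(V); the
# V-nullcline solves C dV/dt = 0 for h and moves over time with afferent
# feedback and presynaptic activity.  Intersections are classified by the
# eigenvalues of the frozen 2-variable Jacobian; trajectory samples are
# annotated as fast (far from the V-nullcline, large |dV/dt|) or slow.

# frozen context: everything membrane_derivative needs for one population
frozen_context <- function(pop_id, V_all, s_all, p, reg = population_registry()) {
  np <- network_params(p, reg)
  conn <- connectivity_from_params(p, reg)
  i <- match(pop_id, reg$id)
  if (is.na(i)) stop("unknown population ", pop_id)
  if (!reg$has_h[i]) stop(pop_id, " carries no h variable")
  f_all <- output_f(V_all, np$Vth, np$Vmax)
  excit <- sum(conn$A[i, ] * f_all) + conn$gamma[i] * p$drive$d + s_all[i]
  inhib <- sum(conn$B[i, ] * f_all)
  list(i = i, np = np, excit = excit, inhib = inhib)
}

# dV/dt of the frozen 2-variable system (pA / pF = mV/ms)
frozen_dV <- function(V, h, ctx) {
  np <- ctx$np; i <- ctx$i
  INaP <- np$gNaP[i] * m_NaP(V) * h * (V - np$ENa)
  ILeak <- np$gLeak[i] * (V - np$ELeak[i])
  ISynE <- np$gSynE * (V - np$ESynE) * ctx$excit
  ISynI <- np$gSynI * (V - np$ESynI[i]) * ctx$inhib
  (-INaP - ILeak - ISynE - ISynI) / np$C
}

#' V-nullcline of a population with the rest of the system frozen
#'
#' Solves `dV/dt = 0` for `h` on a grid of `V`:
#' `h(V) = (-ILeak - ISynE - ISynI) / (gNaP * m_NaP(V) * (V - ENa))`.
#' The curve moves over time because the synaptic input (including
#' afferent feedback `s`) moves with the recorded simulation.
#'
#' @param pop_id population id, e.g. `"left:RG-F"`
#' @param V_all all membrane potentials at the analysis time (registry
#'   order)
#' @param s_all afferent feedback per population at the analysis time
#' @param p parameter bundle
#' @param V_grid potentials (mV) at which to sample; must exclude `ENa`
#' @return data.frame with `V` and `h` (h unbounded: values outside
#'   \[0, 1\] are returned, the caller decides the window)
#' @export
v_nullcline <- function(pop_id, V_all, s_all, p,
                        V_grid = seq(-70, -10, by = 0.25)) {
  ctx <- frozen_context(pop_id, V_all, s_all, p)
  np <- ctx$np; i <- ctx$i
  if (any(abs(V_grid - np$ENa) < 1e-9))
    stop("V grid contains ENa where the nullcline is singular")
  num <- -(np$gLeak[i] * (V_grid - np$ELeak[i]) +
           np$gSynE * (V_grid - np$ESynE) * ctx$excit +
           np$gSynI * (V_grid - np$ESynI[i]) * ctx$inhib)
  den <- np$gNaP[i] * m_NaP(V_grid) * (V_grid - np$ENa)
  data.frame(V = V_grid, h = num / den)
}

#' h-nullcline (static)
#'
#' Exactly the steady-state inactivation curve `h_inf(V)`; it does not
#' depend on the frozen context and does not change over time.
#'
#' @param V_grid potentials (mV)
#' @return data.frame with `V` and `h`
#' @export
h_nullcline <- function(V_grid = seq(-70, -10, by = 0.25))
  data.frame(V = V_grid, h = h_inf(V_grid))

# Jacobian of the frozen (V, h) system at a point
frozen_jacobian <- function(V, h, ctx, eps = 1e-5) {
  dh_dt <- function(V, h) (h_inf(V) - h) / tau_h(V)
  J <- matrix(0, 2, 2)
  J[1, 1] <- (frozen_dV(V + eps, h, ctx) - frozen_dV(V - eps, h, ctx)) / (2 * eps)
  J[1, 2] <- (frozen_dV(V, h + eps, ctx) - frozen_dV(V, h - eps, ctx)) / (2 * eps)
  J[2, 1] <- (dh_dt(V + eps, h) - dh_dt(V - eps, h)) / (2 * eps)
  J[2, 2] <- (dh_dt(V, h + eps) - dh_dt(V, h - eps)) / (2 * eps)
  J
}

#' Find and classify nullcline intersections
#'
#' Intersections of the frozen V-nullcline with h_inf are located by sign
#' change of their difference on the grid and refined by bisection; each
#' is classified from the eigenvalues of the frozen 2-variable Jacobian
#' (both real parts negative: stable node/focus; real parts of opposite
#' sign: saddle).  Also reports whether the V-nullcline has two interior
#' extremes (the cubic shape responsible for relaxation oscillations).
#'
#' @param pop_id,V_all,s_all,p,V_grid as in [v_nullcline()]
#' @param tol bisection tolerance on V (mV)
#' @return list with data.frame `intersections` (`V`, `h`, `type`) and
#'   logical `two_extremes`
#' @export
classify_intersections <- function(pop_id, V_all, s_all, p,
                                   V_grid = seq(-70, -10, by = 0.25),
                                   tol = 1e-6) {
  ctx <- frozen_context(pop_id, V_all, s_all, p)
  nv <- v_nullcline(pop_id, V_all, s_all, p, V_grid)
  difffun <- function(V) {
    h_on_nv <- v_nullcline(pop_id, V_all, s_all, p, V)$h
    h_on_nv - h_inf(V)
  }
  dvals <- nv$h - h_inf(nv$V)
  idx <- which(diff(sign(dvals)) != 0)
  out <- list()
  for (k in idx) {
    lo <- nv$V[k]; hi <- nv$V[k + 1]
    if (!is.finite(dvals[k]) || !is.finite(dvals[k + 1])) next
    root <- tryCatch(stats::uniroot(difffun, c(lo, hi), tol = tol)$root,
                     error = function(e) NA_real_)
    if (is.na(root)) next
    hstar <- h_inf(root)
    J <- frozen_jacobian(root, hstar, ctx)
    ev <- eigen(J, only.values = TRUE)$values
    re <- Re(ev)
    type <- if (all(re < 0)) "stable node"
            else if (all(re > 0)) "unstable node"
            else if (prod(re) < 0) "saddle"
            else "indeterminate"
    if (abs(prod(re)) < 1e-12) type <- "indeterminate"  # tangential crossing
    out[[length(out) + 1]] <- data.frame(V = root, h = hstar, type = type)
  }
  inter <- if (length(out)) do.call(rbind, out) else
    data.frame(V = numeric(), h = numeric(), type = character())
  # two extremes of h(V) on the physical branch (h in [0,1])
  sel <- nv$h > -0.5 & nv$h < 1.5 & is.finite(nv$h)
  dh <- diff(nv$h[sel])
  nflips <- sum(diff(sign(dh[dh != 0])) != 0)
  list(intersections = inter, two_extremes = nflips >= 2)
}

#' Reconstruct afferent feedback from a logged trajectory sample
#'
#' @param traj trajectory from [run_simulation()]
#' @param k sample index
#' @param p parameter bundle
#' @return named feedback vector `s` over populations
#' @export
feedback_at_sample <- function(traj, k, p) {
  em <- engine_muscles(p)
  mstate <- data.frame(side = em$side, name = em$name,
                       l = traj$l[k, ], v = traj$v[k, ], F = traj$F[k, ])
  gains <- feedback_gains(p$feedback$kFv, p$feedback$kFl, p$feedback$kEf,
                          p$feedback$eta_v, p$feedback$eta_l, p$feedback$eta_f)
  feedback_signal(mstate, gains, p)
}

#' Fast/slow regime annotation of a trajectory
#'
#' A sample is `slow` when the frozen |dV/dt| of the analyzed population
#' is below `thresh` (mV/ms) -- the state is then tracking the
#' V-nullcline -- and `fast` otherwise (jumping between branches).  The
#' threshold is a reported, configurable parameter.
#'
#' @param traj trajectory from [run_simulation()]
#' @param pop_id population to analyze
#' @param p parameter bundle
#' @param thresh regime threshold (mV/ms)
#' @return data.frame with `t`, `V`, `h`, `dVdt`, `regime`
#' @export
annotate_fast_slow <- function(traj, pop_id, p, thresh = 0.05) {
  reg <- population_registry()
  i <- match(pop_id, reg$id)
  hslot <- match(i, which(reg$has_h))
  if (is.na(hslot)) stop(pop_id, " carries no h variable")
  n <- length(traj$t)
  dV <- numeric(n)
  for (k in seq_len(n)) {
    ctx <- frozen_context(pop_id, traj$V[k, ], traj$s[k, ], p, reg)
    dV[k] <- frozen_dV(traj$V[k, i], traj$h[k, hslot], ctx)
  }
  data.frame(t = traj$t, V = traj$V[, i], h = traj$h[, hslot], dVdt = dV,
             regime = ifelse(abs(dV) < thresh, "slow", "fast"))
}
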