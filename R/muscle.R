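# Hill-type muscle model: first-order activation filter, affine
# joint-angle-to-length geometry with constant moment arms, and
# force generation F = Fmax * (a * Fl(l) * Fv(v) + Fp(l)).
#
# Lengths l are fractions of the normalizing length lmax; velocities v are
# in lmax/s, positive = lengthening.  The three force curves are
# injectable (arguments of muscle_force) so alternative companion forms
# can be dropped in; the defaults are the standard Hill shapes of this
# model lineage (bell-shaped force-length, hyperbolic shortening /
# saturating lengthening force-velocity, exponential passive engagement).

#' Activation filter derivative
#'
#' First-order low-pass filter between the motor command `u = f(V_MN)` and
#' the muscle activation, with distinct activation (20 ms) and
#' deactivation (32 ms) time constants:
#' `da/dt = u/tau_act - (1/tau_act) * (tau_act/tau_dact + (1 - tau_act/tau_dact) * u) * a`.
#'
#' @param a current activation in \[0, 1\]
#' @param u motor command in \[0, 1\]
#' @param tau_act,tau_dact activation / deactivation time constants (ms)
#' @return da/dt (1/ms)
#' @export
activation_derivative <- function(a, u, tau_act = 20, tau_dact = 32) {
  if (any(u < 0 | u > 1)) stop("motor command u must lie in [0, 1]")
  r <- tau_act / tau_dact
  u / tau_act - (r + (1 - r) * u) * a / tau_act
}

#' Muscle lengths and velocities from joint angles
#'
#' Affine map anchored at the muscle-neutral posture (hip 60 deg, knee
#' 90 deg, ankle 100 deg), where uni-articular muscles sit at 0.85 lmax
#' and bi-articular at 0.75 lmax.  Each spanned joint contributes 1% of
#' lmax per 2 deg of motion (GA: 1.5 deg at the ankle, 4.5 deg at the
#' knee per 1%).  Flexor action at a joint means the muscle lengthens as
#' that joint extends (angles increase with extension); extensor action
#' the opposite.
#'
#' @param angles_deg named joint angles in degrees (`hip`, `knee`,
#'   `ankle`) for one limb
#' @param vel_deg joint angular velocities (deg/s), same names; default 0
#' @param muscles muscle table (component `muscles` of [default_params()])
#' @return data.frame with `name`, `l` (fraction of lmax) and `v` (lmax/s)
#' @export
muscle_length <- function(angles_deg, vel_deg = c(hip = 0, knee = 0, ankle = 0),
                          muscles = default_params(optimized = FALSE)$muscles) {
  neutral <- c(hip = 60, knee = 90, ankle = 100)
  l <- muscles$l_neutral
  v <- numeric(nrow(muscles))
  for (j in c("hip", "knee", "ankle")) {
    dpp <- muscles[[paste0(j, "_dpp")]]
    sgn <- muscles[[paste0(j, "_sign")]]
    coef <- ifelse(dpp > 0, sgn * 0.01 / dpp, 0)   # fraction of lmax per degree
    l <- l + coef * (angles_deg[[j]] - neutral[[j]])
    v <- v + coef * vel_deg[[j]]
  }
  data.frame(name = muscles$name, l = l, v = v, stringsAsFactors = FALSE)
}

#' Default force-length curve
#' @param l normalized length (fraction of lmax)
#' @param cv curve constants (component `curves` of [default_params()])
#' @return multiplicative factor in (0, 1]
#' @export
force_length <- function(l, cv = default_params(optimized = FALSE)$curves)
  exp(-abs((l^cv$fl_beta - 1) / cv$fl_omega)^cv$fl_rho)

#' Default force-velocity curve
#'
#' Hyperbolic Hill curve for shortening (`v < 0`, zero at `-vmax`) and a
#' saturating eccentric branch for lengthening (`v > 0`, tending to
#' `1 + fv_ecc_gain`).
#'
#' @param v normalized velocity (lmax/s, positive = lengthening)
#' @param cv curve constants
#' @return multiplicative factor >= 0
#' @export
force_velocity <- function(v, cv = default_params(optimized = FALSE)$curves) {
  out <- numeric(length(v))
  sh <- v < 0
  s <- pmin(-v[sh], cv$vmax)
  out[sh] <- (cv$vmax - s) / (cv$vmax + s / cv$fv_af)
  out[!sh] <- 1 + cv$fv_ecc_gain * v[!sh] / (v[!sh] + cv$fv_ecc_sat)
  out
}

#' Default passive force curve
#'
#' Exponential engagement above the slack length; identically zero below.
#'
#' @param l normalized length
#' @param cv curve constants
#' @return passive force as a fraction of Fmax, >= 0
#' @export
force_passive <- function(l, cv = default_params(optimized = FALSE)$curves) {
  e <- pmax(l - cv$fp_slack, 0)
  cv$fp_k * (exp(cv$fp_c * e) - 1)
}

#' Muscle force
#'
#' `F = Fmax * (a * Fl(l) * Fv(v) + Fp(l))`, guaranteed non-negative.
#'
#' @param a activation in \[0, 1\]
#' @param l normalized length
#' @param v normalized velocity (lmax/s)
#' @param Fmax maximum isometric force (N)
#' @param cv curve constants
#' @param fl,fv,fp the three curves (injectable)
#' @return force (N)
#' @export
muscle_force <- function(a, l, v, Fmax,
                         cv = default_params(optimized = FALSE)$curves,
                         fl = force_length, fv = force_velocity,
                         fp = force_passive) {
  pmax(Fmax * (a * fl(l, cv) * fv(v, cv) + fp(l, cv)), 0)
}

#' Joint torques from muscle forces (one limb)
#'
#' With constant moment arms the torque of each muscle on each spanned
#' joint is `-dl/dq * F` where `dl/dq` is the length Jacobian in meters
#' per radian: a flexor (which lengthens on extension, `dl/dq > 0`) pulls
#' its joint toward flexion.
#'
#' @param forces named muscle forces (N), names from the muscle table
#' @param muscles muscle table
#' @return named torques (N m) for `hip`, `knee`, `ankle`
#' @export
joint_torques <- function(forces, muscles = default_params(optimized = FALSE)$muscles) {
  if (any(forces < 0)) stop("muscle forces must be non-negative")
  tq <- c(hip = 0, knee = 0, ankle = 0)
  for (j in names(tq)) {
    dpp <- muscles[[paste0(j, "_dpp")]]
    sgn <- muscles[[paste0(j, "_sign")]]
    dldq <- ifelse(dpp > 0, sgn * (0.01 / dpp) * (180 / pi), 0) * muscles$lmax  # m/rad
    tq[[j]] <- -sum(dldq * forces[muscles$name])
  }
  tq
}
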