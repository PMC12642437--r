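# Engine: couples network, muscles, skeleton and afferents into one state
# vector and integrates it with fixed-step RK4.
#
# Full state vector (length 84):
#   V (30 populations) | h (22 slots) | a (14 muscles) | q (9) | qd (9)

#' Index map of the full state vector
#' @return list of integer index vectors `V`, `h`, `a`, `q`, `qd`
#' @export
state_index <- function() {
  list(V = 1:30, h = 31:52, a = 53:66, q = 67:75, qd = 76:84)
}

# muscle bookkeeping in engine order (left IP..GA then right)
engine_muscles <- function(p) {
  data.frame(side = rep(.sides, each = 7), name = rep(.muscles, 2),
             p$muscles[rep(.muscles, 2), c("Fmax", "lmax", "l_neutral")],
             row.names = NULL, stringsAsFactors = FALSE)
}

# 14 x 9 length Jacobian in fractions of lmax per radian
muscle_jacobian <- function(p) {
  D <- matrix(0, 14, 9)
  for (s in 1:2) {
    cols <- if (s == 1) 4:6 else 7:9
    for (m in seq_along(.muscles)) {
      row <- (s - 1) * 7 + m
      mu <- p$muscles[.muscles[m], ]
      for (j in 1:3) {
        dpp <- mu[[c("hip_dpp", "knee_dpp", "ankle_dpp")[j]]]
        sgn <- mu[[c("hip_sign", "knee_sign", "ankle_sign")[j]]]
        if (dpp > 0) D[row, cols[j]] <- sgn * (0.01 / dpp) * (180 / pi)
      }
    }
  }
  D
}

#' Initial full state
#'
#' V at the leak reversal potential of each population, with fixed
#' opposite offsets on the two RG-F centers (+asym on the left, -asym on
#' the right) that deterministically break the left-right symmetry so
#' the commissural pathways lock anti-phase during the settle period;
#' h at its steady state, activations at zero, skeleton at the standing
#' posture with zero velocity.
#'
#' @param p parameter bundle
#' @param asym depolarizing kick (mV) applied to left RG-F
#' @param preload initial downward offset of the whole body (m) so the
#'   feet carry weight at release rather than resting exactly at the
#'   surface
#' @return state vector of length 84
#' @export
initial_state <- function(p, asym = 6, preload = 0.0012) {
  reg <- population_registry()
  np <- network_params(p, reg)
  V <- np$ELeak
  V[pop_index(reg, "left", "RG-F")] <- V[pop_index(reg, "left", "RG-F")] + asym
  V[pop_index(reg, "right", "RG-F")] <- V[pop_index(reg, "right", "RG-F")] - asym
  h <- h_inf(V[np$h_index])
  q <- stand_posture(p)
  q[2] <- q[2] - preload
  c(V, h, rep(0, 14), q, rep(0, 9))
}

#' Pack a parameter bundle for the C++ core
#'
#' @param p parameter bundle
#' @return flat list consumed by the compiled right-hand side
#' @export
pack_params <- function(p) {
  reg <- population_registry()
  np <- network_params(p, reg)
  conn <- connectivity_from_params(p, reg)
  eidx <- which(conn$A > 0, arr.ind = TRUE)
  iidx <- which(conn$B > 0, arr.ind = TRUE)
  edgesE <- cbind(eidx[, 1] - 1, eidx[, 2] - 1, conn$A[eidx])
  edgesI <- cbind(iidx[, 1] - 1, iidx[, 2] - 1, conn$B[iidx])
  em <- engine_muscles(p)
  mn_pop <- vapply(seq_len(14), function(i)
    pop_index(reg, em$side[i], paste0("MN-", em$name[i])) - 1L, 0L)
  tgtF <- t(vapply(.sides, function(s)
    vapply(c("RG-F", "IN-F", "PF-F"), function(n) pop_index(reg, s, n) - 1L, 0L),
    integer(3)))
  tgtE <- t(vapply(.sides, function(s)
    vapply(c("RG-E", "IN-E", "PF-E"), function(n) pop_index(reg, s, n) - 1L, 0L),
    integer(3)))
  qn <- numeric(9)
  qn[4:9] <- rep(deg2rad(unname(p$skeleton$neutral_deg)), 2)
  sk <- p$skeleton; cp <- p$contact
  list(edgesE = edgesE, edgesI = edgesI,
       gamma = unname(conn$gamma), d = p$drive$d,
       gNaP = np$gNaP, gLeak = np$gLeak, ELeak = np$ELeak, ESynI = np$ESynI,
       Cmem = np$C, ENa = np$ENa, ESynE = np$ESynE,
       gSynE = np$gSynE, gSynI = np$gSynI, Vth = np$Vth, Vmax = np$Vmax,
       hpop = np$h_index - 1L,
       tau_act = 20, tau_dact = 32,
       Fmax = em$Fmax, lmax = em$lmax, l0 = em$l_neutral,
       Dfrac = muscle_jacobian(p), q_neutral = qn,
       mn_pop = as.integer(mn_pop),
       is_flex = as.integer(em$name %in% .flexors),
       fl_beta = p$curves$fl_beta, fl_omega = p$curves$fl_omega,
       fl_rho = p$curves$fl_rho, vmax = p$curves$vmax, fv_af = p$curves$fv_af,
       fv_ecc_gain = p$curves$fv_ecc_gain, fv_ecc_sat = p$curves$fv_ecc_sat,
       fp_k = p$curves$fp_k, fp_c = p$curves$fp_c, fp_slack = p$curves$fp_slack,
       kFv = p$feedback$kFv, kFl = p$feedback$kFl, kEf = p$feedback$kEf,
       etav = p$feedback$eta_v, etal = p$feedback$eta_l, etaf = p$feedback$eta_f,
       l_th = 0.9,
       tgtF = tgtF, tgtE = tgtE,
       m_tr = sk$trunk$m, L_tr = sk$trunk$L, c_tr = sk$trunk$com, I_tr = sk$trunk$I,
       m_th = sk$thigh$m, L_th = sk$thigh$L, c_th = sk$thigh$com, I_th = sk$thigh$I,
       m_cr = sk$crus$m, L_cr = sk$crus$L, c_cr = sk$crus$com, I_cr = sk$crus$I,
       m_ft = sk$foot$m, L_ft = sk$foot$L, c_ft = sk$foot$com, I_ft = sk$foot$I,
       L_fore = sk$L_fore, grav = sk$g, joint_damp = sk$joint_damping,
       lim_k = sk$joint_limits$k, lim_c = sk$joint_limits$c,
       lim_lo = rep(deg2rad(unname(sk$joint_limits$lo_deg)), 2),
       lim_hi = rep(deg2rad(unname(sk$joint_limits$hi_deg)), 2),
       k_n = cp$k_n, c_n = cp$c_n, c_t = cp$c_t, v_belt = cp$v_belt,
       pf_h = cp$platform$height, pf_kh = cp$platform$k_h, pf_ch = cp$platform$c_h,
       pf_kv = cp$platform$k_v, pf_cv = cp$platform$c_v,
       pf_ax = cp$platform$anchor_x, pf_hl = cp$platform$half_length,
       gravity_on = TRUE, contacts_on = TRUE, limits_on = TRUE)
}

#' Full coupled right-hand side (reference implementation)
#'
#' Pure-R composition of the module derivatives, in the documented
#' evaluation order: kinematics, muscle lengths/velocities, forces,
#' afferent signals, motor commands `u = f(V_MN)`, neural and activation
#' derivatives, torques, skeleton accelerations.  The compiled core is
#' cross-checked against this function in the tests.
#'
#' @param y full state vector
#' @param p parameter bundle
#' @param ground per-limb ground heights `c(left, right)` (m)
#' @param hole_left left support absent
#' @param frozen hold the skeleton (settle phase)
#' @return list with `dy` and diagnostic components (muscle state, s,
#'   contact forces, torques, accelerations)
#' @export
engine_rhs <- function(y, p, ground = c(0, 0), hole_left = FALSE,
                       frozen = FALSE) {
  ix <- state_index()
  V <- y[ix$V]; h <- y[ix$h]; a <- y[ix$a]; q <- y[ix$q]; qd <- y[ix$qd]
  reg <- population_registry()
  np <- network_params(p, reg)
  conn <- connectivity_from_params(p, reg)
  em <- engine_muscles(p)
  D <- muscle_jacobian(p)
  qn <- numeric(9); qn[4:9] <- rep(deg2rad(unname(p$skeleton$neutral_deg)), 2)
  l <- em$l_neutral + drop(D %*% (q - qn))
  v <- if (frozen) numeric(14) else drop(D %*% qd)
  u <- output_f(V[match(paste0(em$side, ":MN-", em$name), reg$id)],
                np$Vth, np$Vmax)
  F <- muscle_force(a, l, v, em$Fmax, p$curves)
  mstate <- data.frame(side = em$side, name = em$name, l = l, v = v, F = F)
  gains <- feedback_gains(p$feedback$kFv, p$feedback$kFl, p$feedback$kEf,
                          p$feedback$eta_v, p$feedback$eta_l, p$feedback$eta_f)
  s <- feedback_signal(mstate, gains, p, reg)
  if (frozen) s[] <- 0   # fictive settle: afferents disengaged
  nd <- membrane_derivative(V, h, np, conn, p$drive$d, unname(s))
  da <- activation_derivative(a, u)
  # torques: muscles + damping + soft limits
  tq <- -drop(t(D * em$lmax) %*% F)[4:9]
  tq <- tq - p$skeleton$joint_damping * qd[4:9]
  lim <- p$skeleton$joint_limits
  lo <- rep(deg2rad(unname(lim$lo_deg)), 2); hi <- rep(deg2rad(unname(lim$hi_deg)), 2)
  qj <- q[4:9]
  tq <- tq - ifelse(qj > hi, lim$k * (qj - hi) + lim$c * qd[4:9], 0)
  tq <- tq - ifelse(qj < lo, lim$k * (qj - lo) + lim$c * qd[4:9], 0)
  pts <- skeleton_points(q, qd, p)
  ext <- list()
  cforce <- list()
  for (s2 in 1:2) {
    nm <- c("toe_L", "toe_R")[s2]
    fc <- contact_force(pts[[nm]]$pos, pts[[nm]]$vel, ground[s2], p$contact,
                        hole_active = (s2 == 1 && hole_left))
    cforce[[s2]] <- fc
    ext[[length(ext) + 1]] <- list(point = nm, F = fc)
  }
  ext[[length(ext) + 1]] <- list(point = "fore_tip",
                                 F = forelimb_constraint_force(pts$fore_tip$pos,
                                                              pts$fore_tip$vel,
                                                              p$contact))
  dy <- numeric(84)
  dy[ix$V] <- nd$dV; dy[ix$h] <- nd$dh; dy[ix$a] <- da
  qdd <- numeric(9)
  if (!frozen) {
    eom <- equations_of_motion(q, qd, p, joint_torques = tq, ext_forces = ext)
    qdd <- eom$qdd
    dy[ix$q] <- qd / 1000
    dy[ix$qd] <- qdd / 1000
  }
  list(dy = dy, l = l, v = v, F = F, u = u, s = s, torque = tq, qdd = qdd,
       contact = c(cforce[[1]][2], cforce[[1]][1], cforce[[2]][2], cforce[[2]][1]),
       hip_y = pts$hip$pos[2])
}

#' Run a treadmill simulation
#'
#' Integrates the full model with fixed-step RK4 (default dt = 0.04 ms)
#' after a settle-in period during which the skeleton is held at the
#' standing posture while the CPG reaches its limit cycle.  The trial
#' stops at a fall (hip below 5 cm, or a limb airborne longer than 1.5
#' of its recent step cycle) or at the cap.
#'
#' @param p parameter bundle
#' @param scenario from [scenario_spec()]
#' @param cap trial cap (s); defaults to the scenario's cap
#' @param dt integration step (ms)
#' @param settle settle-in period (ms)
#' @param log_stride steps between logged samples
#' @param debounce contact debounce (ms) for event bookkeeping
#' @return object of class `cpg_trajectory`: decimated time series of the
#'   full state, muscle state, feedback signals, contact forces, events,
#'   fall time, walked duration `T_walked` and the activation-squared
#'   integral used by the optimization cost
#' @export
run_simulation <- function(p, scenario = scenario_spec("flat"),
                           cap = scenario$cap, dt = p$sim$dt,
                           settle = p$sim$settle,
                           log_stride = p$sim$log_stride, debounce = 15) {
  y0 <- initial_state(p)
  q0 <- y0[state_index()$q]
  # anchor the forelimb element at the initial tip position
  p$contact$platform$anchor_x <- skeleton_points(q0, p = p)$fore_tip$pos[1]
  pk <- pack_params(p)
  scen <- list(type = match(scenario$type, c("flat", "random", "hole")) - 1L,
               drawsL = scenario$draws[, 1], drawsR = scenario$draws[, 2],
               hole_on = scenario$hole_start,
               hole_off = scenario$hole_start + scenario$hole_duration,
               trigger = if (identical(scenario$hole_trigger, "timed")) 0L else 1L)
  out <- cpp_simulate(pk, y0, scen, dt, settle, as.integer(log_stride),
                      cap, p$sim$fall_hip, p$sim$airborne_factor,
                      p$sim$airborne_default, debounce)
  ix <- state_index()
  reg <- population_registry()
  traj <- list(
    t = as.numeric(out$t),
    V = structure(out$Y[, ix$V, drop = FALSE], dimnames = list(NULL, reg$id)),
    h = out$Y[, ix$h, drop = FALSE],
    a = out$Y[, ix$a, drop = FALSE],
    q = out$Y[, ix$q, drop = FALSE],
    qd = out$Y[, ix$qd, drop = FALSE],
    l = out$L, v = out$Vmus, F = out$Fmus,
    s = structure(out$S, dimnames = list(NULL, reg$id)),
    contact = structure(out$contact,
                        dimnames = list(NULL, c("Fn_L", "Ft_L", "Fn_R", "Ft_R"))),
    ground = out$ground,
    events = data.frame(t = out$events[, 1],
                        limb = .sides[out$events[, 2] + 1],
                        type = c("touchdown", "liftoff")[out$events[, 3]]),
    fall_time = out$fall_time,
    hole_window = out$hole_window,
    T_walked = out$T_walked,
    status = out$status,
    act_integral = out$act_integral,
    y_end = out$y_end,
    scenario = scenario, dt = dt)
  class(traj) <- "cpg_trajectory"
  traj
}

#' @export
print.cpg_trajectory <- function(x, ...) {
  cat("cpg_trajectory:", x$scenario$type, "scenario,",
      sprintf("T = %.2f s,", x$T_walked),
      if (is.finite(x$fall_time)) sprintf("fell at %.2f s,", x$fall_time)
      else "no fall,",
      nrow(x$V), "samples,", nrow(x$events), "events\n")
  invisible(x)
}

#' Hip height trace of a trajectory
#' @param traj trajectory
#' @param p parameter bundle
#' @return numeric vector (m)
#' @export
hip_height <- function(traj, p = default_params(optimized = FALSE)) {
  traj$q[, 2] - p$skeleton$trunk$L * sin(traj$q[, 3])
}
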