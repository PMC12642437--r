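# Planar rigid-body dynamics of the trunk + 2 x (thigh, crus, foot) chain.
#
# Generalized coordinates q (SI units, radians):
#   q[1:2] shoulder (forelimb attachment) position x, y
#   q[3]   trunk pitch theta (0 = horizontal, hip behind shoulder)
#   q[4:6] left hip, knee, ankle joint angles
#   q[7:9] right hip, knee, ankle joint angles
# Joint angles follow the convention that angles increase with extension;
# with the trunk horizontal and the limb straight and perpendicular to
# the trunk, hip = 135 deg and knee = ankle = 180 deg.
#
# The equations of motion are assembled in Jacobian (virtual-work) form:
#   sum_k [ m_k J_k^T (J_k qdd + Jdot_k qd) + I_k w_k (w_k . qdd) ] = Q
# which for a chain of segments whose orientations are linear in q is an
# exact restatement of the Lagrangian equations.

.q_names <- c("x", "y", "theta", "hip_L", "knee_L", "ankle_L",
              "hip_R", "knee_R", "ankle_R")

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# angle/term table for one configuration ------------------------------------
# Each "angle" has a value and a constant gradient w.r.t. q; each chain
# point is shoulder + sum of coef * unit(angle).
skeleton_terms <- function(q, p) {
  sk <- p$skeleton
  ang <- list()
  grad <- function(ix, w) { g <- numeric(9); g[ix] <- w; g }
  ang$trunk_back <- list(val = q[3] + pi, g = grad(3, 1))    # shoulder -> hip
  ang$trunk <- list(val = q[3], g = grad(3, 1))
  ang$fore <- list(val = q[3] - pi / 2, g = grad(3, 1))      # shoulder -> forelimb tip
  off <- deg2rad(135) - pi / 2
  for (s in c("L", "R")) {
    j <- if (s == "L") 4:6 else 7:9
    th <- list(val = q[3] + off - q[j[1]], g = grad(c(3, j[1]), c(1, -1)))
    cr <- list(val = th$val - pi + q[j[2]],
               g = grad(c(3, j[1], j[2]), c(1, -1, 1)))
    ft <- list(val = cr$val + pi - q[j[3]],
               g = grad(c(3, j[1], j[2], j[3]), c(1, -1, 1, -1)))
    ang[[paste0("thigh_", s)]] <- th
    ang[[paste0("crus_", s)]] <- cr
    ang[[paste0("foot_", s)]] <- ft
  }
  ang
}

# terms: list of (coef, angle name); point = shoulder + sum coef*u(angle)
.point_terms <- function(p, point) {
  sk <- p$skeleton
  base <- list()
  limb <- function(s, upto, comfrac = NULL, seg = NULL) {
    t <- list(list(coef = sk$trunk$L, ang = "trunk_back"))
    segs <- c("thigh", "crus", "foot")
    Ls <- c(sk$thigh$L, sk$crus$L, sk$foot$L)
    n <- match(upto, segs)
    if (n > 1) for (k in seq_len(n - 1))
      t[[length(t) + 1]] <- list(coef = Ls[k], ang = paste0(segs[k], "_", s))
    cf <- if (is.null(comfrac)) Ls[n] else comfrac * Ls[n]
    t[[length(t) + 1]] <- list(coef = cf, ang = paste0(upto, "_", s))
    t
  }
  switch(point,
    shoulder = list(),
    hip = list(list(coef = sk$trunk$L, ang = "trunk_back")),
    trunk_com = list(list(coef = sk$trunk$com * sk$trunk$L, ang = "trunk_back")),
    fore_tip = list(list(coef = sk$L_fore, ang = "fore")),
    knee_L = limb("L", "thigh"), knee_R = limb("R", "thigh"),
    ankle_L = limb("L", "crus"), ankle_R = limb("R", "crus"),
    toe_L = limb("L", "foot"), toe_R = limb("R", "foot"),
    thigh_com_L = limb("L", "thigh", sk$thigh$com),
    thigh_com_R = limb("R", "thigh", sk$thigh$com),
    crus_com_L = limb("L", "crus", sk$crus$com),
    crus_com_R = limb("R", "crus", sk$crus$com),
    foot_com_L = limb("L", "foot", sk$foot$com),
    foot_com_R = limb("R", "foot", sk$foot$com),
    stop("unknown point ", point))
}

point_eval <- function(q, qd, p, point, ang = skeleton_terms(q, p)) {
  terms <- .point_terms(p, point)
  pos <- c(q[1], q[2]); J <- matrix(0, 2, 9); J[1, 1] <- 1; J[2, 2] <- 1
  bias <- c(0, 0)
  for (t in terms) {
    a <- ang[[t$ang]]
    u <- c(cos(a$val), sin(a$val)); du <- c(-sin(a$val), cos(a$val))
    pos <- pos + t$coef * u
    J <- J + t$coef * du %o% a$g
    ad <- sum(a$g * qd)
    bias <- bias - t$coef * ad^2 * u
  }
  vel <- drop(J %*% qd)
  list(pos = pos, vel = vel, J = J, bias = bias)
}

#' Forward kinematics of the skeleton
#'
#' @param q generalized coordinates (length 9, SI/radians)
#' @param qd generalized velocities (default 0)
#' @param p parameter bundle
#' @return list of named points (each with `pos`, `vel`): shoulder, hip,
#'   fore_tip, and per side knee, ankle, toe
#' @export
skeleton_points <- function(q, qd = numeric(9), p = default_params(optimized = FALSE)) {
  ang <- skeleton_terms(q, p)
  pts <- c("shoulder", "hip", "fore_tip", "knee_L", "ankle_L", "toe_L",
           "knee_R", "ankle_R", "toe_R")
  out <- lapply(pts, function(nm) {
    e <- point_eval(q, qd, p, nm, ang)
    list(pos = e$pos, vel = e$vel)
  })
  names(out) <- pts
  out
}

.bodies <- function(p) {
  sk <- p$skeleton
  list(
    list(com = "trunk_com", ang = "trunk", m = sk$trunk$m, I = sk$trunk$I),
    list(com = "thigh_com_L", ang = "thigh_L", m = sk$thigh$m, I = sk$thigh$I),
    list(com = "crus_com_L", ang = "crus_L", m = sk$crus$m, I = sk$crus$I),
    list(com = "foot_com_L", ang = "foot_L", m = sk$foot$m, I = sk$foot$I),
    list(com = "thigh_com_R", ang = "thigh_R", m = sk$thigh$m, I = sk$thigh$I),
    list(com = "crus_com_R", ang = "crus_R", m = sk$crus$m, I = sk$crus$I),
    list(com = "foot_com_R", ang = "foot_R", m = sk$foot$m, I = sk$foot$I))
}

#' Equations of motion of the 7-link chain
#'
#' @param q,qd coordinates and velocities (length 9)
#' @param p parameter bundle
#' @param joint_torques torques on the 6 joint coordinates, in q order
#'   (hip_L, knee_L, ankle_L, hip_R, knee_R, ankle_R); default 0
#' @param ext_forces list of external point forces, each
#'   `list(point = "toe_L", F = c(fx, fy))`
#' @param gravity include gravity
#' @param fixed integer indices of coordinates to freeze (their
#'   acceleration is forced to zero); used by reduced-chain oracles
#' @return list with `qdd` (length 9), mass matrix `M` and generalized
#'   force `Q`
#' @export
equations_of_motion <- function(q, qd, p = default_params(optimized = FALSE),
                                joint_torques = numeric(6),
                                ext_forces = list(), gravity = TRUE,
                                fixed = integer()) {
  ang <- skeleton_terms(q, p)
  M <- matrix(0, 9, 9); Q <- numeric(9)
  for (b in .bodies(p)) {
    e <- point_eval(q, qd, p, b$com, ang)
    g <- ang[[b$ang]]$g
    M <- M + b$m * crossprod(e$J) + b$I * (g %o% g)
    Q <- Q + b$m * drop(t(e$J) %*% e$bias) * (-1)  # move J'*m*bias to RHS
    if (gravity) Q <- Q + drop(t(e$J) %*% c(0, -b$m * p$skeleton$g))
  }
  Q[4:9] <- Q[4:9] + joint_torques
  for (f in ext_forces) {
    e <- point_eval(q, qd, p, f$point, ang)
    Q <- Q + drop(t(e$J) %*% f$F)
  }
  free <- setdiff(1:9, fixed)
  qdd <- numeric(9)
  Msub <- M[free, free, drop = FALSE]
  cn <- tryCatch(rcond(Msub), error = function(e) 0)
  if (!is.finite(cn) || cn < 1e-12) stop("singular mass matrix: check skeleton parameters")
  qdd[free] <- solve(Msub, Q[free])
  list(qdd = qdd, M = M, Q = Q)
}

#' Total mechanical energy of the chain
#'
#' @param q,qd coordinates and velocities
#' @param p parameter bundle
#' @return kinetic + gravitational potential energy (J)
#' @export
mechanical_energy <- function(q, qd, p = default_params(optimized = FALSE)) {
  ang <- skeleton_terms(q, p)
  KE <- 0; PE <- 0
  for (b in .bodies(p)) {
    e <- point_eval(q, qd, p, b$com, ang)
    w <- sum(ang[[b$ang]]$g * qd)
    KE <- KE + 0.5 * b$m * sum(e$vel^2) + 0.5 * b$I * w^2
    PE <- PE + b$m * p$skeleton$g * e$pos[2]
  }
  KE + PE
}

# contact --------------------------------------------------------------------

#' Viscoelastic foot-belt contact force
#'
#' Zero above the local ground height.  Below it, the normal force is
#' stiffness x penetration plus damping x penetration rate, clamped
#' non-negative, with the damping (and the tangential viscous coupling to
#' the belt) ramped in over the first millimetre of penetration so the
#' force is continuous in position at the surface.  Over an active hole
#' the force is zero regardless of depth.
#'
#' @param pos,vel planar position and velocity of the foot point (m, m/s)
#' @param ground_h local ground height (m)
#' @param cp contact constants (component `contact` of [default_params()])
#' @param hole_active logical: the point is over a hole
#' @return force `c(fx, fy)` (N)
#' @export
contact_force <- function(pos, vel, ground_h, cp, hole_active = FALSE) {
  pen <- ground_h - pos[2]
  if (hole_active || pen <= 0) return(c(0, 0))
  ramp <- min(1, pen / 0.001)
  fn <- max(0, cp$k_n * pen + cp$c_n * (-vel[2]) * ramp)
  ft <- -cp$c_t * (vel[1] + cp$v_belt) * ramp   # belt surface moves at -v_belt
  c(ft, fn)
}

#' Forelimb-platform constraint force
#'
#' Horizontal viscoelastic element anchoring the forelimb tip near its
#' rest position, plus one-sided vertical viscoelastic support at the
#' platform height (2 cm above the belt).  The platform is finite: the
#' vertical support fades out (1 cm ramp) beyond `half_length` from the
#' anchor, so a body that drags its forelimbs off the platform loses its
#' front support.
#'
#' @param pos,vel forelimb tip position and velocity
#' @param cp contact constants
#' @return force `c(fx, fy)` (N)
#' @export
forelimb_constraint_force <- function(pos, vel, cp) {
  pf <- cp$platform
  fx <- -pf$k_h * (pos[1] - pf$anchor_x) - pf$c_h * vel[1]
  pen <- pf$height - pos[2]
  fy <- 0
  if (pen > 0) {
    ramp <- min(1, pen / 0.001)
    edge <- min(1, max(0, (pf$half_length + 0.01 - abs(pos[1] - pf$anchor_x)) / 0.01))
    fy <- max(0, pf$k_v * pen + pf$c_v * (-vel[2]) * ramp) * edge
  }
  c(fx, fy)
}

# ground profiles ------------------------------------------------------------

#' Scenario / ground-profile specification
#'
#' `flat`: belt at height 0 for both limbs.  `random`: each limb's belt
#' height is redrawn among -2, 0 and +2 cm at each of its steps (applied
#' at lift-off so the new height is met at the next touchdown), from a
#' seeded pre-drawn sequence.  `hole`: ground support of the left limb is
#' absent during a time window, emulating a hole passing under the foot.
#'
#' @param type one of `"flat"`, `"random"`, `"hole"`
#' @param seed integer seed for the randomized profile
#' @param n_draws length of the pre-drawn height sequence per limb
#' @param heights the three belt levels (m)
#' @param hole_start earliest time (s, from release) at which the hole can
#'   open
#' @param hole_duration length of the support-loss window (s)
#' @param hole_trigger `"contact"` (default): the window opens at the first
#'   left-foot landing attempt at or after `hole_start`, i.e. the foot
#'   steps into the hole; `"timed"`: the window opens exactly at
#'   `hole_start`
#' @param cap trial cap (s)
#' @return list of class `cpg_scenario`
#' @export
scenario_spec <- function(type = c("flat", "random", "hole"), seed = 1,
                          n_draws = 500, heights = c(-0.02, 0, 0.02),
                          hole_start = 5, hole_duration = 0.65, cap = 100,
                          hole_trigger = c("contact", "timed")) {
  type <- match.arg(type)
  hole_trigger <- match.arg(hole_trigger)
  draws <- matrix(0, n_draws, 2)
  if (type == "random") {
    # draw under a local RNG state so callers' streams are untouched
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    draws <- matrix(sample(heights, 2 * n_draws, replace = TRUE), n_draws, 2)
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
  }
  structure(list(type = type, seed = seed, draws = draws,
                 hole_start = hole_start, hole_duration = hole_duration,
                 hole_trigger = hole_trigger, cap = cap),
            class = "cpg_scenario")
}

# events ---------------------------------------------------------------------

#' Touchdown / lift-off / fall detection on a logged trajectory
#'
#' Scans the logged contact-force traces: a touchdown is a sample where a
#' limb's normal force becomes positive, a lift-off where it becomes
#' zero.  The fall flag is set when the hip height drops below the
#' threshold, or when a limb stays airborne longer than
#' `airborne_factor` times its most recent step cycle (or
#' `airborne_default` seconds before a cycle exists).
#'
#' @param t time stamps (s)
#' @param contact matrix with columns `Fn_L`, `Fn_R` (normal forces, N)
#' @param hip_height hip height trace (m)
#' @param p parameter bundle (fall thresholds in `p$sim`)
#' @return list with data.frame `events` (`t`, `limb`, `type`) and
#'   `fall_time` (NA if no fall)
#' @export
detect_events <- function(t, contact, hip_height,
                          p = default_params(optimized = FALSE)) {
  ev <- list()
  fall_time <- NA_real_
  for (k in 1:2) {
    on <- contact[, k] > 0
    chg <- diff(on)
    td <- t[which(chg == 1) + 1]
    lo <- t[which(chg == -1) + 1]
    limb <- c("left", "right")[k]
    if (length(td)) ev[[length(ev) + 1]] <-
      data.frame(t = td, limb = limb, type = "touchdown")
    if (length(lo)) ev[[length(ev) + 1]] <-
      data.frame(t = lo, limb = limb, type = "liftoff")
    # airborne clause: no touchdown within airborne_factor x the limb's
    # most recent cycle (or airborne_default before a cycle exists)
    offs <- c(t[1][!on[1]], lo)   # airborne phase starts
    for (i in seq_along(offs)) {
      k <- sum(td <= offs[i])
      lim <- if (k >= 2) p$sim$airborne_factor * (td[k] - td[k - 1])
             else p$sim$airborne_default
      nxt <- td[td > offs[i]]
      gap <- if (length(nxt)) nxt[1] - offs[i] else max(t) - offs[i]
      if (isTRUE(gap > lim)) {
        fall_time <- min(fall_time, offs[i] + lim, na.rm = TRUE)
        break
      }
    }
  }
  low <- which(hip_height < p$sim$fall_hip)
  if (length(low)) fall_time <- min(fall_time, t[low[1]], na.rm = TRUE)
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(t = numeric(), limb = character(), type = character())
  events <- events[order(events$t), ]
  rownames(events) <- NULL
  list(events = events, fall_time = fall_time)
}

#' Standing posture
#'
#' Solves for the shoulder height and trunk pitch that put both toes on
#' the belt (y = 0) and the forelimb tips on the platform, at the given
#' limb joint angles.
#'
#' @param p parameter bundle
#' @param angles_deg hip/knee/ankle angles (deg) used for both limbs
#' @return coordinate vector q (length 9)
#' @export
stand_posture <- function(p = default_params(optimized = FALSE),
                          angles_deg = c(hip = 110, knee = 115, ankle = 115)) {
  jr <- deg2rad(unname(angles_deg))
  toe_y <- function(theta) {
    q <- c(0, 0, theta, jr, jr)
    q[2] <- p$contact$platform$height + p$skeleton$L_fore * cos(theta)
    skeleton_points(q, p = p)$toe_L$pos[2]
  }
  theta <- stats::uniroot(toe_y, c(-0.6, 0.6))$root
  q <- c(0, p$contact$platform$height + p$skeleton$L_fore * cos(theta), theta, jr, jr)
  q
}
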