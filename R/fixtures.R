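# Seeded test fixtures and tabular/JSON I/O shared by the CLI commands.

#' Deterministic seeded fixtures
#'
#' `random-profile`: a per-step randomized belt-height sequence over
#' {-2, 0, +2} cm (uniform over the three levels; the distribution is the
#' fixture's documented choice).  `toy-nullcline`: a cubic V-nullcline /
#' sigmoid h-nullcline pair with a known middle-branch saddle, plus a
#' monotone variant with a single stable node.  `toy-chain`: parameters
#' and initial state of a passive 2-link chain (thigh + crus) for the
#' double-pendulum oracle.
#'
#' @param kind one of `"random-profile"`, `"toy-nullcline"`, `"toy-chain"`
#' @param seed integer seed
#' @param n length of the profile sequence
#' @return fixture object (see details per kind)
#' @export
make_fixture <- function(kind = c("random-profile", "toy-nullcline", "toy-chain"),
                         seed = 1, n = 100) {
  kind <- match.arg(kind)
  switch(kind,
    "random-profile" = {
      sc <- scenario_spec("random", seed = seed, n_draws = n)
      list(heights_left = sc$draws[, 1], heights_right = sc$draws[, 2],
           levels = c(-0.02, 0, 0.02))
    },
    "toy-nullcline" = {
      # cubic with two extremes crossing the sigmoid on its middle branch
      list(cubic = function(V) 0.5 + 0.55 * (V + 45) / 10 -
             0.9 * ((V + 45) / 10)^3,
           mono = function(V) 0.5 + 0.08 * (V + 45),
           sigmoid = h_inf)
    },
    "toy-chain" = {
      p <- default_params(optimized = FALSE)
      list(m1 = p$skeleton$thigh$m, L1 = p$skeleton$thigh$L,
           c1 = p$skeleton$thigh$com, I1 = p$skeleton$thigh$I,
           m2 = p$skeleton$crus$m, L2 = p$skeleton$crus$L,
           c2 = p$skeleton$crus$com, I2 = p$skeleton$crus$I,
           g = p$skeleton$g)
    })
}

#' Write a trajectory to plain-text tables
#'
#' Emits `timeseries.csv` (decimated state and signals), `events.csv`,
#' and `meta.json` (scenario, seeds, cap, fall time, walked duration,
#' activation integral) into `dir`.
#'
#' @param traj trajectory from [run_simulation()]
#' @param dir output directory (created if absent)
#' @return `dir`, invisibly
#' @export
write_trajectory <- function(traj, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  em <- paste(rep(c("l", "r"), each = 7), rep(.muscles, 2), sep = "_")
  ts <- data.frame(t = traj$t, traj$V, h = traj$h, a = traj$a,
                   q = traj$q, qd = traj$qd, len = traj$l, vel = traj$v,
                   force = traj$F, traj$contact, ground = traj$ground,
                   check.names = TRUE)
  utils::write.csv(ts, file.path(dir, "timeseries.csv"), row.names = FALSE)
  utils::write.csv(traj$events, file.path(dir, "events.csv"), row.names = FALSE)
  meta <- list(scenario = traj$scenario[c("type", "seed", "hole_start",
                                          "hole_duration", "cap")],
               dt = traj$dt, T_walked = traj$T_walked,
               fall_time = traj$fall_time, status = traj$status,
               act_integral = traj$act_integral)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Stick-diagram coordinates of a trajectory
#'
#' Returns the planar joint chain (shoulder, hip, knee, ankle, toe per
#' side plus the forelimb tip) at a set of sample times, suitable for
#' stick-figure plotting with base graphics.
#'
#' @param traj trajectory
#' @param p parameter bundle
#' @param times times (s) at which to extract frames
#' @return list of frames; each frame is a named list of xy coordinates
#' @export
stick_frames <- function(traj, p, times) {
  lapply(times, function(tt) {
    k <- which.min(abs(traj$t - tt))
    pts <- skeleton_points(traj$q[k, ], traj$qd[k, ], p)
    lapply(pts, function(e) e$pos)
  })
}

#' Plot stick diagrams of a walking trajectory
#'
#' @param traj trajectory
#' @param p parameter bundle
#' @param times frame times (s); default 8 frames over the trajectory
#' @param ... passed to [graphics::plot()]
#' @export
plot_sticks <- function(traj, p = default_params(),
                        times = seq(min(traj$t), max(traj$t), length.out = 8),
                        ...) {
  frames <- stick_frames(traj, p, times)
  xr <- range(vapply(frames, function(f) f$shoulder[1], 0)) + c(-0.3, 0.3)
  graphics::plot(NA, xlim = xr, ylim = c(-0.05, 0.35), asp = 1,
                 xlab = "x (m)", ylab = "y (m)", ...)
  graphics::abline(h = 0, col = "grey")
  for (f in frames) {
    seg <- function(a, b, col) graphics::segments(a[1], a[2], b[1], b[2], col = col)
    seg(f$shoulder, f$hip, "black"); seg(f$shoulder, f$fore_tip, "grey40")
    seg(f$hip, f$knee_L, "red"); seg(f$knee_L, f$ankle_L, "red")
    seg(f$ankle_L, f$toe_L, "red")
    seg(f$hip, f$knee_R, "blue"); seg(f$knee_R, f$ankle_R, "blue")
    seg(f$ankle_R, f$toe_R, "blue")
  }
  invisible(frames)
}
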