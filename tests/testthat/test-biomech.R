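# Planar multibody dynamics, contact, events, ground profiles.

test_that("thigh+crus sub-chain matches the closed-form double pendulum", {
  p <- base_params()
  p$skeleton$foot$m <- 0; p$skeleton$foot$I <- 0   # massless distal segment
  sk <- p$skeleton
  m1 <- sk$thigh$m; L1 <- sk$thigh$L; a1 <- sk$thigh$com * L1; I1 <- sk$thigh$I
  m2 <- sk$crus$m; L2 <- sk$crus$L; a2 <- sk$crus$com * L2; I2 <- sk$crus$I
  g <- sk$g
  # textbook compound double pendulum in absolute segment angles
  oracle <- function(al1, al2, w1, w2) {
    A11 <- m1 * a1^2 + I1 + m2 * L1^2
    A22 <- m2 * a2^2 + I2
    A12 <- m2 * L1 * a2 * cos(al1 - al2)
    b1 <- -m2 * L1 * a2 * sin(al1 - al2) * w2^2 - g * (m1 * a1 + m2 * L1) * cos(al1)
    b2 <- m2 * L1 * a2 * sin(al1 - al2) * w1^2 - g * m2 * a2 * cos(al2)
    solve(matrix(c(A11, A12, A12, A22), 2, 2), c(b1, b2))
  }
  set.seed(9)
  for (rep in 1:5) {
    q <- stand_posture(p)
    q[4] <- runif(1, 1.2, 2.4); q[5] <- runif(1, 1.2, 2.8)
    qd <- numeric(9)
    qd[4] <- rnorm(1); qd[5] <- rnorm(1)
    eom <- equations_of_motion(q, qd, p, fixed = c(1:3, 6:9))
    off <- 135 * pi / 180 - pi / 2
    al1 <- q[3] + off - q[4]; al2 <- al1 - pi + q[5]
    w1 <- -qd[4]; w2 <- -qd[4] + qd[5]
    alp <- oracle(al1, al2, w1, w2)
    expect_equal(-eom$qdd[4], alp[1], tolerance = 1e-9)
    expect_equal(-eom$qdd[4] + eom$qdd[5], alp[2], tolerance = 1e-9)
  }
})

test_that("chain at rest in equilibrium has zero acceleration", {
  p <- base_params()
  # hang the limbs straight down (hip 135, knee/ankle 180): a potential extremum
  q <- c(0, 0.4, 0, rep(c(135, 180, 180) * pi / 180, 2))
  eom <- equations_of_motion(q, numeric(9), p, gravity = TRUE,
                             fixed = 1:3)   # trunk held
  expect_equal(eom$qdd, numeric(9), tolerance = 1e-9)
})

test_that("passive conservative runs conserve energy under RK4", {
  p <- base_params()
  p$skeleton$joint_damping <- 0
  ix <- state_index()
  y <- initial_state(p)
  set.seed(21)
  y[ix$qd] <- rnorm(9, 0, 0.3)
  pk <- pack_params(p)
  pk$contacts_on <- FALSE; pk$limits_on <- FALSE; pk$joint_damp <- 0
  pk$Fmax <- rep(0, 14)                         # no actuation
  y[ix$a] <- 0
  scen <- list(type = 0L, drawsL = 0, drawsR = 0, hole_on = 0, hole_off = 0)
  out <- cpgwalk:::cpp_simulate(pk, y, scen, 0.04, 0, 1000L, 1.0,
                                -100, 10, 1e6, 15)
  E0 <- mechanical_energy(y[ix$q], y[ix$qd], p)
  E1 <- mechanical_energy(out$y_end[ix$q], out$y_end[ix$qd], p)
  expect_lt(abs(E1 - E0) / abs(E0), 1e-6)
})

test_that("mirroring the state mirrors the accelerations exactly", {
  p <- base_params()
  p$contact$platform$anchor_x <- -0.013
  y <- random_full_state(p, seed = 31)
  pk <- pack_params(p)
  d1 <- cpgwalk:::cpp_rhs(pk, y, 0.0, 0.0, FALSE, FALSE)
  d2 <- cpgwalk:::cpp_rhs(pk, mirror_state(y), 0.0, 0.0, FALSE, FALSE)
  expect_equal(mirror_dy(d2$dy), d1$dy, tolerance = 1e-10)
})

test_that("contact force handles separation, belt matching, holes, continuity", {
  p <- base_params()
  cp <- p$contact
  # 1 mm above ground: zero
  expect_equal(contact_force(c(0, 0.001), c(0, 0), 0, cp), c(0, 0))
  # penetrating, moving exactly with the belt: zero tangential
  f <- contact_force(c(0, -0.005), c(-cp$v_belt, 0), 0, cp)
  expect_equal(f[1], 0)
  expect_gt(f[2], 0)
  # inside a hole: zero regardless of depth
  expect_equal(contact_force(c(0, -0.05), c(0, -1), 0, cp, hole_active = TRUE),
               c(0, 0))
  # continuity in position at the surface: forces vanish as pen -> 0
  for (vy in c(-0.5, 0, 0.5)) {
    f_eps <- contact_force(c(0, -1e-6), c(0.1, vy), 0, cp)
    expect_lt(max(abs(f_eps)), 0.2)
  }
  # normal force never negative (fast separation while penetrated)
  f <- contact_force(c(0, -1e-4), c(0, 5), 0, cp)
  expect_gte(f[2], 0)
})

test_that("forelimb platform element anchors the tips", {
  p <- base_params()
  cp <- p$contact
  expect_equal(forelimb_constraint_force(c(cp$platform$anchor_x, 0.05),
                                         c(0, 0), cp), c(0, 0))
  f <- forelimb_constraint_force(c(cp$platform$anchor_x + 0.01, 0.05),
                                 c(0.2, 0), cp)
  expect_equal(f[1], -cp$platform$k_h * 0.01 - cp$platform$c_h * 0.2)
  # below platform: upward support
  f2 <- forelimb_constraint_force(c(cp$platform$anchor_x, 0.01), c(0, 0), cp)
  expect_gt(f2[2], 0)
})

test_that("pitch perturbations decay back under the platform element", {
  # a fully passive body settles to an equilibrium tilt on the platform
  # element; perturbing the pitch from there decays back (damped return)
  p <- base_params()
  ix <- state_index()
  y <- initial_state(p)
  pk <- pack_params(p)
  pk$Fmax <- rep(0, 14)
  pk$pf_ax <- skeleton_points(y[ix$q], p = p)$fore_tip$pos[1]
  scen <- list(type = 0L, drawsL = 0, drawsR = 0, hole_on = 0, hole_off = 0)
  out1 <- cpgwalk:::cpp_simulate(pk, y, scen, 0.05, 0, 1000L, 4.0,
                                 -100, 100, 1e6, 15)
  th_eq <- out1$y_end[ix$q][3]
  y2 <- out1$y_end
  y2[ix$q][3] <- th_eq + 0.1              # pitch the trunk up 5.7 deg
  y2[ix$qd] <- 0
  out2 <- cpgwalk:::cpp_simulate(pk, y2, scen, 0.05, 0, 1000L, 4.0,
                                 -100, 100, 1e6, 15)
  th_end <- out2$y_end[ix$q][3]
  expect_lt(abs(th_end - th_eq), 0.03)    # returned to the equilibrium tilt
})

test_that("event detection matches a brute-force sign-change scan", {
  p <- base_params()
  t <- seq(0, 5, by = 0.01)
  fn_l <- as.numeric(sin(2 * pi * t) > 0) * 10
  fn_r <- as.numeric(sin(2 * pi * t + pi) > 0) * 8
  hip <- rep(0.2, length(t))
  got <- detect_events(t, cbind(fn_l, fn_r), hip, p)
  # oracle: raw scan
  td_l <- t[which(diff(fn_l > 0) == 1) + 1]
  lo_l <- t[which(diff(fn_l > 0) == -1) + 1]
  ev_l <- got$events[got$events$limb == "left", ]
  expect_equal(ev_l$t[ev_l$type == "touchdown"], td_l)
  expect_equal(ev_l$t[ev_l$type == "liftoff"], lo_l)
  expect_true(is.na(got$fall_time))
  # hip dip sets the fall flag at the first offending sample
  hip[301] <- 0.049
  got2 <- detect_events(t, cbind(fn_l, fn_r), hip, p)
  expect_equal(got2$fall_time, t[301])
  # permanently airborne limb trips the one-step clause
  got3 <- detect_events(t, cbind(rep(0, length(t)), fn_r), hip, p)
  expect_false(is.na(got3$fall_time))
})

test_that("standing posture puts toes on the belt and tips on the platform", {
  p <- base_params()
  q0 <- stand_posture(p)
  pts <- skeleton_points(q0, p = p)
  expect_equal(pts$toe_L$pos[2], 0, tolerance = 1e-6)
  expect_equal(pts$toe_R$pos[2], 0, tolerance = 1e-6)
  expect_equal(pts$fore_tip$pos[2], p$contact$platform$height, tolerance = 1e-9)
  expect_gt(pts$hip$pos[2], 0.15)
})

test_that("randomized profiles are seeded, per-step, three-level", {
  f1 <- make_fixture("random-profile", seed = 42, n = 200)
  f2 <- make_fixture("random-profile", seed = 42, n = 200)
  expect_identical(f1, f2)
  expect_true(all(f1$heights_left %in% c(-0.02, 0, 0.02)))
  f3 <- make_fixture("random-profile", seed = 43, n = 200)
  expect_false(identical(f1$heights_left, f3$heights_left))
  # empirical frequencies approach 1/3 (documented uniform choice)
  big <- make_fixture("random-profile", seed = 7, n = 10000)
  tab <- table(big$heights_left) / 10000
  expect_true(all(abs(tab - 1 / 3) < 0.02))
})
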