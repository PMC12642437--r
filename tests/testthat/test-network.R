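# Neuron kinetics, synaptic currents and network dynamics.

test_that("registry enumerates the bilateral architecture", {
  reg <- population_registry()
  expect_equal(nrow(reg), 30)                      # 15 populations per side
  expect_equal(sum(reg$side == "left"), 15)
  expect_setequal(unique(reg$class), c("RG", "IN", "CIN", "PF", "MN"))
  # RG/PF/MN carry h; IN/CIN do not
  expect_true(all(reg$has_h[reg$class %in% c("RG", "PF", "MN")]))
  expect_false(any(reg$has_h[reg$class %in% c("IN", "CIN")]))
  expect_equal(length(h_index(reg)), 22)
})

test_that("output function is the closed piecewise-linear map", {
  expect_equal(output_f(-50), 0)           # V = Vth
  expect_equal(output_f(0), 1)             # V = Vmax
  expect_equal(output_f(-25), 0.5)         # midpoint
  expect_equal(output_f(-80), 0)
  expect_equal(output_f(40), 1)
  # linearity inside the band
  v <- seq(-49, -1, by = 1)
  expect_equal(output_f(v), (v + 50) / 50)
  expect_error(output_f(0, Vth = 0, Vmax = 0))
})

test_that("NaP activation and slow inactivation kinetics", {
  expect_equal(m_NaP(-40), 0.5)
  expect_equal(m_NaP(-34), 1 / (1 + exp(-1)))     # direct sigmoid evaluation
  expect_lt(m_NaP(-200), 1e-10)
  expect_true(all(diff(m_NaP(seq(-90, 10, 1))) > 0))
  expect_equal(h_inf(-45), 0.5)
  expect_true(all(diff(h_inf(seq(-90, 10, 1))) < 0))
  expect_equal(tau_h(-35), 640)
  expect_lt(tau_h(-350), 320.0001)
  expect_gt(min(tau_h(seq(-200, 100, 0.5))), 320)
  expect_lte(max(tau_h(seq(-200, 100, 0.5))), 640)
})

test_that("synaptic currents match a term-by-term summation oracle", {
  p <- base_params()
  reg <- population_registry()
  np <- network_params(p, reg)
  conn <- connectivity_from_params(p, reg)
  set.seed(7)
  V <- runif(30, -70, -10)
  s <- runif(30, 0, 0.5)
  d <- 1.3
  got <- synaptic_currents(V, conn, np, d, s)
  # independent brute-force sum over every source term
  f <- pmin(1, pmax(0, (V - np$Vth) / (np$Vmax - np$Vth)))
  for (j in sample(30, 8)) {
    exc <- sum(vapply(1:30, function(k) conn$A[j, k] * f[k], 0)) +
      unname(conn$gamma[j]) * d + s[j]
    inh <- sum(vapply(1:30, function(k) conn$B[j, k] * f[k], 0))
    expect_equal(unname(got$ISynE[j]), np$gSynE * (V[j] - np$ESynE) * exc)
    expect_equal(unname(got$ISynI[j]), np$gSynI * (V[j] - np$ESynI[j]) * inh)
  }
  # empty input
  rest <- synaptic_currents(rep(-70, 30), conn, np, drive = 0, s = 0)
  expect_equal(unname(rest$ISynE), rep(0, 30))
  expect_equal(unname(rest$ISynI), rep(0, 30))
  expect_error(synaptic_currents(V, conn, np, 1, s = rep(-1, 30)),
               "non-negative")
})

test_that("membrane derivative agrees with a finite-difference assembly", {
  p <- base_params()
  reg <- population_registry()
  np <- network_params(p, reg)
  conn <- connectivity_from_params(p, reg)
  set.seed(11)
  V <- runif(30, -70, -20); h <- runif(22)
  got <- membrane_derivative(V, h, np, conn, drive = 1, s = 0)
  # independent oracle: assemble the right-hand side current-by-current
  f <- output_f(V, np$Vth, np$Vmax)
  hfull <- numeric(30); hfull[np$h_index] <- h
  for (j in seq_len(30)) {
    INaP <- np$gNaP[j] * (1 / (1 + exp(-(V[j] + 40) / 6))) * hfull[j] * (V[j] - np$ENa)
    IL <- np$gLeak[j] * (V[j] - np$ELeak[j])
    IE <- np$gSynE * (V[j] - np$ESynE) * (sum(conn$A[j, ] * f) + unname(conn$gamma[j]) * 1)
    II <- np$gSynI * (V[j] - np$ESynI[j]) * sum(conn$B[j, ] * f)
    expect_equal(unname(got$dV[j]), (-INaP - IL - IE - II) / np$C, tolerance = 1e-12)
  }
  expect_equal(unname(got$dh), (h_inf(V[np$h_index]) - h) / tau_h(V[np$h_index]))
  # fixed points
  expect_equal(unname(membrane_derivative(V, h_inf(V[np$h_index]), np, conn, 1, 0)$dh),
               rep(0, 22))
  expect_error(membrane_derivative(V[1:10], h, np, conn, 1, 0), "length")
})

test_that("h stays in [0,1] along network trajectories", {
  sim <- net_sim(base_params(), t_end = 4000)
  expect_true(all(sim$h >= 0 & sim$h <= 1))
})

test_that("uncoupled RG-E is tonic, PF/MN are silent, RG-F oscillates", {
  p <- uncoupled_params()
  sim <- net_sim(p, t_end = 8000)
  late <- sim$t >= 4000
  vE <- sim$V[late, pop_col("left:RG-E")]
  expect_lt(diff(range(vE)), 0.1)                   # sustained, non-oscillating
  expect_gt(output_f(mean(vE)), 0.1)                # active
  for (id in c("left:PF-F", "left:PF-E", "left:MN-IP", "left:MN-SO")) {
    vp <- sim$V[late, pop_col(id)]
    expect_lt(diff(range(vp)), 0.1)                 # no rhythm without RG input
  }
  vF <- sim$V[late, pop_col("left:RG-F")]
  expect_gt(diff(range(vF)), 5)                     # intrinsic V oscillation
})

test_that("single-side RG produces sustained flexor-extensor alternation", {
  p <- base_params()
  # cut commissural pathways: one side in isolation
  p$weights$a_rgf_c1 <- p$weights$b_c1_rgf <- 0
  p$weights$a_rge_v3 <- p$weights$a_v3_ine <- 0
  sim <- net_sim(p, t_end = 12000)
  late <- sim$t >= 5000
  fF <- output_f(sim$V[late, pop_col("left:RG-F")])
  fE <- output_f(sim$V[late, pop_col("left:RG-E")])
  expect_gt(diff(range(fF)), 0.3)                   # rhythmic
  expect_gt(diff(range(fE)), 0.3)
  expect_lt(mean(fF > 0.05 & fE > 0.05), 0.2)       # little burst overlap
})

test_that("bilateral network locks anti-phase left/right flexor bursting", {
  sim <- net_sim(base_params(), t_end = 12000)
  late <- sim$t >= 6000
  fL <- output_f(sim$V[late, pop_col("left:RG-F")])
  fR <- output_f(sim$V[late, pop_col("right:RG-F")])
  expect_lt(cor(fL, fR), -0.5)
  expect_lt(mean(fL > 0.05 & fR > 0.05), 0.1)
})

test_that("connectivity validation enforces the sign and target rules", {
  reg <- population_registry()
  edges <- data.frame(src = "left:RG-F", dst = "left:IN-F",
                      type = "alpha", weight = -0.1)
  expect_error(build_connectivity(edges, c(), reg), "non-negative")
  edges <- data.frame(src = "left:MN-IP", dst = "left:IN-F",
                      type = "alpha", weight = 0.1)
  expect_error(build_connectivity(edges, c(), reg), "sources")
  edges <- data.frame(src = "left:IN-F", dst = "left:C1",
                      type = "beta", weight = 0.1)
  expect_error(build_connectivity(edges, c(), reg), "CIN/MN")
  expect_error(build_connectivity(
    data.frame(src = character(), dst = character(),
               type = character(), weight = numeric()),
    c("left:PF-F" = 0.1), reg), "RG centers")
})
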