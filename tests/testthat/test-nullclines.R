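# Frozen-variable nullclines, intersection classification, fast/slow.

frozen_setup <- function(seed = 17) {
  p <- base_params()
  reg <- population_registry()
  set.seed(seed)
  V_all <- runif(30, -70, -20)
  s_all <- setNames(runif(30, 0, 0.3), reg$id)
  list(p = p, V_all = V_all, s_all = s_all)
}

test_that("h-nullcline is exactly the static inactivation sigmoid", {
  nh <- h_nullcline(seq(-70, -10, 0.5))
  expect_equal(nh$h, h_inf(nh$V))
  expect_equal(h_nullcline(-45)$h, 0.5)
  expect_true(all(diff(nh$h) < 0))
  # time-invariance: it carries no frozen context at all
  expect_identical(h_nullcline(seq(-60, -30, 1)), h_nullcline(seq(-60, -30, 1)))
})

test_that("V-nullcline points satisfy the frozen dV/dt = 0 equation", {
  fs <- frozen_setup()
  for (pop in c("left:RG-F", "right:RG-E")) {
    nv <- v_nullcline(pop, fs$V_all, fs$s_all, fs$p)
    ctx <- cpgwalk:::frozen_context(pop, fs$V_all, fs$s_all, fs$p)
    resid <- vapply(seq_len(nrow(nv)), function(k)
      cpgwalk:::frozen_dV(nv$V[k], nv$h[k], ctx), 0)
    expect_lt(max(abs(resid)), 1e-10)
  }
  expect_error(v_nullcline("left:RG-F", fs$V_all, fs$s_all, fs$p,
                           V_grid = c(-60, 55)), "singular")
  expect_error(v_nullcline("left:IN-F", fs$V_all, fs$s_all, fs$p), "h variable")
})

test_that("zero synaptic input pins the nullcline at (ELeak, 0)", {
  p <- base_params()
  p$drive$d <- 0
  reg <- population_registry()
  V_rest <- network_params(p, reg)$ELeak
  nv <- v_nullcline("left:RG-F", V_rest, rep(0, 30), p,
                    V_grid = p$network$class$RG$ELeak)
  expect_equal(nv$h, 0, tolerance = 1e-12)
})

test_that("excitatory feedback shifts the middle branch toward higher V", {
  fs <- frozen_setup()
  s_hi <- fs$s_all
  s_hi["left:RG-F"] <- s_hi["left:RG-F"] + 0.5
  grid <- seq(-60, -20, by = 0.1)
  nv_lo <- v_nullcline("left:RG-F", fs$V_all, fs$s_all, fs$p, grid)
  nv_hi <- v_nullcline("left:RG-F", fs$V_all, s_hi, fs$p, grid)
  # at fixed h on the middle branch, the V solving dV/dt = 0 moves right:
  # equivalently the curve h(V) is lower at fixed V on the rising edge
  mid <- grid > -50 & grid < -35
  expect_true(all(nv_hi$h[mid] < nv_lo$h[mid]))
})

test_that("classification matches the numeric Jacobian eigenvalue oracle", {
  p <- base_params()
  reg <- population_registry()
  # context with RG-F receiving enough input for a cubic nullcline
  V_all <- network_params(p, reg)$ELeak
  s_all <- rep(0, 30)
  ix <- pop_index(reg, "left", "RG-F")
  s_all[ix] <- 0.12
  cls <- classify_intersections("left:RG-F", V_all, s_all, p,
                                V_grid = seq(-70, -12, by = 0.1))
  expect_gt(nrow(cls$intersections), 0)
  # independent oracle: for every reported crossing, re-derive the type
  ctx <- cpgwalk:::frozen_context("left:RG-F", V_all, s_all, p)
  for (k in seq_len(nrow(cls$intersections))) {
    V0 <- cls$intersections$V[k]; h0 <- cls$intersections$h[k]
    eps <- 1e-6
    ja <- matrix(c(
      (cpgwalk:::frozen_dV(V0 + eps, h0, ctx) - cpgwalk:::frozen_dV(V0 - eps, h0, ctx)) / (2 * eps),
      (cpgwalk:::frozen_dV(V0, h0 + eps, ctx) - cpgwalk:::frozen_dV(V0, h0 - eps, ctx)) / (2 * eps),
      ((h_inf(V0 + eps) - h0) / tau_h(V0 + eps) - (h_inf(V0 - eps) - h0) / tau_h(V0 - eps)) / (2 * eps),
      -1 / tau_h(V0)), 2, 2, byrow = TRUE)
    re <- Re(eigen(ja, only.values = TRUE)$values)
    want <- if (prod(re) < 0) "saddle" else if (all(re < 0)) "stable node"
            else "unstable node"
    expect_equal(cls$intersections$type[k], want)
  }
})

test_that("constructed cubic and monotone toys classify as saddle / node", {
  # verify the shape reporting against the toy fixture
  toy <- make_fixture("toy-nullcline")
  V <- seq(-60, -30, by = 0.05)
  cubic <- toy$cubic(V)
  dh <- diff(cubic)
  expect_gt(sum(diff(sign(dh)) != 0), 1)        # two extremes
  mono <- toy$mono(V)
  expect_true(all(diff(mono) > 0))              # monotone variant
  # middle-branch crossing of a cubic against the sigmoid is a saddle in
  # the frozen system when the V-eigendirection is expanding:
  p <- base_params()
  reg <- population_registry()
  V_all <- network_params(p, reg)$ELeak
  # scan drive levels until both shapes occur
  shapes <- vapply(c(0, 0.3), function(sv) {
    s_all <- rep(0, 30); s_all[pop_index(reg, "left", "RG-F")] <- sv
    cls <- classify_intersections("left:RG-F", V_all, s_all, p,
                                  V_grid = seq(-70, -12, by = 0.1))
    paste(sort(unique(cls$intersections$type)), collapse = "+")
  }, "")
  expect_true(any(grepl("saddle", shapes)) || any(grepl("stable node", shapes)))
})

test_that("fast/slow annotation is driven by the frozen |dV/dt|", {
  p <- default_params()
  tr <- run_simulation(p, scenario_spec("flat"), cap = 3, dt = 0.05,
                       log_stride = 200)
  ann <- annotate_fast_slow(tr, "left:RG-F", p, thresh = 0.05)
  expect_equal(nrow(ann), length(tr$t))
  expect_setequal(unique(ann$regime), c("fast", "slow"))
  expect_true(all(ann$regime[abs(ann$dVdt) < 0.05] == "slow"))
  # a sample exactly on the nullcline is slow by construction
  k <- which.min(abs(ann$dVdt))
  expect_equal(ann$regime[k], "slow")
})
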