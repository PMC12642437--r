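# Afferent feedback: rectified channels, gain structure, ablation.

test_that("rectified channels follow the printed thresholds", {
  ch <- rectified_channels(l = 0.85, v = -2, F = 0, Fmax = 100)
  expect_equal(ch$vhat, 0)                       # shortening is rectified away
  expect_equal(ch$lhat, 0)                       # below the 0.9 lmax threshold
  expect_equal(rectified_channels(1.0, 0, 0, 1)$lhat, 0.1)   # l = lmax
  expect_equal(rectified_channels(0.8, 0, 50, 50)$Fhat, 1)   # F = Fmax
  expect_equal(rectified_channels(0.8, 3, 25, 50)$vhat, 3)
})

test_that("feedback matches an exhaustive per-muscle per-channel oracle", {
  p <- base_params()
  reg <- population_registry()
  g <- feedback_gains(0.3, 0.7, 0.5, 0.4, 0.6, 0.8)
  set.seed(13)
  em <- engine_muscles(p)
  mstate <- data.frame(side = em$side, name = em$name,
                       l = runif(14, 0.7, 1.2), v = runif(14, -3, 3),
                       F = runif(14, 0, 80))
  s <- feedback_signal(mstate, g, p, reg)
  flex <- c("IP", "TA", "BF")
  # brute-force triple sum, written independently
  oracle <- setNames(numeric(nrow(reg)), reg$id)
  for (i in 1:14) {
    m <- mstate$name[i]; side <- mstate$side[i]
    vh <- max(mstate$v[i], 0)
    lh <- max(mstate$l[i] - 0.9, 0)
    Fh <- max(mstate$F[i] / p$muscles[m, "Fmax"], 0)
    for (tgt in reg$id) {
      tside <- sub(":.*", "", tgt); tname <- sub(".*:", "", tgt)
      if (tside != side) next                       # strictly ipsilateral
      if (m %in% flex) {
        k <- if (tname %in% c("RG-F", "IN-F", "PF-F")) c(g$kFv, g$kFl)
             else if (tname == paste0("MN-", m)) c(g$eta_v * g$kFv, g$eta_l * g$kFl)
             else c(0, 0)
        oracle[tgt] <- oracle[tgt] + k[1] * vh^0.6 + k[2] * lh
      } else {
        k <- if (tname %in% c("RG-E", "IN-E", "PF-E")) g$kEf
             else if (tname == paste0("MN-", m)) g$eta_f * g$kEf
             else 0
        oracle[tgt] <- oracle[tgt] + k * Fh
      }
    }
  }
  expect_equal(s, oracle)
  expect_true(all(s >= 0))
})

test_that("feedback is strictly ipsilateral and silent at rest", {
  p <- base_params()
  g <- feedback_gains(0.3, 0.7, 0.5, 0.4, 0.6, 0.8)
  em <- engine_muscles(p)
  rest <- data.frame(side = em$side, name = em$name,
                     l = rep(0.8, 14), v = rep(-1, 14), F = rep(0, 14))
  expect_true(all(feedback_signal(rest, g, p) == 0))
  # perturb only right-side muscles: left targets unchanged (zero)
  active <- rest
  active$l[active$side == "right"] <- 1.1
  active$F[active$side == "right"] <- 40
  s <- feedback_signal(active, g, p)
  left <- grepl("^left", names(s))
  expect_true(all(s[left] == 0))
  expect_gt(sum(s[!left]), 0)
})

test_that("the 0.6 power applies to the velocity channel only", {
  p <- base_params()
  g <- feedback_gains(1, 1, 1, 0, 0, 0)
  em <- engine_muscles(p)
  base <- data.frame(side = em$side, name = em$name,
                     l = rep(0.8, 14), v = rep(0, 14), F = rep(0, 14))
  vdot <- base; vdot$v[1] <- 0.5                 # left IP lengthening
  s <- feedback_signal(vdot, g, p)
  expect_equal(unname(s["left:RG-F"]), 0.5^0.6)
  ldot <- base; ldot$l[1] <- 1.4                 # lhat = 0.5
  s2 <- feedback_signal(ldot, g, p)
  expect_equal(unname(s2["left:RG-F"]), 0.5)     # linear, no power
})

test_that("single flexor at unit rectified velocity gives s = kFv", {
  p <- base_params()
  g <- feedback_gains(0.37, 0, 0, 0, 0, 0)
  em <- engine_muscles(p)
  st <- data.frame(side = em$side, name = em$name,
                   l = rep(0.8, 14), v = c(1, rep(0, 13)), F = rep(0, 14))
  expect_equal(unname(feedback_signal(st, g, p)["left:RG-F"]), 0.37)
})

test_that("feedback is monotone in each rectified channel", {
  p <- base_params()
  g <- feedback_gains(0.3, 0.7, 0.5, 0.4, 0.6, 0.8)
  em <- engine_muscles(p)
  st <- data.frame(side = em$side, name = em$name,
                   l = rep(0.95, 14), v = rep(1, 14), F = rep(20, 14))
  s0 <- feedback_signal(st, g, p)
  for (col in c("l", "v", "F")) {
    st2 <- st; st2[[col]] <- st2[[col]] * 1.5
    expect_true(all(feedback_signal(st2, g, p) >= s0 - 1e-12))
  }
})

test_that("ablation zeroes a channel and is idempotent", {
  g <- feedback_gains(0.3, 0.7, 0.5, 0.4, 0.6, 0.8)
  gv <- ablate(g, "velocity")
  expect_equal(gv$kFv, 0); expect_equal(gv$eta_v, 0)
  expect_equal(gv$kFl, g$kFl)
  expect_identical(ablate(gv, "velocity"), gv)
  gf <- ablate(g, "force")
  p <- base_params()
  em <- engine_muscles(p)
  st <- data.frame(side = em$side, name = em$name,
                   l = rep(0.8, 14), v = rep(0, 14), F = rep(50, 14))
  expect_true(all(feedback_signal(st, gf, p) == 0))  # extensor input gone
  # velocity-ablated lengthening flexor keeps only the length term
  ga <- ablate(g, "velocity")
  st2 <- data.frame(side = em$side, name = em$name,
                    l = c(1.0, rep(0.8, 13)), v = c(2, rep(0, 13)),
                    F = rep(0, 14))
  expect_equal(unname(feedback_signal(st2, ga, p)["left:RG-F"]), g$kFl * 0.1)
  expect_error(ablate(g, "touch"))
})
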