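# Shared helpers for the cpgwalk test suite.

base_params <- function() default_params(optimized = FALSE)

# fast compiled network-only integration; returns t (ms), V, h matrices
net_sim <- function(p, t_end = 8000, s = rep(0, 30), dt = 0.05,
                    stride = 20L, asym = 6) {
  reg <- population_registry()
  pk <- pack_params(p)
  np <- network_params(p, reg)
  V0 <- np$ELeak
  V0[pop_index(reg, "left", "RG-F")] <- V0[pop_index(reg, "left", "RG-F")] + asym
  V0[pop_index(reg, "right", "RG-F")] <- V0[pop_index(reg, "right", "RG-F")] - asym
  cpgwalk:::cpp_network_sim(pk, V0, h_inf(V0[np$h_index]), s, dt, t_end, stride)
}

pop_col <- function(id) match(id, population_registry()$id)

# zero all coupling weights (keeps drives)
uncoupled_params <- function(p = base_params()) {
  for (w in c("a_rgf_inf", "a_rge_ine", "b_in_rg", "a_rgf_c1", "b_c1_rgf",
              "a_rge_v3", "a_v3_ine", "a_rgf_pff", "a_rge_pfe", "b_in_pf"))
    p$weights[[w]] <- 0
  p$weights$mn[] <- 0
  p
}

# a random full engine state around the standing posture
random_full_state <- function(p, seed = 1) {
  set.seed(seed)
  ix <- state_index()
  y <- initial_state(p)
  y[ix$V] <- y[ix$V] + rnorm(30, 0, 5)
  y[ix$h] <- pmin(1, pmax(0, y[ix$h] + rnorm(22, 0, 0.1)))
  y[ix$a] <- runif(14, 0, 0.8)
  y[ix$q][4:9] <- y[ix$q][4:9] + rnorm(6, 0, 0.15)
  y[ix$q][2] <- y[ix$q][2] - 0.005
  y[ix$qd] <- rnorm(9, 0, 0.5)
  y
}

# engine-order mirror map of a full state (exchange left/right)
mirror_state <- function(y) {
  ix <- state_index()
  swap <- function(v, k) c(v[(k + 1):(2 * k)], v[1:k])
  y2 <- y
  y2[ix$V] <- swap(y[ix$V], 15)
  y2[ix$h] <- swap(y[ix$h], 11)
  y2[ix$a] <- swap(y[ix$a], 7)
  q <- y[ix$q]; qd <- y[ix$qd]
  y2[ix$q] <- c(q[1:3], q[7:9], q[4:6])
  y2[ix$qd] <- c(qd[1:3], qd[7:9], qd[4:6])
  y2
}

mirror_dy <- mirror_state   # same index structure applies to derivatives
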