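# Gait optimization: cost function and CMA-ES search over the 13 free
# parameters (seven PF-to-MN weights, six afferent feedback gains) on the
# per-step randomized belt-height surface.

#' Optimization cost of a trial
#'
#' `eps = kappa * integral(sum a^2 dt) / (vbelt * T) - T` where `T` is the
#' walked duration (s, capped) and the integral runs over all 14 muscle
#' activations.  Longer, lower-effort walking is cheaper; an immediate
#' fall (`T = 0`) scores `+Inf`.  The evaluation is a pure function of the
#' stored trajectory (the activation integral is accumulated at full
#' integration resolution during the run and carried by the trajectory).
#'
#' @param traj trajectory from [run_simulation()], or any list with
#'   `act_integral` and `T_walked`
#' @param kappa effort weight (20)
#' @param vbelt belt speed in cm/s (20)
#' @return cost (dimensionless model units)
#' @export
trial_cost <- function(traj, kappa = 20, vbelt = 20) {
  T <- traj$T_walked
  if (!is.finite(T) || T <= 0) return(Inf)
  kappa * traj$act_integral / (vbelt * T) - T
}

#' Covariance matrix adaptation evolution strategy
#'
#' Standard (mu/mu_w, lambda) CMA-ES with rank-one and rank-mu covariance
#' updates and cumulative step-size adaptation, with box constraints
#' enforced by projection.  Minimizes `fn`.
#'
#' @param fn objective, called on a parameter vector
#' @param x0 initial mean
#' @param sigma0 initial step size
#' @param lower,upper box bounds (recycled)
#' @param n_gen number of generations
#' @param lambda population size (default `4 + floor(3 log n)`)
#' @param seed integer seed (controls all sampling)
#' @param trace print per-generation progress
#' @param callback optional `function(gen, xbest, fbest)` hook
#' @return list with `xbest`, `fbest`, `history` (data.frame of per-trial
#'   costs: `gen`, `trial`, `f`, `fbest`), `mean`
#' @export
cma_es <- function(fn, x0, sigma0, lower = -Inf, upper = Inf,
                   n_gen = 50, lambda = NULL, seed = 1, trace = FALSE,
                   callback = NULL) {
  set.seed(seed)
  n <- length(x0)
  if (is.null(lambda)) lambda <- 4 + floor(3 * log(n))
  lower <- rep_len(lower, n); upper <- rep_len(upper, n)
  mu <- floor(lambda / 2)
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mueff <- 1 / sum(w^2)
  cc <- (4 + mueff / n) / (n + 4 + 2 * mueff / n)
  cs <- (mueff + 2) / (n + mueff + 5)
  c1 <- 2 / ((n + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((n + 2)^2 + mueff))
  damps <- 1 + 2 * max(0, sqrt((mueff - 1) / (n + 1)) - 1) + cs
  chiN <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))

  xmean <- pmin(pmax(x0, lower), upper)
  sigma <- sigma0
  pc <- ps <- numeric(n)
  B <- diag(n); D <- rep(1, n); C <- diag(n)
  eig_age <- 0
  xbest <- xmean; fbest <- Inf
  hist <- vector("list", n_gen)

  for (g in seq_len(n_gen)) {
    Z <- matrix(rnorm(n * lambda), n, lambda)
    Yv <- B %*% (D * Z)
    X <- xmean + sigma * Yv
    Xe <- pmin(pmax(X, lower), upper)          # projection repair
    fvals <- numeric(lambda)
    for (k in seq_len(lambda)) {
      fvals[k] <- fn(Xe[, k]) +
        1e4 * sum((X[, k] - Xe[, k])^2)        # mild out-of-bounds penalty
    }
    ord <- order(fvals)
    if (fvals[ord[1]] < fbest) { fbest <- fvals[ord[1]]; xbest <- Xe[, ord[1]] }
    hist[[g]] <- data.frame(gen = g, trial = seq_len(lambda),
                            f = fvals, fbest = fbest)
    sel <- ord[seq_len(mu)]
    ymean <- drop((Yv[, sel, drop = FALSE] %*% w))
    xmean <- xmean + sigma * ymean
    # cumulative paths
    Cinvsqrt_y <- B %*% ((1 / D) * crossprod(B, ymean))
    ps <- (1 - cs) * ps + sqrt(cs * (2 - cs) * mueff) * Cinvsqrt_y
    hsig <- sqrt(sum(ps^2)) / sqrt(1 - (1 - cs)^(2 * g)) / chiN < 1.4 + 2 / (n + 1)
    pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mueff) * ymean
    # covariance update
    artmp <- Yv[, sel, drop = FALSE]
    C <- (1 - c1 - cmu) * C +
      c1 * (pc %o% pc + (1 - hsig) * cc * (2 - cc) * C) +
      cmu * artmp %*% (w * t(artmp))
    sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chiN - 1))
    eig_age <- eig_age + 1
    if (eig_age >= max(1, floor(1 / ((c1 + cmu) * n * 10)))) {
      eig_age <- 0
      C <- (C + t(C)) / 2
      e <- eigen(C, symmetric = TRUE)
      D <- sqrt(pmax(e$values, 1e-20))
      B <- e$vectors
    }
    if (trace) cat(sprintf("gen %3d  fbest %.4f  sigma %.3g\n", g, fbest, sigma))
    if (!is.null(callback)) callback(g, xbest, fbest)
  }
  list(xbest = xbest, fbest = fbest, history = do.call(rbind, hist),
       mean = xmean, sigma = sigma)
}

# which entries of the 13-vector belong to each feedback channel
.channel_slots <- function(channel) {
  switch(channel,
         velocity = c(8, 11),   # kFv, eta_v
         length = c(9, 12),     # kFl, eta_l
         force = c(10, 13),     # kEf, eta_f
         stop("unknown channel ", channel))
}

#' CMA-ES gait optimization on the randomized stepping surface
#'
#' Optimizes the 13 free parameters (or fewer when a feedback channel is
#' ablated: the ablated channel's gains are removed from the search space
#' and pinned at zero) against [trial_cost()] on per-step randomized
#' belt heights.  Each candidate is scored on one trial whose profile
#' seed is refreshed every generation.
#'
#' @param p base parameter bundle
#' @param n_gen generations
#' @param cap per-trial cap (s); scaled down from the full 100 s for
#'   desk-sized runs
#' @param dt integration step (ms) used during search
#' @param seed master seed
#' @param ablate_channel NULL or one of `"velocity"`, `"length"`, `"force"`
#' @param sigma0 initial CMA step
#' @param lambda population size
#' @param x0 starting vector (defaults to the bundle's current free
#'   parameters)
#' @param n_avg trials averaged per candidate (distinct profile seeds);
#'   1 reproduces the single-trial default, larger values reduce the
#'   noise of the profile lottery at proportional cost
#' @param trace print progress
#' @return list with `par` (full 13-vector, ablated entries zero), `p`
#'   (bundle with the vector installed), `fbest`, `history`
#' @export
optimize_gait <- function(p = default_params(), n_gen = 40, cap = 20,
                          dt = 0.1, seed = 1, ablate_channel = NULL,
                          sigma0 = 0.3, lambda = NULL, x0 = NULL,
                          n_avg = 1, trace = FALSE) {
  full0 <- if (is.null(x0)) free_param_vector(p) else x0
  stopifnot(length(full0) == 13)
  lower <- rep(0, 13)
  upper <- c(rep(8, 7), rep(4, 3), rep(2, 3))
  keep <- seq_len(13)
  if (!is.null(ablate_channel)) {
    drop_ix <- .channel_slots(ablate_channel)
    full0[drop_ix] <- 0
    keep <- setdiff(keep, drop_ix)
  }
  expand <- function(x) { v <- numeric(13); v[keep] <- x; v }
  obj <- function(x) {
    v <- expand(x)
    pc <- set_free_params(p, v)
    costs <- vapply(seq_len(n_avg), function(k) {
      sc <- scenario_spec("random",
                          seed = (.trial_seed_env$seed + 7919L * (k - 1L)) %%
                            .Machine$integer.max,
                          cap = cap)
      tr <- run_simulation(pc, sc, cap = cap, dt = dt, log_stride = 1000)
      trial_cost(tr)
    }, 0)
    mean(costs)
  }
  .trial_seed_env <- new.env()
  .trial_seed_env$seed <- seed
  cb <- function(gen, xbest, fbest) {
    .trial_seed_env$seed <- (seed + gen) %% .Machine$integer.max
  }
  res <- cma_es(obj, full0[keep], sigma0, lower[keep], upper[keep],
                n_gen = n_gen, lambda = lambda, seed = seed, trace = trace,
                callback = cb)
  par <- expand(res$xbest)
  names(par) <- names(free_param_vector(p))
  par_mean <- expand(res$mean)
  names(par_mean) <- names(par)
  list(par = par, par_mean = par_mean, p = set_free_params(p, par),
       fbest = res$fbest, history = res$history)
}

#' Re-optimize with one feedback channel ablated
#'
#' Convenience wrapper around [optimize_gait()] used by the
#' feedback-ablation experiments: the named channel's base gain and MN
#' scaling are removed from the search space and fixed at zero.
#'
#' @param channel `"velocity"`, `"length"` or `"force"`
#' @param ... passed to [optimize_gait()]
#' @return as [optimize_gait()]
#' @export
reoptimize_ablated <- function(channel, ...) {
  optimize_gait(ablate_channel = channel, ...)
}

.ablated_slots <- function(channel)
  switch(channel, velocity = c("kFv", "eta_v"), length = c("kFl", "eta_l"),
         force = c("kEf", "eta_f"), stop("unknown channel ", channel))

#' Shipped re-optimized vectors of the ablated models
#'
#' Loads the 13-parameter vector obtained by [reoptimize_ablated()] for a
#' model lacking one feedback channel (the channel's gains are
#' identically zero).  Produced by this package's own scaled-down
#' optimization runs on the randomized stepping surface and shipped as
#' synthetic reference vectors.
#'
#' @param channel `"velocity"`, `"length"` or `"force"`
#' @return named numeric vector of length 13
#' @export
ablated_param_vector <- function(channel = c("velocity", "length", "force")) {
  channel <- match.arg(channel)
  path <- system.file("extdata",
                      sprintf("ablated_vector_%s_synthetic.tsv", channel),
                      package = "cpgwalk")
  if (path == "") stop("ablated vector file not installed")
  tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  setNames(tab$value, tab$name)
}
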