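# Afferent feedback: muscle-state-derived signals injected as excitatory
# synaptic input to the ipsilateral CPG.  Velocity and length channels
# (spindle-like) come from flexor muscles only; the force channel
# (tendon-organ-like) from extensor muscles only.

#' Rectified feedback channels of one muscle
#'
#' `vhat = v / lmax` if lengthening else 0 (note `v` here is already in
#' lmax/s, so the normalization is the identity and the channel is pure
#' rectification); `lhat = (l - 0.9) ` if `l > 0.9` lmax else 0;
#' `Fhat = F / Fmax` if positive else 0.
#'
#' @param l normalized length (fraction of lmax)
#' @param v normalized velocity (lmax/s, positive = lengthening)
#' @param F force (N)
#' @param Fmax maximum force (N)
#' @param l_th length-feedback threshold as a fraction of lmax (0.9)
#' @return list with `vhat`, `lhat`, `Fhat`, all non-negative
#' @export
rectified_channels <- function(l, v, F, Fmax, l_th = 0.9) {
  list(vhat = pmax(v, 0),
       lhat = pmax(l - l_th, 0),
       Fhat = pmax(F / Fmax, 0))
}

#' Afferent feedback gain set
#'
#' @param kFv,kFl,kEf base gains of the velocity, length (flexor sources)
#'   and force (extensor sources) channels
#' @param eta_v,eta_l,eta_f motoneuron-level scaling factors
#' @return list of class `cpg_gains`
#' @export
feedback_gains <- function(kFv, kFl, kEf, eta_v, eta_l, eta_f) {
  g <- list(kFv = kFv, kFl = kFl, kEf = kEf,
            eta_v = eta_v, eta_l = eta_l, eta_f = eta_f)
  if (any(unlist(g) < 0)) stop("feedback gains must be non-negative")
  class(g) <- "cpg_gains"
  g
}

#' Feedback signals s_j for every population
#'
#' For each side, flexor muscles contribute
#' `kFv * vhat^0.6 + kFl * lhat` to RG-F, IN-F and PF-F and the
#' eta-scaled version to their homonymous motoneuron pool; extensor
#' muscles contribute `kEf * Fhat` to RG-E, IN-E and PF-E and
#' `eta_f * kEf * Fhat` to their motoneuron pool.  The 0.6 power applies
#' to the rectified normalized velocity only.  Feedback is strictly
#' ipsilateral.
#'
#' @param mstate data.frame with columns `side`, `name`, `l`, `v`, `F`
#'   (one row per muscle; 14 rows for the full model)
#' @param gains gain set from [feedback_gains()]
#' @param p parameter bundle (for Fmax)
#' @param reg population registry
#' @return named numeric vector `s` over all populations (>= 0)
#' @export
feedback_signal <- function(mstate, gains, p = default_params(optimized = FALSE),
                            reg = population_registry()) {
  s <- setNames(numeric(nrow(reg)), reg$id)
  for (i in seq_len(nrow(mstate))) {
    m <- mstate$name[i]; side <- mstate$side[i]
    ch <- rectified_channels(mstate$l[i], mstate$v[i], mstate$F[i],
                             p$muscles[m, "Fmax"])
    if (m %in% .flexors) {
      base <- gains$kFv * ch$vhat^0.6 + gains$kFl * ch$lhat
      tgt <- paste0(side, ":", c("RG-F", "IN-F", "PF-F"))
      s[tgt] <- s[tgt] + base
      mn <- paste0(side, ":MN-", m)
      s[mn] <- s[mn] + gains$eta_v * gains$kFv * ch$vhat^0.6 +
        gains$eta_l * gains$kFl * ch$lhat
    } else {
      base <- gains$kEf * ch$Fhat
      tgt <- paste0(side, ":", c("RG-E", "IN-E", "PF-E"))
      s[tgt] <- s[tgt] + base
      mn <- paste0(side, ":MN-", m)
      s[mn] <- s[mn] + gains$eta_f * gains$kEf * ch$Fhat
    }
  }
  s
}

#' Remove one feedback channel
#'
#' Sets the named channel's base gain and its motoneuron scaling factor
#' to zero; used by the feedback-ablation experiments.
#'
#' @param gains gain set
#' @param which one of `"velocity"`, `"length"`, `"force"`
#' @return modified gain set
#' @export
ablate <- function(gains, which = c("velocity", "length", "force")) {
  which <- match.arg(which)
  f <- switch(which,
              velocity = c("kFv", "eta_v"),
              length = c("kFl", "eta_l"),
              force = c("kEf", "eta_f"))
  gains[f] <- list(0, 0)
  gains
}
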