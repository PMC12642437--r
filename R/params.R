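# Parameter bundle.
#
# The numeric values below are a synthetic parameter set constructed for
# this package in the style of activity-based half-center CPG /
# neuromechanical cat models (see the methods vignette).  Everything
# structural -- the equations, activation functions, feedback structure,
# belt speed, thresholds, the optimization cost -- is fixed by the model
# definition; the constants were calibrated so the stated network and
# locomotor behaviors hold.

#' Default (synthetic) parameter bundle
#'
#' Returns the full parameter set of the model: network constants and
#' per-population-class values, structural connection weights, supraspinal
#' drive, muscle table and Hill-curve constants, skeleton, contact and
#' platform constants, afferent feedback gains, and integrator settings.
#'
#' The 13 free parameters of the model (seven PF-to-MN weights and six
#' feedback gains) default to the optimized vector shipped with the
#' package (see [optimized_param_vector()]); pass `optimized = FALSE` for
#' the pre-optimization seed values.
#'
#' @param optimized load the shipped optimized 13-parameter vector
#' @return nested list of class `cpg_params`
#' @export
default_params <- function(optimized = TRUE) {
  p <- list(
    network = list(
      C = 20,                      # pF
      ENa = 55, ESynE = -10,       # mV
      gSynE = 10, gSynI = 10,      # nS
      Vth = -50, Vmax = 0,         # mV, output function thresholds
      # per population class: persistent sodium / leak conductances (nS),
      # leak and inhibitory reversal potentials (mV)
      class = list(
        RG  = list(gNaP = 5.0, gLeak = 4.5, ELeak = -62.5, ESynI = -75),
        IN  = list(gNaP = 0.0, gLeak = 5.0, ELeak = -60.0, ESynI = -75),
        CIN = list(gNaP = 0.0, gLeak = 5.0, ELeak = -60.0, ESynI = -75),
        PF  = list(gNaP = 0.5, gLeak = 5.0, ELeak = -60.0, ESynI = -75),
        MN  = list(gNaP = 0.3, gLeak = 5.0, ELeak = -60.0, ESynI = -75)
      )
    ),
    weights = list(                 # structural (non-optimized) weights
      a_rgf_inf = 1.20,             # RG-F -> IN-F
      a_rge_ine = 0.40,             # RG-E -> IN-E
      b_in_rg = 2.00,               # IN -| opposing RG center
      a_rgf_c1 = 0.40,              # RG-F -> C1
      b_c1_rgf = 0.60,              # C1 -| contralateral RG-F
      a_rge_v3 = 0.30,              # RG-E -> V3
      a_v3_ine = 0.30,              # V3 -> contralateral IN-E
      a_rgf_pff = 0.80,             # RG-F -> PF-F
      a_rge_pfe = 1.50,             # RG-E -> PF-E
      b_in_pf = 1.00,               # IN -| opposing PF
      mn = setNames(rep(2, 7), .muscles)    # PF -> MN (optimized)
    ),
    drive = list(d = 1.0, gamma_RGF = 0.08, gamma_RGE = 0.50),
    feedback = list(kFv = 0.1, kFl = 0.15, kEf = 0.4,
                    eta_v = 0.3, eta_l = 0.3, eta_f = 0.3),
    muscles = local({
      # dpp = degrees of joint motion per 1% length change (the GA differs)
      df <- data.frame(
        name = .muscles,
        role = ifelse(.muscles %in% .flexors, "flexor", "extensor"),
        Fmax = c(80, 250, 300, 40, 150, 80, 160),     # N
        lmax = c(0.065, 0.070, 0.070, 0.055, 0.060, 0.095, 0.075),  # m
        l_neutral = c(0.85, 0.85, 0.85, 0.85, 0.85, 0.75, 0.75),
        hip_dpp   = c(2, 2, 0, 0, 0, 2, 0),
        knee_dpp  = c(0, 0, 2, 0, 0, 2, 4.5),
        ankle_dpp = c(0, 0, 0, 2, 2, 0, 1.5),
        # action sign per joint: +1 flexor action (lengthens on extension),
        # -1 extensor action, 0 joint not spanned
        hip_sign   = c(+1, -1, 0, 0, 0, -1, 0),
        knee_sign  = c(0, 0, -1, 0, 0, +1, +1),
        ankle_sign = c(0, 0, 0, +1, -1, 0, -1),
        stringsAsFactors = FALSE
      )
      rownames(df) <- df$name
      df
    }),
    curves = list(        # Hill-type force-length / velocity / passive
      fl_beta = 1.55, fl_omega = 0.81, fl_rho = 2.12,
      vmax = 8,           # lmax/s, maximal shortening velocity
      fv_af = 0.25,       # concentric curvature
      fv_ecc_gain = 0.8,  # eccentric force excess at large stretch velocity
      fv_ecc_sat = 2,     # lmax/s, eccentric saturation scale
      fp_k = 0.02, fp_c = 6, fp_slack = 1.0
    ),
    skeleton = list(
      g = 9.81,
      trunk = list(m = 2.0, L = 0.25, com = 0.72, I = 0.015),
      thigh = list(m = 0.25, L = 0.10, com = 0.45, I = 2.5e-4),
      crus  = list(m = 0.10, L = 0.12, com = 0.45, I = 1.4e-4),
      foot  = list(m = 0.03, L = 0.07, com = 0.5,  I = 2.0e-5),
      L_fore = 0.21,          # rigid forelimb strut, shoulder to tip (m)
      neutral_deg = c(hip = 60, knee = 90, ankle = 100),  # muscle-neutral posture
      joint_damping = 0.02,   # N m s / rad, small physiological dissipation
      joint_limits = list(    # soft range-of-motion stops
        lo_deg = c(hip = 30, knee = 40, ankle = 40),
        hi_deg = c(hip = 160, knee = 175, ankle = 175),
        k = 30, c = 0.5       # N m / rad, N m s / rad
      )
    ),
    contact = list(
      k_n = 10000, c_n = 120,   # normal viscoelastic element (N/m, N s/m)
      c_t = 400,                # tangential viscous coupling to belt (N s/m)
      v_belt = 0.20,            # m/s, belt speed
      platform = list(height = 0.02, k_h = 500, c_h = 30,
                      k_v = 3000, c_v = 60, anchor_x = 0,
                      half_length = 0.06)   # platform extent about the anchor (m)
    ),
    sim = list(dt = 0.04,       # ms, RK4 time step
               settle = 3000,   # ms held standing before release (see vignette)
               log_stride = 25, # steps between logged samples (1 ms)
               fall_hip = 0.05, # m, hip-height fall threshold
               airborne_factor = 1.5, airborne_default = 2.0,  # s
               cap = 100)       # s, maximal trial duration
  )
  class(p) <- "cpg_params"
  if (optimized) p <- set_free_params(p, optimized_param_vector())
  p
}

#' The 13 free parameters as a named vector
#'
#' Seven PF-to-MN excitatory weights (one per muscle) followed by the six
#' afferent feedback gains, in the fixed order used by the optimizer.
#'
#' @param p parameter bundle
#' @return named numeric vector of length 13
#' @export
free_param_vector <- function(p) {
  c(setNames(as.numeric(p$weights$mn[.muscles]), paste0("mn_", .muscles)),
    kFv = p$feedback$kFv, kFl = p$feedback$kFl, kEf = p$feedback$kEf,
    eta_v = p$feedback$eta_v, eta_l = p$feedback$eta_l, eta_f = p$feedback$eta_f)
}

#' Install a 13-parameter vector into a bundle
#'
#' @param p parameter bundle
#' @param x numeric vector of length 13 in the order of
#'   [free_param_vector()] (names optional); all entries must be >= 0
#' @return updated bundle
#' @export
set_free_params <- function(p, x) {
  stopifnot(length(x) == 13, all(x >= 0))
  x <- as.numeric(x)
  p$weights$mn <- setNames(x[1:7], .muscles)
  p$feedback[c("kFv", "kFl", "kEf", "eta_v", "eta_l", "eta_f")] <-
    as.list(x[8:13])
  p
}

#' Connectivity of a parameter bundle
#'
#' @param p parameter bundle
#' @param reg population registry
#' @return connectivity list (see [build_connectivity()])
#' @export
connectivity_from_params <- function(p, reg = population_registry()) {
  gamma <- c(setNames(rep(p$drive$gamma_RGF, 2), paste0(.sides, ":RG-F")),
             setNames(rep(p$drive$gamma_RGE, 2), paste0(.sides, ":RG-E")))
  build_connectivity(architecture_edges(p$weights), gamma, reg)
}

#' Per-population network parameter vectors
#'
#' Expands the per-class constants of the bundle to one value per
#' registered population, in registry order, for use by
#' [membrane_derivative()].
#'
#' @param p parameter bundle
#' @param reg population registry
#' @return list with scalars `C`, `ENa`, `ESynE`, `gSynE`, `gSynI`, `Vth`,
#'   `Vmax` and vectors `gNaP`, `gLeak`, `ELeak`, `ESynI`, plus `h_index`
#' @export
network_params <- function(p, reg = population_registry()) {
  cl <- p$network$class
  pick <- function(field) vapply(reg$class, function(k) cl[[k]][[field]], 0)
  out <- list(C = p$network$C, ENa = p$network$ENa, ESynE = p$network$ESynE,
              gSynE = p$network$gSynE, gSynI = p$network$gSynI,
              Vth = p$network$Vth, Vmax = p$network$Vmax,
              gNaP = unname(pick("gNaP")), gLeak = unname(pick("gLeak")),
              ELeak = unname(pick("ELeak")), ESynI = unname(pick("ESynI")),
              h_index = which(reg$has_h))
  out
}

# serialization --------------------------------------------------------------

flatten_params <- function(x, prefix = character()) {
  if (is.list(x) && !is.data.frame(x)) {
    out <- list()
    for (nm in names(x))
      out <- c(out, flatten_params(x[[nm]], c(prefix, nm)))
    return(out)
  }
  key <- paste(prefix, collapse = ".")
  if (is.data.frame(x)) {
    out <- list()
    for (col in names(x)) if (is.numeric(x[[col]]))
      out[[paste0(key, ".", col)]] <- x[[col]]
    return(out)
  }
  if (is.numeric(x)) return(setNames(list(unname(x)), key))
  list()
}

#' Write a parameter bundle to a flat key-value file
#'
#' One `key<TAB>value...` line per numeric leaf (vectors are written as
#' tab-separated values on one line).  Non-numeric structure (muscle
#' names, signs table layout) is fixed by the package and not serialized.
#'
#' @param p parameter bundle
#' @param path output file
#' @export
write_params <- function(p, path) {
  fl <- flatten_params(unclass(p))
  lines <- vapply(names(fl), function(k)
    paste(c(k, format(fl[[k]], digits = 17, scientific = FALSE, trim = TRUE)),
          collapse = "\t"), "")
  writeLines(lines, path)
}

#' Load a parameter bundle from a flat key-value file
#'
#' The file must provide exactly the numeric leaves of the canonical
#' bundle: any missing or unknown key is a hard error naming the key, so
#' an incomplete table can never run silently.
#'
#' @param path file written by [write_params()]
#' @return parameter bundle of class `cpg_params`
#' @export
load_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  keys <- vapply(parts, `[[`, "", 1)
  vals <- lapply(parts, function(x) as.numeric(x[-1]))
  if (anyDuplicated(keys)) stop("duplicate key: ", keys[duplicated(keys)][1])
  names(vals) <- keys
  template <- default_params(optimized = FALSE)
  want <- flatten_params(unclass(template))
  missing <- setdiff(names(want), keys)
  extra <- setdiff(keys, names(want))
  if (length(missing)) stop("missing parameter key(s): ",
                            paste(missing, collapse = ", "))
  if (length(extra)) stop("unknown parameter key(s): ",
                          paste(extra, collapse = ", "))
  for (k in names(want)) {
    if (length(vals[[k]]) != length(want[[k]]))
      stop("parameter ", k, " has length ", length(vals[[k]]),
           ", expected ", length(want[[k]]))
    template <- assign_flat(template, strsplit(k, ".", fixed = TRUE)[[1]], vals[[k]])
  }
  template
}

assign_flat <- function(x, path, value) {
  put <- function(old, value) {
    # keep template names (e.g. per-muscle weight names) on the new values
    if (!is.null(names(old)) && length(old) == length(value))
      value <- setNames(value, names(old))
    value
  }
  if (length(path) == 1) {
    if (is.data.frame(x)) stop("internal: leaf inside data.frame expected one deeper")
    x[[path]] <- put(x[[path]], value)
    return(x)
  }
  if (is.data.frame(x[[path[1]]]) && length(path) == 2) {
    x[[path[1]]][[path[2]]] <- put(x[[path[1]]][[path[2]]], value)
    return(x)
  }
  x[[path[1]]] <- assign_flat(x[[path[1]]], path[-1], value)
  x
}

#' The shipped optimized 13-parameter vector
#'
#' Loads the CMA-ES-optimized parameter vector distributed with the
#' package (`inst/extdata/optimized_vector_synthetic.tsv`).  The vector was
#' obtained by running [optimize_gait()] on the per-step randomized
#' belt-height surface; it is synthetic in the sense that it belongs to
#' this package's calibrated parameter set.
#'
#' @return named numeric vector of length 13
#' @export
optimized_param_vector <- function() {
  path <- system.file("extdata", "optimized_vector_synthetic.tsv",
                      package = "cpgwalk")
  if (path == "") stop("optimized vector file not installed")
  tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  setNames(tab$value, tab$name)
}
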