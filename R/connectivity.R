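# Network architecture of the bilateral two-level CPG.
#
# Within each side: RG-F and RG-E mutually inhibit through IN-F and IN-E;
# PF-F/PF-E are excited by the homolateral RG center and inhibited by the
# opposing IN; flexor MNs are driven by PF-F and extensor MNs by PF-E.
# Across the midline: C1 mediates inhibition of the contralateral RG-F by
# the ipsilateral RG-F, and V3 mediates inhibition of the contralateral
# RG-F by the ipsilateral RG-E through the contralateral IN-E.

#' Edge table realizing the CPG architecture
#'
#' @param w named list of structural weights (see [default_params()]
#'   element `weights`); `mn` is a named vector of the seven PF-to-MN
#'   weights (part of the optimized parameter vector).
#' @return data.frame with columns `src`, `dst`, `type` (alpha/beta),
#'   `weight`, rows for both sides.
#' @export
architecture_edges <- function(w) {
  rows <- list()
  add <- function(src, dst, type, weight)
    rows[[length(rows) + 1]] <<- data.frame(src = src, dst = dst,
                                            type = type, weight = weight)
  for (s in .sides) {
    o <- other_side(s)
    p <- function(n) paste0(s, ":", n)
    q <- function(n) paste0(o, ":", n)
    add(p("RG-F"), p("IN-F"), "alpha", w$a_rgf_inf)
    add(p("RG-E"), p("IN-E"), "alpha", w$a_rge_ine)
    add(p("IN-F"), p("RG-E"), "beta",  w$b_in_rg)
    add(p("IN-E"), p("RG-F"), "beta",  w$b_in_rg)
    add(p("RG-F"), p("C1"),   "alpha", w$a_rgf_c1)
    add(p("C1"),   q("RG-F"), "beta",  w$b_c1_rgf)
    add(p("RG-E"), p("V3"),   "alpha", w$a_rge_v3)
    add(p("V3"),   q("IN-E"), "alpha", w$a_v3_ine)
    add(p("RG-F"), p("PF-F"), "alpha", w$a_rgf_pff)
    add(p("RG-E"), p("PF-E"), "alpha", w$a_rge_pfe)
    add(p("IN-E"), p("PF-F"), "beta",  w$b_in_pf)
    add(p("IN-F"), p("PF-E"), "beta",  w$b_in_pf)
    for (m in .muscles) {
      pf <- if (m %in% .flexors) "PF-F" else "PF-E"
      add(p(pf), p(paste0("MN-", m)), "alpha", unname(w$mn[m]))
    }
  }
  do.call(rbind, rows)
}

#' Build connectivity matrices from an edge table
#'
#' Validates the sign convention (weights non-negative, signs live in the
#' current expressions), that MN pools are never sources, that CIN and MN
#' targets receive no inhibition, and that supraspinal drive reaches only
#' the RG centers.
#'
#' @param edges edge table as from [architecture_edges()]
#' @param gamma named numeric: supraspinal drive weight per population id
#'   (ids absent get 0)
#' @param reg population registry
#' @return list with dense matrices `A` (excitatory) and `B` (inhibitory),
#'   rows = target, cols = source, and `gamma` per population.
#' @export
build_connectivity <- function(edges, gamma, reg = population_registry()) {
  n <- nrow(reg)
  A <- B <- matrix(0, n, n, dimnames = list(reg$id, reg$id))
  if (any(edges$weight < 0))
    stop("connection weights must be non-negative; signs are carried by the synaptic currents")
  si <- match(edges$src, reg$id); di <- match(edges$dst, reg$id)
  if (anyNA(si) || anyNA(di)) stop("edge refers to unknown population")
  if (any(reg$class[si] == "MN")) stop("MN populations cannot be presynaptic sources")
  bad <- edges$type == "beta" & reg$class[di] %in% c("CIN", "MN")
  if (any(bad)) stop("inhibitory weights onto CIN/MN targets must be zero")
  for (k in seq_len(nrow(edges))) {
    if (edges$type[k] == "alpha") A[di[k], si[k]] <- A[di[k], si[k]] + edges$weight[k]
    else B[di[k], si[k]] <- B[di[k], si[k]] + edges$weight[k]
  }
  g <- setNames(numeric(n), reg$id)
  if (length(gamma)) {
    gi <- match(names(gamma), reg$id)
    if (anyNA(gi)) stop("gamma refers to unknown population")
    if (any(gamma < 0)) stop("gamma must be non-negative")
    if (any(!reg$name[gi] %in% c("RG-F", "RG-E") & gamma > 0))
      stop("supraspinal drive reaches only the RG centers")
    g[gi] <- gamma
  }
  list(A = A, B = B, gamma = g)
}
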