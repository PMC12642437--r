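#' @importFrom stats setNames approx optim rnorm runif
#' @importFrom utils head tail read.delim write.table modifyList
NULL

# Canonical orderings used throughout the package. Every state vector,
# parameter table and connectivity matrix is indexed in this order.
.sides   <- c("left", "right")
.muscles <- c("IP", "GM", "VL", "TA", "SO", "BF", "GA")
.flexors   <- c("IP", "TA", "BF")
.extensors <- c("GM", "VL", "SO", "GA")
.pop_names <- c("RG-F", "RG-E", "IN-F", "IN-E", "C1", "V3", "PF-F", "PF-E",
                paste0("MN-", .muscles))

#' Population registry of the bilateral two-level CPG
#'
#' Declarative table of all neural populations: the rhythm-generator
#' half-centers (RG-F, RG-E), their inhibitory interneurons (IN-F, IN-E),
#' the commissural populations (C1, V3), the pattern-formation layer
#' (PF-F, PF-E) and one motoneuron pool per muscle, on each side.
#' RG, PF and MN populations carry the slow persistent-sodium inactivation
#' variable `h`; IN and CIN populations do not.
#'
#' @return A data.frame with one row per population and columns
#'   `id` (e.g. `"left:RG-F"`), `side`, `name`, `class`
#'   (RG/IN/CIN/PF/MN), `has_h` (logical) and, for MN pools, `muscle`.
#' @export
#' @examples
#' r <- population_registry()
#' table(r$class) / 2   # populations per side by class
population_registry <- function() {
  cls <- function(name) {
    if (grepl("^RG", name)) "RG"
    else if (grepl("^IN", name)) "IN"
    else if (name %in% c("C1", "V3")) "CIN"
    else if (grepl("^PF", name)) "PF"
    else "MN"
  }
  rows <- do.call(rbind, lapply(.sides, function(s) {
    data.frame(id = paste0(s, ":", .pop_names),
               side = s, name = .pop_names,
               class = vapply(.pop_names, cls, ""),
               stringsAsFactors = FALSE)
  }))
  rows$has_h <- rows$class %in% c("RG", "PF", "MN")
  rows$muscle <- ifelse(rows$class == "MN", sub("^MN-", "", rows$name), NA)
  rownames(rows) <- rows$id
  rows
}

# index helpers -------------------------------------------------------------

pop_index <- function(reg, side, name) {
  i <- match(paste0(side, ":", name), reg$id)
  if (anyNA(i)) stop("unknown population: ", paste0(side, ":", name))
  i
}

#' Index map of the slow variable h
#'
#' @param reg registry from [population_registry()]
#' @return integer vector: for each h slot, the row of the population that
#'   owns it (RG, PF and MN populations, in registry order).
#' @export
h_index <- function(reg = population_registry()) which(reg$has_h)

other_side <- function(s) ifelse(s == "left", "right", "left")

muscle_table_index <- function(side, muscle) {
  match(side, .sides) * 0L + (match(side, .sides) - 1L) * 7L + match(muscle, .muscles)
}
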