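#' Nearest-neighbor energy table for hairpin folding
#'
#' Stack energies (kcal/mol) for Watson-Crick and G-U wobble pair steps plus
#' loop-length penalties for hairpin loops, bulges and internal loops,
#' rounded from standard published nearest-neighbor parameter sets for RNA
#' at 37 C. Loop penalties beyond the tabulated lengths are extrapolated
#' logarithmically (Jacobson-Stockmayer form, coefficient `lxc`). The table
#' is deliberately compact: the folding model here is hairpin-only (one
#' stem with bulges/internal loops) and its absolute energies carry a
#' tolerance of about +-2 kcal/mol relative to full-featured folding tools.
#'
#' @return A list with components `stack` (6x6 matrix over pair steps in
#'   the order CG, GC, GU, UG, AU, UA), `hairpin`, `bulge`, `internal`
#'   (penalty vectors indexed by loop length, position 1 = length 0),
#'   `asym`, `asym_max` (internal-loop asymmetry penalty per nucleotide and
#'   its cap), and `lxc` (log extrapolation coefficient).
#' @export
#' @examples
#' tab <- default_energy_table()
#' tab$stack["CG", "GC"]
default_energy_table <- function() {
  pairs <- c("CG", "GC", "GU", "UG", "AU", "UA")
  stack <- matrix(c(
    # CG     GC     GU     UG     AU     UA    (inner pair ->)
    -3.3,  -3.4,  -2.1,  -1.4,  -2.1,  -2.1,  # outer CG
    -2.4,  -3.3,  -2.5,  -2.1,  -2.2,  -2.4,  # outer GC
    -2.1,  -2.5,  -1.4,   0.3,  -1.4,  -1.3,  # outer GU
    -1.4,  -2.1,   0.5,  -0.5,  -1.0,  -0.6,  # outer UG
    -2.1,  -2.4,  -1.3,  -1.0,  -0.9,  -1.1,  # outer AU
    -2.4,  -2.1,  -1.0,  -0.6,  -1.3,  -0.9   # outer UA
  ), nrow = 6, byrow = TRUE, dimnames = list(pairs, pairs))
  list(
    stack = stack,
    # index 1 = loop length 0; lengths < 3 are forbidden in the DP itself
    hairpin = c(99, 99, 99, 5.4, 5.6, 5.7, 5.4, 6.0, 5.5, 6.4),
    bulge = c(99, 3.8, 2.8, 3.2, 3.6, 4.0, 4.4),
    internal = c(99, 99, 1.5, 1.6, 1.7, 2.0, 2.0, 2.2, 2.3, 2.4, 2.5),
    asym = 0.5,
    asym_max = 3.0,
    lxc = 1.08
  )
}

# Convert the R-facing table into the 0-indexed layout used by the C++ DP.
energy_table_for_dp <- function(table = default_energy_table()) {
  stopifnot(is.matrix(table$stack), all(dim(table$stack) == c(6, 6)))
  list(stack = table$stack, hairpin = unname(table$hairpin),
       bulge = unname(table$bulge), internal = unname(table$internal),
       asym = table$asym, asym_max = table$asym_max, lxc = table$lxc)
}
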