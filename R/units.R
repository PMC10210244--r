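#' Unit system constants
#'
#' The package works in a single fixed unit system throughout: lengths in nm,
#' time in ps, mass in g/mol, energy in kJ/mol and charge in units of the
#' elementary charge e.  Velocities are nm/ps and forces kJ/mol/nm.  The two
#' physical constants needed in these units are fixed here and are not
#' per-run inputs:
#'
#' * `k_e` — the Coulomb prefactor 1/(4 pi eps0), 138.935458 kJ mol^-1 nm e^-2;
#' * `R`   — the molar gas constant, 8.31446261815324e-3 kJ mol^-1 K^-1
#'   (so RT at 323 K is about 2.686 kJ/mol).
#'
#' @return A named list with elements `k_e`, `R` and a `units` character
#'   vector naming the base units.
#' @examples
#' hhpf_constants()$k_e
#' @export
hhpf_constants <- function() {
  list(
    k_e = 138.935458,
    R = 8.31446261815324e-3,
    units = c(length = "nm", time = "ps", mass = "g/mol",
              energy = "kJ/mol", charge = "e", velocity = "nm/ps",
              force = "kJ/mol/nm", temperature = "K")
  )
}

.KE <- 138.935458
.RGAS <- 8.31446261815324e-3
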