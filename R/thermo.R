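# Nearest-neighbour duplex thermodynamics.
#
# Enthalpy/entropy increments for dinucleotide stacks, keyed "XY/WZ" meaning
# 5'-XY-3' paired against 3'-WZ-5' (X with W, Y with Z).  Watson-Crick values
# are the unified oligonucleotide set (SantaLucia 1998); single internal
# mismatch values are the Allawi & SantaLucia / Peyret series compiled for
# G.T, G.A, C.T, A.C and like-with-like mismatches.  dH in kcal/mol, dS in
# cal/(mol K).  Duplex initiation terms are deliberately omitted: dimer
# interactions are compared relatively, so the constant offset cancels.

NN_TABLE <- local({
  wc <- list(
    "AA/TT" = c(-7.9, -22.2),
    "AT/TA" = c(-7.2, -20.4),
    "TA/AT" = c(-7.2, -21.3),
    "CA/GT" = c(-8.5, -22.7),
    "GT/CA" = c(-8.4, -22.4),
    "CT/GA" = c(-7.8, -21.0),
    "GA/CT" = c(-8.2, -22.2),
    "CG/GC" = c(-10.6, -27.2),
    "GC/CG" = c(-9.8, -24.4),
    "GG/CC" = c(-8.0, -19.9)
  )
  # single internal mismatches; mismatch in the second column of each key
  gt <- list(  # G.T
    "AG/TT" = c(1.0, 0.9),  "AT/TG" = c(-2.5, -8.3),
    "CG/GT" = c(-4.1, -11.7), "CT/GG" = c(-2.8, -8.0),
    "GG/CT" = c(3.3, 10.4), "GG/TT" = c(5.8, 16.3),
    "GT/CG" = c(-4.4, -12.3), "GT/TG" = c(4.1, 9.5),
    "TG/AT" = c(-0.1, -1.7), "TG/GT" = c(-1.4, -6.2),
    "TT/AG" = c(-1.3, -5.3)
  )
  ga <- list(  # G.A
    "AA/TG" = c(-0.6, -2.3), "AG/TA" = c(-0.7, -2.3),
    "CA/GG" = c(-0.7, -2.3), "CG/GA" = c(-4.0, -13.2),
    "GA/CG" = c(-0.6, -1.0), "GG/CA" = c(0.5, 3.2),
    "TA/AG" = c(0.7, 0.7),   "TG/AA" = c(3.0, 7.4)
  )
  ct <- list(  # C.T
    "AC/TT" = c(0.7, 0.2),   "AT/TC" = c(-1.2, -6.2),
    "CC/GT" = c(-0.8, -4.5), "CT/GC" = c(-1.5, -6.1),
    "GC/CT" = c(2.3, 5.4),   "GT/CC" = c(5.2, 13.5),
    "TC/AT" = c(1.2, 0.7),   "TT/AC" = c(1.0, 0.7)
  )
  ac <- list(  # A.C
    "AA/TC" = c(2.3, 4.6),   "AC/TA" = c(5.3, 14.6),
    "CA/GC" = c(1.9, 3.7),   "CC/GA" = c(0.6, -0.6),
    "GA/CC" = c(5.2, 14.2),  "GC/CA" = c(-0.7, -3.8),
    "TA/AC" = c(3.4, 8.0),   "TC/AA" = c(7.6, 20.2)
  )
  like <- list(  # A.A, C.C, G.G, T.T
    "AA/TA" = c(1.2, 1.7),   "CA/GA" = c(-0.9, -4.2),
    "GA/CA" = c(-2.9, -9.8), "TA/AA" = c(4.7, 12.9),
    "AC/TC" = c(0.0, -4.4),  "CC/GC" = c(-1.5, -7.2),
    "GC/CC" = c(3.6, 8.9),   "TC/AC" = c(6.1, 16.4),
    "AG/TG" = c(-3.1, -9.5), "CG/GG" = c(-4.9, -15.3),
    "GG/CG" = c(-6.0, -15.8), "TG/AG" = c(1.6, 3.6),
    "AT/TT" = c(-2.7, -10.8), "CT/GT" = c(-5.0, -15.8),
    "GT/CT" = c(-2.2, -8.4), "TT/AT" = c(0.2, -1.5)
  )
  c(wc, gt, ga, ct, ac, like)
})

WC_PAIRS <- c(A = "T", C = "G", G = "C", T = "A")

is_wc <- function(x, y) !is.na(WC_PAIRS[x]) && WC_PAIRS[[x]] == y

#' Thermodynamic parameters for duplex stability
#'
#' Bundles the nearest-neighbour dH/dS table with the reaction conditions.
#' The free energy of a stack at temperature T is
#' `dG(T) = dH - (T + 273.15) * dS' / 1000` with the salt-corrected entropy
#' `dS' = dS + 0.368 * ln([Na+])` (cal/(mol K) per stack).
#'
#' @param temperature Reaction temperature in degrees Celsius, in \[0, 100\].
#' @param sodium Monovalent cation concentration in mol/L (> 0).
#' @return An object of class `thermo_params`.
#' @examples
#' thermo_params(temperature = 60, sodium = 0.05)
#' @export
thermo_params <- function(temperature = 37, sodium = 0.05) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L,
            temperature >= 0, temperature <= 100,
            is.numeric(sodium), length(sodium) == 1L, sodium > 0)
  structure(list(nn_dg_table = NN_TABLE,
                 temperature = temperature,
                 sodium = sodium),
            class = "thermo_params")
}

#' @export
print.thermo_params <- function(x, ...) {
  cat(sprintf("Nearest-neighbour parameters: %d stack entries; T = %g C, [Na+] = %g M\n",
              length(x$nn_dg_table), x$temperature, x$sodium))
  invisible(x)
}

# dH/dS of the stack 5'-XY-3'/3'-WZ-5'; a key absent in the table is looked
# up via the duplex read from the other strand (ZW/YX).  Returns NULL when
# neither orientation is tabulated (e.g. adjacent double mismatches beyond
# the tandem G.T entries).
nn_lookup <- function(x, y, w, z, table = NN_TABLE) {
  key <- paste0(x, y, "/", w, z)
  hit <- table[[key]]
  if (!is.null(hit)) return(hit)
  table[[paste0(z, w, "/", y, x)]]
}

#' Free energy of one stack at the given conditions
#' @keywords internal
stack_dg <- function(hs, params) {
  t_kelvin <- params$temperature + 273.15
  ds <- hs[2] + 0.368 * log(params$sodium)
  hs[1] - t_kelvin * ds / 1000
}
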