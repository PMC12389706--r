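# Embedded atomic constants for the 14 elements occurring in the pad and
# tissue materials. Transcribed from standard atomic-data compilations:
# A = atomic mass (g/mol); I = mean excitation energy (eV); k_edge = K-shell
# binding energy (keV); omega_K = K fluorescence yield; e_Kx = mean K X-ray
# energy (keV); f_K = fraction of photoelectric absorption on the K shell
# for photon energies above the K edge (from edge-jump ratios, (J-1)/J);
# l_edge = effective outer-shell (L) binding energy (keV) assigned to
# non-K photoelectric events.
.element_table <- data.frame(
  symbol  = c("H", "C", "N", "O", "Na", "Mg", "P", "S", "Cl", "K", "Ca",
              "Fe", "Zn", "Bi"),
  Z       = c(1, 6, 7, 8, 11, 12, 15, 16, 17, 19, 20, 26, 30, 83),
  A       = c(1.008, 12.011, 14.007, 15.999, 22.990, 24.305, 30.974, 32.06,
              35.45, 39.098, 40.078, 55.845, 65.38, 208.980),
  I       = c(19.2, 78, 82, 95, 149, 156, 173, 180, 174, 190, 191,
              286, 330, 823),
  k_edge  = c(0.0136, 0.284, 0.410, 0.543, 1.072, 1.305, 2.146, 2.472,
              2.822, 3.607, 4.038, 7.112, 9.659, 90.526),
  omega_K = c(0, 0.0028, 0.0052, 0.0083, 0.023, 0.030, 0.063, 0.078,
              0.097, 0.140, 0.163, 0.340, 0.474, 0.958),
  e_Kx    = c(0.0105, 0.277, 0.392, 0.525, 1.041, 1.254, 2.014, 2.308,
              2.622, 3.314, 3.692, 6.404, 8.639, 77.0),
  f_K     = c(1.00, 0.95, 0.95, 0.95, 0.94, 0.94, 0.93, 0.93, 0.93,
              0.92, 0.92, 0.89, 0.87, 0.78),
  l_edge  = c(0.0136, 0.010, 0.020, 0.028, 0.063, 0.074, 0.132, 0.163,
              0.200, 0.297, 0.346, 0.710, 1.020, 13.42),
  stringsAsFactors = FALSE
)

#' Atomic data for the supported elements
#'
#' Returns the embedded table of atomic constants used throughout the
#' package: atomic number and mass, mean excitation energy (for electron
#' stopping power), K-edge binding energy, K fluorescence yield and mean
#' K X-ray energy (for photoelectric relaxation), the K-shell photoelectric
#' fraction above the edge, an effective outer-shell binding energy, and
#' the radiation length.
#'
#' @return A data frame with one row per element and columns
#'   \code{symbol}, \code{Z}, \code{A} (g/mol), \code{I} (eV),
#'   \code{k_edge} (keV), \code{omega_K}, \code{e_Kx} (keV), \code{f_K},
#'   \code{l_edge} (keV) and \code{X0} (radiation length, g/cm2).
#' @examples
#' element_data()[element_data()$symbol == "Bi", ]
#' @export
element_data <- function() {
  tab <- .element_table
  tab$X0 <- element_radiation_length(tab$Z, tab$A)
  tab
}

#' Radiation length of an element
#'
#' Dahl's closed-form approximation X0 = 716.4 A / (Z (Z+1) ln(287/sqrt(Z)))
#' in g/cm2, accurate to a few percent across the periodic table and
#' sufficient for Highland multiple-scattering angles.
#'
#' @param Z atomic number(s)
#' @param A atomic mass(es), g/mol
#' @return radiation length(s) in g/cm2
#' @export
element_radiation_length <- function(Z, A) {
  716.408 * A / (Z * (Z + 1) * log(287 / sqrt(Z)))
}

.element_row <- function(symbol) {
  i <- match(symbol, .element_table$symbol)
  if (anyNA(i)) {
    stop("unknown element symbol: ",
         paste(symbol[is.na(i)], collapse = ", "), call. = FALSE)
  }
  .element_table[i, , drop = FALSE]
}
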