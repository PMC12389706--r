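# Materials: compositions by mass fraction, mixture rules, pad composites
# and the ICRP-style tissue library.

#' Construct a material
#'
#' A material is a named density plus an elemental composition by mass
#' fraction. Compositions must be non-negative and sum to one within 1e-9.
#'
#' @param name material name
#' @param density bulk density in g/cm3 (> 0)
#' @param composition named numeric vector of element mass fractions
#' @param provenance one of "paper-table", "ICRP-embedded", "derived-mixture"
#' @return an object of class \code{padmc_material}
#' @export
material <- function(name, density, composition,
                     provenance = c("derived-mixture", "paper-table",
                                    "ICRP-embedded")) {
  provenance <- match.arg(provenance)
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(density) || length(density) != 1L || density <= 0) {
    stop("density must be a single positive number", call. = FALSE)
  }
  composition <- validate_composition(composition)
  structure(
    list(name = name, density = density, composition = composition,
         provenance = provenance),
    class = "padmc_material"
  )
}

validate_composition <- function(w) {
  if (is.null(names(w)) || any(!nzchar(names(w)))) {
    stop("composition must be a named numeric vector", call. = FALSE)
  }
  .element_row(names(w)) # errors on unknown symbols
  if (any(w < 0)) stop("mass fractions must be >= 0", call. = FALSE)
  s <- sum(w)
  if (abs(s - 1) > 1e-9) {
    stop(sprintf("mass fractions must sum to 1 (observed sum %.12f)", s),
         call. = FALSE)
  }
  # collapse duplicates, keep stable element order
  tapply_sym <- tapply(unname(w), names(w), sum)
  w <- setNames(as.numeric(tapply_sym), names(tapply_sym))
  ord <- order(match(names(w), .element_table$symbol))
  w[ord]
}

#' @export
print.padmc_material <- function(x, ...) {
  cat(sprintf("<material> %s  (rho = %.4f g/cm3, %s)\n",
              x$name, x$density, x$provenance))
  w <- x$composition
  cat(paste(sprintf("  %-2s %.6f", names(w), w), collapse = "\n"), "\n")
  invisible(x)
}

#' Elemental mass fractions from a stoichiometric formula
#'
#' Converts an element -> atom-count mapping into mass fractions
#' w_i = n_i A_i / sum_j n_j A_j.
#'
#' @param formula named numeric vector of atom counts, e.g.
#'   \code{c(H = 2, O = 1)} for water or \code{c(Bi = 2, O = 3)}.
#' @return named numeric vector of mass fractions summing to one
#' @examples
#' composition_from_formula(c(H = 2, O = 1))  # w_H ~ 0.1119
#' @export
composition_from_formula <- function(formula) {
  if (is.null(names(formula))) stop("formula must be named", call. = FALSE)
  if (any(formula <= 0)) stop("atom counts must be > 0", call. = FALSE)
  el <- .element_row(names(formula))
  m <- formula * el$A
  w <- m / sum(m)
  validate_composition(setNames(as.numeric(w), names(formula)))
}

#' Mix materials by mass fraction
#'
#' Element fractions are mass-weighted sums of the component fractions.
#' The mixture density follows the inverse-volume (mass-weighted specific
#' volume) rule 1/rho = sum f_k / rho_k, the standard rule for intimate
#' composites; pass \code{density} to pin the density instead (e.g. for
#' sensitivity checks against the base-gel density).
#'
#' @param components list of \code{padmc_material}
#' @param fractions numeric mass fractions, same length, summing to 1
#' @param name optional mixture name; default records the recipe
#' @param density optional density override in g/cm3
#' @return a \code{padmc_material} with provenance "derived-mixture"
#' @examples
#' w <- material("water", 1.0, composition_from_formula(c(H = 2, O = 1)))
#' cel <- material("cellulose", 1.10,
#'                 composition_from_formula(c(C = 6, H = 10, O = 5)))
#' mix_by_mass(list(w, cel), c(0.8, 0.2))  # rho ~ 1.0185
#' @export
mix_by_mass <- function(components, fractions, name = NULL, density = NULL) {
  stopifnot(is.list(components), length(components) == length(fractions))
  lapply(components, function(m) {
    if (!inherits(m, "padmc_material")) {
      stop("components must be padmc_material objects", call. = FALSE)
    }
  })
  if (any(fractions < 0)) stop("fractions must be >= 0", call. = FALSE)
  s <- sum(fractions)
  if (abs(s - 1) > 1e-9) {
    stop(sprintf("fractions must sum to 1 (observed sum %.12f)", s),
         call. = FALSE)
  }
  syms <- unique(unlist(lapply(components, function(m) names(m$composition))))
  w <- setNames(numeric(length(syms)), syms)
  for (k in seq_along(components)) {
    ck <- components[[k]]$composition
    w[names(ck)] <- w[names(ck)] + fractions[k] * ck
  }
  w <- w / sum(w) # remove rounding drift; drift itself is < 1e-12
  if (is.null(density)) {
    density <- 1 / sum(fractions / vapply(components, `[[`, 0, "density"))
  }
  if (is.null(name)) {
    name <- paste(sprintf("%.3g*%s", fractions,
                          vapply(components, `[[`, "", "name")),
                  collapse = " + ")
  }
  material(name, density, w[w > 0], provenance = "derived-mixture")
}

# dry polymer / filler / water building blocks (densities from the base
# hydrogel and dopant tables: dry alginate and chitosan 1.05, cellulose
# 1.10, Bi2O3 8.90, ZnO 5.60 g/cm3)
.pad_library <- list(
  alginate  = list(density = 1.05, formula = c(C = 6, H = 7, Na = 1, O = 6)),
  chitosan  = list(density = 1.05, formula = c(C = 6, H = 11, N = 1, O = 4)),
  cellulose = list(density = 1.10, formula = c(C = 6, H = 10, O = 5)),
  Bi2O3     = list(density = 8.90, formula = c(Bi = 2, O = 3)),
  ZnO       = list(density = 5.60, formula = c(Zn = 1, O = 1))
)

#' Water as a material
#' @param density density in g/cm3, default 1.0
#' @return a \code{padmc_material}
#' @export
water_material <- function(density = 1.0) {
  material("water", density, composition_from_formula(c(H = 2, O = 1)),
           provenance = "paper-table")
}

#' Dry polymer or filler from the pad library
#' @param name one of "alginate", "chitosan", "cellulose", "Bi2O3", "ZnO"
#' @return a \code{padmc_material}
#' @export
library_material <- function(name) {
  rec <- .pad_library[[name]]
  if (is.null(rec)) {
    stop("unknown library material: ", name, " (known: ",
         paste(names(.pad_library), collapse = ", "), ")", call. = FALSE)
  }
  material(name, rec$density, composition_from_formula(rec$formula),
           provenance = "paper-table")
}

#' Build a hydrogel pad material
#'
#' A pad is a hydrated composite of 80\% water and 20\% dry polymer by
#' weight, optionally doped with a high-Z filler at \code{filler_wt} mass
#' fraction: pad = (1 - filler_wt) * hydrated gel + filler_wt * filler.
#' Densities combine by the inverse-volume rule; pass \code{density} to
#' override.
#'
#' @param polymer "alginate", "chitosan" or "cellulose"
#' @param filler "none", "ZnO" or "Bi2O3"
#' @param filler_wt filler mass fraction in [0, 0.5]; study grid uses
#'   0, 0.05 and 0.10
#' @param density optional density override (g/cm3)
#' @return a \code{padmc_material}
#' @examples
#' make_pad_material("alginate", "Bi2O3", 0.10)  # w_Bi ~ 0.0897
#' @export
make_pad_material <- function(polymer = c("alginate", "chitosan", "cellulose"),
                              filler = c("none", "ZnO", "Bi2O3"),
                              filler_wt = 0, density = NULL) {
  polymer <- match.arg(polymer)
  filler <- match.arg(filler)
  if (filler_wt < 0 || filler_wt > 0.5) {
    stop("filler_wt must be in [0, 0.5] (physically plausible loading)",
         call. = FALSE)
  }
  if (filler == "none" && filler_wt != 0) {
    stop("filler_wt must be 0 when filler is \"none\"", call. = FALSE)
  }
  gel <- mix_by_mass(list(water_material(), library_material(polymer)),
                     c(0.8, 0.2),
                     name = paste0(polymer, " hydrogel"))
  if (filler == "none" || filler_wt == 0) {
    out <- gel
    if (!is.null(density)) out$density <- density
    return(out)
  }
  mix_by_mass(list(gel, library_material(filler)),
              c(1 - filler_wt, filler_wt),
              name = sprintf("%s + %s %g%%", polymer, filler, 100 * filler_wt),
              density = density)
}

# ICRP-style tissue compositions (mass fractions) and densities, as used by
# the standard simulation material database: skin, soft tissue (dermis),
# adipose (subcutaneous fat), skeletal muscle. Backing is pure water.
.tissue_library <- list(
  epidermis = list(density = 1.09, w = c(
    H = 0.100588, C = 0.228250, N = 0.046420, O = 0.619002,
    Na = 0.000070, Mg = 0.000060, P = 0.000330, S = 0.001590,
    Cl = 0.002670, K = 0.000850, Ca = 0.000150, Fe = 0.000010,
    Zn = 0.000010)),
  dermis = list(density = 1.00, w = c(
    H = 0.104472, C = 0.232190, N = 0.024880, O = 0.630238,
    Na = 0.001130, Mg = 0.000130, P = 0.001330, S = 0.001990,
    Cl = 0.001340, K = 0.001990, Ca = 0.000230, Fe = 0.000050,
    Zn = 0.000030)),
  subcut = list(density = 0.92, w = c(
    H = 0.119477, C = 0.637240, N = 0.007970, O = 0.232333,
    Na = 0.000500, Mg = 0.000020, P = 0.000160, S = 0.000730,
    Cl = 0.001190, K = 0.000320, Ca = 0.000020, Fe = 0.000020,
    Zn = 0.000020)),
  muscle = list(density = 1.05, w = c(
    H = 0.100637, C = 0.107830, N = 0.027680, O = 0.754773,
    Na = 0.000750, Mg = 0.000190, P = 0.001800, S = 0.002410,
    Cl = 0.000790, K = 0.003020, Ca = 0.000030, Fe = 0.000040,
    Zn = 0.000050))
)

#' Tissue material for a phantom layer
#'
#' Embedded ICRP-style compositions: skin (epidermis), soft tissue
#' (dermis), adipose tissue (subcutaneous fat), skeletal muscle, and pure
#' water for the backing volume. Layer thicknesses are a property of the
#' geometry (\code{\link{build_stack}}), not of the material.
#'
#' @param layer one of "epidermis", "dermis", "subcut", "muscle", "backing"
#' @return a \code{padmc_material}
#' @export
tissue_material <- function(layer) {
  if (identical(layer, "backing")) {
    out <- water_material()
    out$provenance <- "ICRP-embedded"
    return(out)
  }
  rec <- .tissue_library[[layer]]
  if (is.null(rec)) {
    stop("unknown tissue layer: ", layer, " (known: ",
         paste(c(names(.tissue_library), "backing"), collapse = ", "), ")",
         call. = FALSE)
  }
  w <- rec$w / sum(rec$w)
  material(layer, rec$density, w, provenance = "ICRP-embedded")
}

#' Effective electron-physics parameters of a material
#'
#' Mixture-rule aggregates needed by the electron transport model:
#' \code{z_over_a} = sum w_i Z_i/A_i; Bragg-additivity mean excitation
#' energy ln I = sum(w_i Z_i/A_i ln I_i) / <Z/A>; radiation length by
#' inverse additivity 1/X0 = sum w_i / X0_i; and
#' \code{z_eff} = sum(w_i Z_i^2/A_i) / <Z/A> used by the radiative
#' stopping-power scaling.
#'
#' @param mat a \code{padmc_material}
#' @return list with \code{z_over_a}, \code{I_eff_eV}, \code{ln_I},
#'   \code{X0_gcm2}, \code{z_eff}
#' @examples
#' effective_params(water_material())$z_over_a  # ~0.555
#' @export
effective_params <- function(mat) {
  stopifnot(inherits(mat, "padmc_material"))
  w <- mat$composition
  el <- .element_row(names(w))
  zoa_i <- el$Z / el$A
  zoa <- sum(w * zoa_i)
  ln_i <- sum(w * zoa_i * log(el$I)) / zoa
  x0 <- 1 / sum(w / element_radiation_length(el$Z, el$A))
  zeff <- sum(w * el$Z^2 / el$A) / zoa
  list(z_over_a = zoa, I_eff_eV = exp(ln_i), ln_I = ln_i,
       X0_gcm2 = x0, z_eff = zeff)
}
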