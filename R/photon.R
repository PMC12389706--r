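# Photon physics: loading the embedded element tables, mixture-rule
# material models, log-log interpolation of partial attenuation
# coefficients, and sampling of interaction type and outcome.

#' Load the embedded per-element photon cross-section tables
#'
#' Reads the frozen columnar table shipped with the package (or a
#' regenerated copy), validates it (strictly increasing per-element energy
#' grids, positive partials, common master grid covering all beam
#' energies) and caches the parsed structure for the session.
#'
#' @param path optional path to a \code{photon_xs.tsv}; default is the
#'   table installed with the package
#' @return a list of class \code{padmc_photon_tables} with the energy grid
#'   (keV) and per-element partial coefficient matrices (cm2/g)
#' @export
photon_tables <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.padmc_cache$tables)) return(.padmc_cache$tables)
    path <- system.file("extdata", "photon_xs.tsv", package = "padMC")
    if (!nzchar(path)) stop("embedded photon_xs.tsv not found", call. = FALSE)
    cache <- TRUE
  } else cache <- FALSE
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("element", "energy_keV", "mu_pe", "mu_incoh", "mu_coh")
  if (!all(need %in% names(df))) {
    stop("malformed cross-section table: expected columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  syms <- unique(df$element)
  grid <- df$energy_keV[df$element == syms[1]]
  if (any(diff(grid) <= 0)) {
    stop("energy grid must be strictly increasing", call. = FALSE)
  }
  if (min(grid) > 10 || max(grid) < 2000) {
    stop("energy grid must span 10-2000 keV", call. = FALSE)
  }
  mats <- list()
  for (s in syms) {
    sub <- df[df$element == s, ]
    if (!isTRUE(all.equal(sub$energy_keV, grid))) {
      stop("element ", s, " is not on the common master grid", call. = FALSE)
    }
    if (any(sub$mu_pe <= 0 | sub$mu_incoh <= 0 | sub$mu_coh <= 0)) {
      stop("non-positive partial coefficient for element ", s, call. = FALSE)
    }
    mats[[s]] <- cbind(pe = sub$mu_pe, incoh = sub$mu_incoh, coh = sub$mu_coh)
  }
  out <- structure(list(energy_keV = grid, elements = mats),
                   class = "padmc_photon_tables")
  if (cache) .padmc_cache$tables <- out
  out
}

# log-log linear interpolation on the master grid; errors outside span
.loglog_interp <- function(logE_grid, log_vals, E_keV) {
  if (any(E_keV < exp(logE_grid[1]) - 1e-9) ||
      any(E_keV > exp(logE_grid[length(logE_grid)]) + 1e-9)) {
    stop(sprintf("photon energy outside table span [%.4g, %.4g] keV",
                 exp(logE_grid[1]), exp(logE_grid[length(logE_grid)])),
         call. = FALSE)
  }
  exp(approx(logE_grid, log_vals, xout = log(E_keV), method = "linear",
             ties = "ordered", rule = 2)$y)
}

#' Photon attenuation model for a material
#'
#' Combines the per-element partial mass attenuation coefficients with the
#' mixture rule mu/rho(material) = sum_i w_i mu/rho(element i) on the
#' common master grid, and keeps the element-resolved photoelectric
#' contributions needed to choose the absorbing element in a
#' photoelectric event.
#'
#' @param mat a \code{padmc_material}
#' @param tables photon tables from \code{\link{photon_tables}}
#' @return an object of class \code{padmc_photon_model}
#' @export
material_photon_model <- function(mat, tables = photon_tables()) {
  stopifnot(inherits(mat, "padmc_material"),
            inherits(tables, "padmc_photon_tables"))
  w <- mat$composition
  miss <- setdiff(names(w), names(tables$elements))
  if (length(miss)) {
    stop("no cross-section table for element(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  ng <- length(tables$energy_keV)
  pe <- incoh <- coh <- numeric(ng)
  elem_pe <- elem_inc <- elem_coh <-
    matrix(0, ng, length(w), dimnames = list(NULL, names(w)))
  for (s in names(w)) {
    m <- tables$elements[[s]]
    pe <- pe + w[[s]] * m[, "pe"]
    incoh <- incoh + w[[s]] * m[, "incoh"]
    coh <- coh + w[[s]] * m[, "coh"]
    elem_pe[, s] <- w[[s]] * m[, "pe"]
    elem_inc[, s] <- w[[s]] * m[, "incoh"]
    elem_coh[, s] <- w[[s]] * m[, "coh"]
  }
  structure(
    list(material = mat, energy_keV = tables$energy_keV,
         logE = log(tables$energy_keV),
         pe = pe, incoh = incoh, coh = coh, total = pe + incoh + coh,
         elem_pe = elem_pe, elem_inc = elem_inc, elem_coh = elem_coh),
    class = "padmc_photon_model"
  )
}

#' Partial and total mass attenuation coefficients at an energy
#'
#' Log-log interpolation per partial on the master grid; the total is the
#' sum of the partials. Absorption-edge discontinuities are represented by
#' duplicated-energy grid pairs, so interpolation never crosses an edge.
#' Energies outside the table span are an error, never an extrapolation.
#'
#' @param model a \code{padmc_photon_model}
#' @param E_keV photon energy (keV), vectorized
#' @return data frame with columns \code{photoelectric},
#'   \code{incoherent}, \code{coherent}, \code{total} (cm2/g)
#' @examples
#' m <- material_photon_model(water_material())
#' mu_over_rho(m, 100)
#' @export
mu_over_rho <- function(model, E_keV) {
  stopifnot(inherits(model, "padmc_photon_model"))
  # interpolate per element, then apply the mixture rule, so the
  # element-weighted-sum identity holds between grid nodes too
  sum_cols <- function(m) {
    out <- 0
    for (j in seq_len(ncol(m))) {
      out <- out + .loglog_interp(model$logE, log(pmax(m[, j], 1e-300)),
                                  E_keV)
    }
    out
  }
  out <- data.frame(
    photoelectric = sum_cols(model$elem_pe),
    incoherent = sum_cols(model$elem_inc),
    coherent = sum_cols(model$elem_coh)
  )
  out$total <- out$photoelectric + out$incoherent + out$coherent
  out
}

#' Sample free-flight path lengths
#'
#' Exponential path lengths with mean 1/(mu/rho * rho) for a photon of the
#' given energy in the model's material. Uses R's RNG, so results are
#' reproducible under \code{set.seed}.
#'
#' @param model a \code{padmc_photon_model}
#' @param E_keV photon energy (keV)
#' @param n number of samples
#' @param density density override (g/cm3); default the material's
#' @return distances in cm
#' @export
sample_path_length <- function(model, E_keV, n = 1,
                               density = model$material$density) {
  mu <- mu_over_rho(model, E_keV)$total * density
  rexp(n, rate = mu)
}

#' Sample the interaction type at an energy
#'
#' Draws photoelectric / incoherent / coherent categories with
#' probabilities proportional to the partial attenuation coefficients.
#'
#' @inheritParams sample_path_length
#' @param include_coherent set \code{FALSE} to zero the coherent channel
#' @return character vector of interaction types
#' @export
select_interaction <- function(model, E_keV, n = 1, include_coherent = TRUE) {
  p <- mu_over_rho(model, E_keV)
  probs <- c(p$photoelectric, p$incoherent,
             if (include_coherent) p$coherent else 0)
  sample(c("photoelectric", "incoherent", "coherent"), n, replace = TRUE,
         prob = probs)
}

#' Sample Compton (incoherent) scattering outcomes
#'
#' Klein-Nishina sampling on a free electron at rest by Kahn's
#' acceptance-rejection method: E_scattered = E / (1 + alpha (1 - cos
#' theta)) with alpha = E/511 keV; the electron takes the remainder with
#' its direction from two-body kinematics. Energy is conserved exactly per
#' sample.
#'
#' @param E_keV incident photon energy (keV)
#' @param n number of samples
#' @return data frame with \code{E_scattered}, \code{cos_theta_photon},
#'   \code{E_electron}, \code{cos_theta_electron}
#' @export
sample_compton <- function(E_keV, n = 1) {
  stopifnot(E_keV > 0)
  m <- cpp_sample_compton(E_keV, as.integer(n))
  data.frame(E_scattered = m[, 1], cos_theta_photon = m[, 2],
             E_electron = m[, 3], cos_theta_electron = m[, 4])
}

#' Sample a coherent (Rayleigh) scattering angle
#'
#' Thomson angular distribution, proportional to 1 + cos^2(theta); no
#' energy loss. Retained so that total attenuation stays consistent with
#' the tables; the form-factor forward peaking is deliberately omitted.
#'
#' @param E_keV photon energy (unused by the Thomson distribution; kept
#'   for interface symmetry)
#' @param n number of samples
#' @return sampled cos(theta) values in [-1, 1]
#' @export
sample_coherent_angle <- function(E_keV = NULL, n = 1) {
  cpp_sample_thomson(as.integer(n))
}

#' Sample photoelectric absorption events
#'
#' The absorbing element is chosen proportional to w_i mu_pe,i(E). Above
#' the element's K edge a K-shell event occurs with the element's K-shell
#' photoelectric fraction: the photoelectron carries E - E_K and the
#' vacancy relaxes by K fluorescence (probability omega_K, X-ray of the
#' mean K energy emitted isotropically, E_K - E_Kx deposited locally) or
#' non-radiatively (E_K deposited locally). Otherwise an outer-shell event
#' ejects a photoelectron of E - E_L with the L binding deposited locally.
#'
#' @param model a \code{padmc_photon_model}
#' @param E_keV photon energy (keV)
#' @param n number of events
#' @return data frame with \code{E_electron}, \code{E_fluorescence} (0
#'   when no X-ray escapes the atom) and \code{E_local}, summing to E
#' @export
photoelectric_event <- function(model, E_keV, n = 1) {
  stopifnot(inherits(model, "padmc_photon_model"))
  wtau <- .loglog_interp_matrix(model$logE, model$elem_pe, E_keV)
  el <- .element_row(colnames(model$elem_pe))
  meta <- as.matrix(el[, c("k_edge", "omega_K", "e_Kx", "f_K", "l_edge")])
  m <- cpp_photoelectric(E_keV, as.integer(n), wtau, meta)
  data.frame(E_electron = m[, 1], E_fluorescence = m[, 2], E_local = m[, 3])
}

.loglog_interp_matrix <- function(logE, mat, E_keV) {
  out <- vapply(seq_len(ncol(mat)), function(j) {
    .loglog_interp(logE, log(pmax(mat[, j], 1e-300)), E_keV[1])
  }, numeric(1))
  names(out) <- colnames(mat)
  out
}
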