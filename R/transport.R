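# Geometry, beams and the batched history-loop driver.

#' Build a generic layered slab stack
#'
#' Layers are contiguous, non-overlapping slabs along z (depth increases
#' with z); the beam enters the first layer travelling in +z. Used
#' directly for oracle geometries (single slabs, semi-infinite absorbers);
#' \code{\link{build_stack}} builds the standard skin phantom.
#'
#' @param names character layer names
#' @param materials list of \code{padmc_material}, one per layer
#' @param thicknesses_mm positive layer thicknesses (mm)
#' @param z0_mm z of the top surface of the first layer (mm)
#' @return an object of class \code{padmc_stack}
#' @export
layer_stack <- function(names, materials, thicknesses_mm, z0_mm = 0) {
  stopifnot(length(names) == length(materials),
            length(names) == length(thicknesses_mm))
  if (any(thicknesses_mm <= 0)) {
    stop("layer thicknesses must be positive", call. = FALSE)
  }
  z <- z0_mm + cumsum(c(0, thicknesses_mm))
  df <- data.frame(
    name = names,
    z_min_mm = z[-length(z)],
    z_max_mm = z[-1],
    density = vapply(materials, `[[`, 0, "density"),
    stringsAsFactors = FALSE
  )
  structure(list(layers = df, materials = setNames(materials, names)),
            class = "padmc_stack")
}

#' Build the skin phantom stack, optionally with a pad on top
#'
#' Standard geometry: optional pad on [-t_pad, 0) mm, epidermis
#' [0, 0.1), dermis [0.1, 1.1), subcutaneous fat [1.1, 11.1), muscle
#' [11.1, 111.1), and a 100 mm water backing. Without a pad the beam
#' enters the epidermis directly. Upstream of the stack is vacuum (the
#' source abuts the first surface).
#'
#' @param pad_material optional \code{padmc_material} for the pad
#' @param pad_thickness_mm pad thickness in mm (study grid: 2 or 10;
#'   any positive value accepted)
#' @param backing include the 100 mm water backing volume (default TRUE)
#' @return a \code{padmc_stack}
#' @examples
#' build_stack()  # bare phantom
#' build_stack(make_pad_material("alginate", "Bi2O3", 0.10), 2)
#' @export
build_stack <- function(pad_material = NULL, pad_thickness_mm = NULL,
                        backing = TRUE) {
  nm <- c("epidermis", "dermis", "subcut", "muscle")
  th <- c(0.1, 1.0, 10, 100)
  mats <- lapply(nm, tissue_material)
  if (backing) {
    nm <- c(nm, "backing")
    th <- c(th, 100)
    mats <- c(mats, list(tissue_material("backing")))
  }
  z0 <- 0
  if (!is.null(pad_material)) {
    if (is.null(pad_thickness_mm) || pad_thickness_mm <= 0) {
      stop("pad thickness must be a positive number of mm", call. = FALSE)
    }
    nm <- c("pad", nm)
    th <- c(pad_thickness_mm, th)
    mats <- c(list(pad_material), mats)
    z0 <- -pad_thickness_mm
  }
  layer_stack(nm, mats, th, z0_mm = z0)
}

#' @export
print.padmc_stack <- function(x, ...) {
  cat("<layer stack>\n")
  df <- x$layers
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-10s [%8.1f, %8.1f) mm  %-30s rho=%.3f\n",
                df$name[i], df$z_min_mm[i], df$z_max_mm[i],
                x$materials[[i]]$name, df$density[i]))
  }
  invisible(x)
}

#' Specify a monoenergetic beam
#'
#' Pencil beam at the top surface, normally incident (+z). The study grid
#' uses 50, 100, 300, 500 and 1000 keV for both photons and electrons.
#'
#' @param particle "photon" or "electron"
#' @param energy_keV beam kinetic energy in keV (> 0)
#' @param n_histories number of primary histories (>= 1)
#' @param seed master seed for the run
#' @return an object of class \code{padmc_beam}
#' @export
beam_spec <- function(particle = c("photon", "electron"), energy_keV,
                      n_histories = 1e5, seed = 1L) {
  particle <- match.arg(particle)
  stopifnot(energy_keV > 0, n_histories >= 1)
  structure(list(particle = particle, energy_keV = energy_keV,
                 n = as.integer(n_histories), seed = as.integer(seed)),
            class = "padmc_beam")
}

#' Transport physics options
#'
#' @param photon_cutoff_keV photons below this are deposited locally
#'   (default 10 keV, the table floor; sub-10 keV photons have sub-2 mm
#'   mean free paths in tissue)
#' @param electron_cutoff_keV electrons below this are deposited locally
#'   (default 10 keV; range under 3 um in tissue)
#' @param include_coherent include coherent scattering in attenuation and
#'   sampling (Thomson angles)
#' @param attenuation_only test mode: every interaction absorbs the
#'   photon, no secondaries (narrow-beam transmission oracle)
#' @param step_energy_frac condensed-history step control: maximum
#'   fractional energy loss per step (default 0.05)
#' @param tables photon tables (default: embedded)
#' @return an options list of class \code{padmc_physics}
#' @export
transport_physics <- function(photon_cutoff_keV = 10,
                              electron_cutoff_keV = 10,
                              include_coherent = TRUE,
                              attenuation_only = FALSE,
                              step_energy_frac = 0.05,
                              tables = NULL) {
  structure(list(photon_cutoff = photon_cutoff_keV,
                 electron_cutoff = electron_cutoff_keV,
                 include_coherent = include_coherent,
                 attenuation_only = attenuation_only,
                 step_frac = step_energy_frac,
                 tables = tables),
            class = "padmc_physics")
}

# Assemble the per-layer physics tables consumed by the C++ engine.
build_engine_model <- function(stack, physics = transport_physics()) {
  tables <- physics$tables
  if (is.null(tables)) tables <- photon_tables()
  egrid <- exp(seq(log(.ELECTRON_E_MIN), log(.ELECTRON_E_MAX),
                   length.out = 160))
  layers <- lapply(seq_along(stack$materials), function(i) {
    mat <- stack$materials[[i]]
    pm <- material_photon_model(mat, tables)
    ep <- effective_params(mat)
    list(
      lpe = log(pm$pe), linc = log(pm$incoh), lcoh = log(pm$coh),
      lelem = log(pmax(pm$elem_pe, 1e-300)),
      meta = as.matrix(.element_row(colnames(pm$elem_pe))[,
                c("k_edge", "omega_K", "e_Kx", "f_K", "l_edge")]),
      scol = 1000 * .scol_from_params(ep$z_over_a, ep$I_eff_eV, egrid),
      srad = 1000 * .scol_from_params(ep$z_over_a, ep$I_eff_eV, egrid) *
        ep$z_eff * (egrid / 1000) / 800,
      X0 = ep$X0_gcm2
    )
  })
  list(
    z0 = stack$layers$z_min_mm / 10,  # cm
    z1 = stack$layers$z_max_mm / 10,
    rho = stack$layers$density,
    pgrid_log = log(tables$energy_keV),
    egrid_log = log(egrid),
    layers = layers
  )
}

# batch seed splitting rule: documented, keeps seeds below 2^31
.batch_seed <- function(master, b) {
  as.integer((as.numeric(master) * 1000003 + 7919 * b) %% 2147483647)
}

#' Run a beam through a stack and tally per-layer energy deposition
#'
#' Analog transport of \code{n} primary histories split into batches for
#' standard-error estimation. Each batch uses its own RNG stream derived
#' from the master seed by a fixed splitting rule, so a run is bit-for-bit
#' reproducible for a given (seed, N, batches) and batches could be
#' executed in any order. Tallies are means per primary particle in MeV;
#' escaped energy is accounted separately upstream (backscatter out of the
#' top surface) and downstream.
#'
#' @param beam a \code{padmc_beam}
#' @param stack a \code{padmc_stack}
#' @param physics a \code{padmc_physics} options object
#' @param batches number of batches (default 20; N is rounded to a
#'   multiple of the batch count)
#' @return an object of class \code{padmc_tally}: data frame of layer
#'   means and standard errors plus escape accounts and run metadata
#' @examples
#' \donttest{
#' tl <- run_beam(beam_spec("photon", 100, 2e4), build_stack())
#' tl
#' }
#' @export
run_beam <- function(beam, stack, physics = transport_physics(),
                     batches = 20) {
  stopifnot(inherits(beam, "padmc_beam"), inherits(stack, "padmc_stack"))
  if (batches < 2) stop("need at least 2 batches for an SE", call. = FALSE)
  nb <- max(1L, as.integer(round(beam$n / batches)))
  n_actual <- nb * batches
  model <- build_engine_model(stack, physics)
  opts <- list(photon_cutoff = physics$photon_cutoff,
               electron_cutoff = physics$electron_cutoff,
               include_coherent = physics$include_coherent,
               attenuation_only = physics$attenuation_only,
               step_frac = physics$step_frac)
  kind <- if (beam$particle == "photon") 0L else 1L
  nl <- nrow(stack$layers)
  dep <- matrix(0, batches, nl)
  esc <- matrix(0, batches, 2)
  for (b in seq_len(batches)) {
    set.seed(.batch_seed(beam$seed, b))
    r <- cpp_run_batch(kind, beam$energy_keV, nb, model, opts)
    dep[b, ] <- r$dep_keV / nb / 1000       # MeV per primary
    esc[b, ] <- c(r$esc_up_keV, r$esc_dn_keV) / nb / 1000
  }
  lay <- data.frame(
    layer = stack$layers$name,
    mean_MeV = colMeans(dep),
    se_MeV = apply(dep, 2, sd) / sqrt(batches),
    stringsAsFactors = FALSE
  )
  esc_df <- data.frame(
    account = c("escape_upstream", "escape_downstream"),
    mean_MeV = colMeans(esc),
    se_MeV = apply(esc, 2, sd) / sqrt(batches),
    stringsAsFactors = FALSE
  )
  structure(list(layers = lay, escapes = esc_df,
                 particle = beam$particle, energy_keV = beam$energy_keV,
                 n = n_actual, batches = batches, seed = beam$seed),
            class = "padmc_tally")
}

#' @export
print.padmc_tally <- function(x, ...) {
  cat(sprintf("<tally> %s beam, %g keV, N = %d (%d batches, seed %d)\n",
              x$particle, x$energy_keV, x$n, x$batches, x$seed))
  df <- rbind(x$layers,
              setNames(x$escapes, names(x$layers)))
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-18s %12.6g MeV/primary  (se %.2g)\n",
                df$layer[i], df$mean_MeV[i], df$se_MeV[i]))
  }
  tot <- sum(df$mean_MeV)
  cat(sprintf("  %-18s %12.6g MeV  (beam %g)\n", "sum",
              tot, x$energy_keV / 1000))
  invisible(x)
}

#' @export
as.data.frame.padmc_tally <- function(x, ...) {
  cbind(x$layers, particle = x$particle, energy_keV = x$energy_keV,
        n = x$n, seed = x$seed)
}

#' Energy-conservation audit of a tally
#'
#' Sum of layer means plus escape accounts must equal the beam energy;
#' analog transport conserves energy exactly per history, so the residual
#' is floating-point noise, reported here against the combined standard
#' error.
#'
#' @param tally a \code{padmc_tally}
#' @return list with \code{sum_MeV}, \code{beam_MeV}, \code{residual},
#'   \code{combined_se}
#' @export
conservation_check <- function(tally) {
  s <- sum(tally$layers$mean_MeV) + sum(tally$escapes$mean_MeV)
  e0 <- tally$energy_keV / 1000
  se <- sqrt(sum(tally$layers$se_MeV^2) + sum(tally$escapes$se_MeV^2))
  list(sum_MeV = s, beam_MeV = e0, residual = s - e0, combined_se = se)
}

#' Layer mean from a tally
#' @param tally a \code{padmc_tally}
#' @param layer layer name
#' @return named numeric c(mean, se) in MeV/primary
#' @export
tally_layer <- function(tally, layer) {
  i <- match(layer, tally$layers$layer)
  if (is.na(i)) stop("no layer named ", layer, call. = FALSE)
  c(mean = tally$layers$mean_MeV[i], se = tally$layers$se_MeV[i])
}
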