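# Study grid: configuration enumeration, sweeps, derived shielding
# metrics and pad-layer heatmaps.

.filler_states <- c("none", "ZnO-5", "ZnO-10", "Bi2O3-5", "Bi2O3-10")

parse_filler_state <- function(state) {
  if (state == "none") return(list(filler = "none", wt = 0))
  parts <- strsplit(state, "-", fixed = TRUE)[[1]]
  list(filler = parts[1], wt = as.numeric(parts[2]) / 100)
}

#' Define a sweep over the pad configuration grid
#'
#' Defaults reproduce the full study grid: 3 polymers x 5 filler states
#' (pure, ZnO 5/10\%, Bi2O3 5/10\%) x 2 thicknesses (2, 10 mm) plus the
#' No-Pad control, irradiated by photon and electron beams at 50, 100,
#' 300, 500 and 1000 keV - 310 runs.
#'
#' @param polymers subset of c("alginate", "chitosan", "cellulose")
#' @param fillers subset of c("none", "ZnO-5", "ZnO-10", "Bi2O3-5",
#'   "Bi2O3-10")
#' @param thicknesses pad thicknesses in mm
#' @param particles subset of c("photon", "electron")
#' @param energies beam energies in keV
#' @param n_histories histories per configuration
#' @param seed master seed; every run derives its own stream
#' @param include_no_pad include the bare-phantom control
#' @return an object of class \code{padmc_sweep_config}
#' @export
sweep_config <- function(polymers = c("alginate", "chitosan", "cellulose"),
                         fillers = .filler_states,
                         thicknesses = c(2, 10),
                         particles = c("photon", "electron"),
                         energies = c(50, 100, 300, 500, 1000),
                         n_histories = 1e5,
                         seed = 1L,
                         include_no_pad = TRUE) {
  stopifnot(all(fillers %in% .filler_states),
            all(particles %in% c("photon", "electron")),
            n_histories >= 1)
  structure(list(polymers = polymers, fillers = fillers,
                 thicknesses = thicknesses, particles = particles,
                 energies = energies, n = n_histories,
                 seed = as.integer(seed),
                 include_no_pad = include_no_pad),
            class = "padmc_sweep_config")
}

#' Enumerate the runnable configurations of a sweep
#'
#' Deterministic ordering; the No-Pad control appears exactly once per
#' particle x energy. The default grid yields 31 pad states x 2 particles
#' x 5 energies = 310 runs.
#'
#' @param cfg a \code{padmc_sweep_config}
#' @return data frame, one row per run, with pad descriptors, beam
#'   parameters and the derived per-run seed
#' @export
enumerate_configs <- function(cfg) {
  stopifnot(inherits(cfg, "padmc_sweep_config"))
  pads <- expand.grid(polymer = cfg$polymers, filler_state = cfg$fillers,
                      thickness = cfg$thicknesses,
                      stringsAsFactors = FALSE)
  pads$pad_id <- ifelse(
    pads$filler_state == "none",
    sprintf("%s @%gmm", pads$polymer, pads$thickness),
    sprintf("%s+%s @%gmm", pads$polymer, pads$filler_state, pads$thickness))
  if (cfg$include_no_pad) {
    pads <- rbind(data.frame(polymer = NA, filler_state = NA, thickness = NA,
                             pad_id = "no-pad", stringsAsFactors = FALSE),
                  pads)
  }
  grid <- expand.grid(idx = seq_len(nrow(pads)), particle = cfg$particles,
                      energy_keV = cfg$energies, stringsAsFactors = FALSE)
  out <- cbind(pads[grid$idx, ], grid[c("particle", "energy_keV")])
  out$n <- cfg$n
  out$run <- seq_len(nrow(out))
  out$seed <- as.integer((as.numeric(cfg$seed) + 7919 * out$run) %% 2147483647)
  rownames(out) <- NULL
  out
}

.config_stack <- function(row) {
  if (row$pad_id == "no-pad") return(build_stack())
  fs <- parse_filler_state(row$filler_state)
  build_stack(make_pad_material(row$polymer, fs$filler, fs$wt),
              row$thickness)
}

#' Run a configuration sweep
#'
#' Executes every run of \code{\link{enumerate_configs}} and returns the
#' long-format result table: one record per configuration x particle x
#' energy x layer, with per-primary means and batch standard errors, plus
#' escape accounts per run.
#'
#' @param cfg a \code{padmc_sweep_config}
#' @param physics transport options
#' @param batches batches per run
#' @param progress print one line per run
#' @return an object of class \code{padmc_sweep} (a data frame with
#'   attributes \code{escapes} and \code{config})
#' @export
run_sweep <- function(cfg, physics = transport_physics(), batches = 10,
                      progress = FALSE) {
  runs <- enumerate_configs(cfg)
  res <- vector("list", nrow(runs))
  escs <- vector("list", nrow(runs))
  for (i in seq_len(nrow(runs))) {
    row <- runs[i, ]
    if (progress) {
      message(sprintf("[%d/%d] %s %s %g keV", i, nrow(runs), row$pad_id,
                      row$particle, row$energy_keV))
    }
    tl <- run_beam(beam_spec(row$particle, row$energy_keV, row$n, row$seed),
                   .config_stack(row), physics, batches)
    res[[i]] <- cbind(row[c("pad_id", "polymer", "filler_state",
                            "thickness", "particle", "energy_keV")],
                      tl$layers, n = tl$n, row.names = NULL)
    escs[[i]] <- cbind(row[c("pad_id", "particle", "energy_keV")],
                       tl$escapes, row.names = NULL)
  }
  out <- do.call(rbind, res)
  structure(out, escapes = do.call(rbind, escs), config = cfg,
            class = c("padmc_sweep", "data.frame"))
}

.sweep_record <- function(sweep, pad_id, layer, energy_keV, particle) {
  i <- sweep$pad_id == pad_id & sweep$layer == layer &
    sweep$energy_keV == energy_keV & sweep$particle == particle
  if (!any(i)) {
    stop(sprintf("no record for (%s, %s, %g keV, %s)", pad_id, layer,
                 energy_keV, particle), call. = FALSE)
  }
  sweep[which(i)[1], ]
}

#' Percent change of a layer dose relative to the No-Pad control
#'
#' 100 (mean_pad - mean_nopad) / mean_nopad with first-order propagated
#' standard error. Positive values are dose enhancement, negative values
#' shielding.
#'
#' @param sweep a \code{padmc_sweep} containing both records
#' @param pad_id pad identifier as in \code{enumerate_configs}
#' @param layer layer name
#' @param energy_keV beam energy
#' @param particle "photon" or "electron"
#' @return named numeric c(percent, se)
#' @export
relative_metric <- function(sweep, pad_id, layer, energy_keV, particle) {
  pad <- .sweep_record(sweep, pad_id, layer, energy_keV, particle)
  ref <- .sweep_record(sweep, "no-pad", layer, energy_keV, particle)
  if (ref$mean_MeV <= 0) stop("No-Pad mean is zero", call. = FALSE)
  pct <- 100 * (pad$mean_MeV - ref$mean_MeV) / ref$mean_MeV
  se <- 100 * sqrt((pad$se_MeV / ref$mean_MeV)^2 +
                   (pad$mean_MeV * ref$se_MeV / ref$mean_MeV^2)^2)
  c(percent = pct, se = se)
}

#' All relative metrics of a sweep
#'
#' Applies \code{\link{relative_metric}} to every pad record that has a
#' matching No-Pad control.
#'
#' @param sweep a \code{padmc_sweep}
#' @return data frame with pad descriptors and \code{percent}, \code{se}
#' @export
relative_metrics <- function(sweep) {
  ctl_layers <- unique(sweep$layer[sweep$pad_id == "no-pad"])
  pads <- sweep[sweep$pad_id != "no-pad" & sweep$layer %in% ctl_layers, ]
  out <- pads[c("pad_id", "polymer", "filler_state", "thickness",
                "particle", "energy_keV", "layer")]
  vals <- t(mapply(function(p, l, e, pa) {
    relative_metric(sweep, p, l, e, pa)
  }, pads$pad_id, pads$layer, pads$energy_keV, pads$particle))
  out$percent <- vals[, 1]
  out$se <- vals[, 2]
  rownames(out) <- NULL
  out
}

#' Pad-layer energy-deposition heatmap matrix
#'
#' Mean energy deposited inside the pad itself (MeV per primary), as a
#' matrix with one row per pad composition (polymer x filler state) and
#' one column per beam energy, for one particle type and thickness. The
#' No-Pad control has no pad layer and is excluded.
#'
#' @param sweep a \code{padmc_sweep} containing pad-layer records
#' @param particle "photon" or "electron"
#' @param thickness pad thickness (mm) to slice
#' @return numeric matrix (compositions x energies)
#' @export
pad_heatmap <- function(sweep, particle, thickness) {
  sub <- sweep[sweep$layer == "pad" & sweep$particle == particle &
               !is.na(sweep$thickness) & sweep$thickness == thickness, ]
  if (!nrow(sub)) stop("no pad-layer records in this slice", call. = FALSE)
  comp <- unique(sub[c("polymer", "filler_state")])
  rn <- ifelse(comp$filler_state == "none", comp$polymer,
               paste0(comp$polymer, "+", comp$filler_state))
  en <- sort(unique(sub$energy_keV))
  m <- matrix(NA_real_, nrow(comp), length(en),
              dimnames = list(rn, paste0(en, " keV")))
  for (i in seq_len(nrow(comp))) {
    for (j in seq_along(en)) {
      r <- sub[sub$polymer == comp$polymer[i] &
               sub$filler_state == comp$filler_state[i] &
               sub$energy_keV == en[j], ]
      if (nrow(r)) m[i, j] <- r$mean_MeV[1]
    }
  }
  m
}

#' Plot a pad-layer heatmap
#'
#' Base-graphics rendering of \code{\link{pad_heatmap}} with the
#' per-primary normalization stated on the axis label.
#'
#' @param m matrix from \code{\link{pad_heatmap}}
#' @param main plot title
#' @export
plot_pad_heatmap <- function(m, main = "Pad-layer energy deposition") {
  op <- par(mar = c(4, 10, 3, 2))
  on.exit(par(op))
  image(x = seq_len(ncol(m)), y = seq_len(nrow(m)), z = t(m),
        col = hcl.colors(64, "YlOrRd", rev = TRUE), axes = FALSE,
        xlab = "beam energy", ylab = "", main = main)
  axis(1, at = seq_len(ncol(m)), labels = colnames(m))
  axis(2, at = seq_len(nrow(m)), labels = rownames(m), las = 2,
       cex.axis = 0.7)
  text(rep(seq_len(ncol(m)), each = nrow(m)),
       rep(seq_len(nrow(m)), ncol(m)),
       labels = signif(as.vector(m), 2), cex = 0.5)
  invisible(m)
}

#' Per-layer shielding effectiveness table
#'
#' Percent dose reduction versus the No-Pad control (the negated relative
#' metric, so +100\% is complete absorption) for every pad configuration,
#' layer, particle and energy in the sweep.
#'
#' @param sweep a \code{padmc_sweep}
#' @return data frame with \code{reduction_percent} (positive = dose
#'   lowered relative to No Pad) and its standard error
#' @export
attenuation_summary <- function(sweep) {
  rm <- relative_metrics(sweep)
  rm$reduction_percent <- -rm$percent
  rm$percent <- NULL
  rm
}
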