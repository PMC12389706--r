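# Plain-text serialization: materials library round trip and tally/sweep
# export.

#' Write a materials library to JSON
#'
#' Full double precision (no rounding), so the round trip through
#' \code{\link{read_materials_json}} is lossless to better than 1e-12.
#'
#' @param materials list of \code{padmc_material}
#' @param path output file
#' @export
write_materials_json <- function(materials, path) {
  if (inherits(materials, "padmc_material")) materials <- list(materials)
  recs <- lapply(materials, function(m) {
    list(name = m$name, density = m$density, provenance = m$provenance,
         mass_fractions = as.list(m$composition))
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a materials library from JSON
#'
#' Accepts records carrying either explicit \code{mass_fractions} or a
#' stoichiometric \code{formula}.
#'
#' @param path JSON file written by \code{\link{write_materials_json}} or
#'   hand-authored in the same dialect
#' @return list of \code{padmc_material}
#' @export
read_materials_json <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(recs, function(r) {
    w <- if (!is.null(r$mass_fractions)) {
      unlist(r$mass_fractions)
    } else if (!is.null(r$formula)) {
      composition_from_formula(unlist(r$formula))
    } else stop("material record needs mass_fractions or formula",
                call. = FALSE)
    prov <- if (is.null(r$provenance)) "derived-mixture" else r$provenance
    material(r$name, r$density, w / sum(w), provenance = prov)
  })
}

#' Export a tally as columnar text
#'
#' One row per layer plus the two escape accounts: configuration id,
#' layer, mean MeV/primary, standard error, N.
#'
#' @param tally a \code{padmc_tally}
#' @param path CSV output file
#' @param id configuration identifier recorded in the file
#' @export
write_tally_csv <- function(tally, path, id = "run") {
  df <- rbind(
    data.frame(config = id, layer = tally$layers$layer,
               mean_MeV = tally$layers$mean_MeV,
               se_MeV = tally$layers$se_MeV, stringsAsFactors = FALSE),
    data.frame(config = id, layer = tally$escapes$account,
               mean_MeV = tally$escapes$mean_MeV,
               se_MeV = tally$escapes$se_MeV, stringsAsFactors = FALSE)
  )
  df$n <- tally$n
  df$particle <- tally$particle
  df$energy_keV <- tally$energy_keV
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a sweep result for machine use
#'
#' JSON with the long-format records, escape accounts and run metadata.
#'
#' @param sweep a \code{padmc_sweep}
#' @param path JSON output file
#' @export
write_sweep_json <- function(sweep, path) {
  cfg <- attr(sweep, "config")
  jsonlite::write_json(
    list(records = as.data.frame(sweep),
         escapes = attr(sweep, "escapes"),
         meta = list(seed = cfg$seed, n_histories = cfg$n,
                     engine = as.character(utils::packageVersion("padMC")))),
    path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}
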