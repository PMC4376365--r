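#' Write a lattice snapshot as a legacy VTK image-data file
#'
#' One scalar point field per substrate concentration, per-state volume
#' fraction and per-state growth rate, on the structured-points geometry
#' of the lattice (ASCII legacy VTK, readable by ParaView/VisIt).
#'
#' @param lattice a `colony_lattice`
#' @param path output file
#' @return the path, invisibly
#' @export
write_vtk <- function(lattice, path) {
  cfg <- lattice$config
  d <- cfg$dims
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "colonyFBA lattice snapshot",
               "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", d[1], d[2], d[3]),
               sprintf("ORIGIN %g %g %g", cfg$lambda / 2, cfg$lambda / 2, cfg$lambda / 2),
               sprintf("SPACING %g %g %g", cfg$lambda, cfg$lambda, cfg$lambda),
               sprintf("POINT_DATA %d", prod(d))), con)
  emit <- function(name, a) {
    writeLines(c(sprintf("SCALARS %s double 1", name), "LOOKUP_TABLE default"), con)
    writeLines(paste(format(as.numeric(a), digits = 8, trim = TRUE,
                            scientific = TRUE), collapse = " "), con)
  }
  emit("site_type", lattice$site_type)
  for (nm in names(lattice$ext)) emit(paste0("conc_", nm), lattice$ext[[nm]])
  for (id in names(lattice$rho)) {
    emit(paste0("rho_", id), lattice$rho[[id]])
    if (!is.null(lattice$growth[[id]])) emit(paste0("growth_", id), lattice$growth[[id]])
  }
  invisible(path)
}

#' Read a simulation configuration file
#'
#' YAML with sections `lattice` (any [lattice_config()] argument),
#' `substrates` (a map of substrate name to [substrate_spec()] arguments;
#' omitted fields fall back to the built-in glucose/oxygen/acetate
#' defaults), `states` (a map of state id to reaction-bound overrides) and
#' `run` (e.g. `hours`, `variant`, `glucose_g_per_l`). All defaults are
#' baked in, so an empty file is a valid full-scale configuration.
#'
#' @param path YAML file
#' @return list with `config`, `substrates`, `states`, `run`
#' @export
read_sim_config <- function(path) {
  y <- if (is.null(path)) list() else yaml::read_yaml(path)
  lat_args <- y$lattice %||% list()
  config <- do.call(lattice_config, lat_args)
  glc_b <- if (!is.null(y$run$glucose_g_per_l))
    mass_conc_to_molar(y$run$glucose_g_per_l, MOLAR_MASS_GLUCOSE) else 1.39e-2
  substrates <- default_substrates(glc_boundary = glc_b)
  for (nm in names(y$substrates)) {
    args <- y$substrates[[nm]]
    base <- if (nm %in% names(substrates)) unclass(substrates[[nm]]) else list(name = nm)
    base$vmax_volumetric <- NULL
    base[names(args)] <- args
    substrates[[nm]] <- do.call(substrate_spec, base)
  }
  states <- lapply(names(y$states %||% list()), function(id) {
    ov <- lapply(y$states[[id]], function(b) c(b[[1]], b[[2]]))
    cell_state(id, overrides = ov)
  })
  list(config = config, substrates = substrates, states = states,
       run = y$run %||% list())
}
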