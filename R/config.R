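#' Read and validate a run configuration
#'
#' Run configurations are YAML (or JSON) with sections `geometry`,
#' `materials`, `illumination`, `transport`, `integration`, `output` and a
#' top-level `seed`. Unknown keys are rejected so typos fail loudly. All
#' lengths are nm; rotation is given as ZYX Euler angles in degrees.
#'
#' @param path file path to a YAML/JSON run configuration.
#' @return validated config list of class `run_config`, with defaults filled.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

run_config_defaults <- function() {
  list(
    schema_version = 1L,
    seed = 1L,
    geometry = list(radius_nm = 1000, lattice_nm = 400,
                    rotation = c(0, 0, 0), phase_offset = c(0, 0, 0)),
    materials = list(n_A = 1.33, n_B = 1.48, n_exterior = 1.33,
                     wall = "reference"),
    illumination = list(wavelength_nm = 550, spacing_nm = 10,
                        polarization = c(1, 0)),
    transport = list(strategy = "ii", epsilon = 1e-9, max_depth = 60),
    integration = list(planes_nm = seq(500, 6000, by = 100),
                       pixel_nm = NULL, model = "first_order"),
    output = list(dir = ".", prefix = "run")
  )
}

#' @rdname read_run_config
#' @param cfg a raw configuration list.
#' @export
validate_run_config <- function(cfg) {
  def <- run_config_defaults()
  bad_top <- setdiff(names(cfg), names(def))
  if (length(bad_top))
    stop("unknown config keys: ", paste(bad_top, collapse = ", "))
  for (sec in names(def)) {
    if (is.list(def[[sec]]) && !is.null(cfg[[sec]])) {
      bad <- setdiff(names(cfg[[sec]]), names(def[[sec]]))
      if (length(bad))
        stop(sprintf("unknown keys in `%s`: %s", sec, paste(bad, collapse = ", ")))
      def[[sec]] <- utils::modifyList(def[[sec]], cfg[[sec]])
    } else if (!is.null(cfg[[sec]])) {
      def[[sec]] <- cfg[[sec]]
    }
  }
  g <- def$geometry
  if (!is.numeric(g$radius_nm) || g$radius_nm <= 0)
    stop("geometry.radius_nm: must be a positive number")
  if (!is.numeric(g$lattice_nm) || g$lattice_nm <= 0)
    stop("geometry.lattice_nm: must be a positive number")
  m <- def$materials
  for (f in c("n_A", "n_B", "n_exterior"))
    if (!is.numeric(m[[f]]) || m[[f]] < 1)
      stop("materials.", f, ": refractive index must be >= 1")
  if (!def$transport$strategy %in% c("i", "ii", "iii"))
    stop("transport.strategy: must be one of i, ii, iii")
  structure(def, class = "run_config")
}

#' Build the model described by a run configuration
#' @param cfg a `run_config`.
#' @return a `mitochondrion_model`.
#' @export
model_from_config <- function(cfg) {
  g <- cfg$geometry
  m <- cfg$materials
  lat <- gyroid_lattice(g$lattice_nm,
                        rotation_zyx(g$rotation[1], g$rotation[2], g$rotation[3]),
                        g$phase_offset)
  wall <- if (identical(m$wall, "reference")) NULL
          else list(n = vapply(m$wall, `[[`, numeric(1), 1),
                    d = vapply(m$wall, `[[`, numeric(1), 2))
  build_mitochondrion(radius = g$radius_nm, lattice = lat,
                      n_A = m$n_A, n_B = m$n_B, n_exterior = m$n_exterior,
                      wall = wall)
}

#' Write a reproducibility manifest
#'
#' Captures the full configuration, seed, package version and the energy
#' ledger of a run; a run can be replayed from its manifest alone.
#'
#' @param path output JSON path.
#' @param cfg the `run_config` used.
#' @param extra named list of additional fields (ledger, fitted parameters,
#'   warnings, ...).
#' @return the path, invisibly.
#' @export
write_manifest <- function(path, cfg, extra = list()) {
  man <- c(list(package = "mitolens",
                version = as.character(utils::packageVersion("mitolens")),
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                config = unclass(cfg)),
           extra)
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}
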