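# Configuration loading, trajectory CSV round-trip and run manifests.
# CSV dialect: comma-separated, UTF-8, header row, '.' decimal, numbers
# written with 17 significant digits so doubles round-trip exactly. Nested
# structures go through JSON/YAML.

default_config <- function() {
  list(
    constants = unclass(physical_constants()),
    field = list(B = 0, direction_angle = pi / 2),
    geometry = list(a = 300, b = 150),
    spindle = list(center = c(0, 0), alpha = 0, half_separation = 30),
    dynamics = unclass(dynamic_instability_params()),
    forces = unclass(force_params()),
    sim = list(dt = 0.5, t_max = 1500, n_mt = 100, seed = 1, ensemble_n = 20,
               speedup = 25, stride = 1, cortex_tol = 0.5)
  )
}

merge_section <- function(base, new, path) {
  unknown <- setdiff(names(new), names(base))
  if (length(unknown))
    abort_config(sprintf("unknown configuration key%s: %s",
                         if (length(unknown) > 1) "s" else "",
                         paste0(path, unknown, collapse = ", ")))
  for (nm in names(new)) {
    if (is.list(base[[nm]]) && is.list(new[[nm]])) {
      base[[nm]] <- merge_section(base[[nm]], new[[nm]],
                                  paste0(path, nm, "."))
    } else {
      base[[nm]] <- new[[nm]]
    }
  }
  base
}

#' Load and resolve a simulation configuration
#'
#' Precedence: package defaults, then the YAML file, then `overrides`
#' (highest). Unknown keys at any level are rejected with the offending
#' key named.
#'
#' @param path Path to a YAML configuration file, or `NULL` for pure
#'   defaults. An empty file also yields the defaults.
#' @param overrides Named nested list applied on top of the file, mirroring
#'   the configuration sections (`constants`, `field`, `geometry`,
#'   `spindle`, `dynamics`, `forces`, `sim`).
#' @return Resolved nested configuration list (class `spindlemag_config`).
#' @seealso [config_objects()] to turn the resolved list into model objects.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  conf <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) abort_config(sprintf("no such config file: %s", path))
    loaded <- yaml::read_yaml(path)
    if (!is.null(loaded)) conf <- merge_section(conf, loaded, "")
  }
  if (length(overrides)) conf <- merge_section(conf, overrides, "")
  structure(conf, class = "spindlemag_config")
}

#' Build model objects from a resolved configuration
#'
#' @param conf A resolved configuration from [load_config()].
#' @return List with `consts`, `field`, `geom`, `init`, `di`, `fp`, `cfg`.
#' @export
config_objects <- function(conf) {
  consts <- do.call(physical_constants, conf$constants)
  field <- do.call(field_spec, conf$field)
  geom <- do.call(cell_geometry, conf$geometry)
  init <- spindle_state(unlist(conf$spindle$center), conf$spindle$alpha,
                        conf$spindle$half_separation, geom)
  di <- do.call(dynamic_instability_params, conf$dynamics)
  fp <- do.call(force_params, conf$forces)
  cfg <- do.call(sim_config, c(conf$sim, list(field = field)))
  list(consts = consts, field = field, geom = geom, init = init,
       di = di, fp = fp, cfg = cfg)
}

#' Write a trajectory to CSV
#'
#' Columns `t_s`, `d_um`, `alpha_rad`; numbers carry 17 significant digits
#' so that [read_trajectory()] recovers them bit-exactly.
#'
#' @param traj A `spindle_trajectory` (or any list with `t`, `d`, `alpha`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  lines <- c("t_s,d_um,alpha_rad",
             if (length(traj$t))
               sprintf("%.17g,%.17g,%.17g", traj$t, traj$d, traj$alpha))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a trajectory CSV written by [write_trajectory()]
#'
#' @param path CSV path.
#' @return A `spindle_trajectory` (metadata limited to the source path).
#'   Malformed or non-finite rows raise a `parse_error` naming the line.
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) abort_parse(sprintf("no such file: %s", path))
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines) || lines[1] != "t_s,d_um,alpha_rad")
    abort_parse(sprintf("%s: expected header 't_s,d_um,alpha_rad'", path))
  body <- lines[-1]
  body <- body[nzchar(body)]
  n <- length(body)
  t <- d <- a <- numeric(n)
  for (i in seq_len(n)) {
    parts <- strsplit(body[i], ",", fixed = TRUE)[[1]]
    vals <- suppressWarnings(as.numeric(parts))
    if (length(vals) != 3L || anyNA(vals) || any(!is.finite(vals)))
      abort_parse(sprintf("%s: malformed row at line %d", path, i + 1L))
    t[i] <- vals[1]; d[i] <- vals[2]; a[i] <- vals[3]
  }
  structure(list(t = t, d = d, alpha = a, meta = list(source = path)),
            class = "spindle_trajectory")
}

#' Write a run manifest
#'
#' Ties outputs to the resolved configuration and seeds that produced
#' them; re-running with the manifest's config and seeds reproduces the
#' outputs bitwise.
#'
#' @param path Output JSON path.
#' @param config Resolved configuration list.
#' @param seeds Integer seeds used.
#' @param outputs Character vector of output file paths (checksummed).
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, config, seeds, outputs = character()) {
  existing <- outputs[file.exists(outputs)]
  manifest <- list(
    package = "spindlemag",
    version = as.character(utils::packageVersion("spindlemag")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seeds = as.integer(seeds),
    config = config,
    outputs = if (length(existing))
      data.frame(path = existing,
                 md5 = unname(tools::md5sum(existing)),
                 bytes = unname(file.size(existing)))
    else data.frame(path = character(), md5 = character(), bytes = numeric())
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a run manifest
#' @param path Manifest JSON path.
#' @return The manifest as a list.
#' @export
read_run_manifest <- function(path) {
  if (!file.exists(path)) abort_parse(sprintf("no such file: %s", path))
  jsonlite::read_json(path, simplifyVector = TRUE)
}
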