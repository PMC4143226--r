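#' Read and write recordings and CSD estimates as delimited text
#'
#' Plain-text serialization: a short `#`-prefixed header carrying the
#' sampling interval, conductivity and lateral offset, followed by a
#' tab-separated table whose first column is depth (um) and remaining
#' columns are time samples. Round-trips at full double precision.
#'
#' @param recording a [potential_recording()].
#' @param path file path.
#' @return `write_*` return the path invisibly; `read_*` return the object.
#' @name recording_io
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "potential_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# lampop potential_recording"),
    sprintf("# dt_ms %.17g", recording$dt),
    sprintf("# sigma_S_per_m %.17g", recording$sigma),
    sprintf("# lateral_um %.17g %.17g", recording$array$lateral[1],
            recording$array$lateral[2])), con)
  utils::write.table(
    cbind(depth = recording$array$depths, recording$values),
    con, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname recording_io
#' @export
read_recording <- function(path) {
  hdr <- readLines(path, n = 4L)
  if (!startsWith(hdr[1], "# lampop potential_recording")) {
    stop("not a lampop recording file")
  }
  dt <- as.numeric(strsplit(hdr[2], " ")[[1]][3])
  sigma <- as.numeric(strsplit(hdr[3], " ")[[1]][3])
  lateral <- as.numeric(strsplit(hdr[4], " ")[[1]][3:4])
  tab <- utils::read.table(path, sep = "\t", comment.char = "#")
  vals <- unname(as.matrix(tab[, -1, drop = FALSE]))
  potential_recording(electrode_array(tab[[1]], lateral = lateral),
                      vals, sigma, dt)
}

#' @rdname recording_io
#' @param csd a [csd_estimate()].
#' @export
write_csd <- function(csd, path) {
  stopifnot(inherits(csd, "csd_estimate"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# lampop csd_estimate"),
    sprintf("# dt_ms %.17g", csd$dt),
    sprintf("# lambda %.17g", csd$lambda)), con)
  utils::write.table(cbind(grid = csd$grid, csd$values), con, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname recording_io
#' @export
read_csd <- function(path) {
  hdr <- readLines(path, n = 3L)
  if (!startsWith(hdr[1], "# lampop csd_estimate")) {
    stop("not a lampop CSD file")
  }
  dt <- as.numeric(strsplit(hdr[2], " ")[[1]][3])
  lambda <- as.numeric(strsplit(hdr[3], " ")[[1]][3])
  tab <- utils::read.table(path, sep = "\t", comment.char = "#")
  csd_estimate(tab[[1]], unname(as.matrix(tab[, -1, drop = FALSE])),
               lambda = lambda, dt = dt)
}

#' Scenario files
#'
#' Scenarios serialize to a structured YAML file naming every population
#' (depth range, source count, rank, amplitude, temporal class, frequency,
#' latency, dipole extent), the column geometry, the electrode array and
#' the global parameters; reading it back reproduces the scenario
#' losslessly.
#'
#' @param scenario a `lampop_scenario`.
#' @param path file path.
#' @name scenario_io
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "lampop_scenario"))
  obj <- list(
    populations = lapply(scenario$specs, function(s) {
      list(name = s$name, depth_range = s$depth_range,
           n_sources = s$n_sources, rank = s$rank, amplitude = s$amplitude,
           temporal = s$temporal, frequency = s$frequency,
           delay_ms = s$delay_ms, dipole_extent = s$dipole_extent)
    }),
    geometry = list(
      layer = scenario$geometry$layers$layer,
      top = scenario$geometry$layers$top,
      bottom = scenario$geometry$layers$bottom,
      radius = scenario$geometry$radius),
    array = list(depths = scenario$array$depths,
                 lateral = scenario$array$lateral),
    sigma = scenario$sigma, dt = scenario$dt, duration = scenario$duration,
    coupling = scenario$coupling, seed = scenario$seed)
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname scenario_io
#' @export
read_scenario <- function(path) {
  obj <- yaml::read_yaml(path)
  specs <- lapply(obj$populations, function(p) {
    population_spec(p$name, p$depth_range, n_sources = p$n_sources,
                    rank = p$rank, amplitude = p$amplitude,
                    temporal = p$temporal, frequency = p$frequency,
                    delay_ms = p$delay_ms, dipole_extent = p$dipole_extent)
  })
  geometry <- column_geometry(
    tibble::tibble(layer = obj$geometry$layer, top = obj$geometry$top,
                   bottom = obj$geometry$bottom),
    radius = obj$geometry$radius)
  structure(list(
    specs = specs, geometry = geometry,
    array = electrode_array(obj$array$depths, lateral = obj$array$lateral),
    sigma = obj$sigma, dt = obj$dt, duration = obj$duration,
    coupling = obj$coupling, seed = obj$seed),
    class = "lampop_scenario")
}

#' Dataset container on disk
#'
#' Writes a ground-truth dataset as a directory tree of delimited text
#' files mirroring its structure: `total/lfp.tsv`, `total/lfp_noisy.tsv`
#' (when noise was applied) and `population/<name>/{positions,currents,
#' lfp}`, plus the generating scenario metadata in `meta.yaml`.
#'
#' @param dataset a `ground_truth_dataset`.
#' @param dir directory to create.
#' @name dataset_io
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "ground_truth_dataset"))
  dir.create(file.path(dir, "total"), recursive = TRUE, showWarnings = FALSE)
  write_recording(dataset$lfp_clean, file.path(dir, "total", "lfp.tsv"))
  if (dataset$noise_percent > 0) {
    write_recording(dataset$lfp, file.path(dir, "total", "lfp_noisy.tsv"))
  }
  for (nm in names(dataset$populations)) {
    p <- dataset$populations[[nm]]
    safe <- gsub("[^A-Za-z0-9_-]", "_", nm)
    pd <- file.path(dir, "population", safe)
    dir.create(pd, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(p$sources$positions, file.path(pd, "positions.tsv"),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
    utils::write.table(p$sources$currents, file.path(pd, "currents.tsv"),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
    write_recording(p$lfp, file.path(pd, "lfp.tsv"))
  }
  yaml::write_yaml(list(
    populations = names(dataset$populations),
    noise_percent = dataset$noise_percent, seed = dataset$seed,
    dt = dataset$dt, sigma = dataset$sigma), file.path(dir, "meta.yaml"))
  invisible(dir)
}
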