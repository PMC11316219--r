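fmt17 <- function(x) {
  out <- vapply(x, function(v) sprintf("%.17g", v), character(1))
  out[is.na(x)] <- "NA"
  out
}

#' Write a trajectory to CSV
#'
#' Deterministic formatting (17 significant digits), one row per generation,
#' header `generation,sigma2_0,sigma_0,mu,total_deficit,injected_mass`.
#'
#' @param traj A `recursion_trajectory`, `sim_result`, or trajectory
#'   data.frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  tr <- trajectory_frame(traj)
  cols <- c("generation", "sigma2_0", "sigma_0", "mu",
            "total_deficit", "injected_mass")
  lines <- c(paste(cols, collapse = ","),
             vapply(seq_len(nrow(tr)), function(i) {
               paste(c(sprintf("%d", tr$generation[i]),
                       fmt17(as.numeric(tr[i, cols[-1L]]))), collapse = ",")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a trajectory CSV
#' @param path CSV file written by [write_trajectory()].
#' @return A trajectory data.frame.
#' @export
read_trajectory <- function(path) {
  utils::read.csv(path, colClasses = "numeric")
}

#' Write full-spectrum snapshots to CSV (long format)
#'
#' Header `generation,k,one_minus_sigma2`; snapshots are taken by
#' [iterate_recursion()] at power-of-2 generations.
#'
#' @param traj A `recursion_trajectory` run with `snapshots = TRUE`, or a
#'   named list of deficit vectors keyed by generation.
#' @param path Output file; a `.gz` suffix writes a gzip-compressed file.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(traj, path) {
  spectra <- if (inherits(traj, "recursion_trajectory")) traj$spectra else traj
  if (is.null(spectra) || !length(spectra))
    stop("no spectrum snapshots recorded (run with snapshots = TRUE)")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines("generation,k,one_minus_sigma2", con)
  for (gname in names(spectra)) {
    d <- spectra[[gname]]
    writeLines(paste(gname, seq_along(d) - 1L, fmt17(d), sep = ","), con)
  }
  invisible(path)
}

#' Write the empirical spectrum of a simulation to CSV
#'
#' Header `generation,k,emp_variance,std_err`.
#'
#' @param sim A `sim_result`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sim_spectrum <- function(sim, path) {
  sp <- if (inherits(sim, "sim_result")) sim$spectrum else sim
  lines <- c("generation,k,emp_variance,std_err",
             paste(sp$generation, sp$k, fmt17(sp$emp_variance),
                   fmt17(sp$std_err), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Write a run manifest
#'
#' Records the subcommand, the full parameter set, seeds, timestamps, output
#' paths and the package version, so that every run is reconstructible from
#' its manifest alone. Written even on failure, with an `error` field.
#'
#' @param path Output JSON file.
#' @param subcommand Subcommand name.
#' @param params Named list of parameters.
#' @param outputs Character vector of output file paths.
#' @param started,finished POSIXct timestamps.
#' @param error `NULL` on success, or an error message.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, subcommand, params, outputs,
                           started = Sys.time(), finished = Sys.time(),
                           error = NULL) {
  manifest <- list(
    subcommand = subcommand,
    params = params,
    outputs = as.list(outputs),
    started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(finished, "%Y-%m-%dT%H:%M:%S%z"),
    elapsed_seconds = as.numeric(difftime(finished, started, units = "secs")),
    package_version = as.character(utils::packageVersion("linkinf")),
    error = error)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a flat key-value YAML configuration file
#'
#' The configuration mirrors the CLI flags of the corresponding subcommand
#' (e.g. `cutoff: 8192`, `generations: 2048`, `beta: 1`).
#'
#' @param path YAML file.
#' @return A named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a flat key-value mapping")
  cfg
}
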