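#' Read an event-timing CSV
#'
#' Expected columns: `unit_id`, `temperature_c`, `interval_name`,
#' `duration_min`. Temperatures are degrees Celsius, durations minutes.
#'
#' @param path CSV file path.
#' @return a [timing_dataset()].
#' @export
read_timing_csv <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- read.csv(path)
  need <- c("unit_id", "temperature_c", "interval_name", "duration_min")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns in ", path, ": ",
                         paste(miss, collapse = ", "))
  timing_dataset(df$unit_id, df$temperature_c, df$duration_min,
                 interval_name = df$interval_name)
}

#' Write an event-timing CSV
#' @param ds a `timing_dataset`.
#' @param path output path.
#' @export
write_timing_csv <- function(ds, path) {
  write.csv(as.data.frame(ds), path, row.names = FALSE)
  invisible(path)
}

#' Write droplet recordings as a long series CSV plus a metadata CSV
#'
#' The long format (`droplet_id`, `time_min`, `fret_ratio`) plus metadata
#' (`droplet_id`, `radius_um`, `track_start_min`, `temperature_c`) matches
#' a flat export of droplet tracking tables.
#'
#' @param droplets list of [droplet_record()]s.
#' @param series_path,meta_path output paths.
#' @export
write_droplets_csv <- function(droplets, series_path, meta_path) {
  ser <- do.call(rbind, lapply(droplets, function(d)
    data.frame(droplet_id = d$droplet_id, time_min = d$time_min,
               fret_ratio = d$fret_ratio)))
  meta <- do.call(rbind, lapply(droplets, function(d)
    data.frame(droplet_id = d$droplet_id, radius_um = d$radius_um,
               track_start_min = d$track_start_min,
               temperature_c = d$temperature_c)))
  write.csv(ser, series_path, row.names = FALSE)
  write.csv(meta, meta_path, row.names = FALSE)
  invisible(c(series_path, meta_path))
}

#' Read droplet recordings from series + metadata CSVs
#' @param series_path,meta_path paths written by [write_droplets_csv()].
#' @return list of [droplet_record()]s.
#' @export
read_droplets_csv <- function(series_path, meta_path) {
  for (p in c(series_path, meta_path))
    if (!file.exists(p)) stop("input file not found: ", p)
  ser <- read.csv(series_path)
  meta <- read.csv(meta_path)
  lapply(seq_len(nrow(meta)), function(j) {
    id <- meta$droplet_id[j]
    s <- ser[ser$droplet_id == id, , drop = FALSE]
    s <- s[order(s$time_min), , drop = FALSE]
    droplet_record(id, meta$radius_um[j], meta$track_start_min[j],
                   meta$temperature_c[j], s$time_min, s$fret_ratio)
  })
}

#' Write a period curve as tidy CSV
#' @param curve a `period_curve`.
#' @param path output path.
#' @export
write_period_curve_csv <- function(curve, path) {
  df <- data.frame(temperature_c = curve$temperature_c,
                   period_min = curve$period,
                   rising_min = curve$rising,
                   falling_min = curve$falling,
                   oscillating = curve$oscillating)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a trajectory as tidy CSV
#' @param sim a `cellcycle_sim`.
#' @param path output path.
#' @export
write_sim_csv <- function(sim, path) {
  write.csv(as.data.frame(sim)[, c("time", "cyc", "cdk1a")], path,
            row.names = FALSE)
  invisible(path)
}

#' Write an ABC posterior as CSV (one row per particle)
#' @param ps an `abc_posterior`.
#' @param path output path.
#' @export
write_posterior_csv <- function(ps, path) {
  write.csv(as.data.frame(ps), path, row.names = FALSE)
  invisible(path)
}

#' Write a reproducibility manifest
#'
#' JSON record of the configuration, seed and package version beside every
#' run output; the manifest suffices to reproduce the run.
#'
#' @param path output path (.json).
#' @param config named list of run settings.
#' @param seed the seed used.
#' @export
write_manifest <- function(path, config, seed) {
  manifest <- list(package = "oscitemp",
                   version = as.character(packageVersion("oscitemp")),
                   seed = seed, config = config,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
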