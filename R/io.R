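# Plain-text file interfaces. Time-series and event tables are
# tab-delimited text with a one-line header; times are seconds from the
# recording start.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE)
}

#' Write a tag recording to delimited text files
#'
#' Writes the fast stream (`time_s, ax_g, ay_g, az_g, mx, my, mz`) and slow
#' stream (`time_s, depth_m, temp_c`) as tab-delimited files.
#'
#' @param recording a `tag_recording`.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return named character vector of the written paths.
#' @export
write_recording <- function(recording, dir, prefix = "recording") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fast <- file.path(dir, paste0(prefix, "_fast.tsv"))
  slow <- file.path(dir, paste0(prefix, "_slow.tsv"))
  write_tsv(recording$fast, fast)
  write_tsv(recording$slow, slow)
  c(fast = fast, slow = slow)
}

#' Read a tag recording from delimited text files
#'
#' @param fast_path,slow_path paths written by [write_recording()].
#' @param mass_kg,mantle_length_cm animal metadata.
#' @param fs fast-stream sampling rate (Hz).
#' @return a `tag_recording`.
#' @export
read_recording <- function(fast_path, slow_path, mass_kg = NA_real_,
                           mantle_length_cm = NA_real_, fs = 100) {
  structure(list(fast = read_tsv(fast_path), slow = read_tsv(slow_path),
                 fs = fs, mass_kg = mass_kg,
                 mantle_length_cm = mantle_length_cm),
            class = "tag_recording")
}

#' Write / read a fin-event train
#'
#' Event trains are stored as `time_s, prominence, width_s`.
#'
#' @param events a `fin_events` data frame.
#' @param path file path.
#' @return `write_fin_events` the path; `read_fin_events` a `fin_events`
#'   data frame.
#' @export
write_fin_events <- function(events, path) {
  write_tsv(as.data.frame(events)[, c("time_s", "prominence", "width_s")],
            path)
}

#' @rdname write_fin_events
#' @export
read_fin_events <- function(path) {
  out <- read_tsv(path)
  class(out) <- c("fin_events", "data.frame")
  out
}

#' Write / read a classified segment table
#'
#' @param segments segment table (`start_s`, `end_s`, `state`, ...).
#' @param path file path.
#' @return `write_segments` the path; `read_segments` the table.
#' @export
write_segments <- function(segments, path) {
  write_tsv(as.data.frame(segments), path)
}

#' @rdname write_segments
#' @export
read_segments <- function(path) {
  read_tsv(path)
}

#' Write / read ground-truth labels of a synthetic recording
#'
#' @param truth a `ground_truth` (fin-event times and state intervals).
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return `write_ground_truth` the written paths; `read_ground_truth` a
#'   `ground_truth`.
#' @export
write_ground_truth <- function(truth, dir, prefix = "truth") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ev <- file.path(dir, paste0(prefix, "_events.tsv"))
  iv <- file.path(dir, paste0(prefix, "_intervals.tsv"))
  write_tsv(data.frame(time_s = truth$fin_events), ev)
  write_tsv(truth$intervals, iv)
  c(events = ev, intervals = iv)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(dir, prefix = "truth") {
  ev <- read_tsv(file.path(dir, paste0(prefix, "_events.tsv")))
  iv <- read_tsv(file.path(dir, paste0(prefix, "_intervals.tsv")))
  structure(list(fin_events = ev$time_s, intervals = iv),
            class = "ground_truth")
}

#' Write / read a respirometry trial trace
#'
#' Traces are stored as `time_s, do_mg_l, temp_c`; metadata (mass, volume,
#' motor level) travels in a separate metadata table.
#'
#' @param trial a `respirometry_trial`.
#' @param path file path.
#' @return `write_respirometry_trial` the path; `read_respirometry_trial` a
#'   `respirometry_trial` (metadata fields NA unless supplied).
#' @export
write_respirometry_trial <- function(trial, path) {
  write_tsv(trial$data, path)
}

#' @rdname write_respirometry_trial
#' @param mass_kg,volume_l trial metadata to attach on read.
#' @export
read_respirometry_trial <- function(path, mass_kg = NA_real_,
                                    volume_l = NA_real_) {
  d <- read_tsv(path)
  structure(list(data = d, mass_kg = mass_kg, volume_l = volume_l,
                 temp_c = d$temp_c[1L], is_control = is.na(mass_kg)),
            class = "respirometry_trial")
}
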