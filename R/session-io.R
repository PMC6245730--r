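# Plain-text session-directory IO. A session directory holds:
#   manifest.yaml  - metadata (fs, waveform_fs, duration_s, seed, ...)
#   spikes.tsv     - unit_id, spike_time_s (one row per spike)
#   units.tsv      - unit_id, cell_type, tagged (unit roster; keeps
#                    spike-less units representable)
#   waveforms.tsv  - unit_id, sample_index, voltage
#   lfp.tsv        - first line "fs_hz <tab> <fs>", then one sample (uV)
#                    per line
#   events.tsv     - onset_s, duration_s, intensity, kind (laser|injection)
#   wheel.tsv      - time_s, speed (optional)
# All times are seconds from recording start. Missing metric values are
# serialised as empty fields, never sentinel numbers.

#' Write a session to a directory
#'
#' @param session An `ephys_session`.
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "ephys_session"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  units <- session$units
  spikes <- tibble::tibble(
    unit_id = rep(units$unit_id, purrr::map_int(units$spike_times, length)),
    spike_time_s = unlist(units$spike_times) %||% numeric(0)
  )
  readr::write_tsv(spikes, file.path(path, "spikes.tsv"))
  readr::write_tsv(
    tibble::tibble(unit_id = units$unit_id, cell_type = units$cell_type,
                   tagged = units$tagged),
    file.path(path, "units.tsv")
  )
  waveforms <- tibble::tibble(
    unit_id = rep(units$unit_id, purrr::map_int(units$waveform, length)),
    sample_index = unlist(purrr::map(units$waveform, seq_along)) %||% integer(0),
    voltage = unlist(units$waveform) %||% numeric(0)
  )
  readr::write_tsv(waveforms, file.path(path, "waveforms.tsv"))
  lfp_lines <- c(sprintf("fs_hz\t%.17g", session$lfp$fs),
                 sprintf("%.17g", session$lfp$samples))
  writeLines(lfp_lines, file.path(path, "lfp.tsv"))
  events <- tibble::tibble(
    onset_s = c(session$pulses$onset_s, session$injection_time_s),
    duration_s = c(session$pulses$duration_s, 0),
    intensity = c(session$pulses$intensity, NA_real_),
    kind = c(rep("laser", nrow(session$pulses)), "injection")
  )
  readr::write_tsv(events, file.path(path, "events.tsv"), na = "")
  if (!is.null(session$wheel)) {
    readr::write_tsv(session$wheel, file.path(path, "wheel.tsv"))
  }
  manifest <- list(
    format = "preictal-session-v1",
    duration_s = session$duration_s,
    lfp_fs = session$lfp$fs,
    lfp_start_s = session$lfp$start_s,
    waveform_fs = session$waveform_fs,
    injection_time_s = session$injection_time_s,
    n_units = nrow(units),
    seed = if (!is.null(session$truth)) session$truth$seed else NULL
  )
  yaml::write_yaml(manifest, file.path(path, "manifest.yaml"),
                   precision = 17)
  invisible(path)
}

#' Load a session from a directory
#'
#' Validates the layout on load: exactly one injection event, monotone
#' spike times per unit, positive sampling rates.
#'
#' @param path Session directory written by [write_session()].
#' @return An `ephys_session`.
#' @export
load_session <- function(path) {
  need <- c("manifest.yaml", "spikes.tsv", "units.tsv", "waveforms.tsv",
            "lfp.tsv", "events.tsv")
  missing <- need[!file.exists(file.path(path, need))]
  if (length(missing) > 0) {
    abort(paste0("missing session file(s): ", paste(missing, collapse = ", ")),
          class = "preictal_missing_input")
  }
  manifest <- yaml::read_yaml(file.path(path, "manifest.yaml"))
  if (is.null(manifest$lfp_fs) || manifest$lfp_fs <= 0) {
    abort("manifest lfp_fs must be > 0", class = "preictal_validation_error")
  }
  spikes <- readr::read_tsv(file.path(path, "spikes.tsv"),
                            col_types = "cd", progress = FALSE)
  roster <- readr::read_tsv(file.path(path, "units.tsv"),
                            col_types = "ccl", progress = FALSE)
  waveforms <- readr::read_tsv(file.path(path, "waveforms.tsv"),
                               col_types = "cid", progress = FALSE)
  events <- readr::read_tsv(file.path(path, "events.tsv"),
                            col_types = "dddc", progress = FALSE)
  lfp_lines <- readLines(file.path(path, "lfp.tsv"))
  fs <- as.numeric(strsplit(lfp_lines[1], "\t")[[1]][2])
  samples <- as.numeric(lfp_lines[-1])
  inj <- events[events$kind == "injection", ]
  if (nrow(inj) != 1) {
    abort("events file must contain exactly one injection event",
          class = "preictal_validation_error")
  }
  units <- tibble::tibble(
    unit_id = roster$unit_id,
    cell_type = roster$cell_type,
    tagged = roster$tagged,
    spike_times = purrr::map(roster$unit_id, function(id) {
      st <- spikes$spike_time_s[spikes$unit_id == id]
      if (length(st) > 1 && is.unsorted(st)) {
        abort(sprintf("non-monotonic spike times for unit %s", id),
              class = "preictal_validation_error")
      }
      st
    }),
    waveform = purrr::map(roster$unit_id, function(id) {
      w <- waveforms[waveforms$unit_id == id, ]
      w$voltage[order(w$sample_index)]
    })
  )
  pulses <- events[events$kind == "laser", c("onset_s", "duration_s", "intensity")]
  wheel_path <- file.path(path, "wheel.tsv")
  wheel <- if (file.exists(wheel_path)) {
    readr::read_tsv(wheel_path, col_types = "dd", progress = FALSE)
  } else {
    NULL
  }
  new_ephys_session(
    units = units,
    lfp = lfp_signal(samples, fs = fs, start_s = manifest$lfp_start_s %||% 0),
    pulses = tibble::as_tibble(pulses),
    injection_time_s = inj$onset_s,
    duration_s = manifest$duration_s,
    waveform_fs = manifest$waveform_fs,
    wheel = wheel
  )
}

#' Write analysis result tables to a directory
#'
#' One delimited table per stage, with `NaN`/`NA` metric values serialised
#' as empty fields, plus a manifest echoing the run configuration.
#'
#' @param tables Named list of data frames (e.g. the tables of an
#'   [analyze_session()] result).
#' @param path Output directory.
#' @param config Optional named list echoed into the manifest (seed,
#'   thresholds actually used, ...).
#' @return `path`, invisibly.
#' @export
write_results <- function(tables, path, config = NULL) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (name in names(tables)) {
    tbl <- tables[[name]]
    if (!is.data.frame(tbl)) next
    tbl <- dplyr::mutate(tbl, dplyr::across(
      dplyr::where(is.numeric), function(x) ifelse(is.nan(x), NA, x)
    ))
    tbl <- dplyr::select(tbl, !dplyr::where(is.list))
    readr::write_tsv(tbl, file.path(path, paste0(name, ".tsv")), na = "")
  }
  manifest <- list(
    format = "preictal-results-v1",
    tables = as.list(names(tables)),
    config = config
  )
  yaml::write_yaml(manifest, file.path(path, "manifest.yaml"), precision = 17)
  invisible(path)
}
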