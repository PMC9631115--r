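#' Write a session to a directory
#'
#' Plain-text layout: `trials.csv` (one row per trial), `bouts.csv` (the
#' wheel's bout table, from which the trace reconstructs exactly), and
#' `session.json` (sampling rate, delay grid, regime mode, metadata).
#'
#' @param session a `vm_session`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(session$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  utils::write.csv(session$bouts, file.path(dir, "bouts.csv"),
                   row.names = FALSE)
  meta <- list(fs = session$fs, duration = session$wheel$duration,
               move_floor = session$move_floor,
               mouse = session$mouse, day = session$day,
               truncated = isTRUE(session$truncated),
               grid = list(iti = session$grid$iti,
                           quiescence = session$grid$quiescence,
                           increment = session$grid$increment),
               regime_mode = session$regime$mode)
  jsonlite::write_json(meta, file.path(dir, "session.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a session written by [write_session()]
#' @param dir session directory.
#' @return a `vm_session` (the `regime` field holds only the stored mode).
#' @export
read_session <- function(dir) {
  trials <- utils::read.csv(file.path(dir, "trials.csv"))
  bouts <- utils::read.csv(file.path(dir, "bouts.csv"))
  meta <- jsonlite::read_json(file.path(dir, "session.json"),
                              simplifyVector = TRUE)
  wheel <- bouts_to_trace(bouts, meta$duration, meta$fs)
  structure(list(trials = trials, wheel = wheel, bouts = bouts,
                 grid = delay_grid(meta$grid$iti, meta$grid$quiescence,
                                   meta$grid$increment),
                 regime = list(mode = meta$regime_mode),
                 move_floor = meta$move_floor, truncated = meta$truncated,
                 mouse = meta$mouse, day = meta$day, fs = meta$fs),
            class = "vm_session")
}

#' Write a frame stack as multi-page TIFF plus JSON sidecar
#'
#' Frames are stored as 32-bit float TIFF pages; frame times, illumination
#' labels and geometry go to `<stem>.json`.
#'
#' @param stack a `vm_framestack`.
#' @param path output TIFF path (sidecar written next to it).
#' @return `path`, invisibly.
#' @export
write_framestack <- function(stack, path) {
  nr <- stack$geometry[1]; nc <- stack$geometry[2]
  pages <- lapply(seq_len(ncol(stack$frames)), function(i)
    matrix(stack$frames[, i], nr, nc))
  rng <- range(stack$frames)
  offset <- rng[1]
  scale <- max(rng[2] - rng[1], .Machine$double.eps)
  tiff::writeTIFF(lapply(pages, function(p) (p - offset) / scale), path,
                  bits.per.sample = 32L)
  side <- sub("\\.tiff?$", ".json", path)
  jsonlite::write_json(list(frame_times = stack$frame_times,
                            illumination = stack$illumination,
                            geometry = stack$geometry,
                            frame_rate = stack$frame_rate,
                            intensity_scale = scale,
                            intensity_offset = offset),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a frame stack written by [write_framestack()]
#' @param path TIFF path.
#' @return a `vm_framestack` (without `truth`).
#' @export
read_framestack <- function(path) {
  side <- sub("\\.tiff?$", ".json", path)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  frames <- vapply(pages, function(p)
    as.vector(p) * meta$intensity_scale + meta$intensity_offset,
    numeric(prod(meta$geometry)))
  structure(list(frames = frames, frame_times = meta$frame_times,
                 illumination = meta$illumination,
                 geometry = meta$geometry, frame_rate = meta$frame_rate),
            class = "vm_framestack")
}

#' Write units to a phy-style directory of CSV files
#'
#' One subdirectory per unit with `spike_times.csv`, `amplitudes.csv`,
#' `waveform.csv`, and `channels.csv` (positions and per-channel
#' amplitudes).
#'
#' @param units list of `vm_unit` objects.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_units <- function(units, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_along(units)) {
    u <- units[[i]]
    ud <- file.path(dir, sprintf("unit%03d", i))
    dir.create(ud, showWarnings = FALSE)
    utils::write.csv(data.frame(spike_time = u$spike_times,
                                amplitude = u$amplitudes),
                     file.path(ud, "spikes.csv"), row.names = FALSE)
    utils::write.csv(data.frame(sample = seq_along(u$waveform),
                                value = u$waveform),
                     file.path(ud, "waveform.csv"), row.names = FALSE)
    utils::write.csv(data.frame(position = u$channel_positions,
                                amplitude = u$channel_amplitudes),
                     file.path(ud, "channels.csv"), row.names = FALSE)
    jsonlite::write_json(list(fs_wave = u$fs_wave, duration = u$duration),
                         file.path(ud, "unit.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(dir)
}

#' Read units written by [write_units()]
#' @param dir units directory.
#' @return list of `vm_unit` objects.
#' @export
read_units <- function(dir) {
  uds <- sort(list.dirs(dir, recursive = FALSE))
  lapply(uds, function(ud) {
    sp <- utils::read.csv(file.path(ud, "spikes.csv"))
    wf <- utils::read.csv(file.path(ud, "waveform.csv"))
    ch <- utils::read.csv(file.path(ud, "channels.csv"))
    meta <- jsonlite::read_json(file.path(ud, "unit.json"),
                                simplifyVector = TRUE)
    structure(list(spike_times = sp$spike_time, amplitudes = sp$amplitude,
                   waveform = wf$value, fs_wave = meta$fs_wave,
                   channel_amplitudes = ch$amplitude,
                   channel_positions = ch$position,
                   duration = meta$duration),
              class = "vm_unit")
  })
}
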