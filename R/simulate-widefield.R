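#' Ground-truth description for a synthetic widefield stack
#'
#' Defines the planted components of a two-wavelength widefield movie: a
#' unilateral (left-hemisphere) visual component driven by stimulus onsets,
#' a bilateral movement component driven by wheel speed, a shared
#' heartbeat-band artifact (10 Hz sinusoid with slow amplitude modulation)
#' entering both channels with channel- and pixel-specific gain, and white
#' noise. Gain and component maps are smooth, as hemodynamic and mesoscale
#' calcium signals are.
#'
#' @param rows,cols pixel geometry (left hemisphere = columns
#'   `1:(cols/2)`).
#' @param frame_rate camera frame rate, Hz (alternating illumination halves
#'   the per-channel rate).
#' @param baseline_blue,baseline_violet mean fluorescence levels.
#' @param visual_amp,motor_amp planted component amplitudes.
#' @param heartbeat_freq artifact frequency, Hz (default 10, inside the
#'   5-15 Hz correction band).
#' @param heartbeat_amp artifact amplitude scale.
#' @param violet_gain artifact gain of the violet channel relative to blue.
#' @param noise_sd white noise sd per pixel and frame.
#' @param visual_gain_right visual gain of the mirrored right-hemisphere
#'   map relative to left (`v_R / v_L`).
#' @param motor_gain_left movement gain of the left hemisphere relative to
#'   right (`m_L / m_R`).
#' @return list of class `vm_wf_truth`.
#' @export
widefield_truth <- function(rows = 24, cols = 40, frame_rate = 70,
                            baseline_blue = 100, baseline_violet = 80,
                            visual_amp = 5, motor_amp = 5,
                            heartbeat_freq = 10, heartbeat_amp = 2,
                            violet_gain = 1.5, noise_sd = 0,
                            visual_gain_right = 0.2,
                            motor_gain_left = 0.8) {
  blob <- function(r0, c0, sig) {
    rr <- matrix(seq_len(rows), rows, cols)
    cc <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
    exp(-((rr - r0)^2 + (cc - c0)^2) / (2 * sig^2))
  }
  half <- cols / 2
  # left-hemisphere visual areas (posterior VIS + anterior mPFC blobs),
  # mirrored weakly on the right
  vis_l <- blob(rows * 0.7, half * 0.5, rows / 8) +
    0.8 * blob(rows * 0.25, half * 0.85, rows / 10)
  vis_r <- vis_l[, rev(seq_len(cols))]
  visual_map <- vis_l + visual_gain_right * vis_r
  mot_r <- blob(rows * 0.45, half + half * 0.5, rows / 6)
  motor_map <- motor_gain_left * mot_r[, rev(seq_len(cols))] + mot_r
  gain_map <- 1 + 0.5 * blob(rows / 2, cols / 2, rows)
  structure(list(rows = rows, cols = cols, frame_rate = frame_rate,
                 baseline_blue = baseline_blue,
                 baseline_violet = baseline_violet,
                 visual_map = visual_map * visual_amp,
                 motor_map = motor_map * motor_amp,
                 heartbeat_freq = heartbeat_freq,
                 heartbeat_amp = heartbeat_amp,
                 gain_map = gain_map, violet_gain = violet_gain,
                 noise_sd = noise_sd,
                 visual_gain_right = visual_gain_right,
                 motor_gain_left = motor_gain_left),
            class = "vm_wf_truth")
}

#' Simulate an interleaved two-wavelength widefield stack
#'
#' Builds a frames matrix with strictly alternating blue/violet
#' illumination. Blue frames carry baseline + visual component (stimulus
#' onsets convolved with the calcium kernel) + movement component (wheel
#' speed convolved with the kernel) + heartbeat artifact + noise; violet
#' frames carry baseline + heartbeat artifact (channel-specific gain) +
#' noise.
#'
#' @param session a `vm_session` providing stimulus onsets and the wheel
#'   trace; `NULL` gives a stimulus/movement-free stack.
#' @param truth a [widefield_truth()].
#' @param seed RNG seed.
#' @param duration stack length in seconds; defaults to the session's wheel
#'   duration (or 60 s without a session).
#' @return class `vm_framestack`: `frames` (pixels x frames, column-major
#'   pixels), `frame_times`, `illumination` (`"blue"`/`"violet"`),
#'   `geometry`, and the `truth` used (with planted temporal traces added:
#'   `visual_trace`, `motor_trace`, `heartbeat` sampled per frame).
#' @export
simulate_widefield <- function(session = NULL, truth = widefield_truth(),
                               seed = 1, duration = NULL) {
  set.seed(seed)
  if (is.null(duration))
    duration <- if (is.null(session)) 60 else session$wheel$duration
  fr <- truth$frame_rate
  n_frames <- floor(duration * fr)
  ft <- (seq_len(n_frames) - 1) / fr
  illum <- rep(c("blue", "violet"), length.out = n_frames)
  fs_chan <- fr / 2
  kern <- gcamp_kernel(fr)
  impulse <- numeric(n_frames)
  if (!is.null(session)) {
    st <- session$trials$stim_onset
    st <- st[!is.na(st) & st < duration]
    impulse[pmin(n_frames, floor(st * fr) + 1L)] <- 1
    sp <- abs(session$wheel$velocity)
    move <- sp[pmin(length(sp), floor(ft * session$wheel$fs) + 1L)]
    move <- move / max(max(move), 1)
  } else move <- numeric(n_frames)
  conv_full <- function(x) {
    y <- stats::convolve(x, rev(kern), type = "open")
    y[seq_along(x)]
  }
  visual_trace <- conv_full(impulse)
  motor_trace <- conv_full(move)
  slow_mod <- 1 + 0.3 * sin(2 * pi * 0.2 * ft)
  heartbeat <- truth$heartbeat_amp * slow_mod *
    sin(2 * pi * truth$heartbeat_freq * ft)
  npix <- truth$rows * truth$cols
  vmap <- as.vector(truth$visual_map)
  mmap <- as.vector(truth$motor_map)
  gmap <- as.vector(truth$gain_map)
  frames <- matrix(0, npix, n_frames)
  blue_idx <- illum == "blue"
  frames[, blue_idx] <- truth$baseline_blue +
    outer(vmap, visual_trace[blue_idx]) +
    outer(mmap, motor_trace[blue_idx]) +
    outer(gmap, heartbeat[blue_idx])
  frames[, !blue_idx] <- truth$baseline_violet +
    truth$violet_gain * outer(gmap, heartbeat[!blue_idx])
  if (truth$noise_sd > 0)
    frames <- frames + matrix(stats::rnorm(npix * n_frames, 0,
                                           truth$noise_sd), npix, n_frames)
  truth$visual_trace <- visual_trace
  truth$motor_trace <- motor_trace
  truth$heartbeat <- heartbeat
  structure(list(frames = frames, frame_times = ft, illumination = illum,
                 geometry = c(truth$rows, truth$cols),
                 frame_rate = fr, channel_rate = fs_chan, truth = truth),
            class = "vm_framestack")
}

#' Split an interleaved stack into per-channel matrices
#'
#' @param stack a `vm_framestack` (or list with `frames`, `frame_times`,
#'   `illumination`).
#' @return list with `blue`, `violet` (pixels x frames), `times_blue`,
#'   `times_violet`, `geometry`.
#' @export
split_channels <- function(stack) {
  lab <- stack$illumination
  if (any(lab[-1] == lab[-length(lab)]))
    stop("illumination labels do not strictly alternate")
  b <- lab == "blue"
  list(blue = stack$frames[, b, drop = FALSE],
       violet = stack$frames[, !b, drop = FALSE],
       times_blue = stack$frame_times[b],
       times_violet = stack$frame_times[!b],
       geometry = stack$geometry)
}

#' Left/right hemisphere ROI masks mirrored about the midline
#'
#' @param geometry `c(rows, cols)`.
#' @param center `c(row, col)` of the left-hemisphere ROI center.
#' @param radius ROI radius in pixels.
#' @return list of logical matrices `left` and `right` (mirror image).
#' @export
hemisphere_rois <- function(geometry, center, radius) {
  nr <- geometry[1]; nc <- geometry[2]
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  left <- (rr - center[1])^2 + (cc - center[2])^2 <= radius^2
  right <- left[, rev(seq_len(nc))]
  list(left = left, right = right)
}
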