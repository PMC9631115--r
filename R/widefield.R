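#' Truncated SVD compression of a fluorescence movie
#'
#' Compresses a pixels-by-time fluorescence matrix as `F = U S V'`, keeping
#' the top `k` components. All temporal (orthogonally invariant) operations
#' downstream act on the small `S V'` matrix rather than on pixels. The full
#' recordings this emulates retain 2000 components; synthetic fixtures use
#' far fewer.
#'
#' @param x pixels-by-time numeric matrix.
#' @param k number of components to retain (default `min(dim(x), 2000)`).
#' @return class `vm_svd`: `U` (pixels x k), `SV` (k x time), `d` (singular
#'   values, length k), plus `geometry`/`frame_times` carried through when
#'   present as attributes on `x`.
#' @export
svd_compress <- function(x, k = min(dim(x), 2000L)) {
  x <- as.matrix(x)
  if (k < 1 || k > min(dim(x))) stop("k out of range")
  s <- svd(x, nu = k, nv = k)
  d <- s$d[seq_len(k)]
  structure(list(U = s$u, SV = d * t(s$v), d = d,
                 geometry = attr(x, "geometry"),
                 frame_times = attr(x, "frame_times")),
            class = "vm_svd")
}

#' Reconstruct pixels from SVD components
#' @param sv a `vm_svd` object.
#' @return pixels-by-time matrix `U %*% SV`.
#' @export
svd_reconstruct <- function(sv) sv$U %*% sv$SV

filtfilt_rows <- function(x, filt) {
  if (is.null(dim(x))) return(as.numeric(signal::filtfilt(filt, x)))
  t(apply(x, 1, function(r) signal::filtfilt(filt, r)))
}

# Block-average spatial downsampling of a pixels-by-time matrix with known
# geometry (rows, cols); returns the small matrix plus the mapping from full
# pixels to blocks.
spatial_downsample <- function(x, geometry, factor) {
  nr <- geometry[1]; nc <- geometry[2]
  br <- ceiling(nr / factor); bc <- ceiling(nc / factor)
  ri <- pmin((seq_len(nr) - 1L) %/% factor, br - 1L)
  ci <- pmin((seq_len(nc) - 1L) %/% factor, bc - 1L)
  block <- outer(ri, ci * br, "+") + 1L   # column-major pixel -> block id
  block_v <- as.vector(block)
  agg <- rowsum(x, group = block_v, reorder = TRUE)
  cnt <- tabulate(block_v, nbins = br * bc)
  list(x = agg / cnt, block = block_v, n_blocks = br * bc)
}

#' Dual-wavelength hemodynamic correction
#'
#' Removes blood-volume artifacts from calcium-dependent (blue-illuminated)
#' fluorescence using the calcium-independent (violet-illuminated) channel.
#' The violet channel is sub-sample shifted onto the blue frame times by
#' linear interpolation; both channels are band-pass filtered (default
#' 5-15 Hz) to emphasize the heartbeat frequency; a per-pixel scaling factor
#' is regressed (ordinary least squares, no intercept) from the filtered
#' violet to the filtered blue signal; and the unfiltered, shifted violet
#' signal scaled by that factor is subtracted from the blue signal.
#' Fitting is performed after 3-fold spatial downsampling when pixel
#' geometry is supplied, with block factors broadcast back to full pixels.
#'
#' @param blue,violet pixels-by-time matrices (one row per pixel).
#' @param times_blue,times_violet frame times, seconds.
#' @param band band-pass edges in Hz (default `c(5, 15)`).
#' @param spatial_ds spatial downsampling factor for the fit (default 3).
#' @param geometry `c(rows, cols)` of the image, or `NULL` to fit per pixel.
#' @return list with `corrected` (pixels x time, on the blue time grid),
#'   `model` (class `vm_hemo`: per-pixel `scale`, `band`, `spatial_ds`,
#'   `fs`), and `violet_shifted`.
#' @export
hemodynamic_correct <- function(blue, violet, times_blue, times_violet,
                                band = c(5, 15), spatial_ds = 3,
                                geometry = NULL) {
  blue <- as.matrix(blue); violet <- as.matrix(violet)
  if (nrow(blue) != nrow(violet)) stop("channel pixel counts differ")
  if (ncol(blue) != length(times_blue) || ncol(violet) != length(times_violet))
    stop("frame times do not match trace lengths")
  fs <- 1 / stats::median(diff(times_blue))
  if (any(band >= fs / 2)) stop("band exceeds the per-channel Nyquist rate")
  if (all(abs(violet) < .Machine$double.eps)) {
    warning("violet channel is silent; returning blue unchanged")
    return(list(corrected = blue,
                model = structure(list(scale = rep(0, nrow(blue)),
                                       band = band, spatial_ds = spatial_ds,
                                       fs = fs), class = "vm_hemo"),
                violet_shifted = violet[, rep(1, ncol(blue)), drop = FALSE]))
  }
  # sub-sample shift: linear interpolation of violet onto blue frame times
  i0 <- pmin(pmax(findInterval(times_blue, times_violet), 1L),
             length(times_violet) - 1L)
  w <- (times_blue - times_violet[i0]) /
    (times_violet[i0 + 1L] - times_violet[i0])
  w <- pmin(pmax(w, 0), 1)
  v_shift <- violet[, i0, drop = FALSE] * rep(1 - w, each = nrow(violet)) +
    violet[, i0 + 1L, drop = FALSE] * rep(w, each = nrow(violet))

  if (!is.null(geometry) && spatial_ds > 1) {
    db <- spatial_downsample(blue, geometry, spatial_ds)
    dv <- spatial_downsample(v_shift, geometry, spatial_ds)
    fit_b <- db$x; fit_v <- dv$x; block <- db$block
  } else {
    fit_b <- blue; fit_v <- v_shift; block <- seq_len(nrow(blue))
  }
  bp <- signal::butter(2, band / (fs / 2), type = "pass")
  bf <- filtfilt_rows(fit_b, bp)
  vf <- filtfilt_rows(fit_v, bp)
  den <- rowSums(vf^2)
  sc_block <- ifelse(den > .Machine$double.eps, rowSums(bf * vf) / den, 0)
  scale <- sc_block[block]
  corrected <- blue - scale * v_shift
  list(corrected = corrected,
       model = structure(list(scale = scale, band = band,
                              spatial_ds = spatial_ds, fs = fs),
                         class = "vm_hemo"),
       violet_shifted = v_shift)
}

#' dF/F normalization with slow-drift removal
#'
#' Linearly detrends each trace, high-pass filters above `highpass` Hz
#' (zero-phase, order 2), and normalizes to `(F - F0) / (F0 + c)` where `F0`
#' is the per-pixel session mean and the softening constant `c` is the
#' median of `F0` across pixels (additive regularization; prevents division
#' blow-up in dim pixels).
#'
#' @param x pixels-by-time matrix (or a vector).
#' @param fs sampling rate, Hz.
#' @param highpass high-pass cutoff in Hz (default 0.01; `0` disables).
#' @param soften optional softening constant; default `median(F0)`.
#' @return class `vm_dff`: `dff` (same shape), `F0`, `soften`.
#' @export
normalize_dff <- function(x, fs, highpass = 0.01, soften = NULL) {
  vec <- is.null(dim(x))
  x <- rbind(as.matrix(if (vec) matrix(x, nrow = 1) else x))
  F0 <- rowMeans(x)
  soften <- if (is.null(soften)) stats::median(F0) else soften
  nt <- ncol(x)
  tc <- seq_len(nt) - (nt + 1) / 2
  beta <- (x %*% tc) / sum(tc^2)
  resid <- x - F0 - beta %*% t(tc)
  if (highpass > 0 && nt > 12) {
    hp <- signal::butter(2, min(highpass / (fs / 2), 0.99), type = "high")
    resid <- filtfilt_rows(resid, hp)
  }
  den <- F0 + soften
  bad <- abs(den) < .Machine$double.eps
  if (any(bad)) {
    warning("zero baseline fluorescence in ", sum(bad),
            " pixel(s); their dF/F set to 0")
    den[bad] <- 1
    resid[bad, ] <- 0
  }
  dff <- resid / den
  if (vec) dff <- as.numeric(dff)
  structure(list(dff = dff, F0 = F0, soften = soften), class = "vm_dff")
}

#' Calcium indicator impulse-response kernel
#'
#' Difference-of-exponentials kernel with GCaMP6s-like rise and decay,
#' normalized to unit peak, used as the deconvolution asset in synthetic
#' pipelines (kernel fitting from paired imaging/electrophysiology is out of
#' scope; any externally fitted kernel resampled to the trace rate can be
#' passed instead).
#'
#' @param fs sampling rate, Hz.
#' @param tau_rise,tau_decay time constants, seconds.
#' @param duration kernel support, seconds.
#' @return numeric kernel sampled at `fs`.
#' @export
gcamp_kernel <- function(fs, tau_rise = 0.05, tau_decay = 0.8,
                         duration = 4) {
  t <- seq(0, duration, by = 1 / fs)
  k <- (1 - exp(-t / tau_rise)) * exp(-t / tau_decay)
  k / max(k)
}

#' Regularized linear deconvolution
#'
#' Frequency-domain division with Tikhonov regularization: traces and kernel
#' are zero-padded, and the deconvolved spectrum is
#' `X conj(K) / (|K|^2 + lambda * max |K|^2)`. Applied row-wise, so it can
#' run on the `S V'` temporal components of an SVD-compressed movie; by
#' linearity the result equals pixel-space deconvolution after
#' reconstruction.
#'
#' @param x matrix (components/pixels x time) or numeric vector.
#' @param kernel deconvolution kernel sampled at the trace rate.
#' @param lambda relative Tikhonov regularizer (default 1e-3; `0` gives the
#'   exact inverse filter).
#' @return deconvolved traces, same shape as `x`.
#' @export
deconvolve <- function(x, kernel, lambda = 1e-3) {
  vec <- is.null(dim(x))
  x <- if (vec) matrix(x, nrow = 1) else as.matrix(x)
  nt <- ncol(x)
  if (length(kernel) < 1) stop("empty kernel")
  L <- stats::nextn(nt + length(kernel), 2)
  K <- stats::fft(c(kernel, numeric(L - length(kernel))))
  den <- Mod(K)^2 + lambda * max(Mod(K)^2)
  out <- t(apply(x, 1, function(r) {
    X <- stats::fft(c(r, numeric(L - nt)))
    Re(stats::fft(X * Conj(K) / den, inverse = TRUE))[seq_len(nt)] / L
  }))
  if (vec) as.numeric(out) else out
}

#' Recast temporal components into a master spatial basis
#'
#' Combines recordings that were compressed with experiment-specific spatial
#' components by projecting onto a shared master basis:
#' `SV_recast = t(U_master) U_exp SV_exp`.
#'
#' @param U_master,U_exp pixels-by-k spatial component matrices on the same
#'   (aligned) pixel space.
#' @param SV_exp k-by-time temporal components of the experiment.
#' @return recast temporal components, `k_master` x time.
#' @export
recast_to_master <- function(U_master, U_exp, SV_exp) {
  if (nrow(U_master) != nrow(U_exp)) stop("pixel spaces differ")
  if (ncol(U_exp) != nrow(SV_exp)) stop("component dimensions differ")
  crossprod(U_master, U_exp %*% SV_exp)
}

#' ROI mean trace in component space
#'
#' Mean fluorescence over a pixel mask computed without reconstructing the
#' movie: `mean_rows(U[mask, ]) %*% SV`.
#'
#' @param U pixels-by-k spatial components.
#' @param SV k-by-time temporal components.
#' @param mask logical vector over pixels, or a logical matrix in the image
#'   geometry (column-major vectorized).
#' @return numeric trace.
#' @export
roi_trace <- function(U, SV, mask) {
  mask <- as.vector(mask)
  if (length(mask) != nrow(U)) stop("mask does not match pixel count")
  if (!any(mask)) stop("empty ROI mask")
  as.numeric(colMeans(U[mask, , drop = FALSE]) %*% SV)
}

#' Fit the movement gain ratio between hemispheres
#'
#' Under the additive model `F_L = v_L V + m_L M`, `F_R = v_R V + m_R M`
#' (unilateral visual gains `v`, bilateral movement gains `m`), epochs of
#' movement with no stimulus present identify the ratio `m_L / m_R`.
#' Epoch-triggered snippets are averaged within day, then across days, and
#' a least-squares scale from the right to the left average is fitted
#' without intercept.
#'
#' @param left,right region traces (numeric vectors) sampled at `fs`,
#'   starting at time 0.
#' @param epochs data.frame with `onset` (seconds) and optionally `day`.
#' @param fs sampling rate, Hz.
#' @param window epoch window around onset, seconds (default `c(-0.2, 0.6)`).
#' @param min_epochs minimum qualifying epochs (default 3).
#' @return class `vm_hemi`: `ratio` (m_L/m_R), `residual` (RMS of the fit),
#'   `n_epochs`, `avg_left`, `avg_right`, `window`, `fs`.
#' @export
fit_hemisphere_ratio <- function(left, right, epochs, fs,
                                 window = c(-0.2, 0.6), min_epochs = 3) {
  if (is.null(epochs$day)) epochs$day <- 1L
  rel <- seq(round(window[1] * fs), round(window[2] * fs))
  nt <- length(left)
  snip <- function(trace, onset) {
    idx <- round(onset * fs) + 1L + rel
    if (any(idx < 1L | idx > nt)) return(NULL)
    trace[idx]
  }
  days <- split(epochs$onset, epochs$day)
  avg_day <- function(trace) {
    m <- lapply(days, function(on) {
      s <- lapply(on, snip, trace = trace)
      s <- s[!vapply(s, is.null, logical(1))]
      if (length(s) == 0) return(NULL)
      Reduce(`+`, s) / length(s)
    })
    m <- m[!vapply(m, is.null, logical(1))]
    if (length(m) == 0) return(NULL)
    Reduce(`+`, m) / length(m)
  }
  n_ok <- sum(vapply(epochs$onset, function(o) !is.null(snip(left, o)),
                     logical(1)))
  if (n_ok < min_epochs)
    stop("only ", n_ok, " qualifying epochs (need ", min_epochs, ")")
  aL <- avg_day(left); aR <- avg_day(right)
  ratio <- sum(aL * aR) / sum(aR^2)
  structure(list(ratio = ratio,
                 residual = sqrt(mean((aL - ratio * aR)^2)),
                 n_epochs = n_ok, avg_left = aL, avg_right = aR,
                 window = window, fs = fs),
            class = "vm_hemi")
}

#' Movement-weighted hemisphere subtraction
#'
#' `F_L - (m_L/m_R) F_R`: cancels the bilateral movement component exactly
#' when the fitted ratio is exact, leaving a signal proportional to the
#' unilateral visual component `(v_L - m_L v_R / m_R) V`. Positive values
#' mean more left-hemisphere activity.
#'
#' @param left,right traces or pixels-by-time matrices.
#' @param model a `vm_hemi` fit or a numeric ratio.
#' @return asymmetry trace, same shape as `left`.
#' @export
hemisphere_subtract <- function(left, right, model) {
  ratio <- if (inherits(model, "vm_hemi")) model$ratio else as.numeric(model)
  if (ratio <= 0) stop("movement gain ratio must be positive")
  left - ratio * right
}
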