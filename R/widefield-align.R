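# Small image helpers on plain matrices (row = image row, column-major
# pixel vectorization everywhere in the package).

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

#' Separable Gaussian blur of an image matrix
#' @param img numeric matrix.
#' @param sigma blur standard deviation in pixels.
#' @return blurred matrix, same size (replicate-padded edges).
#' @export
gaussian_blur <- function(img, sigma) {
  k <- gaussian_kernel_1d(sigma)
  r <- (length(k) - 1L) / 2L
  pad_conv <- function(v) {
    vp <- c(rep(v[1], r), v, rep(v[length(v)], r))
    as.numeric(stats::filter(vp, k, sides = 2))[(r + 1):(r + length(v))]
  }
  t(apply(apply(img, 2, pad_conv), 1, pad_conv))
}

#' Vasculature edge map
#'
#' Unsharp-mask edge image used for day-to-day alignment: the raw average
#' image minus its Gaussian-blurred version.
#'
#' @param img average image for one day.
#' @param sigma blur standard deviation in pixels (default 4).
#' @return edge matrix.
#' @export
edge_map <- function(img, sigma = 4) img - gaussian_blur(img, sigma)

#' Apply a rigid transform to an image
#'
#' Rotates by `theta` degrees about the image center then translates by
#' (`dx`, `dy`) pixels (columns, rows), using bilinear interpolation with
#' zero fill.
#'
#' @param img numeric matrix.
#' @param dx,dy translation in pixels (columns, rows).
#' @param theta rotation in degrees, counterclockwise in (row, col) axes.
#' @return transformed matrix.
#' @export
apply_rigid <- function(img, dx = 0, dy = 0, theta = 0) {
  nr <- nrow(img); nc <- ncol(img)
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  th <- theta * pi / 180
  co <- cos(th); si <- sin(th)
  rr <- matrix(seq_len(nr), nr, nc) - cr
  cm <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - cc
  # inverse map: undo translation, then rotate by -theta
  r2 <- rr - dy; c2 <- cm - dx
  src_r <- co * r2 + si * c2 + cr
  src_c <- -si * r2 + co * c2 + cc
  r0 <- floor(src_r); c0 <- floor(src_c)
  fr <- src_r - r0; fc <- src_c - c0
  get <- function(ri, ci) {
    ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
    out <- numeric(length(ri))
    out[ok] <- img[cbind(ri[ok], ci[ok])]
    out
  }
  v <- get(r0, c0) * (1 - fr) * (1 - fc) + get(r0 + 1, c0) * fr * (1 - fc) +
    get(r0, c0 + 1) * (1 - fr) * fc + get(r0 + 1, c0 + 1) * fr * fc
  matrix(v, nr, nc)
}

# FFT cross-correlation peak with parabolic sub-pixel refinement.
# Returns the (dx, dy) that best maps `mov` onto `ref`, plus the peak score.
xcorr_shift <- function(ref, mov) {
  A <- ref - mean(ref); B <- mov - mean(mov)
  C <- Re(stats::fft(stats::fft(A) * Conj(stats::fft(B)),
                     inverse = TRUE)) / length(A)
  pk <- which(C == max(C), arr.ind = TRUE)[1, ]
  nr <- nrow(C); nc <- ncol(C)
  wrap <- function(i, n) ifelse(i - 1 > n / 2, i - 1 - n, i - 1)
  subpix <- function(cm, c0, cp) {
    den <- cm - 2 * c0 + cp
    if (abs(den) < .Machine$double.eps) 0 else 0.5 * (cm - cp) / den
  }
  im <- ifelse(pk[1] == 1, nr, pk[1] - 1); ip <- ifelse(pk[1] == nr, 1, pk[1] + 1)
  jm <- ifelse(pk[2] == 1, nc, pk[2] - 1); jp <- ifelse(pk[2] == nc, 1, pk[2] + 1)
  dr <- wrap(pk[1], nr) + subpix(C[im, pk[2]], C[pk[1], pk[2]], C[ip, pk[2]])
  dc <- wrap(pk[2], nc) + subpix(C[pk[1], jm], C[pk[1], pk[2]], C[pk[1], jp])
  list(dy = dr, dx = dc, score = max(C) / sqrt(sum(A^2) * sum(B^2)))
}

#' Rigid alignment of daily average images
#'
#' Aligns each day's average image to a reference day by rigid transform
#' (rotation + translation) of their vasculature edge maps. The rotation is
#' searched over a grid and the translation found by FFT cross-correlation
#' with sub-pixel (parabolic) refinement; ties in score break toward the
#' smallest displacement.
#'
#' @param mean_images list of matrices, one per day (same geometry).
#' @param reference index of the reference day (default 1).
#' @param blur_sigma Gaussian sigma of the unsharp edge map (default 4).
#' @param rotations candidate rotations in degrees
#'   (default `seq(-5, 5, by = 0.25)`).
#' @return data.frame with one row per day: `day`, `dx`, `dy`, `theta`,
#'   `score`. Applying [apply_rigid()] with a row's parameters maps that
#'   day's image onto the reference.
#' @export
align_days <- function(mean_images, reference = 1, blur_sigma = 4,
                       rotations = seq(-5, 5, by = 0.25)) {
  dims <- vapply(mean_images, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("images must share geometry")
  flat <- vapply(mean_images, function(m) stats::sd(m) < 1e-12, logical(1))
  if (any(flat)) stop("degenerate (flat) image at day ", which(flat)[1])
  edges <- lapply(mean_images, edge_map, sigma = blur_sigma)
  ref <- edges[[reference]]
  out <- lapply(seq_along(edges), function(i) {
    if (i == reference)
      return(data.frame(day = i, dx = 0, dy = 0, theta = 0, score = 1))
    best <- NULL
    for (th in rotations) {
      rot <- if (th == 0) edges[[i]] else apply_rigid(edges[[i]], theta = th)
      sh <- xcorr_shift(ref, rot)
      cand <- data.frame(day = i, dx = sh$dx, dy = sh$dy, theta = th,
                         score = sh$score)
      if (is.null(best) || cand$score > best$score + 1e-12 ||
          (abs(cand$score - best$score) <= 1e-12 &&
           cand$dx^2 + cand$dy^2 < best$dx^2 + best$dy^2))
        best <- cand
    }
    best
  })
  do.call(rbind, out)
}
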