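#' Simulate sparse-noise retinotopy responses
#'
#' Emulates asynchronous sparse-noise mapping: small white squares on a grid
#' of azimuth/elevation positions, each pixel responding through a Gaussian
#' receptive field centered at its planted retinotopic location. One or more
#' cortical areas can be planted, each a horizontal band of columns with a
#' linear azimuth progression (optionally mirrored) and elevation mapped
#' along rows.
#'
#' @param map_spec list with `rows`, `cols`, `areas` (list of lists with
#'   `cols` = column range and `mirror` flag), `rf_sigma` (receptive field
#'   sd in degrees, default 8), `noise_sd` (response noise, default 0),
#'   `n_rep` (presentations per square, default 5). See
#'   [retinotopy_spec()].
#' @param stim_grid list with numeric `azimuth` and `elevation` vectors
#'   (degrees) of square centers.
#' @param seed RNG seed.
#' @return list with `responses` (rows x cols x presentations array),
#'   `positions` (data.frame `azimuth`, `elevation` per presentation), and
#'   `truth` (planted `azimuth`/`elevation` pixel maps, `area` id map).
#' @export
simulate_retinotopy <- function(map_spec = retinotopy_spec(),
                                stim_grid = list(azimuth = seq(0, 80, 10),
                                                 elevation = seq(0, 60, 10)),
                                seed = 1) {
  set.seed(seed)
  nr <- map_spec$rows; nc <- map_spec$cols
  az_rng <- range(stim_grid$azimuth); el_rng <- range(stim_grid$elevation)
  az_map <- matrix(NA_real_, nr, nc)
  el_map <- matrix(NA_real_, nr, nc)
  area_map <- matrix(NA_integer_, nr, nc)
  for (ai in seq_along(map_spec$areas)) {
    a <- map_spec$areas[[ai]]
    cols <- a$cols[1]:a$cols[2]
    frac_c <- (seq_along(cols) - 1) / max(1, length(cols) - 1)
    if (isTRUE(a$mirror)) frac_c <- rev(frac_c)
    az_map[, cols] <- matrix(az_rng[1] + frac_c * diff(az_rng),
                             nr, length(cols), byrow = TRUE)
    frac_r <- (seq_len(nr) - 1) / max(1, nr - 1)
    el_map[, cols] <- matrix(el_rng[1] + frac_r * diff(el_rng),
                             nr, length(cols))
    area_map[, cols] <- ai
  }
  squares <- expand.grid(azimuth = stim_grid$azimuth,
                         elevation = stim_grid$elevation)
  pres <- squares[rep(seq_len(nrow(squares)), map_spec$n_rep), ]
  pres <- pres[sample.int(nrow(pres)), ]
  rownames(pres) <- NULL
  resp <- array(0, dim = c(nr, nc, nrow(pres)))
  s2 <- 2 * map_spec$rf_sigma^2
  for (p in seq_len(nrow(pres))) {
    g <- exp(-((pres$azimuth[p] - az_map)^2 +
               (pres$elevation[p] - el_map)^2) / s2)
    g[is.na(g)] <- 0
    if (map_spec$noise_sd > 0)
      g <- g + matrix(stats::rnorm(nr * nc, 0, map_spec$noise_sd), nr, nc)
    resp[, , p] <- g
  }
  list(responses = resp, positions = pres,
       truth = list(azimuth = az_map, elevation = el_map, area = area_map))
}

#' Retinotopy map specification
#' @param rows,cols cortical pixel geometry.
#' @param areas list of areas; each `list(cols = c(from, to), mirror = FALSE)`.
#' @param rf_sigma receptive field sd, degrees.
#' @param noise_sd additive response noise sd.
#' @param n_rep presentations per square.
#' @return list usable as `map_spec` in [simulate_retinotopy()].
#' @export
retinotopy_spec <- function(rows = 30, cols = 30,
                            areas = list(list(cols = c(1, 30),
                                              mirror = FALSE)),
                            rf_sigma = 8, noise_sd = 0, n_rep = 5) {
  list(rows = rows, cols = cols, areas = areas, rf_sigma = rf_sigma,
       noise_sd = noise_sd, n_rep = n_rep)
}

image_gradient <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  gr <- (m[pmin(seq_len(nr) + 1, nr), ] - m[pmax(seq_len(nr) - 1, 1), ]) /
    matrix(pmin(seq_len(nr) + 1, nr) - pmax(seq_len(nr) - 1, 1), nr, nc)
  gc <- (m[, pmin(seq_len(nc) + 1, nc)] - m[, pmax(seq_len(nc) - 1, 1)]) /
    matrix(pmin(seq_len(nc) + 1, nc) - pmax(seq_len(nc) - 1, 1), nr, nc,
           byrow = TRUE)
  list(dr = gr, dc = gc)
}

#' Retinotopic visual field sign map
#'
#' For each bootstrap resample of square presentations: averages responses
#' per square, Gaussian-smooths each square's mean response image, computes
#' every cortical pixel's response-weighted center of mass in azimuth and
#' elevation (rectified weights), takes the spatial gradients of the two
#' center-of-mass maps, and evaluates the sine of the angle between them.
#' The reported map is the mean over bootstraps. With azimuth advancing
#' along image columns and elevation along rows, a non-mirror area has sign
#' +1; mirror-image areas have sign -1.
#'
#' @param responses rows x cols x presentations array of responses, averaged
#'   in the indicator's response window (0.3-0.5 s after square onset in the
#'   emulated recordings).
#' @param positions data.frame with `azimuth` and `elevation` per
#'   presentation.
#' @param n_boot bootstrap count (default 10).
#' @param smooth_sigma Gaussian smoothing of square-response images, pixels.
#' @param seed RNG seed for the bootstrap.
#' @return class `vm_fieldsign`: `sign` (matrix in \[-1, 1\]), `azimuth`,
#'   `elevation` center-of-mass maps (degrees), `n_boot`, `smooth_sigma`.
#' @export
field_sign_map <- function(responses, positions, n_boot = 10,
                           smooth_sigma = 2, seed = 1) {
  set.seed(seed)
  np <- dim(responses)[3]
  key <- paste(positions$azimuth, positions$elevation)
  squares <- !duplicated(key)
  if (sum(squares) < 4) stop("too few distinct squares for gradient maps")
  sq_key <- key[squares]
  sq_az <- positions$azimuth[squares]
  sq_el <- positions$elevation[squares]
  nr <- dim(responses)[1]; nc <- dim(responses)[2]
  one_boot <- function(idx) {
    az_num <- matrix(0, nr, nc); el_num <- matrix(0, nr, nc)
    den <- matrix(0, nr, nc)
    for (s in seq_along(sq_key)) {
      sel <- idx[key[idx] == sq_key[s]]
      if (length(sel) == 0) sel <- which(key == sq_key[s])  # fallback: all
      m <- apply(responses[, , sel, drop = FALSE], c(1, 2), mean)
      m <- gaussian_blur(m, smooth_sigma)
      w <- pmax(m, 0)
      az_num <- az_num + w * sq_az[s]
      el_num <- el_num + w * sq_el[s]
      den <- den + w
    }
    den[den < .Machine$double.eps] <- NA
    az <- az_num / den; el <- el_num / den
    g_az <- image_gradient(az); g_el <- image_gradient(el)
    sgn <- sin(atan2(g_el$dr, g_el$dc) - atan2(g_az$dr, g_az$dc))
    list(az = az, el = el, sgn = sgn)
  }
  boots <- lapply(seq_len(n_boot), function(b)
    one_boot(sample.int(np, np, replace = TRUE)))
  avg <- function(f) Reduce(`+`, lapply(boots, `[[`, f)) / n_boot
  structure(list(sign = avg("sgn"), azimuth = avg("az"),
                 elevation = avg("el"), n_boot = n_boot,
                 smooth_sigma = smooth_sigma),
            class = "vm_fieldsign")
}
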