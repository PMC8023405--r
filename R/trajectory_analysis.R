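#' Tip track container
#'
#' Planar (top-view) projection of a tip trajectory with provenance tag.
#'
#' @param times sample times \[s\], monotone.
#' @param x,y planar tip coordinates \[m\].
#' @param z optional vertical coordinate \[m\].
#' @param provenance one of `"simulated"`, `"measured"`, `"synthetic"`.
#' @return object of class `tip_track`.
#' @export
tip_track <- function(times, x, y, z = NULL,
                      provenance = c("simulated", "measured", "synthetic")) {
  provenance <- match.arg(provenance)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  stopifnot(length(x) == length(times), length(y) == length(times))
  structure(list(times = times, x = x, y = y, z = z,
                 provenance = provenance), class = "tip_track")
}

#' Synthetic two-tone tip track
#'
#' x = A cos(w1 t) + B cos(sign w2 t), y = A sin(w1 t) + B sin(sign w2 t)
#' plus optional isotropic Gaussian noise: the superposition of two
#' circular motions whose relative rotation direction (`sign`) produces
#' epitrochoid-like (concordant) or hypotrochoid-like (discordant)
#' patterns.
#'
#' @param A,B tone amplitudes \[m\] (>= 0).
#' @param omega1,omega2 angular frequencies \[rad/s\] (> 0).
#' @param sign +1 concordant, -1 discordant second tone.
#' @param duration track length \[s\].
#' @param dt sampling step \[s\].
#' @param noise sd of added Gaussian noise \[m\].
#' @return a `tip_track` with provenance `"synthetic"`.
#' @export
make_synthetic_track <- function(A, B, omega1, omega2, sign = 1,
                                 duration, dt, noise = 0) {
  stopifnot(A >= 0, B >= 0, omega1 > 0, omega2 > 0, sign %in% c(-1, 1))
  t <- seq(0, duration, by = dt)
  x <- A * cos(omega1 * t) + B * cos(sign * omega2 * t)
  y <- A * sin(omega1 * t) + B * sin(sign * omega2 * t)
  if (noise > 0) {
    x <- x + stats::rnorm(length(t), sd = noise)
    y <- y + stats::rnorm(length(t), sd = noise)
  }
  tip_track(t, x, y, provenance = "synthetic")
}

#' Dominant rotation tones of a tip track
#'
#' Windowed periodogram of the complex signal x + i y with parabolic peak
#' interpolation. Signed frequencies carry the rotation direction; up to
#' `n_tones` significant peaks are returned (a peak is significant when it
#' exceeds `floor_factor` times the median spectral magnitude and
#' `min_rel_amp` times the dominant peak).
#'
#' @param track a `tip_track`.
#' @param n_tones maximum number of tones (default 2).
#' @param min_rel_amp minimum amplitude relative to the dominant tone.
#' @param floor_factor noise-floor multiplier for significance.
#' @param min_periods minimum track duration in units of the dominant
#'   period (input-length guard; set 0 to disable for windowed band
#'   comparisons).
#' @return data.frame with columns `frequency` \[1/s, signed\], `period`
#'   \[s\], `amplitude` \[m\]; zero rows when no significant tone exists.
#' @export
estimate_periods <- function(track, n_tones = 2, min_rel_amp = 0.05,
                             floor_factor = 8, min_periods = 4) {
  t <- track$times
  N <- length(t)
  if (N < 16) stop("track too short for spectral estimation")
  dt <- stats::median(diff(t))
  z <- complex(real = track$x, imaginary = track$y)
  # remove mean and linear drift (slow lean of the organ)
  tt <- t - mean(t)
  fit_r <- stats::lm.fit(cbind(1, tt), track$x)$coefficients
  fit_i <- stats::lm.fit(cbind(1, tt), track$y)$coefficients
  z <- z - complex(real = fit_r[1] + fit_r[2] * tt,
                   imaginary = fit_i[1] + fit_i[2] * tt)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, N - 1) / (N - 1))  # Hann
  Z <- stats::fft(z * w)
  amp <- Mod(Z) / sum(w)
  freq <- seq(0, N - 1) / (N * dt)
  freq[freq >= 1 / (2 * dt)] <- freq[freq >= 1 / (2 * dt)] - 1 / dt
  floor_amp <- floor_factor * stats::median(amp)
  peaks <- list()
  excluded <- rep(FALSE, N)
  excluded[1] <- TRUE  # DC
  for (k in seq_len(n_tones)) {
    cand <- which(!excluded)
    if (!length(cand)) break
    i <- cand[which.max(amp[cand])]
    a <- amp[i]
    if (a <= floor_amp) break
    if (length(peaks) && a < min_rel_amp * peaks[[1]]$amplitude) break
    # parabolic interpolation on log amplitude across neighbors
    im <- if (i == 1) N else i - 1
    ip <- if (i == N) 1 else i + 1
    la <- log(pmax(amp[c(im, i, ip)], 1e-300))
    denom <- la[1] - 2 * la[2] + la[3]
    delta <- if (abs(denom) > 1e-12) 0.5 * (la[1] - la[3]) / denom else 0
    delta <- max(-0.5, min(0.5, delta))
    f <- freq[i] + delta / (N * dt)
    peaks[[length(peaks) + 1]] <- list(frequency = f, amplitude = a)
    excluded[max(1, i - 3):min(N, i + 3)] <- TRUE
    if (i <= 4) excluded[(N - (4 - i)):N] <- TRUE
  }
  if (!length(peaks))
    return(data.frame(frequency = numeric(0), period = numeric(0),
                      amplitude = numeric(0)))
  out <- data.frame(frequency = vapply(peaks, `[[`, 0, "frequency"),
                    amplitude = vapply(peaks, `[[`, 0, "amplitude"))
  out$period <- 1 / abs(out$frequency)
  if (min_periods > 0 && is.finite(out$period[1]) &&
      (t[N] - t[1]) < min_periods * out$period[1])
    stop("track shorter than ", min_periods, " estimated periods")
  out[, c("frequency", "period", "amplitude")]
}

#' Orbit ellipticity of the late-time track
#'
#' Ratio of the singular values (minor/major) of the centered (x, y)
#' sample covariance over the last `window` fraction of the track:
#' 0 for a straight segment, 1 for a circle.
#'
#' @param track a `tip_track`.
#' @param window fraction of the record (from the end).
#' @return ellipticity in \[0, 1\].
#' @export
orbit_ellipticity <- function(track, window = 0.5) {
  n <- length(track$times)
  i0 <- max(1, floor(n * (1 - window)))
  xy <- cbind(track$x[i0:n], track$y[i0:n])
  xy <- sweep(xy, 2, colMeans(xy))
  sv <- svd(xy, nu = 0, nv = 0)$d
  if (sv[1] < 1e-300) return(1)
  sv[2] / sv[1]
}

#' Classify a nutation pattern
#'
#' Single-tone tracks are labelled by the orbit ellipticity e:
#' pendular (e < `thresholds$pendular`), circular
#' (e > `thresholds$circular`), elliptic in between. Tracks with two
#' significant tones at distinct |frequency| (beyond the spectral
#' resolution) are trochoid-like: epitrochoid_like when the tones
#' co-rotate, hypotrochoid_like when they counter-rotate.
#'
#' @param track a `tip_track`.
#' @param thresholds list(`pendular` = 0.2, `circular` = 0.8); the
#'   operational cutoffs are configurable since the regime labels are
#'   qualitative.
#' @param ... passed to [estimate_periods()].
#' @return object of class `pattern_report`: `label`, `dominant_period`
#'   \[s\], `secondary_period` \[s\] or NA, `ellipticity`,
#'   `rotation_sign`, `tones` (the data.frame).
#' @export
classify_pattern <- function(track, thresholds = list(pendular = 0.2,
                                                      circular = 0.8), ...) {
  tones <- estimate_periods(track, ...)
  if (!nrow(tones))
    return(structure(list(label = NA_character_, dominant_period = NA_real_,
                          secondary_period = NA_real_,
                          ellipticity = NA_real_, rotation_sign = 0L,
                          tones = tones, flag = "no_significant_tone"),
                     class = "pattern_report"))
  e <- orbit_ellipticity(track)
  dur <- diff(range(track$times))
  res <- 1.5 / dur  # spectral resolution in Hz
  two_tone <- nrow(tones) >= 2 &&
    abs(abs(tones$frequency[1]) - abs(tones$frequency[2])) > res
  label <- if (two_tone) {
    if (sign(tones$frequency[1]) == sign(tones$frequency[2]))
      "epitrochoid_like" else "hypotrochoid_like"
  } else if (e < thresholds$pendular) "pendular"
  else if (e > thresholds$circular) "circular"
  else "elliptic"
  structure(list(label = label,
                 dominant_period = tones$period[1],
                 secondary_period = if (two_tone) tones$period[2] else NA_real_,
                 ellipticity = e,
                 rotation_sign = as.integer(sign(tones$frequency[1])),
                 tones = tones, flag = "ok"),
            class = "pattern_report")
}

#' @export
print.pattern_report <- function(x, ...) {
  cat("nutation pattern:", x$label, "\n")
  cat("  dominant period :", format(x$dominant_period), "s\n")
  if (!is.na(x$secondary_period))
    cat("  secondary period:", format(x$secondary_period), "s\n")
  cat("  ellipticity     :", format(round(x$ellipticity, 3)), "\n")
  cat("  rotation sign   :", x$rotation_sign, "\n")
  invisible(x)
}

#' Read / write tip tracks as delimited text
#'
#' Columns t, x, y\[, z\] with a header line; SI units.
#' @param path file path.
#' @param provenance tag for the loaded track.
#' @export
read_tip_track <- function(path, provenance = "measured") {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("t", "x", "y") %in% names(df)))
    stop("track file must have columns t, x, y")
  tip_track(df$t, df$x, df$y, z = df$z, provenance = provenance)
}

#' @rdname read_tip_track
#' @param track a `tip_track`.
#' @export
write_tip_track <- function(track, path) {
  df <- data.frame(t = track$times, x = track$x, y = track$y)
  if (!is.null(track$z)) df$z <- track$z
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
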