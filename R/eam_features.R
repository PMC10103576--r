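#' Voltage amplitude of a unipolar signal
#'
#' Peak-to-peak deflection: the difference between the maximum and minimum
#' voltage of the signal. Invariant to baseline shift.
#'
#' @param signal numeric vector (mV)
#' @return amplitude (mV)
#' @export
voltage_amplitude <- function(signal) {
  if (!length(signal)) stop("empty signal")
  max(signal) - min(signal)
}

#' Per-point conduction velocity by element triangulation
#'
#' For each triangle with all three vertices activated, the activation time
#' is fitted as a plane over the element in local 2D coordinates; the
#' element CV is the inverse gradient magnitude (converted to cm/s).
#' Each point's CV is the mean of element CVs whose centroids lie within
#' `radius` mm (Euclidean) of the point. Elements with near-zero gradient
#' or implausibly fast fits (above `cv_cap`) are excluded.
#'
#' @param surface an `eam_surface`
#' @param activation per-point activation times (ms)
#' @param radius averaging radius (mm)
#' @param cv_cap element CVs above this (cm/s) are treated as far-field
#'   artefacts and skipped
#' @return list with `cv` (cm/s per point, NA where undefined) and
#'   `element_cv` (per triangle)
#' @export
conduction_velocity_map <- function(surface, activation, radius = 5,
                                    cv_cap = 200) {
  tri <- surface$triangles
  pts <- surface$points
  t1 <- activation[tri[, 1]]; t2 <- activation[tri[, 2]]; t3 <- activation[tri[, 3]]
  ok <- !is.na(t1) & !is.na(t2) & !is.na(t3)
  ecv <- rep(NA_real_, nrow(tri))
  idx <- which(ok)
  if (length(idx)) {
    p1 <- pts[tri[idx, 1], , drop = FALSE]
    e1 <- pts[tri[idx, 2], , drop = FALSE] - p1
    e2 <- pts[tri[idx, 3], , drop = FALSE] - p1
    # local orthonormal frame in the triangle plane
    u <- normalize_rows(e1)
    w <- e2 - u * rowSums(e2 * u)
    w <- normalize_rows(w)
    x2 <- rowSums(e1 * u)               # vertex 2 at (x2, 0)
    x3 <- rowSums(e2 * u); y3 <- rowSums(e2 * w)
    dt2 <- t2[idx] - t1[idx]; dt3 <- t3[idx] - t1[idx]
    gx <- dt2 / x2
    gy <- (dt3 - gx * x3) / y3
    gmag <- sqrt(gx^2 + gy^2)           # ms/mm
    cv <- 100 / gmag                    # cm/s
    cv[gmag < 1e-6] <- NA
    cv[cv > cv_cap] <- NA
    ecv[idx] <- cv
  }
  cent <- (pts[tri[, 1], , drop = FALSE] + pts[tri[, 2], , drop = FALSE] +
             pts[tri[, 3], , drop = FALSE]) / 3
  pcv <- rep(NA_real_, nrow(pts))
  valid_el <- which(!is.na(ecv))
  if (length(valid_el)) {
    vc <- cent[valid_el, , drop = FALSE]
    for (i in seq_len(nrow(pts))) {
      d2 <- (vc[, 1] - pts[i, 1])^2 + (vc[, 2] - pts[i, 2])^2 +
        (vc[, 3] - pts[i, 3])^2
      sel <- d2 <= radius^2
      if (any(sel)) pcv[i] <- mean(ecv[valid_el[sel]])
    }
  }
  list(cv = pcv, element_cv = ecv)
}

#' Point neighbourhoods within a surface radius
#'
#' Geodesic (default) or Euclidean neighbourhoods used by isochronal
#' crowding. Geodesic distances run along the triangulated surface edges.
#'
#' @param surface an `eam_surface`
#' @param radius radius in mm
#' @param geodesic use surface geodesic distance (else Euclidean)
#' @return list of integer vectors, one per point (each includes the point
#'   itself)
#' @export
surface_neighbors <- function(surface, radius = 10, geodesic = TRUE) {
  p <- nrow(surface$points)
  out <- vector("list", p)
  if (geodesic) {
    batch <- 400L
    for (s in seq(1L, p, by = batch)) {
      v <- s:min(s + batch - 1L, p)
      d <- igraph::distances(surface$graph, v = v)
      for (q in seq_along(v)) out[[v[q]]] <- which(d[q, ] <= radius)
    }
  } else {
    pts <- surface$points
    for (i in seq_len(p)) {
      d2 <- (pts[, 1] - pts[i, 1])^2 + (pts[, 2] - pts[i, 2])^2 +
        (pts[, 3] - pts[i, 3])^2
      out[[i]] <- which(d2 <= radius^2)
    }
  }
  out
}

#' Isochronal crowding
#'
#' Sixteen equally spaced time windows (isochrones) are defined between the
#' earliest and latest activation time of the map; the crowding at a point
#' is the number of distinct isochrones represented among the points within
#' a 1 cm surface radius. Uniform activation gives 1 everywhere.
#'
#' @param surface an `eam_surface`
#' @param activation per-point activation times (ms)
#' @param n_bins number of isochrones
#' @param radius neighbourhood radius (mm)
#' @param neighbors optional precomputed [surface_neighbors()] list
#' @param geodesic geodesic (default) or Euclidean neighbourhoods
#' @return integer crowding count per point (NA where no activated
#'   neighbours)
#' @export
isochronal_crowding <- function(surface, activation, n_bins = 16, radius = 10,
                                neighbors = NULL, geodesic = TRUE) {
  if (is.null(neighbors)) neighbors <- surface_neighbors(surface, radius, geodesic)
  rng <- range(activation, na.rm = TRUE)
  if (!is.finite(rng[1])) return(rep(NA_integer_, length(activation)))
  if (diff(rng) < 1e-9) {
    bins <- ifelse(is.na(activation), NA_integer_, 1L)
  } else {
    bins <- as.integer(pmin(
      floor((activation - rng[1]) / diff(rng) * n_bins) + 1L, n_bins))
  }
  vapply(seq_along(activation), function(i) {
    b <- bins[neighbors[[i]]]
    b <- b[!is.na(b)]
    if (!length(b)) NA_integer_ else length(unique(b))
  }, integer(1))
}

# zero-phase low-pass smoothing used as the "normal signal" template:
# spectral multiplication by the squared magnitude response of an order-4
# Butterworth (the forward-backward filtering equivalent), applied
# circularly so the operation is exactly linear-phase-free and vectorizable
smooth_template <- function(signal, fs = 400, cutoff = 30, order = 4) {
  n <- length(signal)
  if (n < 4) return(signal)
  f <- (seq_len(n) - 1) / n * fs
  f <- pmin(f, fs - f)
  H <- 1 / (1 + (f / cutoff)^(2 * order))
  Re(fft(fft(signal) * H, inverse = TRUE)) / n
}

#' Fractionation index
#'
#' Estimates the number of deflections in a unipolar signal: the signal is
#' compared with a smoothed "normal" template (zero-phase 30 Hz low-pass),
#' and significant deflections are counted in the residual as local-maximum
#' to following-local-minimum drops whose size exceeds
#' `max(min_mV, mad_mult * median(|residual|), rel_frac * largest drop)`.
#' The relative term suppresses filter ringing around a dominant
#' deflection. Invariant to baseline shift; a flat signal scores 0.
#'
#' @param signal numeric vector (mV), sampled at `fs`
#' @param fs sampling rate (Hz)
#' @param min_mV absolute deflection floor (mV)
#' @param mad_mult noise-scaled threshold multiplier
#' @param rel_frac threshold as a fraction of the largest drop
#' @return integer deflection count
#' @export
fractionation_index <- function(signal, fs = 400, min_mV = 0.05, mad_mult = 4,
                                rel_frac = 0.2) {
  if (!length(signal)) stop("empty signal")
  if (diff(range(signal)) < 1e-12) return(0L)
  resid <- signal - smooth_template(signal, fs)
  d <- diff(resid)
  # local extrema (plateau-safe via filled sign changes)
  sgn <- sign(d)
  sgn[sgn == 0] <- NA
  sgn <- zoo_fill(sgn)
  turns <- which(diff(sgn) != 0) + 1L
  if (!length(turns)) return(0L)
  kinds <- sgn[turns - 1L]              # +1 -> local max, -1 -> local min
  drops <- numeric(0)                   # max -> following-min falls
  i <- 1L
  while (i <= length(turns)) {
    if (kinds[i] > 0) {
      j <- i + 1L
      while (j <= length(turns) && kinds[j] > 0) j <- j + 1L
      if (j <= length(turns)) {
        drops <- c(drops, resid[turns[i]] - resid[turns[j]])
        i <- j
        next
      }
    }
    i <- i + 1L
  }
  if (!length(drops)) return(0L)
  thr <- max(min_mV, mad_mult * median(abs(resid)), rel_frac * max(drops))
  sum(drops > thr)
}

# forward-fill then backward-fill NAs in a vector
zoo_fill <- function(x) {
  ok <- !is.na(x)
  if (!any(ok)) return(rep(1, length(x)))
  idx <- cummax(ifelse(ok, seq_along(x), 0L))
  idx[idx == 0L] <- which(ok)[1]
  x[idx]
}

#' Electrogram duration
#'
#' A sliding window (27.5 ms, 11 samples at 400 Hz, stride one sample) is
#' moved across the signal and the standard deviation computed within each
#' window. The duration is the time between the centres of the first and
#' last windows whose SD exceeds `sd_fraction` of the maximum window SD;
#' a flat signal (max SD = 0) scores 0.
#'
#' @param signal numeric vector (mV) at `fs` Hz
#' @param fs sampling rate (Hz)
#' @param window_ms window length (ms)
#' @param sd_fraction active-window threshold as a fraction of the max SD
#' @return duration (ms)
#' @export
egm_duration <- function(signal, fs = 400, window_ms = 27.5, sd_fraction = 0.10) {
  w <- round(window_ms * fs / 1000)          # 11 samples at 400 Hz
  n <- length(signal)
  if (n < w) stop("signal shorter than one analysis window")
  sds <- rolling_sd(signal, w)
  mx <- max(sds)
  if (mx <= 0) return(0)
  active <- which(sds > sd_fraction * mx)
  centres <- (seq_len(n - w + 1L) - 1L + (w - 1L) / 2) / fs * 1000
  centres[max(active)] - centres[min(active)]
}

# rolling standard deviation (window w, stride 1) via cumulative sums;
# sample (n-1) denominator to match sd()
rolling_sd <- function(x, w) {
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x * x))
  i <- seq_len(length(x) - w + 1L)
  s <- cs[i + w] - cs[i]
  s2 <- cs2[i + w] - cs2[i]
  sqrt(pmax((s2 - s * s / w) / (w - 1), 0))
}

#' Frequency power
#'
#' Area under the one-sided power spectrum of the de-meaned signal
#' (rectangular window periodogram). With the convention used here the
#' spectral bins are scaled so that their sum equals the population
#' variance of the signal times the sampling rate in kHz, i.e. Parseval's
#' identity holds exactly and FP has units mV^2/ms. A flat signal scores 0;
#' doubling the amplitude quadruples FP.
#'
#' @param signal numeric vector (mV) at `fs` Hz
#' @param fs sampling rate (Hz)
#' @return frequency power (mV^2/ms)
#' @export
frequency_power <- function(signal, fs = 400) {
  if (!length(signal)) stop("empty signal")
  x <- signal - mean(signal)
  n <- length(x)
  X <- fft(x)
  pxx <- Mod(X)^2 / n^2                 # two-sided, sums to pop. variance
  half <- seq_len(floor(n / 2) + 1L)
  scale <- rep(2, length(half))
  scale[1] <- 1
  if (n %% 2 == 0) scale[length(half)] <- 1
  sum(pxx[half] * scale) * (fs / 1000)  # mV^2 * kHz = mV^2/ms
}

#' Extract the six EAM features from an electrogram map
#'
#' Computes voltage amplitude, conduction velocity, isochronal crowding,
#' fractionation index, electrogram duration and frequency power for every
#' anatomical (non-lid) surface point of one paced map.
#'
#' @param egm_map an `electrogram_map`
#' @param surface the matching `eam_surface`
#' @param neighbors optional precomputed [surface_neighbors()] (10 mm)
#' @param geodesic geodesic (default) or Euclidean crowding neighbourhoods
#' @return an object of class `feature_map`: data.frame with point id,
#'   side, `v_amp`, `cv`, `ic`, `fi`, `egm_dur`, `fp`, `activation`, and a
#'   logical validity flag per feature column attached as attribute "valid"
#' @export
extract_features <- function(egm_map, surface, neighbors = NULL,
                             geodesic = TRUE) {
  sig <- egm_map$signals
  p <- nrow(sig)
  anat <- !surface$lid
  v_amp <- fi <- dur <- fp <- rep(NA_real_, p)
  for (i in which(anat)) {
    s <- sig[i, ]
    v_amp[i] <- voltage_amplitude(s)
    fi[i] <- fractionation_index(s)
    dur[i] <- egm_duration(s)
    fp[i] <- frequency_power(s)
  }
  act <- egm_map$activation
  cv <- conduction_velocity_map(surface, act)$cv
  ic <- isochronal_crowding(surface, act, neighbors = neighbors,
                            geodesic = geodesic)
  cv[!anat] <- NA; ic[!anat] <- NA
  df <- data.frame(point = seq_len(p), side = surface$side,
                   v_amp = v_amp, cv = cv, ic = as.numeric(ic),
                   egm_dur = dur, fi = fi, fp = fp, activation = act)
  attr(df, "valid") <- !is.na(df[, c("v_amp", "cv", "ic", "egm_dur", "fi", "fp")])
  attr(df, "beat") <- egm_map$beat
  attr(df, "site_id") <- egm_map$site_id
  class(df) <- c("feature_map", "data.frame")
  df
}

#' Names of the six EAM features
#' @return character vector of feature column names
#' @export
eam_feature_names <- function() c("v_amp", "cv", "ic", "fi", "egm_dur", "fp")
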