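#' Axial displacement of a rod trajectory
#'
#' Projects the frame-to-frame centre-of-mass increments onto the
#' instantaneous rod axis: `z(t_k) = sum_{j<k} dr(j) . u(j)`. The axis is a
#' nematic director, so its stored sign is arbitrary; consecutive frames are
#' sign-aligned (`u_k -> -u_k` whenever `u_k . u_{k-1} < 0`) before
#' projection, which makes the result invariant to sign flips in the input.
#'
#' @param traj a `rod_trajectory` (from [run_dpd()]) or any data frame with
#'   columns `time`, `x`, `y`, `z` (unwrapped COM) and `ux`, `uy`, `uz`.
#' @param a_x optional mesh size to attach for downstream analysis.
#' @return an `axial_series`: data frame with `time` and cumulative `z`
#'   (starting at 0), with the aligned axis history as an attribute.
#' @export
axial_displacement <- function(traj, a_x = NULL) {
  stopifnot(all(c("time", "x", "y", "z", "ux", "uy", "uz") %in% names(traj)))
  tt <- traj$time
  if (any(diff(tt) <= 0)) stop("non-monotonic frame times")
  u <- as.matrix(traj[, c("ux", "uy", "uz")])
  u <- u / sqrt(rowSums(u^2))
  n <- nrow(u)
  if (n > 1) {
    flip <- cumprod(c(1, ifelse(rowSums(u[-1, , drop = FALSE] *
                                          u[-n, , drop = FALSE]) < 0, -1, 1)))
    u <- u * flip
  }
  r <- as.matrix(traj[, c("x", "y", "z")])
  dz <- rowSums((r[-1, , drop = FALSE] - r[-n, , drop = FALSE]) *
                  u[-n, , drop = FALSE])
  out <- data.frame(time = tt, z = c(0, cumsum(dz)))
  attr(out, "axis") <- u
  attr(out, "a_x") <- a_x
  class(out) <- c("axial_series", "data.frame")
  out
}

#' Construct an axial series from a plain time/displacement table
#'
#' Entry point for externally tracked displacement data (e.g. single-particle
#' tracking exports): any two-column time/z series can be analysed.
#'
#' @param time,z numeric vectors.
#' @param a_x optional mesh size in the same length unit as `z`.
#' @return an `axial_series` (z is shifted so the series starts at 0).
#' @export
axial_series <- function(time, z, a_x = NULL) {
  stopifnot(length(time) == length(z), all(diff(time) > 0))
  out <- data.frame(time = time, z = z - z[1])
  attr(out, "a_x") <- a_x
  class(out) <- c("axial_series", "data.frame")
  out
}

#' Principal axis of a bead cloud
#'
#' Eigenvector of the gyration tensor with the largest eigenvalue; used to
#' recover the rod direction from raw bead coordinates.
#'
#' @param beads n x 3 matrix.
#' @return unit 3-vector.
#' @export
principal_axis <- function(beads) {
  c0 <- sweep(beads, 2, colMeans(beads))
  ev <- eigen(crossprod(c0) / nrow(c0), symmetric = TRUE)
  v <- ev$vectors[, 1]
  v / sqrt(sum(v^2))
}

default_lags <- function(n, n_lags = 40, max_frac = 0.1) {
  lmax <- max(1, floor(n * max_frac))
  unique(round(exp(seq(log(1), log(lmax), length.out = n_lags))))
}

#' Time-averaged axial mean squared displacement
#'
#' `<dz^2(lag)> = <[z(t0 + lag) - z(t0)]^2>` averaged over all admissible
#' time origins for each lag; lags are log-spaced by default. The local
#' log-log exponent `d log <dz^2> / d log t` is estimated by central
#' differences on the log-spaced lags.
#'
#' @param series an `axial_series`, or a list of them (replica average).
#' @param lags integer lags in frames (default: log-spaced up to n/10).
#' @param n_lags number of log-spaced lags when `lags` is NULL.
#' @return an `msd_result`: list with `lags` (time units), `lag_frames`,
#'   `msd`, `local_exponent` and `n_origins`.
#' @export
axial_msd <- function(series, lags = NULL, n_lags = 40) {
  many <- !is.data.frame(series) && is.list(series)
  slist <- if (many) series else list(series)
  n <- min(vapply(slist, nrow, 1L))
  if (n < 100) stop("need at least 100 frames")
  if (is.null(lags)) lags <- default_lags(n, n_lags)
  lags <- lags[lags < n]
  dtf <- stats::median(diff(slist[[1]]$time))
  msd <- sapply(lags, function(l) {
    acc <- 0; cnt <- 0
    for (s in slist) {
      zz <- s$z
      d <- zz[(1 + l):length(zz)] - zz[1:(length(zz) - l)]
      acc <- acc + sum(d^2); cnt <- cnt + length(d)
    }
    acc / cnt
  })
  lt <- log(lags * dtf)
  lm_ <- log(pmax(msd, .Machine$double.xmin))
  expo <- rep(NA_real_, length(lags))
  if (length(lags) > 2) {
    k <- 2:(length(lags) - 1)
    expo[k] <- (lm_[k + 1] - lm_[k - 1]) / (lt[k + 1] - lt[k - 1])
    expo[1] <- (lm_[2] - lm_[1]) / (lt[2] - lt[1])
    expo[length(lags)] <- (lm_[length(lags)] - lm_[length(lags) - 1]) /
      (lt[length(lags)] - lt[length(lags) - 1])
  }
  structure(list(lags = lags * dtf, lag_frames = lags, msd = msd,
                 local_exponent = expo,
                 n_origins = vapply(lags, function(l) sum(vapply(slist, nrow, 1L)) -
                                      l * length(slist), 1)),
            class = "msd_result")
}

# smoothed local exponent: regression of log msd on log lag in a sliding
# window of about a third of a decade (noise-robust version of the central
# difference)
smoothed_exponent <- function(msd, window_decades = 0.35) {
  lt <- log10(msd$lags)
  lm_ <- log(pmax(msd$msd, .Machine$double.xmin))
  n <- length(lt)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    sel <- which(abs(lt - lt[i]) <= window_decades / 2)
    if (length(sel) >= 3) {
      out[i] <- stats::coef(stats::lm.fit(cbind(1, log(msd$lags[sel])),
                                          lm_[sel]))[2]
    } else out[i] <- msd$local_exponent[i]
  }
  out
}

# longest contiguous index run satisfying pred, returned as index range,
# or NULL if no run spans span_ratio in lag
contiguous_window <- function(lags, ok, span_ratio = sqrt(10)) {
  ok[is.na(ok)] <- FALSE
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  best <- NULL
  for (j in which(r$values)) {
    i0 <- starts[j]; i1 <- ends[j]
    if (lags[i1] / lags[i0] >= span_ratio) {
      if (is.null(best) || lags[i1] / lags[i0] > lags[best[2]] / lags[best[1]])
        best <- c(i0, i1)
    }
  }
  best
}

#' Long-time diffusion coefficient from the axial MSD
#'
#' Locates a Fickian window -- a contiguous stretch of at least half a decade
#' of lags whose smoothed local exponent lies in `exponent_band` -- and fits
#' `<dz^2> = 2 D t` through the origin on that window (1-D convention). When
#' no Fickian window exists (e.g. trapped rods) the status is
#' `"no_fickian_window"` and `D` is `NA`: a number is never fabricated.
#'
#' @param msd an `msd_result`.
#' @param reference optional `msd_result` of the same rod in neat solvent;
#'   when given, `D_ratio` = D / D_0 is reported.
#' @param exponent_band acceptable local exponents for Fickian scaling.
#' @return list with `D`, `status`, the fitted `window` (time units), and
#'   optionally `D0` and `D_ratio`.
#' @export
diffusion_coefficient <- function(msd, reference = NULL,
                                  exponent_band = c(0.9, 1.1)) {
  expo <- smoothed_exponent(msd)
  win <- contiguous_window(msd$lags,
                           expo >= exponent_band[1] & expo <= exponent_band[2])
  if (is.null(win)) {
    return(list(D = NA_real_, status = "no_fickian_window", window = NULL))
  }
  sel <- win[1]:win[2]
  # origin-constrained WLS; time-averaged MSD noise has variance ~ t^3, so
  # inverse-variance weights are 1 / t^3
  w <- 1 / msd$lags[sel]^3
  D <- sum(w * msd$msd[sel] * msd$lags[sel]) / (2 * sum(w * msd$lags[sel]^2))
  out <- list(D = D, status = "ok", window = range(msd$lags[sel]))
  if (!is.null(reference)) {
    ref <- diffusion_coefficient(reference, exponent_band = exponent_band)
    out$D0 <- ref$D
    out$D_ratio <- if (ref$status == "ok") D / ref$D else NA_real_
  }
  out
}

#' Displacement probability distribution function G_s(z, t)
#'
#' Self part of the van Hove function: the normalised histogram of axial
#' displacements `z(t0 + lag) - z(t0)` over all time origins, one curve per
#' requested lag. Each curve integrates to one
#' (`sum(gs) * bin_width = 1`).
#'
#' @param series an `axial_series` or list of replicas.
#' @param lags integer lags in frames.
#' @param bin_width histogram bin width in the units of `z`.
#' @return a `dpdf_result`: list with `z` (bin centres), `gs` (matrix, one
#'   column per lag), `lags` (time units) and `n_increments`.
#' @export
dpdf <- function(series, lags, bin_width = 0.25) {
  slist <- if (!is.data.frame(series) && is.list(series)) series else list(series)
  n <- min(vapply(slist, nrow, 1L))
  if (any(lags >= n / 10))
    stop("lags must be below a tenth of the series span")
  dtf <- stats::median(diff(slist[[1]]$time))
  incs <- lapply(lags, function(l) {
    unlist(lapply(slist, function(s) {
      s$z[(1 + l):nrow(s)] - s$z[1:(nrow(s) - l)]
    }))
  })
  rng <- range(unlist(incs))
  breaks <- seq(floor(rng[1] / bin_width) * bin_width - bin_width / 2,
                ceiling(rng[2] / bin_width) * bin_width + bin_width,
                by = bin_width)
  gs <- sapply(incs, function(d) {
    h <- graphics::hist(d, breaks = breaks, plot = FALSE)
    h$density
  })
  if (all(gs == 0)) stop("empty displacement histogram")
  structure(list(z = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 gs = as.matrix(gs), lags = lags * dtf, lag_frames = lags,
                 bin_width = bin_width,
                 n_increments = vapply(incs, length, 1L)),
            class = "dpdf_result")
}

#' Non-Gaussian parameter alpha_1(t)
#'
#' `alpha_1(t) = (1/3) <dz^4(t)> / <dz^2(t)>^2 - 1` for one-dimensional
#' displacements; zero for Gaussian increments, -2/3 for a two-point
#' distribution, 1 for Laplace-distributed displacements.
#'
#' @param series an `axial_series` or list of replicas.
#' @param lags integer lags in frames (default log-spaced up to n/10).
#' @return list with `lags` (time units), `alpha1` and `n_increments`.
#' @export
non_gaussian_alpha1 <- function(series, lags = NULL) {
  slist <- if (!is.data.frame(series) && is.list(series)) series else list(series)
  n <- min(vapply(slist, nrow, 1L))
  if (is.null(lags)) lags <- default_lags(n)
  lags <- lags[lags < n]
  dtf <- stats::median(diff(slist[[1]]$time))
  a1 <- sapply(lags, function(l) {
    d <- unlist(lapply(slist, function(s)
      s$z[(1 + l):nrow(s)] - s$z[1:(nrow(s) - l)]))
    m2 <- mean(d^2)
    if (m2 <= 0) return(NA_real_)
    mean(d^4) / (3 * m2^2) - 1
  })
  list(lags = lags * dtf, lag_frames = lags, alpha1 = a1,
       n_increments = vapply(lags, function(l)
         sum(vapply(slist, nrow, 1L)) - l * length(slist), 1))
}

# ---- wavelet smoothing and hop detection -------------------------------

haar_dwt <- function(x) {
  J <- ceiling(log2(length(x)))
  n2 <- 2^J
  if (n2 > length(x)) x <- c(x, rev(x)[seq_len(n2 - length(x))]) # reflect pad
  details <- vector("list", J)
  a <- x
  for (j in seq_len(J)) {
    even <- a[seq(2, length(a), 2)]; odd <- a[seq(1, length(a), 2)]
    details[[j]] <- (odd - even) / sqrt(2)
    a <- (odd + even) / sqrt(2)
  }
  list(approx = a, details = details, n = length(x))
}

haar_idwt <- function(w) {
  a <- w$approx
  for (j in rev(seq_along(w$details))) {
    d <- w$details[[j]]
    odd <- (a + d) / sqrt(2); even <- (a - d) / sqrt(2)
    a <- as.vector(rbind(odd, even))
  }
  a
}

#' Wavelet smoothing and hop detection for a displacement series
#'
#' Haar multiresolution denoising with the universal threshold
#' `sigma sqrt(2 log n)`, the noise scale `sigma` estimated from the median
#' absolute deviation of the finest-detail coefficients. The hard-thresholded
#' reconstruction is approximately piecewise flat; steps (hops) are detected
#' where the increments of the smoothed signal deviate from their median by
#' more than the threshold, and each detected location is refined on the raw
#' signal by a local two-level change-point fit.
#'
#' @param series an `axial_series`.
#' @param refine_halfwidth frames searched around each candidate when
#'   refining the step location on the raw data.
#' @return list with `smoothed` (an `axial_series`), `steps` (data frame of
#'   frame, time, amplitude) and the `threshold` used.
#' @export
smooth_trajectory <- function(series, refine_halfwidth = 8) {
  z <- series$z
  n <- length(z)
  if (n < 256) stop("need at least 256 frames for wavelet smoothing")
  w <- haar_dwt(z)
  sigma <- stats::mad(w$details[[1]])
  thr <- sigma * sqrt(2 * log(n))
  w$details <- lapply(w$details, function(d) ifelse(abs(d) > thr, d, 0))
  sm <- haar_idwt(w)[seq_len(n)]
  s <- diff(sm)
  dev <- abs(s - stats::median(s))
  scale_ <- stats::mad(s)
  floor_ <- 1e-7 * max(diff(range(z)), .Machine$double.eps) # round-off dust
  cand <- which(dev > pmax(thr, 6 * scale_, floor_))
  steps <- list()
  if (length(cand) > 0) {
    grp <- cumsum(c(1, diff(cand) > 2))
    for (g in unique(grp)) {
      idx <- cand[grp == g]
      centre <- idx[which.max(dev[idx])]
      lo <- max(1, centre - refine_halfwidth)
      hi <- min(n - 1, centre + refine_halfwidth)
      sse <- vapply(lo:hi, function(k) {
        left <- z[lo:k]; right <- z[(k + 1):(hi + 1)]
        sum((left - mean(left))^2) + sum((right - mean(right))^2)
      }, 1)
      k <- (lo:hi)[which.min(sse)]
      amp <- mean(z[(k + 1):min(n, k + refine_halfwidth)]) -
        mean(z[max(1, k - refine_halfwidth + 1):k])
      steps[[length(steps) + 1]] <- data.frame(
        frame = k, time = series$time[k], amplitude = amp)
    }
  }
  smoothed <- series
  smoothed$z <- sm
  list(smoothed = smoothed,
       steps = if (length(steps)) do.call(rbind, steps) else
         data.frame(frame = integer(0), time = numeric(0),
                    amplitude = numeric(0)),
       threshold = thr)
}

# ---- peak detection -----------------------------------------------------

#' Local maxima of a curve with a prominence filter
#'
#' Kernel-smooths `y`, finds local maxima and keeps those whose prominence
#' (height above the higher of the two flanking minima separating them from
#' taller peaks) exceeds `prominence_frac` of the global maximum.
#'
#' @param x,y coordinates of the curve.
#' @param prominence_frac minimum prominence as a fraction of `max(y)`.
#' @param smooth_points width (points) of the moving-average pre-smoother.
#' @return data frame with peak `x`, `y` and `prominence`.
#' @export
find_peaks <- function(x, y, prominence_frac = 0.1, smooth_points = 3) {
  if (smooth_points > 1) {
    k <- rep(1 / smooth_points, smooth_points)
    ys <- stats::filter(y, k, sides = 2)
    ys[is.na(ys)] <- y[is.na(ys)]
    y <- as.numeric(ys)
  }
  n <- length(y)
  if (n < 3) return(data.frame(x = numeric(0), y = numeric(0),
                               prominence = numeric(0)))
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n], FALSE)
  idx <- which(is_max)
  if (!length(idx)) return(data.frame(x = numeric(0), y = numeric(0),
                                      prominence = numeric(0)))
  prom <- vapply(idx, function(i) {
    left <- y[1:i]; right <- y[i:n]
    hl <- if (any(left > y[i])) min(left[seq(max(which(left > y[i])), i)]) else min(left)
    hr <- if (any(right > y[i])) min(right[seq(1, min(which(right > y[i])))]) else min(right)
    y[i] - max(hl, hr)
  }, 1)
  keep <- prom >= prominence_frac * max(y)
  data.frame(x = x[idx[keep]], y = y[idx[keep]], prominence = prom[keep])
}

# ---- regime classification ---------------------------------------------

#' Classifier thresholds
#'
#' All decision thresholds of [classify_regime()], exposed for tuning:
#' `trapped_exponent` (MSD saturation), `plateau_exponent` (intermediate
#' plateau), `fickian_band`, `alpha1_threshold` (non-Gaussianity separating
#' sliding from Brownian), `peak_spacing` (lattice-commensurate G_s comb, in
#' units of a_x), `trapped_range` (maximum excursion of a trapped rod, in
#' a_x) and `span_ratio` (minimal lag span -- half a decade -- for a window).
#'
#' @param ... overrides of the defaults.
#' @return named list of thresholds.
#' @export
classifier_config <- function(...) {
  cfg <- list(trapped_exponent = 0.1, plateau_exponent = 0.25,
              fickian_band = c(0.9, 1.1), alpha1_threshold = 0.3,
              peak_spacing = c(0.8, 1.2), trapped_range = 0.8,
              span_ratio = sqrt(10))
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown classifier options: ", paste(bad, collapse = ", "))
  modifyList(cfg, over)
}

#' Classify the dynamical regime of a rod trajectory
#'
#' Decision rules over the trajectory observables:
#' \itemize{
#' \item trapped: the MSD saturates (smoothed local exponent below
#'   `trapped_exponent` over the last decade of lags) and the rod never
#'   leaves its cell (`z_range < trapped_range * a_x`);
#' \item hopping: an intermediate plateau (exponent below
#'   `plateau_exponent` over at least half a decade before the terminal
#'   lags) together with a G_s peak comb spaced within `peak_spacing` of
#'   a_x;
#' \item sliding_fast: a Fickian window with no plateau, but non-Gaussian
#'   displacements (peak alpha_1 at or above `alpha1_threshold`) or a
#'   multi-peaked G_s;
#' \item brownian: a Fickian window, no plateau, near-Gaussian G_s.
#' }
#' Conflicting evidence resolves by precedence trapped > hopping >
#' sliding_fast > brownian; if no rule fires the nearest label is chosen and
#' flagged low-confidence.
#'
#' @param msd an `msd_result`.
#' @param dpdf_res a `dpdf_result` evaluated at a lag where the displacement
#'   spread is of order a_x (see [classify_trajectory()]).
#' @param alpha1 output of [non_gaussian_alpha1()].
#' @param steps optional hop table from [smooth_trajectory()].
#' @param a_x mesh size in the units of `z`.
#' @param z_range maximum |z - z[1]| over the trajectory.
#' @param config a [classifier_config()].
#' @return a `regime_label`: list with `label`, `confidence` and `evidence`.
#' @export
classify_regime <- function(msd, dpdf_res, alpha1, steps = NULL, a_x,
                            z_range, config = classifier_config()) {
  expo <- smoothed_exponent(msd)
  nl <- length(msd$lags)
  last_dec <- which(msd$lags >= msd$lags[nl] / 10)
  sat_exponent <- mean(expo[last_dec], na.rm = TRUE)
  fick <- contiguous_window(msd$lags,
                            expo >= config$fickian_band[1] &
                              expo <= config$fickian_band[2],
                            config$span_ratio)
  # plateau: a low-exponent window that is not the terminal decade
  plat_ok <- expo < config$plateau_exponent
  if (!is.null(fick)) plat_ok[fick[1]:nl] <- FALSE
  plat_ok[msd$lags >= msd$lags[nl] / 3] <-
    plat_ok[msd$lags >= msd$lags[nl] / 3] & sat_exponent >= config$trapped_exponent
  plateau <- contiguous_window(msd$lags, plat_ok, config$span_ratio)
  # G_s peaks at the evaluation lag (last column)
  gs <- dpdf_res$gs[, ncol(dpdf_res$gs)]
  pk <- find_peaks(dpdf_res$z, gs)
  spacing <- if (nrow(pk) >= 2) mean(diff(sort(pk$x))) else NA_real_
  comb_like <- !is.na(spacing) &&
    spacing >= config$peak_spacing[1] * a_x &&
    spacing <= config$peak_spacing[2] * a_x
  # alpha_1 summary: only lags with >= 100 independent increments carry a
  # usable kurtosis estimate; a running median suppresses single-lag noise
  a1_ok <- is.finite(alpha1$alpha1)
  if (!is.null(alpha1$lag_frames) && !is.null(alpha1$n_increments))
    a1_ok <- a1_ok & alpha1$n_increments / pmax(alpha1$lag_frames, 1) >= 100
  a1_vals <- alpha1$alpha1[a1_ok]
  if (length(a1_vals) >= 3) a1_vals <- stats::runmed(a1_vals, 3)
  a1_peak <- if (length(a1_vals)) max(a1_vals) else NA_real_
  evidence <- list(sat_exponent = sat_exponent, fickian_window = !is.null(fick),
                   plateau = !is.null(plateau), peak_spacing = spacing,
                   n_peaks = nrow(pk), alpha1_peak = a1_peak,
                   z_range = z_range,
                   n_hops = if (!is.null(steps)) nrow(steps) else NA_integer_)
  conf <- "ok"
  # a Fickian window only counts as "reached" if the MSD is still growing
  # at the terminal lags (rules out the short-time diffusive stretch of a
  # confined process)
  fick_reached <- !is.null(fick) && !is.na(sat_exponent) && sat_exponent >= 0.5
  label <- if (!is.na(sat_exponent) && sat_exponent < config$trapped_exponent &&
               z_range < config$trapped_range * a_x) {
    "trapped"
  } else if (!is.null(plateau) && comb_like) {
    "hopping"
  } else if (fick_reached && is.null(plateau) &&
             ((!is.na(a1_peak) && a1_peak >= config$alpha1_threshold) ||
              nrow(pk) >= 2)) {
    "sliding_fast"
  } else if (fick_reached && is.null(plateau)) {
    "brownian"
  } else {
    conf <- "low"
    if (!is.null(plateau) || (!is.na(sat_exponent) &&
                              sat_exponent < config$plateau_exponent)) {
      if (z_range < config$trapped_range * a_x) "trapped" else "hopping"
    } else if (!is.na(a1_peak) && a1_peak >= config$alpha1_threshold) {
      "sliding_fast"
    } else "brownian"
  }
  structure(list(label = label, confidence = conf, evidence = evidence),
            class = "regime_label")
}

#' @export
print.regime_label <- function(x, ...) {
  cat("Regime:", x$label, if (x$confidence != "ok") "(low confidence)", "\n")
  ev <- x$evidence
  cat(sprintf("  saturation exponent %.2f | fickian %s | plateau %s | peaks %d (spacing %.2f) | alpha1 %.2f\n",
              ev$sat_exponent, ev$fickian_window, ev$plateau, ev$n_peaks,
              ev$peak_spacing, ev$alpha1_peak))
  invisible(x)
}

#' One-call regime classification of an axial series
#'
#' Computes the MSD, non-Gaussian parameter and displacement distribution at
#' an automatically chosen evaluation lag (the smallest lag whose root mean
#' squared displacement exceeds 1.5 a_x, so neighbouring comb peaks are
#' populated), then applies [classify_regime()].
#'
#' @param series an `axial_series` with a known mesh size.
#' @param a_x mesh size (defaults to the series attribute).
#' @param config a [classifier_config()].
#' @param bin_width G_s histogram bin (defaults to a_x / 10).
#' @return a `regime_label`.
#' @export
classify_trajectory <- function(series, a_x = attr(series, "a_x"),
                                config = classifier_config(),
                                bin_width = a_x / 10) {
  stopifnot(!is.null(a_x))
  n <- nrow(series)
  msd <- axial_msd(series)
  a1 <- non_gaussian_alpha1(series, lags = msd$lag_frames)
  eval_lag <- msd$lag_frames[which(msd$msd >= (1.5 * a_x)^2)[1]]
  if (is.na(eval_lag)) eval_lag <- msd$lag_frames[length(msd$lag_frames)]
  eval_lag <- min(eval_lag, floor(n / 10) - 1)
  gs <- dpdf(series, lags = max(1, eval_lag), bin_width = bin_width)
  classify_regime(msd, gs, a1, steps = NULL, a_x = a_x,
                  z_range = max(abs(series$z - series$z[1])), config = config)
}
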