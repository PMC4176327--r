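#' Locate alternating peaks and troughs of an oscillatory signal
#'
#' Local extrema on the stored grid, with three refinements: plateaus
#' (runs of equal values, as produced by saturating signals) are resolved to
#' their centre; isolated extrema are refined by three-point quadratic
#' interpolation; and ripples whose peak-to-trough prominence is below
#' \code{min_prominence} times the signal range are merged away, so the
#' returned sequence strictly alternates peak/trough.
#'
#' @param traj a \code{clock_trajectory}, or a numeric vector of times (then
#'   \code{values} must be given).
#' @param signal signal name (for a trajectory).
#' @param discard initial transient to drop (h); default 240 (ten nominal
#'   cycles).
#' @param values numeric vector of signal values when \code{traj} is a time
#'   vector.
#' @param min_prominence relative prominence below which a peak/trough pair
#'   is treated as numerical ripple (default 1e-3 of the signal range).
#'
#' @return A data frame with columns \code{time}, \code{value}, \code{type}
#'   (\code{"peak"}/\code{"trough"}), strictly alternating; zero rows when
#'   the signal has no alternating extrema (e.g. a constant).
#' @export
extrema <- function(traj, signal = NULL, discard = 240, values = NULL,
                    min_prominence = 1e-3) {
  if (inherits(traj, "clock_trajectory")) {
    time <- traj$time
    y <- trajectory_signal(traj, signal)
  } else {
    time <- as.numeric(traj)
    y <- as.numeric(values)
  }
  keep <- time >= (min(time) + discard)
  time <- time[keep]; y <- y[keep]
  n <- length(y)
  if (n < 5) return(.empty_extrema())
  rng <- max(y) - min(y)
  if (rng <= 0 || rng < 1e-12 * max(abs(y), 1e-300)) return(.empty_extrema())

  s <- sign(diff(y))
  nz <- which(s != 0)
  if (length(nz) < 2) return(.empty_extrema())
  idx <- integer(0); typ <- character(0)
  for (k in seq_len(length(nz) - 1)) {
    a <- nz[k]; b <- nz[k + 1]
    if (s[a] > 0 && s[b] < 0) {
      idx <- c(idx, as.integer(round((a + 1 + b) / 2)))
      typ <- c(typ, "peak")
    } else if (s[a] < 0 && s[b] > 0) {
      idx <- c(idx, as.integer(round((a + 1 + b) / 2)))
      typ <- c(typ, "trough")
    }
  }
  if (!length(idx)) return(.empty_extrema())

  # merge sub-threshold ripples: drop adjacent pairs with tiny prominence
  tol <- min_prominence * rng
  repeat {
    if (length(idx) < 2) break
    prom <- abs(diff(y[idx]))
    j <- which(prom < tol)
    if (!length(j)) break
    drop <- sort(unique(c(j[1], j[1] + 1)))
    idx <- idx[-drop]; typ <- typ[-drop]
  }
  if (!length(idx)) return(.empty_extrema())
  # enforce strict alternation (keep the more extreme of equal-type runs)
  keep <- rep(TRUE, length(idx))
  for (k in seq_len(length(idx) - 1)) {
    if (!keep[k]) next
    if (typ[k + 1] == typ[k]) {
      better <- if (typ[k] == "peak") y[idx[k + 1]] > y[idx[k]]
                else y[idx[k + 1]] < y[idx[k]]
      if (better) keep[k] <- FALSE else keep[k + 1] <- FALSE
    }
  }
  idx <- idx[keep]; typ <- typ[keep]

  # quadratic refinement away from plateaus and boundaries
  tref <- time[idx]; vref <- y[idx]
  dt <- time[2] - time[1]
  for (k in seq_along(idx)) {
    i <- idx[k]
    if (i <= 1 || i >= n) next
    y0 <- y[i - 1]; y1 <- y[i]; y2 <- y[i + 1]
    den <- y0 - 2 * y1 + y2
    if (abs(den) > 1e-14 * max(abs(y1), 1e-300)) {
      off <- 0.5 * (y0 - y2) / den
      if (abs(off) <= 1) {
        tref[k] <- time[i] + off * dt
        vref[k] <- y1 - 0.25 * (y0 - y2) * off
      }
    }
  }
  data.frame(time = tref, value = vref, type = typ,
             stringsAsFactors = FALSE)
}

.empty_extrema <- function() {
  data.frame(time = numeric(0), value = numeric(0), type = character(0),
             stringsAsFactors = FALSE)
}

#' Period, amplitude and phases of one signal
#'
#' The period is the mean of successive peak-to-peak intervals over the
#' post-transient measurement window; the amplitude is the mean peak value
#' minus the mean trough value (averaging over cycles damps numerical
#' ripple).  The coefficient of variation of the peak intervals is reported,
#' with a non-stationarity warning flag when it exceeds 5 per cent.
#'
#' @inheritParams extrema
#' @param min_cycles minimum number of full cycles (peaks) required to call
#'   the signal rhythmic.
#' @return An object of class \code{osc_stats}: list with \code{period},
#'   \code{amplitude}, \code{peak_phase} and \code{trough_phase} (h, modulo
#'   the period), \code{period_cv}, \code{n_peaks}, \code{is_rhythmic},
#'   \code{nonstationary} and the signal name.
#' @export
osc_stats <- function(traj, signal, discard = 240, min_prominence = 1e-3,
                      min_cycles = 3) {
  ex <- extrema(traj, signal, discard = discard,
                min_prominence = min_prominence)
  pk <- ex[ex$type == "peak", , drop = FALSE]
  tr <- ex[ex$type == "trough", , drop = FALSE]
  out <- list(signal = signal, period = NA_real_, amplitude = NA_real_,
              peak_phase = NA_real_, trough_phase = NA_real_,
              period_cv = NA_real_, n_peaks = nrow(pk),
              is_rhythmic = FALSE, nonstationary = FALSE)
  class(out) <- "osc_stats"
  if (nrow(pk) < min_cycles || nrow(tr) < min_cycles - 1) return(out)
  iv <- diff(pk$time)
  out$period <- mean(iv)
  out$period_cv <- stats::sd(iv) / out$period
  out$amplitude <- mean(pk$value) - mean(tr$value)
  out$peak_phase <- pk$time[1] %% out$period
  out$trough_phase <- tr$time[1] %% out$period
  out$is_rhythmic <- TRUE
  if (is.finite(out$period_cv) && out$period_cv > 0.05) {
    out$nonstationary <- TRUE
    warning("peak-interval CV exceeds 5%; oscillation may be non-stationary",
            call. = FALSE)
  }
  out
}

#' @export
print.osc_stats <- function(x, ...) {
  if (!x$is_rhythmic) {
    cat("<osc_stats> ", x$signal, ": not rhythmic (", x$n_peaks,
        " peaks)\n", sep = "")
  } else {
    cat(sprintf("<osc_stats> %s: period %.3f h (CV %.2g), amplitude %.4g, peak phase %.2f h\n",
                x$signal, x$period, x$period_cv, x$amplitude, x$peak_phase))
  }
  invisible(x)
}

#' Combined period/amplitude summary for a signal
#'
#' Convenience wrapper returning the \code{osc_stats} fields as a one-row
#' data frame, the form used by the sweep tables.
#'
#' @inheritParams osc_stats
#' @return One-row data frame.
#' @export
period_and_amplitude <- function(traj, signal, discard = 240) {
  s <- suppressWarnings(osc_stats(traj, signal, discard = discard))
  data.frame(signal = signal, period = s$period, amplitude = s$amplitude,
             period_cv = s$period_cv, is_rhythmic = s$is_rhythmic,
             stringsAsFactors = FALSE)
}

#' Transcriptional delay of the repressor mRNA peak behind its binding trough
#'
#' In the two-loop conceptual model the PLBS activity peak marks the trough
#' of R1 protein binding.  Without the auxiliary loop the total
#' transcriptional drive of \emph{R1} is the PLBS activity itself, so drive
#' peak and binding trough coincide and the delay is zero.  The auxiliary
#' loop adds the later-phased ALBS drive, which pulls the total drive peak
#' -- and with it the \emph{R1} mRNA peak -- behind the binding trough by
#' the transcriptional delay returned here.  It is measured as the mean
#' circular difference (modulo the period) from each PLBS-activity peak to
#' the nearest subsequent peak of the total \emph{R1} transcriptional drive
#' \code{v_P * PLBS + v_A * ALBS}.
#'
#' @param traj a \code{clock_trajectory} from the conceptual model.
#' @param discard transient to drop (h).
#' @return Delay in hours (in [0, period)).
#' @export
transcriptional_delay <- function(traj, discard = 240) {
  stopifnot(inherits(traj, "clock_trajectory"))
  p <- traj$params
  if (!inherits(p, "conceptual_params"))
    stop("transcriptional_delay is defined for the conceptual two-loop model")
  st <- suppressWarnings(osc_stats(traj, "PLBS", discard = discard))
  if (!st$is_rhythmic) stop("trajectory is not rhythmic")
  drive <- p$v_P * traj$signals[, "PLBS"] + p$v_A * traj$signals[, "ALBS"]
  exP <- extrema(traj, "PLBS", discard = discard)
  exD <- extrema(traj$time, values = drive, discard = discard)
  pkP <- exP$time[exP$type == "peak"]
  pkD <- exD$time[exD$type == "peak"]
  if (length(pkD) < 2) stop("total drive has no alternating extrema")
  lags <- vapply(pkP, function(tt) {
    d <- pkD - tt
    d <- d[d >= -1e-6]
    if (!length(d)) NA_real_ else min(d)
  }, numeric(1))
  lags <- lags[is.finite(lags)]
  if (!length(lags)) stop("could not pair binding troughs with drive peaks")
  mean(pmax(lags, 0)) %% st$period
}

#' Remove a slow baseline by a centred running average
#'
#' Subtracts the centred moving average of the stated window (24 h by
#' default, the convention for luminometry records), dropping half a window
#' at each edge where the average is undefined.
#'
#' @param time uniformly sampled times (h).
#' @param value signal values.
#' @param window running-average window (h).
#' @return Data frame with columns \code{time} and \code{value} (detrended),
#'   shorter than the input by one window.
#' @export
detrend <- function(time, value, window = 24) {
  stopifnot(length(time) == length(value), length(time) > 2)
  dt <- diff(time)
  if (max(dt) - min(dt) > 1e-6 * mean(dt))
    stop("detrend requires uniform sampling")
  span <- time[length(time)] - time[1]
  if (span <= window) stop("record shorter than the detrending window")
  k <- round(window / mean(dt))
  if (k %% 2 == 0) k <- k + 1  # centred window
  if (k >= length(value)) stop("record shorter than the detrending window")
  base <- zoo::rollmean(value, k, fill = NA, align = "center")
  ok <- !is.na(base)
  data.frame(time = time[ok], value = value[ok] - base[ok])
}

#' Period from a damped sine fit to a detrended trace
#'
#' Least-squares fit of \eqn{A e^{-\lambda t} \sin(2\pi t/T + \phi)} to a
#' detrended record, the standard way period is read from luminometry
#' rhythms.  The period is initialised from the dominant discrete-spectrum
#' frequency and the fit is restarted over a small grid of nearby periods;
#' the best converged fit is returned.  A trace whose fitted oscillation is
#' not distinguishable from its residual noise is flagged as non-rhythmic
#' rather than given a confident period.
#'
#' @param time uniformly sampled times (h) of the detrended trace.
#' @param value detrended values.
#' @param period_range admissible period window (h).
#' @return List with \code{period}, \code{amplitude}, \code{damping}
#'   (1/h), \code{phase} (rad), \code{rmse}, \code{rhythmic} (logical:
#'   fitted amplitude at mid-record above twice the residual scale) and
#'   \code{converged}.
#' @export
sine_fit_period <- function(time, value, period_range = c(16, 36)) {
  stopifnot(length(time) == length(value), length(time) > 10)
  t0 <- time - time[1]
  span <- t0[length(t0)]
  if (span < 3 * period_range[1])
    stop("trace must cover at least three cycles")
  dt <- mean(diff(time))
  # periodogram initialisation
  sp <- stats::spec.pgram(stats::ts(value, deltat = dt), plot = FALSE,
                          detrend = TRUE, taper = 0.1)
  per <- 1 / sp$freq
  inwin <- per >= period_range[1] & per <= period_range[2]
  T0 <- if (any(inwin)) per[inwin][which.max(sp$spec[inwin])]
        else per[which.max(sp$spec)]
  A0 <- stats::sd(value) * sqrt(2)
  best <- NULL
  for (Tinit in unique(pmin(pmax(T0 * c(0.9, 1, 1.1), period_range[1]),
                            period_range[2]))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        value ~ A * exp(-lam * t0) * sin(2 * pi * t0 / T + phi),
        start = list(A = A0, lam = 0.005, T = Tinit, phi = 0),
        lower = c(A = 0, lam = -0.05, T = period_range[1], phi = -2 * pi),
        upper = c(A = Inf, lam = 0.5, T = period_range[2], phi = 2 * pi),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rmse <- sqrt(mean(stats::residuals(fit)^2))
    if (is.null(best) || rmse < best$rmse) {
      cf <- stats::coef(fit)
      best <- list(period = unname(cf["T"]), amplitude = unname(cf["A"]),
                   damping = unname(cf["lam"]), phase = unname(cf["phi"]),
                   rmse = rmse, converged = TRUE)
    }
  }
  if (is.null(best))
    stop("damped sine fit failed to converge from any initialisation")
  # amplitude at mid-record vs residual scale: rhythmicity call
  amp_mid <- best$amplitude * exp(-best$damping * span / 2)
  best$rhythmic <- is.finite(amp_mid) && amp_mid > 2 * best$rmse
  best
}
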