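#' Rotation angle of a point in the amplitude plane
#'
#' The angle theta of the ray through a point (Amp_PLBS, Amp_ALBS) of the
#' amplitude plane, defined by cot(theta) = Amp_PLBS / Amp_ALBS, i.e.
#' \code{theta = atan(amp_albs / amp_plbs)}.  The period surface rises with
#' theta: rays of constant intensity ratio are (approximate) contour lines.
#'
#' @param amp_plbs,amp_albs positive oscillation amplitudes of the PLBS and
#'   ALBS (RORE) activity.
#' @return Angle in radians, in (0, pi/2).
#' @examples
#' rotation_angle(1, 1)            # pi/4
#' rotation_angle(4.2888, 1)       # 0.2291 rad
#' @export
rotation_angle <- function(amp_plbs, amp_albs) {
  if (any(!is.finite(amp_plbs)) || any(!is.finite(amp_albs)) ||
      any(amp_plbs <= 0) || any(amp_albs <= 0))
    stop("amplitudes must be positive")
  atan2(amp_albs, amp_plbs)
}

.sweep_discard <- 240
.sweep_tend <- 480

# measure one conceptual run: list(period, amp_plbs, amp_albs, cv, rhythmic)
.measure_conceptual <- function(params, t_end = .sweep_tend, dt = 0.05,
                                discard = .sweep_discard) {
  traj <- integrate_dde(params, t_span = c(0, t_end), dt = dt)
  sR <- suppressWarnings(osc_stats(traj, "R1", discard = discard))
  sP <- suppressWarnings(osc_stats(traj, "PLBS", discard = discard))
  sA <- suppressWarnings(osc_stats(traj, "ALBS", discard = discard))
  list(period = sR$period, period_cv = sR$period_cv,
       amp_plbs = sP$amplitude, amp_albs = sA$amplitude,
       rhythmic = sR$is_rhythmic && sP$is_rhythmic && sA$is_rhythmic)
}

#' Period surface over the PLBS-ALBS amplitude plane
#'
#' Reproduces the in-silico amplitude manipulation: for every pair of
#' modulation scales on the default grid, the PLBS and ALBS activities are
#' re-scaled about their midpoints, the model is integrated, and the
#' realized activity amplitudes and the period are measured.  Points that do
#' not sustain a circadian limit cycle are flagged
#' (\code{is_rhythmic = FALSE}) and retained, never dropped silently: this
#' covers true arrhythmicity, periods outside the circadian plausibility
#' window, and marginal oscillators whose realized PLBS modulation falls
#' below \code{integrity} times the imposed modulation (sub-limit-cycle
#' ringing near the oscillatory boundary).
#'
#' @param base a [conceptual_params()] object (wild-type calibration).
#' @param scales_P,scales_A modulation scale factors applied to
#'   \code{amp_scale_P} / \code{amp_scale_A}; default 25 log-spaced values
#'   in [0.2, 1] (attenuation of either element's modulation depth).
#' @param dt integration step (h) for the sweep.
#' @param t_end,discard integration end and transient discard (h).
#' @param period_window circadian plausibility window (h) outside which a
#'   measured period is flagged non-circadian.
#' @param integrity minimal fraction of the imposed PLBS modulation that
#'   must be realized for a point to count as a robust limit cycle.
#' @return Data frame of sweep records: \code{scale_P}, \code{scale_A},
#'   \code{amp_plbs}, \code{amp_albs}, \code{ratio}, \code{theta},
#'   \code{period}, \code{period_cv}, \code{is_rhythmic}.
#' @seealso [ratio_period_curve()], [rotation_angle()]
#' @export
sweep_surface <- function(base = conceptual_params(),
                          scales_P = exp(seq(log(0.2), log(1), length.out = 25)),
                          scales_A = exp(seq(log(0.2), log(1), length.out = 25)),
                          dt = 0.05, t_end = .sweep_tend,
                          discard = .sweep_discard,
                          period_window = c(16, 32), integrity = 0.55) {
  validate_params(base)
  wt <- .measure_conceptual(base, t_end, dt, discard)
  raw_wt <- wt$amp_plbs / base$amp_scale_P
  rows <- vector("list", length(scales_P) * length(scales_A))
  k <- 0
  for (gP in scales_P) for (gA in scales_A) {
    p <- base
    p$amp_scale_P <- base$amp_scale_P * gP
    p$amp_scale_A <- base$amp_scale_A * gA
    m <- tryCatch(.measure_conceptual(p, t_end, dt, discard),
                  error = function(e) list(period = NA_real_,
                                           period_cv = NA_real_,
                                           amp_plbs = NA_real_,
                                           amp_albs = NA_real_,
                                           rhythmic = FALSE))
    ok <- isTRUE(m$rhythmic) &&
      is.finite(m$period) &&
      m$period >= period_window[1] && m$period <= period_window[2] &&
      is.finite(m$amp_plbs) && is.finite(m$amp_albs) &&
      m$amp_plbs >= max(0.05, integrity * p$amp_scale_P * raw_wt) &&
      m$amp_albs >= 0.02
    k <- k + 1
    rows[[k]] <- data.frame(
      scale_P = gP, scale_A = gA,
      amp_plbs = m$amp_plbs, amp_albs = m$amp_albs,
      ratio = m$amp_plbs / m$amp_albs,
      theta = ifelse(is.finite(m$amp_plbs) && is.finite(m$amp_albs) &&
                       m$amp_plbs > 0 && m$amp_albs > 0,
                     atan2(m$amp_albs, m$amp_plbs), NA_real_),
      period = m$period, period_cv = m$period_cv, is_rhythmic = ok)
  }
  out <- do.call(rbind, rows)
  attr(out, "wild_type") <- wt
  out
}

#' Ratio-versus-period relation of a sweep
#'
#' Orders the rhythmic sweep records by intensity ratio and quantifies the
#' ratio law: the Spearman correlation of (ratio, period), expected strongly
#' negative, together with the per-axis correlations of each single
#' amplitude with the period, expected weak -- one amplitude alone does not
#' determine the period.
#'
#' @param records a sweep table from [sweep_surface()].
#' @param min_points minimum number of rhythmic records required.
#' @return List with \code{curve} (data frame of rhythmic (ratio, period)
#'   pairs sorted by ratio), \code{rho_ratio}, \code{rho_amp_plbs},
#'   \code{rho_amp_albs} and \code{n}.
#' @export
ratio_period_curve <- function(records, min_points = 10) {
  ok <- records$is_rhythmic & is.finite(records$ratio) &
    is.finite(records$period)
  if (sum(ok) < min_points)
    stop("fewer than ", min_points, " rhythmic sweep records")
  r <- records[ok, ]
  r <- r[order(r$ratio), ]
  list(curve = data.frame(ratio = r$ratio, period = r$period),
       rho_ratio = stats::cor(r$ratio, r$period, method = "spearman"),
       rho_amp_plbs = stats::cor(r$amp_plbs, r$period, method = "spearman"),
       rho_amp_albs = stats::cor(r$amp_albs, r$period, method = "spearman"),
       n = nrow(r))
}

#' Period span along fixed-ratio rays
#'
#' Collects rhythmic sweep records whose intensity ratio lies within a
#' narrow band around each target ratio and reports the spread of their
#' periods; on the model's period surface, rays of constant ratio are
#' approximate contour lines.
#'
#' @param records sweep table from [sweep_surface()].
#' @param ratios target ratios (rays).
#' @param band half-width of the log-ratio band defining a ray.
#' @return Data frame with one row per ray: ratio, n, mean/min/max period,
#'   span.
#' @export
ray_period_span <- function(records, ratios = c(4.2888, 1.3764, 0.6682),
                            band = 0.05) {
  ok <- records$is_rhythmic & is.finite(records$ratio) &
    is.finite(records$period)
  do.call(rbind, lapply(ratios, function(rt) {
    sel <- ok & abs(log(records$ratio / rt)) < band
    if (!any(sel))
      return(data.frame(ratio = rt, n = 0L, period_mean = NA_real_,
                        period_min = NA_real_, period_max = NA_real_,
                        span = NA_real_))
    Tn <- records$period[sel]
    data.frame(ratio = rt, n = sum(sel), period_mean = mean(Tn),
               period_min = min(Tn), period_max = max(Tn),
               span = diff(range(Tn)))
  }))
}

#' Transmission of an amplitude perturbation between loops
#'
#' Perturbs the inhibition strength of one loop -- the depth with which its
#' repressor modulates its binding element, i.e. the element's modulation
#' scale -- over a range of factors, and records both normalized activity
#' amplitudes relative to the wild type.  The fitted slope (through the
#' wild-type point (1,1)) of the responding loop's normalized amplitude
#' against the perturbed loop's is the transmission coefficient: near 1 for
#' primary-loop perturbations (complete transmission to the ALBS/RORE),
#' clearly below 1 for auxiliary-loop perturbations (partial transmission to
#' the PLBS).
#'
#' @param base a [conceptual_params()] object.
#' @param loop which loop's inhibition strength to perturb.
#' @param scales perturbation factors (default 9 log-spaced in
#'   [0.85, 1.18]).
#' @param dt,t_end,discard integration settings.
#' @return List with \code{table} (scale, normalized Amp_PLBS and
#'   Amp_ALBS, period), \code{slope}, \code{loop}.
#' @export
transmission_curve <- function(base = conceptual_params(),
                               loop = c("primary", "auxiliary"),
                               scales = exp(seq(log(0.85), log(1.18),
                                                length.out = 9)),
                               dt = 0.05, t_end = .sweep_tend,
                               discard = .sweep_discard) {
  loop <- match.arg(loop)
  validate_params(base)
  wt <- .measure_conceptual(base, t_end, dt, discard)
  rows <- lapply(scales, function(s) {
    p <- base
    if (loop == "primary") p$amp_scale_P <- base$amp_scale_P * s
    else p$amp_scale_A <- base$amp_scale_A * s
    m <- tryCatch(.measure_conceptual(p, t_end, dt, discard),
                  error = function(e) list(period = NA, amp_plbs = NA,
                                           amp_albs = NA, rhythmic = FALSE))
    data.frame(scale = s, amp_plbs_rel = m$amp_plbs / wt$amp_plbs,
               amp_albs_rel = m$amp_albs / wt$amp_albs, period = m$period,
               is_rhythmic = isTRUE(m$rhythmic))
  })
  tab <- do.call(rbind, rows)
  ok <- tab$is_rhythmic & is.finite(tab$amp_plbs_rel) &
    is.finite(tab$amp_albs_rel)
  if (sum(ok) < 3) stop("too few rhythmic transmission points")
  x <- if (loop == "primary") tab$amp_plbs_rel[ok] else tab$amp_albs_rel[ok]
  y <- if (loop == "primary") tab$amp_albs_rel[ok] else tab$amp_plbs_rel[ok]
  slope <- sum((x - 1) * (y - 1)) / sum((x - 1)^2)
  list(table = tab, slope = slope, loop = loop)
}

#' Period over a two-dimensional inhibition-strength grid
#'
#' Scans the modulation strengths of both loops jointly and reports the
#' maximal period deviation from the wild type along each single axis and
#' along the diagonal (both strengths perturbed together).
#'
#' @param base a [conceptual_params()] object.
#' @param scales_primary,scales_auxiliary symmetric perturbation factors
#'   (default 9 log-spaced in [0.7, 1.43]; the centre value is the wild
#'   type).
#' @param dt,t_end,discard integration settings.
#' @return List with \code{period} (matrix, primary scale x auxiliary
#'   scale), \code{period_wt}, \code{span_primary}, \code{span_auxiliary},
#'   \code{span_diagonal} and \code{diagonal_dominant} (logical: diagonal
#'   span exceeds 1.5 times each single-axis span).
#' @export
dual_perturbation_grid <- function(base = conceptual_params(),
                                   scales_primary =
                                     exp(seq(log(0.7), log(1.43),
                                             length.out = 9)),
                                   scales_auxiliary =
                                     exp(seq(log(0.7), log(1.43),
                                             length.out = 9)),
                                   dt = 0.05, t_end = .sweep_tend,
                                   discard = .sweep_discard) {
  validate_params(base)
  n1 <- length(scales_primary); n2 <- length(scales_auxiliary)
  Tg <- matrix(NA_real_, n1, n2,
               dimnames = list(signif(scales_primary, 4),
                               signif(scales_auxiliary, 4)))
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    p <- base
    p$amp_scale_P <- base$amp_scale_P * scales_primary[i]
    p$amp_scale_A <- base$amp_scale_A * scales_auxiliary[j]
    m <- tryCatch(.measure_conceptual(p, t_end, dt, discard),
                  error = function(e) list(period = NA_real_))
    Tg[i, j] <- m$period
  }
  iwt <- which.min(abs(log(scales_primary)))
  jwt <- which.min(abs(log(scales_auxiliary)))
  Twt <- Tg[iwt, jwt]
  spanP <- max(abs(Tg[, jwt] - Twt), na.rm = TRUE)
  spanA <- max(abs(Tg[iwt, ] - Twt), na.rm = TRUE)
  ndiag <- min(n1, n2)
  spanD <- max(abs(Tg[cbind(seq_len(ndiag), seq_len(ndiag))] - Twt),
               na.rm = TRUE)
  list(period = Tg, period_wt = Twt, span_primary = spanP,
       span_auxiliary = spanA, span_diagonal = spanD,
       diagonal_dominant = spanD > 1.5 * max(spanP, spanA))
}

#' Deterministic calibration of the conceptual wild type
#'
#' Fixes the two free defaults of the conceptual model -- the auxiliary
#' drive rate \code{v_A} and the ALBS repression constant \code{K2} -- so
#' that the unmanipulated wild-type limit cycle attains a target period at a
#' target PLBS/ALBS amplitude ratio.  The search is a deterministic
#' shrinking-grid refinement (no randomness): each round evaluates a 7 x 7
#' grid around the current centre and recentres on the best point.
#'
#' @param target_period target wild-type period (h).
#' @param target_ratio target Amp_PLBS / Amp_ALBS.
#' @param base starting [conceptual_params()].
#' @param rounds refinement rounds.
#' @param dt,t_end,discard integration settings used during calibration.
#' @return List with \code{params} (calibrated), \code{period},
#'   \code{ratio}.
#' @export
calibrate_conceptual <- function(target_period = 23.92,
                                 target_ratio = 1.3764,
                                 base = conceptual_params(), rounds = 5,
                                 dt = 0.05, t_end = .sweep_tend,
                                 discard = .sweep_discard) {
  obj <- function(vA, K2) {
    p <- base; p$v_A <- vA; p$K2 <- K2
    m <- tryCatch(.measure_conceptual(p, t_end, dt, discard),
                  error = function(e) NULL)
    if (is.null(m) || !isTRUE(m$rhythmic) || !is.finite(m$period))
      return(Inf)
    abs(m$period - target_period) / 0.1 +
      abs(m$amp_plbs / m$amp_albs - target_ratio) / 0.02
  }
  ctr <- c(base$v_A, base$K2); span <- c(0.2, 0.8)
  for (r in seq_len(rounds)) {
    vs <- seq(max(0.02, ctr[1] - span[1]), ctr[1] + span[1], length.out = 7)
    ks <- seq(max(0.2, ctr[2] - span[2]), ctr[2] + span[2], length.out = 7)
    best <- NULL
    for (v in vs) for (k in ks) {
      o <- obj(v, k)
      if (is.null(best) || o < best$o) best <- list(o = o, x = c(v, k))
    }
    ctr <- best$x
    span <- span / 2.2
  }
  p <- base; p$v_A <- ctr[1]; p$K2 <- ctr[2]
  m <- .measure_conceptual(p, t_end, dt, discard)
  list(params = p, period = m$period, ratio = m$amp_plbs / m$amp_albs)
}

#' Ratio-law robustness under random parameter jitter
#'
#' Re-runs a (reduced) amplitude-plane sweep after multiplying each kinetic
#' parameter of the conceptual model by an independent factor uniform in
#' [1 - jitter, 1 + jitter], and reports the Spearman ratio-period
#' correlation of each jittered replicate.
#'
#' @param base a [conceptual_params()] object.
#' @param jitter relative half-width of the jitter (default 0.2).
#' @param n_seeds number of jittered replicates.
#' @param seed base RNG seed; replicate k uses \code{seed + k}.
#' @param scales_P,scales_A sweep grid (reduced by default).
#' @param ... passed to [sweep_surface()].
#' @return Data frame with one row per replicate: seed, rho, n_rhythmic.
#' @export
jittered_ratio_law <- function(base = conceptual_params(), jitter = 0.2,
                               n_seeds = 5, seed = 1,
                               scales_P = exp(seq(log(0.35), log(1),
                                                  length.out = 9)),
                               scales_A = exp(seq(log(0.2), log(1),
                                                  length.out = 9)), ...) {
  kin <- c("v_P", "v_A", "K1", "K2", "c", "d1", "d2")
  out <- lapply(seq_len(n_seeds), function(k) {
    set.seed(seed + k)
    p <- base
    for (nm in kin) p[[nm]] <- p[[nm]] * stats::runif(1, 1 - jitter, 1 + jitter)
    rec <- sweep_surface(p, scales_P = scales_P, scales_A = scales_A, ...)
    ok <- rec$is_rhythmic
    rho <- if (sum(ok) >= 8)
      stats::cor(rec$ratio[ok], rec$period[ok], method = "spearman")
    else NA_real_
    data.frame(seed = seed + k, rho = rho, n_rhythmic = sum(ok))
  })
  do.call(rbind, out)
}
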