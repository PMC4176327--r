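#' Configuration of the synthetic mutant-panel generator
#'
#' Describes a qPCR-like replicate panel: per genotype a true relative
#' \emph{Per1} amplitude, true relative \emph{Bmal1} amplitude, true
#' free-running period and \emph{Per1} peak phase.  The default panel embeds
#' a decreasing ratio-to-period map -- mutants with a high Per1/Bmal1
#' amplitude ratio run short, those with a low ratio run long -- with the
#' \emph{Cry1} knockout placed deliberately off that curve (its auxiliary
#' loop is destroyed, so the ratio rule is not expected to hold there).
#' Periods are free-running values typical of the corresponding mouse
#' strains.
#'
#' @param genotypes data frame with columns \code{genotype},
#'   \code{rel_amp_Per1}, \code{rel_amp_Bmal1}, \code{period},
#'   \code{phase_Per1}; default panel described above.
#' @param cv multiplicative (lognormal) replicate noise coefficient of
#'   variation.
#' @param n_rep replicates per (genotype, gene, CT).
#' @param ct_grid sampling grid (h), 4-h resolution over one cycle.
#' @param bmal1_offset phase offset of \emph{Bmal1} behind \emph{Per1} (h);
#'   12 h, the approximately antiphase arrangement.
#' @param seed RNG seed (mandatory).
#' @return A \code{panel_config} list.
#' @export
panel_config <- function(genotypes = default_panel_truth(), cv = 0.1,
                         n_rep = 3, ct_grid = seq(0, 24, by = 4),
                         bmal1_offset = 12, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  need <- c("genotype", "rel_amp_Per1", "rel_amp_Bmal1", "period",
            "phase_Per1")
  miss <- setdiff(need, names(genotypes))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(genotypes$rel_amp_Per1 <= 0) || any(genotypes$rel_amp_Bmal1 <= 0))
    stop("true relative amplitudes must be positive")
  if (cv < 0) stop("noise CV must be non-negative")
  if (n_rep < 1) stop("at least one replicate")
  structure(list(genotypes = genotypes, cv = cv, n_rep = n_rep,
                 ct_grid = ct_grid, bmal1_offset = bmal1_offset,
                 seed = as.integer(seed)),
            class = "panel_config")
}

#' Default truth table of the synthetic mutant panel
#'
#' @return Data frame of the default genotypes (wild type plus ten
#'   mutants), their programmed relative amplitudes, free-running periods
#'   (h) and \emph{Per1} peak phases (h).
#' @export
default_panel_truth <- function() {
  data.frame(
    genotype = c("WT", "Per2-KO", "Maged1-KO", "Cry1-KO", "hiPer2",
                 "Fbxl3;Rev-erba", "Rev-erba-KO", "Fbxl3;Cry1", "Cry2-KO",
                 "Clock-d19", "Fbxl3-KO"),
    rel_amp_Per1 = c(1.00, 1.50, 1.30, 0.63, 1.32,
                     0.52, 0.56, 0.66, 0.61, 0.25, 0.30),
    rel_amp_Bmal1 = c(1.00, 0.50, 0.50, 0.70, 0.60,
                      0.50, 0.80, 1.10, 1.10, 1.00, 1.50),
    period = c(23.7, 22.1, 22.3, 22.5, 22.9,
               23.7, 24.2, 24.5, 24.6, 27.3, 27.5),
    phase_Per1 = c(10, 9, 9.5, 10.5, 10, 10, 11, 10.5, 11, 12, 12),
    stringsAsFactors = FALSE)
}

.lognorm_factors <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic mutant-panel time-course table
#'
#' Per genotype and gene, the noiseless mean curve is
#' \code{baseline + (amp/2) * cos(2*pi*(CT - phase)/period)} sampled on the
#' CT grid (\emph{Bmal1} phase-shifted by the antiphase offset); replicate
#' values multiply the mean by lognormal noise of the configured CV (mean
#' 1, positivity-preserving).  The returned ground truth contains the
#' grid-sampled relative amplitudes of the noiseless curves -- exactly what
#' a perfect analysis of this table recovers -- along with the programmed
#' periods.
#'
#' @param config a [panel_config()].
#' @return List with \code{table} (a [timecourse_table()]) and
#'   \code{truth} (data frame: genotype, rel_amp_Per1, rel_amp_Bmal1,
#'   ratio, period).
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "panel_config"))
  set.seed(config$seed)
  g <- config$genotypes
  grid <- config$ct_grid
  amp0 <- c(Per1 = 1.0, Bmal1 = 0.8)  # wild-type raw peak-trough amplitudes
  rows <- list(); k <- 0
  truth_amp <- matrix(NA_real_, nrow(g), 2,
                      dimnames = list(g$genotype, c("Per1", "Bmal1")))
  mean_curve <- function(amp, period, phase, ct)
    (amp / 2) * 1.1 + 0.2 + (amp / 2) * cos(2 * pi * (ct - phase) / period)
  for (i in seq_len(nrow(g))) {
    for (gene in c("Per1", "Bmal1")) {
      rel <- if (gene == "Per1") g$rel_amp_Per1[i] else g$rel_amp_Bmal1[i]
      phase <- g$phase_Per1[i] +
        if (gene == "Bmal1") config$bmal1_offset else 0
      mu <- mean_curve(rel * amp0[[gene]], g$period[i], phase, grid)
      truth_amp[i, gene] <- max(mu) - min(mu)
      for (r in seq_len(config$n_rep)) {
        k <- k + 1
        rows[[k]] <- data.frame(
          genotype = g$genotype[i], gene = gene, CT = grid, replicate = r,
          value = mu * .lognorm_factors(length(grid), config$cv),
          stringsAsFactors = FALSE)
      }
    }
  }
  tab <- timecourse_table(do.call(rbind, rows), ct_grid = grid)
  iwt <- match("WT", g$genotype)
  truth <- data.frame(
    genotype = g$genotype,
    rel_amp_Per1 = truth_amp[, "Per1"] / truth_amp[iwt, "Per1"],
    rel_amp_Bmal1 = truth_amp[, "Bmal1"] / truth_amp[iwt, "Bmal1"],
    period = g$period, stringsAsFactors = FALSE)
  truth$ratio <- truth$rel_amp_Per1 / truth$rel_amp_Bmal1
  list(table = tab, truth = truth)
}

#' Configuration of the synthetic bioluminescence-trace generator
#'
#' @param period true period (h).
#' @param damping multiplicative damping rate (1/h).
#' @param amplitude initial oscillation amplitude (counts).
#' @param baseline constant baseline (counts).
#' @param drift linear baseline drift (counts/h).
#' @param curvature slow quadratic baseline term (counts/h^2).
#' @param noise_sd additive Gaussian noise SD (counts).
#' @param interval sampling interval (h); default 10 min.
#' @param duration record length (h); must cover at least three cycles.
#' @param seed RNG seed (mandatory).
#' @return A \code{trace_config} list.
#' @export
trace_config <- function(period = 24.5, damping = 0.01, amplitude = 100,
                         baseline = 200, drift = -0.5, curvature = 0.002,
                         noise_sd = 10, interval = 1 / 6, duration = 120,
                         seed) {
  if (missing(seed)) stop("a seed is mandatory")
  if (duration < 3 * period)
    stop("duration must cover at least three periods")
  structure(list(period = period, damping = damping, amplitude = amplitude,
                 baseline = baseline, drift = drift, curvature = curvature,
                 noise_sd = noise_sd, interval = interval,
                 duration = duration, seed = as.integer(seed)),
            class = "trace_config")
}

#' Generate a synthetic bioluminescence trace
#'
#' \code{value(t) = baseline(t) + A * exp(-damping * t) * sin(2*pi*t/period)
#' + noise}, with a constant-plus-drift-plus-slow-quadratic baseline and
#' additive Gaussian noise; the stand-in for a luminometry recording of an
#' oscillating reporter.
#'
#' @param config a [trace_config()].
#' @return List with \code{trace} (data frame: time, value) and
#'   \code{truth} (the configuration, including the true period).
#' @export
generate_trace <- function(config) {
  stopifnot(inherits(config, "trace_config"))
  set.seed(config$seed)
  t <- seq(0, config$duration, by = config$interval)
  base <- config$baseline + config$drift * t + config$curvature * t^2
  osc <- config$amplitude * exp(-config$damping * t) *
    sin(2 * pi * t / config$period)
  value <- base + osc + stats::rnorm(length(t), 0, config$noise_sd)
  list(trace = data.frame(time = t, value = value), truth = config)
}

#' Panel generated from the comprehensive model itself
#'
#' Simulates each genotype of the virtual panel, samples its \emph{Per1}
#' and \emph{Bmal1} trajectories on the CT grid (the window is anchored so
#' that the wild-type-like \emph{Per1} peak sits at CT 10), and applies the
#' configured replicate noise -- an end-to-end bridge from the simulator to
#' the experimental-data pipeline.  Arrhythmic genotypes are flagged and
#' excluded from the ground-truth periods; their (flat) sampled rows are
#' still emitted.
#'
#' @param genotypes character vector of panel genotype names.
#' @param base wild-type [comprehensive_params()].
#' @param cv,n_rep,ct_grid,seed as in [panel_config()].
#' @param t_end,dt,discard integration settings.
#' @return List with \code{table} (a [timecourse_table()]) and
#'   \code{truth} (genotype, period, is_rhythmic).
#' @export
panel_from_model <- function(genotypes = names(genotype_panel()),
                             base = comprehensive_params(), cv = 0.1,
                             n_rep = 3, ct_grid = seq(0, 24, by = 4),
                             seed, t_end = 700, dt = 0.05, discard = 420) {
  if (missing(seed)) stop("a seed is mandatory")
  if (cv < 0) stop("noise CV must be non-negative")
  set.seed(seed)
  panel <- genotype_panel()
  bad <- setdiff(genotypes, names(panel))
  if (length(bad)) stop("unknown genotype(s): ", paste(bad, collapse = ", "))
  rows <- list(); k <- 0
  truth <- list()
  for (g in genotypes) {
    p <- virtual_genotype(base, panel[[g]])
    traj <- integrate_dde(p, t_span = c(0, t_end), dt = dt)
    s1 <- suppressWarnings(osc_stats(traj, "Per1", discard = discard))
    rhythmic <- s1$is_rhythmic
    if (rhythmic) {
      ex <- extrema(traj, "Per1", discard = discard)
      pk <- ex$time[ex$type == "peak"]
      anchor <- pk[length(pk) - 2] - 10  # Per1 peak at CT 10
    } else {
      anchor <- t_end - 48
    }
    at <- anchor + ct_grid
    vals <- trajectory_at(traj, at)
    for (gene in c("Per1", "Bmal1")) {
      mu <- pmax(vals[, gene], 0)
      for (r in seq_len(n_rep)) {
        k <- k + 1
        rows[[k]] <- data.frame(genotype = g, gene = gene, CT = ct_grid,
                                replicate = r,
                                value = mu * .lognorm_factors(length(mu), cv),
                                stringsAsFactors = FALSE)
      }
    }
    truth[[g]] <- data.frame(genotype = g,
                             period = if (rhythmic) s1$period else NA_real_,
                             is_rhythmic = rhythmic,
                             stringsAsFactors = FALSE)
  }
  list(table = timecourse_table(do.call(rbind, rows), ct_grid = ct_grid),
       truth = do.call(rbind, truth))
}
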