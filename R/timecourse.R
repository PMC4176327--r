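#' Construct and validate a replicate expression time-course table
#'
#' Long-format table of qPCR-style expression values: one row per
#' (genotype, gene, circadian time, replicate).  Circadian times must come
#' from a declared sampling grid (4-h resolution over one cycle by
#' default); values must be non-negative and every (genotype, gene, CT)
#' cell must have at least one replicate.
#'
#' @param data data frame with columns \code{genotype}, \code{gene},
#'   \code{CT}, \code{replicate}, \code{value}.
#' @param ct_grid declared sampling grid (h).
#' @param normalization one of \code{"raw"}, \code{"reference-normalized"},
#'   \code{"percent-of-max"}.
#' @return The validated data frame with class \code{timecourse_table} and
#'   attributes \code{ct_grid}, \code{normalization}.
#' @export
timecourse_table <- function(data, ct_grid = seq(0, 24, by = 4),
                             normalization = c("raw",
                                               "reference-normalized",
                                               "percent-of-max")) {
  normalization <- match.arg(normalization)
  need <- c("genotype", "gene", "CT", "replicate", "value")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(!data$CT %in% ct_grid))
    stop("CT values outside the declared sampling grid")
  if (any(!is.finite(data$value)) || any(data$value < 0))
    stop("expression values must be finite and non-negative")
  cells <- unique(data[, c("genotype", "gene")])
  for (i in seq_len(nrow(cells))) {
    sub <- data[data$genotype == cells$genotype[i] &
                  data$gene == cells$gene[i], ]
    if (!all(ct_grid %in% sub$CT))
      stop("genotype ", cells$genotype[i], ", gene ", cells$gene[i],
           ": not every CT of the grid is sampled")
  }
  structure(as.data.frame(data), class = c("timecourse_table", "data.frame"),
            ct_grid = ct_grid, normalization = normalization)
}

#' Read a time-course table from long-format CSV
#'
#' @param path CSV with columns genotype, gene, CT, replicate, value.
#' @param ... passed to [timecourse_table()].
#' @return A \code{timecourse_table}.
#' @export
read_timecourse <- function(path, ...) {
  timecourse_table(utils::read.csv(path, stringsAsFactors = FALSE), ...)
}

#' Rescale a time-course table to percent of maximum
#'
#' Divides each (genotype, gene) profile by its maximal replicate-mean
#' value, the display convention for relative RNA levels.  Idempotent.
#'
#' @param table a \code{timecourse_table}.
#' @return A \code{timecourse_table} with normalization
#'   \code{"percent-of-max"}.  Because the wild-type-relative amplitude is
#'   a ratio of within-gene differences, this rescaling cancels there.
#' @export
normalize_percent_max <- function(table) {
  stopifnot(inherits(table, "timecourse_table"))
  grid <- attr(table, "ct_grid")
  out <- table
  cells <- unique(out[, c("genotype", "gene")])
  for (i in seq_len(nrow(cells))) {
    sel <- out$genotype == cells$genotype[i] & out$gene == cells$gene[i]
    m <- stats::aggregate(value ~ CT, data = out[sel, ], FUN = mean)
    out$value[sel] <- out$value[sel] / max(m$value)
  }
  timecourse_table(out, ct_grid = grid, normalization = "percent-of-max")
}

#' Replicate mean and SD profile of one genotype and gene
#'
#' @param table a \code{timecourse_table}.
#' @param genotype,gene profile selectors.
#' @return Data frame with \code{CT}, \code{mean}, \code{sd}, \code{n};
#'   single replicates give sd 0.
#' @export
mean_profile <- function(table, genotype, gene) {
  stopifnot(inherits(table, "timecourse_table"))
  sub <- table[table$genotype == genotype & table$gene == gene, ]
  if (!nrow(sub)) stop("no rows for ", genotype, " / ", gene)
  grid <- attr(table, "ct_grid")
  out <- do.call(rbind, lapply(grid, function(ct) {
    v <- sub$value[sub$CT == ct]
    data.frame(CT = ct, mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else 0,
               n = length(v))
  }))
  nmax <- max(out$n)
  if (any(out$n < nmax))
    warning(genotype, "/", gene, ": missing replicates at some CTs; ",
            "means computed over available ones", call. = FALSE)
  out
}

#' Wild-type-relative amplitude of a mutant profile
#'
#' The Methods convention for comparing amplitudes across genotypes: the
#' mutant profile's peak minus trough, each taken over the sampled CT points
#' only (no interpolation), divided by the wild-type peak-minus-trough:
#' \deqn{Amp = \frac{mut_{peak} - mut_{trough}}{WT_{peak} - WT_{trough}}.}
#' The wild type is 1 by construction.  Any normalization that rescales a
#' gene's profiles by a common factor (reference gene, percent-of-max)
#' cancels in this ratio.
#'
#' @param mutant,wt mean profiles from [mean_profile()] on the same CT grid.
#' @param spline_refine logical; refine the extrema with a periodic spline
#'   through the CT means before differencing (off by default, which
#'   mirrors what a 4-h sampling grid can actually measure).
#' @return Relative amplitude (dimensionless fraction of wild type).
#' @export
relative_amplitude <- function(mutant, wt, spline_refine = FALSE) {
  stopifnot(all(c("CT", "mean") %in% names(mutant)),
            all(c("CT", "mean") %in% names(wt)))
  if (!isTRUE(all.equal(mutant$CT, wt$CT)))
    stop("profiles are not on the same CT grid")
  rng <- function(p) {
    y <- p$mean
    if (spline_refine) {
      f <- stats::splinefun(p$CT, y, method = "periodic")
      xx <- seq(min(p$CT), max(p$CT), length.out = 481)
      y <- f(xx)
    }
    max(y) - min(y)
  }
  denom <- rng(wt)
  if (denom <= 0) stop("wild-type profile is flat (peak equals trough)")
  rng(mutant) / denom
}

#' Per1/Bmal1 amplitude ratio with first-order error propagation
#'
#' @param amp_per1,amp_bmal1 relative amplitudes (> 0).
#' @param sd_per1,sd_bmal1 optional standard deviations of the two
#'   amplitudes; if given, the ratio SD is propagated to first order as
#'   \code{ratio * sqrt((sd_p/amp_p)^2 + (sd_b/amp_b)^2)} (independent
#'   errors).
#' @return List with \code{ratio} and \code{sd} (NA when no SDs given).
#' @export
amplitude_ratio <- function(amp_per1, amp_bmal1, sd_per1 = NA,
                            sd_bmal1 = NA) {
  if (!is.finite(amp_per1) || !is.finite(amp_bmal1) ||
      amp_per1 <= 0 || amp_bmal1 <= 0)
    stop("amplitudes must be positive")
  ratio <- amp_per1 / amp_bmal1
  sd <- if (is.finite(sd_per1) && is.finite(sd_bmal1))
    ratio * sqrt((sd_per1 / amp_per1)^2 + (sd_bmal1 / amp_bmal1)^2)
  else NA_real_
  list(ratio = ratio, sd = sd)
}

#' Monotonicity of the amplitude-ratio/period relation across genotypes
#'
#' Spearman correlation between the Per1/Bmal1 amplitude ratio and the
#' free-running period over a genotype panel, with a one-sided permutation
#' p-value for a decreasing relation.  \emph{Cry1} knockouts are excluded
#' by default: removing \emph{Cry1} destroys the REV-ERBalpha/Cry1
#' auxiliary loop itself, so that genotype is expected off the curve.
#' Ties are handled by average ranks.
#'
#' @param summaries data frame with columns \code{genotype}, \code{ratio}
#'   and \code{period}.
#' @param exclusions genotype names to drop before testing.
#' @param n_perm number of permutations (>= 10000 for the reported p).
#' @param seed RNG seed for the permutations.
#' @return List with \code{rho}, \code{p_value} (one-sided, decreasing),
#'   \code{n}, \code{excluded}.
#' @export
monotonicity_test <- function(summaries, exclusions = "Cry1-KO",
                              n_perm = 10000, seed = 1) {
  need <- c("genotype", "ratio", "period")
  miss <- setdiff(need, names(summaries))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  keep <- !(summaries$genotype %in% exclusions) &
    is.finite(summaries$ratio) & is.finite(summaries$period)
  d <- summaries[keep, ]
  if (nrow(d) < 5) stop("fewer than 5 genotypes after exclusions")
  if (length(unique(d$ratio)) == 1 || length(unique(d$period)) == 1)
    stop("all values tied; monotonicity undefined")
  rho <- stats::cor(d$ratio, d$period, method = "spearman")
  set.seed(seed)
  perm <- replicate(n_perm,
                    stats::cor(d$ratio, sample(d$period), method = "spearman"))
  p <- (sum(perm <= rho) + 1) / (n_perm + 1)
  list(rho = rho, p_value = p, n = nrow(d),
       excluded = intersect(summaries$genotype, exclusions))
}

#' Genotype summaries from a time-course table plus period data
#'
#' Runs the experimental pipeline: replicate mean profiles, wild-type
#' relative amplitudes of \emph{Per1} and \emph{Bmal1} (Methods formula),
#' their ratio with first-order error propagation from the replicate SDs,
#' joined with externally supplied free-running periods.  Periods enter as
#' data (wheel-running measurements or generator truth); they are never
#' estimated from the 4-h qPCR profiles.
#'
#' @param table a \code{timecourse_table} containing genes \code{Per1} and
#'   \code{Bmal1}.
#' @param periods data frame with columns \code{genotype}, \code{period}
#'   and optionally \code{period_sd}.
#' @param wt name of the reference genotype.
#' @return Data frame with one row per genotype: relative amplitudes, their
#'   propagated SDs, ratio, ratio SD, period.
#' @export
genotype_summaries <- function(table, periods, wt = "WT") {
  stopifnot(inherits(table, "timecourse_table"))
  gts <- unique(table$genotype)
  if (!wt %in% gts) stop("reference genotype '", wt, "' not in table")
  wtP <- mean_profile(table, wt, "Per1")
  wtB <- mean_profile(table, wt, "Bmal1")
  amp_sd <- function(prof) {
    # first-order SD of (max - min): combine the SDs of the mean at the
    # extreme CTs
    i <- which.max(prof$mean); j <- which.min(prof$mean)
    sqrt((prof$sd[i]^2 / prof$n[i]) + (prof$sd[j]^2 / prof$n[j]))
  }
  rows <- lapply(gts, function(g) {
    mP <- mean_profile(table, g, "Per1")
    mB <- mean_profile(table, g, "Bmal1")
    aP <- relative_amplitude(mP, wtP)
    aB <- relative_amplitude(mB, wtB)
    sP <- amp_sd(mP) / (max(wtP$mean) - min(wtP$mean))
    sB <- amp_sd(mB) / (max(wtB$mean) - min(wtB$mean))
    rt <- amplitude_ratio(aP, aB, sP, sB)
    data.frame(genotype = g, rel_amp_Per1 = aP, rel_amp_Bmal1 = aB,
               sd_amp_Per1 = sP, sd_amp_Bmal1 = sB,
               ratio = rt$ratio, ratio_sd = rt$sd,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  m <- match(out$genotype, periods$genotype)
  out$period <- periods$period[m]
  out$period_sd <- if ("period_sd" %in% names(periods))
    periods$period_sd[m] else NA_real_
  out
}
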