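#' Define a virtual genotype as a list of parameter edits
#'
#' @param name genotype label.
#' @param edits list of edits, each a list with elements \code{param}
#'   (a parameter name of the comprehensive model), \code{op} (\code{"scale"},
#'   \code{"set"} or \code{"add"}) and \code{value}.
#' @return A \code{genotype_spec} object.
#' @seealso [virtual_genotype()], [genotype_panel()]
#' @export
genotype_spec <- function(name, edits) {
  stopifnot(is.character(name), length(name) == 1, is.list(edits))
  for (e in edits) {
    if (!all(c("param", "op", "value") %in% names(e)))
      stop("each edit needs 'param', 'op' and 'value'")
    if (!e$op %in% c("scale", "set", "add"))
      stop("unknown edit op '", e$op, "'")
  }
  structure(list(name = name, edits = edits), class = "genotype_spec")
}

#' @export
print.genotype_spec <- function(x, ...) {
  cat("<genotype_spec>", x$name, "\n")
  for (e in x$edits)
    cat(sprintf("  %s %s %g\n", e$param, e$op, e$value))
  invisible(x)
}

#' Apply a genotype to the comprehensive model parameters
#'
#' Pure function: returns an edited copy of the parameter set, leaving the
#' input untouched.  Unknown parameter names are rejected.
#'
#' @param base a [comprehensive_params()] object.
#' @param spec a [genotype_spec()].
#' @return Edited, validated \code{comprehensive_params}.
#' @export
virtual_genotype <- function(base, spec) {
  stopifnot(inherits(base, "comprehensive_params"),
            inherits(spec, "genotype_spec"))
  p <- base
  for (e in spec$edits) {
    if (!e$param %in% names(p))
      stop("genotype '", spec$name, "' edits unknown parameter '",
           e$param, "'")
    p[[e$param]] <- switch(e$op,
                           scale = p[[e$param]] * e$value,
                           set = e$value,
                           add = p[[e$param]] + e$value)
  }
  validate_params(p)
  p
}

#' The shipped virtual genotype panel
#'
#' Parameter mappings for the mutant strains and overexpression conditions
#' the package simulates.  Knockouts zero the gene's transcription terms
#' (for \emph{Rev-erbalpha} this pins the RORE at maximal, derepressed
#' activity); \emph{Clock-delta19} halves every E-box-driven maximal rate
#' (a hypomorphic transactivator); \emph{Fbxl3} loss stabilises the CRY
#' proteins, modelled as doubled CRY repressor weights plus two extra hours
#' of repressor action delay; overexpression adds a constitutive production
#' term expressed as a fraction (\code{dose}) of the gene's maximal driven
#' rate.
#'
#' @param dose overexpression dose as a fraction of the wild-type maximal
#'   drive (default 0.25).
#' @return Named list of [genotype_spec()] objects (including \code{WT}).
#' @export
genotype_panel <- function(dose = 0.25) {
  ed <- function(param, op, value) list(param = param, op = op, value = value)
  fbxl3 <- list(ed("w_C1", "scale", 2), ed("w_C2", "scale", 2),
                ed("tau_P", "add", 2))
  specs <- list(
    genotype_spec("WT", list()),
    genotype_spec("Cry1-KO", list(ed("v_C1", "set", 0),
                                  ed("v_C1r", "set", 0))),
    genotype_spec("Cry2-KO", list(ed("v_C2", "set", 0))),
    genotype_spec("Rev-erba-KO", list(ed("v_R", "set", 0))),
    genotype_spec("Per2-KO", list(ed("v_P2", "set", 0))),
    genotype_spec("Clock-d19", list(ed("v_P1", "scale", 0.5),
                                    ed("v_P2", "scale", 0.5),
                                    ed("v_C1", "scale", 0.5),
                                    ed("v_C2", "scale", 0.5),
                                    ed("v_R", "scale", 0.5))),
    genotype_spec("Fbxl3-KO", fbxl3),
    genotype_spec("hiPer2", list(ed("b_P2", "set", 0.5 * 1.2))),
    genotype_spec("CRY1-OE", list(ed("b_C1", "set", dose * 0.8))),
    genotype_spec("REV-OE", list(ed("b_R", "set", dose * 1.2))),
    genotype_spec("CRY1+REV-OE", list(ed("b_C1", "set", dose * 0.8),
                                      ed("b_R", "set", dose * 1.2))),
    genotype_spec("Fbxl3;Rev-erba", c(fbxl3, list(ed("v_R", "set", 0)))),
    genotype_spec("Fbxl3;Cry1", c(fbxl3, list(ed("v_C1", "set", 0),
                                              ed("v_C1r", "set", 0))))
  )
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}

#' Simulate one genotype and summarise its rhythm
#'
#' @param spec a [genotype_spec()] or a genotype name from
#'   [genotype_panel()].
#' @param base wild-type [comprehensive_params()].
#' @param t_end,dt,discard integration settings.
#' @return One-row data frame: genotype, period, amp_Per1, amp_Bmal1,
#'   is_rhythmic.
#' @export
simulate_genotype <- function(spec, base = comprehensive_params(),
                              t_end = 700, dt = 0.05, discard = 420) {
  if (is.character(spec)) {
    panel <- genotype_panel()
    if (!spec %in% names(panel)) stop("unknown genotype '", spec, "'")
    spec <- panel[[spec]]
  }
  p <- virtual_genotype(base, spec)
  traj <- integrate_dde(p, t_span = c(0, t_end), dt = dt)
  s1 <- suppressWarnings(osc_stats(traj, "Per1", discard = discard))
  sB <- suppressWarnings(osc_stats(traj, "Bmal1", discard = discard))
  data.frame(genotype = spec$name,
             period = s1$period,
             amp_Per1 = if (s1$is_rhythmic) s1$amplitude else 0,
             amp_Bmal1 = if (sB$is_rhythmic) sB$amplitude else 0,
             is_rhythmic = s1$is_rhythmic,
             stringsAsFactors = FALSE)
}

#' Genotype path in the Per1-Bmal1 amplitude plane
#'
#' Simulates a sequence of genotypes, normalises their \emph{Per1} and
#' \emph{Bmal1} mRNA amplitudes to the wild type (which maps to (1, 1)
#' exactly), and reports each point's distance from the wild-type-ratio ray
#' -- the ray through the origin and (1, 1) in normalized coordinates, on
#' which the amplitude ratio (and, by the ratio law, the period) equals the
#' wild type's.  Used to display destruction and rescue routes.
#'
#' @param genotypes character vector of panel genotype names (or a list of
#'   [genotype_spec()]); the wild type is always simulated as reference.
#' @param base wild-type [comprehensive_params()].
#' @param ... passed to [simulate_genotype()].
#' @return Data frame with genotype, period, normalized amplitudes
#'   \code{rel_amp_Per1} / \code{rel_amp_Bmal1}, \code{ratio},
#'   \code{dist_wt_ray} and \code{is_rhythmic}; arrhythmic genotypes are
#'   flagged, their path entries retained.
#' @export
rescue_route <- function(genotypes, base = comprehensive_params(), ...) {
  if (is.character(genotypes)) {
    panel <- genotype_panel()
    bad <- setdiff(genotypes, names(panel))
    if (length(bad)) stop("unknown genotype(s): ", paste(bad, collapse = ", "))
    specs <- panel[genotypes]
  } else specs <- genotypes
  wt <- simulate_genotype(genotype_spec("WT", list()), base, ...)
  rows <- lapply(specs, function(sp) {
    g <- simulate_genotype(sp, base, ...)
    relP <- g$amp_Per1 / wt$amp_Per1
    relB <- g$amp_Bmal1 / wt$amp_Bmal1
    data.frame(genotype = g$genotype, period = g$period,
               rel_amp_Per1 = relP, rel_amp_Bmal1 = relB,
               ratio = relP / relB,
               dist_wt_ray = abs(relP - relB) / sqrt(2),
               is_rhythmic = g$is_rhythmic, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
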