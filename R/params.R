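#' Parameters of the conceptual two-loop oscillator
#'
#' The conceptual model reduces the mammalian circadian network to a repressor
#' gene \emph{R1} (Cry1-like) driven by primary-loop binding sites (PLBS,
#' the lumped E-box/D-box) and, when the auxiliary loop is enabled, by an
#' auxiliary-loop binding site (ALBS, the RORE).  A second repressor
#' \emph{R2} (Rev-erbalpha-like) is driven by the PLBS and represses the
#' ALBS.  Protein action at a binding site is the mRNA level delayed by a
#' fixed post-transcriptional delay \code{tau_P}; transcription activity is a
#' Hill repression function of the delayed repressor.
#'
#' Default values are fixed by the deterministic calibration in
#' [calibrate_conceptual()]: with the auxiliary loop enabled the wild-type
#' limit cycle has period about 23.9 h at a PLBS/ALBS amplitude ratio of
#' about 1.38.
#'
#' @param v_P maximal PLBS-driven transcription rate (conc/h).
#' @param v_A maximal ALBS-driven transcription rate (conc/h).
#' @param K1 repression constant of R1 protein on the PLBS (conc).
#' @param K2 repression constant of R2 protein on the ALBS (conc).
#' @param h Hill coefficient of both repression terms (>= 1).
#' @param c scale of the PLBS drive onto \emph{R2} (dimensionless).
#' @param d1,d2 first-order mRNA degradation rates (1/h).
#' @param tau_P post-transcriptional delay (h) between an mRNA level and its
#'   protein's action at a binding site.
#' @param tau_A action delay (h) of R2 protein on the ALBS.  The default
#'   exceeds \code{tau_P}: the RORE activity phase runs later than the
#'   E-box/D-box phase, which is what lets the auxiliary loop delay the
#'   repressor mRNA peak.
#' @param al_enabled logical; \code{FALSE} removes the auxiliary loop
#'   (primary-only topology), forcing the ALBS term to zero.
#' @param amp_scale_P,amp_scale_A in-silico amplitude manipulation of the
#'   PLBS / ALBS activity (the strength with which the repressor modulates
#'   its element): the normalized activity is re-scaled about the
#'   half-activity midpoint by this factor and clamped to [0, 1]
#'   (1 = unmanipulated Hill activity).  These are the knobs the
#'   amplitude-plane sweeps and loop-perturbation experiments turn.
#'
#' @return An object of class \code{c("conceptual_params", "clock_params")}.
#' @seealso [comprehensive_params()], [integrate_dde()], [calibrate_conceptual()]
#' @export
conceptual_params <- function(v_P = 1, v_A = 0.373663,
                              K1 = 0.45, K2 = 4.392858, h = 4, c = 1,
                              d1 = 1.5, d2 = 0.14,
                              tau_P = 10.5, tau_A = 14, al_enabled = TRUE,
                              amp_scale_P = 1, amp_scale_A = 1) {
  p <- list(v_P = v_P, v_A = v_A, K1 = K1, K2 = K2, h = h, c = c,
            d1 = d1, d2 = d2, tau_P = tau_P, tau_A = tau_A,
            al_enabled = al_enabled,
            amp_scale_P = amp_scale_P, amp_scale_A = amp_scale_A)
  class(p) <- c("conceptual_params", "clock_params")
  validate_params(p)
  p
}

#' Parameters of the comprehensive six-gene oscillator
#'
#' Delay model of \emph{Bmal1}, \emph{Per1}, \emph{Per2}, \emph{Cry1},
#' \emph{Cry2} and \emph{Rev-erbalpha}.  The PLBS (lumped E-box/D-box)
#' activity is BMAL1 activation multiplied by pooled PER/CRY Hill repression;
#' the RORE activity is Hill repression by delayed REV-ERBalpha.  \emph{Bmal1}
#' is driven solely by the RORE; \emph{Per1}, \emph{Per2}, \emph{Cry2} and
#' \emph{Rev-erbalpha} solely by the PLBS; \emph{Cry1} is the only gene with a
#' dual drive, combined by the addition rule
#' \code{a_E * (PLBS term) + a_R * (RORE term)}.  Repressor proteins act with
#' delay \code{tau_P}, BMAL1 with delay \code{tau_B}.
#'
#' @param v_B,v_P1,v_P2,v_C1,v_C2,v_R maximal transcription rates (conc/h) of
#'   the RORE drive on \emph{Bmal1} and the PLBS drives on \emph{Per1},
#'   \emph{Per2}, \emph{Cry1} (E-box arm), \emph{Cry2}, \emph{Rev-erbalpha}.
#' @param v_C1r maximal rate of the RORE arm of the \emph{Cry1} drive (conc/h).
#' @param K_B activation constant of delayed BMAL1 on the PLBS (conc).
#' @param h_B Hill coefficient of BMAL1 activation.
#' @param K_E repression constant of the pooled PER/CRY signal on the PLBS
#'   (conc).
#' @param w_P1,w_P2,w_C1,w_C2 weights of delayed PER1/PER2/CRY1/CRY2 in the
#'   pooled PLBS repressor (dimensionless).
#' @param h_E Hill coefficient of the pooled PLBS repression.
#' @param K_R repression constant of delayed REV-ERBalpha on the RORE (conc).
#' @param h_R Hill coefficient of the RORE repression.
#' @param a_E,a_R addition-rule weights of the \emph{Cry1} PLBS and RORE arms
#'   (dimensionless).  \emph{Cry1} is the only gene with both positive.
#' @param d_B,d_P1,d_P2,d_C1,d_C2,d_R degradation rates (1/h).
#' @param tau_P PER/CRY repressor action delay (h): the long
#'   post-transcriptional interval between repressor mRNA and repressive
#'   action at the E-box.
#' @param tau_B BMAL1 action delay (h); short.
#' @param tau_R REV-ERBalpha action delay (h) at the \emph{Bmal1} promoter
#'   RORE; short, which places the RORE activity (and hence \emph{Bmal1})
#'   approximately in antiphase to the E-box.
#' @param tau_RC action delay (h) of the REV-ERBalpha/corepressor complex at
#'   the \emph{Cry1} intronic RORE.  Long: the repressor-binding peak at this
#'   element runs late, which delays the \emph{Cry1} mRNA peak relative to
#'   the E-box peak and is the source of the auxiliary loop's transcriptional
#'   delay in this model.
#' @param b_B,b_P1,b_P2,b_C1,b_C2,b_R constitutive production rates (conc/h),
#'   zero in the wild type; used by overexpression genotypes.
#' @param amp_scale_P,amp_scale_A in-silico amplitude manipulation of the
#'   PLBS / RORE activity about its midpoint, clamped to [0, 1]; 1 leaves
#'   the activities unmanipulated.
#'
#' @return An object of class \code{c("comprehensive_params", "clock_params")}.
#' @seealso [conceptual_params()], [virtual_genotype()], [genotype_panel()]
#' @export
comprehensive_params <- function(v_B = 1.4, v_P1 = 1.2, v_P2 = 1.2,
                                 v_C1 = 0.8, v_C1r = 0.8, v_C2 = 0.8,
                                 v_R = 1.2,
                                 K_B = 0.05, h_B = 2,
                                 K_E = 1.62,
                                 w_P1 = 0.3, w_P2 = 0.3, w_C1 = 0.5,
                                 w_C2 = 0.2, h_E = 4,
                                 K_R = 0.49, h_R = 4,
                                 a_E = 0.6, a_R = 0.4,
                                 d_B = 1, d_P1 = 0.4, d_P2 = 0.4,
                                 d_C1 = 0.4, d_C2 = 0.4, d_R = 1.2,
                                 tau_P = 9.399, tau_B = 2, tau_R = 0.75,
                                 tau_RC = 17,
                                 b_B = 0, b_P1 = 0, b_P2 = 0, b_C1 = 0,
                                 b_C2 = 0, b_R = 0,
                                 amp_scale_P = 1, amp_scale_A = 1) {
  p <- list(v_B = v_B, v_P1 = v_P1, v_P2 = v_P2, v_C1 = v_C1,
            v_C1r = v_C1r, v_C2 = v_C2, v_R = v_R,
            K_B = K_B, h_B = h_B, K_E = K_E,
            w_P1 = w_P1, w_P2 = w_P2, w_C1 = w_C1, w_C2 = w_C2, h_E = h_E,
            K_R = K_R, h_R = h_R, a_E = a_E, a_R = a_R,
            d_B = d_B, d_P1 = d_P1, d_P2 = d_P2, d_C1 = d_C1,
            d_C2 = d_C2, d_R = d_R,
            tau_P = tau_P, tau_B = tau_B, tau_R = tau_R, tau_RC = tau_RC,
            b_B = b_B, b_P1 = b_P1, b_P2 = b_P2, b_C1 = b_C1,
            b_C2 = b_C2, b_R = b_R,
            amp_scale_P = amp_scale_P, amp_scale_A = amp_scale_A)
  class(p) <- c("comprehensive_params", "clock_params")
  validate_params(p)
  p
}

#' Validate a parameter object against its invariants
#'
#' Checks strict positivity of rates, constants and delays, the Hill
#' coefficient bounds, and the wiring invariants (only \emph{Cry1} has a dual
#' drive; \emph{Bmal1} is driven solely by the RORE term).  Called by the
#' constructors and by [load_params()].
#'
#' @param p a \code{clock_params} object.
#' @return \code{p}, invisibly; errors name the offending parameter.
#' @export
validate_params <- function(p) {
  UseMethod("validate_params")
}

.check_positive <- function(p, keys, strict = TRUE) {
  for (k in keys) {
    v <- p[[k]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1 || is.na(v))
      stop("parameter '", k, "' must be a single finite number", call. = FALSE)
    if (strict && v <= 0)
      stop("parameter '", k, "' must be strictly positive", call. = FALSE)
    if (!strict && v < 0)
      stop("parameter '", k, "' must be non-negative", call. = FALSE)
  }
  invisible(p)
}

#' @export
validate_params.conceptual_params <- function(p) {
  .check_positive(p, c("v_P", "K1", "K2", "c", "d1", "d2", "tau_P", "tau_A"))
  .check_positive(p, "v_A", strict = FALSE)
  if (p$h < 1) stop("parameter 'h' must be >= 1", call. = FALSE)
  if (!is.logical(p$al_enabled) || length(p$al_enabled) != 1)
    stop("parameter 'al_enabled' must be a single logical", call. = FALSE)
  for (k in c("amp_scale_P", "amp_scale_A"))
    if (!is.numeric(p[[k]]) || p[[k]] <= 0)
      stop("parameter '", k, "' must be strictly positive", call. = FALSE)
  invisible(p)
}

#' @export
validate_params.comprehensive_params <- function(p) {
  .check_positive(p, c("K_B", "K_E", "K_R", "d_B", "d_P1", "d_P2",
                       "d_C1", "d_C2", "d_R", "tau_P", "tau_B", "tau_R",
                       "tau_RC"))
  # maximal rates and weights may be zero: knockouts zero a gene's drive
  .check_positive(p, c("v_B", "v_P1", "v_P2", "v_R", "v_C1", "v_C1r",
                       "v_C2", "w_P1", "w_P2", "w_C1", "w_C2", "a_E",
                       "a_R", "b_B", "b_P1", "b_P2", "b_C1", "b_C2",
                       "b_R"), strict = FALSE)
  for (k in c("h_B", "h_E", "h_R"))
    if (p[[k]] < 1) stop("parameter '", k, "' must be >= 1", call. = FALSE)
  for (k in c("amp_scale_P", "amp_scale_A"))
    if (!is.numeric(p[[k]]) || p[[k]] <= 0)
      stop("parameter '", k, "' must be strictly positive", call. = FALSE)
  invisible(p)
}

# Fixed parameter orders used by the compiled right-hand sides.
.conceptual_order <- c("v_P", "v_A", "K1", "K2", "h", "c", "d1", "d2",
                       "tau_P", "tau_A", "al_enabled",
                       "amp_scale_P", "amp_scale_A")
.comprehensive_order <- c("v_B", "v_P1", "v_P2", "v_C1", "v_C1r", "v_C2",
                          "v_R", "K_B", "h_B", "K_E", "w_P1", "w_P2", "w_C1",
                          "w_C2", "h_E", "K_R", "h_R", "a_E", "a_R",
                          "d_B", "d_P1", "d_P2", "d_C1", "d_C2", "d_R",
                          "tau_P", "tau_B", "tau_R", "tau_RC",
                          "b_B", "b_P1", "b_P2", "b_C1", "b_C2", "b_R",
                          "amp_scale_P", "amp_scale_A")

param_vector <- function(p) {
  ord <- if (inherits(p, "conceptual_params")) .conceptual_order
         else .comprehensive_order
  v <- vapply(p[ord], as.numeric, numeric(1))
  names(v) <- ord
  v
}

#' State-variable names of a model variant
#'
#' @param p a \code{clock_params} object.
#' @return Character vector of mRNA state names, in integration order.
#' @export
state_names <- function(p) {
  if (inherits(p, "conceptual_params")) c("R1", "R2")
  else c("Bmal1", "Per1", "Per2", "Cry1", "Cry2", "Rev")
}

#' Derived cis-element signal names of a model variant
#'
#' @param p a \code{clock_params} object.
#' @return Character vector: \code{c("PLBS", "ALBS")} for the conceptual
#'   model, \code{c("PLBS", "RORE")} for the comprehensive model.
#' @export
signal_names <- function(p) {
  if (inherits(p, "conceptual_params")) c("PLBS", "ALBS")
  else c("PLBS", "RORE")
}

#' @export
print.clock_params <- function(x, ...) {
  variant <- if (inherits(x, "conceptual_params")) "conceptual (two-loop)"
             else "comprehensive (six-gene)"
  cat("<clock_params>", variant, "\n")
  v <- unlist(x)
  cat(paste0("  ", format(names(v), width = 10), " = ",
             vapply(v, format, character(1))), sep = "\n")
  invisible(x)
}

#' Read model parameters from a YAML or JSON file
#'
#' The file must carry a \code{model: conceptual} or
#' \code{model: comprehensive} discriminator; every other key must name a
#' parameter of that variant (unknown keys are rejected, naming the offender).
#' Omitted parameters take the package defaults.
#'
#' @param path path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return A validated \code{clock_params} object.
#' @seealso [save_params()]
#' @export
load_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(raw$model))
    stop("parameter file must contain a 'model:' discriminator")
  model <- match.arg(raw$model, c("conceptual", "comprehensive"))
  raw$model <- NULL
  ctor <- if (model == "conceptual") conceptual_params else comprehensive_params
  known <- names(formals(ctor))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "))
  do.call(ctor, raw)
}

#' Write model parameters to a YAML file
#'
#' @param p a \code{clock_params} object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
save_params <- function(p, path) {
  validate_params(p)
  model <- if (inherits(p, "conceptual_params")) "conceptual" else "comprehensive"
  out <- c(list(model = model), unclass(p))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Hash of a parameter object, for provenance records
#'
#' @param p a \code{clock_params} object.
#' @return A short hexadecimal digest of the parameter values.
#' @keywords internal
params_hash <- function(p) {
  v <- param_vector(p)
  s <- paste(names(v), sprintf("%.12g", v), sep = "=", collapse = ";")
  # polynomial rolling hash mod a Mersenne prime; cheap and dependency-free
  hash <- 0
  for (ch in utf8ToInt(s)) hash <- (hash * 131 + ch) %% 2147483647
  sprintf("%08x", as.integer(hash))
}
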