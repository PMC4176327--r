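#' PLBS transcription activity under delayed repression
#'
#' Hill repression of the primary-loop binding sites: the transcription
#' activity driven by the PLBS when the pooled repressor level that was
#' current \code{tau_P} hours ago (i.e. the protein now acting at the site)
#' equals \code{repressor_delayed}.  At zero repressor the activity is
#' maximal (\code{v_P}); at \code{repressor_delayed == K1} it is exactly half
#' maximal for any Hill coefficient.
#'
#' @param repressor_delayed non-negative repressor level (conc).
#' @param params a [conceptual_params()] object (uses \code{v_P}, \code{K1},
#'   \code{h}).
#' @return Activity in conc/h, strictly decreasing in the repressor, in
#'   \code{(0, v_P]}.
#' @export
plbs_activity <- function(repressor_delayed, params) {
  if (any(repressor_delayed < 0))
    stop("repressor level must be non-negative")
  params$v_P * conceptual_activity(repressor_delayed, params, "PLBS")
}

#' ALBS (RORE) transcription activity under delayed repression
#'
#' As [plbs_activity()] with \code{(v_A, K2)}; returns zero for any input
#' when the auxiliary loop is disabled (\code{al_enabled = FALSE}).
#'
#' @inheritParams plbs_activity
#' @param params a [conceptual_params()] object (uses \code{v_A}, \code{K2},
#'   \code{h}, \code{al_enabled}).
#' @return Activity in conc/h.
#' @export
albs_activity <- function(repressor_delayed, params) {
  if (any(repressor_delayed < 0))
    stop("repressor level must be non-negative")
  params$v_A * conceptual_activity(repressor_delayed, params, "ALBS")
}

#' Hill repression factor
#'
#' Fraction of maximal transcription remaining at repressor level \code{x}:
#' \code{K^h / (K^h + x^h)}.
#'
#' @param x repressor level (conc), non-negative.
#' @param K repression constant (conc).
#' @param h Hill coefficient.
#' @return Value in (0, 1].
#' @export
hill_repression <- function(x, K, h) {
  ifelse(x <= 0, 1, 1 / (1 + (x / K)^h))
}

#' Hill activation factor
#'
#' \code{x^h / (K^h + x^h)}; zero at zero activator.
#'
#' @param x activator level (conc), non-negative.
#' @param K activation constant (conc).
#' @param h Hill coefficient.
#' @return Value in [0, 1).
#' @export
hill_activation <- function(x, K, h) {
  ifelse(x <= 0, 0, {r <- (x / K)^h; r / (1 + r)})
}

#' Right-hand side of the conceptual two-loop model
#'
#' \deqn{dR1/dt = PLBS(R1_{t-\tau_P}) + ALBS(R2_{t-\tau_A}) - d_1 R1}
#' \deqn{dR2/dt = c \cdot v_P \cdot plbs(R1_{t-\tau_P}) - d_2 R2}
#' where PLBS and ALBS are the Hill-repressed binding-site activities of
#' [plbs_activity()] and [albs_activity()]; with \code{al_enabled = FALSE}
#' the ALBS term vanishes.  This R-level function mirrors the compiled model
#' used by [integrate_dde()] and is exposed for inspection and testing.
#'
#' @param now named state vector (\code{R1}, \code{R2}) at time t.
#' @param delayed_P named state vector at time t - tau_P (R1 protein action).
#' @param delayed_A named state vector at time t - tau_A (R2 protein action
#'   on the ALBS).
#' @param params a [conceptual_params()] object.
#' @return Named derivative vector (conc/h).
#' @export
conceptual_rhs <- function(now, delayed_P, delayed_A, params) {
  if (any(now < 0) || any(delayed_P < 0) || any(delayed_A < 0))
    stop("states must be non-negative")
  plbs <- plbs_activity(delayed_P[["R1"]], params)
  albs <- albs_activity(delayed_A[["R2"]], params)
  c(R1 = plbs + albs - params$d1 * now[["R1"]],
    R2 = params$c * params$v_P *
           conceptual_activity(delayed_P[["R1"]], params, "PLBS") -
         params$d2 * now[["R2"]])
}

#' Normalized, possibly amplitude-manipulated element activity
#'
#' The occupancy-style activity of a binding element: the Hill factor of the
#' delayed repressor, re-scaled about the half-activity midpoint by the
#' model's \code{amp_scale_P} / \code{amp_scale_A} manipulation factor.
#' At scale 1 this is exactly the Hill factor.  These are the signals whose
#' peak-to-trough amplitudes define Amp_PLBS and Amp_ALBS.
#'
#' @param repressor_delayed delayed repressor level (conc).
#' @param params a [conceptual_params()] object.
#' @param element \code{"PLBS"} or \code{"ALBS"}.
#' @return Activity in [0, 1] (zero for ALBS when the loop is disabled).
#' @export
conceptual_activity <- function(repressor_delayed, params,
                                element = c("PLBS", "ALBS")) {
  element <- match.arg(element)
  act <- if (element == "PLBS")
    0.5 + params$amp_scale_P *
      (hill_repression(repressor_delayed, params$K1, params$h) - 0.5)
  else if (!params$al_enabled) rep(0, length(repressor_delayed))
  else 0.5 + params$amp_scale_A *
      (hill_repression(repressor_delayed, params$K2, params$h) - 0.5)
  pmin(1, pmax(0, act))
}

#' Right-hand side of the comprehensive six-gene model
#'
#' The PLBS activity is BMAL1 Hill activation (delayed by \code{tau_B})
#' multiplied by Hill repression of the pooled, weighted PER1/PER2/CRY1/CRY2
#' signal (delayed by \code{tau_P}); the RORE activity is Hill repression of
#' delayed REV-ERBalpha.  Each gene's rate is its cis-element drive minus
#' first-order degradation; \emph{Cry1} combines both elements by the
#' addition rule, \emph{Bmal1} is driven solely by the RORE.
#'
#' @param now named state vector (\code{Bmal1}, \code{Per1}, \code{Per2},
#'   \code{Cry1}, \code{Cry2}, \code{Rev}) at time t.
#' @param delayed_P named state vector at time t - tau_P (PER/CRY action).
#' @param delayed_B named state vector at time t - tau_B (BMAL1 action).
#' @param delayed_R named state vector at time t - tau_R (REV-ERBalpha
#'   action).
#' @param params a [comprehensive_params()] object.
#' @return Named derivative vector (conc/h).
#' @export
comprehensive_rhs <- function(now, delayed_P, delayed_B, delayed_R, params) {
  if (any(now < 0) || any(delayed_P < 0) || any(delayed_B < 0) ||
      any(delayed_R < 0))
    stop("states must be non-negative")
  el <- cis_activities(delayed_P, delayed_B, delayed_R, params)
  p <- params
  c(Bmal1 = p$v_B * el[["RORE"]] + p$b_B - p$d_B * now[["Bmal1"]],
    Per1  = p$v_P1 * el[["PLBS"]] + p$b_P1 - p$d_P1 * now[["Per1"]],
    Per2  = p$v_P2 * el[["PLBS"]] + p$b_P2 - p$d_P2 * now[["Per2"]],
    Cry1  = p$a_E * p$v_C1 * el[["PLBS"]] + p$a_R * p$v_C1r * el[["RORE"]] +
            p$b_C1 - p$d_C1 * now[["Cry1"]],
    Cry2  = p$v_C2 * el[["PLBS"]] + p$b_C2 - p$d_C2 * now[["Cry2"]],
    Rev   = p$v_R * el[["PLBS"]] + p$b_R - p$d_R * now[["Rev"]])
}

#' Normalized cis-element activities of the comprehensive model
#'
#' @param delayed_P state vector at t - tau_P.
#' @param delayed_B state vector at t - tau_B.
#' @param delayed_R state vector at t - tau_R.
#' @param params a [comprehensive_params()] object.
#' @return Named vector \code{c(PLBS = ..., RORE = ...)}, each in [0, 1].
#' @export
cis_activities <- function(delayed_P, delayed_B, delayed_R, params) {
  p <- params
  pool <- p$w_P1 * delayed_P[["Per1"]] + p$w_P2 * delayed_P[["Per2"]] +
          p$w_C1 * delayed_P[["Cry1"]] + p$w_C2 * delayed_P[["Cry2"]]
  raw <- c(PLBS = hill_activation(delayed_B[["Bmal1"]], p$K_B, p$h_B) *
             hill_repression(pool, p$K_E, p$h_E),
           RORE = hill_repression(delayed_R[["Rev"]], p$K_R, p$h_R))
  sc <- c(p$amp_scale_P, p$amp_scale_A)
  out <- 0.5 + sc * (raw - 0.5)
  pmin(pmax(out, 0), 1)
}

#' Fixed point of the non-delayed conceptual system
#'
#' Solves \code{conceptual_rhs == 0} with all delayed states equal to the
#' current state, by damped fixed-point iteration on the production/
#' degradation balance.  Useful as an independent check of the right-hand
#' side and as a well-defined history state.
#'
#' @param params a [conceptual_params()] object.
#' @param tol convergence tolerance on the state.
#' @return Named state vector at the fixed point.
#' @export
conceptual_fixed_point <- function(params, tol = 1e-12) {
  x <- c(R1 = 0.1, R2 = 0.1)
  for (i in 1:10000) {
    plbs <- plbs_activity(x[["R1"]], params)
    albs <- albs_activity(x[["R2"]], params)
    nxt <- c(R1 = (plbs + albs) / params$d1,
             R2 = params$c * params$v_P *
                    conceptual_activity(x[["R1"]], params, "PLBS") /
                    params$d2)
    nxt <- 0.5 * x + 0.5 * nxt
    if (max(abs(nxt - x)) < tol) return(nxt)
    x <- nxt
  }
  stop("fixed-point iteration did not converge")
}
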