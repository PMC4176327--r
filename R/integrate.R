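#' Integrate a delay differential equation model
#'
#' Deterministic method-of-steps integration with classical fixed-step
#' fourth-order Runge-Kutta.  Delayed state lookups use cubic Hermite
#' interpolation of the stored solution (the history function before the
#' start time), so the integrator provides its own dense output.  Identical
#' inputs give bitwise identical trajectories.
#'
#' @param model either a \code{clock_params} object (the compiled conceptual
#'   or comprehensive oscillator) or, for generic problems, a list with
#'   elements \code{rhs} (a function \code{f(t, y, ylag)} returning the
#'   derivative vector, where \code{ylag} is an \code{nvar x ndelay} matrix
#'   of delayed states), \code{delays} (numeric vector, possibly empty) and
#'   optionally \code{state_names}.
#' @param t_span numeric length-2, integration interval in hours.  For
#'   limit-cycle work the span should cover at least 20 nominal cycles; the
#'   default 480 h leaves 10 cycles after the default 240 h transient.
#' @param dt fixed step (h).  Must not exceed one tenth of the smallest
#'   delay, so every delayed lookup falls in the already computed part of
#'   the solution.
#' @param history constant pre-\code{t0} state (one value per variable), or
#'   \code{NULL} for the standard initial state (0.1 for every mRNA).
#'
#' @return A \code{clock_trajectory}: list with \code{time} (uniform grid),
#'   \code{states} (matrix, one named column per variable), \code{signals}
#'   (derived cis-element activities, PLBS and ALBS/RORE, for the compiled
#'   models), \code{derivs}, \code{dt}, \code{t_span}, \code{history} and
#'   \code{params}.
#' @examples
#' traj <- integrate_dde(conceptual_params(), t_span = c(0, 480), dt = 0.02)
#' osc_stats(traj, "R1")$period
#' @export
integrate_dde <- function(model, t_span = c(0, 480), dt = 0.01,
                          history = NULL) {
  stopifnot(length(t_span) == 2, t_span[2] > t_span[1], dt > 0)
  if (inherits(model, "clock_params")) {
    validate_params(model)
    pv <- param_vector(model)
    delays <- if (inherits(model, "conceptual_params"))
                pv[c("tau_P", "tau_A")]
              else pv[c("tau_P", "tau_B", "tau_R", "tau_RC")]
    if (dt > min(delays) / 10)
      stop("dt = ", dt, " too large: must be <= min(delays)/10 = ",
           min(delays) / 10)
    nm <- state_names(model)
    if (is.null(history)) history <- rep(0.1, length(nm))
    if (length(history) != length(nm))
      stop("history must have one value per state variable")
    mid <- if (inherits(model, "conceptual_params")) 1L else 2L
    res <- dde_integrate_compiled(mid, unname(pv), as.numeric(history),
                                  t_span[1], t_span[2], dt)
    colnames(res$states) <- nm
    colnames(res$derivs) <- nm
    colnames(res$signals) <- signal_names(model)
    signals <- res$signals
  } else {
    if (!is.list(model) || !is.function(model$rhs))
      stop("model must be a clock_params object or a list with an rhs function")
    delays <- as.numeric(model$delays %||% numeric(0))
    if (length(delays) && dt > min(delays) / 10)
      stop("dt = ", dt, " too large: must be <= min(delays)/10 = ",
           min(delays) / 10)
    if (is.null(history)) stop("history is required for generic models")
    res <- dde_integrate_callback(model$rhs, delays, as.numeric(history),
                                  t_span[1], t_span[2], dt)
    nm <- model$state_names %||% paste0("y", seq_along(history))
    colnames(res$states) <- nm
    colnames(res$derivs) <- nm
    signals <- NULL
  }
  structure(list(time = res$time, states = res$states, signals = signals,
                 derivs = res$derivs, dt = dt, t_span = t_span,
                 history = as.numeric(history), params = model),
            class = "clock_trajectory")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate a stored trajectory at arbitrary times
#'
#' Uses the same cubic Hermite dense output the integrator used for its
#' delayed lookups; at grid points this reproduces the stored values exactly,
#' and before the start time it returns the history state.
#'
#' @param traj a \code{clock_trajectory}.
#' @param at numeric vector of times (h).
#' @return Matrix with one row per time and one named column per variable.
#' @export
trajectory_at <- function(traj, at) {
  stopifnot(inherits(traj, "clock_trajectory"))
  out <- dense_eval(traj$time, traj$states, traj$derivs,
                    traj$history, as.numeric(at))
  colnames(out) <- colnames(traj$states)
  out
}

#' Extract one signal (state variable or derived cis-activity) by name
#'
#' @param traj a \code{clock_trajectory}.
#' @param signal a column name of \code{traj$states} or \code{traj$signals}.
#' @return Numeric vector along the trajectory grid.
#' @export
trajectory_signal <- function(traj, signal) {
  stopifnot(inherits(traj, "clock_trajectory"))
  if (signal %in% colnames(traj$states)) return(traj$states[, signal])
  if (!is.null(traj$signals) && signal %in% colnames(traj$signals))
    return(traj$signals[, signal])
  stop("unknown signal '", signal, "'; available: ",
       paste(c(colnames(traj$states), colnames(traj$signals)),
             collapse = ", "))
}

#' @export
print.clock_trajectory <- function(x, ...) {
  cat("<clock_trajectory> ", ncol(x$states), " states, t in [",
      x$t_span[1], ", ", x$t_span[2], "] h, dt = ", x$dt, " h\n", sep = "")
  cat("  states : ", paste(colnames(x$states), collapse = ", "), "\n")
  if (!is.null(x$signals))
    cat("  signals: ", paste(colnames(x$signals), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.clock_trajectory <- function(x, ...) {
  df <- data.frame(time = x$time, x$states, check.names = FALSE)
  if (!is.null(x$signals)) df <- cbind(df, as.data.frame(x$signals))
  df
}

#' Write a trajectory to CSV
#'
#' Columns: \code{time}, then the state variables, then the derived
#' cis-element activity signals.
#'
#' @param traj a \code{clock_trajectory}.
#' @param path output path.
#' @param thin keep every \code{thin}-th grid point (default 1, all points).
#' @return \code{path}, invisibly.
#' @export
write_trajectory <- function(traj, path, thin = 1L) {
  df <- as.data.frame(traj)
  if (thin > 1L) df <- df[seq(1, nrow(df), by = thin), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
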