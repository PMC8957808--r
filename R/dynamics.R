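#' Simulation parameters
#'
#' Time discretisation for the Euler integration of the rate equations.
#' Units are dimensionless model time: the membrane time constant `tau`
#' sets the scale and `dt` the step. A trial lasts `trial_length` steps.
#'
#' @param dt Euler step size. Must satisfy `dt/tau <= 1` (stability of the
#'   explicit discretisation of the leak term).
#' @param tau Membrane time constant applied to units whose own `tau` is
#'   missing.
#' @param trial_length Number of steps per trial.
#' @return An object of class `sfc_sim_params`.
#' @export
#' @examples
#' sim_params()
sim_params <- function(dt = 0.1, tau = 1, trial_length = 500) {
  stopifnot(is.numeric(dt), length(dt) == 1, is.finite(dt),
            is.numeric(tau), length(tau) == 1, is.finite(tau),
            is.numeric(trial_length), length(trial_length) == 1)
  if (dt <= 0) stop("`dt` must be > 0")
  if (tau <= 0) stop("`tau` must be > 0")
  if (trial_length < 1) stop("`trial_length` must be >= 1")
  if (dt / tau > 1) stop("`dt`/`tau` must be <= 1 for a stable Euler leak")
  structure(list(dt = dt, tau = tau, trial_length = as.integer(trial_length)),
            class = "sfc_sim_params")
}

#' Rectified hyperbolic tangent activation
#'
#' Maps voltages to firing rates in `[0, 1]`: `F(v) = max(tanh(v), 0)`.
#' Negative voltages (hyperpolarisation) yield a rate of exactly zero.
#'
#' @param v Numeric vector of voltages. Must be finite; a non-finite value
#'   signals numerical blow-up upstream and is an error.
#' @return Firing rates in `[0, 1]`, same shape as `v`.
#' @export
#' @examples
#' activation(c(-5, 0, 1))
activation <- function(v) {
  if (!is.numeric(v)) stop("`v` must be numeric")
  if (any(!is.finite(v)))
    stop("non-finite voltage: the simulation has diverged upstream")
  pmax(tanh(v), 0)
}

new_state <- function(spec) {
  n <- nrow(spec$units)
  nm <- spec$units$name
  list(V = stats::setNames(numeric(n), nm),
       F = stats::setNames(numeric(n), nm),
       W = weight_matrix(spec))
}

check_state <- function(state, spec) {
  n <- nrow(spec$units)
  if (length(state$V) != n || length(state$F) != n ||
      !all(dim(state$W) == c(n, n)))
    stop("state dimensions do not match the network spec")
  invisible(state)
}

#' One synchronous Euler step
#'
#' Advances all units by one step of the leaky rate equation
#' `V <- V + (dt/tau) * (-V + I + W F(V))`, using the pre-step rates for
#' every presynaptic term (synchronous update), then recomputes
#' `F = activation(V)`. Weights are left untouched; plasticity is applied
#' separately (see [apply_plasticity()]).
#'
#' @param state List with elements `V`, `F` (per-unit) and `W` (weight
#'   matrix indexed post x pre), as produced by [run_protocol()] internals.
#' @param I External input per unit (0 for undriven units).
#' @param spec An `sfc_network` (see [build_basic_model()]).
#' @param params An [sim_params()] object.
#' @return The updated state.
#' @export
euler_step <- function(state, I, spec, params = sim_params()) {
  check_state(state, spec)
  if (length(I) != nrow(spec$units))
    stop("`I` must have one entry per unit (",
         nrow(spec$units), "), got ", length(I))
  r <- params$dt / unit_tau(spec, params)
  v_new <- state$V + r * (-state$V + I + drop(state$W %*% state$F))
  if (any(!is.finite(v_new))) {
    bad <- spec$units$name[which(!is.finite(v_new))[1]]
    stop("voltage diverged for unit '", bad, "'")
  }
  state$V <- v_new
  state$F <- activation(v_new)
  state
}

unit_tau <- function(spec, params) {
  tau <- spec$units$tau
  tau[is.na(tau)] <- params$tau
  tau
}

#' Integrate a fixed number of steps
#'
#' Applies [euler_step()] `n` times, optionally invoking a plasticity hook
#' after each step, and records the per-step firing rates of every unit.
#' This is the reference (pure R) integration path; [run_trial()] uses a
#' compiled equivalent.
#'
#' @inheritParams euler_step
#' @param n Number of steps (>= 1).
#' @param plasticity_hook Optional `function(state)` returning a modified
#'   state, called after each step (e.g. a BCM update).
#' @return A list with `state` (final state) and `trace`
#'   (units x steps matrix of firing rates).
#' @export
run_timesteps <- function(state, I, spec, params = sim_params(), n,
                          plasticity_hook = NULL) {
  stopifnot(length(n) == 1, n >= 1)
  n <- as.integer(n)
  trace <- matrix(NA_real_, nrow(spec$units), n,
                  dimnames = list(spec$units$name, NULL))
  for (step in seq_len(n)) {
    state <- tryCatch(
      euler_step(state, I, spec, params),
      error = function(e) stop("at step ", step, ": ", conditionMessage(e),
                               call. = FALSE)
    )
    if (!is.null(plasticity_hook)) state <- plasticity_hook(state)
    trace[, step] <- state$F
  }
  list(state = state, trace = trace)
}
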