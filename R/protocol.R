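#' Protocol phase
#'
#' One block of identical trials with a fixed set of active input channels.
#'
#' @param name Phase label, e.g. `"baseline"`, `"conditioning"`,
#'   `"extinction"` or any custom label.
#' @param n_trials Number of trials in the phase (>= 1).
#' @param inputs Named numeric vector of channel amplitudes (>= 0), e.g.
#'   `c(conspecific = 1, context1 = 1)`. Channels absent from the vector
#'   are silent.
#' @return An object of class `sfc_phase`.
#' @export
phase <- function(name, n_trials, inputs = numeric(0)) {
  stopifnot(is.character(name), length(name) == 1, n_trials >= 1)
  inputs <- unlist(inputs)
  if (length(inputs) > 0 &&
      (is.null(names(inputs)) || any(!nzchar(names(inputs)))))
    stop("`inputs` must be a named vector of channel amplitudes")
  if (any(inputs < 0)) stop("channel amplitudes must be >= 0")
  structure(list(name = name, n_trials = as.integer(n_trials),
                 inputs = inputs), class = "sfc_phase")
}

#' Protocol specification
#'
#' @param phases List of [phase()] objects, run in order. Weights persist
#'   across phases and trials; voltages reset at every trial start.
#' @param sim An [sim_params()] object.
#' @return An object of class `sfc_protocol`.
#' @export
protocol_spec <- function(phases, sim = sim_params()) {
  stopifnot(length(phases) >= 1,
            all(vapply(phases, inherits, logical(1), "sfc_phase")))
  structure(list(phases = phases, sim = sim), class = "sfc_protocol")
}

#' The three-phase social-fear protocol
#'
#' One baseline trial of social interaction (conspecific + context 1),
#' three conditioning trials that add the defeat input (driving lPBN and
#' Som1), and eleven extinction trials of re-exposure without defeat.
#' Each trial lasts `sim$trial_length` steps.
#'
#' @param sim An [sim_params()] object.
#' @param n_baseline,n_conditioning,n_extinction Trial counts per phase.
#' @return An `sfc_protocol`.
#' @export
default_protocol <- function(sim = sim_params(), n_baseline = 1,
                             n_conditioning = 3, n_extinction = 11) {
  protocol_spec(list(
    phase("baseline", n_baseline, c(conspecific = 1, context1 = 1)),
    phase("conditioning", n_conditioning,
          c(conspecific = 1, context1 = 1, defeat = 1)),
    phase("extinction", n_extinction, c(conspecific = 1, context1 = 1))
  ), sim = sim)
}

#' In-silico manipulation
#'
#' A timed perturbation of the running circuit, emulating optogenetic or
#' pharmacological interventions:
#' \describe{
#'   \item{silence_unit}{clamps the target unit's firing rate to 0 (the
#'     leak dynamics of its voltage continue).}
#'   \item{stimulate_unit}{adds `magnitude` to the target's external input.}
#'   \item{block_connection}{sets the effective weight of the target edge
#'     to 0 without touching the stored weight.}
#'   \item{scale_connection}{multiplies the effective weight by
#'     `magnitude` (stored weight untouched; plasticity still acts on the
#'     stored weight).}
#'   \item{freeze_plasticity}{disables the BCM update on the target edges.}
#' }
#'
#' @param kind One of the five kinds above.
#' @param target A unit name (silence/stimulate), a `c(pre, post)` pair
#'   (block/scale), or for `freeze_plasticity` either `"all"`, a vector of
#'   unit names (freezes plastic edges terminating on those units) or a
#'   two-column matrix of `(pre, post)` pairs.
#' @param magnitude Stimulation drive or scale factor (>= 0 for scaling).
#' @param phases Phase names in which the manipulation is active
#'   (`NULL` = all phases).
#' @param trials Within-phase trial numbers (`NULL` = all trials of the
#'   selected phases).
#' @param steps Optional `c(from, to)` step range within each active trial.
#' @return An object of class `sfc_manipulation`.
#' @export
manipulation <- function(kind, target, magnitude = 1, phases = NULL,
                         trials = NULL, steps = NULL) {
  kinds <- c("silence_unit", "stimulate_unit", "block_connection",
             "scale_connection", "freeze_plasticity")
  kind <- match.arg(kind, kinds)
  if (kind == "scale_connection" && magnitude < 0)
    stop("scale factor must be >= 0")
  if (!is.null(steps)) {
    stopifnot(length(steps) == 2, steps[1] >= 1, steps[2] >= steps[1])
    steps <- as.integer(steps)
  }
  structure(list(kind = kind, target = target, magnitude = magnitude,
                 phases = phases, trials = trials, steps = steps),
            class = "sfc_manipulation")
}

manip_active <- function(m, phase_name, trial_in_phase) {
  (is.null(m$phases) || phase_name %in% m$phases) &&
    (is.null(m$trials) || trial_in_phase %in% m$trials)
}

check_manipulations <- function(spec, manipulations) {
  for (m in manipulations) {
    if (m$kind %in% c("silence_unit", "stimulate_unit")) {
      if (!all(m$target %in% spec$units$name))
        stop("manipulation targets unknown unit '",
             paste(setdiff(m$target, spec$units$name), collapse = ", "), "'")
    } else if (m$kind %in% c("block_connection", "scale_connection")) {
      edge_index(spec, m$target[1], m$target[2])
    } else if (m$kind == "freeze_plasticity") {
      resolve_freeze(spec, m$target)
    }
  }
  invisible(TRUE)
}

# Logical mask over spec$connections rows frozen by a freeze target.
resolve_freeze <- function(spec, target) {
  co <- spec$connections
  if (is.matrix(target) || is.data.frame(target)) {
    mask <- rep(FALSE, nrow(co))
    for (i in seq_len(nrow(target))) {
      mask[edge_index(spec, target[i, 1], target[i, 2])] <- TRUE
    }
    return(mask)
  }
  if (identical(target, "all")) return(rep(TRUE, nrow(co)))
  if (is.character(target)) {
    if (!all(target %in% spec$units$name))
      stop("freeze_plasticity targets unknown unit '",
           paste(setdiff(target, spec$units$name), collapse = ", "), "'")
    return(co$post %in% target)
  }
  stop("unsupported freeze_plasticity target")
}

assemble_input <- function(spec, ph) {
  I <- stats::setNames(numeric(nrow(spec$units)), spec$units$name)
  for (ch in names(ph$inputs)) {
    amp <- ph$inputs[[ch]]
    if (amp == 0) next
    tgt <- spec$input_channels[[ch]]
    if (is.null(tgt)) stop("phase '", ph$name, "' drives unknown channel '",
                           ch, "'")
    I[tgt$unit] <- I[tgt$unit] + amp * tgt$gain
  }
  I
}

#' Run a single trial
#'
#' Resets voltages to zero, assembles the external input from the phase's
#' channels plus any stimulation manipulations, and integrates
#' `sim$trial_length` Euler steps with per-step BCM plasticity. Silencing,
#' blocking, scaling and freezing manipulations are applied for the steps
#' of their window; stored weights are only changed by plasticity.
#'
#' @param spec An `sfc_network`.
#' @param ph An [phase()] object.
#' @param state Network state; its weights carry over, its voltages do not.
#' @param manipulations List of [manipulation()] objects already filtered
#'   to this trial (phase/trial windows are handled by [run_protocol()];
#'   step windows are handled here).
#' @param sim An [sim_params()] object.
#' @return List with `state` (after the trial) and `trace` (units x steps
#'   firing-rate matrix).
#' @export
run_trial <- function(spec, ph, state = new_state(spec),
                      manipulations = list(), sim = sim_params()) {
  check_state(state, spec)
  check_manipulations(spec, manipulations)
  state$V[] <- 0
  state$F[] <- 0
  n_steps <- sim$trial_length
  nm <- spec$units$name

  # split the trial at step-window boundaries; manipulations are constant
  # within a segment
  breaks <- c(1L, n_steps + 1L)
  for (m in manipulations) {
    if (!is.null(m$steps))
      breaks <- c(breaks, m$steps[1], min(m$steps[2] + 1L, n_steps + 1L))
  }
  breaks <- sort(unique(pmax(1L, pmin(breaks, n_steps + 1L))))

  trace <- matrix(NA_real_, length(nm), n_steps, dimnames = list(nm, NULL))
  dtt <- sim$dt / unit_tau(spec, sim)
  base_I <- assemble_input(spec, ph)

  for (b in seq_len(length(breaks) - 1)) {
    seg <- breaks[b]:(breaks[b + 1] - 1)
    active <- Filter(function(m)
      is.null(m$steps) || (m$steps[1] <= seg[1] && m$steps[2] >= seg[length(seg)]),
      manipulations)
    I <- base_I
    silenced <- integer(0)
    S <- matrix(1, length(nm), length(nm))
    frozen <- rep(FALSE, nrow(spec$connections))
    for (m in active) {
      if (m$kind == "stimulate_unit") {
        I[m$target] <- I[m$target] + m$magnitude
      } else if (m$kind == "silence_unit") {
        silenced <- c(silenced, match(m$target, nm) - 1L)
      } else if (m$kind %in% c("block_connection", "scale_connection")) {
        f <- if (m$kind == "block_connection") 0 else m$magnitude
        S[match(m$target[2], nm), match(m$target[1], nm)] <- f
      } else if (m$kind == "freeze_plasticity") {
        frozen <- frozen | resolve_freeze(spec, m$target)
      }
    }
    pe <- plastic_edge_table(spec, frozen)
    out <- tryCatch(
      cpp_run_block(state$V, state$W, S, I, dtt, length(seg),
                    as.integer(silenced), as.integer(pe$post - 1L),
                    as.integer(pe$pre - 1L), as.numeric(pe$alpha),
                    as.numeric(pe$w_min), as.numeric(pe$w_max),
                    as.numeric(pe$theta), TRUE),
      error = function(e) {
        msg <- conditionMessage(e)
        idx <- regmatches(msg, regexpr("unit index [0-9]+", msg))
        if (length(idx) == 1) {
          i <- as.integer(sub("unit index ", "", idx))
          stop("voltage diverged for unit '", nm[i], "'", call. = FALSE)
        }
        stop(e)
      })
    state$V <- stats::setNames(out$V, nm)
    state$F <- stats::setNames(out$F, nm)
    state$W <- out$W
    dimnames(state$W) <- list(nm, nm)
    trace[, seg] <- out$trace
  }
  list(state = state, trace = trace)
}

#' Run a full protocol
#'
#' Starts from a fresh state (initial weights from the spec, zero
#' voltages), runs the protocol's phases in order with weights carried
#' across trials, and records the complete firing-rate trace plus a weight
#' snapshot at the end of every trial. The simulation is fully
#' deterministic.
#'
#' @param spec An `sfc_network`.
#' @param protocol An `sfc_protocol`; defaults to [default_protocol()].
#' @param manipulations List of [manipulation()] objects.
#' @param state Optional starting state (e.g. to chain protocols).
#' @return An object of class `sfc_result` with fields `traces`
#'   (unit x step x trial array), `weights` (post x pre x trial array of
#'   end-of-trial snapshots), `meta` (one row per trial: global trial
#'   number, phase, within-phase trial), and the spec, protocol and
#'   manipulations used.
#' @export
#' @examples
#' \donttest{
#' res <- run_protocol(build_basic_model())
#' round(avoidance_index(res), 2)
#' }
run_protocol <- function(spec, protocol = default_protocol(),
                         manipulations = list(), state = NULL) {
  check_manipulations(spec, manipulations)
  if (is.null(state)) state <- new_state(spec)
  sim <- protocol$sim
  n_trials <- sum(vapply(protocol$phases, function(p) p$n_trials, integer(1)))
  nm <- spec$units$name
  traces <- array(NA_real_, c(length(nm), sim$trial_length, n_trials),
                  dimnames = list(nm, NULL, NULL))
  weights <- array(NA_real_, c(length(nm), length(nm), n_trials),
                   dimnames = list(nm, nm, NULL))
  meta <- data.frame(trial = integer(0), phase = character(0),
                     trial_in_phase = integer(0), stringsAsFactors = FALSE)
  k <- 0L
  for (ph in protocol$phases) {
    for (tr in seq_len(ph$n_trials)) {
      k <- k + 1L
      active <- Filter(function(m) manip_active(m, ph$name, tr),
                       manipulations)
      out <- tryCatch(
        run_trial(spec, ph, state, active, sim),
        error = function(e) stop("in phase '", ph$name, "', trial ", tr,
                                 ": ", conditionMessage(e), call. = FALSE))
      state <- out$state
      traces[, , k] <- out$trace
      weights[, , k] <- state$W
      meta <- rbind(meta, data.frame(trial = k, phase = ph$name,
                                     trial_in_phase = tr,
                                     stringsAsFactors = FALSE))
    }
  }
  structure(list(traces = traces, weights = weights, meta = meta,
                 spec = spec, protocol = protocol,
                 manipulations = manipulations, final_state = state),
            class = "sfc_result")
}

#' @export
print.sfc_result <- function(x, ...) {
  cat("<sfc_result> ", dim(x$traces)[3], " trials x ", dim(x$traces)[2],
      " steps, ", dim(x$traces)[1], " units\n", sep = "")
  ai <- avoidance_index(x)
  cat("phases: ", paste(rle(x$meta$phase)$values, collapse = " -> "),
      "\n", sep = "")
  cat("avoidance index (dPag1 trial means):\n")
  print(round(stats::setNames(ai, x$meta$phase), 3))
  invisible(x)
}

#' MDT high-/low-frequency stimulation bundle
#'
#' Builds the stimulation block administered between conditioning and
#' extinction: a phase of trials with a tonic exogenous drive to MDT and
#' plasticity restricted to the MDT efferents. A high drive (HFS) pushes
#' the downstream Pyr2 and Pv rates above the BCM threshold by the end of
#' the block (net LTP on MDT->Pyr2 and MDT->Pv); a low drive (LFS) keeps
#' them strictly between 0 and the threshold (net LTD). The returned phase
#' and manipulations are inserted between conditioning and extinction by
#' [run_prediction()].
#'
#' @param spec An `sfc_network`.
#' @param mode `"HFS"` or `"LFS"`.
#' @param amplitude Tonic drive to MDT; defaults to the shipped calibration
#'   (2.0 for HFS, 0.35 for LFS).
#' @param n_trials Number of stimulation trials (defaults to 20 for HFS,
#'   15 for LFS).
#' @param check If `TRUE`, simulate baseline + conditioning + block and
#'   verify the rate conditions on the final block trial, erroring on a
#'   mis-calibrated amplitude.
#' @param sim An [sim_params()] object (used by the check).
#' @return List with `phase` (an [phase()]), `manipulations` (freeze of all
#'   non-MDT plastic edges plus the MDT drive) and `mode`.
#' @export
mdt_stimulation_block <- function(spec, mode = c("HFS", "LFS"),
                                  amplitude = NULL, n_trials = NULL,
                                  check = TRUE, sim = sim_params()) {
  mode <- match.arg(mode)
  if (is.null(amplitude)) amplitude <- if (mode == "HFS") 2.0 else 0.35
  if (is.null(n_trials)) n_trials <- if (mode == "HFS") 20 else 15
  ph <- phase("stimulation", n_trials, numeric(0))
  co <- spec$connections
  non_mdt <- co[co$plastic & co$pre != "MDT", c("pre", "post"), drop = FALSE]
  manips <- list(
    manipulation("stimulate_unit", "MDT", magnitude = amplitude,
                 phases = "stimulation"),
    manipulation("freeze_plasticity", as.matrix(non_mdt),
                 phases = "stimulation")
  )
  if (check) {
    proto <- protocol_spec(list(
      phase("baseline", 1, c(conspecific = 1, context1 = 1)),
      phase("conditioning", 3, c(conspecific = 1, context1 = 1, defeat = 1)),
      ph), sim = sim)
    res <- run_protocol(spec, proto, manips)
    last <- dim(res$traces)[3]
    rates <- rowMeans(res$traces[, , last])
    # each efferent is judged against its own BCM threshold
    edge_theta <- function(post) {
      th <- co$theta[co$pre == "MDT" & co$post == post]
      if (length(th) == 0 || is.na(th)) spec$plasticity$theta else th
    }
    ok <- if (mode == "HFS") {
      rates["Pyr2"] > edge_theta("Pyr2") && rates["Pv"] > edge_theta("Pv")
    } else {
      rates["Pyr2"] > 0 && rates["Pyr2"] < edge_theta("Pyr2") &&
        rates["Pv"] > 0 && rates["Pv"] < edge_theta("Pv")
    }
    if (!ok)
      stop("calibration error: ", mode, " amplitude ", amplitude,
           " does not put Pyr2/Pv rates in the required range ",
           "(Pyr2 = ", signif(rates["Pyr2"], 3), " vs theta ",
           edge_theta("Pyr2"), "; Pv = ", signif(rates["Pv"], 3),
           " vs theta ", edge_theta("Pv"), ")")
  }
  list(phase = ph, manipulations = manips, mode = mode,
       amplitude = amplitude)
}
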