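#' Social-avoidance index
#'
#' The trial-mean firing rate of the dPAG output unit: the model's readout
#' of social avoidance. For a single trial trace this is the arithmetic
#' mean over the trial's steps; for a full result it returns one value per
#' trial.
#'
#' @param x A units-x-steps trace matrix or an `sfc_result`.
#' @param unit Readout unit (default `"dPag1"`).
#' @return A number in `[0, 1]`, or a per-trial vector for an `sfc_result`.
#' @export
avoidance_index <- function(x, unit = "dPag1") {
  if (inherits(x, "sfc_result")) return(trial_means(x, unit))
  if (!is.matrix(x) || !(unit %in% rownames(x)))
    stop("trace does not contain unit '", unit, "'")
  mean(x[unit, ])
}

#' Per-trial mean firing rate of one unit
#'
#' @param result An `sfc_result`.
#' @param unit Unit name.
#' @return Numeric vector, one entry per trial.
#' @export
trial_means <- function(result, unit) {
  if (!(unit %in% dimnames(result$traces)[[1]]))
    stop("result does not contain unit '", unit, "'")
  apply(result$traces[unit, , , drop = FALSE], 3, mean)
}

#' Trials to extinction
#'
#' The first extinction trial (1-based within the extinction phase) whose
#' avoidance index falls below the threshold, or `NA` if the model never
#' extinguishes within the phase.
#'
#' @param result An `sfc_result` from a protocol with an `"extinction"`
#'   phase.
#' @param threshold Avoidance threshold on the dPag1 trial mean
#'   (default 0.1).
#' @return Integer trial number, or `NA_integer_` ("not extinguished").
#' @export
trials_to_extinction <- function(result, threshold = 0.1) {
  ext <- result$meta$phase == "extinction"
  if (!any(ext)) stop("protocol has no extinction phase")
  ai <- avoidance_index(result)[ext]
  below <- which(ai < threshold)
  if (length(below) == 0) NA_integer_ else as.integer(below[1])
}

#' Classify a unit as fear, extinction, persistent or none
#'
#' Responsiveness to the conditioned stimulus is measured on the first and
#' last extinction trials (the exposures immediately after conditioning
#' and after extinction): a unit is responsive if its trial-mean rate
#' reaches the threshold. Fear units respond after conditioning only,
#' extinction units after extinction only, persistent units after both.
#'
#' @param result An `sfc_result` from the default protocol.
#' @param unit Unit name.
#' @param threshold Responsiveness threshold on the trial-mean rate
#'   (default 0.15).
#' @return A list with `unit`, `class` and the two responsiveness flags.
#' @export
classify_unit <- function(result, unit, threshold = 0.15) {
  ext <- which(result$meta$phase == "extinction")
  if (length(ext) < 2) stop("need at least two extinction trials")
  tm <- trial_means(result, unit)
  post_cond <- tm[ext[1]] >= threshold
  post_ext <- tm[ext[length(ext)]] >= threshold
  cls <- if (post_cond && post_ext) "persistent"
         else if (post_cond) "fear"
         else if (post_ext) "extinction"
         else "none"
  list(unit = unit, class = cls,
       responsive_post_conditioning = post_cond,
       responsive_post_extinction = post_ext,
       mean_post_conditioning = unname(tm[ext[1]]),
       mean_post_extinction = unname(tm[ext[length(ext)]]))
}

#' Classify all units of a result
#'
#' @inheritParams classify_unit
#' @param units Units to classify (default: all).
#' @return Data frame with one row per unit.
#' @export
classify_units <- function(result, units = dimnames(result$traces)[[1]],
                           threshold = 0.15) {
  do.call(rbind, lapply(units, function(u) {
    cl <- classify_unit(result, u, threshold)
    data.frame(unit = cl$unit, class = cl$class,
               responsive_post_conditioning = cl$responsive_post_conditioning,
               responsive_post_extinction = cl$responsive_post_extinction,
               stringsAsFactors = FALSE)
  }))
}

excitatory_vmhvl_units <- function(spec) {
  spec$units$name[spec$units$area == "VMHvl" & spec$units$sign == "+"]
}

#' Reproduce a published target experiment
#'
#' Runs one of the five in-silico reproductions against a matched control
#' (identical configuration apart from the manipulation) and evaluates its
#' qualitative criterion:
#' \describe{
#'   \item{silva_vmhvl_inhibition}{silencing the excitatory VMHvl units
#'     during a post-conditioning exposure reduces dPag1 activity below
#'     the control exposure.}
#'   \item{franklin_pyr2_block}{blocking the Pyr2 -> dPag1 projection makes
#'     dPag1 active during plain conspecific + context exposure, with no
#'     conditioning ever applied.}
#'   \item{xu_pv_stimulation}{stimulating Pv during the first extinction
#'     trial lowers dPag1 on that trial and completes extinction earlier
#'     than control.}
#'   \item{xu_som_inhibition}{silencing Som1-3 during the first extinction
#'     trial has the same two effects.}
#'   \item{krzywkowski_context}{after the full protocol, re-exposure to the
#'     conditioning context alone reactivates Hyp1 and drives dPag1, while
#'     the alternative context does not recruit Hyp1.}
#' }
#'
#' @param name Experiment identifier (see above).
#' @param spec An `sfc_network` (main model by default).
#' @param sim An [sim_params()] object.
#' @param avoidance_threshold,responsiveness_threshold Metric cutoffs.
#' @param control Optional precomputed control `sfc_result` of the default
#'   protocol (shared across experiments to avoid rerunning it).
#' @return List with `name`, `pass`, and a `metrics` list.
#' @export
reproduce_experiment <- function(name, spec = build_basic_model(),
                                 sim = sim_params(),
                                 avoidance_threshold = 0.1,
                                 responsiveness_threshold = 0.15,
                                 control = NULL) {
  names_ok <- c("silva_vmhvl_inhibition", "franklin_pyr2_block",
                "xu_pv_stimulation", "xu_som_inhibition",
                "krzywkowski_context")
  if (!(name %in% names_ok))
    stop("unknown experiment '", name, "'; valid names: ",
         paste(names_ok, collapse = ", "))
  proto <- default_protocol(sim)
  if (is.null(control)) control <- run_protocol(spec, proto)
  ext1 <- which(control$meta$phase == "extinction")[1]

  if (name == "silva_vmhvl_inhibition") {
    manip <- manipulation("silence_unit", excitatory_vmhvl_units(spec),
                          phases = "extinction", trials = 1)
    res <- run_protocol(spec, proto, list(manip))
    m <- avoidance_index(res)[ext1]
    c0 <- avoidance_index(control)[ext1]
    return(list(name = name, pass = m < c0,
                metrics = list(dpag_manipulated = m, dpag_control = c0)))
  }

  if (name == "franklin_pyr2_block") {
    exposure <- protocol_spec(list(
      phase("exposure", 1, c(conspecific = 1, context1 = 1))), sim)
    blocked <- run_protocol(spec, exposure, list(
      manipulation("block_connection", c("Pyr2", "dPag1"))))
    plain <- run_protocol(spec, exposure)
    m <- avoidance_index(blocked)[1]
    c0 <- avoidance_index(plain)[1]
    return(list(name = name,
                pass = m >= avoidance_threshold && c0 < avoidance_threshold,
                metrics = list(dpag_blocked = m, dpag_control = c0)))
  }

  if (name %in% c("xu_pv_stimulation", "xu_som_inhibition")) {
    manip <- if (name == "xu_pv_stimulation") {
      manipulation("stimulate_unit", "Pv", magnitude = 1.5,
                   phases = "extinction", trials = 1)
    } else {
      manipulation("silence_unit", c("Som1", "Som2", "Som3"),
                   phases = "extinction", trials = 1)
    }
    res <- run_protocol(spec, proto, list(manip))
    m1 <- avoidance_index(res)[ext1]
    c1 <- avoidance_index(control)[ext1]
    tm <- trials_to_extinction(res, avoidance_threshold)
    tc <- trials_to_extinction(control, avoidance_threshold)
    return(list(name = name,
                pass = m1 < c1 && !is.na(tm) && !is.na(tc) && tm < tc,
                metrics = list(dpag_first_extinction = m1,
                               dpag_first_extinction_control = c1,
                               trials_to_extinction = tm,
                               trials_to_extinction_control = tc)))
  }

  # krzywkowski_context: context-only probes from the post-protocol state
  probe <- function(channel) {
    ph <- phase(paste0("probe_", channel), 1,
                stats::setNames(1, channel))
    run_trial(spec, ph, control$final_state, list(), sim)$trace
  }
  tr1 <- probe("context1")
  tr2 <- probe("context2")
  hyp1_c1 <- mean(tr1["Hyp1", ])
  hyp1_c2 <- mean(tr2["Hyp1", ])
  dpag_c1 <- mean(tr1["dPag1", ])
  list(name = name,
       pass = hyp1_c1 >= responsiveness_threshold &&
         dpag_c1 >= avoidance_threshold &&
         hyp1_c2 < responsiveness_threshold,
       metrics = list(hyp1_context1 = hyp1_c1, hyp1_context2 = hyp1_c2,
                      dpag_context1 = dpag_c1))
}

#' Run a model prediction experiment
#'
#' The manipulations that generate the model's testable predictions:
#' \describe{
#'   \item{vmhvl_plasticity_block}{freezing plasticity on the VMHvl
#'     afferents during conditioning leaves acute avoidance intact but the
#'     fear memory collapses at the first extinction trial.}
#'   \item{lpbn_block}{silencing lPBN during conditioning keeps Hyp1
#'     silent throughout and conditioning fails.}
#'   \item{pyr2_stimulation}{stimulating Pyr2 during the first extinction
#'     trial produces one-trial extinction.}
#'   \item{mdt_hfs}{high-frequency-like MDT stimulation after conditioning
#'     accelerates extinction.}
#'   \item{mdt_lfs}{low-frequency-like MDT stimulation abolishes
#'     extinction; Pyr1 stays elevated and Pyr2 suppressed.}
#'   \item{ls_scaling}{(alternative model only) scaling down the LS output
#'     during extinction slows and eventually abolishes extinction; see
#'     [ls_scaling_sweep()].}
#' }
#'
#' @inheritParams reproduce_experiment
#' @param ... Extra arguments for specific predictions (`reductions` for
#'   `ls_scaling`, `amplitude`/`n_trials` for the MDT modes).
#' @return List with `name`, `pass` and a `metrics` list.
#' @export
run_prediction <- function(name, spec = build_basic_model(),
                           sim = sim_params(), avoidance_threshold = 0.1,
                           responsiveness_threshold = 0.15, control = NULL,
                           ...) {
  names_ok <- c("vmhvl_plasticity_block", "lpbn_block", "pyr2_stimulation",
                "mdt_hfs", "mdt_lfs", "ls_scaling")
  if (!(name %in% names_ok))
    stop("unknown prediction '", name, "'; valid names: ",
         paste(names_ok, collapse = ", "))
  if (name == "ls_scaling") {
    if (!("LS" %in% spec$units$name))
      stop("ls_scaling requires the alternative model (unit LS missing)")
    sweep <- ls_scaling_sweep(spec, sim = sim,
                              threshold = avoidance_threshold, ...)
    th <- ls_thresholds(sweep)
    return(list(name = name,
                pass = sweep$trials_to_extinction[sweep$reduction == 0] ==
                  attr(sweep, "control"),
                metrics = list(control_trials_to_extinction =
                                 attr(sweep, "control"),
                               slowdown_reduction_pct = th$slowdown,
                               abolition_reduction_pct = th$abolition),
                sweep = sweep))
  }
  proto <- default_protocol(sim)
  if (is.null(control)) control <- run_protocol(spec, proto)
  ext <- which(control$meta$phase == "extinction")
  cond <- which(control$meta$phase == "conditioning")
  tc <- trials_to_extinction(control, avoidance_threshold)

  if (name == "vmhvl_plasticity_block") {
    manip <- manipulation("freeze_plasticity", c("Hyp1", "Hyp2"),
                          phases = "conditioning")
    res <- run_protocol(spec, proto, list(manip))
    ai <- avoidance_index(res)
    pass <- all(ai[cond] >= avoidance_threshold) &&
      ai[ext[1]] < avoidance_threshold &&
      ai[ext[1]] < avoidance_index(control)[ext[1]]
    return(list(name = name, pass = pass,
                metrics = list(dpag_conditioning = unname(ai[cond]),
                               dpag_first_extinction = unname(ai[ext[1]]),
                               dpag_first_extinction_control =
                                 unname(avoidance_index(control)[ext[1]]))))
  }

  if (name == "lpbn_block") {
    manip <- manipulation("silence_unit", "lPBN", phases = "conditioning")
    res <- run_protocol(spec, proto, list(manip))
    hyp1 <- trial_means(res, "Hyp1")
    ai <- avoidance_index(res)
    pass <- all(hyp1[c(cond, ext)] < responsiveness_threshold) &&
      ai[ext[1]] < avoidance_threshold
    return(list(name = name, pass = pass,
                metrics = list(hyp1_max_after_baseline =
                                 max(hyp1[c(cond, ext)]),
                               dpag_first_extinction = unname(ai[ext[1]]))))
  }

  if (name == "pyr2_stimulation") {
    manip <- manipulation("stimulate_unit", "Pyr2", magnitude = 1.5,
                          phases = "extinction", trials = 1)
    res <- run_protocol(spec, proto, list(manip))
    tm <- trials_to_extinction(res, avoidance_threshold)
    return(list(name = name,
                pass = !is.na(tm) && tm <= 2 && !is.na(tc) && tm < tc,
                metrics = list(trials_to_extinction = tm,
                               trials_to_extinction_control = tc)))
  }

  # mdt_hfs / mdt_lfs
  mode <- if (name == "mdt_hfs") "HFS" else "LFS"
  bundle <- mdt_stimulation_block(spec, mode, sim = sim, ...)
  proto_stim <- protocol_spec(append(proto$phases, list(bundle$phase),
                                     after = 2), sim)
  res <- run_protocol(spec, proto_stim, bundle$manipulations)
  tm <- trials_to_extinction(res, avoidance_threshold)
  if (mode == "HFS") {
    pass <- !is.na(tm) && !is.na(tc) && tm < tc
    metrics <- list(trials_to_extinction = tm,
                    trials_to_extinction_control = tc)
  } else {
    last_m <- dim(res$traces)[3]
    last_c <- dim(control$traces)[3]
    pyr1_m <- trial_means(res, "Pyr1")[last_m]
    pyr1_c <- trial_means(control, "Pyr1")[last_c]
    pyr2_m <- trial_means(res, "Pyr2")[last_m]
    pyr2_c <- trial_means(control, "Pyr2")[last_c]
    pass <- is.na(tm) && pyr1_m > pyr1_c && pyr2_m < pyr2_c
    metrics <- list(trials_to_extinction = tm,
                    trials_to_extinction_control = tc,
                    pyr1_last_extinction = unname(pyr1_m),
                    pyr1_last_extinction_control = unname(pyr1_c),
                    pyr2_last_extinction = unname(pyr2_m),
                    pyr2_last_extinction_control = unname(pyr2_c))
  }
  list(name = name, pass = pass, metrics = metrics)
}

#' Qualitative criteria checklist
#'
#' The battery of qualitative facts the shipped calibration must
#' reproduce: a quiet baseline, conditioning that recruits dPag1,
#' extinction completing within the extinction phase, stability of the
#' VMHvl afferent weights during extinction (main model), and the five
#' target-experiment reproductions. Used as the pass/fail oracle by the
#' sensitivity analysis and as a permanent calibration regression.
#'
#' @inheritParams reproduce_experiment
#' @param include_weight_stability Include the VMHvl weight-stability flag
#'   (drop it when checking variants, such as the alternative model, where
#'   VMHvl weights are expected to move during extinction).
#' @return Named logical vector; attribute `"details"` carries the metric
#'   values behind each flag.
#' @export
qualitative_criteria <- function(spec = build_basic_model(),
                                 sim = sim_params(),
                                 avoidance_threshold = 0.1,
                                 responsiveness_threshold = 0.15,
                                 include_weight_stability = TRUE) {
  control <- run_protocol(spec, default_protocol(sim))
  ai <- avoidance_index(control)
  meta <- control$meta
  flags <- c(
    baseline_quiet = unname(ai[meta$phase == "baseline"][1]) <
      avoidance_threshold,
    conditioning_avoidance = any(ai[meta$phase == "conditioning"] >=
                                   avoidance_threshold),
    extinction_completes =
      !is.na(trials_to_extinction(control, avoidance_threshold))
  )
  details <- list(avoidance_index = ai,
                  trials_to_extinction =
                    trials_to_extinction(control, avoidance_threshold))
  if (include_weight_stability) {
    flags <- c(flags, vmhvl_weights_stable =
                 vmhvl_weight_stability(control) < 0.01)
    details$vmhvl_max_relative_change <- vmhvl_weight_stability(control)
  }
  for (nm in c("silva_vmhvl_inhibition", "franklin_pyr2_block",
               "xu_pv_stimulation", "xu_som_inhibition",
               "krzywkowski_context")) {
    rep <- reproduce_experiment(nm, spec, sim, avoidance_threshold,
                                responsiveness_threshold, control = control)
    flags[nm] <- rep$pass
    details[[nm]] <- rep$metrics
  }
  attr(flags, "details") <- details
  flags
}

# Largest relative change of any VMHvl afferent weight across the
# extinction phase (snapshot at the end of conditioning vs the last trial).
vmhvl_weight_stability <- function(result) {
  meta <- result$meta
  last_cond <- max(meta$trial[meta$phase == "conditioning"])
  last_ext <- max(meta$trial[meta$phase == "extinction"])
  co <- result$spec$connections
  aff <- co[co$post %in% c("Hyp1", "Hyp2") &
              co$pre %in% c("MeA", "Hip1", "Hip2"), , drop = FALSE]
  ij <- cbind(match(aff$post, dimnames(result$weights)[[1]]),
              match(aff$pre, dimnames(result$weights)[[2]]))
  w0 <- result$weights[, , last_cond][ij]
  w1 <- result$weights[, , last_ext][ij]
  max(abs(w1 - w0) / pmax(abs(w0), .Machine$double.eps))
}

#' Sweep the LS output reduction during extinction
#'
#' On the alternative model, scales the effective LS -> Hyp1 weight by
#' `1 - reduction/100` during the extinction phase and records the number
#' of trials to extinction for each reduction.
#'
#' @param spec The alternative model (must contain the LS unit).
#' @param reductions Integer percent reductions to evaluate.
#' @param threshold Avoidance threshold.
#' @param sim An [sim_params()] object.
#' @return Data frame with columns `reduction`, `trials_to_extinction`
#'   (NA when extinction never completes) and `completed`; attribute
#'   `"control"` holds the unmanipulated trials-to-extinction.
#' @export
ls_scaling_sweep <- function(spec, reductions = 0:100, threshold = 0.1,
                             sim = sim_params()) {
  if (!("LS" %in% spec$units$name))
    stop("ls_scaling requires the alternative model (unit LS missing)")
  proto <- default_protocol(sim)
  control <- trials_to_extinction(run_protocol(spec, proto), threshold)
  tte <- vapply(reductions, function(r) {
    manip <- manipulation("scale_connection", c("LS", "Hyp1"),
                          magnitude = 1 - r / 100, phases = "extinction")
    trials_to_extinction(run_protocol(spec, proto, list(manip)), threshold)
  }, integer(1))
  out <- data.frame(reduction = reductions, trials_to_extinction = tte,
                    completed = !is.na(tte))
  attr(out, "control") <- control
  out
}

#' Slowdown and abolition thresholds of an LS-reduction sweep
#'
#' @param sweep Result of [ls_scaling_sweep()].
#' @return List with `slowdown` (smallest reduction whose
#'   trials-to-extinction strictly exceeds the unmanipulated control while
#'   extinction still completes) and `abolition` (smallest reduction for
#'   which extinction never completes), each `NA` if absent from the sweep.
#' @export
ls_thresholds <- function(sweep) {
  control <- attr(sweep, "control")
  slower <- sweep$completed & sweep$trials_to_extinction > control
  list(
    slowdown = if (any(slower)) min(sweep$reduction[slower]) else NA_integer_,
    abolition = if (any(!sweep$completed))
      min(sweep$reduction[!sweep$completed]) else NA_integer_
  )
}

#' Weight sensitivity analysis
#'
#' Rescales the initial weight of each connection over a multiplicative
#' grid and reruns the qualitative criteria suite (baseline silence,
#' conditioning response, extinction completion and the five
#' reproductions) at every scale. For each edge the tolerated range is the
#' widest contiguous pass interval around the shipped value (scale 1.0),
#' reported as percent deviation.
#'
#' @param spec An `sfc_network` (main model).
#' @param edges Data frame with columns `pre`, `post` selecting the swept
#'   connections; default all connections.
#' @param scales Multiplicative scale grid; must contain 1.0.
#' @param sim An [sim_params()] object.
#' @param progress Print one line per edge while sweeping.
#' @return Data frame (class `sfc_sensitivity`) with one row per edge:
#'   `pre`, `post`, `lo_pct`, `hi_pct`, `width_pct`; attribute `"grid"`
#'   holds the full pass/fail matrix.
#' @export
sensitivity_sweep <- function(spec, edges = NULL,
                              scales = seq(0, 2, by = 0.05),
                              sim = sim_params(), progress = FALSE) {
  if (!any(abs(scales - 1) < 1e-12))
    stop("`scales` must contain 1.0 (the shipped configuration)")
  if (is.null(edges))
    edges <- spec$connections[, c("pre", "post"), drop = FALSE]
  passes <- matrix(NA, nrow(edges), length(scales),
                   dimnames = list(paste0(edges$pre, "->", edges$post),
                                   scales))
  for (i in seq_len(nrow(edges))) {
    ei <- edge_index(spec, edges$pre[i], edges$post[i])
    w0 <- spec$connections$weight[ei]
    for (j in seq_along(scales)) {
      spec2 <- spec
      spec2$connections$weight[ei] <- w0 * scales[j]
      flags <- qualitative_criteria(spec2, sim,
                                    include_weight_stability = FALSE)
      passes[i, j] <- all(flags)
    }
    if (progress)
      message(rownames(passes)[i], ": ",
              sum(passes[i, ]), "/", length(scales), " scales pass")
  }
  one <- which(abs(scales - 1) < 1e-12)
  range_of <- function(p) {
    if (!p[one]) return(c(NA_real_, NA_real_))
    lo <- one
    while (lo > 1 && p[lo - 1]) lo <- lo - 1
    hi <- one
    while (hi < length(p) && p[hi + 1]) hi <- hi + 1
    c((scales[lo] - 1) * 100, (scales[hi] - 1) * 100)
  }
  rng <- t(apply(passes, 1, range_of))
  out <- data.frame(pre = edges$pre, post = edges$post,
                    lo_pct = rng[, 1], hi_pct = rng[, 2],
                    width_pct = rng[, 2] - rng[, 1],
                    stringsAsFactors = FALSE)
  attr(out, "grid") <- passes
  class(out) <- c("sfc_sensitivity", class(out))
  out
}

#' @export
print.sfc_sensitivity <- function(x, ...) {
  cat("<sfc_sensitivity> tolerated weight ranges (percent around shipped "
      , "value)\n", sep = "")
  ord <- order(x$width_pct)
  print.data.frame(x[ord, ], row.names = FALSE, digits = 3)
  invisible(x)
}
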