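network_to_list <- function(spec) {
  co <- spec$connections
  list(
    units = lapply(seq_len(nrow(spec$units)), function(i)
      as.list(spec$units[i, , drop = FALSE])),
    connections = lapply(seq_len(nrow(co)), function(i) {
      x <- as.list(co[i, , drop = FALSE])
      x[!vapply(x, function(v) is.na(v) || identical(v, FALSE), logical(1)) |
          names(x) %in% c("pre", "post", "weight")]
    }),
    input_channels = lapply(spec$input_channels, function(tgt)
      lapply(seq_len(nrow(tgt)), function(i) as.list(tgt[i, , drop = FALSE]))),
    plasticity = spec$plasticity
  )
}

network_from_list <- function(x) {
  units <- do.call(rbind, lapply(x$units, function(u)
    data.frame(name = u$name, area = u$area, sign = u$sign,
               tau = if (is.null(u$tau)) 1 else u$tau,
               stringsAsFactors = FALSE)))
  connections <- do.call(rbind, lapply(x$connections, function(co)
    data.frame(pre = co$pre, post = co$post, weight = co$weight,
               plastic = isTRUE(co$plastic),
               w_min = if (is.null(co$w_min)) NA_real_ else co$w_min,
               w_max = if (is.null(co$w_max)) NA_real_ else co$w_max,
               alpha = if (is.null(co$alpha)) NA_real_ else co$alpha,
               theta = if (is.null(co$theta)) NA_real_ else co$theta,
               sign_exception = isTRUE(co$sign_exception),
               stringsAsFactors = FALSE)))
  channels <- lapply(x$input_channels, function(tgt)
    do.call(rbind, lapply(tgt, function(t)
      data.frame(unit = t$unit, gain = t$gain, stringsAsFactors = FALSE))))
  pl <- x$plasticity
  if (is.null(pl)) pl <- default_plasticity()
  pl$enabled <- if (is.null(pl$enabled)) TRUE else isTRUE(pl$enabled)
  network_spec(units, connections, channels, pl)
}

protocol_to_list <- function(proto) {
  list(
    phases = lapply(proto$phases, function(ph)
      list(name = ph$name, n_trials = ph$n_trials,
           inputs = as.list(ph$inputs))),
    sim = unclass(proto$sim)
  )
}

protocol_from_list <- function(x) {
  sim <- if (is.null(x$sim)) sim_params()
         else do.call(sim_params, x$sim)
  protocol_spec(lapply(x$phases, function(ph)
    phase(ph$name, ph$n_trials, unlist(ph$inputs))), sim)
}

manipulation_from_list <- function(x) {
  target <- x$target
  if (is.list(target)) {
    target <- if (all(lengths(target) == 2))
      do.call(rbind, lapply(target, unlist)) else unlist(target)
  }
  manipulation(x$kind, target,
               magnitude = if (is.null(x$magnitude)) 1 else x$magnitude,
               phases = unlist(x$phases), trials = unlist(x$trials),
               steps = unlist(x$steps))
}

manipulation_to_list <- function(m) {
  tgt <- m$target
  if (is.matrix(tgt))
    tgt <- lapply(seq_len(nrow(tgt)), function(i) as.list(tgt[i, ]))
  out <- list(kind = m$kind, target = tgt, magnitude = m$magnitude)
  for (f in c("phases", "trials", "steps"))
    if (!is.null(m[[f]])) out[[f]] <- m[[f]]
  out
}

#' Read or write a network configuration file
#'
#' Networks are stored as YAML with sections `units`, `connections`,
#' `input_channels` and `plasticity`. The two published circuit variants
#' ship with the package under `inst/extdata/` (`basic_model.yaml`,
#' `alternative_model.yaml`) and load to the same objects that
#' [build_basic_model()] and [build_alternative_model()] construct.
#'
#' @param path File path.
#' @return `load_network()` returns an `sfc_network`; `write_network()`
#'   returns `path` invisibly.
#' @export
load_network <- function(path) {
  if (!file.exists(path)) stop("network config not found: ", path)
  network_from_list(yaml::read_yaml(path))
}

#' @rdname load_network
#' @param spec An `sfc_network`.
#' @export
write_network <- function(spec, path) {
  yaml::write_yaml(network_to_list(spec), path)
  invisible(path)
}

shipped_network_path <- function(model) {
  system.file("extdata", paste0(model, "_model.yaml"),
              package = "socialfear", mustWork = TRUE)
}

#' Load a run configuration
#'
#' A run configuration bundles a network (inline, a file path relative to
#' the configuration file, or the shipped names `"basic"` /
#' `"alternative"`), a protocol (inline or `"default"`), a list of
#' manipulations and output options. Loading validates the network and
#' fails with the full list of violations.
#'
#' @param path Path to a YAML run configuration.
#' @return A list of class `sfc_run_config` with elements `network`,
#'   `protocol`, `manipulations` and `outputs`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  x <- yaml::read_yaml(path)
  net <- x$network
  if (is.null(net)) net <- "basic"
  network <- if (is.character(net)) {
    if (net %in% c("basic", "alternative")) {
      if (net == "basic") build_basic_model() else build_alternative_model()
    } else {
      p <- if (file.exists(net)) net else file.path(dirname(path), net)
      load_network(p)
    }
  } else network_from_list(net)
  proto <- x$protocol
  protocol <- if (is.null(proto) || identical(proto, "default"))
    default_protocol() else protocol_from_list(proto)
  manips <- lapply(x$manipulations, manipulation_from_list)
  check_manipulations(network, manips)
  structure(list(network = network, protocol = protocol,
                 manipulations = manips,
                 outputs = x$outputs), class = "sfc_run_config")
}

#' @rdname load_config
#' @param config An `sfc_run_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(list(
    network = network_to_list(config$network),
    protocol = protocol_to_list(config$protocol),
    manipulations = lapply(config$manipulations, manipulation_to_list),
    outputs = config$outputs
  ), path)
  invisible(path)
}

#' Digest of a canonicalised configuration
#'
#' MD5 of the canonical JSON serialisation of a network (or run
#' configuration); embedded in result files for provenance.
#'
#' @param x An `sfc_network` or `sfc_run_config`.
#' @return Character MD5 digest.
#' @export
config_digest <- function(x) {
  lst <- if (inherits(x, "sfc_network")) network_to_list(x)
         else list(network = network_to_list(x$network),
                   protocol = protocol_to_list(x$protocol),
                   manipulations = lapply(x$manipulations,
                                          manipulation_to_list))
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(lst, f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

#' Export a simulation result
#'
#' Writes a long-format CSV of the activation traces (`phase, trial, step,
#' unit, activation`), a CSV of end-of-trial weight snapshots (`phase,
#' trial, pre, post, weight`) and a JSON summary (avoidance index per
#' trial, trials to extinction where applicable, unit classifications for
#' protocols with an extinction phase, and the network digest). Output is
#' deterministic: rerunning an identical configuration reproduces the
#' files byte for byte.
#'
#' @param result An `sfc_result`.
#' @param dir Output directory (created if missing).
#' @param formats Subset of `c("csv", "json")`.
#' @return Character vector of written file paths (the manifest).
#' @export
write_result <- function(result, dir, formats = c("csv", "json")) {
  formats <- match.arg(formats, several.ok = TRUE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- character(0)
  meta <- result$meta
  if ("csv" %in% formats) {
    d <- dim(result$traces)
    traces <- data.frame(
      phase = rep(meta$phase, each = d[1] * d[2]),
      trial = rep(meta$trial, each = d[1] * d[2]),
      step = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
      unit = rep(dimnames(result$traces)[[1]], times = d[2] * d[3]),
      activation = as.vector(result$traces),
      stringsAsFactors = FALSE)
    f <- file.path(dir, "traces.csv")
    utils::write.csv(traces, f, row.names = FALSE)
    manifest <- c(manifest, f)

    co <- result$spec$connections
    nm <- dimnames(result$weights)[[1]]
    ij <- cbind(match(co$post, nm), match(co$pre, nm))
    snap <- do.call(rbind, lapply(seq_len(d[3]), function(k)
      data.frame(phase = meta$phase[k], trial = meta$trial[k],
                 pre = co$pre, post = co$post,
                 weight = result$weights[, , k][ij],
                 stringsAsFactors = FALSE)))
    f <- file.path(dir, "weights.csv")
    utils::write.csv(snap, f, row.names = FALSE)
    manifest <- c(manifest, f)
  }
  if ("json" %in% formats) {
    summary <- list(
      network_digest = config_digest(result$spec),
      phases = rle(meta$phase)$values,
      avoidance_index = as.numeric(avoidance_index(result))
    )
    if (any(meta$phase == "extinction")) {
      summary$trials_to_extinction <- trials_to_extinction(result)
      summary$classification <- classify_units(result)
    }
    f <- file.path(dir, "summary.json")
    jsonlite::write_json(summary, f, auto_unbox = TRUE, digits = NA,
                         na = "null")
    manifest <- c(manifest, f)
  }
  manifest
}
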