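#' Construct a network specification
#'
#' Low-level constructor for the circuit graph: units, signed connections,
#' input channels and plasticity parameters. Most users will start from
#' [build_basic_model()] or [build_alternative_model()] instead.
#'
#' @param units Data frame with columns `name`, `area`, `sign` (`"+"` for
#'   glutamatergic, `"-"` for GABAergic) and `tau`.
#' @param connections Data frame with columns `pre`, `post`, `weight`,
#'   `plastic`, `w_min`, `w_max`, `alpha` (NA means the global learning
#'   rate) and `sign_exception` (documented sign-rule exceptions).
#' @param input_channels Named list mapping a channel name to a data frame
#'   with columns `unit` and `gain`.
#' @param plasticity List with `alpha` (global learning rate), `theta`
#'   (BCM threshold) and `enabled`.
#' @return An object of class `sfc_network`.
#' @export
network_spec <- function(units, connections, input_channels,
                         plasticity = default_plasticity()) {
  if (!("sign_exception" %in% names(connections)))
    connections$sign_exception <- FALSE
  if (!("alpha" %in% names(connections))) connections$alpha <- NA_real_
  if (!("theta" %in% names(connections))) connections$theta <- NA_real_
  spec <- structure(
    list(units = units, connections = connections,
         input_channels = input_channels, plasticity = plasticity),
    class = "sfc_network")
  bad <- validate_spec(spec)
  if (length(bad) > 0)
    stop("invalid network spec:\n  - ", paste(bad, collapse = "\n  - "))
  spec
}

#' Validate a network specification
#'
#' Checks the structural invariants of a circuit: unique unit names, signs
#' in `{+, -}`, no self-connections, connection endpoints that exist,
#' weight signs consistent with the presynaptic unit's neurotransmitter
#' (unless flagged as a documented exception), plastic edges carrying
#' finite clip bounds with `w_min <= w_max`, input channels referencing
#' existing units, and valid plasticity parameters.
#'
#' @param spec An `sfc_network` (or a bare list with the same fields).
#' @return Character vector of human-readable violations; empty if valid.
#' @export
#' @examples
#' validate_spec(build_basic_model())  # character(0)
validate_spec <- function(spec) {
  v <- character(0)
  u <- spec$units
  co <- spec$connections
  if (anyDuplicated(u$name))
    v <- c(v, paste0("duplicated unit names: ",
                     paste(unique(u$name[duplicated(u$name)]), collapse = ", ")))
  if (!all(u$sign %in% c("+", "-")))
    v <- c(v, "unit sign must be '+' or '-'")
  if (any(!is.na(u$tau) & u$tau <= 0))
    v <- c(v, "unit tau must be > 0")
  edge_lab <- paste0(co$pre, "->", co$post)
  missing_pre <- !(co$pre %in% u$name)
  missing_post <- !(co$post %in% u$name)
  for (i in which(missing_pre | missing_post))
    v <- c(v, paste0("connection ", edge_lab[i], " references unknown unit"))
  for (i in which(co$pre == co$post))
    v <- c(v, paste0("self-connection not allowed: ", edge_lab[i]))
  if (anyDuplicated(edge_lab))
    v <- c(v, paste0("duplicated connection: ",
                     paste(unique(edge_lab[duplicated(edge_lab)]),
                           collapse = ", ")))
  pre_sign <- u$sign[match(co$pre, u$name)]
  sign_ok <- ifelse(pre_sign == "+", co$weight >= 0, co$weight <= 0)
  for (i in which(!is.na(sign_ok) & !sign_ok & !co$sign_exception))
    v <- c(v, paste0("weight sign of ", edge_lab[i],
                     " contradicts the presynaptic unit's sign (",
                     pre_sign[i], ")"))
  for (i in which(co$plastic)) {
    if (!is.finite(co$w_min[i]) || !is.finite(co$w_max[i]))
      v <- c(v, paste0("plastic edge ", edge_lab[i], " lacks clip bounds"))
    else if (co$w_min[i] > co$w_max[i])
      v <- c(v, paste0("plastic edge ", edge_lab[i], " has w_min > w_max"))
  }
  if ("theta" %in% names(co)) {
    for (i in which(!is.na(co$theta) & (co$theta < 0 | co$theta > 1)))
      v <- c(v, paste0("edge theta of ", edge_lab[i],
                       " must lie in [0, 1]"))
  }
  for (ch in names(spec$input_channels)) {
    tgt <- spec$input_channels[[ch]]
    for (i in which(!(tgt$unit %in% u$name)))
      v <- c(v, paste0("input channel '", ch, "' drives unknown unit '",
                       tgt$unit[i], "'"))
  }
  pl <- spec$plasticity
  if (!is.numeric(pl$alpha) || pl$alpha < 0)
    v <- c(v, "plasticity alpha must be >= 0")
  if (!is.numeric(pl$theta) || pl$theta < 0 || pl$theta > 1)
    v <- c(v, "plasticity theta must lie in [0, 1]")
  v
}

apply_param_overrides <- function(units, edges, channels, plasticity,
                                  params) {
  if (is.null(params)) params <- list()
  if (!is.null(params$weights)) {
    lab <- paste0(edges$pre, "->", edges$post)
    for (nm in names(params$weights)) {
      i <- match(nm, lab)
      if (is.na(i)) stop("override for unknown edge '", nm, "'")
      edges$weight[i] <- params$weights[[nm]]
    }
  }
  for (fld in c("w_min", "w_max", "alpha", "theta")) {
    ov <- params[[paste0("edge_", fld)]]
    if (!is.null(ov)) {
      lab <- paste0(edges$pre, "->", edges$post)
      for (nm in names(ov)) {
        i <- match(nm, lab)
        if (is.na(i)) stop("override for unknown edge '", nm, "'")
        edges[[fld]][i] <- ov[[nm]]
      }
    }
  }
  if (!is.null(params$theta)) plasticity$theta <- params$theta
  if (!is.null(params$alpha)) plasticity$alpha <- params$alpha
  if (!is.null(params$input_gains)) {
    for (ch in names(params$input_gains)) {
      g <- params$input_gains[[ch]]
      if (!(ch %in% names(channels)))
        stop("override for unknown input channel '", ch, "'")
      for (nm in names(g)) {
        i <- match(nm, channels[[ch]]$unit)
        if (is.na(i)) stop("channel '", ch, "' does not drive unit '", nm, "'")
        channels[[ch]]$gain[i] <- g[[nm]]
      }
    }
  }
  list(units = units, edges = edges, channels = channels,
       plasticity = plasticity)
}

#' Build the main social-fear circuit
#'
#' Returns the 16-unit network: conspecific input to the medial amygdala
#' (MeA), two hippocampal context units (Hip1, Hip2), the nociceptive lPBN,
#' the mediodorsal thalamus (MDT) relaying to the mPFC, the antagonistic
#' hypothalamic populations Hyp1 (threat) and Hyp2 (interaction) coupled by
#' inhibitory interneurons into a winner-take-all, the prefrontal fear-ON /
#' fear-OFF pyramidal populations (Pyr1, Pyr2) with their Pv and Som
#' interneurons, and the dPAG output unit whose activation represents
#' social avoidance. Plastic edges (BCM with clipping) are the MeA and vHIP
#' afferents of the VMHvl and the MDT efferents to Pyr1, Pyr2 and Pv.
#'
#' @param params Optional named list of overrides: `weights` (named vector
#'   `"pre->post"` = value), `edge_w_min`, `edge_w_max`, `edge_alpha`
#'   (same naming), `theta`, `alpha`, and `input_gains` (named list
#'   channel -> named gain vector).
#' @return An `sfc_network`.
#' @export
#' @examples
#' net <- build_basic_model()
#' nrow(net$units)
build_basic_model <- function(params = NULL) {
  parts <- apply_param_overrides(basic_units(), basic_edges(),
                                 basic_channels(), default_plasticity(),
                                 params)
  network_spec(parts$units, parts$edges, parts$channels, parts$plasticity)
}

#' Build the alternative circuit with a lateral-septum afferent
#'
#' The main model plus a GABAergic lateral septum (LS) unit, driven by the
#' conspecific input, that sends a fixed inhibitory projection onto the
#' threat population Hyp1. Under this variant the VMHvl takes part in
#' extinction: Hyp1 afferents depotentiate and Hyp2 afferents potentiate
#' across extinction trials, so Hyp1 classifies as an extinction rather
#' than a persistent population.
#'
#' @inheritParams build_basic_model
#' @return An `sfc_network` with 17 units.
#' @export
build_alternative_model <- function(params = NULL) {
  add <- alternative_additions()
  units <- rbind(basic_units(), add$unit)
  edges <- rbind(basic_edges(), add$edge)
  channels <- basic_channels()
  channels$conspecific <- rbind(
    channels$conspecific,
    data.frame(unit = "LS", gain = add$conspecific_gain,
               stringsAsFactors = FALSE))
  # the variant's own calibration, then any user overrides on top
  parts <- apply_param_overrides(units, edges, channels,
                                 default_plasticity(),
                                 add[c("weights", "edge_w_min", "edge_w_max",
                                       "edge_alpha")])
  parts <- apply_param_overrides(parts$units, parts$edges, parts$channels,
                                 parts$plasticity, params)
  network_spec(parts$units, parts$edges, parts$channels, parts$plasticity)
}

#' Initial weight matrix of a network
#'
#' @param spec An `sfc_network`.
#' @return Numeric matrix indexed `(post, pre)` with the initial weights.
#' @export
weight_matrix <- function(spec) {
  n <- nrow(spec$units)
  W <- matrix(0, n, n, dimnames = list(spec$units$name, spec$units$name))
  co <- spec$connections
  W[cbind(match(co$post, spec$units$name),
          match(co$pre, spec$units$name))] <- co$weight
  W
}

edge_index <- function(spec, pre, post) {
  i <- which(spec$connections$pre == pre & spec$connections$post == post)
  if (length(i) != 1)
    stop("no connection ", pre, "->", post, " in the network")
  i
}

#' Modify an initial connection weight
#'
#' @param spec An `sfc_network`.
#' @param pre,post Unit names of the connection.
#' @param weight New initial weight (sign must stay consistent with the
#'   presynaptic unit unless the edge is a documented exception).
#' @return The modified `sfc_network`.
#' @export
set_weight <- function(spec, pre, post, weight) {
  i <- edge_index(spec, pre, post)
  spec$connections$weight[i] <- weight
  bad <- validate_spec(spec)
  if (length(bad) > 0)
    stop("invalid weight: ", paste(bad, collapse = "; "))
  spec
}

#' Remove a unit (and its incident connections) from a network
#'
#' Used by the structural part of the sensitivity analysis, e.g. deleting
#' one of the hypothalamic interneurons.
#'
#' @param spec An `sfc_network`.
#' @param name Unit to remove.
#' @return The reduced `sfc_network`.
#' @export
remove_unit <- function(spec, name) {
  if (!(name %in% spec$units$name)) stop("unknown unit '", name, "'")
  spec$units <- spec$units[spec$units$name != name, , drop = FALSE]
  keep <- spec$connections$pre != name & spec$connections$post != name
  spec$connections <- spec$connections[keep, , drop = FALSE]
  spec$input_channels <- lapply(spec$input_channels, function(tgt)
    tgt[tgt$unit != name, , drop = FALSE])
  spec
}

#' Remove a single connection from a network
#'
#' @inheritParams set_weight
#' @return The reduced `sfc_network`.
#' @export
remove_connection <- function(spec, pre, post) {
  i <- edge_index(spec, pre, post)
  spec$connections <- spec$connections[-i, , drop = FALSE]
  spec
}

#' @export
print.sfc_network <- function(x, ...) {
  co <- x$connections
  cat("<sfc_network> ", nrow(x$units), " units, ", nrow(co),
      " connections (", sum(co$plastic), " plastic)\n", sep = "")
  cat("areas: ", paste(unique(x$units$area), collapse = ", "), "\n", sep = "")
  cat("input channels: ",
      paste(vapply(names(x$input_channels), function(ch)
        paste0(ch, " -> ",
               paste(x$input_channels[[ch]]$unit, collapse = "+")),
        character(1)), collapse = "; "), "\n", sep = "")
  cat("plasticity: alpha = ", x$plasticity$alpha, ", theta = ",
      x$plasticity$theta,
      if (!x$plasticity$enabled) " (disabled)", "\n", sep = "")
  invisible(x)
}
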