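#' BCM weight increment
#'
#' Simplified Bienenstock-Cooper-Munro rule with a fixed threshold:
#' `dW = alpha * (f_post - theta) * f_pre`. Postsynaptic rates above the
#' threshold potentiate (LTP), rates below depress (LTD), and a silent
#' presynaptic unit gates the update off entirely.
#'
#' @param f_pre,f_post Pre- and postsynaptic firing rates in `[0, 1]`.
#' @param alpha Learning rate (>= 0).
#' @param theta BCM threshold in `[0, 1]`.
#' @return The weight increment (same shape as the rate inputs).
#' @export
#' @examples
#' bcm_delta(1, 1, alpha = 0.01, theta = 0.5)  # +0.005
bcm_delta <- function(f_pre, f_post, alpha, theta) {
  stopifnot(all(f_pre >= 0 & f_pre <= 1), all(f_post >= 0 & f_post <= 1),
            alpha >= 0, theta >= 0, theta <= 1)
  alpha * (f_post - theta) * f_pre
}

# Resolve the plastic-edge bookkeeping for a spec: matrix indices,
# per-edge learning rates and BCM thresholds (edge values falling back to
# the global ones) and clip bounds. `frozen` is a logical mask over
# connection rows.
plastic_edge_table <- function(spec, frozen = NULL) {
  co <- spec$connections
  sel <- co$plastic & spec$plasticity$enabled
  if (!is.null(frozen)) sel <- sel & !frozen
  idx <- which(sel)
  nm <- spec$units$name
  theta <- if ("theta" %in% names(co)) co$theta[idx]
           else rep(NA_real_, length(idx))
  list(
    post = match(co$post[idx], nm),
    pre = match(co$pre[idx], nm),
    alpha = ifelse(is.na(co$alpha[idx]), spec$plasticity$alpha,
                   co$alpha[idx]),
    theta = ifelse(is.na(theta), spec$plasticity$theta, theta),
    w_min = co$w_min[idx],
    w_max = co$w_max[idx],
    rows = idx
  )
}

#' Apply one BCM update to all plastic connections
#'
#' For each plastic edge of the network the stored weight is moved by
#' [bcm_delta()] evaluated at the current firing rates and clipped into the
#' edge's `[w_min, w_max]` range. Non-plastic edges are untouched. With
#' plasticity disabled (`spec$plasticity$enabled = FALSE`) or a frozen
#' edge set covering everything, the state is returned unchanged.
#'
#' @param state Network state (`V`, `F`, `W`).
#' @param spec An `sfc_network`.
#' @param frozen Optional logical mask over `spec$connections` rows marking
#'   edges whose plasticity is frozen by a manipulation.
#' @return The state with an updated weight matrix.
#' @export
apply_plasticity <- function(state, spec, frozen = NULL) {
  pe <- plastic_edge_table(spec, frozen)
  if (length(pe$post) == 0) return(state)
  ij <- cbind(pe$post, pe$pre)
  dw <- bcm_delta(state$F[pe$pre], state$F[pe$post], pe$alpha, pe$theta)
  state$W[ij] <- pmin(pmax(state$W[ij] + dw, pe$w_min), pe$w_max)
  state
}
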