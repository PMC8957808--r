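# Small fixture networks built in code.

# Two excitatory units driven by one channel; optionally one plastic edge.
tiny_net <- function(w12 = 0.8, plastic = FALSE) {
  units <- data.frame(name = c("a", "b"), area = c("A", "B"),
                      sign = "+", tau = 1, stringsAsFactors = FALSE)
  connections <- data.frame(
    pre = "a", post = "b", weight = w12, plastic = plastic,
    w_min = if (plastic) 0 else NA_real_,
    w_max = if (plastic) 2 else NA_real_,
    alpha = NA_real_, theta = NA_real_, sign_exception = FALSE,
    stringsAsFactors = FALSE)
  network_spec(units, connections,
               list(drive = data.frame(unit = "a", gain = 1,
                                       stringsAsFactors = FALSE)))
}

# Random valid network for property-style tests. The simulator itself is
# seedless; seeds here only make the harness reproducible.
random_net <- function(seed, n_units = NULL) {
  set.seed(seed)
  n <- if (is.null(n_units)) sample(4:8, 1) else n_units
  units <- data.frame(
    name = paste0("u", seq_len(n)),
    area = sample(c("X", "Y"), n, replace = TRUE),
    sign = sample(c("+", "-"), n, replace = TRUE, prob = c(0.7, 0.3)),
    tau = 1, stringsAsFactors = FALSE)
  pairs <- expand.grid(pre = units$name, post = units$name,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$pre != pairs$post, ]
  pairs <- pairs[sample(nrow(pairs), min(nrow(pairs), 3 * n)), ]
  mag <- runif(nrow(pairs), 0.1, 1.2)
  sgn <- ifelse(units$sign[match(pairs$pre, units$name)] == "+", 1, -1)
  plastic <- runif(nrow(pairs)) < 0.3
  connections <- data.frame(
    pre = pairs$pre, post = pairs$post, weight = mag * sgn,
    plastic = plastic,
    w_min = ifelse(plastic, mag * sgn - 0.3, NA_real_),
    w_max = ifelse(plastic, mag * sgn + 0.3, NA_real_),
    alpha = NA_real_, theta = NA_real_,
    sign_exception = FALSE, stringsAsFactors = FALSE)
  driven <- sample(units$name, max(1, n %/% 2))
  network_spec(units, connections,
               list(drive = data.frame(unit = driven, gain = 1,
                                       stringsAsFactors = FALSE)))
}

random_protocol <- function(seed) {
  set.seed(seed + 1000)
  protocol_spec(list(
    phase("one", sample(1:2, 1), c(drive = runif(1, 0.5, 1.5))),
    phase("two", sample(1:3, 1), c(drive = runif(1, 0, 1)))
  ), sim = sim_params(trial_length = 120))
}

# Independent fixed-point oracle: iterate V = I + W F(V) directly.
fixed_point_oracle <- function(W, I, tol = 1e-12, max_iter = 50000) {
  v <- rep(0, length(I))
  for (i in seq_len(max_iter)) {
    v_new <- I + drop(W %*% pmax(tanh(v), 0))
    if (max(abs(v_new - v)) < tol) return(v_new)
    v <- v_new
  }
  NULL  # did not converge; caller should skip the comparison
}
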