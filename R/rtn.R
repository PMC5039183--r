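#' Sample random threshold network weights
#'
#' One weight per causal link (j -> i), equal to +1 or -1 with equal
#' probability; all thresholds are zero. Weights are stored both as a
#' per-edge vector and as a dense N x N matrix `W` with `W[i, j]` the
#' weight of the link j -> i (0 where no causal link exists).
#'
#' @param net an `hf_network` with direction tags.
#' @return An object of class `"hf_weights"` with elements `w` (per-edge,
#'   aligned with `net$edges`), `W` (dense matrix) and `h` (thresholds,
#'   all zero).
#' @export
rtn_weights <- function(net) {
  if (any(net$dir == 0L)) stop("network has untagged edges; assign directions first")
  E <- n_edges(net)
  w <- sample(c(-1L, 1L), E, replace = TRUE)
  src <- ifelse(net$dir == 1L, net$edges[, 1], net$edges[, 2])
  tgt <- ifelse(net$dir == 1L, net$edges[, 2], net$edges[, 1])
  W <- matrix(0, net$N, net$N)
  W[cbind(tgt, src)] <- w
  structure(list(w = w, W = W, h = rep(0, net$N), src = src, tgt = tgt),
            class = "hf_weights")
}

#' Sample a uniform random state
#'
#' @param N node count.
#' @return Integer vector of +1/-1 values.
#' @export
rtn_random_state <- function(N) sample(c(-1L, 1L), N, replace = TRUE)

#' One synchronous update step of the threshold dynamics
#'
#' Every node simultaneously takes the sign of the weighted sum of its
#' inputs plus its threshold, with the convention `sgn(0) = +1` (so nodes
#' with zero in-degree and zero threshold go to +1).
#'
#' @param x state vector of +1/-1 values.
#' @param wts weights from [rtn_weights()].
#' @return The next state.
#' @export
rtn_step <- function(x, wts) {
  field <- as.vector(wts$W %*% x) + wts$h
  ifelse(field >= 0, 1L, -1L)
}

#' Simulate a threshold-network trajectory
#'
#' @param wts weights from [rtn_weights()].
#' @param x0 initial state.
#' @param steps number of synchronous updates (>= 0).
#' @return An N x (steps + 1) integer matrix of states, column t+1 holding
#'   the state at time t; column 1 is `x0`.
#' @export
rtn_simulate <- function(wts, x0, steps) {
  stopifnot(steps >= 0)
  N <- length(x0)
  out <- matrix(0L, N, steps + 1)
  out[, 1] <- x0
  x <- x0
  for (t in seq_len(steps)) {
    x <- rtn_step(x, wts)
    out[, t + 1] <- x
  }
  out
}

#' Normalized Hamming distance between two states
#'
#' Fraction of nodes at which the two +1/-1 states differ.
#'
#' @param x,y state vectors of equal length.
#' @return Value in `[0, 1]`.
#' @export
hamming_distance <- function(x, y) {
  if (length(x) != length(y)) stop("states have different lengths")
  sum(abs(x - y)) / (2 * length(x))
}

#' Damage spreading curve
#'
#' For each of `n_weights` weight realizations and `n_init` random initial
#' conditions per realization, a random node of the initial state is
#' flipped and both trajectories are run for `horizon` steps under the
#' same weights. The curve `delta_t = d(x(t), y(t)) - d(x(0), y(0))`
#' (with `d(x(0), y(0)) = 1/N`) is averaged over all trials. A positive
#' long-time value indicates the chaotic phase; negative, the ordered
#' phase.
#'
#' @param net an `hf_network` with direction tags.
#' @param horizon number of time steps (>= 1).
#' @param n_weights number of weight realizations.
#' @param n_init number of random initial conditions per realization.
#' @param seed optional seed.
#' @return Numeric vector `delta` of length `horizon + 1` with
#'   `delta[t + 1]` the mean damage at time t; `delta[1]` is exactly 0.
#' @export
damage_spreading <- function(net, horizon, n_weights = 20, n_init = 20,
                             seed = NULL) {
  stopifnot(horizon >= 1)
  N <- net$N
  with_seed(seed, {
    acc <- numeric(horizon + 1)
    for (r in seq_len(n_weights)) {
      wts <- rtn_weights(net)
      for (s in seq_len(n_init)) {
        x <- rtn_random_state(N)
        y <- x
        flip <- sample.int(N, 1L)
        y[flip] <- -y[flip]
        d <- numeric(horizon + 1)
        d[1] <- 1 / N
        xy <- cbind(x, y)
        for (t in seq_len(horizon)) {
          # both trajectories share the weights: one multiply updates both
          xy <- ifelse(wts$W %*% xy >= 0, 1L, -1L)
          d[t + 1] <- sum(xy[, 1] != xy[, 2]) / N
        }
        acc <- acc + (d - 1 / N)
      }
    }
    acc / (n_weights * n_init)
  })
}
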