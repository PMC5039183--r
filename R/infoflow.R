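#' Accumulate per-link transition counts from a trajectory
#'
#' For every causal link j -> i, tabulates the 8-cell joint histogram of
#' `(x_i(t+1), x_i(t), x_j(t))` over all consecutive state pairs of the
#' trajectory. Cell index (1..8) is `1 + 4*a + 2*b + c` with
#' `a = [x_i(t+1) = +1]`, `b = [x_i(t) = +1]`, `c = [x_j(t) = +1]`.
#'
#' @param traj N x (T+1) state matrix from [rtn_simulate()].
#' @param net an `hf_network` with direction tags.
#' @return An 8 x E integer matrix of counts, one column per causal link,
#'   columns aligned with `net$edges` (link direction given by `net$dir`).
#' @export
transition_counts <- function(traj, net) {
  if (ncol(traj) < 2) stop("trajectory must contain at least 2 states")
  E <- n_edges(net)
  if (E == 0) return(matrix(0L, 8, 0))
  src <- ifelse(net$dir == 1L, net$edges[, 1], net$edges[, 2])
  tgt <- ifelse(net$dir == 1L, net$edges[, 2], net$edges[, 1])
  Tn <- ncol(traj) - 1
  P <- traj > 0
  A <- P[tgt, -1, drop = FALSE]        # x_i(t+1)
  B <- P[tgt, -ncol(P), drop = FALSE]  # x_i(t)
  C <- P[src, -ncol(P), drop = FALSE]  # x_j(t)
  code <- 4L * A + 2L * B + C          # 0..7, E x T
  off <- 8L * (seq_len(E) - 1L)        # recycles down columns: row = link
  matrix(tabulate(code + off + 1L, nbins = 8L * E), nrow = 8)
}

#' Plug-in transfer entropy from an 8-cell count table
#'
#' `T_{j->i} = H(X_i(t+1) | X_i(t)) - H(X_i(t+1) | X_i(t), X_j(t))` with
#' conditional entropies in bits estimated by plugging normalized counts
#' in for probabilities; empty cells contribute 0 (the 0 log 0 = 0
#' convention) and the result is clamped to be >= 0 against roundoff.
#'
#' @param counts an 8-vector, or an 8 x E matrix of per-link tables, cell
#'   order as in [transition_counts()].
#' @return Transfer entropy in bits (vector of length E for a matrix).
#' @export
transfer_entropy <- function(counts) {
  if (is.vector(counts)) counts <- matrix(counts, ncol = 1)
  if (nrow(counts) != 8) stop("counts must have 8 cells per link")
  n <- colSums(counts)
  if (any(n < 1)) stop("empty count table")
  ent <- function(m) {
    # column-wise plug-in entropy in bits of count tables m (cells x E)
    p <- sweep(m, 2, n, "/")
    terms <- p * log2(p)
    terms[m == 0] <- 0
    -colSums(terms)
  }
  ab <- counts[c(1, 3, 5, 7), , drop = FALSE] +
        counts[c(2, 4, 6, 8), , drop = FALSE]          # (x_i', x_i)
  b  <- ab[c(1, 2), , drop = FALSE] + ab[c(3, 4), , drop = FALSE]  # (x_i)
  bc <- counts[c(1, 2, 3, 4), , drop = FALSE] +
        counts[c(5, 6, 7, 8), , drop = FALSE]          # (x_i, x_j)
  te <- ent(ab) - ent(b) - ent(counts) + ent(bc)
  pmax(te, 0)
}

#' Construct an edge flow
#'
#' A skew-symmetric assignment of real values to the edges of a network,
#' stored as one signed value per canonical edge `(u, v)`, `u < v`:
#' `values[r]` is the flow from u to v (`e_uv`), so `e_vu = -values[r]`.
#'
#' @param net an `hf_network`.
#' @param values numeric vector, one value per edge of `net`.
#' @return An object of class `"hf_flow"`.
#' @export
edge_flow <- function(net, values) {
  if (length(values) != n_edges(net)) stop("one flow value per edge required")
  structure(list(N = net$N, edges = net$edges, values = as.numeric(values)),
            class = "hf_flow")
}

#' @export
print.hf_flow <- function(x, ...) {
  cat(sprintf("edge flow on %d nodes, %d edges; ||e||^2 = %.4g\n",
              x$N, nrow(x$edges), flow_norm(x)))
  invisible(x)
}

#' Squared l2-norm of an edge flow
#'
#' Computed over the full skew-symmetric matrix, i.e. every edge counted
#' twice: `||e||^2 = sum_{i,j} e_ij^2 = 2 * sum_{u<v} e_uv^2`. All
#' component ratios are invariant to this factor of two.
#'
#' @param flow an `hf_flow`.
#' @return Non-negative scalar.
#' @export
flow_norm <- function(flow) 2 * sum(flow$values^2)

#' Full skew-symmetric matrix of an edge flow
#'
#' @param flow an `hf_flow`.
#' @return An N x N matrix `e` with `e[u, v] = -e[v, u]`, zero off-edges.
#' @export
flow_matrix <- function(flow) {
  e <- matrix(0, flow$N, flow$N)
  e[flow$edges] <- flow$values
  e[flow$edges[, c(2, 1), drop = FALSE]] <- -flow$values
  e
}

#' Estimate the information flow generated by threshold dynamics
#'
#' For each realization, fresh +1/-1 weights and a random initial state
#' are drawn, the dynamics is run for `transient + length` steps, and the
#' per-link transfer entropy is computed from the `length` post-transient
#' transitions. The per-link values are averaged over realizations and
#' assembled into the skew-symmetric information flow: positive along the
#' causal direction of each link, zero off-edges.
#'
#' @param net an `hf_network` with direction tags.
#' @param n_realizations number of weight/initial-state realizations.
#' @param transient discarded initial steps.
#' @param length number of recorded transitions per realization.
#' @param seed optional seed.
#' @param pooled if TRUE, compute one transfer entropy per link from the
#'   counts pooled across realizations instead of averaging per-realization
#'   estimates (the default matches the per-realization procedure).
#' @return An `hf_flow`; attribute `"te"` holds the averaged transfer
#'   entropy along the causal direction of each link.
#' @export
estimate_flow <- function(net, n_realizations = 100, transient = 100,
                          length = 1000, seed = NULL, pooled = FALSE) {
  stopifnot(n_realizations >= 1, transient >= 1, length >= 1)
  E <- n_edges(net)
  with_seed(seed, {
    te_acc <- numeric(E)
    pool <- matrix(0L, 8, E)
    for (r in seq_len(n_realizations)) {
      wts <- rtn_weights(net)
      x0 <- rtn_random_state(net$N)
      traj <- rtn_simulate(wts, x0, transient + length)
      rec <- traj[, (transient + 1):(transient + length + 1), drop = FALSE]
      cnt <- transition_counts(rec, net)
      if (pooled) pool <- pool + cnt
      else te_acc <- te_acc + transfer_entropy(cnt)
    }
    te <- if (pooled) transfer_entropy(pool) else te_acc / n_realizations
    flow <- edge_flow(net, ifelse(net$dir == 1L, te, -te))
    attr(flow, "te") <- te
    flow
  })
}

#' Write an edge flow to TSV
#'
#' Rows `u<TAB>v<TAB>flow` with `u < v`, 0-based ids, flow signed with
#' respect to the canonical orientation u -> v.
#'
#' @param flow an `hf_flow`.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_flow_tsv <- function(flow, path) {
  df <- data.frame(u = flow$edges[, 1] - 1L, v = flow$edges[, 2] - 1L,
                   flow = format(flow$values, digits = 17))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# N=%d", flow$N), con)
  write.table(df, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an edge flow from TSV
#'
#' @param path file written by [write_flow_tsv()].
#' @param net optional `hf_network` the flow must live on; when given, the
#'   file's edges are checked against (and ordered as) the network's.
#' @return An `hf_flow`.
#' @export
read_flow_tsv <- function(path, net = NULL) {
  first <- readLines(path, n = 1)
  df <- read.table(path, sep = "\t", comment.char = "#",
                   col.names = c("u", "v", "flow"),
                   colClasses = c("integer", "integer", "numeric"))
  edges <- cbind(df$u + 1L, df$v + 1L)
  N <- if (startsWith(first, "# N="))
    as.integer(sub("# N=", "", first)) else max(edges)
  if (!is.null(net)) {
    key <- function(e) paste(e[, 1], e[, 2])
    idx <- match(key(net$edges), key(edges))
    if (anyNA(idx)) stop("flow file does not cover the network's edges")
    return(edge_flow(net, df$flow[idx]))
  }
  flow <- structure(list(N = N, edges = edges, values = df$flow),
                    class = "hf_flow")
  flow
}
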