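# Shared fixtures and independent oracles used across the suite.

# small network built directly from an edge list (1-based, u < v)
make_net <- function(N, edges, dir = rep(1L, nrow(edges))) {
  hf_network(N, edges, dir = dir)
}

complete_net <- function(N) {
  e <- t(combn(N, 2))
  make_net(N, e)
}

star_net <- function(N) {
  make_net(N, cbind(1L, 2:N))
}

path_net <- function(N) {
  make_net(N, cbind(seq_len(N - 1), 2:N))
}

cycle_net <- function(N) {
  make_net(N, rbind(cbind(seq_len(N - 1), 2:N), c(1L, N)))
}

# Erdos-Renyi test graph with random directions (may be disconnected)
random_net <- function(N, p_edge = 0.4) {
  e <- t(combn(N, 2))
  keep <- runif(nrow(e)) < p_edge
  if (!any(keep)) keep[sample(nrow(e), 1)] <- TRUE
  make_net(N, e[keep, , drop = FALSE],
           dir = sample(c(-1L, 1L), sum(keep), replace = TRUE))
}

# O(N^3) brute-force triangle enumeration
brute_triangles <- function(net) {
  N <- net$N
  adj <- matrix(FALSE, N, N)
  adj[net$edges] <- TRUE
  adj[net$edges[, c(2, 1), drop = FALSE]] <- TRUE
  out <- list()
  for (i in seq_len(N)) for (j in seq_len(N)) for (k in seq_len(N)) {
    if (i < j && j < k && adj[i, j] && adj[j, k] && adj[i, k])
      out[[length(out) + 1]] <- c(i, j, k)
  }
  if (length(out) == 0) return(matrix(integer(0), ncol = 3))
  do.call(rbind, out)
}

# Literal plug-in evaluation of the transfer entropy from an 8-cell table:
# conditional entropies written out as -sum p(joint) * log2 p(cond).
# Cell order matches transition_counts(): index = 1 + 4a + 2b + c with
# a = [x_i(t+1)=+1], b = [x_i(t)=+1], c = [x_j(t)=+1].
brute_te <- function(counts) {
  stopifnot(length(counts) == 8)
  n <- sum(counts)
  p3 <- array(0, c(2, 2, 2))  # [a, b, c]
  for (a in 0:1) for (b in 0:1) for (cc in 0:1)
    p3[a + 1, b + 1, cc + 1] <- counts[1 + 4 * a + 2 * b + cc] / n
  p_ab <- apply(p3, c(1, 2), sum)   # p(x_i', x_i)
  p_b <- apply(p3, 2, sum)          # p(x_i)
  p_bc <- apply(p3, c(2, 3), sum)   # p(x_i, x_j)
  H_cond1 <- 0
  for (a in 1:2) for (b in 1:2) {
    if (p_ab[a, b] > 0)
      H_cond1 <- H_cond1 - p_ab[a, b] * log2(p_ab[a, b] / p_b[b])
  }
  H_cond2 <- 0
  for (a in 1:2) for (b in 1:2) for (cc in 1:2) {
    if (p3[a, b, cc] > 0)
      H_cond2 <- H_cond2 - p3[a, b, cc] * log2(p3[a, b, cc] / p_bc[b, cc])
  }
  H_cond1 - H_cond2
}

# Naive Hodge oracle: explicit orthonormal bases for the image of G, the
# row space of C and their common orthogonal complement, built by a
# generic orthogonalization (QR), then plain basis projections.
orthonormal_basis <- function(M, tol = 1e-10) {
  if (ncol(M) == 0) return(matrix(0, nrow(M), 0))
  qrd <- qr(M, tol = tol)
  r <- qrd$rank
  if (r == 0) return(matrix(0, nrow(M), 0))
  qr.Q(qrd)[, seq_len(r), drop = FALSE]
}

brute_hodge <- function(flow, net) {
  e <- flow$values
  Bg <- orthonormal_basis(gradient_operator(net))
  Bc <- orthonormal_basis(t(curl_operator(net)))
  g <- as.vector(Bg %*% crossprod(Bg, e))
  cc <- if (ncol(Bc) > 0) as.vector(Bc %*% crossprod(Bc, e)) else numeric(length(e))
  list(g = g, c = cc, h = e - g - cc)
}
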