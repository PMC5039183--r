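#' Gradient (edge-node incidence) operator
#'
#' Matrix `G` with one row per canonical edge `(u, v)`: -1 at u, +1 at v,
#' so `(G f)_(u,v) = f_v - f_u` is the gradient flow of a node potential
#' f. Its rank equals the number of nodes minus the number of connected
#' components.
#'
#' @param net an `hf_network`.
#' @return An E x N numeric matrix.
#' @export
gradient_operator <- function(net) {
  E <- n_edges(net)
  G <- matrix(0, E, net$N)
  if (E > 0) {
    G[cbind(seq_len(E), net$edges[, 1])] <- -1
    G[cbind(seq_len(E), net$edges[, 2])] <- 1
  }
  G
}

#' Curl (triangle-edge incidence) operator
#'
#' Matrix `C` with one row per triangle `(i < j < k)`: +1 at edge (i, j),
#' +1 at (j, k), -1 at (i, k), so `(C e)_tri = e_ij + e_jk + e_ki` is the
#' circulation of the flow around the triangle. Satisfies `C G = 0`
#' exactly (the curl of a gradient vanishes).
#'
#' @param net an `hf_network`.
#' @param tris triangle matrix from [triangle_set()] (computed if NULL).
#' @return A T x E numeric matrix (0 x E when triangle-free).
#' @export
curl_operator <- function(net, tris = NULL) {
  if (is.null(tris)) tris <- triangle_set(net)
  E <- n_edges(net)
  Tn <- nrow(tris)
  C <- matrix(0, Tn, E)
  if (Tn == 0) return(C)
  eidx <- edge_index_map(net)
  r <- seq_len(Tn)
  C[cbind(r, eidx(tris[, 1], tris[, 2]))] <- 1
  C[cbind(r, eidx(tris[, 2], tris[, 3]))] <- 1
  C[cbind(r, eidx(tris[, 1], tris[, 3]))] <- -1
  C
}

# lookup canonical edge row index by endpoints (u < v assumed)
edge_index_map <- function(net) {
  key <- net$edges[, 1] * (net$N + 1) + net$edges[, 2]
  lut <- setNames(seq_along(key), key)
  function(u, v) {
    idx <- unname(lut[as.character(u * (net$N + 1) + v)])
    if (anyNA(idx)) stop("triangle references a non-edge")
    idx
  }
}

# numerical rank from singular values with the standard tolerance
numerical_rank <- function(d, nrow, ncol) {
  if (length(d) == 0 || max(d) == 0) return(0L)
  tol <- max(nrow, ncol) * .Machine$double.eps * max(d)
  sum(d > tol)
}

#' Combinatorial Hodge decomposition of an edge flow
#'
#' Splits an edge flow e into three mutually orthogonal components:
#' the gradient flow g (projection of e onto the image of the gradient
#' operator G, i.e. potential differences `f_v - f_u`), the curl flow c
#' (projection onto the row space of the curl operator, spanned by
#' circulations around triangles), and the harmonic flow `h = e - g - c`
#' (divergence-free and triangle-curl-free). The loop flow `l = h + c` is
#' exactly the divergence-free part. Projections are computed from the
#' Moore-Penrose pseudoinverse via SVD (`method = "pinv"`), or by solving
#' the equivalent least-squares problems with a QR factorization
#' (`method = "lsq"`); the two agree to machine precision.
#'
#' @param flow an `hf_flow` supported on `net`'s edges.
#' @param net an `hf_network`.
#' @param method `"pinv"` (default) or `"lsq"`.
#' @return An object of class `"hf_hodge"`: edge flows `g`, `h`, `c`,
#'   `l`; node `potential` (a potential realizing g; the least-norm one
#'   for `method = "pinv"`); squared
#'   norms `norm_e`, `norm_g`, `norm_h`, `norm_c`, `norm_l`; and ratios
#'   `gamma`, `eta`, `chi`, `lambda`.
#' @export
hodge_decompose <- function(flow, net, method = c("pinv", "lsq")) {
  method <- match.arg(method)
  if (!identical(dim(flow$edges), dim(net$edges)) ||
      !all(flow$edges == net$edges) || flow$N != net$N)
    stop("flow and network edge sets differ")
  e <- flow$values
  G <- gradient_operator(net)
  C <- curl_operator(net)
  if (method == "pinv") {
    sG <- svd(G)
    rG <- numerical_rank(sG$d, nrow(G), ncol(G))
    Ug <- sG$u[, seq_len(rG), drop = FALSE]
    g <- as.vector(Ug %*% crossprod(Ug, e))
    potential <- as.vector(sG$v[, seq_len(rG), drop = FALSE] %*%
                             (crossprod(Ug, e) / sG$d[seq_len(rG)]))
    if (nrow(C) > 0) {
      sC <- svd(t(C))  # columns of u span the row space of C
      rC <- numerical_rank(sC$d, nrow(C), ncol(C))
      Uc <- sC$u[, seq_len(rC), drop = FALSE]
      cc <- as.vector(Uc %*% crossprod(Uc, e))
    } else cc <- numeric(length(e))
  } else {
    # rank deficiency is intrinsic here (constants are in the null space
    # of G); lm.fit pivots, leaving NA coefficients for aliased columns
    fit <- stats::lm.fit(G, e)
    potential <- unname(fit$coefficients)
    potential[is.na(potential)] <- 0
    g <- as.vector(fit$fitted.values)
    if (nrow(C) > 0) {
      cc <- as.vector(stats::lm.fit(t(C), e)$fitted.values)
    } else cc <- numeric(length(e))
  }
  h <- e - g - cc
  comp <- list(
    e = flow,
    g = edge_flow(net, g),
    h = edge_flow(net, h),
    c = edge_flow(net, cc),
    l = edge_flow(net, h + cc),
    potential = potential,
    norm_e = 2 * sum(e^2),
    norm_g = 2 * sum(g^2),
    norm_h = 2 * sum(h^2),
    norm_c = 2 * sum(cc^2),
    norm_l = 2 * sum((h + cc)^2)
  )
  if (comp$norm_e > 0) {
    comp$gamma <- comp$norm_g / comp$norm_e
    comp$eta <- comp$norm_h / comp$norm_e
    comp$chi <- comp$norm_c / comp$norm_e
    comp$lambda <- comp$norm_l / comp$norm_e
  } else {
    comp$gamma <- comp$eta <- comp$chi <- comp$lambda <- NA_real_
  }
  structure(comp, class = "hf_hodge")
}

#' @export
print.hf_hodge <- function(x, ...) {
  cat(sprintf(paste0(
    "Hodge decomposition: ||e||^2 = %.4g\n",
    "  gradient gamma = %.4f  harmonic eta = %.4f  curl chi = %.4f",
    "  loop lambda = %.4f\n"),
    x$norm_e, x$gamma, x$eta, x$chi, x$lambda))
  invisible(x)
}

#' Component ratios of a decomposition
#'
#' `gamma = ||g||^2/||e||^2`, `eta = ||h||^2/||e||^2`,
#' `chi = ||c||^2/||e||^2`, `lambda = ||l||^2/||e||^2 = 1 - gamma`.
#' Orthogonality gives `gamma + eta + chi = 1`.
#'
#' @param comp an `hf_hodge` from [hodge_decompose()].
#' @return Named numeric vector `(gamma, eta, chi, lambda)`.
#' @export
flow_ratios <- function(comp) {
  if (comp$norm_e == 0) stop("ratios undefined for the zero flow")
  c(gamma = comp$gamma, eta = comp$eta, chi = comp$chi, lambda = comp$lambda)
}

#' Divergence of an edge flow
#'
#' Net outflow at each node: `div_i = sum_j e_ij`, so a canonical edge
#' `(u, v)` with value f contributes +f at u and -f at v. Skew-symmetry
#' makes the divergences sum to zero; the loop component of any
#' decomposition is divergence-free at every node.
#'
#' @param flow an `hf_flow`.
#' @return Numeric vector of length N.
#' @export
flow_divergence <- function(flow) {
  div <- numeric(flow$N)
  if (nrow(flow$edges) > 0) {
    idx <- factor(c(flow$edges[, 1], flow$edges[, 2]),
                  levels = seq_len(flow$N))
    div <- as.vector(tapply(c(flow$values, -flow$values), idx, sum,
                            default = 0))
  }
  div
}

#' Structural (rank-based) component ratios
#'
#' Dimensions of the gradient, harmonic and curl subspaces relative to the
#' dimension of the space of all edge flows (the edge count E):
#' `Gamma = rank(G)/E`, `X = rank(C)/E`, `H = 1 - Gamma - X`,
#' `Lambda = 1 - Gamma`. Ranks are numerical ranks from singular values.
#' These ratios depend only on the topology, and equal the expected
#' component ratios of a uniformly random edge flow of fixed norm.
#'
#' @param net an `hf_network`.
#' @return Named list with `Gamma`, `H`, `X`, `Lambda`, plus the ranks
#'   `rank_G`, `rank_C` and edge count `E`.
#' @export
structural_ratios <- function(net) {
  E <- n_edges(net)
  if (E == 0) stop("network has no edges")
  G <- gradient_operator(net)
  C <- curl_operator(net)
  rG <- numerical_rank(svd(G, nu = 0, nv = 0)$d, nrow(G), ncol(G))
  rC <- if (nrow(C) > 0)
    numerical_rank(svd(C, nu = 0, nv = 0)$d, nrow(C), ncol(C)) else 0L
  list(Gamma = rG / E, H = 1 - rG / E - rC / E, X = rC / E,
       Lambda = 1 - rG / E, rank_G = rG, rank_C = rC, E = E)
}

#' Closed-form predictions for the structural ratios of the WS ensemble
#'
#' For the Watts-Strogatz ensemble with parameters (N, k, p):
#' `Gamma = 1/k` (N nodes, ~1 component, kN edges); the lattice triangle
#' count is thinned by `(1 - p)^3` under rewiring, so
#' `X = (k - 1)(1 - p)^3 / k` for p < 1, while at p = 1 the expected
#' triangle count of the random graph, `4 k^3 / 3`, gives
#' `X = 4 k^2 / (3 N)`; `H = 1 - Gamma - X`.
#'
#' @param N,k Watts-Strogatz parameters.
#' @param p rewiring probability in `[0, 1]`.
#' @return Named list with `Gamma`, `X`, `H`.
#' @export
predicted_structural_ratios <- function(N, k, p) {
  if (p < 0 || p > 1) stop("p must be in [0, 1]")
  Gamma <- 1 / k
  X <- if (p < 1) (k - 1) * (1 - p)^3 / k else 4 * k^2 / (3 * N)
  list(Gamma = Gamma, X = X, H = 1 - Gamma - X)
}
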