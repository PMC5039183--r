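#' @importFrom stats runif sd setNames
#' @importFrom utils read.table write.table
NULL

# Run code under a locally-seeded RNG without disturbing the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a reproducible child seed from a root seed
#'
#' Mixes a root seed with one or more non-negative integer indices (network
#' index, p index, purpose code, ...) into a new seed below 2^31, so that
#' independent parts of an ensemble each get their own deterministic stream.
#'
#' @param root integer root seed.
#' @param ... non-negative integer indices identifying the child stream.
#' @return A single integer seed.
#' @export
child_seed <- function(root, ...) {
  idx <- c(...)
  h <- as.double(root) %% 2147483647
  for (i in idx) {
    # 64-bit-safe multiplicative mixing in double precision
    h <- (h * 48271 + as.double(i) + 1) %% 2147483647
    h <- (h * 16807 + 12345) %% 2147483647
  }
  as.integer(h)
}

#' Construct a Watts-Strogatz network object
#'
#' The network is stored on its undirected skeleton: a canonical edge list
#' with `u < v` plus a per-edge direction tag giving the causal link
#' direction (`+1` for u -> v, `-1` for v -> u).
#'
#' @param N node count.
#' @param edges two-column integer matrix of canonical edges, `u < v`,
#'   1-based node ids.
#' @param dir integer vector of direction tags in `{-1, 0, +1}` (0 =
#'   undirected / not yet assigned).
#' @param meta optional list of generation parameters (k, p, seed).
#' @return An object of class `"hf_network"`.
#' @export
hf_network <- function(N, edges, dir = rep(0L, nrow(edges)), meta = list()) {
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) > 0) {
    if (any(edges[, 1] >= edges[, 2]))
      stop("edges must be canonical: u < v")
    if (any(edges < 1L) || any(edges > N))
      stop("node ids out of range")
    if (anyDuplicated(edges[, 1] * (N + 1) + edges[, 2]))
      stop("duplicate edges")
  }
  if (length(dir) != nrow(edges)) stop("dir length must equal edge count")
  structure(list(N = as.integer(N), edges = edges, dir = as.integer(dir),
                 meta = meta),
            class = "hf_network")
}

#' @export
print.hf_network <- function(x, ...) {
  cat(sprintf("Watts-Strogatz network: %d nodes, %d edges", x$N, n_edges(x)))
  if (!is.null(x$meta$k))
    cat(sprintf(" (k=%s, p=%s)", x$meta$k, x$meta$p))
  cat("\n")
  invisible(x)
}

#' Number of edges of a network
#' @param net an `hf_network`.
#' @return Integer edge count.
#' @export
n_edges <- function(net) nrow(net$edges)

# igraph view of the undirected skeleton (direction tags dropped);
# built explicitly so isolated nodes are preserved.
skeleton_igraph <- function(net) {
  g <- igraph::make_empty_graph(n = net$N, directed = FALSE)
  if (n_edges(net) > 0) g <- igraph::add_edges(g, t(net$edges))
  g
}

#' Build the ring lattice underlying the Watts-Strogatz model
#'
#' `N` nodes on a ring, each connected to its `2k` nearest neighbours
#' (offsets 1..k clockwise and counter-clockwise), giving exactly `k*N`
#' edges and uniform degree `2k`.
#'
#' @param N node count (>= 3).
#' @param k half-neighbourhood size; requires `2k < N`.
#' @return An `hf_network` with undirected (untagged) edges.
#' @export
ws_lattice <- function(N, k) {
  N <- as.integer(N); k <- as.integer(k)
  if (N < 3L) stop("N must be >= 3")
  if (2L * k >= N) stop("2k must be < N (2k >= N creates self/duplicate edges)")
  if (k < 1L) stop("k must be >= 1")
  u <- rep(seq_len(N), k)
  d <- rep(seq_len(k), each = N)
  v <- ((u - 1L + d) %% N) + 1L
  e <- cbind(pmin(u, v), pmax(u, v))
  # order lap by lap (offset, then node) to fix the rewiring scan order
  hf_network(N, e, meta = list(k = k, p = 0, lattice = TRUE))
}

#' Rewire lattice edges with probability p
#'
#' Scans the lattice edges lap by lap (offset 1 first, then offset 2, ...);
#' each edge is independently rewired with probability `p`, meaning it is
#' replaced by a uniformly random node pair, resampling while the choice
#' would create a self-loop or a duplicate edge. Edge count is preserved;
#' `p = 0` returns the input unchanged, and at `p = 1` the ensemble is the
#' uniform random graph with `kN` edges (the Erdos-Renyi G(N, m) model),
#' whose expected triangle count is `4 k^3 / 3`. A lattice triangle
#' survives rewiring only if all three of its edges do, so the triangle
#' count decays by the factor `(1 - p)^3` up to O(1/N) terms.
#'
#' @param net an `hf_network`, typically from [ws_lattice()].
#' @param p rewiring probability in `[0, 1]`.
#' @return A rewired `hf_network` (direction tags reset to 0).
#' @export
ws_rewire <- function(net, p) {
  if (p < 0 || p > 1) stop("p must be in [0, 1]")
  if (p == 0) {
    net$meta$p <- 0
    return(net)
  }
  N <- net$N
  E <- n_edges(net)
  adj <- matrix(FALSE, N, N)
  adj[net$edges] <- TRUE
  adj[net$edges[, c(2, 1), drop = FALSE]] <- TRUE
  edges <- net$edges
  do_rewire <- runif(E) < p
  for (r in seq_len(E)) {
    if (!do_rewire[r]) next
    a <- edges[r, 1]; b <- edges[r, 2]
    adj[a, b] <- FALSE; adj[b, a] <- FALSE
    repeat {
      uv <- sample.int(N, 2L)
      if (!adj[uv[1], uv[2]]) break
    }
    adj[uv[1], uv[2]] <- TRUE; adj[uv[2], uv[1]] <- TRUE
    edges[r, ] <- c(min(uv), max(uv))
  }
  hf_network(N, edges, meta = utils::modifyList(net$meta,
                                               list(p = p, lattice = NULL)))
}

#' Assign a random causal direction to every edge
#'
#' Each edge independently receives one of its two directions with equal
#' probability. Directions are part of network construction and stay fixed
#' across all threshold-network realizations on the network.
#'
#' @param net an `hf_network`.
#' @return The network with `dir` tags in `{-1, +1}`.
#' @export
ws_assign_directions <- function(net) {
  net$dir <- sample(c(-1L, 1L), n_edges(net), replace = TRUE)
  net
}

#' Generate a directed Watts-Strogatz network
#'
#' Convenience pipeline: ring lattice, rewiring, random edge directions.
#'
#' @param N node count.
#' @param k half-neighbourhood size (`2k < N`).
#' @param p rewiring probability.
#' @param seed optional seed; when given the construction is fully
#'   deterministic and the caller's RNG stream is left untouched.
#' @return An `hf_network` with direction tags.
#' @export
ws_network <- function(N, k, p, seed = NULL) {
  with_seed(seed, {
    net <- ws_assign_directions(ws_rewire(ws_lattice(N, k), p))
    net$meta$seed <- seed
    net
  })
}

#' Enumerate the triangles of a network
#'
#' Returns every 3-clique of the undirected skeleton exactly once, in
#' canonical order `i < j < k`.
#'
#' @param net an `hf_network`.
#' @return Integer matrix with three columns, one row per triangle.
#' @export
triangle_set <- function(net) {
  if (n_edges(net) == 0)
    return(matrix(integer(0), ncol = 3))
  tri <- igraph::triangles(skeleton_igraph(net))
  if (length(tri) == 0)
    return(matrix(integer(0), ncol = 3))
  m <- matrix(as.integer(tri), ncol = 3, byrow = TRUE)
  m <- t(apply(m, 1, sort))
  m <- m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
  m
}

#' Clustering coefficient (Watts-Strogatz definition)
#'
#' Average over nodes of the local clustering coefficient (links among
#' neighbours / pairs of neighbours); nodes of degree < 2 contribute 0.
#'
#' @param net an `hf_network`.
#' @return Clustering coefficient in `[0, 1]`.
#' @export
clustering_coeff <- function(net) {
  if (n_edges(net) == 0) return(0)
  igraph::transitivity(skeleton_igraph(net), type = "localaverage",
                       isolates = "zero")
}

#' Mean shortest path length
#'
#' Average hop distance over unordered node pairs of the largest connected
#' component; direction tags are ignored. Warns when the graph is
#' disconnected.
#'
#' @param net an `hf_network`.
#' @return Mean path length in hops.
#' @export
mean_path_length <- function(net) {
  g <- skeleton_igraph(net)
  if (!igraph::is_connected(g)) {
    warning("graph is disconnected; mean path length computed on the largest component")
    g <- igraph::largest_component(g)
  }
  igraph::mean_distance(g, directed = FALSE)
}

#' Small-world index omega
#'
#' `omega = L_r / L - C / C_c` where `L` and `C` are the mean path length
#' and clustering coefficient of the network, `L_r` is the mean path length
#' averaged over `n_ref` fully rewired (p = 1) reference networks with the
#' same N and k, and `C_c` is the clustering coefficient of the p = 0 ring
#' lattice. Omega is near 0 for small-world networks, negative toward the
#' lattice and positive toward random graphs.
#'
#' @param net an `hf_network` generated with parameters `(N, k)`.
#' @param k half-neighbourhood size used to build the references (defaults
#'   to `net$meta$k`).
#' @param n_ref number of p = 1 reference networks for `L_r`.
#' @param seed optional seed for the reference ensemble.
#' @param L_r,C_c optional precomputed reference values (used by the sweep
#'   to share references across networks).
#' @return A list with `L`, `C`, `L_r`, `C_c` and `omega`.
#' @export
small_world_index <- function(net, k = net$meta$k, n_ref = 20, seed = NULL,
                              L_r = NULL, C_c = NULL) {
  if (is.null(k)) stop("k is required (not recorded in net$meta)")
  L <- mean_path_length(net)
  C <- clustering_coeff(net)
  if (is.null(L_r))
    L_r <- reference_path_length(net$N, k, n_ref = n_ref, seed = seed)
  if (is.null(C_c))
    C_c <- clustering_coeff(ws_lattice(net$N, k))
  omega <- L_r / L - C / C_c
  if (omega <= -1 || omega >= 1)
    warning(sprintf("omega = %.3f outside (-1, 1)", omega))
  list(L = L, C = C, L_r = L_r, C_c = C_c, omega = omega)
}

#' Mean path length of the fully rewired reference ensemble
#'
#' @param N,k Watts-Strogatz parameters.
#' @param n_ref number of independent p = 1 networks to average over.
#' @param seed optional seed.
#' @return Scalar reference mean path length `L_r`.
#' @export
reference_path_length <- function(N, k, n_ref = 20, seed = NULL) {
  with_seed(seed, {
    mean(vapply(seq_len(n_ref), function(i) {
      suppressWarnings(mean_path_length(ws_rewire(ws_lattice(N, k), 1)))
    }, numeric(1)))
  })
}

#' Write a network to TSV
#'
#' Format: a header comment `# N=<N> k=<k> p=<p> seed=<s>`, then one row
#' `u<TAB>v<TAB>dir` per edge with `u < v`, `dir` in `{uv, vu}`, 0-based
#' node ids.
#'
#' @param net an `hf_network` with direction tags.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_network_tsv <- function(net, path) {
  if (any(net$dir == 0L)) stop("network has untagged edges; assign directions first")
  meta <- net$meta
  hdr <- sprintf("# N=%d k=%s p=%s seed=%s", net$N,
                 fmt_meta(meta$k), fmt_meta(meta$p), fmt_meta(meta$seed))
  df <- data.frame(u = net$edges[, 1] - 1L, v = net$edges[, 2] - 1L,
                   dir = ifelse(net$dir == 1L, "uv", "vu"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(df, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

fmt_meta <- function(x) if (is.null(x)) "NA" else format(x, digits = 15)

#' Read a network from TSV
#'
#' @param path file written by [write_network_tsv()].
#' @return An `hf_network`.
#' @export
read_network_tsv <- function(path) {
  first <- readLines(path, n = 1)
  meta <- list()
  if (startsWith(first, "#")) {
    kv <- regmatches(first, gregexpr("[A-Za-z_]+=[^ ]+", first))[[1]]
    for (item in kv) {
      parts <- strsplit(item, "=", fixed = TRUE)[[1]]
      val <- suppressWarnings(as.numeric(parts[2]))
      meta[[parts[1]]] <- if (is.na(val)) NULL else val
    }
  }
  df <- read.table(path, sep = "\t", comment.char = "#",
                   col.names = c("u", "v", "dir"),
                   colClasses = c("integer", "integer", "character"))
  N <- if (!is.null(meta$N)) as.integer(meta$N) else max(df$u, df$v) + 1L
  hf_network(N, cbind(df$u + 1L, df$v + 1L),
             dir = ifelse(df$dir == "uv", 1L, -1L),
             meta = meta[setdiff(names(meta), "N")])
}
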