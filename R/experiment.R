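#' Geometric grid of rewiring probabilities
#'
#' `p_n = p0 * factor^n` for `n = 0 .. n_points - 1`, clipped to at most
#' 1. The default reproduces a 7-point grid from 0.001 to ~0.985 that is
#' equally spaced on the logarithmic scale.
#'
#' @param p0 first grid value (> 0).
#' @param n_points number of grid points.
#' @param factor geometric ratio (> 1).
#' @return Strictly increasing numeric vector of probabilities.
#' @export
default_p_grid <- function(p0 = 0.001, n_points = 7, factor = 0.985261^(1 / 6) / 0.001^(1 / 6)) {
  stopifnot(p0 > 0, factor > 1, n_points >= 1)
  pmin(p0 * factor^(seq_len(n_points) - 1), 1)
}

#' Sweep configuration
#'
#' Bundles every parameter of the rewiring-probability sweep: network
#' parameters, the p grid, ensemble sizes, trajectory lengths and the
#' root seed from which all child streams are derived.
#'
#' @param N,k Watts-Strogatz parameters.
#' @param p_grid vector of rewiring probabilities.
#' @param n_networks networks per grid point.
#' @param n_realizations threshold-network realizations per network for
#'   the flow estimate.
#' @param transient,length discarded / recorded steps per realization.
#' @param n_ref reference networks for the small-world index.
#' @param root_seed integer root seed.
#' @return A list of class `"hf_sweep_config"`.
#' @export
sweep_config <- function(N = 400, k = 3, p_grid = default_p_grid(),
                         n_networks = 10, n_realizations = 10,
                         transient = 100, length = 1000,
                         n_ref = 20, root_seed = 1) {
  stopifnot(n_networks >= 1, n_realizations >= 1, transient >= 1,
            length >= 1, n_ref >= 1, all(p_grid >= 0 & p_grid <= 1))
  structure(list(N = N, k = k, p_grid = p_grid, n_networks = n_networks,
                 n_realizations = n_realizations, transient = transient,
                 length = length, n_ref = n_ref,
                 root_seed = as.integer(root_seed)),
            class = "hf_sweep_config")
}

#' Run the rewiring-probability sweep
#'
#' For every p in the grid and every network index: generate a directed
#' WS network, estimate its information flow, Hodge-decompose it, and
#' compute the structural ratios and the small-world index. Results are
#' aggregated per p as mean and standard deviation over networks; the
#' closed-form structural-ratio predictions are appended. The whole sweep
#' is a deterministic function of the configuration: child seeds are
#' derived from `(root_seed, p index, network index)`, and the
#' small-world references (L_r, C_c) are computed once per (N, k) and
#' shared across networks.
#'
#' @param cfg an `hf_sweep_config`.
#' @param verbose log per-p progress to stderr.
#' @return A data.frame of class `"hf_sweep_result"`, one row per p, with
#'   mean/sd columns for `norm_per_node` (||e||^2/N), `gamma`, `eta`,
#'   `chi`, `lambda`, `Gamma`, `H`, `X`, `Lambda`, `omega`, and columns
#'   `Gamma_pred`, `X_pred`, `H_pred`. The configuration is attached as
#'   attribute `"config"`.
#' @export
run_sweep <- function(cfg, verbose = TRUE) {
  stopifnot(inherits(cfg, "hf_sweep_config"))
  L_r <- reference_path_length(cfg$N, cfg$k, n_ref = cfg$n_ref,
                               seed = child_seed(cfg$root_seed, 0, 0, 1))
  C_c <- clustering_coeff(ws_lattice(cfg$N, cfg$k))
  metrics <- c("norm_per_node", "gamma", "eta", "chi", "lambda",
               "Gamma", "H", "X", "Lambda", "omega")
  rows <- vector("list", length(cfg$p_grid))
  for (pi in seq_along(cfg$p_grid)) {
    p <- cfg$p_grid[pi]
    if (verbose)
      message(sprintf("p = %g (%d/%d): %d networks ...", p, pi,
                      length(cfg$p_grid), cfg$n_networks))
    per_net <- matrix(NA_real_, cfg$n_networks, length(metrics),
                      dimnames = list(NULL, metrics))
    failed <- 0L
    for (ni in seq_len(cfg$n_networks)) {
      res <- tryCatch(
        sweep_one_network(cfg, p, pi, ni, L_r, C_c),
        error = function(e) {
          message(sprintf("  network %d at p = %g failed: %s", ni, p,
                          conditionMessage(e)))
          NULL
        })
      if (is.null(res)) failed <- failed + 1L
      else per_net[ni, ] <- res
    }
    if (failed > 0.01 * cfg$n_networks)
      stop(sprintf("%d of %d networks failed at p = %g", failed,
                   cfg$n_networks, p))
    row <- data.frame(p = p)
    for (m in metrics) {
      row[[paste0(m, "_mean")]] <- mean(per_net[, m], na.rm = TRUE)
      row[[paste0(m, "_sd")]] <- sd(per_net[, m], na.rm = TRUE)
    }
    pred <- predicted_structural_ratios(cfg$N, cfg$k, p)
    row$Gamma_pred <- pred$Gamma
    row$X_pred <- pred$X
    row$H_pred <- pred$H
    rows[[pi]] <- row
  }
  out <- do.call(rbind, rows)
  attr(out, "config") <- cfg
  class(out) <- c("hf_sweep_result", "data.frame")
  out
}

sweep_one_network <- function(cfg, p, pi, ni, L_r, C_c) {
  net <- ws_network(cfg$N, cfg$k, p, seed = child_seed(cfg$root_seed, pi, ni, 2))
  flow <- estimate_flow(net, n_realizations = cfg$n_realizations,
                        transient = cfg$transient, length = cfg$length,
                        seed = child_seed(cfg$root_seed, pi, ni, 3))
  comp <- hodge_decompose(flow, net)
  sr <- structural_ratios(net)
  sw <- suppressWarnings(small_world_index(net, k = cfg$k,
                                           L_r = L_r, C_c = C_c))
  c(norm_per_node = comp$norm_e / cfg$N,
    gamma = comp$gamma, eta = comp$eta, chi = comp$chi,
    lambda = comp$lambda,
    Gamma = sr$Gamma, H = sr$H, X = sr$X, Lambda = sr$Lambda,
    omega = sw$omega)
}

#' Write sweep results to CSV
#'
#' One row per p; the full configuration is echoed as `# key=value`
#' header comments for provenance.
#'
#' @param res an `hf_sweep_result`.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_sweep_csv <- function(res, path) {
  stopifnot(nrow(res) > 0)
  cfg <- attr(res, "config")
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(cfg))
    writeLines(sprintf("# %s=%s", nm,
                       paste(format(cfg[[nm]], digits = 15), collapse = ",")),
               con)
  write.csv(format(as.data.frame(res), digits = 15), con, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Read sweep results from CSV
#'
#' @param path file written by [write_sweep_csv()].
#' @return An `hf_sweep_result` with the configuration restored.
#' @export
read_sweep_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines, value = TRUE)
  cfg <- list()
  for (line in hdr) {
    kv <- strsplit(sub("^# ", "", line), "=", fixed = TRUE)[[1]]
    vals <- as.numeric(strsplit(kv[2], ",", fixed = TRUE)[[1]])
    cfg[[kv[1]]] <- vals
  }
  df <- read.csv(textConnection(lines[!startsWith(lines, "#")]))
  if (length(cfg) > 0) {
    cfg$root_seed <- as.integer(cfg$root_seed)
    attr(df, "config") <- do.call(sweep_config, cfg)
  }
  class(df) <- c("hf_sweep_result", "data.frame")
  df
}

#' @importFrom utils write.csv read.csv modifyList
NULL
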