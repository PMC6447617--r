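## Reproducible in-silico experiment drivers.  Every run can write its
## tabular outputs plus a JSON manifest (resolved configuration, seed,
## package version) sufficient to re-run identically.

.write_manifest <- function(out_dir, experiment, config) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(experiment = experiment, config = config,
                   package = "coopnet",
                   version = as.character(utils::packageVersion("coopnet")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

.write_tsv <- function(df, out_dir, name) {
  if (is.null(out_dir)) return(invisible(NULL))
  utils::write.table(df, file.path(out_dir, name), sep = "\t",
                     row.names = FALSE, quote = FALSE)
}

#' Coexistence and cascade motifs
#'
#' Runs the two built-in network motifs (or a user edge list): the directed
#' cooperation cycle, where every species has one mutualistic partner and
#' all coexist at the uniform state, and the chain with a terminal
#' self-link, where the unsupported head species triggers an extinction
#' cascade leaving a single survivor.  Survivor sets are computed both by
#' topological pruning and by mean-field integration and cross-checked.
#'
#' @param fixture \code{"cycle"} or \code{"cascade"}, ignored when
#'   \code{edgelist} is given.
#' @param S number of species for the built-in fixtures.
#' @param eps1 cooperation intensity.
#' @param edgelist optional path to an edge-list file (see
#'   \code{\link{read_edgelist}}); its \code{M} matrix is used.
#' @param edgelist_S species count for the edge list.
#' @param times trajectory recording grid.
#' @param out_dir optional output directory (trajectory TSV, summary JSON,
#'   manifest).
#' @param seed RNG seed recorded in the manifest (the computation itself is
#'   deterministic).
#' @return list with \code{survivors_pruning}, \code{survivors_integration},
#'   \code{m}, \code{trajectory}, \code{agree}.
#' @export
run_motif <- function(fixture = c("cycle", "cascade"), S = 7, eps1 = 1,
                      edgelist = NULL, edgelist_S = NULL,
                      times = seq(0, 60, by = 0.5),
                      out_dir = NULL, seed = NULL) {
  fixture <- match.arg(fixture)
  if (!is.null(edgelist)) {
    M <- read_edgelist(edgelist, edgelist_S)$M
    fixture <- "edgelist"
  } else {
    M <- if (fixture == "cycle") cycle_matrix(S) else chain_selfloop_matrix(S)
  }
  com <- coop_community(M, eps1 = eps1, eps2 = 0, eps3 = 0)
  pr <- prune_unsupported(M)
  traj <- meanfield_trajectory(com, times = times)
  fit <- coop_equilibrium(com, method = "integrate")
  cl <- fit$classification
  res <- list(fixture = fixture,
              survivors_pruning = pr$survivors,
              survivors_integration = cl$survivors,
              removal_sequence = pr$removed,
              m = fit$m, trajectory = traj,
              agree = identical(sort(pr$survivors), sort(cl$survivors)))
  cfg <- list(fixture = fixture, S = nrow(M), eps1 = eps1, seed = seed)
  .write_manifest(out_dir, "motif", cfg)
  if (!is.null(out_dir)) {
    df <- data.frame(time = times, traj)
    names(df) <- c("time", paste0("sp", seq_len(nrow(M))))
    .write_tsv(df, out_dir, "trajectory.tsv")
    jsonlite::write_json(res[c("fixture", "survivors_pruning",
                               "survivors_integration", "m", "agree")],
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}

#' Extinction scan over harmful-interaction connectivity
#'
#' Cooperation-plus-harm ensemble: for every grid value of the harmful
#' connectivity \code{c_H} the cooperative connectivity is complementary
#' (\code{c_M = 1 - c_H}), strengths are magnitudes of
#' \code{N(mu, mu/3)} draws (negated for \code{H}), and each cell is
#' replicated.  Every realization is integrated to its stationary state;
#' extinctions (abundance below \code{1/S^2}), feasibility (no extinctions)
#' and linear stability of the surviving sub-community are recorded.  Cells
#' where no realization yields a stable solution are flagged.
#'
#' @param c_H_grid harmful-connectivity grid.
#' @param mu_values mean interaction magnitudes (\code{mu_M = -mu_H}).
#' @param S number of species.
#' @param replicates realizations per (mu, c_H) cell.
#' @param eps1,eps3 cooperation and harm intensities.
#' @param seed RNG seed.
#' @param t_max,stat_tol integration controls.
#' @param out_dir optional output directory.
#' @return object of class \code{"harm_scan"}: \code{results} (one row per
#'   realization), \code{summary} (per-cell mean extinction fraction over
#'   stable realizations, flags), and
#'   \code{max_feasible_stable_cH}, the largest grid value with at least one
#'   feasible and stable realization.
#' @export
run_harm_scan <- function(c_H_grid = seq(0, 1, by = 0.1),
                          mu_values = c(0.05, 0.1, 0.3, 1),
                          S = 50, replicates = 10,
                          eps1 = 1, eps3 = 1, seed = NULL,
                          t_max = 600, stat_tol = 1e-8,
                          out_dir = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (mu in mu_values) {
    for (ch in c_H_grid) {
      for (r in seq_len(replicates)) {
        spec <- ensemble_spec(S, c_M = 1 - ch, c_H = ch,
                              family = "abs-normal", mu = mu, sigma = mu / 3)
        com <- sample_community(spec, eps1 = eps1, eps2 = 0, eps3 = eps3)
        fit <- coop_equilibrium(com, method = "integrate",
                                t_max = t_max, stat_tol = stat_tol)
        cl <- fit$classification
        m0 <- fit$m
        m0[cl$extinct] <- 0            # below-threshold species count as extinct
        stable <- if (sum(m0 > 0) == 0) FALSE else {
          jac <- community_jacobian(com, m0, check = FALSE)
          is_stable(jac)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          mu = mu, c_H = ch, replicate = r,
          fraction_extinct = cl$fraction_extinct,
          feasible = cl$feasible, stable = stable,
          converged = fit$converged)
      }
    }
  }
  results <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(results, list(results$mu, results$c_H)),
    function(d) {
      st <- d$stable
      data.frame(mu = d$mu[1], c_H = d$c_H[1],
                 n_stable = sum(st),
                 mean_fraction_extinct = if (any(st))
                   mean(d$fraction_extinct[st]) else NA_real_,
                 any_feasible_stable = any(d$feasible & st))
    }))
  agg <- agg[order(agg$mu, agg$c_H), ]
  rownames(agg) <- NULL
  fs <- results$feasible & results$stable
  max_ch <- if (any(fs)) max(results$c_H[fs]) else NA_real_
  cfg <- list(c_H_grid = c_H_grid, mu_values = mu_values, S = S,
              replicates = replicates, eps1 = eps1, eps3 = eps3, seed = seed)
  .write_manifest(out_dir, "harm_scan", cfg)
  .write_tsv(results, out_dir, "realizations.tsv")
  .write_tsv(agg, out_dir, "summary.tsv")
  structure(list(results = results, summary = agg,
                 max_feasible_stable_cH = max_ch),
            class = "harm_scan")
}

#' @export
print.harm_scan <- function(x, ...) {
  cat(sprintf("Harm-connectivity scan: %d realizations; largest c_H with a feasible stable solution: %g\n",
              nrow(x$results), x$max_feasible_stable_cH))
  invisible(x)
}

#' Jacobian eigenvalue clouds and ellipse overlays
#'
#' Panel \code{"A"}: purely exploitative interactions (\code{c_L = 1},
#' \code{eps2 = 1}, \code{eps1 = 0}); the Jacobian is evaluated at the
#' uniform reference state and, following the classical complexity-stability
#' argument, its spectrum straddles the instability threshold for large
#' \code{S}.  Panel \code{"B"}: mixed exploitative and cooperative
#' interactions (\code{c_L = c_M = 0.5}, \code{eps1 = 0.75},
#' \code{eps2 = 1}); the equilibrium is obtained by integration and the
#' cooperation-centered ellipse prediction is overlaid.  Entry magnitudes
#' are uniform on (0, 1).
#'
#' @param panel \code{"A"} or \code{"B"}.
#' @param S number of species.
#' @param seed RNG seed.
#' @param out_dir optional output directory (eigenvalue CSV + JSON summary).
#' @return list with \code{spectrum} (a \code{spectrum_summary}),
#'   \code{stable}, \code{stats} (cooperation-matrix statistics, panel B),
#'   \code{panel}.
#' @export
run_spectrum <- function(panel = c("A", "B"), S = 400, seed = NULL,
                         out_dir = NULL) {
  panel <- match.arg(panel)
  if (!is.null(seed)) set.seed(seed)
  mu <- 0.5; sigma <- 1 / sqrt(12)   # U(0, 1) magnitudes
  if (panel == "A") {
    spec <- ensemble_spec(S, c_L = 1, family = "uniform", mu = mu, sigma = sigma)
    L <- sample_exploitation(spec)
    com <- coop_community(matrix(0, S, S), L, eps1 = 0, eps2 = 1, eps3 = 0)
    m <- rep(1 / S, S)
    jac <- community_jacobian(com, m, check = FALSE)
    sp <- jacobian_spectrum(jac, stats = effective_stats(jac$J), eps1 = 1)
    stats <- NULL
  } else {
    spec <- ensemble_spec(S, c_M = 0.5, c_L = 0.5, family = "uniform",
                          mu = mu, sigma = sigma)
    com <- sample_community(spec, eps1 = 0.75, eps2 = 1, eps3 = 0)
    fit <- coop_equilibrium(com, method = "integrate", stat_tol = 1e-8,
                            t_max = 300)
    jac <- community_jacobian(com, fit$m, check = FALSE)
    stats <- effective_stats(com$M)
    sp <- jacobian_spectrum(jac, stats = stats, eps1 = com$eps1)
  }
  res <- list(panel = panel, spectrum = sp,
              stable = sp$max_re_tangent < -1e-10, stats = stats)
  cfg <- list(panel = panel, S = S, seed = seed)
  .write_manifest(out_dir, "spectrum", cfg)
  if (!is.null(out_dir)) {
    ev <- sp$eigenvalues_tangent
    utils::write.table(data.frame(re = Re(ev), im = Im(ev)),
                       file.path(out_dir, "eigenvalues.csv"), sep = ",",
                       row.names = FALSE)
    jsonlite::write_json(list(panel = panel, center = sp$center,
                              semi_re = sp$semi_re, semi_im = sp$semi_im,
                              predicted_max = sp$predicted_max,
                              max_re_tangent = sp$max_re_tangent,
                              stable = res$stable),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}

#' RSA experiment driver
#'
#' Thin wrapper around \code{\link{rsa_experiment}} that writes the averaged
#' curves (TSV), the distance summary (JSON) and a manifest.
#'
#' @param out_dir optional output directory.
#' @param ... passed to \code{\link{rsa_experiment}}.
#' @return the \code{\link{rsa_experiment}} result.
#' @export
run_rsa <- function(out_dir = NULL, ...) {
  args <- list(...)
  ex <- rsa_experiment(...)
  .write_manifest(out_dir, "rsa", args)
  if (!is.null(out_dir)) {
    df <- data.frame(n = ex$grid, t(ex$curves))
    names(df) <- c("n", paste0(ex$cells$family, "_cv", ex$cells$cv))
    .write_tsv(df, out_dir, "curves.tsv")
    jsonlite::write_json(list(median_within_cv = ex$median_within_cv,
                              median_across_cv = ex$median_across_cv,
                              within_cv = ex$within_cv,
                              across_cv = ex$across_cv,
                              skipped = ex$skipped),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  ex
}

#' Dispatch an experiment by name from a configuration list
#'
#' Entry point used by the \code{coopnet} command-line script: merges the
#' configuration (e.g. parsed from YAML) with each driver's defaults and
#' runs it.
#'
#' @param experiment one of \code{"motif"}, \code{"harm_scan"},
#'   \code{"spectrum"}, \code{"rsa"}.
#' @param config named list of driver arguments.
#' @param out_dir output directory.
#' @param seed RNG seed (overrides any seed in \code{config}).
#' @return the driver's result.
#' @export
run_experiment <- function(experiment, config = list(), out_dir = NULL,
                           seed = NULL) {
  experiment <- match.arg(experiment, c("motif", "harm_scan", "spectrum", "rsa"))
  if (!is.null(seed)) config$seed <- seed
  config$out_dir <- out_dir
  fn <- switch(experiment, motif = run_motif, harm_scan = run_harm_scan,
               spectrum = run_spectrum, rsa = run_rsa)
  do.call(fn, config)
}
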