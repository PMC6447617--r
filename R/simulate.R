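## Exact finite-N stochastic simulation of the replacement process.

#' Replacement rates of the finite-community process
#'
#' Per-species insertion rates
#' \deqn{\omega_j = \bar\eta^j + \epsilon_1 \sum_k \bar\eta^k M_{kj}\,
#'   \theta(\bar\eta^j) + \epsilon_2 \sum_k \bar\eta^k L_{kj}\,\bar\eta^j
#'   + \epsilon_3 \sum_k \bar\eta^k H_{kj}\,\theta(\bar\eta^j),}
#' with \eqn{\theta(x) = 1} for \eqn{x > 0} and 0 otherwise: an extinct
#' species has rate exactly zero.  Harmful interactions can push a rate
#' negative, which invalidates the process (and the mean-field limit); this
#' raises a condition of class \code{"coopnet_negative_rate"} rather than
#' silently clipping.
#'
#' @param eta relative abundance vector (fractions; counts are accepted and
#'   normalized).
#' @param com a \code{\link{coop_community}}.
#' @return rate vector \code{omega} of length \code{S}.
#' @export
replacement_rates <- function(eta, com) {
  stopifnot(inherits(com, "coop_community"))
  if (length(eta) != com$S) stop("state dimension does not match community")
  if (any(eta < 0)) stop("abundances must be nonnegative")
  eta <- eta / sum(eta)
  th <- as.numeric(eta > 0)
  w <- eta +
    com$eps1 * as.vector(crossprod(com$M, eta)) * th +
    com$eps2 * as.vector(crossprod(com$L, eta)) * eta +
    com$eps3 * as.vector(crossprod(com$H, eta)) * th
  bad <- which(w < -1e-12)
  if (length(bad)) {
    j <- bad[1]
    stop(structure(class = c("coopnet_negative_rate", "error", "condition"),
                   list(message = sprintf(
                     "negative replacement rate for species %d (omega = %g)",
                     j, w[j]), call = sys.call(-1),
                     species = j, omega = w[j])))
  }
  pmax(w, 0)
}

#' One Gillespie event (reference R implementation)
#'
#' Draws the waiting time (exponential with total rate \code{N * sum(omega)}),
#' the inserted species (probability proportional to \code{omega}) and the
#' dying individual (uniform over the \code{N} individuals), and returns the
#' updated counts.  The compiled engine used by
#' \code{\link{simulate_community}} implements the same process; this
#' function exists for transparency and for distributional tests.
#'
#' @param counts integer species counts.
#' @param com a \code{\link{coop_community}}.
#' @return list with \code{dt}, \code{born}, \code{die}, \code{counts}; or
#'   \code{NULL} when the state is absorbing (at most one species alive).
#' @export
gillespie_step <- function(counts, com) {
  N <- sum(counts)
  if (sum(counts > 0) <= 1) return(NULL)
  w <- replacement_rates(counts / N, com)
  tot <- sum(w)
  if (tot <= 0) return(NULL)
  dt <- rexp(1, rate = N * tot)
  born <- sample.int(com$S, 1, prob = w)
  die <- sample.int(com$S, 1, prob = counts)
  counts[die] <- counts[die] - 1L
  counts[born] <- counts[born] + 1L
  list(dt = dt, born = born, die = die, counts = counts)
}

#' Simulate the community replacement process
#'
#' Exact continuous-time simulation (compiled event loop) recording species
#' counts on a fixed time grid; the hard carrying capacity
#' \code{sum(counts) = N} holds after every event and extinction is
#' absorbing.  Reproducible through R's RNG (\code{set.seed}).
#'
#' @param com a \code{\link{coop_community}}.
#' @param n0 integer initial counts (length \code{S}).
#' @param times increasing recording grid; the state reported at time
#'   \code{tau} is the state after all events up to \code{tau}.
#' @param t_max convenience: when \code{times} is NULL, a 101-point grid on
#'   \code{[0, t_max]} is used.
#' @return object of class \code{"coop_sim"}: list with \code{times},
#'   \code{counts} (matrix \code{length(times) x S}), \code{N},
#'   \code{absorbed}, \code{events}, \code{community}.
#' @examples
#' com <- coop_community(cycle_matrix(5), eps1 = 1, eps2 = 0, eps3 = 0)
#' set.seed(1)
#' sim <- simulate_community(com, rep(20L, 5), t_max = 2)
#' @export
simulate_community <- function(com, n0, times = NULL, t_max = 10) {
  stopifnot(inherits(com, "coop_community"))
  if (length(n0) != com$S) stop("n0 has wrong length")
  n0 <- as.integer(n0)
  if (any(n0 < 0) || sum(n0) <= 0) stop("n0 must be nonnegative with positive total")
  if (is.null(times)) times <- seq(0, t_max, length.out = 101)
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  res <- gillespie_run_cpp(n0, com$M, com$L, com$H,
                           com$eps1, com$eps2, com$eps3, as.numeric(times))
  structure(list(times = times, counts = res$counts, N = sum(n0),
                 absorbed = res$absorbed, events = res$events,
                 community = com),
            class = "coop_sim")
}

#' @export
print.coop_sim <- function(x, ...) {
  cat(sprintf("Stochastic trajectory: N = %d, S = %d, %d snapshots, %.0f events%s\n",
              x$N, ncol(x$counts), nrow(x$counts), x$events,
              if (x$absorbed) " (absorbed)" else ""))
  invisible(x)
}

#' @export
plot.coop_sim <- function(x, ...) {
  graphics::matplot(x$times, x$counts / x$N, type = "l", lty = 1,
                    xlab = "time", ylab = "relative abundance", ...)
  invisible(x)
}

#' Export a trajectory as TSV with a JSON metadata sidecar
#'
#' @param sim a \code{\link{simulate_community}} result.
#' @param path TSV output path (columns: time, sp1..spS counts); metadata
#'   (N, S, intensities, events) is written to \code{paste0(path, ".json")}.
#' @return \code{path}, invisibly.
#' @export
write_trajectory <- function(sim, path) {
  stopifnot(inherits(sim, "coop_sim"))
  df <- data.frame(time = sim$times, sim$counts)
  names(df) <- c("time", paste0("sp", seq_len(ncol(sim$counts))))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(N = sim$N, S = ncol(sim$counts),
               eps1 = sim$community$eps1, eps2 = sim$community$eps2,
               eps3 = sim$community$eps3, events = sim$events,
               absorbed = sim$absorbed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Scaled fluctuation trajectory around a reference equilibrium
#'
#' Transforms recorded counts into
#' \eqn{x^i(t) = \sqrt{N} (\bar\eta^i(t) - m_i)}; when \code{m} lies on the
#' simplex the components of \code{x} sum to zero at every time.
#'
#' @param sim a \code{\link{simulate_community}} result.
#' @param m reference equilibrium on the simplex.
#' @return matrix \code{length(times) x S} of fluctuation components.
#' @export
fluctuations <- function(sim, m) {
  stopifnot(inherits(sim, "coop_sim"))
  if (length(m) != ncol(sim$counts)) stop("m has wrong length")
  sqrt(sim$N) * (sim$counts / sim$N - matrix(m, nrow(sim$counts),
                                             length(m), byrow = TRUE))
}
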