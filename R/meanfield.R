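## Deterministic mean-field limit of the replacement process.
##
## d/dt eta_s = g_s(eta) - eta_s * sum_i g_i(eta),   with gain
## g_s = eps1 * (M^T eta)_s theta(eta_s) + eps2 * (L^T eta)_s eta_s
##     + eps3 * (H^T eta)_s theta(eta_s),
## theta(x) = 1 for x > 0 and 0 otherwise (an extinct species receives no
## linear boost and stays extinct).  The total abundance sum_s eta_s = 1 is
## conserved exactly: the derivative components sum to zero.

#' Mean-field right-hand side
#'
#' @param eta abundance vector on the simplex (entries >= 0, summing to 1;
#'   sums differing from 1 are accepted, e.g. for finite-difference probes).
#' @param com a \code{\link{coop_community}}.
#' @return derivative vector of the same length; components sum to 0 when
#'   evaluated on the simplex.
#' @export
meanfield_rhs <- function(eta, com) {
  stopifnot(inherits(com, "coop_community"))
  if (length(eta) != com$S) stop("state dimension does not match community")
  e <- pmax(eta, 0)
  th <- as.numeric(eta > 0)
  gain <- numeric(com$S)
  if (com$eps1 > 0) gain <- gain + com$eps1 * as.vector(crossprod(com$M, e)) * th
  if (com$eps2 > 0) gain <- gain + com$eps2 * as.vector(crossprod(com$L, e)) * e
  if (com$eps3 > 0) gain <- gain + com$eps3 * as.vector(crossprod(com$H, e)) * th
  gain - e * sum(gain)
}

## Integrate the mean-field ODE over a fixed time grid, handling the theta
## switching surface by terminal root detection: whenever a positive species
## falls to `floor` the integration stops, the species is clamped to exactly
## zero (so theta switches off as in the exact model), the state is
## renormalized and the integrator restarts.  Between events the RHS
## restricted to the positive support is smooth.
.mf_grid <- function(com, y0, times, rtol = 1e-9, atol = 1e-12, floor = 1e-12) {
  S <- com$S
  out <- matrix(NA_real_, length(times), S)
  out[1, ] <- y0
  y <- y0
  t <- times[1]
  n_clamp <- 0L
  deriv <- function(t, y, parms) list(meanfield_rhs(y, com))
  guard <- 0L
  while (TRUE) {
    remaining <- which(times > t + 1e-12)
    if (!length(remaining)) break
    mask <- y > 0
    root <- function(t, y, parms) {
      if (!any(mask)) return(1)
      min(y[mask]) - floor
    }
    tt <- c(t, times[remaining])
    sol <- deSolve::lsoda(y, tt, deriv, parms = NULL, rtol = rtol, atol = atol,
                          rootfunc = root)
    got <- sol[, 1]
    ## store rows that hit requested grid times
    for (r in seq_along(got)) {
      hit <- remaining[abs(times[remaining] - got[r]) < 1e-9]
      if (length(hit)) out[hit[1], ] <- sol[r, -1]
    }
    tend <- got[length(got)]
    y <- sol[nrow(sol), -1]
    rooted <- !is.null(attr(sol, "troot")) && length(attr(sol, "troot")) > 0
    if (rooted || any(y < floor & y != 0)) {
      n_clamp <- n_clamp + sum(y < floor & y != 0)
      y[y < floor] <- 0
      y <- y / sum(y)
    }
    t <- tend
    guard <- guard + 1L
    if (guard > 20L * S + 50L) stop("mean-field integration failed to advance")
    if (!rooted && t >= times[length(times)] - 1e-12) break
  }
  ## fill any grid point that coincided with a root time
  for (k in seq_along(times)) if (anyNA(out[k, ])) out[k, ] <- if (k > 1) out[k - 1, ] else y0
  attr(out, "n_clamped") <- n_clamp
  out
}

#' Mean-field trajectory on a time grid
#'
#' Adaptive stiff-capable integration (deSolve's \code{lsoda}) of the
#' mean-field equations, with species clamped to exactly zero when they fall
#' below a numerical extinction floor (default \code{1e-12}); integration
#' restarts at every clamping event so the switching surface of the step
#' function never sits inside an integrator step.
#'
#' @param com a \code{\link{coop_community}}.
#' @param init strictly positive initial abundance vector (normalized
#'   internally); defaults to uniform.
#' @param times increasing time grid starting at the initial time.
#' @param rtol,atol integrator tolerances.
#' @param floor numerical extinction floor.
#' @return matrix \code{length(times) x S} of abundances, with attribute
#'   \code{"n_clamped"} counting clamping events.
#' @export
meanfield_trajectory <- function(com, init = NULL, times = seq(0, 10, by = 0.1),
                                 rtol = 1e-9, atol = 1e-12, floor = 1e-12) {
  stopifnot(inherits(com, "coop_community"))
  if (is.null(init)) init <- rep(1 / com$S, com$S)
  if (length(init) != com$S) stop("init has wrong length")
  if (any(init < 0)) stop("init must be nonnegative")
  init <- init / sum(init)
  .mf_grid(com, init, times, rtol = rtol, atol = atol, floor = floor)
}

#' Perron-Frobenius stationary state of the purely cooperative model
#'
#' For an irreducible nonnegative cooperation matrix the mean-field dynamics
#' with \code{eps2 = eps3 = 0} converges, from any strictly positive initial
#' condition, to \code{m = v / sum(v)} where \code{v} is the left eigenvector
#' of \code{M} for its Perron-Frobenius eigenvalue \code{alpha} (the
#' non-degenerate real positive eigenvalue of largest modulus).  The
#' stationary state does not depend on the cooperation intensity
#' \code{eps1 > 0}, which only sets the time scale.
#'
#' @param M irreducible nonnegative square matrix.
#' @param eps1 cooperation intensity (recorded; must be > 0).
#' @return object of class \code{"pf_solution"}: list with \code{m},
#'   \code{alpha}, left eigenvector \code{v} (normalized to sum 1), right
#'   eigenvector \code{w} (scaled so \code{sum(v * w) = 1}; it describes how
#'   press perturbations spread), and \code{residual}, the sup-norm of the
#'   mean-field RHS at \code{m}.
#' @export
pf_stationary <- function(M, eps1 = 1) {
  .check_square(M, "M")
  if (eps1 <= 0) stop("eps1 must be > 0")
  if (!is_irreducible(M))
    stop("IrreducibilityError: M is reducible; prune_unsupported() first and ",
         "work with the surviving sub-community")
  S <- nrow(M)
  eL <- eigen(t(M))
  i <- which.max(Re(eL$values))
  alpha <- eL$values[i]
  if (abs(Im(alpha)) > 1e-8 * (1 + abs(Re(alpha))) || Re(alpha) <= 0)
    stop("leading eigenvalue is not real positive; M is not a valid ",
         "irreducible cooperation matrix")
  alpha <- Re(alpha)
  v <- Re(eL$vectors[, i])
  v <- v * sign(sum(v))
  if (min(v) < -1e-8 * max(v))
    stop("left Perron-Frobenius eigenvector has negative components")
  v <- pmax(v, 0); v <- v / sum(v)
  eR <- eigen(M)
  j <- which.max(Re(eR$values))
  w <- Re(eR$vectors[, j])
  w <- w * sign(sum(w))
  w <- w / sum(v * w)
  com <- coop_community(M, eps1 = eps1, eps2 = 0, eps3 = 0, validate = FALSE)
  structure(list(m = v, alpha = alpha, v = v, w = w, eps1 = eps1,
                 residual = max(abs(meanfield_rhs(v, com)))),
            class = "pf_solution")
}

#' @export
print.pf_solution <- function(x, ...) {
  cat(sprintf("Perron-Frobenius stationary state: S = %d, alpha = %.6g, residual = %.3g\n",
              length(x$m), x$alpha, x$residual))
  invisible(x)
}

#' Closed-form time solution of the purely cooperative mean field
#'
#' For \code{eps2 = eps3 = 0} and a strictly positive state, the mean-field
#' flow is the normalized linear flow
#' \deqn{\bar\eta(t) = \frac{\bar\eta(0)^T e^{\epsilon_1 M t}}
#'   {\sum_s (\bar\eta(0)^T e^{\epsilon_1 M t})_s},}
#' which solves the nonlinear equations exactly as long as every component
#' stays positive (differentiating the normalized flow reproduces the gain
#' and loss terms identically); for irreducible \code{M} it converges to the
#' Perron-Frobenius state.  The exponent is shifted by a scalar before
#' exponentiation (the normalization cancels it) to avoid overflow at
#' large \code{t}.
#'
#' @param M nonnegative square matrix.
#' @param eps1 cooperation intensity.
#' @param init strictly positive initial abundances.
#' @param t time (scalar).
#' @return abundance vector on the simplex.
#' @export
time_solution_pure_cooperation <- function(M, eps1, init, t) {
  .check_square(M, "M")
  if (any(init <= 0)) stop("init must be strictly positive")
  init <- init / sum(init)
  if (t == 0) return(init)
  shift <- eps1 * max(rowSums(M))
  E <- as.matrix(Matrix::expm(eps1 * t * t(M) - shift * t * diag(nrow(M))))
  y <- as.vector(E %*% init)
  y / sum(y)
}

#' Classify a stationary solution
#'
#' A species is extinct when its stationary abundance falls strictly below
#' the extinction threshold \code{1/S^2} (the uniform coexistence abundance
#' is \code{1/S}, so the threshold is a factor \code{S} below it); abundances
#' exactly at the threshold count as survival.  A solution is feasible when
#' no species is extinct.
#'
#' @param m abundance vector (or a \code{coop_fit} / \code{pf_solution}).
#' @param threshold extinction threshold; default \code{1/S^2}.
#' @return list with \code{feasible}, \code{extinct} (indices),
#'   \code{survivors}, \code{fraction_extinct}, \code{threshold}.
#' @export
classify_equilibrium <- function(m, threshold = NULL) {
  if (inherits(m, "coop_fit") || inherits(m, "pf_solution")) m <- m$m
  S <- length(m)
  if (is.null(threshold)) threshold <- 1 / S^2
  extinct <- which(m < threshold)
  list(feasible = length(extinct) == 0L,
       extinct = extinct,
       survivors = setdiff(seq_len(S), extinct),
       fraction_extinct = length(extinct) / S,
       threshold = threshold)
}
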