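#' Fit the stationary state of a community
#'
#' The central estimator of the package: given a community of interacting
#' species it computes the stationary state of the mean-field dynamics,
#' either analytically through the Perron-Frobenius left eigenvector (purely
#' cooperative, irreducible \code{M}) or by adaptive ODE integration to a
#' sustained-residual stationarity criterion.  The result is a classed model
#' object supporting \code{print}, \code{summary}, \code{coef},
#' \code{residuals}, \code{predict}, \code{simulate} and \code{plot}.
#'
#' @param com a \code{\link{coop_community}}.
#' @param init strictly positive initial abundances (default uniform); only
#'   used by the integration method.
#' @param method \code{"auto"} picks the analytic Perron-Frobenius route when
#'   exploitation and harm are absent and \code{M} is irreducible, otherwise
#'   integrates; \code{"pf"} and \code{"integrate"} force a route.
#' @param t_max maximum integration time before giving up (the best state is
#'   then returned flagged non-stationary).
#' @param stat_tol stationarity is declared when the sup-norm of the RHS
#'   stays below this at two consecutive checkpoints.
#' @param rtol,atol integrator tolerances.
#' @param floor numerical extinction floor: abundances below it are clamped
#'   to exactly zero so the step-function gate switches off as in the exact
#'   model.
#' @param keep_trajectory record the integration checkpoints.
#' @return an object of class \code{"coop_fit"} with elements \code{m}
#'   (stationary abundances), \code{method}, \code{converged},
#'   \code{residual}, \code{classification} (see
#'   \code{\link{classify_equilibrium}}), \code{community}, and for the
#'   analytic route \code{alpha}, \code{v}, \code{w}.
#' @examples
#' M <- cycle_matrix(7)
#' fit <- coop_equilibrium(coop_community(M, eps1 = 1, eps2 = 0, eps3 = 0))
#' coef(fit)          # 1/7 each
#' @export
coop_equilibrium <- function(com, init = NULL,
                             method = c("auto", "pf", "integrate"),
                             t_max = 2000, stat_tol = 1e-10,
                             rtol = 1e-9, atol = 1e-12, floor = 1e-12,
                             keep_trajectory = FALSE) {
  stopifnot(inherits(com, "coop_community"))
  method <- match.arg(method)
  pure_coop <- (com$eps2 == 0 || all(com$L == 0)) &&
               (com$eps3 == 0 || all(com$H == 0))
  if (method == "auto")
    method <- if (pure_coop && com$eps1 > 0 && is_irreducible(com$M)) "pf" else "integrate"
  if (method == "pf") {
    if (!pure_coop)
      stop("analytic Perron-Frobenius route requires a purely cooperative community")
    pf <- pf_stationary(com$M, eps1 = com$eps1)
    fit <- list(m = pf$m, method = "pf", converged = TRUE,
                residual = pf$residual, t_final = Inf,
                alpha = pf$alpha, v = pf$v, w = pf$w,
                classification = classify_equilibrium(pf$m),
                community = com, trajectory = NULL)
    return(structure(fit, class = "coop_fit"))
  }
  S <- com$S
  if (is.null(init)) init <- rep(1 / S, S)
  if (any(init < 0) || sum(init) <= 0) stop("init must be nonnegative, not all zero")
  y <- init / sum(init)
  t <- 0; chunk <- 1
  ok_prev <- FALSE; converged <- FALSE
  checkpoints <- list(c(0, y))
  while (t < t_max) {
    tt <- c(t, min(t + chunk, t_max))
    seg <- .mf_grid(com, y, tt, rtol = rtol, atol = atol, floor = floor)
    y <- seg[nrow(seg), ]
    y[y < floor] <- 0
    y <- y / sum(y)
    t <- tt[2]
    if (keep_trajectory) checkpoints[[length(checkpoints) + 1L]] <- c(t, y)
    ok <- max(abs(meanfield_rhs(y, com))) < stat_tol
    if (ok && ok_prev) { converged <- TRUE; break }
    ok_prev <- ok
    chunk <- min(chunk * 2, 50)
  }
  traj <- NULL
  if (keep_trajectory) {
    traj <- do.call(rbind, checkpoints)
    colnames(traj) <- c("time", paste0("sp", seq_len(S)))
  }
  structure(list(m = y, method = "integrate", converged = converged,
                 residual = max(abs(meanfield_rhs(y, com))), t_final = t,
                 alpha = NULL, v = NULL, w = NULL,
                 classification = classify_equilibrium(y),
                 community = com, trajectory = traj),
            class = "coop_fit")
}

#' @export
print.coop_fit <- function(x, digits = 4, ...) {
  cl <- x$classification
  cat(sprintf("Stationary community state (%s method%s)\n", x$method,
              if (x$converged) "" else ", NOT converged"))
  cat(sprintf("  S = %d, survivors = %d, fraction extinct = %.3g, residual = %.3g\n",
              length(x$m), length(cl$survivors), cl$fraction_extinct, x$residual))
  if (!is.null(x$alpha)) cat(sprintf("  PF eigenvalue alpha = %.*g\n", digits, x$alpha))
  cat("  abundances: ")
  m <- signif(x$m, digits)
  if (length(m) <= 10) cat(paste(m, collapse = ", "), "\n")
  else cat(paste(m[1:10], collapse = ", "), "...\n")
  invisible(x)
}

#' @export
coef.coop_fit <- function(object, ...) {
  m <- object$m
  names(m) <- paste0("sp", seq_along(m))
  m
}

#' @export
residuals.coop_fit <- function(object, ...) {
  meanfield_rhs(object$m, object$community)
}

#' Mean-field trajectory from a fitted community
#'
#' Integrates the deterministic dynamics of the fitted community forward on
#' a time grid, by default starting from the fit's own initial interior
#' guess; supply \code{init} to predict relaxation from elsewhere.
#'
#' @param object a \code{\link{coop_equilibrium}} fit.
#' @param times time grid.
#' @param init initial abundances (default uniform).
#' @param ... passed to \code{\link{meanfield_trajectory}}.
#' @return matrix \code{length(times) x S}.
#' @export
predict.coop_fit <- function(object, times = seq(0, 10, by = 0.1),
                             init = NULL, ...) {
  meanfield_trajectory(object$community, init = init, times = times, ...)
}

#' Stochastic realizations around a fitted equilibrium
#'
#' Runs the exact finite-\code{N} replacement process starting from counts
#' obtained by largest-remainder rounding of \code{N * m}.
#'
#' @param object a \code{coop_fit}.
#' @param nsim number of replicate trajectories.
#' @param seed optional seed.
#' @param N community size (total individuals).
#' @param t_max simulated time span.
#' @param times recording grid (default 101 points on \code{[0, t_max]}).
#' @param ... unused.
#' @return list of \code{\link{simulate_community}} results.
#' @export
simulate.coop_fit <- function(object, nsim = 1, seed = NULL, N = 1000,
                              t_max = 10, times = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n0 <- round_counts(object$m, N)
  if (is.null(times)) times <- seq(0, t_max, length.out = 101)
  lapply(seq_len(nsim), function(k)
    simulate_community(object$community, n0, times = times))
}

#' @export
summary.coop_fit <- function(object, ...) {
  jac <- community_jacobian(object$community, object$m, check = FALSE)
  spec <- jacobian_spectrum(jac)
  out <- list(fit = object, jacobian = jac, spectrum = spec,
              stable = spec$max_re_tangent < -1e-10)
  class(out) <- "summary.coop_fit"
  out
}

#' @export
print.summary.coop_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  linear stability (tangent subspace): max Re = %.6g -> %s\n",
              x$spectrum$max_re_tangent,
              if (x$stable) "stable" else "unstable"))
  invisible(x)
}

#' @export
plot.coop_fit <- function(x, ...) {
  if (!is.null(x$trajectory)) {
    tr <- x$trajectory
    graphics::matplot(tr[, 1], tr[, -1], type = "l", lty = 1,
                      xlab = "time", ylab = "relative abundance", ...)
  } else {
    graphics::barplot(x$m, names.arg = seq_along(x$m),
                      xlab = "species", ylab = "stationary abundance", ...)
  }
  invisible(x)
}

#' Largest-remainder rounding of abundances to integer counts
#'
#' @param m abundance vector (normalized internally).
#' @param N total count.
#' @return integer vector summing exactly to \code{N}.
#' @export
round_counts <- function(m, N) {
  m <- m / sum(m)
  n <- floor(m * N)
  rem <- N - sum(n)
  if (rem > 0) {
    frac <- m * N - n
    idx <- order(frac, decreasing = TRUE)[seq_len(rem)]
    n[idx] <- n[idx] + 1
  }
  as.integer(n)
}

#' Built-in network fixtures
#'
#' \code{cycle_matrix(S)} is the directed single-cycle cooperation network
#' (each species has exactly one mutualistic partner,
#' \code{M[i, i+1] = 1}, \code{M[S, 1] = 1}): irreducible, so all species
#' coexist at the uniform state.  \code{chain_selfloop_matrix(S)} is the
#' directed chain \code{1 -> 2 -> ... -> S} with a terminal self-link
#' \code{M[S, S] = w}: species 1 is unsupported and the pruning cascade
#' removes everything except the self-supported terminal species.
#'
#' @param S number of species.
#' @param w self-link weight for the cascade fixture.
#' @return \code{S x S} cooperation matrix.
#' @export
cycle_matrix <- function(S) {
  M <- matrix(0, S, S)
  for (i in seq_len(S - 1)) M[i, i + 1] <- 1
  M[S, 1] <- 1
  M
}

#' @rdname cycle_matrix
#' @export
chain_selfloop_matrix <- function(S, w = 1) {
  M <- matrix(0, S, S)
  for (i in seq_len(S - 1)) M[i, i + 1] <- 1
  M[S, S] <- w
  M
}
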