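## Linear-noise (Ornstein-Uhlenbeck) approximation around an equilibrium.
##
## The scaled fluctuations x = sqrt(N) (eta - m) converge, as N grows, to
## the OU process dX = A X dt + Phi dB_t with A the mean-field Jacobian at m
## and diffusion D = Phi Phi^T obtained from the second jump moments of the
## replacement process: an event (die a, born b) occurs at rate
## N * omega_b * eta_a and displaces eta by (e_b - e_a)/N, so
##   D_ij = sum_{a,b} omega_b eta_a (d_ib - d_ia)(d_jb - d_ja)
##        = d_ij (omega_i + m_i sum_k omega_k) - (omega_i m_j + omega_j m_i).
## A is singular along the conserved all-ones direction, so the stationary
## Lyapunov equation A V + V A^T + D = 0 is solved on the (S-1)-dimensional
## sum-zero tangent subspace and mapped back.

#' Ornstein-Uhlenbeck model of abundance fluctuations
#'
#' Builds the drift matrix \code{A} (the mean-field Jacobian at the
#' equilibrium, shared with the stability module) and the diffusion matrix
#' \code{D} from the closed-form jump-moment sum evaluated at \code{m}.
#' Rows and columns of \code{D} sum to zero because every replacement
#' conserves the total abundance.
#'
#' @param com a \code{\link{coop_community}}.
#' @param m positive equilibrium abundances (sup-norm of the RHS checked
#'   against \code{tol}).
#' @param tol equilibrium residual tolerance.
#' @return object of class \code{"ou_model"}: list with \code{A}, \code{D},
#'   \code{m}, \code{omega}, \code{community}.
#' @export
build_ou <- function(com, m, tol = 1e-6) {
  stopifnot(inherits(com, "coop_community"))
  if (any(m <= 0)) stop("build_ou requires a strictly positive equilibrium")
  r <- max(abs(meanfield_rhs(m, com)))
  if (r > tol) stop("m is not an equilibrium (||rhs||_inf = ", signif(r, 3), ")")
  A <- community_jacobian(com, m, check = FALSE)$J
  w <- replacement_rates(m, com)
  D <- diag(w + m * sum(w)) - (outer(w, m) + outer(m, w))
  structure(list(A = A, D = D, m = m, omega = w, community = com),
            class = "ou_model")
}

#' @export
print.ou_model <- function(x, ...) {
  cat(sprintf("OU fluctuation model: S = %d, max Re(A) on tangent = %.4g\n",
              length(x$m), jacobian_spectrum(x$A)$max_re_tangent))
  invisible(x)
}

## Solve A V + V A^T + D = 0 by the Kronecker/vec identity.
.lyapunov_dense <- function(A, D) {
  n <- nrow(A)
  K <- diag(n) %x% A + A %x% diag(n)
  V <- matrix(solve(K, -as.vector(D)), n, n)
  (V + t(V)) / 2
}

#' Stationary covariance of the fluctuation process
#'
#' Solves the Lyapunov equation \eqn{A V + V A^T + D = 0}.  On the default
#' \code{"tangent"} subspace the equation is projected onto an orthonormal
#' sum-zero basis (where \code{A} is nonsingular for a stable equilibrium)
#' and the solution mapped back to \code{S x S} coordinates; the
#' \code{"full"} option solves in ambient coordinates and exists for
#' unconstrained test systems.
#'
#' @param model an \code{\link{build_ou}} result, or a list with \code{A}
#'   and \code{D}.
#' @param subspace \code{"tangent"} (default) or \code{"full"}.
#' @param tol residual tolerance; the Lyapunov residual on the solved
#'   subspace must be below it.
#' @return covariance matrix with attributes \code{"residual"} and
#'   \code{"subspace"}.
#' @export
stationary_covariance <- function(model, subspace = c("tangent", "full"),
                                  tol = 1e-8) {
  subspace <- match.arg(subspace)
  A <- model$A; D <- model$D
  if (subspace == "full") {
    if (max(Re(eigen(A, only.values = TRUE)$values)) >= 0)
      stop("drift matrix is not stable; no stationary covariance exists")
    V <- .lyapunov_dense(A, D)
    res <- max(abs(A %*% V + V %*% t(A) + D))
  } else {
    S <- nrow(A)
    Tb <- tangent_basis(S)
    At <- crossprod(Tb, A %*% Tb)
    Dt <- crossprod(Tb, D %*% Tb)
    if (max(Re(eigen(At, only.values = TRUE)$values)) >= 0)
      stop("drift matrix is not stable on the tangent subspace; ",
           "no stationary covariance exists")
    Vt <- .lyapunov_dense(At, Dt)
    res <- max(abs(At %*% Vt + Vt %*% t(At) + Dt))
    V <- Tb %*% Vt %*% t(Tb)
  }
  if (res > tol) stop("Lyapunov residual ", signif(res, 3), " exceeds tolerance")
  attr(V, "residual") <- res
  attr(V, "subspace") <- subspace
  V
}

#' Empirical fluctuation covariance from stochastic replicates
#'
#' For each replicate trajectory the scaled fluctuations
#' \eqn{x = \sqrt{N}(\eta - m)} are formed, an initial burn-in fraction of
#' snapshots is discarded, and the per-replicate second-moment matrix about
#' zero is computed (the stationary fluctuations have mean zero by
#' construction around the true equilibrium, so no sample mean is
#' subtracted -- subtracting one would bias the slow modes downward on
#' windows of a few relaxation times); the estimate is the across-replicate
#' mean, with the across-replicate standard error reported per entry.
#'
#' @param sims list of \code{\link{simulate_community}} results.
#' @param m reference equilibrium.
#' @param burn fraction of initial snapshots discarded.
#' @return list with \code{V} (mean covariance), \code{se} (entrywise
#'   standard error), \code{replicates}.
#' @export
empirical_covariance <- function(sims, m, burn = 0.2) {
  stopifnot(length(sims) >= 2)
  Vs <- lapply(sims, function(s) {
    x <- fluctuations(s, m)
    keep <- seq.int(floor(burn * nrow(x)) + 1L, nrow(x))
    crossprod(x[keep, , drop = FALSE]) / length(keep)
  })
  R <- length(Vs)
  arr <- simplify2array(Vs)
  V <- apply(arr, c(1, 2), mean)
  se <- apply(arr, c(1, 2), stats::sd) / sqrt(R)
  list(V = V, se = se, replicates = R)
}

#' Is the stationary covariance a proxy for the interaction matrix?
#'
#' Correlation-based comparison of the stationary covariance \code{V} (and
#' its tangent-subspace pseudo-inverse, the maximum-entropy candidate)
#' against the direct interaction matrix \code{M + L}: Spearman rank
#' correlations over off-diagonal entries and binary edge-recovery
#' precision/recall across a sweep of absolute-value thresholds.  The
#' comparison quantifies how poorly \code{V} and \code{V^-1} recover the
#' interaction network; the pseudo-inverse is invariant under
#' simplex-orthogonal shifts of \code{V}.
#'
#' @param V stationary covariance (\code{S x S}).
#' @param com the \code{\link{coop_community}} that generated it.
#' @param n_thresholds number of threshold levels in the sweep.
#' @return object of class \code{"proxy_report"}: list with
#'   \code{cor_V}, \code{cor_Vinv} (Spearman, off-diagonal),
#'   \code{thresholds}, \code{precision_V}, \code{recall_V},
#'   \code{precision_Vinv}, \code{recall_Vinv}, \code{degenerate}.
#' @export
proxy_comparison <- function(V, com, n_thresholds = 20) {
  stopifnot(inherits(com, "coop_community"))
  S <- nrow(V)
  target <- com$M + com$L
  off <- row(V) != col(V)
  tv <- target[off]
  Tb <- tangent_basis(S)
  Vt <- crossprod(Tb, V %*% Tb)
  Vinv <- Tb %*% solve(Vt) %*% t(Tb)
  degenerate <- stats::sd(tv) == 0 || stats::sd(V[off]) == 0
  cor_V <- if (degenerate) NA_real_ else
    stats::cor(V[off], tv, method = "spearman")
  cor_Vinv <- if (degenerate) NA_real_ else
    stats::cor(Vinv[off], tv, method = "spearman")
  truth <- tv != 0
  pr <- function(score) {
    th <- stats::quantile(abs(score), probs = seq(0, 1 - 1 / n_thresholds,
                                                  length.out = n_thresholds))
    prec <- rec <- numeric(length(th))
    for (k in seq_along(th)) {
      pred <- abs(score) > th[k]
      prec[k] <- if (any(pred)) sum(pred & truth) / sum(pred) else NA_real_
      rec[k] <- if (any(truth)) sum(pred & truth) / sum(truth) else NA_real_
    }
    list(thresholds = unname(th), precision = prec, recall = rec)
  }
  pv <- pr(V[off]); pi <- pr(Vinv[off])
  structure(list(cor_V = cor_V, cor_Vinv = cor_Vinv,
                 thresholds = pv$thresholds,
                 precision_V = pv$precision, recall_V = pv$recall,
                 precision_Vinv = pi$precision, recall_Vinv = pi$recall,
                 degenerate = degenerate),
            class = "proxy_report")
}

#' @export
print.proxy_report <- function(x, ...) {
  if (x$degenerate) {
    cat("Proxy comparison: degenerate (constant target or covariance)\n")
  } else {
    cat(sprintf("Proxy comparison: Spearman(V, M+L) = %.3f, Spearman(V^-1, M+L) = %.3f\n",
                x$cor_V, x$cor_Vinv))
  }
  invisible(x)
}
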