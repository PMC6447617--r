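## Linear stability of mean-field equilibria.
##
## Because the dynamics conserves the total abundance, every Jacobian
## carries a structural eigendirection transversal to the simplex; stability
## is therefore assessed on the (S-1)-dimensional sum-zero tangent subspace.

#' Orthonormal basis of the sum-zero tangent subspace
#'
#' @param S dimension.
#' @return \code{S x (S-1)} matrix with orthonormal columns orthogonal to
#'   the all-ones vector.
#' @export
tangent_basis <- function(S) {
  H <- stats::contr.helmert(S)
  sweep(H, 2, sqrt(colSums(H^2)), "/")
}

#' Jacobian of the mean-field dynamics at an equilibrium
#'
#' Exact analytic derivative of the mean-field RHS.  At an interior
#' equilibrium (all abundances positive) the entries are
#' \deqn{J_{ij} = \epsilon_1 M_{ji} + \epsilon_3 H_{ji}
#'   + \epsilon_2\left(\delta_{ij} (L^T m)_i + m_i L_{ji}\right)
#'   - \delta_{ij} G - m_i \,\partial_j G,}
#' where \eqn{G} is the total gain at \eqn{m} and
#' \eqn{\partial_j G = \epsilon_1 \sum_k M_{jk} + \epsilon_3 \sum_k H_{jk}
#'   + \epsilon_2 ((Lm)_j + (L^T m)_j)}.  The cooperation (and harm) terms
#' are of order \eqn{S} at \eqn{m \sim 1/S} while the exploitation terms are
#' of order 1, which is why the spectrum is cooperation-dominated whenever
#' \eqn{\epsilon_1 > 0}.
#'
#' For a boundary equilibrium (extinct species) the Jacobian of the
#' surviving sub-community is returned together with the transversal
#' re-invasion influx \eqn{\epsilon_1 (M^T m)_i + \epsilon_3 (H^T m)_i} of
#' each extinct species (the rate at which an infinitesimal reintroduction
#' would initially grow; in the exact gated model an extinct species never
#' re-enters).
#'
#' @param com a \code{\link{coop_community}}.
#' @param m equilibrium abundances (extinct species exactly 0).
#' @param check verify that \code{m} is approximately stationary.
#' @param tol residual tolerance for the check.
#' @return object of class \code{"coop_jacobian"}: list with \code{J} (the
#'   Jacobian on the surviving sub-community), \code{support} (indices),
#'   \code{invasion} (named influxes of extinct species), \code{m}.
#' @export
community_jacobian <- function(com, m, check = TRUE, tol = 1e-6) {
  stopifnot(inherits(com, "coop_community"))
  if (length(m) != com$S) stop("m has wrong length")
  if (check) {
    r <- max(abs(meanfield_rhs(m, com)))
    if (r > tol) stop("m is not stationary (||rhs||_inf = ", signif(r, 3),
                      "); integrate to equilibrium first or set check = FALSE")
  }
  supp <- which(m > 0)
  ext <- setdiff(seq_len(com$S), supp)
  invasion <- NULL
  if (length(ext)) {
    influx <- com$eps1 * as.vector(crossprod(com$M, m)) +
              com$eps3 * as.vector(crossprod(com$H, m))
    invasion <- influx[ext]
    names(invasion) <- paste0("sp", ext)
  }
  M <- com$M[supp, supp, drop = FALSE]
  L <- com$L[supp, supp, drop = FALSE]
  H <- com$H[supp, supp, drop = FALSE]
  ms <- m[supp]
  e1 <- com$eps1; e2 <- com$eps2; e3 <- com$eps3
  MTm <- as.vector(crossprod(M, ms))
  HTm <- as.vector(crossprod(H, ms))
  LTm <- as.vector(crossprod(L, ms))
  Lm  <- as.vector(L %*% ms)
  G <- e1 * sum(MTm) + e3 * sum(HTm) + e2 * sum(ms * LTm)
  dG <- e1 * rowSums(M) + e3 * rowSums(H) + e2 * (Lm + LTm)
  n <- length(supp)
  J <- e1 * t(M) + e3 * t(H) + e2 * (diag(LTm, n) + ms * t(L)) -
       diag(G, n) - outer(ms, dG)
  structure(list(J = J, support = supp, invasion = invasion, m = m),
            class = "coop_jacobian")
}

.jac_matrix <- function(J) {
  if (inherits(J, "coop_jacobian")) J$J else as.matrix(J)
}

#' Leading-order random-matrix form of the cooperative Jacobian
#'
#' Around the near-uniform equilibrium of a cooperative ensemble the
#' Jacobian reduces, to leading order in \code{S}, to
#' \deqn{J = \epsilon_1\left(-S\mu_M I + (M - \mu_M \mathbf{1})\right),}
#' i.e. a strong stabilizing diagonal \code{-S mu_M} plus the centered
#' perturbation matrix \code{M' = M - mu_M} with zero mean, variance
#' \code{sigma_M^2} and pair correlation \code{rho_M}.  Exploitation terms
#' are sub-leading and do not appear.
#'
#' @param M cooperation matrix.
#' @param stats a \code{matrix_stats} object (default: empirical stats of
#'   \code{M}).
#' @param eps1 cooperation intensity scale factor.
#' @return matrix of the same dimension as \code{M}.
#' @export
leading_order_jacobian <- function(M, stats = NULL, eps1 = 1) {
  .check_square(M, "M")
  if (is.null(stats)) stats <- effective_stats(M)
  S <- nrow(M)
  eps1 * (-diag(S * stats$mu_Q, S) + (M - stats$mu_Q))
}

#' Perron-Frobenius dominance condition for a random cooperative ensemble
#'
#' TRUE when \eqn{\mu_M \ge \sigma_M \sqrt{(1+\rho_M)/S}} (boundary equality
#' included), i.e. the mean cooperative coupling dominates the random-matrix
#' bulk so the leading eigenvalue of \code{M} is \eqn{\lambda_M = S\mu_M}
#' with a positive eigenvector and the near-uniform equilibrium expansion is
#' valid.
#'
#' @param stats a \code{matrix_stats} object.
#' @param S number of species.
#' @return logical flag.
#' @export
pf_condition <- function(stats, S) {
  stats$mu_Q >= stats$sigma_Q * sqrt((1 + stats$rho_Q) / S)
}

#' Spectrum of a Jacobian with eigenvalue-ellipse predictions
#'
#' Computes all eigenvalues, the maximum real part on the sum-zero tangent
#' subspace (the simplex-transversal structural mode is projected out), and,
#' when ensemble statistics are supplied, the random-matrix prediction: the
#' eigenvalues of the leading-order Jacobian fill an ellipse centered at
#' \eqn{-\epsilon_1 S \mu_M} with real semi-axis
#' \eqn{\epsilon_1\sqrt{S}\sigma_M(1+\rho_M)} and imaginary semi-axis
#' \eqn{\epsilon_1\sqrt{S}\sigma_M(1-\rho_M)}; the predicted largest
#' eigenvalue is center plus real semi-axis.
#'
#' @param J a matrix or \code{\link{community_jacobian}} result.
#' @param stats optional \code{matrix_stats} of the cooperation matrix.
#' @param eps1 cooperation intensity used in the prediction.
#' @return object of class \code{"spectrum_summary"}: \code{eigenvalues}
#'   (full), \code{eigenvalues_tangent}, \code{max_re_tangent},
#'   \code{center}, \code{semi_re}, \code{semi_im}, \code{predicted_max},
#'   \code{lambda_M}.
#' @export
jacobian_spectrum <- function(J, stats = NULL, eps1 = 1) {
  Jm <- .jac_matrix(J)
  S <- nrow(Jm)
  ev <- eigen(Jm, only.values = TRUE)$values
  if (S >= 2) {
    Tb <- tangent_basis(S)
    evt <- eigen(crossprod(Tb, Jm %*% Tb), only.values = TRUE)$values
    maxre <- max(Re(evt))
  } else {
    evt <- complex(0)
    maxre <- -Inf
  }
  center <- semi_re <- semi_im <- predicted_max <- lambda_M <- NA_real_
  if (!is.null(stats)) {
    center <- -eps1 * S * stats$mu_Q
    semi_re <- eps1 * sqrt(S) * stats$sigma_Q * (1 + stats$rho_Q)
    semi_im <- eps1 * sqrt(S) * stats$sigma_Q * (1 - stats$rho_Q)
    predicted_max <- center + semi_re
    lambda_M <- S * stats$mu_Q
  }
  structure(list(eigenvalues = ev, eigenvalues_tangent = evt,
                 max_re_tangent = maxre, center = center,
                 semi_re = semi_re, semi_im = semi_im,
                 predicted_max = predicted_max, lambda_M = lambda_M,
                 S = S),
            class = "spectrum_summary")
}

#' @export
print.spectrum_summary <- function(x, ...) {
  cat(sprintf("Jacobian spectrum (S = %d): max Re on tangent subspace = %.6g\n",
              x$S, x$max_re_tangent))
  if (!is.na(x$center))
    cat(sprintf("  ellipse prediction: center %.6g, semi-axes (%.4g, %.4g), predicted max %.6g\n",
                x$center, x$semi_re, x$semi_im, x$predicted_max))
  invisible(x)
}

#' @export
plot.spectrum_summary <- function(x, inflate = 1, ...) {
  ev <- x$eigenvalues_tangent
  graphics::plot(Re(ev), Im(ev), pch = 20, cex = 0.5,
                 xlab = "Re", ylab = "Im", ...)
  if (!is.na(x$center)) {
    th <- seq(0, 2 * pi, length.out = 200)
    graphics::lines(x$center + inflate * x$semi_re * cos(th),
                    inflate * x$semi_im * sin(th), col = 2)
  }
  graphics::abline(v = 0, lwd = 1)
  invisible(x)
}

#' Fraction of eigenvalues inside the predicted ellipse
#'
#' @param spec a \code{spectrum_summary} with ellipse predictions.
#' @param inflate inflation factor for the semi-axes (finite-size edge
#'   fluctuations make a 5 percent inflation customary).
#' @return fraction in \code{[0, 1]} of tangent-subspace eigenvalues inside.
#' @export
ellipse_fraction <- function(spec, inflate = 1.05) {
  stopifnot(inherits(spec, "spectrum_summary"), !is.na(spec$center))
  ev <- spec$eigenvalues_tangent
  a <- inflate * spec$semi_re
  b <- inflate * spec$semi_im
  if (a <= 0 || b <= 0) {
    inside <- abs(Re(ev) - spec$center) <= a + 1e-12 & abs(Im(ev)) <= b + 1e-12
  } else {
    inside <- ((Re(ev) - spec$center) / a)^2 + (Im(ev) / b)^2 <= 1
  }
  mean(inside)
}

#' Linear stability flag
#'
#' TRUE iff the maximum real part of the Jacobian spectrum on the sum-zero
#' tangent subspace is below \code{-tol}.  A one-species community has an
#' empty tangent subspace and counts as (vacuously) stable.
#'
#' @param J matrix or \code{coop_jacobian}.
#' @param tol margin below zero.
#' @return logical flag.
#' @export
is_stable <- function(J, tol = 1e-10) {
  Jm <- .jac_matrix(J)
  if (nrow(Jm) < 2) return(TRUE)
  jacobian_spectrum(Jm)$max_re_tangent < -tol
}
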