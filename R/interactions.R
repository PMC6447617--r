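#' Random-ensemble specification for interaction matrices
#'
#' Describes the ensemble from which cooperation (\code{M}), exploitation
#' (\code{L}) and harm (\code{H}) matrices are sampled: connectivities (the
#' probability that an unordered species pair carries an interaction of each
#' class), the entry-strength distribution family, its parameters, and the
#' correlation of the two directed strengths of a connected pair.
#'
#' @param S number of species (integer, >= 1).
#' @param c_M,c_L,c_H connectivities in \code{[0, 1]}.  Joint sampling with
#'   \code{\link{sample_community}} assigns each unordered pair to at most one
#'   interaction class, so \code{c_M + c_L + c_H <= 1} is required there.
#' @param family entry-strength family, one of \code{"abs-normal"},
#'   \code{"gamma"}, \code{"lognormal"}, \code{"uniform"}, \code{"constant"}.
#' @param mu,sigma family parameters (see \code{\link{entry_moments}}).
#' @param rho correlation in \code{[-1, 1]} of the latent bivariate draw for
#'   the two directed strengths of a connected pair (Gaussian copula for
#'   non-Gaussian families; exact bivariate-normal correlation for
#'   \code{"abs-normal"} before folding).
#' @param seed optional RNG seed recorded with the spec; when non-NULL the
#'   samplers call \code{set.seed(seed)} before drawing.
#' @return an object of class \code{"ensemble_spec"}.
#' @examples
#' spec <- ensemble_spec(50, c_M = 0.5, mu = 0.1, sigma = 0.03)
#' M <- sample_cooperation(spec)
#' @export
ensemble_spec <- function(S, c_M = 0, c_L = 0, c_H = 0,
                          family = "abs-normal", mu = 1, sigma = 0,
                          rho = 0, seed = NULL) {
  S <- as.integer(S)
  if (length(S) != 1L || is.na(S) || S < 1L) stop("S must be a positive integer")
  for (cc in list(c_M = c_M, c_L = c_L, c_H = c_H)) {
    if (cc < 0 || cc > 1) stop("connectivities must lie in [0, 1]")
  }
  if (abs(rho) > 1) stop("rho must lie in [-1, 1]")
  .validate_family(family, mu, sigma)
  structure(list(S = S, c_M = c_M, c_L = c_L, c_H = c_H, family = family,
                 mu = mu, sigma = sigma, rho = rho, seed = seed),
            class = "ensemble_spec")
}

#' @export
print.ensemble_spec <- function(x, ...) {
  cat(sprintf("Ensemble spec: S = %d, family = %s(mu = %g, sigma = %g), rho = %g\n",
              x$S, x$family, x$mu, x$sigma, x$rho))
  cat(sprintf("  connectivities: c_M = %g, c_L = %g, c_H = %g\n",
              x$c_M, x$c_L, x$c_H))
  invisible(x)
}

.upper_pairs <- function(S) {
  which(upper.tri(matrix(0, S, S)), arr.ind = TRUE)
}

.maybe_seed <- function(spec) if (!is.null(spec$seed)) set.seed(spec$seed)

#' Sample a cooperation matrix
#'
#' Each unordered species pair is connected with probability \code{c_M};
#' connected pairs carry nonnegative strengths in both directions, drawn as a
#' correlated pair from the spec's entry family (magnitudes of a bivariate
#' normal for \code{"abs-normal"}).  The diagonal is zero; self-supporting
#' loops, used by some extinction-cascade fixtures, can be added afterwards
#' (the class invariant \code{M >= 0} permits them).
#'
#' @param spec an \code{\link{ensemble_spec}}.
#' @return an \code{S x S} nonnegative matrix.
#' @export
sample_cooperation <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  .maybe_seed(spec)
  S <- spec$S
  M <- matrix(0, S, S)
  if (S < 2L || spec$c_M == 0) return(M)
  pairs <- .upper_pairs(S)
  sel <- runif(nrow(pairs)) < spec$c_M
  z <- .draw_pairs(spec, sum(sel))
  M[pairs[sel, , drop = FALSE]] <- z[, 1]
  M[pairs[sel, c(2, 1), drop = FALSE]] <- z[, 2]
  M
}

#' Sample an exploitation matrix
#'
#' Connected pairs share one magnitude draw \code{z} and carry antisymmetric
#' signs with random orientation: \code{L[i,j] = +z}, \code{L[j,i] = -z} (so
#' \code{L[i,j] * L[j,i] < 0} for every connected pair).
#'
#' @inheritParams sample_cooperation
#' @return an \code{S x S} signed matrix with zero diagonal.
#' @export
sample_exploitation <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  .maybe_seed(spec)
  S <- spec$S
  L <- matrix(0, S, S)
  if (S < 2L || spec$c_L == 0) return(L)
  pairs <- .upper_pairs(S)
  sel <- which(runif(nrow(pairs)) < spec$c_L)
  if (length(sel) == 0L) return(L)
  z <- .draw_pairs(spec, length(sel))[, 1]
  flip <- runif(length(sel)) < 0.5
  s <- ifelse(flip, -1, 1)
  L[pairs[sel, , drop = FALSE]] <- s * z
  L[pairs[sel, c(2, 1), drop = FALSE]] <- -s * z
  L
}

#' Sample a harm matrix
#'
#' Connected pairs carry a single one-directional negative strength
#' \code{-|z|} (random orientation); the partner direction is zero, matching
#' the (-0) interaction pattern of secreted harmful compounds.
#'
#' @inheritParams sample_cooperation
#' @return an \code{S x S} nonpositive matrix with zero diagonal.
#' @export
sample_harm <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  .maybe_seed(spec)
  S <- spec$S
  H <- matrix(0, S, S)
  if (S < 2L || spec$c_H == 0) return(H)
  pairs <- .upper_pairs(S)
  sel <- which(runif(nrow(pairs)) < spec$c_H)
  if (length(sel) == 0L) return(H)
  z <- .draw_pairs(spec, length(sel))[, 1]
  flip <- runif(length(sel)) < 0.5
  idx <- pairs[sel, , drop = FALSE]
  idx[flip, ] <- idx[flip, c(2, 1), drop = FALSE]
  H[idx] <- -z
  H
}

#' Jointly sample a full community with disjoint interaction supports
#'
#' Every unordered species pair is assigned to exactly one interaction class
#' by an independent categorical draw with probabilities
#' \code{(c_M, c_L, c_H, 1 - c_M - c_L - c_H)}, then strengths are drawn as
#' in the per-class samplers.  This honours the constraint that a pair can
#' carry at most one interaction type.
#'
#' @inheritParams sample_cooperation
#' @param eps1,eps2,eps3 nonnegative interaction intensities (cooperation,
#'   exploitation, harm) stored in the returned community.
#' @return a \code{\link{coop_community}}.
#' @export
sample_community <- function(spec, eps1 = 1, eps2 = 1, eps3 = 1) {
  stopifnot(inherits(spec, "ensemble_spec"))
  if (spec$c_M + spec$c_L + spec$c_H > 1 + 1e-12)
    stop("joint sampling with disjoint supports requires c_M + c_L + c_H <= 1 (got ",
         spec$c_M + spec$c_L + spec$c_H, ")")
  .maybe_seed(spec)
  S <- spec$S
  M <- matrix(0, S, S); L <- matrix(0, S, S); H <- matrix(0, S, S)
  if (S >= 2L) {
    pairs <- .upper_pairs(S)
    u <- runif(nrow(pairs))
    cls <- ifelse(u < spec$c_M, 1L,
           ifelse(u < spec$c_M + spec$c_L, 2L,
           ifelse(u < spec$c_M + spec$c_L + spec$c_H, 3L, 0L)))
    iM <- which(cls == 1L)
    if (length(iM)) {
      z <- .draw_pairs(spec, length(iM))
      M[pairs[iM, , drop = FALSE]] <- z[, 1]
      M[pairs[iM, c(2, 1), drop = FALSE]] <- z[, 2]
    }
    iL <- which(cls == 2L)
    if (length(iL)) {
      z <- .draw_pairs(spec, length(iL))[, 1]
      flip <- runif(length(iL)) < 0.5
      s <- ifelse(flip, -1, 1)
      L[pairs[iL, , drop = FALSE]] <- s * z
      L[pairs[iL, c(2, 1), drop = FALSE]] <- -s * z
    }
    iH <- which(cls == 3L)
    if (length(iH)) {
      z <- .draw_pairs(spec, length(iH))[, 1]
      flip <- runif(length(iH)) < 0.5
      idx <- pairs[iH, , drop = FALSE]
      idx[flip, ] <- idx[flip, c(2, 1), drop = FALSE]
      H[idx] <- -z
    }
  }
  coop_community(M, L, H, eps1 = eps1, eps2 = eps2, eps3 = eps3)
}

## ---------------------------------------------------------------------------
## Community bundle and constraint validation

.check_square <- function(Q, name) {
  if (!is.matrix(Q) || nrow(Q) != ncol(Q))
    stop(name, " must be a square matrix")
}

#' Bundle interaction matrices into a community
#'
#' Validates the class invariants of the three interaction matrices:
#' \itemize{
#'   \item \code{M >= 0} elementwise (self-links on the diagonal permitted);
#'   \item \code{L}: zero diagonal and, per pair,
#'     \code{L[i,j] * L[j,i] < 0} or both zero;
#'   \item \code{H <= 0}, zero diagonal, and per pair at most one direction
#'     nonzero;
#'   \item disjoint supports: for every ordered pair at most one of
#'     \code{M[i,j]}, \code{L[i,j]}, \code{H[i,j]} is nonzero.
#' }
#' Every violated pair is reported.
#'
#' @param M cooperation matrix (nonnegative, \code{S x S}).
#' @param L exploitation matrix or NULL (all zero).
#' @param H harm matrix or NULL (all zero).
#' @param eps1,eps2,eps3 nonnegative interaction intensities.
#' @param validate set FALSE to skip constraint checking.
#' @return an object of class \code{"coop_community"}: a list with elements
#'   \code{M}, \code{L}, \code{H}, \code{eps1}, \code{eps2}, \code{eps3},
#'   \code{S}.
#' @export
coop_community <- function(M, L = NULL, H = NULL,
                           eps1 = 1, eps2 = 1, eps3 = 1, validate = TRUE) {
  .check_square(M, "M")
  S <- nrow(M)
  if (is.null(L)) L <- matrix(0, S, S)
  if (is.null(H)) H <- matrix(0, S, S)
  .check_square(L, "L"); .check_square(H, "H")
  if (nrow(L) != S || nrow(H) != S)
    stop("M, L, H must have identical dimensions")
  if (any(c(eps1, eps2, eps3) < 0)) stop("intensities must be nonnegative")
  com <- structure(list(M = M, L = L, H = H,
                        eps1 = eps1, eps2 = eps2, eps3 = eps3, S = S),
                   class = "coop_community")
  if (validate) {
    bad <- validate_interactions(com)
    if (length(bad)) stop("invalid interaction matrices:\n  ",
                          paste(bad, collapse = "\n  "))
  }
  com
}

#' Itemized constraint check for a community
#'
#' @param com a \code{\link{coop_community}} (or a bare list with M, L, H).
#' @return character vector of violation messages (empty when valid).
#' @export
validate_interactions <- function(com) {
  M <- com$M; L <- com$L; H <- com$H
  S <- nrow(M)
  msgs <- character(0)
  neg <- which(M < 0, arr.ind = TRUE)
  if (nrow(neg)) msgs <- c(msgs, sprintf("M[%d,%d] = %g < 0", neg[, 1], neg[, 2],
                                         M[neg]))
  if (any(diag(L) != 0)) msgs <- c(msgs, "L has nonzero diagonal entries")
  if (any(diag(H) != 0)) msgs <- c(msgs, "H has nonzero diagonal entries")
  pos <- which(H > 0, arr.ind = TRUE)
  if (nrow(pos)) msgs <- c(msgs, sprintf("H[%d,%d] = %g > 0", pos[, 1], pos[, 2],
                                         H[pos]))
  if (S >= 2) {
    pairs <- .upper_pairs(S)
    i <- pairs[, 1]; j <- pairs[, 2]
    lij <- L[pairs]; lji <- L[pairs[, c(2, 1), drop = FALSE]]
    badL <- which(!(lij * lji < 0 | (lij == 0 & lji == 0)))
    if (length(badL))
      msgs <- c(msgs, sprintf("L pair (%d,%d): L_ij = %g, L_ji = %g violates sign antisymmetry",
                              i[badL], j[badL], lij[badL], lji[badL]))
    hij <- H[pairs]; hji <- H[pairs[, c(2, 1), drop = FALSE]]
    badH <- which(hij != 0 & hji != 0)
    if (length(badH))
      msgs <- c(msgs, sprintf("H pair (%d,%d): both directions nonzero", i[badH], j[badH]))
  }
  nz <- (M != 0) + (L != 0) + (H != 0)
  multi <- which(nz > 1, arr.ind = TRUE)
  if (nrow(multi))
    msgs <- c(msgs, sprintf("pair (%d,%d) carries more than one interaction type",
                            multi[, 1], multi[, 2]))
  msgs
}

#' @export
print.coop_community <- function(x, ...) {
  nM <- sum(x$M != 0); nL <- sum(x$L != 0); nH <- sum(x$H != 0)
  cat(sprintf("Community of %d species (eps1 = %g, eps2 = %g, eps3 = %g)\n",
              x$S, x$eps1, x$eps2, x$eps3))
  cat(sprintf("  nonzero links: M %d, L %d, H %d\n", nM, nL, nH))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Ensemble statistics

#' Connectivity and moment statistics of an interaction matrix
#'
#' Empirical mode (matrix input) measures the off-diagonal entries: realized
#' connectivity \code{c_Q} (fraction of nonzero off-diagonal entries), mean
#' \code{mu_Q} and sd \code{sigma_Q} over all off-diagonal entries (zeros
#' included), the Pearson correlation \code{rho_Q} of opposite entries
#' \code{(Q_ij, Q_ji)}, and \code{cv = sigma_Q / |mu_Q|}.
#'
#' Analytic mode (\code{\link{ensemble_spec}} input) returns the effective
#' moments of the diluted ensemble,
#' \deqn{\mu_Q = c\,\mu_z,\qquad \sigma_Q^2 = c\,\sigma_z^2 + c(1-c)\mu_z^2,}
#' \deqn{\rho_Q = \frac{\rho\,\sigma_z^2 + (1-c)\mu_z^2}{\sigma_z^2 + (1-c)\mu_z^2},}
#' where \eqn{(\mu_z, \sigma_z)} are the magnitude moments
#' (\code{\link{entry_moments}}) and \eqn{c} the selected connectivity.  Note
#' that even for \eqn{\rho = 0} the effective correlation \eqn{\rho_Q} is
#' positive at \eqn{c < 1}, because opposite entries share the connection
#' indicator.  The analytic formulas describe the cooperation-style sampling
#' scheme (both directions drawn for a connected pair).
#'
#' @param x a square matrix, or an \code{\link{ensemble_spec}}.
#' @param ... passed on to methods.
#' @return an object of class \code{"matrix_stats"}: list with \code{c_Q},
#'   \code{mu_Q}, \code{sigma_Q}, \code{rho_Q}, \code{cv}.
#' @export
effective_stats <- function(x, ...) UseMethod("effective_stats")

#' @rdname effective_stats
#' @export
effective_stats.matrix <- function(x, ...) {
  S <- nrow(x)
  if (!is.matrix(x) || ncol(x) != S) stop("x must be square")
  if (S < 2) stop("effective_stats needs S >= 2 (no off-diagonal entries)")
  off <- x[row(x) != col(x)]
  pairs <- .upper_pairs(S)
  a <- x[pairs]; b <- x[pairs[, c(2, 1), drop = FALSE]]
  rho_Q <- if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_ else
    stats::cor(c(a, b), c(b, a))
  mu_Q <- mean(off); sigma_Q <- stats::sd(off)
  structure(list(c_Q = mean(off != 0), mu_Q = mu_Q, sigma_Q = sigma_Q,
                 rho_Q = rho_Q,
                 cv = if (mu_Q == 0) Inf else sigma_Q / abs(mu_Q)),
            class = "matrix_stats")
}

#' @rdname effective_stats
#' @param which which connectivity of the spec to use: \code{"M"},
#'   \code{"L"} or \code{"H"} (analytic mode only).
#' @export
effective_stats.ensemble_spec <- function(x, which = c("M", "L", "H"), ...) {
  which <- match.arg(which)
  cc <- switch(which, M = x$c_M, L = x$c_L, H = x$c_H)
  mom <- entry_moments(x)
  mu_z <- mom[["mean"]]; s2 <- mom[["sd"]]^2
  mu_Q <- cc * mu_z
  var_Q <- cc * s2 + cc * (1 - cc) * mu_z^2
  den <- s2 + (1 - cc) * mu_z^2
  rho_Q <- if (den == 0) NA_real_ else (x$rho * s2 + (1 - cc) * mu_z^2) / den
  structure(list(c_Q = cc, mu_Q = mu_Q, sigma_Q = sqrt(var_Q), rho_Q = rho_Q,
                 cv = if (mu_Q == 0) Inf else sqrt(var_Q) / abs(mu_Q)),
            class = "matrix_stats")
}

#' @export
print.matrix_stats <- function(x, ...) {
  cat(sprintf("c_Q = %.4g, mu_Q = %.4g, sigma_Q = %.4g, rho_Q = %.4g, CV = %.4g\n",
              x$c_Q, x$mu_Q, x$sigma_Q, x$rho_Q, x$cv))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Topology: irreducibility, pruning, normalization

#' Is a cooperation matrix irreducible?
#'
#' TRUE iff the directed graph of strictly positive entries is strongly
#' connected (any species reachable from any other along oriented links).
#' Irreducibility is the Perron-Frobenius condition guaranteeing a unique
#' strictly positive coexistence equilibrium of the purely cooperative model.
#'
#' @param M square nonnegative matrix.
#' @return logical flag.
#' @export
is_irreducible <- function(M) {
  .check_square(M, "M")
  if (any(M < 0)) stop("M must be nonnegative")
  S <- nrow(M)
  if (S == 1L) return(TRUE)
  g <- igraph::graph_from_adjacency_matrix(M > 0, mode = "directed")
  igraph::is_connected(g, mode = "strong")
}

#' Prune species without incoming cooperative support
#'
#' A species \code{i} is non-supported when its column sum over the remaining
#' community is zero (\code{sum_j M[j, i] = 0}, self-links included); at
#' stationarity such a species must go extinct, which can leave further
#' species unsupported.  The whole currently-unsupported set is deleted each
#' sweep (synchronous deletion) and sweeps repeat until every remaining
#' species is supported; the fixed point is independent of deletion order.
#'
#' @param M square nonnegative cooperation matrix.
#' @return an object of class \code{"pruning"}: list with \code{survivors}
#'   (sorted indices, possibly empty), \code{removed} (list of index vectors,
#'   one per sweep, the audit trail) and \code{M_pruned} (the surviving
#'   submatrix).
#' @export
prune_unsupported <- function(M) {
  .check_square(M, "M")
  if (any(M < 0)) stop("M must be nonnegative")
  S <- nrow(M)
  alive <- rep(TRUE, S)
  removed <- list()
  repeat {
    idx <- which(alive)
    if (length(idx) == 0L) break
    insupp <- colSums(M[idx, idx, drop = FALSE] > 0) > 0
    dead <- idx[!insupp]
    if (length(dead) == 0L) break
    alive[dead] <- FALSE
    removed[[length(removed) + 1L]] <- dead
  }
  surv <- which(alive)
  structure(list(survivors = surv, removed = removed,
                 M_pruned = M[surv, surv, drop = FALSE]),
            class = "pruning")
}

#' @export
print.pruning <- function(x, ...) {
  cat(sprintf("Pruning cascade: %d survivor(s), %d sweep(s), %d removed\n",
              length(x$survivors), length(x$removed),
              sum(lengths(x$removed))))
  invisible(x)
}

#' Constant-effort normalization
#'
#' Divides every nonzero column by the receiving species' in-degree (the
#' number of nonzero entries in that column), modelling a fixed interaction
#' effort shared among incoming links.  Zero columns are unchanged and the
#' zero/nonzero pattern is preserved.
#'
#' @param Q square matrix.
#' @return matrix of the same dimension.
#' @export
constant_effort_normalize <- function(Q) {
  .check_square(Q, "Q")
  indeg <- colSums(Q != 0)
  sweep(Q, 2, pmax(indeg, 1), "/")
}
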