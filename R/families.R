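## Entry-strength distribution families for random interaction matrices.
## All families describe a nonnegative magnitude distribution; `mu` and
## `sigma` are interpreted family-wise:
##   abs-normal: |N(mu, sigma)| -- mu, sigma are the *underlying* normal
##               parameters ("z ~ N(mu, mu/3), entries |z|" convention);
##               realized moments are folded-normal.
##   gamma, lognormal, uniform: mu and sigma are the mean and sd of the
##               magnitude itself (shape/scale resp. meanlog/sdlog resp.
##               endpoints are solved from them).
##   constant:   degenerate at mu.

.coopnet_families <- c("abs-normal", "gamma", "lognormal", "uniform", "constant")

#' Moments of an entry-strength family
#'
#' Mean and standard deviation of the magnitude distribution described by an
#' ensemble specification (conditional on a pair being connected).  For the
#' \code{abs-normal} family these are the folded-normal moments of
#' \code{|N(mu, sigma)|}; for the other families they equal \code{mu} and
#' \code{sigma} by construction.
#'
#' @param spec an \code{\link{ensemble_spec}}, or a family name (then `mu`,
#'   `sigma` must be given).
#' @param mu,sigma family parameters when `spec` is a character name.
#' @return named numeric vector \code{c(mean = ..., sd = ...)}.
#' @export
entry_moments <- function(spec, mu = NULL, sigma = NULL) {
  if (is.character(spec)) {
    spec <- list(family = match.arg(spec, .coopnet_families), mu = mu, sigma = sigma)
  }
  mu <- spec$mu; sigma <- spec$sigma
  switch(spec$family,
    "abs-normal" = {
      if (sigma == 0) return(c(mean = abs(mu), sd = 0))
      m <- sigma * sqrt(2 / pi) * exp(-mu^2 / (2 * sigma^2)) +
        mu * (1 - 2 * stats::pnorm(-mu / sigma))
      v <- mu^2 + sigma^2 - m^2
      c(mean = m, sd = sqrt(max(v, 0)))
    },
    "constant" = c(mean = mu, sd = 0),
    c(mean = mu, sd = sigma)
  )
}

## Quantile function of the magnitude distribution (used by the Gaussian
## copula for correlated non-Gaussian pairs).
.family_quantile <- function(u, family, mu, sigma) {
  switch(family,
    "gamma" = {
      shape <- (mu / sigma)^2
      qgamma(u, shape = shape, scale = sigma^2 / mu)
    },
    "lognormal" = {
      s2 <- log(1 + (sigma / mu)^2)
      qlnorm(u, meanlog = log(mu) - s2 / 2, sdlog = sqrt(s2))
    },
    "uniform" = qunif(u, min = mu - sqrt(3) * sigma, max = mu + sqrt(3) * sigma),
    "constant" = rep(mu, length(u)),
    stop("no quantile function for family '", family, "'")
  )
}

## Draw `n` correlated magnitude pairs (z_ij, z_ji).  Gaussian pairs are
## drawn directly from the bivariate normal and folded; the other families
## inherit the dependence through a Gaussian copula with latent correlation
## `rho`, which leaves the marginals untouched.
.draw_pairs <- function(spec, n) {
  if (n == 0L) return(matrix(numeric(0), 0, 2))
  rho <- spec$rho
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(max(0, 1 - rho^2)) * rnorm(n)
  if (spec$family == "abs-normal") {
    cbind(abs(spec$mu + spec$sigma * z1), abs(spec$mu + spec$sigma * z2))
  } else if (spec$family == "constant") {
    matrix(spec$mu, n, 2)
  } else {
    cbind(.family_quantile(pnorm(z1), spec$family, spec$mu, spec$sigma),
          .family_quantile(pnorm(z2), spec$family, spec$mu, spec$sigma))
  }
}

.validate_family <- function(family, mu, sigma) {
  if (!family %in% .coopnet_families)
    stop("unknown entry-distribution family '", family, "'; known families: ",
         paste(.coopnet_families, collapse = ", "))
  if (sigma < 0) stop("sigma must be >= 0")
  if (family %in% c("gamma", "lognormal")) {
    if (mu <= 0) stop("family '", family, "' requires mu > 0")
    if (sigma <= 0) stop("family '", family, "' requires sigma > 0")
  }
  if (family == "uniform" && mu - sqrt(3) * sigma < 0)
    stop("uniform family with mean ", mu, " and sd ", sigma,
         " has negative lower endpoint; magnitudes must be nonnegative")
  invisible(TRUE)
}
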