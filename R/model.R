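#' Model family specification
#'
#' The four model families are the combinations of count distribution and
#' spatial structure: Poisson ("BHPLM"), negative binomial ("BHNBLM"), and
#' their spatial versions with BYM effects ("BHSPLM", "BHSNBLM").
#'
#' @param family "poisson" or "negbin".
#' @param spatial logical; include ICAR + heterogeneity effects?
#' @param m number of covariates (>= 1).
#' @param shared_r negbin only: one dispersion parameter shared across
#'   segments instead of the default per-segment `r_s`.
#' @return a `model_spec` object (list with a `label` field).
#' @export
model_spec <- function(family = c("poisson", "negbin"), spatial = FALSE,
                       m = 10L, shared_r = FALSE) {
  family <- match.arg(family)
  if (m < 0) stop("m must be >= 0")  # m = 0 is the intercept-only endpoint of elimination
  label <- paste0("BH", if (spatial) "S" else "",
                  if (family == "poisson") "P" else "NB", "LM")
  structure(list(family = family, spatial = isTRUE(spatial), m = as.integer(m),
                 shared_r = isTRUE(shared_r), label = label),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(x$label, ": ", x$family, if (x$spatial) " + BYM spatial effects", ", m = ",
      x$m, "\n", sep = "")
  invisible(x)
}

#' Prior hyper-parameters
#'
#' Defaults are the study's vague priors: `beta_k ~ N(a_k, b_k)` and
#' `a0 ~ N(alpha0, b0)` with mean 0 and variance 10000; inverse-gamma
#' (shape 0.5, scale 0.00005) on both spatial-effect variances; and
#' Gamma(shape 5, rate 0.5) on each negative-binomial dispersion `r_s`.
#' `c0`/`d0` are the spatial-effect prior locations (0).
#'
#' @param ... named overrides of any hyper-parameter.
#' @return a `prior_spec` object.
#' @export
prior_spec <- function(...) {
  p <- list(ak = 0, bk = 10000, alpha0 = 0, b0 = 10000, c0 = 0, d0 = 0,
            q0 = 0.5, rho0 = 0.00005, x0 = 0.5, z0 = 0.00005, e0 = 5, j0 = 0.5)
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown)) stop("unknown prior parameters: ",
                            paste(unknown, collapse = ", "))
  p[names(over)] <- over
  if (any(unlist(p[c("bk", "b0", "q0", "rho0", "x0", "z0", "e0", "j0")]) <= 0)) {
    stop("prior variances, shapes, scales and rates must be > 0")
  }
  structure(p, class = "prior_spec")
}

#' Log-linear predictor
#'
#' \eqn{\log \lambda_s = a_0 + \sum_k X_{ks} \beta_k (+ \mu_s + v_s)}.
#'
#' @param state parameter list with `beta`, `a0` and, for spatial models,
#'   `mu` and `v`.
#' @param X numeric design matrix (segments x covariates).
#' @param spatial include the spatial effects?
#' @return numeric vector of log-means.
#' @export
linear_predictor <- function(state, X, spatial = !is.null(state$mu)) {
  if (length(state$beta) != ncol(X)) stop("beta length does not match X")
  eta <- as.vector(X %*% state$beta) + state$a0
  if (spatial) {
    if (length(state$mu) != nrow(X) || length(state$v) != nrow(X)) {
      stop("spatial effects do not match the number of segments")
    }
    eta <- eta + state$mu + state$v
  }
  eta
}

#' Poisson log-likelihood
#'
#' \eqn{\sum_s [Y_s \log\lambda_s - \lambda_s - \log\Gamma(Y_s + 1)]}.
#'
#' @param y non-negative integer counts.
#' @param lambda positive means.
#' @return scalar log-likelihood.
#' @export
poisson_loglik <- function(y, lambda) {
  if (any(y < 0) || any(y != round(y))) stop("counts must be non-negative integers")
  if (any(lambda <= 0)) stop("lambda must be > 0")
  sum(y * log(lambda) - lambda - lgamma(y + 1))
}

#' Negative-binomial log-likelihood
#'
#' In the (r, p) parameterization with \eqn{p_s = r_s / (\lambda_s + r_s)}:
#' \eqn{\sum_s [\log\Gamma(y_s + r_s) - \log\Gamma(r_s) - \log\Gamma(y_s + 1)
#' + r_s \log p_s + y_s \log(1 - p_s)]}. The distribution has mean
#' \eqn{\lambda_s} and variance \eqn{\lambda_s (1 + \lambda_s / r_s)}.
#'
#' @param y non-negative integer counts.
#' @param r positive dispersion (scalar or per-segment).
#' @param p success probabilities in (0, 1).
#' @return scalar log-likelihood.
#' @export
negbin_loglik <- function(y, r, p) {
  if (any(y < 0) || any(y != round(y))) stop("counts must be non-negative integers")
  if (any(r <= 0)) stop("r must be > 0")
  if (any(p <= 0 | p >= 1)) stop("p must lie in (0, 1)")
  sum(lgamma(y + r) - lgamma(r) - lgamma(y + 1) + r * log(p) + y * log1p(-p))
}

# negative-binomial log-likelihood in the (r, lambda) parameterization;
# numerically safe where p = r / (lambda + r) would round to 0 or 1
.negbin_ll_lambda <- function(y, r, lambda) {
  sum(lgamma(y + r) - lgamma(r) - lgamma(y + 1) +
        r * (log(r) - log(lambda + r)) + y * (log(lambda) - log(lambda + r)))
}

#' ICAR full conditional of one spatial effect
#'
#' \eqn{\mu_s \mid \mu_{-s} \sim N(\sum_{x \sim s} w_{sx}\mu_x / \sum w_{sx},
#' \; \sigma_\mu^2 / \sum w_{sx})}: normal around the neighbour mean with
#' variance inversely proportional to the neighbour count.
#'
#' @param s segment position (1-based).
#' @param mu current effect vector.
#' @param adjacency binary symmetric weight matrix.
#' @param sigma_mu2 conditional variance scale.
#' @return list `mean`, `var`.
#' @export
icar_conditional <- function(s, mu, adjacency, sigma_mu2) {
  w <- adjacency[s, ]
  sw <- sum(w)
  if (sw == 0) stop("segment ", s, " has no neighbours (mu fixed at 0 upstream)")
  list(mean = sum(w * mu) / sw, var = sigma_mu2 / sw)
}

.log_invgamma <- function(x, shape, scale) {
  shape * log(scale) - lgamma(shape) - (shape + 1) * log(x) - scale / x
}

#' Joint log-prior of a parameter state
#'
#' Normal priors on the coefficients and intercept; for spatial models, iid
#' normal on `v`, the improper ICAR kernel
#' \eqn{-\frac{S - G}{2}\log\sigma_\mu^2 - \frac{1}{2\sigma_\mu^2}
#' \sum_{s<x} w_{sx}(\mu_s - \mu_x)^2} on `mu` (rank deficiency G = number of
#' connected components), and inverse-gamma on both variances; for
#' negative-binomial models, gamma on each dispersion parameter.
#'
#' @param state parameter list (`beta`, `a0`, and per spec `mu`, `v`,
#'   `sigma_mu2`, `sigma_v2`, `r`).
#' @param priors a [prior_spec()].
#' @param spec a [model_spec()].
#' @param adjacency required for spatial models.
#' @return scalar log-density (up to the ICAR constant).
#' @export
log_prior <- function(state, priors, spec, adjacency = NULL) {
  lp <- sum(stats::dnorm(state$beta, priors$ak, sqrt(priors$bk), log = TRUE)) +
    stats::dnorm(state$a0, priors$alpha0, sqrt(priors$b0), log = TRUE)
  if (spec$spatial) {
    if (is.null(adjacency)) stop("spatial model needs adjacency")
    if (state$sigma_mu2 <= 0 || state$sigma_v2 <= 0) {
      stop("variances must be > 0")
    }
    df <- icar_df(adjacency)
    quad <- icar_quadform(state$mu, adjacency)
    lp <- lp - df / 2 * log(state$sigma_mu2) - quad / (2 * state$sigma_mu2) +
      sum(stats::dnorm(state$v, priors$d0, sqrt(state$sigma_v2), log = TRUE)) +
      .log_invgamma(state$sigma_mu2, priors$q0, priors$rho0) +
      .log_invgamma(state$sigma_v2, priors$x0, priors$z0)
  }
  if (spec$family == "negbin") {
    lp <- lp + sum(stats::dgamma(state$r, shape = priors$e0, rate = priors$j0,
                                 log = TRUE))
  }
  lp
}

#' Joint log-posterior (unnormalized)
#'
#' Log-likelihood of the counts under the spec's family plus [log_prior()],
#' up to the constant of proportionality.
#'
#' @param state parameter list.
#' @param y counts (may have length 0, in which case the value equals the
#'   log-prior).
#' @param X design matrix.
#' @param priors a [prior_spec()].
#' @param spec a [model_spec()].
#' @param adjacency required for spatial models.
#' @return scalar.
#' @export
log_posterior <- function(state, y, X, priors, spec, adjacency = NULL) {
  lp <- log_prior(state, priors, spec, adjacency)
  if (length(y) == 0) return(lp)
  lambda <- exp(linear_predictor(state, X, spec$spatial))
  ll <- if (spec$family == "poisson") {
    poisson_loglik(y, lambda)
  } else {
    r <- if (length(state$r) == 1L) rep(state$r, length(y)) else state$r
    .negbin_ll_lambda(y, r, lambda)
  }
  lp + ll
}
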