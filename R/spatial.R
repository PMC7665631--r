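#' Sample BYM spatial effects with known variances
#'
#' Draws the spatially correlated effect `mu` from the intrinsic conditional
#' autoregressive (ICAR) joint density with precision
#' \eqn{\sigma_\mu^{-2} (D - W)} restricted to the sum-to-zero subspace of each
#' connected component (the intrinsic density is improper; sum-to-zero is the
#' identifiability convention also used in fitting), and the heterogeneity
#' effect `v` iid \eqn{N(0, \sigma_v^2)}. Sampling is exact, via
#' eigendecomposition of \eqn{D - W} on the orthogonal complement of the
#' per-component constant vectors.
#'
#' @param adjacency binary symmetric adjacency matrix `W`.
#' @param sigma_mu2 variance of the correlated component (> 0).
#' @param sigma_v2 variance of the heterogeneity component (> 0).
#' @param seed integer RNG seed, or `NULL` to use the current RNG state.
#' @return list with elements `mu`, `v`, `sigma_mu2`, `sigma_v2`.
#' @export
sample_spatial_effects <- function(adjacency, sigma_mu2, sigma_v2, seed = NULL) {
  stopifnot(is.matrix(adjacency), nrow(adjacency) == ncol(adjacency))
  if (!is.numeric(sigma_mu2) || sigma_mu2 <= 0) stop("sigma_mu2 must be > 0")
  if (!is.numeric(sigma_v2) || sigma_v2 <= 0) stop("sigma_v2 must be > 0")
  if (!is.null(seed)) set.seed(seed)
  S <- nrow(adjacency)
  comp <- graph_components(adjacency)
  deg <- rowSums(adjacency)
  if (any(deg == 0)) {
    warning("isolated segments present; their mu is fixed at 0")
  }
  Q <- diag(deg) - adjacency
  mu <- numeric(S)
  for (g in unique(comp)) {
    idx <- which(comp == g)
    if (length(idx) == 1L) next  # isolated: mu = 0
    eg <- eigen(Q[idx, idx, drop = FALSE], symmetric = TRUE)
    # drop the single zero eigenvalue (constant vector) of the component
    keep <- seq_len(length(idx) - 1L)
    vals <- eg$values[keep]
    vecs <- eg$vectors[, keep, drop = FALSE]
    z <- stats::rnorm(length(keep))
    mu[idx] <- sqrt(sigma_mu2) * as.vector(vecs %*% (z / sqrt(vals)))
    mu[idx] <- mu[idx] - mean(mu[idx])  # numerical re-centering
  }
  v <- stats::rnorm(S, 0, sqrt(sigma_v2))
  list(mu = mu, v = v, sigma_mu2 = sigma_mu2, sigma_v2 = sigma_v2)
}

#' ICAR degrees of freedom of a graph
#'
#' Rank of the intrinsic precision \eqn{D - W}: number of non-isolated
#' vertices minus number of connected components of size >= 2. This is the
#' degrees of freedom of the ICAR quadratic form and enters both the improper
#' prior kernel and the conjugate variance update.
#'
#' @param adjacency binary symmetric adjacency matrix.
#' @return integer.
#' @export
icar_df <- function(adjacency) {
  comp <- graph_components(adjacency)
  deg <- rowSums(adjacency)
  live <- deg > 0
  G <- length(unique(comp[live]))
  sum(live) - G
}

#' ICAR pairwise quadratic form
#'
#' \eqn{\sum_{s<x} w_{sx} (\mu_s - \mu_x)^2}, identically
#' \eqn{\mu^T (D - W) \mu} for binary weights.
#'
#' @param mu numeric effect vector.
#' @param adjacency binary symmetric adjacency matrix.
#' @return scalar.
#' @export
icar_quadform <- function(mu, adjacency) {
  deg <- rowSums(adjacency)
  sum(mu * (deg * mu - as.vector(adjacency %*% mu)))
}

#' Simulate per-segment event counts from a fitted-model family
#'
#' Computes \eqn{\lambda_s = \exp(a_0 + \sum_k X_{ks}\beta_k + \mu_s + v_s)}
#' (spatial terms omitted when `truth$effects` is `NULL`) and draws counts:
#' Poisson with mean \eqn{\lambda_s}, or negative binomial with mean
#' \eqn{\lambda_s} and variance \eqn{\lambda_s(1 + \lambda_s/r_s)} under the
#' \eqn{p_s = r_s/(\lambda_s + r_s)} parameterization.
#'
#' @param network a `road_network` with covariates filled, or `NULL` when `X`
#'   is given directly.
#' @param truth list: `beta` (length-m), `a0`, `family` ("poisson" or
#'   "negbin"), optional `effects` (list with `mu`, `v`), optional `r`
#'   (scalar or per-segment, negbin only).
#' @param seed integer RNG seed, or `NULL`.
#' @param X optional numeric design matrix overriding `network$covariates`.
#' @return integer vector of counts `y`, with attribute `lambda`.
#' @export
simulate_counts <- function(network, truth, seed = NULL, X = NULL) {
  if (is.null(X)) {
    if (is.null(network$covariates)) stop("network covariates not generated")
    X <- as.matrix(network$covariates)
  }
  S <- nrow(X)
  if (length(truth$beta) != ncol(X)) {
    stop("truth$beta length does not match covariate count")
  }
  if (!is.null(seed)) set.seed(seed)
  eta <- as.vector(X %*% truth$beta) + truth$a0
  if (!is.null(truth$effects)) {
    eta <- eta + truth$effects$mu + truth$effects$v
  }
  if (any(eta > 700)) {
    stop("exp(linear predictor) overflows at segment ",
         which.max(eta), " (eta = ", round(max(eta), 2), ")")
  }
  lambda <- exp(eta)
  y <- switch(truth$family,
    poisson = stats::rpois(S, lambda),
    negbin = {
      r <- truth$r
      if (is.null(r) || any(r <= 0)) stop("negbin truth requires r > 0")
      if (length(r) == 1L) r <- rep(r, S)
      stats::rnbinom(S, size = r, mu = lambda)
    },
    stop("unknown family: ", truth$family)
  )
  attr(y, "lambda") <- lambda
  y
}

#' Study-condition ground truth for the synthetic generator
#'
#' Default coefficient vectors, intercepts and spatial-effect variances used
#' as the synthetic study conditions: the posterior means reported for the
#' spatial Poisson model fitted to total (or serious) speeding frequencies,
#' completed with the companion-model values for covariates that model
#' dropped (0 where no model retained the covariate).
#'
#' @param outcome "total" or "serious" speeding frequency conditions.
#' @param family "poisson" or "negbin".
#' @param spatial logical; include BYM effects in the truth?
#' @param adjacency required when `spatial = TRUE`.
#' @param seed RNG seed for the spatial-effect draw.
#' @return truth list as consumed by [simulate_counts()].
#' @export
default_truth <- function(outcome = c("total", "serious"),
                          family = "poisson", spatial = TRUE,
                          adjacency = NULL, seed = 1L) {
  outcome <- match.arg(outcome)
  if (outcome == "total") {
    beta <- c(
      speed_limit_ind = 2.538, n_cameras = 0.081, n_lanes_ind = -0.170,
      cross_section_ind = -0.696, one_way_ind = 0.250, non_motor_ind = 0.353,
      bus_lane_ind = 0.248, viaduct_ind = 0.383, work_zone_ind = 1.244,
      length_m = 0.007
    )
    a0 <- 4.667
    sig <- c(0.017, 0.038)
  } else {
    beta <- c(
      speed_limit_ind = 3.577, n_cameras = 0.081, n_lanes_ind = -0.207,
      cross_section_ind = -0.377, one_way_ind = 0.250, non_motor_ind = 0.168,
      bus_lane_ind = 0, viaduct_ind = 1.092, work_zone_ind = 1.220,
      length_m = 0.007
    )
    a0 <- 2.348
    sig <- c(0.013, 0.036)
  }
  truth <- list(beta = beta, a0 = a0, family = family, effects = NULL,
                r = if (family == "negbin") 10 else NULL)
  if (spatial) {
    if (is.null(adjacency)) stop("spatial truth needs an adjacency matrix")
    truth$effects <- sample_spatial_effects(adjacency, sig[1], sig[2],
                                            seed = seed)
  }
  truth
}
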