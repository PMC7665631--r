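#' Posterior summary table
#'
#' Pooled across chains: mean, standard deviation and equal-tailed 95%
#' credible interval per parameter. A parameter is flagged significant when
#' its interval excludes 0; variance parameters are reported without a flag
#' (they are positive by construction).
#'
#' @param fit a `speedcount_fit`.
#' @param parameters parameter names (default: the monitored set).
#' @param level credible level (default 0.95).
#' @return data.frame `parameter`, `mean`, `sd`, `lower`, `upper`,
#'   `significant`.
#' @export
summarize_posterior <- function(fit, parameters = NULL, level = 0.95) {
  draws <- if (inherits(fit, "speedcount_fit")) fit$draws else fit
  if (is.null(parameters)) parameters <- fit$monitored
  pooled <- do.call(rbind, draws)
  if (nrow(pooled) == 0) stop("empty draws")
  a <- (1 - level) / 2
  novar <- c("sigma_mu2", "sigma_v2", "r")
  out <- do.call(rbind, lapply(parameters, function(p) {
    x <- pooled[, p]
    q <- unname(stats::quantile(x, c(a, 1 - a)))
    data.frame(parameter = p, mean = mean(x), sd = stats::sd(x),
               lower = q[1], upper = q[2],
               significant = if (p %in% novar) NA else (q[1] > 0 | q[2] < 0))
  }))
  rownames(out) <- NULL
  out
}

#' Deviance of a parameter state
#'
#' `-2` times the family-appropriate log-likelihood, constants included.
#'
#' @param state parameter list (`beta`, `a0`, and `mu`, `v`, `r` as needed).
#' @param y counts.
#' @param X design matrix.
#' @param spec a [model_spec()].
#' @return scalar deviance.
#' @export
model_deviance <- function(state, y, X, spec) {
  lambda <- exp(linear_predictor(state, as.matrix(X), spec$spatial))
  ll <- if (spec$family == "poisson") {
    poisson_loglik(y, lambda)
  } else {
    r <- if (length(state$r) == 1L) rep(state$r, length(y)) else state$r
    .negbin_ll_lambda(y, r, lambda)
  }
  -2 * ll
}

#' DIC bookkeeping from known components
#'
#' Builds a `dic_result` from the posterior-mean deviance and the effective
#' number of parameters: `DIC = d_bar + p_d`, `d_hat = d_bar - p_d`.
#'
#' @param d_bar posterior mean deviance.
#' @param p_d effective number of parameters.
#' @return a `dic_result`.
#' @export
dic_result <- function(d_bar, p_d) {
  if (p_d < 0) warning("negative p_d (", round(p_d, 3), "): recorded as is")
  structure(list(d_bar = d_bar, d_hat = d_bar - p_d, p_d = p_d,
                 dic = d_bar + p_d),
            class = "dic_result")
}

#' @export
print.dic_result <- function(x, ...) {
  cat(sprintf("DIC = %.3f (D-bar = %.3f, p_d = %.3f)\n", x$dic, x$d_bar, x$p_d))
  invisible(x)
}

#' Deviance information criterion of a fit
#'
#' `D-bar` is the mean of the per-draw deviances stored during sampling;
#' `D(theta-bar)` plugs in the posterior means of every stochastic quantity
#' (coefficients, intercept, random effects, dispersions), the convention of
#' the BUGS-family software this class of models is usually fitted with;
#' `p_d = D-bar - D(theta-bar)` and `DIC = D-bar + p_d`.
#'
#' @param fit a `speedcount_fit`.
#' @return a `dic_result` (with the extra field `d_hat`).
#' @export
dic <- function(fit) {
  d_bar <- mean(unlist(fit$deviance))
  pooled <- colMeans(do.call(rbind, fit$draws))
  S <- nrow(fit$X)
  spec <- fit$spec
  cn <- colnames(fit$X)
  bn <- if (!is.null(cn)) cn else paste0("beta", seq_len(spec$m))
  state <- list(beta = unname(pooled[bn]), a0 = unname(pooled["a0"]))
  if (spec$spatial) {
    state$mu <- unname(pooled[paste0("mu[", seq_len(S), "]")])
    state$v <- unname(pooled[paste0("v[", seq_len(S), "]")])
  }
  if (spec$family == "negbin") {
    state$r <- if (spec$shared_r) unname(pooled["r"]) else
      unname(pooled[paste0("r[", seq_len(S), "]")])
  }
  d_hat <- model_deviance(state, fit$y, fit$X, spec)
  res <- dic_result(d_bar, d_bar - d_hat)
  res$d_hat <- d_hat
  res
}

#' Rank models by DIC
#'
#' Sorts ascending by DIC. Models whose DIC differs from the best by at most
#' 5 are declared equivalent to it; when no rival is within 5 the best model
#' is declared superior.
#'
#' @param results named list of `dic_result` objects.
#' @return a `dic_comparison`: data.frame `model`, `p_d`, `d_bar`, `dic`,
#'   `delta` (difference to the best), `equivalent_to_best`; attribute
#'   `superior` holds the winning model name or `NA` on a tie.
#' @export
compare_models <- function(results) {
  if (length(results) < 2) stop("need >= 2 models to compare")
  if (is.null(names(results))) {
    names(results) <- paste0("model", seq_along(results))
  }
  tab <- data.frame(
    model = names(results),
    p_d = vapply(results, `[[`, 1.0, "p_d"),
    d_bar = vapply(results, `[[`, 1.0, "d_bar"),
    dic = vapply(results, `[[`, 1.0, "dic")
  )
  tab <- tab[order(tab$dic), ]
  tab$delta <- tab$dic - tab$dic[1]
  tab$equivalent_to_best <- tab$delta <= 5
  rownames(tab) <- NULL
  superior <- if (sum(tab$equivalent_to_best) == 1L) tab$model[1] else NA_character_
  structure(tab, class = c("dic_comparison", "data.frame"), superior = superior)
}

#' @export
print.dic_comparison <- function(x, ...) {
  print.data.frame(x, digits = 7)
  s <- attr(x, "superior")
  if (is.na(s)) cat("verdict: top models are equivalent (DIC within 5)\n")
  else cat("verdict:", s, "is superior\n")
  invisible(x)
}

#' Spatial fraction from variance components
#'
#' `frac = sigma_mu2 / (sigma_mu2 + sigma_v2)`: the share of spatial
#' random-effect variance attributable to the correlated (ICAR) component;
#' values near 1 mean spatial correlation dominates, near 0 that spatial
#' heterogeneity does.
#'
#' @param sigma_mu2,sigma_v2 variance components (>= 0, not both 0).
#' @return scalar in \[0, 1\].
#' @export
spatial_fraction_point <- function(sigma_mu2, sigma_v2) {
  if (any(sigma_mu2 < 0) || any(sigma_v2 < 0)) stop("variances must be >= 0")
  if (any(sigma_mu2 + sigma_v2 == 0)) stop("variances must not both be 0")
  sigma_mu2 / (sigma_mu2 + sigma_v2)
}

#' Posterior spatial-fraction analysis
#'
#' Computes the spatial fraction per posterior draw and summarizes it
#' (mean and 95% interval); also reports the point version evaluated at the
#' posterior-mean variances, which is how a published table of posterior
#' means is turned into a single fraction.
#'
#' @param fit a `speedcount_fit` of a spatial model.
#' @return list: `mean`, `lower`, `upper` (per-draw summary), `point`
#'   (fraction of posterior-mean variances), `draws`.
#' @export
spatial_fraction <- function(fit) {
  if (!fit$spec$spatial) stop("spatial fraction requires a spatial model")
  pooled <- do.call(rbind, fit$draws)
  fr <- spatial_fraction_point(pooled[, "sigma_mu2"], pooled[, "sigma_v2"])
  q <- unname(stats::quantile(fr, c(0.025, 0.975)))
  list(mean = mean(fr), lower = q[1], upper = q[2],
       point = spatial_fraction_point(mean(pooled[, "sigma_mu2"]),
                                      mean(pooled[, "sigma_v2"])),
       draws = fr)
}

#' Backward elimination of non-significant covariates
#'
#' Fits the model, and while any covariate's 95% credible interval covers 0,
#' removes the one whose interval covers it most centrally (smallest
#' |mean|/sd) and refits; deterministic given the configuration seed. If
#' every covariate is eliminated an intercept-only model is returned with a
#' warning.
#'
#' @param y counts.
#' @param X design matrix with column names.
#' @param spec a [model_spec()] for the full model.
#' @param adjacency for spatial specs.
#' @param priors a [prior_spec()].
#' @param config an [mcmc_config()].
#' @return list: `fit` (final model), `retained`, `dropped` (data.frame with
#'   the elimination order and |mean|/sd at removal).
#' @export
select_significant <- function(y, X, spec, adjacency = NULL,
                               priors = prior_spec(), config = mcmc_config()) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("beta", seq_len(ncol(X)))
  dropped <- data.frame(step = integer(0), parameter = character(0),
                        z = numeric(0))
  repeat {
    sp <- model_spec(spec$family, spec$spatial, ncol(X), spec$shared_r)
    fit <- fit_model(y, X, sp, adjacency, priors, config)
    if (ncol(X) == 0L) {
      warning("all covariates eliminated; returning intercept-only model")
      break
    }
    summ <- summarize_posterior(fit, colnames(X))
    insig <- summ[!summ$significant, ]
    if (nrow(insig) == 0L) break
    z <- abs(insig$mean) / insig$sd
    worst <- insig$parameter[which.min(z)]
    dropped <- rbind(dropped, data.frame(step = nrow(dropped) + 1L,
                                         parameter = worst, z = min(z)))
    X <- X[, setdiff(colnames(X), worst), drop = FALSE]
  }
  list(fit = fit, retained = colnames(X), dropped = dropped)
}
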