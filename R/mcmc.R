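#' MCMC run configuration
#'
#' Desk-scale defaults (2 chains of 20,000 iterations, 5,000 burn-in) that
#' reproduce model behaviour in seconds; `paper_scale = TRUE` switches to the
#' long protocol of 400,000 iterations with 100,000 burn-in per chain.
#' Proposal scales adapt toward `target_accept` during burn-in only.
#'
#' @param n_chains number of chains (>= 2 for convergence diagnostics).
#' @param n_iter iterations per chain.
#' @param burn_in discarded initial iterations (< n_iter).
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param seed master seed; chain c uses `seed + c - 1`.
#' @param adapt_window iterations between proposal-scale updates.
#' @param target_accept acceptance-rate target during adaptation.
#' @param paper_scale use the long two-chain protocol.
#' @return an `mcmc_config` list.
#' @export
mcmc_config <- function(n_chains = 2L, n_iter = 20000L, burn_in = 5000L,
                        thin = 1L, seed = 1L, adapt_window = 50L,
                        target_accept = 0.35, paper_scale = FALSE) {
  if (paper_scale) {
    n_iter <- 400000L
    burn_in <- 100000L
  }
  if (burn_in >= n_iter) stop("burn_in must be < n_iter")
  if (n_chains < 2) stop("n_chains must be >= 2 for convergence diagnostics")
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed), adapt_window = as.integer(adapt_window),
                 target_accept = target_accept),
            class = "mcmc_config")
}

.adj_to_nbr <- function(adjacency) {
  lapply(seq_len(nrow(adjacency)), function(s) which(adjacency[s, ] != 0))
}

.param_names <- function(spec, S, covnames = NULL) {
  bn <- if (!is.null(covnames)) covnames else paste0("beta", seq_len(spec$m))
  nm <- c(bn, "a0")
  if (spec$spatial) {
    nm <- c(nm, paste0("mu[", seq_len(S), "]"), paste0("v[", seq_len(S), "]"),
            "sigma_mu2", "sigma_v2")
  }
  if (spec$family == "negbin") {
    nm <- c(nm, if (spec$shared_r) "r" else paste0("r[", seq_len(S), "]"))
  }
  nm
}

.monitored_names <- function(spec, covnames = NULL) {
  bn <- if (!is.null(covnames)) covnames else paste0("beta", seq_len(spec$m))
  nm <- c(bn, "a0")
  if (spec$spatial) nm <- c(nm, "sigma_mu2", "sigma_v2")
  if (spec$family == "negbin" && spec$shared_r) nm <- c(nm, "r")
  nm
}

.coef_chol <- function(y, X, flat = FALSE, bk = 10000, b0 = 10000) {
  Xa <- cbind(X, 1)
  prior_prec <- diag(c(rep(1 / bk, ncol(X)), 1 / b0), ncol(Xa))
  if (!flat) {
    w <- y + 0.5
    info <- crossprod(Xa, w * Xa)
    # prior precision as the regularizer: aliased columns fall back to the
    # prior scale instead of an arbitrary ridge
    Sigma <- tryCatch(solve(info + prior_prec), error = function(e) NULL)
    if (!is.null(Sigma)) {
      ch <- tryCatch(t(chol((Sigma + t(Sigma)) / 2)), error = function(e) NULL)
      if (!is.null(ch)) return(ch)
    }
  }
  diag(c(rep(sqrt(bk), ncol(X)), sqrt(b0)))
}

.default_blocks <- function(spec) {
  list(coefficients = TRUE, spatial = spec$spatial, variances = spec$spatial,
       dispersion = spec$family == "negbin")
}

.init_state <- function(y, X, spec, priors, chain, flat = FALSE, chol = NULL) {
  S <- nrow(X)
  if (flat) {
    center <- rep(0, ncol(X) + 1)
  } else {
    w <- y + 0.5
    fit <- tryCatch(stats::lm.wfit(cbind(X, 1), log(y + 0.5), w),
                    error = function(e) NULL)
    center <- if (is.null(fit)) rep(0, ncol(X) + 1) else fit$coefficients
    center[is.na(center)] <- 0  # aliased columns center on the prior mean
  }
  # overdispersed relative to the posterior scale implied by the Fisher
  # information, not to the raw covariate scale (a fixed-sd kick on the
  # length coefficient would start chains at exp(eta) overflow)
  if (is.null(chol)) chol <- .coef_chol(y, X, flat, priors$bk, priors$b0)
  noise <- 5 * as.vector(chol %*% stats::rnorm(ncol(X) + 1))
  st <- list(beta = center[seq_len(ncol(X))] + noise[seq_len(ncol(X))],
             a0 = center[ncol(X) + 1] + noise[ncol(X) + 1])
  if (spec$spatial) {
    st$mu <- stats::rnorm(S, 0, 0.1)
    st$mu <- st$mu - mean(st$mu)
    st$v <- stats::rnorm(S, 0, 0.1)
    st$sigma_mu2 <- exp(stats::rnorm(1, log(0.05), 1))
    st$sigma_v2 <- exp(stats::rnorm(1, log(0.05), 1))
  }
  if (spec$family == "negbin") {
    n_r <- if (spec$shared_r) 1L else S
    st$r <- exp(stats::rnorm(n_r, log(10), 0.5))
  }
  st
}

.run_chain <- function(y, X, spec, priors, adjacency, config, init, blocks,
                       flat_lik = FALSE, chol = NULL, n_iter = NULL,
                       burn_in = NULL,
                       prop = list(coef = 0.5, mu = 0.3, v = 0.3, r = 0.5)) {
  S <- nrow(X)
  nbr <- if (is.null(adjacency)) rep(list(integer(0)), S) else
    .adj_to_nbr(adjacency)
  comp <- if (is.null(adjacency)) rep(1L, S) else graph_components(adjacency)
  dfv <- if (is.null(adjacency)) 0 else icar_df(adjacency)
  if (is.null(chol)) chol <- .coef_chol(y, X, flat_lik, priors$bk, priors$b0)
  sc_mcmc(as.numeric(y), X, nbr, as.integer(comp),
          ifelse(spec$family == "poisson", 0L, 1L), spec$spatial,
          spec$shared_r, flat_lik, unclass(priors), init, blocks,
          if (is.null(n_iter)) config$n_iter else as.integer(n_iter),
          if (is.null(burn_in)) config$burn_in else as.integer(burn_in),
          config$thin, chol, dfv, prop,
          TRUE, config$adapt_window, config$target_accept)
}

#' Fit a hierarchical count model by MH-within-Gibbs
#'
#' Runs `config$n_chains` independent chains from overdispersed starting
#' values (a weighted least-squares center for the coefficients plus
#' chain-specific Gaussian noise; redrawn, up to 100 times, if the posterior
#' is not finite there). Coefficients update as one multivariate random-walk
#' Metropolis block; spatial effects and dispersions one at a time; spatial
#' variances by exact conjugate inverse-gamma draws. Proposal scales adapt
#' during burn-in only. Draws are stored after burn-in along with the
#' deviance of every stored draw.
#'
#' @param y per-segment counts.
#' @param X design matrix (a data.frame is accepted).
#' @param spec a [model_spec()]; `spec$m` must equal `ncol(X)`.
#' @param adjacency binary symmetric matrix, required when `spec$spatial`.
#' @param priors a [prior_spec()].
#' @param config an [mcmc_config()].
#' @return a `speedcount_fit`: list with per-chain `draws` matrices (named
#'   columns), `deviance` vectors, acceptance rates, final states, and the
#'   inputs needed by the assessment functions.
#' @export
fit_model <- function(y, X, spec, adjacency = NULL, priors = prior_spec(),
                      config = mcmc_config()) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (ncol(X) != spec$m) stop("spec$m does not match ncol(X)")
  if (length(y) != nrow(X)) stop("length(y) does not match nrow(X)")
  if (any(y < 0) || any(y != round(y))) stop("counts must be non-negative integers")
  if (spec$spatial && is.null(adjacency)) stop("spatial model needs adjacency")
  zero_cols <- which(apply(X, 2, function(c) all(c == 0)))
  if (length(zero_cols)) {
    warning("all-zero covariate column(s): ",
            paste(colnames(X)[zero_cols], collapse = ", "))
  }
  blocks <- .default_blocks(spec)
  chol <- .coef_chol(y, X, FALSE, priors$bk, priors$b0)
  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + ch - 1L)
    init <- NULL
    for (try in seq_len(100L)) {
      cand <- .init_state(y, X, spec, priors, ch, chol = chol)
      lp <- tryCatch(
        log_posterior(cand, y, X, priors, spec, adjacency),
        error = function(e) -Inf)
      # also reject finite-but-absurd starts (exp overflow territory)
      eta_ok <- all(abs(linear_predictor(cand, X, spec$spatial)) < 50)
      if (is.finite(lp) && eta_ok) {
        init <- cand
        break
      }
    }
    if (is.null(init)) stop("could not find a finite starting point")
    chains[[ch]] <- .run_chain(y, X, spec, priors, adjacency, config, init,
                               blocks, chol = chol)
  }
  pn <- .param_names(spec, nrow(X), colnames(X))
  draws <- lapply(chains, function(c) {
    d <- c$draws
    colnames(d) <- pn
    d
  })
  structure(list(
    spec = spec, priors = priors, config = config,
    draws = draws,
    deviance = lapply(chains, `[[`, "deviance"),
    accept = lapply(chains, `[[`, "accept"),
    state = lapply(chains, `[[`, "state"),
    scales = lapply(chains, `[[`, "scales"),
    y = y, X = X, adjacency = adjacency,
    monitored = .monitored_names(spec, colnames(X))
  ), class = "speedcount_fit")
}

#' @export
print.speedcount_fit <- function(x, ...) {
  cat("speedcount_fit:", x$spec$label, "-", length(x$draws), "chains x",
      nrow(x$draws[[1]]), "stored draws,", ncol(x$draws[[1]]), "parameters\n")
  psrf <- gelman_rubin(x)
  cat("  max PSRF (monitored):", round(max(psrf), 4),
      " coef acceptance:", round(mean(sapply(x$accept, `[[`, "coef")), 3), "\n")
  invisible(x)
}

#' Sample from the joint prior through the MCMC kernels
#'
#' Runs the samplers with the likelihood switched off, so every update kernel
#' targets its prior. Recovering prior moments this way validates the
#' Metropolis kernels jointly (a standard sampler self-check).
#'
#' @param spec a [model_spec()].
#' @param S number of segments (sets the spatial/dispersion dimensions).
#' @param adjacency required for spatial specs.
#' @param priors a [prior_spec()].
#' @param config an [mcmc_config()].
#' @param blocks which update blocks to run (default: all that apply);
#'   list with logical `coefficients`, `spatial`, `variances`, `dispersion`.
#' @param init optional starting state.
#' @return a `speedcount_fit` with prior draws.
#' @export
sample_prior <- function(spec, S, adjacency = NULL, priors = prior_spec(),
                         config = mcmc_config(), blocks = NULL, init = NULL) {
  X <- matrix(0, S, spec$m)
  y <- rep(0, S)
  if (is.null(blocks)) blocks <- .default_blocks(spec)
  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + ch - 1L)
    st <- if (is.null(init)) .init_state(y, X, spec, priors, ch, flat = TRUE)
      else init
    chains[[ch]] <- .run_chain(y, X, spec, priors, adjacency, config, st,
                               blocks, flat_lik = TRUE)
  }
  pn <- .param_names(spec, S)
  draws <- lapply(chains, function(c) {
    d <- c$draws
    colnames(d) <- pn
    d
  })
  structure(list(
    spec = spec, priors = priors, config = config, draws = draws,
    deviance = lapply(chains, `[[`, "deviance"),
    accept = lapply(chains, `[[`, "accept"),
    state = lapply(chains, `[[`, "state"),
    y = y, X = X, adjacency = adjacency,
    monitored = .monitored_names(spec)
  ), class = "speedcount_fit")
}

.one_sweep <- function(state, y, X, spec, priors, adjacency, blocks,
                       flat_lik = FALSE, scales = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  cfg <- mcmc_config(n_chains = 2L, n_iter = 1L, burn_in = 0L)
  if (is.null(scales)) scales <- list(coef = 0.5, mu = 0.3, v = 0.3, r = 0.5)
  res <- .run_chain(y, X, spec, priors, adjacency, cfg, state, blocks,
                    flat_lik = flat_lik, n_iter = 1L, burn_in = 0L,
                    prop = scales)
  res$state
}

#' Single Metropolis update of the coefficient block
#'
#' One random-walk Metropolis update of (beta, a0) against their full
#' conditional. Exposed for kernel-level testing; [fit_model()] runs the same
#' kernel inside its chain loop.
#'
#' @param state parameter list (`beta`, `a0`, plus spatial/dispersion fields
#'   as required by `spec`).
#' @param y,X data (use `flat_lik = TRUE` for a prior-only update).
#' @param spec,priors,adjacency model definition.
#' @param flat_lik drop the likelihood term?
#' @return the updated state list.
#' @export
update_coefficients <- function(state, y, X, spec, priors = prior_spec(),
                                adjacency = NULL, flat_lik = FALSE,
                                scales = NULL) {
  .one_sweep(state, y, X, spec, priors, adjacency,
             list(coefficients = TRUE, spatial = FALSE, variances = FALSE,
                  dispersion = FALSE), flat_lik, scales)
}

#' Single Metropolis sweep over the spatial effects
#'
#' Updates every `mu_s` against likelihood times its ICAR full conditional and
#' every `v_s` against likelihood times its normal prior, then re-centers
#' `mu` to sum to zero per connected component with the removed mean absorbed
#' into the intercept.
#'
#' @inheritParams update_coefficients
#' @return the updated state list.
#' @export
update_spatial_effects <- function(state, y, X, spec, priors = prior_spec(),
                                   adjacency = NULL, flat_lik = FALSE,
                                   scales = NULL) {
  if (!spec$spatial) stop("spatial update requires a spatial model spec")
  .one_sweep(state, y, X, spec, priors, adjacency,
             list(coefficients = FALSE, spatial = TRUE, variances = FALSE,
                  dispersion = FALSE), flat_lik, scales)
}

#' Exact conjugate draw of the spatial variances
#'
#' `sigma_mu2 | mu ~ InvGamma(q0 + (S - G)/2, rho0 + quad/2)` with `quad` the
#' ICAR pairwise quadratic form, and `sigma_v2 | v ~ InvGamma(x0 + S/2,
#' z0 + sum(v - d0)^2 / 2)`.
#'
#' @inheritParams update_coefficients
#' @return the updated state list.
#' @export
update_variances <- function(state, y, X, spec, priors = prior_spec(),
                             adjacency = NULL) {
  if (!spec$spatial) stop("variance update requires a spatial model spec")
  .one_sweep(state, y, X, spec, priors, adjacency,
             list(coefficients = FALSE, spatial = FALSE, variances = TRUE,
                  dispersion = FALSE), flat_lik = TRUE)
}

#' Single Metropolis update of the dispersion parameters
#'
#' Random-walk on `log r_s` with Jacobian correction against the
#' negative-binomial likelihood times the Gamma(e0, j0) prior.
#'
#' @inheritParams update_coefficients
#' @return the updated state list.
#' @export
update_dispersion <- function(state, y, X, spec, priors = prior_spec(),
                              adjacency = NULL, flat_lik = FALSE,
                              scales = NULL) {
  if (spec$family != "negbin") stop("dispersion update requires a negbin spec")
  .one_sweep(state, y, X, spec, priors, adjacency,
             list(coefficients = FALSE, spatial = FALSE, variances = FALSE,
                  dispersion = TRUE), flat_lik, scales)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic PSRF per parameter: with `n` draws per chain, within-chain variance
#' `W` and between-chain variance `B` of the chain means,
#' `PSRF = sqrt(((n - 1)/n * W + B/n) / W)`. Values below 1.1 are taken as
#' convergence evidence.
#'
#' @param fit a `speedcount_fit`, or a list of equal-length draw matrices.
#' @param parameters parameter names to diagnose; defaults to the monitored
#'   scalar parameters of the fit (coefficients, intercept, variances,
#'   shared dispersion).
#' @return named numeric vector of PSRF values.
#' @export
gelman_rubin <- function(fit, parameters = NULL) {
  draws <- if (inherits(fit, "speedcount_fit")) fit$draws else fit
  if (length(draws) < 2) stop("need >= 2 chains")
  n <- unique(vapply(draws, nrow, 1L))
  if (length(n) != 1) stop("chains must have equal lengths")
  if (n < 10) stop("need >= 10 draws per chain")
  if (is.null(parameters)) {
    parameters <- if (inherits(fit, "speedcount_fit")) fit$monitored
      else colnames(draws[[1]])
  }
  vapply(parameters, function(p) {
    x <- sapply(draws, function(d) d[, p])
    W <- mean(apply(x, 2, stats::var))
    B_over_n <- stats::var(colMeans(x))
    if (W == 0) return(if (B_over_n == 0) 1 else Inf)
    sqrt(((n - 1) / n * W + B_over_n) / W)
  }, 1.0)
}

#' Export trace CSVs and trace plots
#'
#' Writes one CSV (`chain`, `iteration`, `value`; full 17-digit precision, so
#' a read-back reproduces the draws exactly) and one PNG trace plot per
#' monitored parameter.
#'
#' @param fit a `speedcount_fit`.
#' @param path output directory (created if missing).
#' @param parameters parameters to export; defaults to the monitored set.
#' @param plots render PNG trace plots as well?
#' @return invisibly, the paths of the CSV files written.
#' @export
export_traces <- function(fit, path, parameters = NULL, plots = TRUE) {
  if (is.null(parameters)) parameters <- fit$monitored
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  safe <- function(p) gsub("[^A-Za-z0-9_.-]", "_", p)
  for (p in parameters) {
    rows <- do.call(rbind, lapply(seq_along(fit$draws), function(ch) {
      data.frame(chain = ch, iteration = seq_len(nrow(fit$draws[[ch]])),
                 value = sprintf("%.17g", fit$draws[[ch]][, p]))
    }))
    f <- file.path(path, paste0("trace_", safe(p), ".csv"))
    utils::write.csv(rows, f, row.names = FALSE, quote = FALSE)
    files <- c(files, f)
    if (plots) {
      png_f <- file.path(path, paste0("trace_", safe(p), ".png"))
      grDevices::png(png_f, width = 900, height = 400)
      ylim <- range(sapply(fit$draws, function(d) range(d[, p])))
      graphics::plot(fit$draws[[1]][, p], type = "l", col = "steelblue",
                     ylim = ylim, xlab = "iteration", ylab = p,
                     main = paste("trace:", p))
      for (ch in seq_along(fit$draws)[-1]) {
        graphics::lines(fit$draws[[ch]][, p], col = "firebrick")
      }
      grDevices::dev.off()
    }
  }
  invisible(files)
}

#' Read traces written by [export_traces()]
#' @param path directory of trace CSVs.
#' @return named list of per-parameter data.frames.
#' @export
read_traces <- function(path) {
  fs <- list.files(path, pattern = "^trace_.*\\.csv$", full.names = TRUE)
  out <- lapply(fs, function(f) {
    d <- utils::read.csv(f)
    d$value <- as.numeric(d$value)
    d
  })
  names(out) <- sub("^trace_(.*)\\.csv$", "\\1", basename(fs))
  out
}
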