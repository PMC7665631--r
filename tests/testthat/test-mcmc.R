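test_that("zero-variance proposals leave the state unchanged", {
  st <- list(beta = c(0.5, -0.2), a0 = 1)
  zero <- list(coef = 0, mu = 0, v = 0, r = 0)
  st2 <- update_coefficients(st, c(3L, 4L), diag(2),
                             model_spec("poisson", FALSE, 2), scales = zero)
  expect_equal(as.numeric(st2$beta), st$beta)
  expect_equal(st2$a0, st$a0)
  stn <- list(beta = 0.1, a0 = 0, r = rep(2, 3))
  stn2 <- update_dispersion(stn, c(1L, 2L, 3L), matrix(0, 3, 1),
                            model_spec("negbin", FALSE, 1), scales = zero)
  expect_equal(as.numeric(stn2$r), stn$r)
})

test_that("with no data every kernel recovers its prior", {
  # coefficients: N(0, 10000); shared dispersion: Gamma(5, 0.5)
  spec <- model_spec("negbin", FALSE, 1, shared_r = TRUE)
  pr <- sample_prior(spec, S = 4,
                     config = mcmc_config(n_iter = 40000, burn_in = 5000,
                                          seed = 90))
  d <- do.call(rbind, pr$draws)
  n_eff <- 400  # conservative effective size for autocorrelated RW draws
  expect_lt(abs(mean(d[, "beta1"])), 3 * 100 / sqrt(n_eff))
  expect_equal(sd(d[, "beta1"]), 100, tolerance = 0.15)
  expect_equal(mean(d[, "r"]), 10, tolerance = 3 * sqrt(20 / n_eff) / 10)
  expect_equal(var(d[, "r"]), 20, tolerance = 0.3)
  # spatial block under a flat likelihood reproduces ICAR + iid moments
  W <- generate_road_network(20, seed = 6)$adjacency
  spec_sp <- model_spec("poisson", TRUE, 1)
  init <- list(beta = 0, a0 = 0, mu = rep(0, 20), v = rep(0, 20),
               sigma_mu2 = 0.5, sigma_v2 = 0.25)
  pr_sp <- sample_prior(spec_sp, S = 20, adjacency = W, init = init,
                        blocks = list(coefficients = FALSE, spatial = TRUE,
                                      variances = FALSE, dispersion = FALSE),
                        config = mcmc_config(n_iter = 30000, burn_in = 5000,
                                             seed = 91))
  d2 <- do.call(rbind, pr_sp$draws)
  q <- apply(d2[, paste0("mu[", 1:20, "]")], 1, icar_quadform, adjacency = W) /
    0.5
  df <- icar_df(W)
  expect_equal(mean(q), df, tolerance = 0.1)
  v_draws <- d2[, paste0("v[", 1:20, "]")]
  expect_equal(mean(v_draws^2), 0.25, tolerance = 0.05)
})

test_that("conjugate variance draws match the analytic inverse-gamma law", {
  W <- generate_road_network(15, seed = 8)$adjacency
  set.seed(92)
  eff <- sample_spatial_effects(W, 0.3, 0.1)
  st <- list(beta = 0, a0 = 0, mu = eff$mu, v = eff$v,
             sigma_mu2 = 1, sigma_v2 = 1)
  spec <- model_spec("poisson", TRUE, 1)
  X <- matrix(0, 15, 1)
  set.seed(93)
  draws_mu <- draws_v <- numeric(3000)
  cur <- st
  for (i in seq_len(3000)) {
    cur <- update_variances(cur, rep(0L, 15), X, spec, adjacency = W)
    draws_mu[i] <- cur$sigma_mu2
    draws_v[i] <- cur$sigma_v2
  }
  df <- icar_df(W)
  quad <- icar_quadform(eff$mu, W)
  pig <- function(x, a, b) pgamma(1 / x, a, rate = b, lower.tail = FALSE)
  ks1 <- ks.test(draws_mu, pig, a = 0.5 + df / 2, b = 5e-5 + quad / 2)
  ks2 <- ks.test(draws_v, pig, a = 0.5 + 15 / 2, b = 5e-5 + sum(eff$v^2) / 2)
  expect_gt(ks1$p.value, 0.01)
  expect_gt(ks2$p.value, 0.01)
  # degenerate fields give the prior-plus-dimension shapes exactly
  cur0 <- list(beta = 0, a0 = 0, mu = rep(1, 15), v = rep(0, 15),
               sigma_mu2 = 1, sigma_v2 = 1)
  set.seed(94)
  z <- replicate(2000, {
    s <- update_variances(cur0, rep(0L, 15), X, spec, adjacency = W)
    c(s$sigma_mu2, s$sigma_v2)
  })
  # 1/sigma2 ~ Gamma(q0 + df/2, rho0): compare means of the precision
  expect_equal(mean(1 / z[1, ]), (0.5 + df / 2) / 5e-5, tolerance = 0.1)
  expect_equal(mean(1 / z[2, ]), (0.5 + 15 / 2) / 5e-5, tolerance = 0.1)
})

test_that("dispersion updates recover prior and simulated truth", {
  # prior recovery is covered above; simulation recovery at informative n
  set.seed(95)
  S <- 400
  y <- rnbinom(S, size = 8, mu = 30)
  X <- matrix(0, S, 1)
  fit <- suppressWarnings(
    fit_model(y, X, model_spec("negbin", FALSE, 1, shared_r = TRUE),
              config = mcmc_config(n_iter = 8000, burn_in = 2000, seed = 96)))
  s <- summarize_posterior(fit, c("a0", "r"))
  expect_equal(exp(s$mean[1]), 30, tolerance = 0.1)
  expect_equal(s$mean[2], 8, tolerance = 0.25)
})

test_that("chains are reproducible and acceptance sits in the adapted band", {
  nw <- cached_network()
  truth <- default_truth("total", adjacency = nw$adjacency, seed = 97)
  y <- simulate_counts(nw, truth, seed = 98)
  cfg <- mcmc_config(n_iter = 4000, burn_in = 1500, seed = 99)
  spec <- model_spec("poisson", TRUE, 10)
  f1 <- fit_model(y, as.matrix(nw$covariates), spec, nw$adjacency, config = cfg)
  f2 <- fit_model(y, as.matrix(nw$covariates), spec, nw$adjacency, config = cfg)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$deviance, f2$deviance)
  for (acc in f1$accept) {
    expect_gt(acc$coef, 0.15)
    expect_lt(acc$coef, 0.6)
    expect_true(all(acc$mu > 0.15 & acc$mu < 0.6))
    expect_true(all(acc$v > 0.15 & acc$v < 0.6))
  }
})

test_that("posterior concentrates on the MLE for a strong one-parameter model", {
  set.seed(100)
  y <- rpois(200, 12)
  X <- matrix(0, 200, 1)
  fit <- suppressWarnings(
    fit_model(y, X, model_spec("poisson", FALSE, 1),
              config = mcmc_config(n_iter = 8000, burn_in = 2000,
                                   seed = 101)))
  d <- do.call(rbind, fit$draws)
  # numerical-integration oracle for the posterior mean of a0
  grid <- seq(log(mean(y)) - 0.2, log(mean(y)) + 0.2, length.out = 4001)
  logpost <- vapply(grid, function(a) {
    sum(dpois(y, exp(a), log = TRUE)) + dnorm(a, 0, 100, log = TRUE)
  }, 1.0)
  wgt <- exp(logpost - max(logpost))
  oracle_mean <- sum(grid * wgt) / sum(wgt)
  expect_equal(mean(d[, "a0"]), oracle_mean, tolerance = 0.01)
})

test_that("recentring leaves the likelihood invariant along the chain", {
  # deviance stored at each draw must equal deviance recomputed from the
  # stored parameters: any recentring inconsistency would break this
  nw <- generate_road_network(30, seed = 11)
  nw <- generate_covariates(nw, seed = 12)
  truth <- default_truth("total", adjacency = nw$adjacency, seed = 13)
  y <- simulate_counts(nw, truth, seed = 14)
  spec <- model_spec("poisson", TRUE, 10)
  fit <- fit_model(y, as.matrix(nw$covariates), spec, nw$adjacency,
                   config = mcmc_config(n_iter = 600, burn_in = 100, seed = 15))
  d <- fit$draws[[1]]
  for (i in c(1, 250, 500)) {
    st <- list(beta = d[i, 1:10], a0 = d[i, "a0"],
               mu = d[i, paste0("mu[", 1:30, "]")],
               v = d[i, paste0("v[", 1:30, "]")])
    expect_equal(model_deviance(st, y, as.matrix(nw$covariates), spec),
                 fit$deviance[[1]][i], tolerance = 1e-10)
  }
})

test_that("gelman_rubin reproduces the classic PSRF formula and edge cases", {
  set.seed(102)
  x <- matrix(rnorm(2e4), ncol = 2)
  chains <- list(cbind(p = x[, 1]), cbind(p = x[, 2]))
  expect_lt(gelman_rubin(chains, "p"), 1.01)
  same <- list(cbind(p = x[, 1]), cbind(p = x[, 1]))
  expect_lte(gelman_rubin(same, "p"), 1)
  apart <- list(cbind(p = x[, 1]), cbind(p = x[, 2] + 100))
  expect_gt(gelman_rubin(apart, "p"), 10)
  expect_error(gelman_rubin(list(cbind(p = x[, 1])), "p"), "2 chains")
  # literal recomputation of the classic formula on arbitrary chains
  y1 <- cumsum(rnorm(5000)) / 40 + rnorm(5000)
  y2 <- cumsum(rnorm(5000)) / 40 + rnorm(5000)
  ours <- gelman_rubin(list(cbind(p = y1), cbind(p = y2)), "p")
  n <- 5000
  Wv <- (var(y1) + var(y2)) / 2
  Bn <- var(c(mean(y1), mean(y2)))
  expect_equal(unname(ours), sqrt(((n - 1) / n * Wv + Bn) / Wv),
               tolerance = 1e-12)
  skip_if_not_installed("coda")
  # coda adds a sampling-df correction, so agreement is loose by design
  theirs <- coda::gelman.diag(coda::mcmc.list(coda::mcmc(y1), coda::mcmc(y2)),
                              autoburnin = FALSE)$psrf[1, 1]
  expect_equal(unname(ours), unname(theirs), tolerance = 0.15)
})

test_that("trace export round-trips draws exactly and renders plots", {
  nw <- generate_road_network(10, seed = 16)
  nw <- generate_covariates(nw, seed = 17)
  y <- simulate_counts(nw, default_truth("total", spatial = FALSE), seed = 18)
  fit <- suppressWarnings(
    fit_model(y, as.matrix(nw$covariates), model_spec("poisson", FALSE, 10),
              config = mcmc_config(n_iter = 300, burn_in = 100, seed = 19)))
  out <- withr::local_tempdir()
  files <- export_traces(fit, out)
  expect_length(files, length(fit$monitored))
  expect_true(all(file.exists(file.path(out, paste0(
    "trace_", gsub("[^A-Za-z0-9_.-]", "_", fit$monitored), ".png")))))
  back <- read_traces(out)
  tr <- back[["a0"]]
  for (ch in 1:2) {
    expect_identical(tr$value[tr$chain == ch],
                     unname(fit$draws[[ch]][, "a0"]))
  }
  expect_identical(nrow(tr), 2L * nrow(fit$draws[[1]]))
})

test_that("variance-split posterior matches the exact Gaussian-integral oracle", {
  # with large counts the field w = mu + v is pinned, so the marginal
  # posterior of the two variances given w is computable by eigen-integration
  nw <- generate_road_network(60, seed = 20)
  nw <- generate_covariates(nw, seed = 21)
  truth <- default_truth("total", adjacency = nw$adjacency, seed = 22)
  y <- simulate_counts(nw, truth, seed = 23)
  fit <- fit_model(y, as.matrix(nw$covariates), model_spec("poisson", TRUE, 10),
                   nw$adjacency, config = mcmc_config(seed = 24))
  pooled <- do.call(rbind, fit$draws)
  W <- nw$adjacency
  Q <- diag(rowSums(W)) - W
  eg <- eigen(Q, symmetric = TRUE)
  df <- icar_df(W)
  U <- eg$vectors[, seq_len(df)]
  lam <- eg$values[seq_len(df)]
  wt <- crossprod(U, truth$effects$mu + truth$effects$v)
  lp <- function(s2m, s2v) {
    sum(dnorm(wt, 0, sqrt(s2m / lam + s2v), log = TRUE)) -
      1.5 * log(s2m) - 5e-5 / s2m - 1.5 * log(s2v) - 5e-5 / s2v
  }
  g <- expand.grid(s2m = exp(seq(log(1e-5), log(1), length.out = 80)),
                   s2v = exp(seq(log(1e-3), log(1), length.out = 80)))
  g$w <- exp(mapply(lp, g$s2m, g$s2v) - max(mapply(lp, g$s2m, g$s2v)))
  wts <- g$w * g$s2m * g$s2v  # log-grid Jacobian
  oracle_v <- sum(g$s2v * wts) / sum(wts)
  expect_equal(mean(pooled[, "sigma_v2"]), oracle_v, tolerance = 0.25)
})
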