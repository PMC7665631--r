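fake_fit <- function(draws1, draws2 = draws1, monitored = colnames(draws1)) {
  structure(list(draws = list(draws1, draws2), monitored = monitored),
            class = "speedcount_fit")
}

test_that("posterior summaries follow the quantile oracle", {
  const <- fake_fit(cbind(b = rep(2.5, 50)))
  s <- summarize_posterior(const, "b")
  expect_equal(s$mean, 2.5)
  expect_equal(s$sd, 0)
  expect_equal(c(s$lower, s$upper), c(2.5, 2.5))
  expect_true(s$significant)
  set.seed(110)
  z <- fake_fit(cbind(b = rnorm(5e4)), cbind(b = rnorm(5e4)))
  s2 <- summarize_posterior(z, "b")
  expect_equal(s2$lower, qnorm(0.025), tolerance = 0.05)
  expect_equal(s2$upper, qnorm(0.975), tolerance = 0.05)
  expect_false(s2$significant)
  pos <- fake_fit(cbind(b = abs(rnorm(1000)) + 0.1))
  expect_true(summarize_posterior(pos, "b")$significant)
  # variance parameters carry no flag
  vfit <- fake_fit(cbind(sigma_mu2 = runif(100)))
  expect_true(is.na(summarize_posterior(vfit, "sigma_mu2")$significant))
})

test_that("deviance equals -2 log-likelihood with constants", {
  y <- c(3L, 0L, 12L)
  X <- matrix(rnorm(6), 3)
  st <- list(beta = c(0.2, -0.1), a0 = 1.5)
  spec <- model_spec("poisson", FALSE, 2)
  lam <- exp(linear_predictor(st, X, FALSE))
  expect_equal(model_deviance(st, y, X, spec),
               -2 * sum(dpois(y, lam, log = TRUE)), tolerance = 1e-12)
  # saturated case: deviance at lambda = y
  expect_equal(model_deviance(list(beta = 0, a0 = log(4)), 4L,
                              matrix(0, 1, 1), model_spec("poisson", FALSE, 1)),
               -2 * dpois(4, 4, log = TRUE), tolerance = 1e-12)
  # additivity under replication
  y2 <- rep(y, 2)
  X2 <- rbind(X, X)
  expect_equal(model_deviance(st, y2, X2, spec),
               2 * model_deviance(st, y, X, spec), tolerance = 1e-12)
})

test_that("DIC bookkeeping reproduces the identity and degenerate cases", {
  r <- dic_result(d_bar = 286137.000, p_d = 11.060)
  expect_equal(r$dic, 286148.060)
  expect_equal(r$d_hat, 286137.000 - 11.060)
  expect_equal(r$dic - r$d_bar, r$p_d, tolerance = 1e-10)
  expect_warning(dic_result(100, -2), "negative p_d")
  # a degenerate (constant) chain has p_d ~ 0 and dic = that deviance
  y <- c(5L, 7L)
  X <- matrix(0, 2, 1)
  d <- cbind(beta1 = c(0, 0), a0 = c(log(6), log(6)))
  fit <- structure(list(
    spec = model_spec("poisson", FALSE, 1), y = y, X = X,
    draws = list(d, d),
    deviance = list(rep(model_deviance(list(beta = 0, a0 = log(6)), y, X,
                                       model_spec("poisson", FALSE, 1)), 2),
                    rep(model_deviance(list(beta = 0, a0 = log(6)), y, X,
                                       model_spec("poisson", FALSE, 1)), 2))),
    class = "speedcount_fit")
  colnames(fit$X) <- "beta1"
  res <- dic(fit)
  expect_equal(res$p_d, 0, tolerance = 1e-10)
  expect_equal(res$dic, fit$deviance[[1]][1], tolerance = 1e-10)
})

test_that("well-identified two-parameter fits have a small effective size", {
  set.seed(111)
  x <- rbinom(300, 1, 0.5)
  y <- rpois(300, exp(1 + 0.5 * x))
  X <- matrix(x, dimnames = list(NULL, "x"))
  fit <- fit_model(y, X, model_spec("poisson", FALSE, 1),
                   config = mcmc_config(n_iter = 8000, burn_in = 2000,
                                        seed = 112))
  res <- dic(fit)
  expect_gt(res$p_d, 1)
  expect_lt(res$p_d, 3)
  expect_equal(res$dic - res$d_bar, res$p_d, tolerance = 1e-10)
})

test_that("model comparison applies the 5-point equivalence rule", {
  res <- list(BHSPLM = dic_result(2704.440, 241.050),
              BHSNBLM = dic_result(4124.600, 30.868))
  cmp <- compare_models(res)
  expect_identical(cmp$model[1], "BHSPLM")
  expect_equal(cmp$dic, c(2945.490, 4155.468))
  expect_equal(cmp$delta[2], 1209.978, tolerance = 1e-9)
  expect_identical(attr(cmp, "superior"), "BHSPLM")
  # serious-outcome spatial pair
  res2 <- list(BHSPLM = dic_result(2275.830, 176.503),
               BHSNBLM = dic_result(2401.750, 169.806))
  cmp2 <- compare_models(res2)
  expect_equal(cmp2$delta[2], 119.223, tolerance = 1e-9)
  # ties within 5 are equivalent, with no superior model
  res3 <- list(a = dic_result(100, 0), b = dic_result(103, 0))
  cmp3 <- compare_models(res3)
  expect_true(all(cmp3$equivalent_to_best))
  expect_true(is.na(attr(cmp3, "superior")))
  expect_error(compare_models(res3[1]), ">= 2")
})

test_that("spatial fraction reproduces the published arithmetic", {
  expect_equal(round(spatial_fraction_point(0.017, 0.038), 3), 0.309)
  expect_equal(round(spatial_fraction_point(0.013, 0.036), 3), 0.265)
  expect_equal(spatial_fraction_point(0.5, 0), 1)
  # invariant to common rescaling
  expect_equal(spatial_fraction_point(0.017, 0.038),
               spatial_fraction_point(1.7, 3.8), tolerance = 1e-12)
  expect_error(spatial_fraction_point(-0.1, 0.2), ">= 0")
  # per-draw version stays in (0, 1) and non-spatial fits are rejected
  set.seed(113)
  d <- cbind(sigma_mu2 = rgamma(500, 2, 10), sigma_v2 = rgamma(500, 2, 10))
  fit <- structure(list(spec = model_spec("poisson", TRUE, 1),
                        draws = list(d, d)), class = "speedcount_fit")
  fr <- spatial_fraction(fit)
  expect_true(all(fr$draws > 0 & fr$draws < 1))
  expect_true(fr$lower <= fr$mean && fr$mean <= fr$upper)
  fitns <- structure(list(spec = model_spec("poisson", FALSE, 1)),
                     class = "speedcount_fit")
  expect_error(spatial_fraction(fitns), "spatial")
})

test_that("backward elimination drops null effects and keeps real ones", {
  set.seed(114)
  n <- 300
  X <- cbind(x1 = rbinom(n, 1, 0.5), x2 = rbinom(n, 1, 0.5),
             x3 = rbinom(n, 1, 0.5))
  y <- rpois(n, exp(1.0 + 1.2 * X[, "x1"] - 0.8 * X[, "x3"]))
  sel <- select_significant(y, X, model_spec("poisson", FALSE, 3),
                            config = mcmc_config(n_iter = 4000,
                                                 burn_in = 1000, seed = 115))
  expect_setequal(sel$retained, c("x1", "x3"))
  expect_identical(sel$dropped$parameter, "x2")
  # nothing is dropped when every effect is huge
  y2 <- rpois(n, exp(0.5 + 2 * X[, "x1"] + 2 * X[, "x2"] - 2 * X[, "x3"]))
  sel2 <- select_significant(y2, X, model_spec("poisson", FALSE, 3),
                             config = mcmc_config(n_iter = 4000,
                                                  burn_in = 1000, seed = 116))
  expect_setequal(sel2$retained, c("x1", "x2", "x3"))
  expect_identical(nrow(sel2$dropped), 0L)
})
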