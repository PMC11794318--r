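test_that("logistic_mean matches its closed form and limits", {
  expect_equal(logistic_mean(5, beta = 10, gamma = 5, k = 1), 5)  # f(gamma)
  expect_equal(logistic_mean(6, beta = 10, gamma = 5, k = 1),
               10 / (1 + exp(-1)))
  expect_equal(logistic_mean(-1e6, 10, 5, 1), 0, tolerance = 1e-12)
  expect_equal(logistic_mean(1e6, 10, 5, 1), 10)
  expect_error(logistic_mean(1, 10, 5, k = 0), "k must be > 0")
  # monotone in week and in beta
  w <- seq(-5, 15, by = 0.5)
  expect_true(all(diff(logistic_mean(w, 10, 5, 1.5)) > 0))
  expect_true(all(logistic_mean(4, 12, 5, 1) > logistic_mean(4, 10, 5, 1)))
})

test_that("exp_correlation yields a valid correlation matrix", {
  reg <- site_registry(1:2, x_km = c(0, 1), y_km = c(0, 0))
  C <- exp_correlation(reg, rho = 1)
  expect_equal(diag(C), c("1" = 1, "2" = 1))
  expect_equal(C[1, 2], exp(-1))
  expect_error(exp_correlation(reg, rho = 0), "positive")
  # limits
  expect_equal(exp_correlation(reg, rho = 1e12)[1, 2], 1, tolerance = 1e-9)
  far <- site_registry(1:2, x_km = c(0, 1e9), y_km = c(0, 0))
  expect_equal(exp_correlation(far, rho = 1)[1, 2], 0)

  # property: symmetric, unit diagonal, entries in (0, 1], PSD, for random
  # registries and ranges
  set.seed(42)
  for (i in 1:20) {
    n <- sample(3:15, 1L)
    reg <- site_registry(seq_len(n), x_km = runif(n, 0, 50),
                         y_km = runif(n, 0, 50))
    C <- exp_correlation(reg, rho = runif(1, 0.5, 50))
    expect_equal(C, t(C))
    expect_equal(unname(diag(C)), rep(1, n))
    expect_true(all(C > 0 & C <= 1))
    expect_true(min(eigen(C, symmetric = TRUE,
                          only.values = TRUE)$values) > -1e-8)
  }
})

test_that("kriging reproduces closed forms", {
  # one training site: beta* = mu + exp(-d/rho) * (beta - mu)
  reg1 <- data.frame(site_id = 1L, x_km = 0, y_km = 0)
  post <- manual_posterior(reg1, beta = 2, gamma = 1, k = 1,
                           mu_beta = 0, rho_beta = 1)
  kp <- krige_params(post, data.frame(x_km = 1, y_km = 0))
  expect_equal(kp$beta_star[1, 1], 2 * exp(-1), tolerance = 1e-6)
  # far target reverts to the process mean
  post <- manual_posterior(reg1, beta = 2, gamma = 1, k = 1, mu_beta = 7,
                           mu_gamma = 3)
  kp <- krige_params(post, data.frame(x_km = 1e7, y_km = 0))
  expect_equal(kp$beta_star[1, 1], 7)
  expect_equal(kp$gamma_star[1, 1], 3)
  # coincident target interpolates the sampled parameter exactly
  reg2 <- site_registry(1:3, x_km = c(0, 3, 8), y_km = c(0, 4, 1))
  post <- manual_posterior(reg2, beta = c(5, 9, 2), gamma = c(4, 6, 5),
                           k = 1.2, mu_beta = 5, mu_gamma = 5,
                           rho_beta = 10, rho_gamma = 10)
  expect_message(
    kp <- krige_params(post, data.frame(x_km = 3, y_km = 4)),
    "coincide")
  expect_equal(kp$beta_star[1, 1], 9, tolerance = 1e-6)
  expect_equal(kp$gamma_star[1, 1], 6, tolerance = 1e-6)
})

test_that("kriging is invariant to rigid motion of the coordinates", {
  reg <- site_registry(1:4, x_km = c(0, 3, 8, 2), y_km = c(0, 4, 1, 7))
  post <- manual_posterior(reg, beta = c(5, 9, 2, 7), gamma = c(4, 6, 5, 3),
                           k = 1.2, mu_beta = 5, mu_gamma = 5,
                           rho_beta = 6, rho_gamma = 9)
  tgt <- data.frame(x_km = 4, y_km = 2)
  kp0 <- krige_params(post, tgt)
  th <- 0.7; Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- function(x, y) cbind(x, y) %*% Rm + 11
  xy <- rot(reg$x_km, reg$y_km)
  post_rot <- post
  post_rot$registry <- site_registry(1:4, xy[, 1], xy[, 2])
  txy <- rot(tgt$x_km, tgt$y_km)
  kp1 <- krige_params(post_rot, data.frame(x_km = txy[1], y_km = txy[2]))
  expect_equal(kp1$beta_star, kp0$beta_star, tolerance = 1e-8)
  expect_equal(kp1$gamma_star, kp0$gamma_star, tolerance = 1e-8)
})

test_that("predict_cumulative averages draws through the growth curve", {
  reg1 <- data.frame(site_id = 1L, x_km = 0, y_km = 0)
  # single draw at the training site: prediction equals logistic_mean
  post <- manual_posterior(reg1, beta = 10, gamma = 5, k = 1)
  pred <- predict_cumulative(post, reg1, weeks = 1:8)
  expect_equal(pred$pred, logistic_mean(1:8, 10, 5, 1), tolerance = 1e-6)
  # two draws with beta 10 and 20, same gamma and k, at week = gamma
  post2 <- manual_posterior(reg1, beta = rbind(10, 20),
                            gamma = rbind(5, 5), k = c(1, 1))
  pred2 <- predict_cumulative(post2, reg1, weeks = 5)
  expect_equal(pred2$pred, 7.5, tolerance = 1e-6)
  expect_error(predict_cumulative(post, reg1, weeks = integer()), "empty")
})

test_that("fit_growth_model validates preconditions", {
  sim <- generate_dataset(tiny_scenario())
  ds <- sim$dataset
  expect_error(fit_growth_model(ds, train_sites = 1L), "at least 2")
})

test_that("fit_growth_model recovers parameters from low-noise data", {
  scen <- tiny_scenario(L = 10L, seed = 21L, sigma2 = 1e-4)
  sim <- generate_dataset(scen)
  post <- suppressWarnings(
    fit_growth_model(sim$dataset, years = 2020:2022,
                     mcmc = mcmc_config(n_chains = 1L, n_warmup = 600L,
                                        n_iter = 600L, thin = 3L,
                                        seed = 4L)))
  bh <- colMeans(post$draws$beta)
  gh <- colMeans(post$draws$gamma)
  # the tiny schedule stops at week 8 while the asymptote sits near week
  # 6 + several k, so beta is mildly extrapolated: 5% relative tolerance on
  # the site medians would be optimistic for sites with late midpoints;
  # gamma and k are well identified
  expect_true(all(abs(bh - sim$truth$beta) / sim$truth$beta < 0.12))
  expect_true(all(abs(gh - sim$truth$gamma) < 0.35))
  expect_equal(mean(post$draws$k), sim$truth$k, tolerance = 0.1)
  expect_gt(cor(bh, sim$truth$beta), 0.98)
})

test_that("prediction at a training site reproduces the fitted curve", {
  sim <- generate_dataset(tiny_scenario(seed = 3L))
  post <- suppressWarnings(
    fit_growth_model(sim$dataset,
                     mcmc = mcmc_config(profile = "fast", seed = 9)))
  j <- 2L
  reg <- as.data.frame(post$registry)[j, ]
  pred <- suppressMessages(predict_cumulative(post, reg, weeks = 1:6))
  manual <- vapply(1:6, function(w) {
    mean(post$draws$beta[, j] *
           plogis((w - post$draws$gamma[, j]) / post$draws$k))
  }, numeric(1))
  expect_equal(pred$pred, manual, tolerance = 1e-5)
})

test_that("credible interval for k covers the truth across replicates", {
  # Calibration check for the sampler. Run at low observation noise so the
  # generator's monotone projection (which inflates near-zero early-season
  # cells and is a documented generator/model mismatch) does not bind, and
  # at the tiny schedule so 8 replicates fit the test budget.
  hits <- 0L
  n_rep <- 8L
  for (r in seq_len(n_rep)) {
    sim <- generate_dataset(tiny_scenario(L = 8L, seed = 100L + r,
                                          sigma2 = 0.01))
    post <- suppressWarnings(
      fit_growth_model(sim$dataset,
                       mcmc = mcmc_config(n_chains = 1L, n_warmup = 400L,
                                          n_iter = 800L, thin = 4L,
                                          seed = 200L + r)))
    ci <- quantile(post$draws$k, c(0.025, 0.975))
    if (ci[1L] <= 1.5 && 1.5 <= ci[2L]) hits <- hits + 1L
  }
  expect_gte(hits, ceiling(0.75 * n_rep))
})
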