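test_that("pure-noise data predict near the training mean", {
  sim <- simulate_met(J = 40, I = 5, p = 100,
                      varcomp = c(env = 0, line = 0, ge = 0, resid = 1),
                      seed = 30)
  sp <- split_env(sim, "E05")
  y <- sim$pheno$y
  fit <- gblup_fit(y[sp$train], sp$idx_train, sp$idx_test,
                   G = sim$G, H = sim$H,
                   iterations = 2000, burn_in = 500, thin = 2, seed = 31)
  m <- mean(y[sp$train])
  expect_true(all(abs(fit$yhat_test - m) <= 3 * fit$yhat_test_sd + 1e-12))
})

test_that("with fixed variance components the sampler matches the BLUP oracle", {
  sim <- simulate_met(J = 10, I = 3, p = 80,
                      varcomp = c(env = 1, line = 1, ge = 0.5, resid = 1),
                      seed = 32)
  sp <- split_env(sim, "E03")
  y <- sim$pheno$y
  vc <- c(env = 1, line = 1, ge = 0.5, resid = 1)
  oracle <- blup_oracle(y[sp$train], sp$idx_train, sp$idx_test,
                        sim$G, sim$H, vc)
  fit <- gblup_fit(y[sp$train], sp$idx_train, sp$idx_test,
                   G = sim$G, H = sim$H, iterations = 6000, burn_in = 1000,
                   thin = 2, seed = 33, fix_varcomp = vc)
  # batch-means Monte-Carlo standard error per test row
  nb <- 20L
  bsize <- floor(fit$n_kept / nb)
  bm <- sapply(seq_len(nb), function(b)
    colMeans(fit$yhat_test_draws[((b - 1) * bsize + 1):(b * bsize), ,
                                 drop = FALSE]))
  mcse <- apply(bm, 1, sd) / sqrt(nb)
  expect_true(all(abs(fit$yhat_test - oracle) <= 3 * mcse + 1e-8))
})

test_that("the oracle reduces to the GLS mean when genetic variances vanish", {
  sim <- simulate_met(J = 6, I = 3, p = 50, seed = 34)
  sp <- split_env(sim, "E02")
  y <- sim$pheno$y
  pred <- blup_oracle(y[sp$train], sp$idx_train, sp$idx_test, sim$G, sim$H,
                      c(env = 0, line = 0, ge = 0, resid = 1))
  expect_equal(unname(diff(range(pred))), 0, tolerance = 1e-12)
  expect_equal(pred[1], attr(pred, "mu_hat"), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("in the no-shrinkage limit predictions approach line training means", {
  # line variance huge, noise tiny, H = I, no GE: a line seen in training
  # is predicted at its own training mean
  J <- 4; I <- 3
  M <- rand_markers(J, 50, seed = 35)
  G <- genomic_kinship(M)
  env <- rep(c("E1", "E2"), each = J)
  line <- rep(rownames(M), 2)
  idx_tr <- obs_index(env, line, env_levels = c("E1", "E2", "E3"),
                      line_levels = rownames(M))
  idx_te <- obs_index(rep("E3", J), rownames(M),
                      env_levels = c("E1", "E2", "E3"),
                      line_levels = rownames(M))
  set.seed(36)
  l_eff <- c(1, 2, 3, 4)
  y <- 5 + rep(l_eff, 2) + rnorm(2 * J, sd = 1e-4)
  pred <- blup_oracle(y, idx_tr, idx_te, G, H = NULL,
                      c(env = 1e-6, line = 1e3, resid = 1e-6),
                      include_GE = FALSE)
  line_means <- tapply(y, line, mean)[rownames(M)]
  expect_equal(unname(pred), unname(line_means), tolerance = 1e-3,
               ignore_attr = TRUE)
})

test_that("oracle agrees with a brute-force Gaussian conditional", {
  sim <- simulate_met(J = 4, I = 3, p = 60, seed = 37)
  y <- sim$pheno$y
  sp <- split_env(sim, "E03")
  vc <- c(env = 1, line = 1, ge = 0.5, resid = 1)
  oracle <- blup_oracle(y[sp$train], sp$idx_train, sp$idx_test,
                        sim$G, sim$H, vc)
  # brute force: full joint covariance over all 12 cells, GLS mean,
  # conditional mean of the test block
  H <- unclass(sim$H); G <- unclass(sim$G)
  ei <- as.integer(sim$index$env); li <- as.integer(sim$index$line)
  K <- vc["env"] * H[ei, ei] + vc["line"] * G[li, li] +
    vc["ge"] * (H[ei, ei] * G[li, li]) + vc["resid"] * diag(12)
  Vi <- solve(K[sp$train, sp$train])
  mu <- sum(Vi %*% y[sp$train]) / sum(Vi)
  bf <- mu + K[sp$test, sp$train] %*% Vi %*% (y[sp$train] - mu)
  expect_lt(max(abs(oracle - drop(bf))), 1e-10)
})

test_that("lines with identical markers and phenotypes get identical predictions", {
  M <- rand_markers(6, 40, seed = 38)
  M[2, ] <- M[1, ]                    # lines 1 and 2 are genomic twins
  G <- genomic_kinship(M)
  lines <- rownames(M)
  env <- rep(c("E1", "E2"), each = 6)
  idx_tr <- obs_index(env, rep(lines, 2),
                      env_levels = c("E1", "E2", "E3"), line_levels = lines)
  idx_te <- obs_index(rep("E3", 6), lines,
                      env_levels = c("E1", "E2", "E3"), line_levels = lines)
  set.seed(39)
  y <- rnorm(12)
  y[c(2, 8)] <- y[c(1, 7)]            # identical phenotypes too
  fit <- gblup_fit(y, idx_tr, idx_te, G = G, H = NULL,
                   iterations = 800, burn_in = 200, thin = 2, seed = 40)
  expect_equal(fit$yhat_test[1], fit$yhat_test[2], tolerance = 1e-10)
})

test_that("the main-effects model equals the GE model with the GE variance pinned to zero", {
  sim <- simulate_met(J = 15, I = 4, p = 80,
                      varcomp = c(env = 0.5, line = 1, ge = 0, resid = 1),
                      seed = 41)
  sp <- split_env(sim, "E04")
  y <- sim$pheno$y
  f_main <- gblup_fit(y[sp$train], sp$idx_train, sp$idx_test, sim$G, sim$H,
                      include_GE = FALSE, iterations = 4000, burn_in = 1000,
                      thin = 2, seed = 42)
  f_ge0 <- gblup_fit(y[sp$train], sp$idx_train, sp$idx_test, sim$G, sim$H,
                     include_GE = TRUE, iterations = 4000, burn_in = 1000,
                     thin = 2, seed = 43, fix_varcomp = c(ge = 1e-10))
  mc <- 3 * (apply(f_main$yhat_test_draws, 2, sd) +
               apply(f_ge0$yhat_test_draws, 2, sd)) / sqrt(f_main$n_kept / 10)
  expect_true(all(abs(f_main$yhat_test - f_ge0$yhat_test) <= mc + 0.02))
})

test_that("posterior predictive means are robust to thinning", {
  sim <- simulate_met(J = 12, I = 3, p = 60, seed = 44)
  sp <- split_env(sim, "E03")
  y <- sim$pheno$y
  f2 <- gblup_fit(y[sp$train], sp$idx_train, sp$idx_test, sim$G, sim$H,
                  iterations = 5000, burn_in = 1000, thin = 2, seed = 45)
  f5 <- gblup_fit(y[sp$train], sp$idx_train, sp$idx_test, sim$G, sim$H,
                  iterations = 5000, burn_in = 1000, thin = 5, seed = 46)
  mc <- 3 * (f2$yhat_test_sd / sqrt(f2$n_kept / 10) +
               f5$yhat_test_sd / sqrt(f5$n_kept / 10))
  expect_true(all(abs(f2$yhat_test - f5$yhat_test) <= mc + 0.02))
})

test_that("variance-component posteriors match exact grid integration", {
  # independent oracle: the marginal posterior of the four variance
  # components on a small dataset, with the flat-prior intercept integrated
  # out analytically and the variances integrated on a log-spaced grid
  sim <- simulate_met(J = 8, I = 3, p = 60,
                      varcomp = c(env = 1, line = 1, ge = 0.5, resid = 1),
                      seed = 77)
  y <- sim$pheno$y; n <- length(y)
  H <- unclass(sim$H); G <- unclass(sim$G)
  ei <- as.integer(sim$index$env); li <- as.integer(sim$index$line)
  Me <- H[ei, ei]; Ml <- G[li, li]; Mg <- Me * Ml
  df0 <- 5; S0 <- (df0 + 2) / df0 * var(y) / 4
  log_prior <- function(s2) (-(df0 / 2 + 1)) * log(s2) - df0 * S0 / (2 * s2)
  log_lik <- function(th) {
    V <- th[1] * Me + th[2] * Ml + th[3] * Mg + th[4] * diag(n)
    ch <- chol(V)
    Vi1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
    Viy <- backsolve(ch, forwardsolve(t(ch), y))
    mu <- sum(Viy) / sum(Vi1)
    -sum(log(diag(ch))) - 0.5 * (sum(y * Viy) - mu^2 * sum(Vi1)) -
      0.5 * log(sum(Vi1))
  }
  gr <- exp(seq(log(0.06), log(10), length.out = 13))
  grids <- as.matrix(expand.grid(gr, gr, gr, gr))
  lw <- apply(grids, 1, function(th)
    log_lik(th) + sum(log_prior(th)) + sum(log(th)))  # log-grid Jacobian
  w <- exp(lw - max(lw)); w <- w / sum(w)
  oracle <- colSums(grids * w)
  fit <- gblup_fit(y, sim$index, NULL, sim$G, sim$H,
                   iterations = 8000, burn_in = 2000, thin = 2, seed = 9)
  est <- fit$varcomp$mean[match(c("env", "line", "ge", "resid"),
                                fit$varcomp$component)]
  expect_true(all(abs(est - oracle) / oracle < 0.10))
})

test_that("chain and kernel validation errors are raised", {
  sim <- simulate_met(J = 5, I = 2, p = 30, seed = 47)
  sp <- split_env(sim, "E02")
  y <- sim$pheno$y
  expect_error(gblup_fit(y[sp$train], sp$idx_train, NULL, sim$G, sim$H,
                         iterations = 100, burn_in = 200),
               "chain settings")
  G_bad <- unclass(sim$G)[1:3, 1:3]
  expect_error(gblup_fit(y[sp$train], sp$idx_train, NULL, G_bad, sim$H,
                         iterations = 300, burn_in = 100),
               "levels")
})
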