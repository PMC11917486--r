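# Shared small synthetic BLUE tables
small_sim <- function(seed = 5, n_genotypes = 30, n_harvests = 6,
                      K = matrix(c(4, 0.8, 0.8, 1.5), 2)) {
  simulate_blues(sim_config(n_genotypes = n_genotypes, n_harvests = n_harvests,
                            beta = c(10, 2, -3, 1), K_g = K,
                            error_variance = 2, seed = seed))
}

test_that("restricted likelihood matches the dense error-contrast oracle", {
  sim <- small_sim(seed = 2, n_genotypes = 3, n_harvests = 4)
  set.seed(31)
  for (i in 1:6) {
    th <- rnorm(4, 0, 1.2)
    expect_equal(reml_loglik(th, sim$blues, 2, 1),
                 dense_reml_oracle(th, sim$blues, 2, 1), tolerance = 1e-8)
  }
})

test_that("with K_g = 0 the likelihood reduces to weighted fixed regression", {
  sim <- small_sim(seed = 3, n_genotypes = 4, n_harvests = 5)
  bl <- sim$blues
  th <- c(-40, 0, -40, log(1.7)) # Cholesky diagonal ~ e-40: K numerically zero
  # direct weighted-regression restricted likelihood, V = s2 * diag(1/w)
  days <- sort(unique(bl$day))
  sc <- -1 + 2 * (bl$day - min(days)) / diff(range(days))
  X <- outer(sc, 0:2, `^`) %*% legendre_lambda(2)
  s2 <- 1.7
  V <- diag(s2 / bl$weight)
  Vi <- solve(V)
  A <- t(X) %*% Vi %*% X
  beta <- solve(A, t(X) %*% Vi %*% bl$blue)
  r <- bl$blue - drop(X %*% beta)
  ll <- -0.5 * ((nrow(bl) - 3) * log(2 * pi) + sum(log(s2 / bl$weight)) +
                  determinant(A)$modulus[1] + drop(t(r) %*% Vi %*% r))
  expect_equal(reml_loglik(th, bl, 2, 1), ll, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("restricted likelihood is invariant to row order", {
  sim <- small_sim(seed = 4, n_genotypes = 5, n_harvests = 5)
  th <- rrm_pack_theta(matrix(c(3, 0.5, 0.5, 1), 2), 1.3)
  set.seed(1)
  perm <- sample(nrow(sim$blues))
  expect_equal(reml_loglik(th, sim$blues[perm, ], 2, 1),
               reml_loglik(th, sim$blues, 2, 1), tolerance = 1e-10)
})

test_that("theta packing and unpacking round-trips the covariance", {
  K <- matrix(c(4, 1, 0.5, 1, 3, -0.2, 0.5, -0.2, 2), 3)
  th <- rrm_pack_theta(K, 0.7)
  up <- rrmforage:::unpack_theta(th, 3)
  expect_equal(up$K, K, tolerance = 1e-12)
  expect_equal(up$sigma_e2, 0.7, tolerance = 1e-12)
})

test_that("optimum dominates every tested starting point", {
  sim <- small_sim(seed = 6)
  fit <- rrm(sim$blues, 3, 1, n_starts = 4, seed = 2)
  expect_true(all(fit$loglik >= fit$start_logliks - 1e-6))
})

test_that("intercept-only fit matches the balanced one-way ANOVA/REML oracle", {
  # equal weights, fixed degree 0: the model is a one-way random-effects
  # layout whose REML solution has a closed form on balanced data
  set.seed(17)
  ng <- 40; nh <- 5
  u <- rnorm(ng, 0, 2)
  tab <- expand.grid(genotype = sprintf("g%02d", 1:ng), day = seq(0, 120, 30),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab$blue <- 50 + u[match(tab$genotype, sprintf("g%02d", 1:ng))] +
    rnorm(nrow(tab), 0, 1.5)
  tab$weight <- 1
  fit <- rrm(tab, fixed_degree = 0, random_degree = 0, n_starts = 3, seed = 1)
  aov_ms <- summary(stats::aov(blue ~ genotype, tab))[[1]]$`Mean Sq`
  sigma_e2_hat <- aov_ms[2]
  sigma_a2_hat <- (aov_ms[1] - aov_ms[2]) / nh
  expect_equal(fit$sigma_e2, sigma_e2_hat, tolerance = 1e-4)
  # random intercept enters through phi0 = sqrt(1/2): var = K[1,1] / 2
  expect_equal(fit$K[1, 1] / 2, sigma_a2_hat, tolerance = 1e-3)
})

test_that("noiseless fixed-curve data drive K_g to zero and recover beta", {
  days <- c(0, 40, 100, 160, 220)
  sc <- rescale_times(days)$scaled
  beta <- c(20, 4, -2, 1)
  tab <- expand.grid(genotype = paste0("g", 1:8), day = days,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab$blue <- rrmforage:::eval_legendre_curve(beta, sc)[match(tab$day, days)]
  tab$weight <- 1
  fit <- suppressWarnings(rrm(tab, 3, 0, n_starts = 2, seed = 1))
  expect_equal(unname(fit$beta), beta, tolerance = 1e-6)
  expect_lt(fit$K[1, 1], 1e-6)
})

test_that("doubling weights is equivalent to halving the residual scale", {
  sim <- small_sim(seed = 8)
  fit1 <- rrm(sim$blues, 3, 1, n_starts = 2, seed = 3)
  bl2 <- sim$blues; bl2$weight <- 2 * bl2$weight
  fit2 <- rrm(bl2, 3, 1, n_starts = 2, seed = 3)
  # sigma_e2 absorbs the rescaling (sigma_e2/pi is unchanged), so the fit
  # with doubled weights at sigma_e2 equals the original at sigma_e2/2
  expect_equal(fit2$sigma_e2 / fit1$sigma_e2, 2, tolerance = 1e-3)
  expect_equal(fit2$K, fit1$K, tolerance = 1e-4)
  expect_equal(predict(fit2), predict(fit1), tolerance = 1e-6)
})

test_that("BLUPs shrink toward zero relative to raw genotype residual means", {
  sim <- small_sim(seed = 9, K = matrix(2, 1, 1))
  fit <- rrm(sim$blues, 3, 0, n_starts = 2, seed = 1)
  bl <- fit$data
  days <- sort(unique(bl$day))
  sc <- rescale_times(days)$scaled
  fixed <- rrmforage:::eval_legendre_curve(fit$beta, sc)
  raw <- tapply(bl$blue - fixed[match(bl$day, days)], bl$genotype, mean)
  blup_effect <- fit$U[, 1] * sqrt(1 / 2) # phi0 u = intercept deviation
  expect_true(all(abs(blup_effect) <= abs(raw[rownames(fit$U)]) + 1e-8))
})

test_that("BIC counts variance parameters and penalizes by effective n", {
  sim <- small_sim(seed = 10)
  fit <- rrm(sim$blues, 3, 1, n_starts = 2, seed = 1)
  expect_equal(fit$n_vpar, 4) # two variances, one covariance, sigma_e2
  fit2 <- rrm(sim$blues, 3, 2, n_starts = 2, seed = 1)
  expect_equal(fit2$n_vpar, 7)
  expect_equal(fit$bic, -2 * fit$loglik + 4 * log(fit$n_obs - 4))
})

test_that("genotypes observed too sparsely are excluded but still predicted", {
  sim <- small_sim(seed = 12, n_genotypes = 10)
  bl <- sim$blues[!(sim$blues$genotype == "G001" & sim$blues$day > 0), ]
  expect_warning(fit <- rrm(bl, 3, 1, n_starts = 2, seed = 1), "excluded")
  expect_true("G001" %in% fit$excluded)
  expect_true("G001" %in% rownames(fit$U))
  expect_true(all(is.finite(fit$U["G001", ])))
})

test_that("prediction refuses extrapolation outside the harvest window", {
  sim <- small_sim(seed = 13)
  fit <- rrm(sim$blues, 2, 1, n_starts = 2, seed = 1)
  expect_error(predict(fit, days = max(fit$schedule$days) + 10), "window")
  expect_error(predict(fit, days = -5), "window")
})

test_that("fixed-degree rule counts smoothed extrema of the mean trajectory", {
  # strictly monotone trajectory: no interior extremum, a line suffices
  mono <- data.frame(genotype = "g", day = seq(0, 200, 25),
                     blue = 100 + 2 * seq(0, 200, 25), weight = 1)
  expect_equal(select_fixed_degree(mono), 1L)
  # one seasonal peak and one trough: cubic
  days <- seq(0, 330, 30)
  wave <- data.frame(genotype = "g", day = days,
                     blue = 2500 + 800 * sin(2 * pi * days / 365), weight = 1)
  expect_equal(select_fixed_degree(wave), 3L)
  # two full seasonal cycles over 12 harvests: four interior extrema
  # two full seasonal cycles: a narrower span is needed to track them
  wave2 <- data.frame(genotype = "g", day = days,
                      blue = 2500 + 800 * sin(2 * pi * days / 165), weight = 1)
  expect_equal(select_fixed_degree(wave2, span = 0.4), 5L)
  few <- data.frame(genotype = "g", day = c(0, 50), blue = c(1, 2), weight = 1)
  expect_warning(expect_equal(select_fixed_degree(few), 1L), "fewer than 3")
})

test_that("BIC selection distinguishes intercept-only from slope variation", {
  # pure intercept variation
  sim0 <- simulate_blues(sim_config(n_genotypes = 80, n_harvests = 8,
                                    beta = c(10, 2, -3), error_variance = 2,
                                    K_g = matrix(4, 1, 1), seed = 21))
  sel0 <- select_random_degree(sim0$blues, 2, m_max = 2, n_starts = 2, seed = 1)
  expect_equal(sel0$random_degree, 0)
  # strong slope variance
  sim1 <- simulate_blues(sim_config(n_genotypes = 80, n_harvests = 8,
                                    beta = c(10, 2, -3), error_variance = 2,
                                    K_g = matrix(c(4, 0, 0, 3), 2), seed = 22))
  sel1 <- select_random_degree(sim1$blues, 2, m_max = 2, n_starts = 2, seed = 1)
  expect_equal(sel1$random_degree, 1)
  # m_max = 0 returns 0 unconditionally
  sel <- select_random_degree(sim1$blues, 2, m_max = 0, n_starts = 2, seed = 1)
  expect_equal(sel$random_degree, 0)
})

test_that("fitted, residuals and logLik are mutually consistent", {
  sim <- small_sim(seed = 14)
  fit <- rrm(sim$blues, 3, 1, n_starts = 2, seed = 1)
  expect_equal(fitted(fit) + residuals(fit), fit$data$blue, tolerance = 1e-10)
  expect_equal(as.numeric(logLik(fit)), fit$loglik)
  gv <- predict(fit)
  expect_equal(dim(gv), c(30, 6))
})
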