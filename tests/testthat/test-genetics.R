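test_that("genetic covariance is the basis congruence of K_g", {
  fit0 <- make_fake_fit(beta = c(10, 1), U = matrix(0, 3, 1),
                        K = matrix(0, 1, 1))
  expect_true(all(genetic_covariance(fit0) == 0))
  # intercept-only model: every entry is phi0^2 * k = k / 2
  fitk <- make_fake_fit(beta = c(10, 1), U = matrix(0, 3, 1),
                        K = matrix(6, 1, 1))
  expect_equal(unname(genetic_covariance(fitk)),
               matrix(3, 3, 3), tolerance = 1e-12)
  # congruence preserves positive semidefiniteness
  set.seed(3)
  for (i in 1:5) {
    L <- matrix(rnorm(9), 3)
    K <- crossprod(L)
    fit <- make_fake_fit(beta = c(1, 1, 1), U = matrix(0, 2, 3),
                         days = c(0, 30, 90, 150), K = K)
    sg <- genetic_covariance(fit)
    ev <- eigen(sg, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10 * sum(diag(sg)))
  }
})

test_that("covariance-to-correlation conversion and summary behave", {
  res <- genetic_correlations(diag(3))
  expect_equal(res$corr, diag(3), ignore_attr = TRUE)
  expect_equal(res$mean, 0)
  res2 <- genetic_correlations(matrix(c(4, 2, 2, 4), 2))
  expect_equal(res2$corr[1, 2], 0.5)
  # intercept-only genetic structure: all harvests perfectly correlated
  fitk <- make_fake_fit(beta = c(10, 1), U = matrix(0, 3, 1),
                        K = matrix(6, 1, 1), days = c(0, 40, 100, 200))
  resk <- genetic_correlations(genetic_covariance(fitk))
  expect_equal(unname(resk$corr), matrix(1, 4, 4), tolerance = 1e-10)
  expect_warning(genetic_correlations(diag(c(1, 0))), "zero genetic variance")
})

test_that("correlations decay with time gap under negative intercept-slope covariance", {
  K <- matrix(c(4, -1.5, -1.5, 1), 2)
  fit <- make_fake_fit(beta = c(1, 1), U = matrix(0, 2, 2),
                       days = seq(0, 200, 50), K = K)
  cg <- genetic_correlations(genetic_covariance(fit))$corr
  first_row <- cg[1, -1]
  expect_true(all(diff(first_row) < 0))
})

test_that("heritability trajectory follows its variance-ratio definition", {
  sg <- diag(c(2, 4, 8))
  expect_equal(unname(heritability_trajectory(sg, 0, 3)), rep(1, 3))
  expect_equal(unname(heritability_trajectory(diag(c(1, 1)), 2, 2)),
               c(0.5, 0.5))
  h2_r2 <- heritability_trajectory(sg, 3, 2)
  h2_r4 <- heritability_trajectory(sg, 3, 4)
  expect_true(all(h2_r4 >= h2_r2))
  expect_true(all(h2_r2 >= 0 & h2_r2 <= 1))
  expect_error(heritability_trajectory(sg, 3, 0), "reps")
})

test_that("heritability is invariant to the yield scale", {
  sg <- matrix(c(4, 1, 1, 2), 2)
  c2 <- 7.3^2
  expect_equal(heritability_trajectory(sg * c2, 5 * c2, 3),
               heritability_trajectory(sg, 5, 3), tolerance = 1e-10)
})

test_that("mean error variance averages the per-harvest estimates", {
  expect_equal(mean_error_variance(c(2, 4)), 3)
  expect_equal(mean_error_variance(c(5)), 5)
  tab <- data.frame(harvest = c("H1", "H1", "H2"), error_variance = c(2, 2, 4))
  expect_equal(mean_error_variance(tab), 3)
})

test_that("eigenfunctions decompose K_g with the stated conventions", {
  # intercept-only variation: flat leading eigenfunction carrying 100%
  ef <- eigenfunctions(matrix(c(5, 0, 0, 0), 2), grid_n = 51)
  expect_equal(ef$importance_pct, c(100, 0))
  expect_equal(ef$curves[, 1], rep(sqrt(1 / 2), 51), ignore_attr = TRUE)
  # degenerate spectrum: equal shares
  ef2 <- eigenfunctions(diag(2), grid_n = 51)
  expect_equal(ef2$importance_pct, c(50, 50))
  # importance always sums to 100; reconstruction matches the congruence
  set.seed(8)
  L <- matrix(rnorm(9), 3)
  K <- crossprod(L)
  ef3 <- eigenfunctions(K, grid_n = 41)
  expect_equal(sum(ef3$importance_pct), 100, tolerance = 1e-6)
  fit <- make_fake_fit(beta = c(1, 0, 0), U = matrix(0, 2, 3),
                       days = c(0, 50, 120, 200), K = K)
  phi2 <- legendre_phi(fit$schedule$scaled, 2)$phi
  recon <- phi2 %*% ef3$vectors %*% diag(ef3$values) %*%
    t(ef3$vectors) %*% t(phi2)
  expect_equal(unname(recon), unname(genetic_covariance(fit)),
               tolerance = 1e-10)
  # sign convention: the largest-magnitude loading is positive
  expect_true(all(apply(ef3$vectors, 2, function(v) v[which.max(abs(v))] > 0)))
  expect_error(eigenfunctions(matrix(c(1, 2, 2, 1), 2)), "negative eigenvalue")
})

test_that("genotypic values combine the fixed curve and BLUP deviations", {
  beta <- c(10, 2, -1)
  days <- c(0, 60, 150)
  sc <- rescale_times(days)$scaled
  fixed <- rrmforage:::eval_legendre_curve(beta, sc)
  # zero BLUPs: every genotype sits on the fixed curve
  fit0 <- make_fake_fit(beta, U = matrix(0, 4, 2), days = days)
  gv0 <- genotypic_values(fit0)
  expect_equal(unname(gv0), matrix(fixed, 4, 3, byrow = TRUE),
               tolerance = 1e-12)
  # intercept-only deviation shifts the curve by phi0 * u everywhere
  fit1 <- make_fake_fit(beta, U = matrix(3, 1, 1), days = days)
  expect_equal(drop(genotypic_values(fit1)), fixed + sqrt(1 / 2) * 3,
               ignore_attr = TRUE)
})

test_that("BLUPs near-center and the summary layer is coherent on real fits", {
  sim <- simulate_blues(sim_config(n_genotypes = 40, n_harvests = 6,
                                   beta = c(10, 2, -3, 1),
                                   K_g = matrix(c(4, 0.8, 0.8, 1.5), 2),
                                   error_variance = 2, seed = 15))
  fit <- rrm(sim$blues, 3, 1, n_starts = 2, seed = 1)
  gv <- genotypic_values(fit)
  sc <- fit$schedule$scaled
  fixed <- rrmforage:::eval_legendre_curve(fit$beta, sc)
  # on balanced data BLUP deviations average out across genotypes
  dev <- colMeans(gv) - fixed
  expect_lt(max(abs(dev)) / stats::sd(gv), 0.1)
  s <- summary(fit, reps = 1)
  expect_true(all(s$h2 >= 0 & s$h2 <= 1))
  expect_true(all(abs(s$corr_g[!is.na(s$corr_g)]) <= 1 + 1e-12))
  expect_equal(sum(s$eigen$importance_pct), 100, tolerance = 1e-6)
})
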