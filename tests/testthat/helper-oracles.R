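# Independent oracles and small fixtures shared across test files. None of
# these reuse the package's computational path for the quantity they check.

# Simpson quadrature of f on [-1, 1] over n+1 points (n even).
simpson_quad <- function(fvals, a = -1, b = 1) {
  n <- length(fvals) - 1L
  stopifnot(n %% 2L == 0L)
  h <- (b - a) / n
  w <- c(1, rep(c(4, 2), length.out = n - 1L), 1)
  h / 3 * sum(w * fvals)
}

# Dense restricted log-likelihood via orthonormal error contrasts: the
# Gaussian log-density of Q2'y with Q2 an orthonormal basis of the null space
# of X', shifted by the constant 0.5 log|X'X| to the package's convention.
dense_reml_oracle <- function(theta, blues, d, m) {
  blues <- blues[order(blues$genotype, blues$day), ]
  days <- sort(unique(blues$day))
  sc <- -1 + 2 * (blues$day - min(days)) / diff(range(days))
  lam1 <- legendre_lambda(d)
  lam2 <- legendre_lambda(m)
  X <- outer(sc, 0:d, `^`) %*% lam1
  P <- outer(sc, 0:m, `^`) %*% lam2
  g <- factor(blues$genotype)
  n <- nrow(blues)
  q <- m + 1L
  Z <- matrix(0, n, nlevels(g) * q)
  for (i in seq_len(n)) {
    Z[i, ((as.integer(g[i]) - 1L) * q + 1L):(as.integer(g[i]) * q)] <- P[i, ]
  }
  nk <- q * (q + 1L) / 2L
  L <- matrix(0, q, q)
  pos <- 1L
  for (j in seq_len(q)) for (i in j:q) {
    L[i, j] <- if (i == j) exp(theta[pos]) else theta[pos]
    pos <- pos + 1L
  }
  K <- L %*% t(L)
  s2 <- exp(theta[nk + 1L])
  V <- Z %*% kronecker(diag(nlevels(g)), K) %*% t(Z) + s2 * diag(1 / blues$weight)
  Q2 <- qr.Q(qr(X), complete = TRUE)[, (ncol(X) + 1L):n, drop = FALSE]
  KtY <- drop(crossprod(Q2, blues$blue))
  ch <- chol(crossprod(Q2, V %*% Q2))
  llc <- -0.5 * ((n - ncol(X)) * log(2 * pi) + 2 * sum(log(diag(ch))) +
                   sum(backsolve(ch, KtY, transpose = TRUE)^2))
  llc - 0.5 * determinant(crossprod(X))$modulus[1]
}

# GLS solution for genotype effects given explicit design matrices and known
# variance components: BLUE = (X'V^-1 X)^-1 X'V^-1 y.
gls_oracle <- function(y, X, Z, sigma_u2, sigma_e2) {
  V <- Z %*% t(Z) * sigma_u2 + diag(sigma_e2, length(y))
  Vi <- solve(V)
  A <- solve(t(X) %*% Vi %*% X)
  list(blues = drop(A %*% t(X) %*% Vi %*% y), vcov = A)
}

# Minimal rrm object for method-level tests that do not need a real fit.
make_fake_fit <- function(beta, U, days = c(0, 50, 100), K = NULL,
                          sigma_e2 = 1, reps = 1) {
  U <- as.matrix(U)
  if (is.null(rownames(U))) rownames(U) <- paste0("G", seq_len(nrow(U)))
  K <- K %||% diag(ncol(U))
  structure(list(beta = beta, U = U, K = K, sigma_e2 = sigma_e2,
                 loglik = NA_real_, bic = NA_real_,
                 fixed_degree = length(beta) - 1L,
                 random_degree = ncol(U) - 1L,
                 schedule = rescale_times(days), reps = reps,
                 n_obs = nrow(U) * length(days), n_genotypes = nrow(U),
                 n_vpar = ncol(U) * (ncol(U) + 1) / 2 + 1,
                 n_eff = nrow(U) * length(days) - length(beta),
                 excluded = character(), converged = TRUE),
            class = "rrm")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small balanced RCBD plot table with additive genotype and block effects.
make_rcbd_plots <- function(geno_effects, block_effects, noise = NULL,
                            base = 100) {
  ng <- length(geno_effects)
  nb <- length(block_effects)
  df <- expand.grid(genotype = paste0("g", seq_len(ng)),
                    block = seq_len(nb), KEEP.OUT.ATTRS = FALSE,
                    stringsAsFactors = FALSE)
  df$yield <- base + geno_effects[match(df$genotype, paste0("g", seq_len(ng)))] +
    block_effects[df$block]
  if (!is.null(noise)) df$yield <- df$yield + noise
  df
}
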