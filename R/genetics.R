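#' Genetic covariance across harvest times
#'
#' The coefficient covariance \eqn{K_g} induces the genetic
#' variance–covariance matrix across the observed harvest times by the
#' congruence \eqn{\Sigma_g = \Phi_2 K_g \Phi_2'}, with \eqn{\Phi_2} the
#' normalized Legendre basis of the random regression evaluated at the
#' rescaled harvest times.
#'
#' @param fit an `rrm` object.
#' @param days optional vector of days at which to evaluate (defaults to the
#'   observed harvest days; must lie inside the harvest window).
#' @return symmetric positive-semidefinite matrix, harvests by harvests.
#' @export
genetic_covariance <- function(fit, days = NULL) {
  stopifnot(inherits(fit, "rrm"))
  days <- days %||% fit$schedule$days
  rng <- range(fit$schedule$days)
  sc <- -1 + 2 * (days - rng[1]) / (rng[2] - rng[1])
  phi2 <- legendre_phi(sc, fit$random_degree)$phi
  sg <- phi2 %*% fit$K %*% t(phi2)
  dimnames(sg) <- list(signif(days, 8), signif(days, 8))
  0.5 * (sg + t(sg))
}

#' Genetic correlations between harvests
#'
#' Converts a genetic covariance matrix to correlations and summarizes the
#' strict upper triangle by its mean and standard deviation, the usual
#' single-number description of how stable genotype rankings are across
#' harvests. Harvests with zero genetic variance get undefined correlations
#' and are excluded from the summary.
#'
#' @param sigma_g genetic covariance matrix, e.g. from
#'   [genetic_covariance()].
#' @return list with `corr` (correlation matrix, `NA` rows for zero-variance
#'   harvests), `mean` and `sd` of the off-diagonal correlations.
#' @export
genetic_correlations <- function(sigma_g) {
  sigma_g <- as.matrix(sigma_g)
  d <- diag(sigma_g)
  ok <- d > 1e-12 * max(d, 1e-300)
  if (!all(ok)) {
    warning(sum(!ok), " harvest(s) with zero genetic variance excluded from ",
            "correlation summary")
  }
  corr <- matrix(NA_real_, nrow(sigma_g), ncol(sigma_g),
                 dimnames = dimnames(sigma_g))
  s <- sqrt(d[ok])
  corr[ok, ok] <- sigma_g[ok, ok] / tcrossprod(s)
  diag(corr)[ok] <- 1
  up <- corr[ok, ok][upper.tri(corr[ok, ok])]
  list(corr = corr,
       mean = if (length(up)) mean(up) else NA_real_,
       sd = if (length(up) > 1) stats::sd(up) else NA_real_)
}

#' Heritability trajectory over harvests
#'
#' Genotype-mean-based heritability at each harvest time:
#' \deqn{H_j^2 = \frac{\mathrm{diag}(\Sigma_g)_j}
#'                    {\mathrm{diag}(\Sigma_g)_j + \bar\sigma_e^2 / r},}
#' where \eqn{\bar\sigma_e^2} is the mean stage-1 error variance across
#' harvests and \eqn{r} the replication count of the trial.
#'
#' @param sigma_g genetic covariance across harvests.
#' @param sigma_e_bar mean error variance across harvests (non-negative).
#' @param reps number of replications, at least 1.
#' @return numeric vector of per-harvest heritabilities in \eqn{[0, 1]}.
#' @export
heritability_trajectory <- function(sigma_g, sigma_e_bar, reps) {
  if (length(reps) != 1L || !is.finite(reps) || reps < 1) {
    stop("'reps' must be a single number >= 1")
  }
  if (!is.finite(sigma_e_bar) || sigma_e_bar < 0) {
    stop("'sigma_e_bar' must be finite and non-negative")
  }
  g <- diag(as.matrix(sigma_g))
  h2 <- g / (g + sigma_e_bar / reps)
  h2[g == 0 & sigma_e_bar == 0] <- 0  # 0/0: no variance at all
  h2
}

#' Mean error variance across harvests
#'
#' Arithmetic mean of the per-harvest stage-1 error-variance estimates,
#' the \eqn{\bar\sigma_e^2} entering the heritability trajectory.
#'
#' @param x a `blue_table` (with `error_variance` column or
#'   `"harvest_error_variances"` attribute) or a numeric vector of
#'   per-harvest error variances.
#' @return scalar mean error variance.
#' @export
mean_error_variance <- function(x) {
  if (is.numeric(x)) return(mean(x))
  hv <- attr(x, "harvest_error_variances")
  if (!is.null(hv)) return(mean(hv))
  x <- as.data.frame(x)
  if (!all(c("harvest", "error_variance") %in% names(x))) {
    stop("no per-harvest error variances available")
  }
  u <- unique(x[, c("harvest", "error_variance")])
  mean(u$error_variance)
}

#' Eigenfunctions of the coefficient covariance
#'
#' Eigendecomposes \eqn{K_g} and forms each eigenfunction
#' \eqn{\Psi_k(t) = \sum_m (v_k)_m \phi_m(t)} on a dense grid over
#' \eqn{[-1, 1]}. A nearly constant leading eigenfunction indicates a gene
#' pool expressed uniformly over time; higher eigenfunctions describe the
#' time-dependent deformations that drive genotype-by-harvest interaction.
#' Importance is reported both as eigenvalue shares and as shares of the
#' \eqn{K_g} diagonal (intercept/slope/... coefficient variances).
#'
#' @param fit an `rrm` object (or a symmetric PSD matrix).
#' @param grid_n grid resolution.
#' @return list with `values` (descending eigenvalues), `vectors`,
#'   `importance_pct` (eigenvalue shares summing to 100),
#'   `diag_share_pct` (coefficient-variance shares), `grid`, and `curves`
#'   (grid by k matrix of eigenfunction values). Eigenvector signs follow the
#'   largest-magnitude-loading-positive convention.
#' @export
eigenfunctions <- function(fit, grid_n = 201L) {
  K <- if (inherits(fit, "rrm")) fit$K else as.matrix(fit)
  if (max(abs(K - t(K))) > 1e-8 * max(abs(K), 1)) {
    stop("K_g must be symmetric")
  }
  ee <- eigen(0.5 * (K + t(K)), symmetric = TRUE)
  tr <- sum(diag(K))
  if (any(ee$values < -1e-10 * max(tr, 1e-300))) {
    stop("K_g has a negative eigenvalue beyond tolerance: not a valid covariance")
  }
  vals <- pmax(ee$values, 0)
  vecs <- ee$vectors
  for (k in seq_len(ncol(vecs))) {
    j <- which.max(abs(vecs[, k]))
    if (vecs[j, k] < 0) vecs[, k] <- -vecs[, k]
  }
  grid <- seq(-1, 1, length.out = grid_n)
  phi <- legendre_phi(grid, nrow(K) - 1L)$phi
  curves <- phi %*% vecs
  colnames(curves) <- paste0("psi", seq_len(ncol(vecs)))
  imp <- if (sum(vals) > 0) 100 * vals / sum(vals) else rep(NA_real_, length(vals))
  dsh <- if (tr > 0) 100 * diag(K) / tr else rep(NA_real_, nrow(K))
  list(values = vals, vectors = vecs, importance_pct = imp,
       diag_share_pct = dsh, grid = grid, curves = curves)
}

#' Genotypic-value matrix across harvests
#'
#' The reaction-norm surface on the original yield scale:
#' \eqn{GV = J \beta' \Phi_1' + U_g \Phi_2'}, one row per genotype, one
#' column per requested time.
#'
#' @inheritParams predict.rrm
#' @param fit an `rrm` object.
#' @return matrix of genotypic values (kg/ha), genotypes by times.
#' @export
genotypic_values <- function(fit, days = NULL, genotypes = NULL) {
  predict(fit, days = days, genotypes = genotypes)
}
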