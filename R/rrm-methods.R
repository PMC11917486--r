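#' @export
print.rrm <- function(x, digits = 4, ...) {
  cat("Weighted random regression model (REML)\n")
  cat(sprintf("  %d genotypes, %d harvests over %g days, %d observations\n",
              x$n_genotypes, length(x$schedule$days),
              diff(range(x$schedule$days)), x$n_obs))
  cat(sprintf("  fixed degree %d, random degree %d\n",
              x$fixed_degree, x$random_degree))
  cat(sprintf("  REML log-likelihood %.*f, BIC %.*f\n",
              digits, x$loglik, digits, x$bic))
  cat("  fixed Legendre coefficients:\n")
  print(round(x$beta, digits))
  cat("  coefficient covariance K_g:\n")
  print(round(x$K, digits))
  cat(sprintf("  residual scale sigma_e^2 = %.*g\n", digits, x$sigma_e2))
  if (length(x$excluded)) {
    cat("  excluded from variance estimation:",
        paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
coef.rrm <- function(object, ...) object$beta

#' Genotype random-coefficient BLUPs
#'
#' @param object an `rrm` fit.
#' @return matrix, genotypes by Legendre coefficients.
#' @export
ranef_rrm <- function(object) {
  stopifnot(inherits(object, "rrm"))
  object$U
}

#' @export
logLik.rrm <- function(object, ...) {
  structure(object$loglik, df = object$n_vpar + length(object$beta),
            nobs = object$n_obs, class = "logLik")
}

#' @export
fitted.rrm <- function(object, ...) {
  dat <- object$data
  days <- object$schedule$days
  sc <- object$schedule$scaled[match(dat$day, days)]
  f <- eval_legendre_curve(object$beta, sc)
  lam2 <- legendre_lambda(object$random_degree)
  P <- outer(sc, 0:object$random_degree, `^`) %*% lam2
  u <- object$U[match(as.character(dat$genotype), rownames(object$U)), ,
                drop = FALSE]
  f + rowSums(P * u)
}

#' @export
residuals.rrm <- function(object, ...) {
  object$data$blue - fitted(object)
}

#' Predict genotypic values from a fitted random regression model
#'
#' Evaluates each genotype's reaction norm (fixed curve plus its BLUP
#' deviation) at the requested days. Prediction is confined to the observed
#' harvest window: polynomial extrapolation outside \eqn{[t_{min}, t_{max}]}
#' is refused.
#'
#' @param object an `rrm` fit.
#' @param days numeric vector of days since first harvest; default the
#'   observed harvest days.
#' @param genotypes character vector of genotypes; default all.
#' @param ... unused.
#' @return matrix of genotypic values, genotypes by days.
#' @export
predict.rrm <- function(object, days = NULL, genotypes = NULL, ...) {
  days <- days %||% object$schedule$days
  rng <- range(object$schedule$days)
  if (any(days < rng[1] - 1e-9) || any(days > rng[2] + 1e-9)) {
    stop("prediction outside the observed harvest window [", rng[1], ", ",
         rng[2], "] days is not supported")
  }
  sc <- -1 + 2 * (days - rng[1]) / (rng[2] - rng[1])
  genotypes <- genotypes %||% rownames(object$U)
  miss <- setdiff(genotypes, rownames(object$U))
  if (length(miss)) stop("unknown genotypes: ", paste(miss, collapse = ", "))
  f <- eval_legendre_curve(object$beta, sc)
  lam2 <- legendre_lambda(object$random_degree)
  P <- outer(sc, 0:object$random_degree, `^`) %*% lam2
  gv <- matrix(rep(f, each = length(genotypes)), nrow = length(genotypes),
               dimnames = list(genotypes, signif(days, 8)))
  gv + object$U[genotypes, , drop = FALSE] %*% t(P)
}

#' Simulate new BLUE tables from a fitted model
#'
#' Draws fresh genotype coefficient matrices from \eqn{N(0, K_g)} and new
#' residuals at the fitted \eqn{\sigma_e^2} and observed weights, i.e. a
#' parametric bootstrap of the fitted model at the observed design.
#'
#' @param object an `rrm` fit.
#' @param nsim number of replicate tables.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return list of `nsim` BLUE tables shaped like `object$data`.
#' @export
simulate.rrm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  dat <- object$data
  days <- object$schedule$days
  sc <- object$schedule$scaled[match(dat$day, days)]
  f <- eval_legendre_curve(object$beta, sc)
  lam2 <- legendre_lambda(object$random_degree)
  P <- outer(sc, 0:object$random_degree, `^`) %*% lam2
  genos <- rownames(object$U)
  gidx <- match(as.character(dat$genotype), genos)
  out <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    U <- rmvnorm_chol(length(genos), object$K)
    mu <- f + rowSums(P * U[gidx, , drop = FALSE])
    e <- stats::rnorm(nrow(dat), 0, sqrt(object$sigma_e2 / dat$weight))
    sim <- dat
    sim$blue <- mu + e
    out[[s]] <- sim
  }
  if (nsim == 1) out[[1]] else out
}

#' @export
summary.rrm <- function(object, reps = NULL, sigma_e_bar = NULL,
                        grid_n = 201L, ...) {
  reps <- reps %||% object$reps
  if (is.null(sigma_e_bar)) {
    sigma_e_bar <- if (!is.null(object$data)) {
      tryCatch(mean_error_variance(object$data), error = function(e) NA_real_)
    } else {
      object$sigma_e_bar %||% NA_real_
    }
  }
  sg <- genetic_covariance(object)
  gc <- genetic_correlations(sg)
  h2 <- if (is.finite(sigma_e_bar)) {
    heritability_trajectory(sg, sigma_e_bar, reps)
  } else NULL
  ef <- eigenfunctions(object, grid_n = grid_n)
  structure(list(fit = object, sigma_g = sg, corr_g = gc$corr,
                 mean_rho_g = gc$mean, sd_rho_g = gc$sd,
                 h2 = h2, sigma_e_bar = sigma_e_bar, reps = reps,
                 eigen = ef), class = "summary.rrm")
}

#' @export
print.summary.rrm <- function(x, digits = 3, ...) {
  print(x$fit, digits = digits)
  cat("\nGenetic correlations between harvests: mean",
      round(x$mean_rho_g, digits), "(SD", paste0(round(x$sd_rho_g, digits), ")\n"))
  if (!is.null(x$h2)) {
    cat("Heritability trajectory (per harvest, r =", x$reps, "):\n")
    print(round(x$h2, digits))
    cat("Mean H^2:", round(mean(x$h2), digits),
        "(SD", paste0(round(stats::sd(x$h2), digits), ")\n"))
  }
  cat("Eigenvalues of K_g and importance (%):\n")
  print(data.frame(eigenvalue = signif(x$eigen$values, digits + 1),
                   importance_pct = round(x$eigen$importance_pct, 1),
                   diag_share_pct = round(x$eigen$diag_share_pct, 1)),
        row.names = FALSE)
  invisible(x)
}

#' Plot reaction norms of a fitted random regression model
#'
#' Draws each genotype's predicted trajectory over the harvest window with
#' the fixed mean curve overlaid.
#'
#' @param x an `rrm` fit.
#' @param n_grid grid resolution across the harvest window.
#' @param highlight optional character vector of genotypes drawn in color.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.rrm <- function(x, n_grid = 101L, highlight = NULL, ...) {
  days <- seq(min(x$schedule$days), max(x$schedule$days), length.out = n_grid)
  gv <- predict(x, days = days)
  graphics::matplot(days, t(gv), type = "l", lty = 1,
                    col = grDevices::grey(0.7), xlab = "days since first harvest",
                    ylab = "genotypic value (kg/ha)", ...)
  sc <- -1 + 2 * (days - min(days)) / diff(range(days))
  graphics::lines(days, eval_legendre_curve(x$beta, sc), lwd = 2)
  if (length(highlight)) {
    cols <- grDevices::hcl.colors(length(highlight), "Dark 2")
    for (i in seq_along(highlight)) {
      graphics::lines(days, gv[highlight[i], ], col = cols[i], lwd = 2)
    }
    graphics::legend("topright", legend = highlight, col = cols, lwd = 2,
                     bty = "n", cex = 0.8)
  }
  invisible(x)
}
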