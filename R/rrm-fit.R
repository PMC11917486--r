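#' Fit a weighted random regression model to a genotype-by-harvest BLUE table
#'
#' Second stage of the two-stage analysis. Models the stage-1 BLUEs as
#' \deqn{y = \Phi_1 \beta + \Phi_2 u_g + e,}
#' where \eqn{\Phi_1} is the normalized Legendre basis of degree `fixed_degree`
#' evaluated at the rescaled harvest times, \eqn{\Phi_2} the basis of degree
#' `random_degree`, \eqn{u_g \sim N(0, I \otimes K_g)} are per-genotype random
#' regression coefficients with unstructured covariance \eqn{K_g}, and
#' \eqn{e \sim N(0, \sigma_e^2\, \mathrm{diag}(1/\pi))} with \eqn{\pi} the
#' Smith weights carried from stage one. \eqn{K_g} (log-Cholesky
#' parameterized) and \eqn{\sigma_e^2} are estimated by restricted maximum
#' likelihood with multiple seeded starts; \eqn{\beta} is the generalized
#' least squares solution at the optimum and the coefficient predictions
#' \eqn{U_g} are BLUPs from the mixed-model equations.
#'
#' `fixed_degree = "auto"` applies the loess rule of [select_fixed_degree()];
#' `random_degree = "auto"` minimizes BIC over `0:m_max` via
#' [select_random_degree()].
#'
#' @param blues a `blue_table` from [stage1_blues()]/[read_blues()], or any
#'   data frame with columns `genotype`, `day`, `blue`, `weight` (and
#'   optionally `error_variance`).
#' @param fixed_degree degree of the fixed Legendre regression, or `"auto"`.
#' @param random_degree degree of the random regression, or `"auto"`.
#' @param m_max largest random degree tried when `random_degree = "auto"`.
#' @param n_starts number of optimizer starts (first from a moment-based
#'   guess, the rest jittered).
#' @param seed integer seed controlling the start jitter.
#' @param reps replication count of the trial, stored for heritability
#'   calculations (defaults to 1 if unknown).
#' @param control list of optimizer settings: `rel_tol` (default `1e-8`),
#'   `max_iter` (default 500).
#' @return An object of class `rrm` with components `beta` (fixed Legendre
#'   coefficients), `U` (genotype-by-coefficient BLUP matrix), `K` (estimated
#'   coefficient covariance \eqn{K_g}), `sigma_e2`, `loglik` (restricted),
#'   `bic`, `fixed_degree`, `random_degree`, `schedule`, `reps`, and the data.
#' @examples
#' sim <- simulate_blues(sim_config(n_genotypes = 40, n_harvests = 6, seed = 1))
#' fit <- rrm(sim$blues, fixed_degree = 2, random_degree = 1, seed = 1)
#' fit
#' @export
rrm <- function(blues, fixed_degree = "auto", random_degree = "auto",
                m_max = 3, n_starts = 5, seed = 1, reps = NULL,
                control = list()) {
  blues <- validate_blues(blues)
  if (identical(fixed_degree, "auto")) {
    fixed_degree <- select_fixed_degree(blues)
  }
  if (identical(random_degree, "auto")) {
    sel <- select_random_degree(blues, fixed_degree, m_max = m_max,
                                n_starts = n_starts, seed = seed,
                                reps = reps, control = control)
    return(sel$fit)
  }
  fit_rrm_fixed(blues, fixed_degree, random_degree, n_starts = n_starts,
                seed = seed, reps = reps, control = control)
}

validate_blues <- function(blues) {
  blues <- as.data.frame(blues)
  need <- c("genotype", "day", "blue", "weight")
  if (!all(need %in% names(blues))) {
    stop("BLUE table must contain columns: ", paste(need, collapse = ", "))
  }
  if (any(!is.finite(blues$blue))) stop("BLUEs must be finite")
  if (any(blues$weight <= 0)) stop("weights must be strictly positive")
  if (anyDuplicated(blues[, c("genotype", "day")])) {
    stop("duplicate (genotype, day) rows")
  }
  blues
}

# Internal representation: observations grouped by identical
# (times, weights) pattern so complete balanced data costs one V factorization
# per likelihood evaluation instead of one per genotype.
build_rrm_data <- function(blues, fixed_degree, random_degree,
                           drop_short = TRUE) {
  blues <- validate_blues(blues)
  days <- sort(unique(blues$day))
  schedule <- rescale_times(days)
  sc <- schedule$scaled[match(blues$day, days)]
  q <- random_degree + 1L

  gsplit <- split(seq_len(nrow(blues)), blues$genotype)
  short <- names(gsplit)[vapply(gsplit, function(i) length(unique(blues$day[i])), 1L) < q]
  if (drop_short && length(short)) {
    warning("genotypes observed at fewer than ", q,
            " distinct times excluded from variance estimation: ",
            paste(short, collapse = ", "))
  }

  lam1 <- legendre_lambda(fixed_degree)
  lam2 <- legendre_lambda(random_degree)
  groups <- list()
  geno_info <- list()
  for (g in names(gsplit)) {
    idx <- gsplit[[g]][order(blues$day[gsplit[[g]]])]
    t_g <- sc[idx]
    w_g <- blues$weight[idx]
    y_g <- blues$blue[idx]
    key <- paste(c(signif(t_g, 12), signif(w_g, 12)), collapse = "|")
    info <- list(genotype = g, t = t_g, w = w_g, y = y_g, rows = idx)
    geno_info[[g]] <- info
    if (g %in% short) next
    if (is.null(groups[[key]])) {
      X <- outer(t_g, 0:fixed_degree, `^`) %*% lam1
      P <- outer(t_g, 0:random_degree, `^`) %*% lam2
      groups[[key]] <- list(X = X, P = P, w = w_g, Y = NULL, genos = character())
    }
    groups[[key]]$Y <- cbind(groups[[key]]$Y, y_g)
    groups[[key]]$genos <- c(groups[[key]]$genos, g)
  }
  n_obs <- sum(vapply(groups, function(gr) length(gr$w) * ncol(gr$Y), 1))
  list(groups = groups, geno_info = geno_info, schedule = schedule,
       fixed_degree = fixed_degree, random_degree = random_degree,
       p = fixed_degree + 1L, q = q, n_obs = n_obs, short = short)
}

# theta = (vech of lower Cholesky factor of K_g, column-wise, with logged
# diagonal entries) followed by log(sigma_e2)
unpack_theta <- function(theta, q) {
  nk <- q * (q + 1L) / 2L
  if (length(theta) != nk + 1L) {
    stop("theta must have length ", nk + 1L, " for random degree ", q - 1L)
  }
  L <- matrix(0, q, q)
  pos <- 1L
  for (j in seq_len(q)) {
    for (i in j:q) {
      L[i, j] <- if (i == j) exp(theta[pos]) else theta[pos]
      pos <- pos + 1L
    }
  }
  list(K = L %*% t(L), L = L, sigma_e2 = exp(theta[nk + 1L]))
}

#' Pack a coefficient covariance and residual variance into a parameter vector
#'
#' The optimizer works on an unconstrained vector: the lower Cholesky factor
#' of \eqn{K_g} stored column-wise with its diagonal on the log scale,
#' followed by \eqn{\log \sigma_e^2}. This helper produces that vector from a
#' covariance matrix, e.g. to evaluate [reml_loglik()] at known parameters.
#'
#' @param K symmetric positive-definite coefficient covariance matrix.
#' @param sigma_e2 positive residual variance scale.
#' @return numeric parameter vector of length `q(q+1)/2 + 1`, `q = nrow(K)`.
#' @export
rrm_pack_theta <- function(K, sigma_e2) {
  K <- as.matrix(K)
  L <- t(chol(K))
  q <- nrow(K)
  th <- numeric(0)
  for (j in seq_len(q)) {
    v <- L[j:q, j]
    v[1] <- log(v[1])
    th <- c(th, v)
  }
  c(th, log(sigma_e2))
}

reml_loglik_internal <- function(theta, dat) {
  pars <- tryCatch(unpack_theta(theta, dat$q), error = function(e) NULL)
  if (is.null(pars) || any(!is.finite(theta))) return(-Inf)
  K <- pars$K
  s2 <- pars$sigma_e2
  p <- dat$p
  logdetV <- 0
  A <- matrix(0, p, p)
  b <- numeric(p)
  yy <- 0
  for (gr in dat$groups) {
    V <- gr$P %*% K %*% t(gr$P) + diag(s2 / gr$w, nrow = length(gr$w))
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    Vi <- chol2inv(ch)
    ng <- ncol(gr$Y)
    logdetV <- logdetV + ng * 2 * sum(log(diag(ch)))
    ViX <- Vi %*% gr$X
    A <- A + ng * crossprod(gr$X, ViX)
    b <- b + drop(crossprod(ViX, rowSums(gr$Y)))
    yy <- yy + sum(gr$Y * (Vi %*% gr$Y))
  }
  cA <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(cA)) return(-Inf)
  beta <- backsolve(cA, forwardsolve(t(cA), b))
  yPy <- yy - sum(b * beta)
  ll <- -0.5 * ((dat$n_obs - p) * log(2 * pi) + logdetV +
                  2 * sum(log(diag(cA))) + yPy)
  if (!is.finite(ll)) return(-Inf)
  attr(ll, "beta") <- beta
  ll
}

#' Restricted log-likelihood of the weighted random regression model
#'
#' Evaluates the REML (residual) log-likelihood of the model fitted by
#' [rrm()] at given variance parameters, with the fixed coefficients profiled
#' out by generalized least squares. The convention is
#' \eqn{-\tfrac12[(n-p)\log 2\pi + \log|V| + \log|X'V^{-1}X| + y'Py]},
#' i.e. without the constant \eqn{\tfrac12 \log|X'X|} that the
#' error-contrast formulation carries.
#'
#' @inheritParams rrm
#' @param theta packed parameter vector, see [rrm_pack_theta()].
#' @param fixed_degree,random_degree basis degrees defining \eqn{\Phi_1},
#'   \eqn{\Phi_2}.
#' @return the restricted log-likelihood (scalar), `-Inf` where the
#'   parameters give a non-positive-definite model.
#' @export
reml_loglik <- function(theta, blues, fixed_degree, random_degree) {
  dat <- build_rrm_data(blues, fixed_degree, random_degree)
  as.numeric(reml_loglik_internal(theta, dat))
}

rrm_start_values <- function(dat) {
  q <- dat$q
  p <- dat$p
  # weighted LS for the fixed curve, errors only
  Xall <- do.call(rbind, lapply(dat$groups, function(gr) {
    gr$X[rep(seq_len(nrow(gr$X)), ncol(gr$Y)), , drop = FALSE]
  }))
  yall <- unlist(lapply(dat$groups, function(gr) as.vector(gr$Y)))
  wall <- unlist(lapply(dat$groups, function(gr) rep(gr$w, ncol(gr$Y))))
  beta0 <- stats::lm.wfit(Xall, yall, wall)$coefficients
  beta0[is.na(beta0)] <- 0
  s2_0 <- max(stats::weighted.mean((yall - Xall %*% beta0)^2 * wall,
                                   rep(1, length(yall))), 1e-8)
  # per-genotype OLS coefficients of residual curves -> moment estimate of K
  coefs <- list()
  for (gr in dat$groups) {
    R <- gr$Y - drop(gr$X %*% beta0)
    if (nrow(gr$P) >= q && qr(gr$P)$rank == q) {
      cf <- qr.coef(qr(gr$P), R)
      coefs[[length(coefs) + 1L]] <- t(cf)
    }
  }
  K0 <- if (length(coefs)) {
    C <- do.call(rbind, coefs)
    S <- stats::cov(C)
    S <- 0.5 * (S + t(S))
    ev <- eigen(S, symmetric = TRUE)
    lam <- pmax(ev$values, 0.05 * max(ev$values, s2_0))
    ev$vectors %*% diag(lam, q) %*% t(ev$vectors)
  } else {
    diag(s2_0, q)
  }
  rrm_pack_theta(K0, s2_0)
}

fit_rrm_fixed <- function(blues, fixed_degree, random_degree, n_starts = 5,
                          seed = 1, reps = NULL, control = list()) {
  rel_tol <- control$rel_tol %||% 1e-8
  max_iter <- control$max_iter %||% 500L
  dat <- build_rrm_data(blues, fixed_degree, random_degree)
  if (length(dat$groups) == 0L) {
    stop("no genotype has enough distinct observation times for random degree ",
         random_degree)
  }
  theta0 <- rrm_start_values(dat)
  npar <- length(theta0)
  obj <- function(th) -as.numeric(reml_loglik_internal(th, dat))

  set.seed(seed %% .Machine$integer.max)
  best <- NULL
  start_lls <- numeric(0)
  for (s in seq_len(max(1L, n_starts))) {
    th_s <- if (s == 1L) theta0 else theta0 + stats::rnorm(npar, 0, 0.5)
    start_lls <- c(start_lls, -obj(th_s))
    opt <- tryCatch(
      stats::nlminb(th_s, obj,
                    lower = rep(-30, npar), upper = rep(30, npar),
                    control = list(rel.tol = rel_tol, iter.max = max_iter,
                                   eval.max = 2L * max_iter)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$objective)) next
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  if (is.null(best)) stop("REML optimization failed from every start")
  converged <- best$convergence == 0
  if (!converged) {
    warning("optimizer did not report convergence (", best$message,
            "); returning best point found")
  }

  ll <- reml_loglik_internal(best$par, dat)
  pars <- unpack_theta(best$par, dat$q)
  beta <- attr(ll, "beta")
  names(beta) <- paste0("phi", 0:fixed_degree)
  K <- pars$K
  dimnames(K) <- list(paste0("g", 0:random_degree), paste0("g", 0:random_degree))
  tr <- sum(diag(K))
  if (tr > 0 && min(eigen(K, symmetric = TRUE, only.values = TRUE)$values) <
        1e-8 * tr) {
    warning("estimated K_g is near-singular (variance component at boundary)")
  }

  # BLUPs for every genotype, including those excluded from estimation
  U <- matrix(0, length(dat$geno_info), dat$q,
              dimnames = list(names(dat$geno_info), colnames(K)))
  lam2 <- legendre_lambda(random_degree)
  lam1 <- legendre_lambda(fixed_degree)
  for (g in names(dat$geno_info)) {
    info <- dat$geno_info[[g]]
    P <- outer(info$t, 0:random_degree, `^`) %*% lam2
    X <- outer(info$t, 0:fixed_degree, `^`) %*% lam1
    V <- P %*% K %*% t(P) + diag(pars$sigma_e2 / info$w, nrow = length(info$w))
    U[g, ] <- drop(K %*% t(P) %*% solve(V, info$y - drop(X %*% beta)))
  }

  n_eff <- dat$n_obs - dat$p
  n_vpar <- dat$q * (dat$q + 1) / 2 + 1
  fit <- structure(list(
    beta = beta, U = U, K = K, sigma_e2 = pars$sigma_e2,
    loglik = as.numeric(ll), bic = NA_real_,
    fixed_degree = fixed_degree, random_degree = random_degree,
    schedule = dat$schedule, reps = reps %||% 1L,
    n_obs = dat$n_obs, n_genotypes = length(dat$geno_info),
    n_vpar = n_vpar, n_eff = n_eff,
    sigma_e_bar = tryCatch(mean_error_variance(blues),
                           error = function(e) NA_real_),
    excluded = dat$short, converged = converged,
    start_logliks = start_lls, theta = best$par,
    data = blues, call = match.call()
  ), class = "rrm")
  fit$bic <- compute_bic(fit)
  fit
}

#' Bayesian information criterion of a fitted random regression model
#'
#' \eqn{\mathrm{BIC} = -2\,\ell_{REML} + p_v \log n_{eff}} with \eqn{p_v}
#' the number of free variance parameters (\eqn{(m+1)(m+2)/2} for \eqn{K_g}
#' plus one for \eqn{\sigma_e^2}) and \eqn{n_{eff}} the number of
#' observations minus the fixed-effect rank. Lower is better.
#'
#' @param fit an `rrm` object.
#' @return scalar BIC.
#' @export
compute_bic <- function(fit) {
  stopifnot(inherits(fit, "rrm"))
  -2 * fit$loglik + fit$n_vpar * log(fit$n_eff)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
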