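#' Adaptability: area under the reaction-norm curve
#'
#' A genotype's broad adaptability is the area under its fitted trajectory
#' over the rescaled harvest interval,
#' \eqn{A_i = \int_{-1}^{1} \left[\sum_k b_k t^k + \sum_k g_{ik} t^k\right] dt},
#' combining the fixed curve and the genotype's random deviation. The fitted
#' Legendre coefficients are converted to the monomial basis via
#' \eqn{\Lambda}, and the integral is evaluated in closed form: odd powers
#' vanish on \eqn{[-1,1]} and each even power \eqn{t^k} contributes
#' \eqn{2 b_k / (k+1)}.
#'
#' @param fit an `rrm` object.
#' @param genotypes genotypes to evaluate (default all).
#' @param scale `"scaled"` integrates over the rescaled axis \eqn{[-1,1]} as
#'   defined; `"days"` multiplies by \eqn{(t_{max}-t_{min})/2} to express the
#'   area in kg/ha x days (rankings are identical).
#' @return named numeric vector of areas.
#' @export
adaptability <- function(fit, genotypes = NULL, scale = c("scaled", "days")) {
  stopifnot(inherits(fit, "rrm"))
  scale <- match.arg(scale)
  genotypes <- genotypes %||% rownames(fit$U)
  miss <- setdiff(genotypes, rownames(fit$U))
  if (length(miss)) stop("unknown genotypes: ", paste(miss, collapse = ", "))
  A <- vapply(genotypes, function(g) {
    cf <- total_curve_legendre(fit, g)
    integrate_monomial(legendre_to_monomial(cf))
  }, numeric(1))
  if (scale == "days") A <- A * diff(range(fit$schedule$days)) / 2
  A
}

# fixed + random Legendre coefficients padded to a common degree
total_curve_legendre <- function(fit, genotype) {
  D <- max(fit$fixed_degree, fit$random_degree)
  cf <- numeric(D + 1L)
  cf[seq_along(fit$beta)] <- fit$beta
  u <- fit$U[genotype, ]
  cf[seq_along(u)] <- cf[seq_along(u)] + u
  cf
}

# closed-form integral of sum b_k t^k over [-1, 1]
integrate_monomial <- function(b) {
  k <- seq_along(b) - 1L
  sum(ifelse(k %% 2L == 0L, 2 * b / (k + 1), 0))
}

#' Stability: coefficient of variation of the reaction-norm curve
#'
#' Type I (biological) stability: the standard deviation of the genotype's
#' fitted curve divided by its overall performance,
#' \eqn{CV_{c,i} = \sigma_{c,i} / (b_0 + g_{i0})}, where \eqn{b_0} and
#' \eqn{g_{i0}} are the degree-0 coefficients of the fixed and random parts
#' on the normalized Legendre basis. \eqn{\sigma_{c,i}} is the population
#' standard deviation of the continuous curve over \eqn{[-1,1]}, computed on
#' a dense uniform grid with Simpson quadrature weights (`at = "grid"`), or
#' the plain SD at the observed harvest times (`at = "harvests"`). A stable
#' genotype varies little across harvests, so lower is better.
#'
#' @inheritParams adaptability
#' @param grid_n grid resolution for the curve SD.
#' @param at evaluate the SD over the continuous curve (default) or only at
#'   the observed harvest times.
#' @return named numeric vector of CV values; `NA` with a warning where the
#'   overall performance is numerically zero.
#' @export
stability <- function(fit, genotypes = NULL, grid_n = 1001L,
                      at = c("grid", "harvests")) {
  stopifnot(inherits(fit, "rrm"))
  at <- match.arg(at)
  genotypes <- genotypes %||% rownames(fit$U)
  miss <- setdiff(genotypes, rownames(fit$U))
  if (length(miss)) stop("unknown genotypes: ", paste(miss, collapse = ", "))
  if (at == "grid") {
    if (grid_n %% 2L == 0L) grid_n <- grid_n + 1L # Simpson needs an odd grid
    tt <- seq(-1, 1, length.out = grid_n)
    # Simpson weights: the grid SD then converges to the SD of the
    # continuous curve instead of carrying O(1/n) endpoint bias
    wq <- c(1, rep(c(4, 2), length.out = grid_n - 2L), 1)
  } else {
    tt <- fit$schedule$scaled
    wq <- rep(1, length(tt))
  }
  cv <- vapply(genotypes, function(g) {
    cf <- total_curve_legendre(fit, g)
    y <- eval_legendre_curve(cf, tt)
    mu <- sum(wq * y) / sum(wq)
    sig <- sqrt(sum(wq * (y - mu)^2) / sum(wq))  # population SD
    denom <- fit$beta[1] + fit$U[g, 1]
    if (abs(denom) < 1e-12) return(NA_real_)
    sig / denom
  }, numeric(1))
  if (anyNA(cv)) {
    warning("undefined CV_c (zero overall performance) for: ",
            paste(genotypes[is.na(cv)], collapse = ", "))
  }
  cv
}

#' Adaptability-stability selection table
#'
#' Computes adaptability `A` and stability `CVc` for every genotype,
#' classifies each into the quadrants of the A-versus-CVc scatter using the
#' across-genotype means as thresholds (the `"select"` quadrant is
#' above-mean A with below-mean CVc), flags the top fraction by A, and
#' reports the Pearson correlation between the two statistics.
#'
#' @inheritParams stability
#' @param top fraction of genotypes flagged by highest adaptability.
#' @return object of class `rrm_selection`: a data frame with columns
#'   `genotype`, `A`, `CVc`, `quadrant`, `selected`, ordered by decreasing
#'   `A`, with attributes `correlation_A_CVc`, `mean_A`, `mean_CVc`.
#' @export
selection_table <- function(fit, top = 0.10, grid_n = 1001L,
                            at = c("grid", "harvests")) {
  stopifnot(inherits(fit, "rrm"))
  if (nrow(fit$U) < 2L) stop("selection requires at least two genotypes")
  A <- adaptability(fit)
  CVc <- stability(fit, grid_n = grid_n, at = at)
  ok <- !is.na(CVc)
  corr <- if (sum(ok) >= 2L && stats::sd(A[ok]) > 0 && stats::sd(CVc[ok]) > 0) {
    stats::cor(A[ok], CVc[ok])
  } else {
    warning("A-CVc correlation undefined (degenerate spread)")
    NA_real_
  }
  mA <- mean(A)
  mC <- mean(CVc, na.rm = TRUE)
  quadrant <- ifelse(A >= mA & CVc <= mC, "select",
              ifelse(A >= mA, "high-A high-CVc",
              ifelse(CVc <= mC, "low-A low-CVc", "low-A high-CVc")))
  quadrant[is.na(CVc)] <- NA_character_
  n_top <- max(1L, floor(top * length(A)))
  selected <- rank(-A, ties.method = "first") <= n_top
  out <- data.frame(genotype = names(A), A = unname(A), CVc = unname(CVc),
                    quadrant = quadrant, selected = selected,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$A), ]
  rownames(out) <- NULL
  structure(out, correlation_A_CVc = corr, mean_A = mA, mean_CVc = mC,
            class = c("rrm_selection", "data.frame"))
}

#' @export
print.rrm_selection <- function(x, digits = 4, ...) {
  cat("Genotype selection by adaptability (A) and stability (CVc)\n")
  cat("  A-CVc Pearson correlation:",
      round(attr(x, "correlation_A_CVc"), 3), "\n")
  cat("  thresholds: mean A =", signif(attr(x, "mean_A"), digits),
      ", mean CVc =", signif(attr(x, "mean_CVc"), digits), "\n")
  print.data.frame(cbind(x[, "genotype", drop = FALSE],
                         round(x[, c("A", "CVc")], digits),
                         x[, c("quadrant", "selected")]),
                   row.names = FALSE, ...)
  invisible(x)
}

#' @export
plot.rrm_selection <- function(x, ...) {
  graphics::plot(x$A, x$CVc, pch = ifelse(x$selected, 19, 1),
                 col = ifelse(x$quadrant == "select", "forestgreen", "grey30"),
                 xlab = "adaptability A (area under curve)",
                 ylab = expression(CV[c]), ...)
  graphics::abline(v = attr(x, "mean_A"), h = attr(x, "mean_CVc"))
  invisible(x)
}
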