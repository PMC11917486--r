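#' Choose the fixed polynomial degree from the mean yield trajectory
#'
#' The fixed regression must track the seasonal peaks and troughs of the mean
#' dry-matter-yield trajectory. The degree is chosen by smoothing the
#' harvest-mean trajectory with local weighted regression (loess), counting
#' the interior local extrema \eqn{c} of the smoothed curve, and returning
#' \eqn{c + 1}: a monotone trajectory gets a line, one peak gets a quadratic,
#' a peak-and-trough season pattern gets a cubic, and so on.
#'
#' @param blues a BLUE table (columns `day`, `blue`) or any data frame of
#'   observations with one `blue` value per `(genotype, day)`.
#' @param span loess span; larger values smooth harder and count fewer
#'   extrema.
#' @param grid_n number of points of the dense evaluation grid on which
#'   extrema are counted.
#' @return integer degree \eqn{d \ge 1}.
#' @export
select_fixed_degree <- function(blues, span = 0.75, grid_n = 201L) {
  blues <- as.data.frame(blues)
  stopifnot(all(c("day", "blue") %in% names(blues)))
  means <- tapply(blues$blue, blues$day, mean)
  days <- as.numeric(names(means))
  o <- order(days)
  days <- days[o]; means <- as.numeric(means)[o]
  if (length(days) < 3L) {
    warning("fewer than 3 harvests: returning fixed degree 1")
    return(1L)
  }
  sc <- rescale_times(days)$scaled
  # with few harvests a narrow span nearly interpolates and over-counts
  # extrema: keep at least ~5 points in each local window
  span_eff <- max(span, min(1, 5 / length(days)))
  smoothed <- tryCatch(suppressWarnings({
    lo <- stats::loess(means ~ sc, span = span_eff, degree = 2,
                       control = stats::loess.control(surface = "direct"))
    grid <- seq(-1, 1, length.out = grid_n)
    list(x = grid, y = stats::predict(lo, data.frame(sc = grid)))
  }), error = function(e) list(x = sc, y = means))
  dy <- diff(smoothed$y)
  tol <- 1e-8 * max(diff(range(smoothed$y)), 1e-12)
  s <- sign(dy)
  s[abs(dy) < tol] <- 0
  s <- s[s != 0]
  c_extrema <- if (length(s) < 2L) 0L else sum(diff(s) != 0)
  # the fixed regression cannot exceed saturation at the observed harvests
  min(as.integer(c_extrema + 1L), length(days) - 1L)
}

#' Choose the random polynomial degree by BIC
#'
#' Fits the random regression model for every random degree `0:m_max` at a
#' given fixed degree and returns the fit minimizing BIC (ties broken toward
#' the smaller degree). Degrees whose fit fails are skipped with a warning.
#'
#' @inheritParams rrm
#' @param fixed_degree fixed regression degree used for every candidate.
#' @return list with `fit` (the chosen `rrm` object), `random_degree`, and
#'   `bic_table` (data frame of degree, log-likelihood, BIC).
#' @export
select_random_degree <- function(blues, fixed_degree, m_max = 3,
                                 n_starts = 5, seed = 1, reps = NULL,
                                 control = list()) {
  blues <- validate_blues(blues)
  n_times <- length(unique(blues$day))
  if (m_max >= n_times) {
    stop("m_max must be smaller than the number of distinct harvests")
  }
  fits <- vector("list", m_max + 1L)
  tab <- data.frame(random_degree = 0:m_max, loglik = NA_real_, bic = NA_real_)
  for (m in 0:m_max) {
    fits[[m + 1L]] <- tryCatch(
      fit_rrm_fixed(blues, fixed_degree, m, n_starts = n_starts,
                    seed = seed + m, reps = reps, control = control),
      error = function(e) {
        warning("random degree ", m, " failed: ", conditionMessage(e))
        NULL
      })
    if (!is.null(fits[[m + 1L]])) {
      tab$loglik[m + 1L] <- fits[[m + 1L]]$loglik
      tab$bic[m + 1L] <- fits[[m + 1L]]$bic
    }
  }
  if (all(is.na(tab$bic))) stop("every candidate random degree failed to fit")
  best <- which.min(tab$bic)  # ties resolve to the smaller degree
  list(fit = fits[[best]], random_degree = tab$random_degree[best],
       bic_table = tab)
}
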