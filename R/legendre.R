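#' Rescale harvest days to the Legendre interval
#'
#' Maps a strictly increasing sequence of harvest days (days since the first
#' harvest, so the first entry is usually 0) onto \eqn{[-1, 1]} by the affine
#' transform \eqn{t^* = -1 + 2 (t - t_{min}) / (t_{max} - t_{min})}. The
#' rescaled axis is the domain on which all Legendre polynomial bases in this
#' package are evaluated.
#'
#' @param days numeric vector of non-negative, strictly increasing harvest
#'   days. At least two distinct values are required.
#' @return An object of class `harvest_schedule`: a list with components
#'   `days` (the input) and `scaled` (the rescaled times in \eqn{[-1, 1]}).
#' @examples
#' rescale_times(c(0, 25, 100))
#' @export
rescale_times <- function(days) {
  days <- as.numeric(days)
  if (length(days) < 2L) {
    stop("at least two harvest days are required")
  }
  if (any(!is.finite(days))) {
    stop("harvest days must be finite")
  }
  if (any(diff(days) <= 0)) {
    stop("harvest days must be strictly increasing")
  }
  rng <- range(days)
  if (rng[1] == rng[2]) {
    stop("degenerate schedule: all harvest days identical")
  }
  scaled <- -1 + 2 * (days - rng[1]) / (rng[2] - rng[1])
  structure(list(days = days, scaled = scaled), class = "harvest_schedule")
}

#' @export
print.harvest_schedule <- function(x, ...) {
  cat("Harvest schedule:", length(x$days), "harvests over",
      diff(range(x$days)), "days\n")
  print(data.frame(day = x$days, scaled = round(x$scaled, 4)), row.names = FALSE)
  invisible(x)
}

#' Monomial coefficients of a raw Legendre polynomial
#'
#' Computes the coefficients of the (unnormalized) Legendre polynomial
#' \eqn{P_n(t)} on the monomial basis, by the three-term recursion
#' \eqn{P_{n+1}(t) = [(2n+1) t P_n(t) - n P_{n-1}(t)] / (n+1)} with
#' \eqn{P_0(t) = 1}.
#'
#' @param n non-negative integer order.
#' @return numeric vector of length `n + 1`; element `k + 1` is the
#'   coefficient of \eqn{t^k}.
#' @examples
#' raw_legendre(2)  # c(-0.5, 0, 1.5): P2(t) = 1.5 t^2 - 0.5
#' @export
raw_legendre <- function(n) {
  if (length(n) != 1L || is.na(n) || n != round(n) || n < 0) {
    stop("'n' must be a single non-negative integer")
  }
  n <- as.integer(n)
  if (n == 0L) return(1)
  if (n == 1L) return(c(0, 1))
  p_prev <- 1          # P0
  p_cur <- c(0, 1)     # P1
  for (k in 1L:(n - 1L)) {
    # (2k+1) t P_k: shift coefficients up one power
    t_pk <- c(0, p_cur) * (2 * k + 1)
    k_pkm1 <- c(p_prev, 0, 0) * k
    p_next <- (t_pk - k_pkm1) / (k + 1)
    p_prev <- p_cur
    p_cur <- p_next
  }
  p_cur
}

.max_degree <- 10L

check_degree <- function(m) {
  if (length(m) != 1L || is.na(m) || m != round(m) || m < 0) {
    stop("polynomial degree must be a single non-negative integer")
  }
  if (m > .max_degree) {
    stop("degrees above ", .max_degree,
         " are not supported (numerically fragile on the monomial basis)")
  }
  as.integer(m)
}

#' Coefficient matrix of the normalized Legendre basis
#'
#' Builds the \eqn{(m+1) \times (m+1)} matrix \eqn{\Lambda} whose column
#' \eqn{n} (0-based) holds the monomial coefficients of the normalized
#' Legendre polynomial \eqn{\phi_n(t) = \sqrt{(2n+1)/2}\, P_n(t)}; rows index
#' powers of \eqn{t}. \eqn{\Lambda} is column-triangular (zero above the
#' leading power) and invertible, so it also converts between Legendre and
#' monomial representations of a fitted curve.
#'
#' @param m non-negative integer degree (at most 10).
#' @return `(m+1) x (m+1)` numeric matrix, rows named by power, columns by
#'   polynomial order.
#' @examples
#' legendre_lambda(2)
#' @export
legendre_lambda <- function(m) {
  m <- check_degree(m)
  lam <- matrix(0, m + 1L, m + 1L,
                dimnames = list(power = paste0("t", 0:m),
                                order = paste0("phi", 0:m)))
  for (n in 0:m) {
    lam[seq_len(n + 1L), n + 1L] <- sqrt((2 * n + 1) / 2) * raw_legendre(n)
  }
  lam
}

#' Evaluate the normalized Legendre basis at scheduled times
#'
#' Forms the time-point monomial matrix \eqn{M} (one row per harvest, columns
#' \eqn{t^0 \dots t^m} of the rescaled time) and the evaluated basis
#' \eqn{\Phi = M \Lambda}.
#'
#' @param schedule a `harvest_schedule` from [rescale_times()], or a numeric
#'   vector of already-rescaled times in \eqn{[-1, 1]}.
#' @param m basis degree.
#' @return An object of class `legendre_basis`: list with `degree`, `lambda`
#'   (\eqn{\Lambda}), `M`, `phi` (\eqn{\Phi}), and the scaled times.
#' @examples
#' sched <- rescale_times(c(0, 50, 100))
#' legendre_phi(sched, 2)$phi
#' @export
legendre_phi <- function(schedule, m) {
  m <- check_degree(m)
  scaled <- if (inherits(schedule, "harvest_schedule")) schedule$scaled
            else as.numeric(schedule)
  if (any(!is.finite(scaled))) stop("times must be finite")
  n_distinct <- length(unique(scaled))
  if (m >= n_distinct) {
    warning("basis degree ", m, " >= number of distinct time points (",
            n_distinct, "): the regression is saturated")
  }
  lam <- legendre_lambda(m)
  M <- outer(scaled, 0:m, `^`)
  dimnames(M) <- list(NULL, paste0("t", 0:m))
  phi <- M %*% lam
  structure(list(degree = m, lambda = lam, M = M, phi = phi, scaled = scaled),
            class = "legendre_basis")
}

#' @export
print.legendre_basis <- function(x, ...) {
  cat("Normalized Legendre basis, degree", x$degree, "at", length(x$scaled),
      "time points\n")
  print(round(x$phi, 4))
  invisible(x)
}

#' Convert Legendre-basis coefficients to monomial coefficients
#'
#' A curve written as \eqn{\sum_n c_n \phi_n(t)} on the normalized Legendre
#' basis equals \eqn{\sum_k b_k t^k} with \eqn{b = \Lambda c}. The monomial
#' form is what closed-form integrals over \eqn{[-1,1]} (the adaptability
#' statistic) are computed from.
#'
#' @param coeffs numeric vector of normalized-Legendre coefficients
#'   \eqn{c_0, \dots, c_m}.
#' @return numeric vector of monomial coefficients \eqn{b_0, \dots, b_m}.
#' @seealso [monomial_to_legendre()] for the inverse map.
#' @export
legendre_to_monomial <- function(coeffs) {
  coeffs <- as.numeric(coeffs)
  if (any(!is.finite(coeffs))) stop("coefficients must be finite")
  m <- length(coeffs) - 1L
  unname(drop(legendre_lambda(m) %*% coeffs))
}

#' @rdname legendre_to_monomial
#' @param b numeric vector of monomial coefficients.
#' @export
monomial_to_legendre <- function(b) {
  b <- as.numeric(b)
  if (any(!is.finite(b))) stop("coefficients must be finite")
  m <- length(b) - 1L
  unname(drop(solve(legendre_lambda(m), b)))
}

# Evaluate a curve given on the normalized Legendre basis at scaled times.
eval_legendre_curve <- function(coeffs, scaled) {
  m <- length(coeffs) - 1L
  phi <- outer(scaled, 0:m, `^`) %*% legendre_lambda(m)
  drop(phi %*% coeffs)
}
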