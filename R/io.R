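#' Serialize a fitted random regression model to JSON
#'
#' Stores the estimated quantities (fixed coefficients, BLUP matrix,
#' coefficient covariance, residual scale, likelihood, BIC, degrees, harvest
#' schedule, replication count and mean stage-1 error variance) in a plain
#' JSON file, enough to recreate predictions and every derived statistic.
#' The observation-level data are not stored.
#'
#' @param fit an `rrm` object.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
rrm_to_json <- function(fit, path) {
  stopifnot(inherits(fit, "rrm"))
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("the 'jsonlite' package is required for JSON serialization")
  }
  obj <- list(beta = unname(fit$beta),
              genotypes = rownames(fit$U),
              U = unname(fit$U),
              K = unname(fit$K),
              sigma_e2 = fit$sigma_e2,
              loglik = fit$loglik, bic = fit$bic,
              fixed_degree = fit$fixed_degree,
              random_degree = fit$random_degree,
              days = fit$schedule$days,
              reps = fit$reps,
              sigma_e_bar = fit$sigma_e_bar)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname rrm_to_json
#' @export
rrm_from_json <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("the 'jsonlite' package is required for JSON serialization")
  }
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  U <- as.matrix(obj$U)
  rownames(U) <- obj$genotypes
  colnames(U) <- paste0("g", seq_len(ncol(U)) - 1L)
  K <- as.matrix(obj$K)
  dimnames(K) <- list(colnames(U), colnames(U))
  beta <- stats::setNames(obj$beta, paste0("phi", seq_along(obj$beta) - 1L))
  structure(list(beta = beta, U = U, K = K, sigma_e2 = obj$sigma_e2,
                 loglik = obj$loglik, bic = obj$bic,
                 fixed_degree = obj$fixed_degree,
                 random_degree = obj$random_degree,
                 schedule = rescale_times(obj$days),
                 reps = obj$reps,
                 sigma_e_bar = obj$sigma_e_bar %||% NA_real_,
                 n_obs = NA_integer_, n_genotypes = nrow(U),
                 n_vpar = ncol(U) * (ncol(U) + 1) / 2 + 1,
                 n_eff = NA_integer_, excluded = character(),
                 converged = NA, data = NULL),
            class = "rrm")
}
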