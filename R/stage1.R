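#' Fit a single-harvest linear mixed model and extract genotype BLUEs
#'
#' First stage of the two-stage analysis. For the plots of one harvest, fits a
#' design-appropriate linear mixed model with genotypes fixed and the design
#' structure random, and returns the genotype best linear unbiased estimates
#' (BLUEs) together with their full variance matrix and the residual error
#' variance. Supported designs:
#' \describe{
#'   \item{`rcbd`}{randomized complete blocks: `yield ~ genotype + (1 | block)`;
#'     the `rep` column is accepted as an alias for `block`.}
#'   \item{`alpha_lattice`}{incomplete blocks within replicates: replicate
#'     fixed alongside genotype, `(1 | rep:block)` random.}
#'   \item{`row_column`}{independent random row and column effects
#'     (`(1 | row) + (1 | col)`), replicate fixed if present. A smooth spatial
#'     surface is deliberately not modelled; externally computed BLUE/weight
#'     tables can be supplied directly to [rrm()] when a spatial analysis is
#'     preferred.}
#' }
#'
#' @param records data frame with columns `genotype`, `yield`, and the design
#'   columns the declared design needs (`block`/`rep`, `row`, `col`).
#' @param design one of `"rcbd"`, `"alpha_lattice"`, `"row_column"`.
#' @return list with `blues` (named vector, one per genotype), `vcov`
#'   (variance matrix of the BLUEs), `error_variance` (REML residual
#'   variance), `varcomp` (named vector of design variance components) and
#'   `dropped` (genotypes absent from all plots).
#' @export
fit_harvest_model <- function(records, design = c("rcbd", "alpha_lattice", "row_column")) {
  design <- match.arg(design)
  records <- as.data.frame(records)
  need <- c("genotype", "yield")
  if (!all(need %in% names(records))) {
    stop("records must contain columns 'genotype' and 'yield'")
  }
  if (any(!is.finite(records$yield)) || any(records$yield < 0)) {
    stop("yields must be finite and non-negative")
  }
  records$genotype <- factor(records$genotype)
  records$genotype <- droplevels(records$genotype)
  if (nlevels(records$genotype) < 2L) {
    stop("at least two genotypes are required per harvest")
  }

  if (design == "rcbd") {
    if (!"block" %in% names(records) && "rep" %in% names(records)) {
      records$block <- records$rep
    }
    if (!"block" %in% names(records)) stop("rcbd design needs a 'block' (or 'rep') column")
    records$block <- factor(records$block)
    form <- yield ~ 0 + genotype + (1 | block)
  } else if (design == "alpha_lattice") {
    if (!all(c("rep", "block") %in% names(records))) {
      stop("alpha_lattice design needs 'rep' and 'block' columns")
    }
    records$rep <- factor(records$rep)
    records$block <- factor(records$block)
    form <- if (nlevels(records$rep) > 1L) {
      yield ~ 0 + genotype + rep + (1 | rep:block)
    } else {
      yield ~ 0 + genotype + (1 | rep:block)
    }
  } else { # row_column
    if (!all(c("row", "col") %in% names(records))) {
      stop("row_column design needs 'row' and 'col' columns")
    }
    records$row <- factor(records$row)
    records$col <- factor(records$col)
    has_rep <- "rep" %in% names(records) && length(unique(records$rep)) > 1L
    if (has_rep) records$rep <- factor(records$rep)
    form <- if (has_rep) yield ~ 0 + genotype + rep + (1 | row) + (1 | col)
            else yield ~ 0 + genotype + (1 | row) + (1 | col)
  }

  # sum-to-zero contrasts for fixed replicates: genotype coefficients are then
  # means over replicates, not cell means at the reference replicate
  ctr <- if ("rep" %in% all.vars(lme4::nobars(form))) list(rep = "contr.sum")
  fit <- suppressMessages(lme4::lmer(form, data = records, REML = TRUE,
                                     contrasts = ctr,
                                     control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                                                 check.nobs.vs.nRE = "ignore")))
  fe <- lme4::fixef(fit)
  vc <- as.matrix(stats::vcov(fit))
  idx <- grep("^genotype", names(fe))
  blues <- fe[idx]
  names(blues) <- sub("^genotype", "", names(blues))
  V <- vc[idx, idx, drop = FALSE]
  dimnames(V) <- list(names(blues), names(blues))

  vcomp <- unlist(lapply(lme4::VarCorr(fit), function(m) m[1, 1]))
  err <- stats::sigma(fit)^2
  eps <- 1e-8 * max(err, 1)
  if (any(vcomp < eps)) {
    vcomp[vcomp < eps] <- eps
  }
  list(blues = blues, vcov = V, error_variance = err, varcomp = vcomp,
       dropped = setdiff(levels(records$genotype), names(blues)))
}

#' Smith weights from the variance matrix of stage-1 BLUEs
#'
#' The per-genotype weights carried into the second stage are the diagonal
#' elements of the inverse of the BLUE variance matrix, so each weight is the
#' precision of that genotype's estimate after accounting for its covariance
#' with the others.
#'
#' @param V symmetric positive-definite variance matrix of the BLUEs.
#' @return numeric vector of strictly positive weights, named like `V`'s rows.
#' @export
smith_weights <- function(V) {
  V <- as.matrix(V)
  if (nrow(V) != ncol(V) || max(abs(V - t(V))) > 1e-8 * max(abs(V), 1)) {
    stop("variance matrix must be symmetric")
  }
  Vinv <- tryCatch(chol2inv(chol(V)), error = function(e) {
    stop("variance matrix is not positive definite (condition estimate ",
         format(kappa(V), digits = 3), ")")
  })
  w <- diag(Vinv)
  names(w) <- rownames(V)
  w
}

#' Run stage one across all harvests and assemble the BLUE table
#'
#' Applies [fit_harvest_model()] to each harvest of a plot-level trial table
#' and assembles the long-format genotype-by-harvest BLUE table with Smith
#' weights and per-harvest error variances that [rrm()] consumes.
#'
#' @param plots data frame of plot records with columns `genotype`, `harvest`,
#'   `day`, `yield` and the design columns (`rep`/`block`/`row`/`col`).
#' @param design field design passed to [fit_harvest_model()].
#' @return data frame of class `blue_table` with columns `genotype`,
#'   `harvest`, `day`, `blue`, `weight`, `error_variance`, sorted by
#'   `(genotype, day)`; the per-harvest error variances are also kept in
#'   attribute `"harvest_error_variances"`.
#' @export
stage1_blues <- function(plots, design = "rcbd") {
  plots <- as.data.frame(plots)
  need <- c("genotype", "harvest", "day", "yield")
  if (!all(need %in% names(plots))) {
    stop("plot table must contain columns: ", paste(need, collapse = ", "))
  }
  hmap <- unique(plots[, c("harvest", "day")])
  if (anyDuplicated(hmap$harvest)) {
    stop("each harvest identifier must map to exactly one day")
  }
  hmap <- hmap[order(hmap$day), ]
  out <- vector("list", nrow(hmap))
  errs <- numeric(nrow(hmap))
  for (i in seq_len(nrow(hmap))) {
    h <- hmap$harvest[i]
    res <- fit_harvest_model(plots[plots$harvest == h, , drop = FALSE], design)
    if (length(res$dropped)) {
      warning("harvest ", h, ": dropped unobserved genotypes: ",
              paste(res$dropped, collapse = ", "))
    }
    w <- smith_weights(res$vcov)
    errs[i] <- res$error_variance
    out[[i]] <- data.frame(genotype = names(res$blues), harvest = h,
                           day = hmap$day[i], blue = unname(res$blues),
                           weight = unname(w),
                           error_variance = res$error_variance,
                           stringsAsFactors = FALSE)
  }
  assemble_blue_table(out, harvest_error_variances = stats::setNames(errs, hmap$harvest))
}

#' Assemble per-harvest BLUE outputs into one table
#'
#' @param pieces list of per-harvest data frames with columns `genotype`,
#'   `harvest`, `day`, `blue`, `weight`, `error_variance`.
#' @param harvest_error_variances optional named vector of per-harvest error
#'   variances; defaults to the per-harvest values found in the pieces.
#' @return `blue_table` data frame sorted by `(genotype, day)`.
#' @export
assemble_blue_table <- function(pieces, harvest_error_variances = NULL) {
  tab <- do.call(rbind, pieces)
  if (anyDuplicated(tab[, c("genotype", "harvest")])) {
    stop("duplicate (genotype, harvest) rows in BLUE table")
  }
  if (any(tab$weight <= 0)) stop("weights must be strictly positive")
  tab <- tab[order(tab$genotype, tab$day), ]
  rownames(tab) <- NULL
  if (is.null(harvest_error_variances)) {
    u <- unique(tab[, c("harvest", "error_variance")])
    harvest_error_variances <- stats::setNames(u$error_variance, u$harvest)
  }
  attr(tab, "harvest_error_variances") <- harvest_error_variances
  class(tab) <- c("blue_table", "data.frame")
  tab
}

#' Read / write BLUE tables as CSV
#'
#' @param path file path.
#' @return `read_blues()` returns a `blue_table`; `write_blues()` invisibly
#'   returns `path`.
#' @export
read_blues <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("genotype", "harvest", "day", "blue", "weight", "error_variance")
  if (!all(need %in% names(tab))) {
    stop("BLUE csv must contain columns: ", paste(need, collapse = ", "))
  }
  assemble_blue_table(list(tab[need]))
}

#' @rdname read_blues
#' @param blues a `blue_table`.
#' @export
write_blues <- function(blues, path) {
  utils::write.csv(as.data.frame(blues), path, row.names = FALSE)
  invisible(path)
}
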