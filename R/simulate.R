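# All simulation randomness flows from the single config seed; each component
# (schedule, genotype coefficients, design effects, plot/BLUE errors) draws
# from its own deterministic sub-stream so e.g. adding harvests does not
# perturb the genotype coefficient draws.
substream <- function(seed, k) {
  as.integer((as.numeric(seed) %% 65011 + 1) * 7919 + k * 104729) %% 2147483629L
}

rmvnorm_chol <- function(n, Sigma) {
  Sigma <- as.matrix(Sigma)
  q <- nrow(Sigma)
  ee <- eigen(0.5 * (Sigma + t(Sigma)), symmetric = TRUE)
  if (any(ee$values < -1e-8 * max(abs(ee$values), 1e-300))) {
    stop("covariance matrix is not positive semidefinite")
  }
  R <- ee$vectors %*% diag(sqrt(pmax(ee$values, 0)), q) %*% t(ee$vectors)
  matrix(stats::rnorm(n * q), n, q) %*% R
}

#' Configuration for a synthetic multi-harvest trial
#'
#' Bundles and validates the generative assumptions of the random regression
#' model into a reusable simulation configuration. The defaults imitate the
#' magnitudes of a tropical-forage yield trial (yields of a few thousand
#' kg/ha, genetic coefficient variances around \eqn{10^5}, plot error around
#' \eqn{3 \times 10^5}, seasonally alternating harvest gaps) so that derived
#' quantities such as heritabilities land in realistic ranges.
#'
#' @param n_genotypes,n_harvests,n_reps trial dimensions.
#' @param harvest_days `"irregular"` (seasonal gap pattern via
#'   [irregular_schedule()]) or an explicit strictly increasing vector with
#'   first entry 0.
#' @param wet_gap,dry_gap,jitter parameters of the irregular schedule.
#' @param beta fixed-curve coefficients on the normalized Legendre basis;
#'   its length sets the fixed degree.
#' @param K_g symmetric PSD covariance of the genotype random coefficients;
#'   its dimension sets the random degree.
#' @param error_variance per-plot (or per-BLUE) error variance: a scalar or a
#'   vector of length `n_harvests`.
#' @param design field design for plot-level simulation.
#' @param sigma_block2,sigma_row2,sigma_col2 design-effect variances.
#' @param seed integer seed; all randomness derives from it.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_genotypes = 100, n_harvests = 10, n_reps = 3,
                       harvest_days = "irregular",
                       wet_gap = 35, dry_gap = 90, jitter = 0.15,
                       beta = c(3500, 300, -450, 250),
                       K_g = matrix(c(2e5, -4e4, -4e4, 8e4), 2, 2),
                       error_variance = 3e5,
                       design = c("rcbd", "alpha_lattice", "row_column"),
                       sigma_block2 = 5e4, sigma_row2 = 3e4, sigma_col2 = 3e4,
                       seed = 1) {
  design <- match.arg(design)
  K_g <- as.matrix(K_g)
  if (max(abs(K_g - t(K_g))) > 1e-10 * max(abs(K_g), 1)) {
    stop("K_g must be symmetric")
  }
  ev <- eigen(K_g, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-10 * max(abs(ev)))) stop("K_g must be positive semidefinite")
  if (is.numeric(harvest_days)) {
    if (harvest_days[1] != 0 || any(diff(harvest_days) <= 0)) {
      stop("explicit harvest_days must start at 0 and be strictly increasing")
    }
    n_harvests <- length(harvest_days)
  }
  ve <- rep_len(error_variance, n_harvests)
  if (!(length(error_variance) %in% c(1L, n_harvests))) {
    stop("error_variance must be scalar or length n_harvests")
  }
  if (any(ve < 0)) stop("error variances must be non-negative")
  structure(list(n_genotypes = as.integer(n_genotypes),
                 n_harvests = as.integer(n_harvests),
                 n_reps = as.integer(n_reps),
                 harvest_days = harvest_days, wet_gap = wet_gap,
                 dry_gap = dry_gap, jitter = jitter,
                 beta = as.numeric(beta), K_g = K_g,
                 error_variance = ve, design = design,
                 sigma_block2 = sigma_block2, sigma_row2 = sigma_row2,
                 sigma_col2 = sigma_col2, seed = as.integer(seed)),
            class = "sim_config")
}

#' Irregular seasonal harvest schedule
#'
#' Harvests in perennial forage trials are frequent in the favorable (wet)
#' season and sparse in the unfavorable (dry) season. This generator
#' alternates a short wet-season gap and a long dry-season gap, optionally
#' jittered, starting at day 0.
#'
#' @param n_harvests number of harvests.
#' @param wet_gap,dry_gap mean gaps in days (both positive).
#' @param seed integer seed (only used when `jitter > 0`).
#' @param jitter relative jitter: each gap is scaled by a uniform draw on
#'   `[1 - jitter, 1 + jitter]`. `0` gives the deterministic pattern.
#' @return numeric vector of strictly increasing days, first entry 0.
#' @examples
#' irregular_schedule(4, wet_gap = 30, dry_gap = 90, jitter = 0)  # 0 30 120 150
#' @export
irregular_schedule <- function(n_harvests, wet_gap = 35, dry_gap = 90,
                               seed = 1, jitter = 0.15) {
  if (wet_gap <= 0 || dry_gap <= 0) stop("gaps must be positive")
  if (n_harvests < 2) stop("need at least two harvests")
  gaps <- rep_len(c(wet_gap, dry_gap), n_harvests - 1L)
  if (jitter > 0) {
    set.seed(substream(seed, 2L))
    gaps <- gaps * stats::runif(length(gaps), 1 - jitter, 1 + jitter)
  }
  round(cumsum(c(0, gaps)), 1)
}

config_days <- function(config) {
  if (is.numeric(config$harvest_days)) as.numeric(config$harvest_days)
  else irregular_schedule(config$n_harvests, config$wet_gap, config$dry_gap,
                          seed = config$seed, jitter = config$jitter)
}

# genotype curves at the scheduled times: fixed part + Phi2 u_g'
config_curves <- function(config, days) {
  sched <- rescale_times(days)
  d <- length(config$beta) - 1L
  m <- nrow(config$K_g) - 1L
  fixed <- eval_legendre_curve(config$beta, sched$scaled)
  set.seed(substream(config$seed, 1L))
  U <- rmvnorm_chol(config$n_genotypes, config$K_g)
  rownames(U) <- sprintf("G%03d", seq_len(config$n_genotypes))
  phi2 <- legendre_phi(sched$scaled, m)$phi
  gv <- matrix(fixed, config$n_genotypes, length(days), byrow = TRUE) +
    U %*% t(phi2)
  rownames(gv) <- rownames(U)
  list(schedule = sched, fixed = fixed, U = U, gv = gv)
}

#' Simulate a plot-level multi-harvest trial with known truth
#'
#' Draws genotype coefficient rows from \eqn{N(0, K_g)}, builds each
#' genotype's curve on the normalized Legendre basis, adds the fixed seasonal
#' curve, per-harvest design effects (blocks, or rows and columns) and
#' per-plot Gaussian error, and returns the plot records together with the
#' full generating truth. Yields are truncated at zero (rare at the default
#' scales).
#'
#' @param config a [sim_config()].
#' @return list with `plots` (data frame: genotype, harvest, day, yield and
#'   design columns) and `truth` (days, beta, U, K_g, error variances, design
#'   variances, genotypic-value matrix).
#' @export
simulate_trial <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  days <- config_days(config)
  cur <- config_curves(config, days)
  ng <- config$n_genotypes
  nh <- length(days)
  nr <- config$n_reps

  set.seed(substream(config$seed, 3L))
  # per-harvest design effects
  if (config$design == "rcbd") {
    blk <- matrix(stats::rnorm(nh * nr, 0, sqrt(config$sigma_block2)), nh, nr)
  } else if (config$design == "alpha_lattice") {
    block_size <- max(2L, floor(sqrt(ng)))
    n_blocks <- ceiling(ng / block_size)
    ib <- array(stats::rnorm(nh * nr * n_blocks, 0, sqrt(config$sigma_block2)),
                c(nh, nr, n_blocks))
    rep_eff <- matrix(stats::rnorm(nh * nr, 0, sqrt(config$sigma_block2 / 2)),
                      nh, nr)
  } else {
    n_row <- max(2L, ceiling(sqrt(ng * nr)))
    n_col <- ceiling(ng * nr / n_row)
    rowe <- matrix(stats::rnorm(nh * n_row, 0, sqrt(config$sigma_row2)), nh, n_row)
    cole <- matrix(stats::rnorm(nh * n_col, 0, sqrt(config$sigma_col2)), nh, n_col)
  }

  set.seed(substream(config$seed, 4L))
  recs <- vector("list", nh)
  for (h in seq_len(nh)) {
    df <- expand.grid(genotype = rownames(cur$U), rep = seq_len(nr),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    mu <- cur$gv[df$genotype, h]
    if (config$design == "rcbd") {
      df$block <- df$rep
      mu <- mu + blk[h, df$rep]
    } else if (config$design == "alpha_lattice") {
      block_size <- max(2L, floor(sqrt(ng)))
      # genotypes permuted into incomplete blocks independently per rep
      df$block <- NA_integer_
      for (r in seq_len(nr)) {
        i <- which(df$rep == r)
        df$block[i] <- ceiling(sample(ng)[match(df$genotype[i], rownames(cur$U))] /
                                 block_size)
      }
      mu <- mu + rep_eff[h, df$rep] + ib[cbind(h, df$rep, df$block)]
    } else {
      n_row <- max(2L, ceiling(sqrt(ng * nr)))
      pos <- sample(nrow(df)) # random field layout per harvest
      df$row <- ((pos - 1L) %% n_row) + 1L
      df$col <- ((pos - 1L) %/% n_row) + 1L
      mu <- mu + rowe[h, df$row] + cole[h, df$col]
    }
    df$harvest <- paste0("H", h)
    df$day <- days[h]
    df$yield <- pmax(0, mu + stats::rnorm(nrow(df), 0,
                                          sqrt(config$error_variance[h])))
    recs[[h]] <- df
  }
  plots <- do.call(rbind, recs)
  rownames(plots) <- NULL
  list(plots = plots,
       truth = list(days = days, beta = config$beta, U = cur$U,
                    K_g = config$K_g, error_variance = config$error_variance,
                    sigma_block2 = config$sigma_block2,
                    design = config$design, gv = cur$gv))
}

#' Simulate a genotype-by-harvest BLUE table with known truth
#'
#' Skips stage one: each BLUE is the genotype's curve value plus Gaussian
#' error with the configured per-harvest variance, and the Smith weight is
#' the reciprocal of that variance (so the stage-2 residual scale
#' \eqn{\sigma_e^2} is 1 by construction).
#'
#' @param config a [sim_config()].
#' @return list with `blues` (a `blue_table`) and `truth`.
#' @export
simulate_blues <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  days <- config_days(config)
  cur <- config_curves(config, days)
  nh <- length(days)
  set.seed(substream(config$seed, 4L))
  tab <- expand.grid(genotype = rownames(cur$U), hidx = seq_len(nh),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab$harvest <- paste0("H", tab$hidx)
  tab$day <- days[tab$hidx]
  ve <- config$error_variance[tab$hidx]
  tab$blue <- cur$gv[cbind(match(tab$genotype, rownames(cur$gv)), tab$hidx)] +
    stats::rnorm(nrow(tab), 0, sqrt(ve))
  tab$weight <- ifelse(ve > 0, 1 / ve, 1) # unit weight for exact BLUEs
  tab$error_variance <- ve
  tab$hidx <- NULL
  blues <- assemble_blue_table(
    list(tab[, c("genotype", "harvest", "day", "blue", "weight", "error_variance")]),
    harvest_error_variances = stats::setNames(config$error_variance,
                                              paste0("H", seq_len(nh))))
  list(blues = blues,
       truth = list(days = days, beta = config$beta, U = cur$U,
                    K_g = config$K_g, sigma_e2 = 1,
                    error_variance = config$error_variance, gv = cur$gv))
}
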