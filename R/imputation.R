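#' Estimate a complete-data normal from a left-censored sample
#'
#' Quantile-regression estimation of the mean and SD of a normal
#' distribution whose lower tail has been censored. The sorted observed
#' values are paired with standard-normal quantiles at plotting positions
#' `p_i = f + (1 - f) * (i - 0.375) / (n + 0.25)` (Blom positions shifted
#' into the uncensored upper region, `f` = missing fraction), and an
#' ordinary least-squares line is fit over the upper probability window
#' `p_i >= max(f, lower_window)`. The slope estimates sigma, the intercept
#' mu; the truncation point is the estimated `f`-quantile of the complete
#' distribution.
#'
#' @param observed Numeric vector of observed (uncensored) values.
#' @param missing_fraction Fraction of the complete sample censored,
#'   in `[0, 1)`.
#' @param lower_window Lower bound of the probability window (default 0.25).
#' @return A `censored_normal_fit` list: `mu`, `sigma`, `missing_fraction`,
#'   `truncation_point`, `n_obs`.
#' @export
fit_censored_normal <- function(observed, missing_fraction,
                                lower_window = 0.25) {
  observed <- sort(as.numeric(observed[!is.na(observed)]))
  n <- length(observed)
  stopifnot(n >= 20, missing_fraction >= 0, missing_fraction < 1)
  if (stats::sd(observed) == 0) {
    stop("cannot estimate sigma: observed values are degenerate",
         call. = FALSE)
  }
  f <- missing_fraction
  p <- f + (1 - f) * (seq_len(n) - 0.375) / (n + 0.25)
  use <- p >= max(f, lower_window)
  if (sum(use) < 2) use <- rep(TRUE, n)
  q <- stats::qnorm(p[use])
  fit <- stats::lm.fit(cbind(1, q), observed[use])
  mu <- unname(fit$coefficients[1])
  sigma <- unname(fit$coefficients[2])
  if (!is.finite(sigma) || sigma <= 0) {
    stop("cannot estimate sigma from the censored sample", call. = FALSE)
  }
  structure(list(
    mu = mu, sigma = sigma, missing_fraction = f,
    truncation_point = if (f > 0) mu + sigma * stats::qnorm(f) else -Inf,
    n_obs = n
  ), class = "censored_normal_fit")
}

# Draw n values from N(mu, sd) truncated above at `upper` by inverse-CDF.
rtruncnorm_upper <- function(n, mu, sd, upper) {
  pu <- stats::pnorm(upper, mu, sd)
  pu <- max(pu, 1e-12)  # guard: never degenerate even far below the mean
  stats::qnorm(stats::runif(n) * pu, mu, sd)
}

# Per-column censored-normal fits for an intensity matrix; columns with
# fewer than `min_obs` observed values fall back to a pooled global fit.
qrilc_fits <- function(values, min_obs = 20) {
  n_total <- nrow(values)
  global_fit <- NULL
  lapply(seq_len(ncol(values)), function(j) {
    col <- values[, j]
    obs <- col[!is.na(col)]
    if (length(obs) == 0) {
      stop("column ", colnames(values)[j], " is entirely missing",
           call. = FALSE)
    }
    f <- 1 - length(obs) / n_total
    if (length(obs) < min_obs) {
      warning("column ", colnames(values)[j],
              " too sparse for per-sample fitting; using global fit",
              call. = FALSE)
      if (is.null(global_fit)) {
        all_obs <- values[!is.na(values)]
        global_fit <<- fit_censored_normal(all_obs, mean(is.na(values)))
      }
      return(global_fit)
    }
    fit_censored_normal(obs, f)
  })
}

#' Impute left-censored missing values (QRILC)
#'
#' For each sample column, fits a censored normal
#' ([fit_censored_normal()]) and replaces each missing cell with an
#' independent draw from `Normal(mu, tune_sigma * sigma)` truncated above
#' at the column's estimated truncation point. Observed cells are never
#' touched. Fitting is per column because censoring reflects the
#' instrument detection limit, a per-run property.
#'
#' @param matrix An [intensity_matrix()] or a plain proteins x samples
#'   log2 matrix with `NA` for missing.
#' @param seed Integer seed; identical seeds give identical output.
#' @param tune_sigma Multiplier on the fitted sigma for the draws
#'   (default 1.0).
#' @param fits Optional precomputed per-column fits (internal reuse).
#' @return A complete numeric matrix with attribute `"fits"` (the
#'   per-column `censored_normal_fit` list).
#' @export
impute_qrilc <- function(matrix, seed = 1L, tune_sigma = 1.0, fits = NULL) {
  values <- if (inherits(matrix, "intensity_matrix")) matrix$values else matrix
  stopifnot(is.matrix(values), tune_sigma > 0)
  if (is.null(fits)) fits <- qrilc_fits(values)
  set.seed(seed)
  for (j in seq_len(ncol(values))) {
    miss <- which(is.na(values[, j]))
    if (!length(miss)) next
    fit <- fits[[j]]
    values[miss, j] <- rtruncnorm_upper(length(miss), fit$mu,
                                        tune_sigma * fit$sigma,
                                        fit$truncation_point)
  }
  attr(values, "fits") <- fits
  values
}

#' Build a multiple-imputation ensemble
#'
#' Runs [impute_qrilc()] `n_replicates` times with per-replicate seeds
#' derived deterministically from `master_seed`, so the ensemble is
#' reproducible regardless of execution order. Replicates differ only in
#' the imputed cells; the censored-normal fits are estimated once from the
#' observed data and shared.
#'
#' @param matrix An [intensity_matrix()].
#' @param n_replicates Ensemble size (>= 2; the study default is 300).
#' @param master_seed Integer master seed.
#' @param tune_sigma Passed to [impute_qrilc()].
#' @return An `imputed_ensemble`: `replicates` (list of complete
#'   matrices), `replicate_seeds`, `source` (the input), `fits`.
#' @export
build_ensemble <- function(matrix, n_replicates = 300, master_seed = 1L,
                           tune_sigma = 1.0) {
  stopifnot(inherits(matrix, "intensity_matrix"))
  if (n_replicates < 2) {
    stop("n_replicates must be >= 2 (pooling undefined)", call. = FALSE)
  }
  fits <- qrilc_fits(matrix$values)
  seeds <- vapply(seq_len(n_replicates), function(r)
    derive_seed(master_seed, r), integer(1))
  replicates <- lapply(seeds, function(s) {
    m <- impute_qrilc(matrix$values, seed = s, tune_sigma = tune_sigma,
                      fits = fits)
    attr(m, "fits") <- NULL
    m
  })
  structure(list(replicates = replicates, replicate_seeds = seeds,
                 source = matrix, fits = fits),
            class = "imputed_ensemble")
}

#' @export
print.imputed_ensemble <- function(x, ...) {
  cat(sprintf("imputed_ensemble: %d replicates of %d proteins x %d samples\n",
              length(x$replicates), nrow(x$source$values),
              ncol(x$source$values)))
  invisible(x)
}
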