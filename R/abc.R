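# Weighted quantile (type-7-like linear interpolation on the weighted CDF).
weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  cw <- cumsum(w) - w / 2
  stats::approx(cw, x, xout = probs, rule = 2)$y
}

# Shortest interval containing `mass` of the weighted sample.
weighted_hpd <- function(x, w, mass = 0.95) {
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  cw <- cumsum(w)
  n <- length(x)
  best <- c(x[1], x[n])
  best_len <- Inf
  j <- 1L
  for (i in seq_len(n)) {
    lo_mass <- if (i > 1) cw[i - 1] else 0
    j <- max(j, i)
    while (j < n && cw[j] - lo_mass < mass) j <- j + 1L
    if (cw[j] - lo_mass >= mass && x[j] - x[i] < best_len) {
      best_len <- x[j] - x[i]
      best <- c(x[i], x[j])
    }
  }
  best
}

# Weighted-KDE mode (Gaussian kernel, Silverman's bandwidth).
weighted_mode <- function(x, w) {
  if (length(unique(x)) == 1) return(x[1])
  d <- suppressWarnings(
    density(x, weights = w / sum(w), bw = "nrd0", n = 512))
  d$x[which.max(d$y)]
}

#' ABC rejection step
#'
#' Standardizes every summary statistic by its median absolute deviation
#' across the reference table, computes Euclidean distances between the
#' observed vector and every reference row over the statistics finite in
#' both (mean of squared standardized differences, so rows with different
#' missingness masks remain comparable), and retains the `top_k` closest
#' rows with Epanechnikov weights `1 - (d/d_k)^2`.
#'
#' @param ref Reference table: list with `params` (tibble/matrix of
#'   parameter draws) and `stats` (matrix of summary statistics, rows
#'   aligned with `params`).
#' @param observed Named numeric vector of observed statistics (same
#'   columns as `ref$stats`).
#' @param top_k Number of simulations to retain (default 1000).
#' @return A list of class `abc_rejection`: retained `params`, centred
#'   standardized `stats_centred`, `distances`, `weights`, `index`, and
#'   the columns used.
#' @export
abc_reject <- function(ref, observed, top_k = 1000) {
  stats_m <- as.matrix(ref$stats)
  n <- nrow(stats_m)
  if (!n) abort("Empty reference table.")
  if (top_k > n) {
    warn("`top_k` exceeds the reference size; retaining everything.")
    top_k <- n
  }
  observed <- observed[colnames(stats_m)]
  scale <- ref$scale %||%
    apply(stats_m, 2, function(x) mad(x[is.finite(x)]))
  usable <- is.finite(observed) & is.finite(scale) & scale > 0
  if (!any(usable)) abort("No usable summary statistics.")
  z <- sweep(stats_m[, usable, drop = FALSE], 2, observed[usable], "-")
  z <- sweep(z, 2, scale[usable], "/")
  z2 <- z^2
  fin <- is.finite(z2)
  z2[!fin] <- 0
  d2 <- rowSums(z2) / pmax(rowSums(fin), 1L)
  d <- sqrt(d2)
  o <- order(d)[seq_len(top_k)]
  dk <- d[o[top_k]]
  w <- if (dk > 0) 1 - (d[o] / dk)^2 else rep(1, top_k)
  # the k-th row gets weight 0; keep it infinitesimally positive so the
  # retained set always has top_k usable rows
  w <- pmax(w, 1e-12)
  structure(
    list(params = tibble::as_tibble(ref$params)[o, ],
         stats_centred = z[o, , drop = FALSE],
         distances = d[o], weights = w, index = o,
         stat_cols = colnames(stats_m)[usable]),
    class = "abc_rejection"
  )
}

#' Local-linear regression adjustment of retained ABC draws
#'
#' Parameters are log-transformed (all are positive times or sizes), then
#' regressed on the centred standardized statistics with the Epanechnikov
#' weights; each draw is corrected by the fitted linear trend
#' (`theta*_i = theta_i - b'(s_i - s_obs)` on the log scale) and
#' back-transformed by exponentiation, which preserves positivity. The
#' posterior summary reports the weighted mean, the weighted-KDE mode
#' (Gaussian kernel, Silverman bandwidth), the 95% HPD interval (shortest
#' weighted interval) and the equal-tailed 90% credible interval.
#'
#' @param rej An `abc_rejection` from [abc_reject()].
#' @param parameters Optional character vector restricting which parameter
#'   columns are summarized (default: all).
#' @param transform `"log"` (default, for positive times/sizes) or
#'   `"none"` (adjust on the natural scale, e.g. for parameters with
#'   support spanning zero).
#' @return An object of class `abc_posterior`; see [tidy.abc_posterior()].
#' @export
regression_adjust <- function(rej, parameters = NULL,
                              transform = c("log", "none")) {
  transform <- match.arg(transform)
  pm <- as.matrix(rej$params)
  if (!is.null(parameters)) pm <- pm[, parameters, drop = FALSE]
  if (transform == "log" && any(pm <= 0)) {
    abort("Parameters must be positive for the log scale.")
  }
  Y <- if (transform == "log") log(pm) else pm
  X <- rej$stats_centred
  keep <- apply(X, 2, function(x) all(is.finite(x)) && sd(x) > 0)
  X <- X[, keep, drop = FALSE]
  w <- rej$weights
  n <- nrow(Y)
  adjusted <- Y
  ok <- FALSE
  if (n >= 2 * ncol(pm) && ncol(X) > 0) {
    fit <- tryCatch(
      stats::lm.wfit(cbind(`(Intercept)` = 1, X), Y, w),
      error = function(e) NULL)
    if (!is.null(fit) && fit$rank == ncol(X) + 1) {
      B <- as.matrix(fit$coefficients)[-1, , drop = FALSE]
      adjusted <- Y - X %*% B
      ok <- TRUE
    }
  }
  if (!ok) {
    warn("Singular or underdetermined regression design; falling back to the unadjusted rejection posterior.")
  }
  draws <- if (transform == "log") exp(adjusted) else adjusted
  summary <- purrr::map_dfr(seq_len(ncol(draws)), function(j) {
    x <- draws[, j]
    hpd <- weighted_hpd(x, w, 0.95)
    ci <- weighted_quantile(x, w, c(0.05, 0.95))
    tibble::tibble(
      parameter = colnames(draws)[j],
      mean = weighted.mean(x, w),
      mode = weighted_mode(x, w),
      hpd95_lower = hpd[1], hpd95_upper = hpd[2],
      ci90_lower = ci[1], ci90_upper = ci[2]
    )
  })
  structure(
    list(summary = summary, draws = draws, weights = w / sum(w),
         adjusted = ok, n_retained = n),
    class = "abc_posterior"
  )
}

#' @export
print.abc_posterior <- function(x, ...) {
  cat(sprintf("<abc_posterior> %d retained draws%s\n", x$n_retained,
              if (x$adjusted) ", regression-adjusted" else " (rejection only)"))
  print(as.data.frame(x$summary), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Tidy an ABC posterior
#' @param x An `abc_posterior`.
#' @param ... Unused.
#' @return Tibble with one row per parameter: `mean`, `mode`,
#'   `hpd95_lower`, `hpd95_upper`, `ci90_lower`, `ci90_upper`.
#' @method tidy abc_posterior
#' @export
tidy.abc_posterior <- function(x, ...) x$summary

#' @method glance abc_posterior
#' @export
glance.abc_posterior <- function(x, ...) {
  tibble::tibble(n_retained = x$n_retained, adjusted = x$adjusted,
                 n_parameters = ncol(x$draws))
}

#' Validation metrics from true values and estimates
#'
#' Per-parameter reliability measures computed across pseudo-observed
#' datasets: squared Pearson correlation of true value versus estimate,
#' relative bias `mean((est - true)/true)`, relative RMSE
#' `sqrt(mean(((est - true)/true)^2))`, coverage of the nominal 90%
#' equal-tailed credible interval, and factor-2 (fraction of estimates
#' within 50%-200% of the truth, boundaries inclusive).
#'
#' @param truth,est Matrices (pods x parameters) of true values and point
#'   estimates, matching column names.
#' @param lo90,hi90 Matrices of the 90% credible-interval bounds.
#' @return A tibble (class `validation_report`) with one row per
#'   parameter: `parameter`, `r2`, `bias`, `rmse`, `coverage`, `factor2`.
#' @export
validation_metrics <- function(truth, est, lo90, hi90) {
  stopifnot(identical(dim(truth), dim(est)))
  out <- purrr::map_dfr(seq_len(ncol(truth)), function(j) {
    tr <- truth[, j]; e <- est[, j]
    rel <- (e - tr) / tr
    tibble::tibble(
      parameter = colnames(truth)[j],
      r2 = suppressWarnings(cor(tr, e))^2,
      bias = mean(rel),
      rmse = sqrt(mean(rel^2)),
      coverage = mean(lo90[, j] <= tr & tr <= hi90[, j]),
      factor2 = mean(e / tr >= 0.5 & e / tr <= 2)
    )
  })
  class(out) <- c("validation_report", class(out))
  out
}

#' @method glance validation_report
#' @export
glance.validation_report <- function(x, ...) {
  tibble::tibble(
    n_parameters = nrow(x),
    r2 = mean(x$r2), abs_bias = mean(abs(x$bias)), rmse = mean(x$rmse),
    coverage = mean(x$coverage), factor2 = mean(x$factor2)
  )
}
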