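# ABC experiment wrappers: reference-table construction for the two
# estimation stages, estimation on observed data, and pseudo-observed
# dataset (pod) validation.

# Internal: draw parameters and simulate summary statistics for one batch.
# Stage 1 draws the six divergence times jointly with TWO independent size
# sets (female sizes driving the mtDNA genealogy, male sizes the NRY one)
# and concatenates both loci's statistics. Stage 2 fixes the times and
# draws the 13 sizes of one locus.
stage1_batch <- function(priors, cfg, n, loci, g) {
  base <- draw_parameters(priors, n)
  nry_sizes <- draw_parameters(priors, n)[SIZE_PARAMS]
  stats_mt <- simulate_sumstats(base, cfg, loci$mt, g)
  nry_params <- dplyr::bind_cols(base[TIME_PARAMS], nry_sizes)
  stats_nry <- simulate_sumstats(nry_params, cfg, loci$nry, g)
  colnames(stats_mt) <- paste0("mt_", colnames(stats_mt))
  colnames(stats_nry) <- paste0("nry_", colnames(stats_nry))
  params <- dplyr::bind_cols(
    base[TIME_PARAMS],
    setNames(base[SIZE_PARAMS], paste0("mt_", SIZE_PARAMS)),
    setNames(nry_sizes, paste0("nry_", SIZE_PARAMS))
  )
  list(params = params, stats = cbind(stats_mt, stats_nry))
}

stage2_batch <- function(priors, cfg, n, locus, g, fixed_times) {
  sizes <- draw_parameters(priors, n)[SIZE_PARAMS]
  tm <- tibble::as_tibble(as.list(fixed_times[TIME_PARAMS]))[
    rep(1, n), ]
  params <- dplyr::bind_cols(tm, sizes)
  stats <- simulate_sumstats(params, cfg, locus, g)
  list(params = sizes, stats = stats, full_params = params)
}

#' Build an ABC reference table
#'
#' Stage 1 (`kind = "stage1"`) estimates the divergence times `T1..T6`
#' from the combined mtDNA + NRY data: each reference row draws the times
#' and two independent size sets (female sizes for the mtDNA genealogy,
#' male sizes for the NRY genealogy) and records both loci's summary
#' statistics; the sizes are nuisance parameters marginalized by ignoring
#' them in the summary. Stage 2 (`kind = "stage2"`) fixes the times
#' (typically at the stage-1 posterior means) and draws the 13 size
#' parameters of a single locus.
#'
#' @param kind `"stage1"` or `"stage2"`.
#' @param priors A [prior_spec()].
#' @param cfg A [sample_config()].
#' @param n_draws Number of reference simulations.
#' @param locus For stage 2: a [locus_spec()] (`"mtDNA"` for female sizes,
#'   `"NRY"` for male sizes).
#' @param fixed_times For stage 2: named vector `T1..T6` in years.
#' @param generation_time Years per generation.
#' @param nry_rate NRY rate choice for the stage-1 locus pair.
#' @param seed Optional integer seed.
#' @return An object of class `abc_reference` with elements `params`
#'   (tibble of draws), `stats` (matrix), `target_params`, and the
#'   configuration needed to simulate pseudo-observed datasets.
#' @export
abc_reference <- function(kind = c("stage1", "stage2"), priors, cfg,
                          n_draws, locus = NULL, fixed_times = NULL,
                          generation_time = 25, nry_rate = "avg",
                          seed = NULL) {
  kind <- match.arg(kind)
  if (!is.null(seed)) set.seed(seed)
  if (kind == "stage1") {
    loci <- list(mt = locus_spec("mtDNA"),
                 nry = locus_spec("NRY", nry_rate = nry_rate))
    batch <- stage1_batch(priors, cfg, n_draws, loci, generation_time)
    target <- TIME_PARAMS
  } else {
    if (is.null(locus) || is.null(fixed_times)) {
      abort("Stage 2 needs `locus` and `fixed_times`.")
    }
    loci <- list(locus = locus)
    batch <- stage2_batch(priors, cfg, n_draws, locus, generation_time,
                          fixed_times)
    target <- SIZE_PARAMS
  }
  scale <- apply(batch$stats, 2, function(x) mad(x[is.finite(x)]))
  structure(
    list(kind = kind, params = batch$params, stats = batch$stats,
         target_params = target, priors = priors, cfg = cfg,
         loci = loci, fixed_times = fixed_times,
         generation_time = generation_time, scale = scale),
    class = "abc_reference"
  )
}

#' @export
print.abc_reference <- function(x, ...) {
  cat(sprintf("<abc_reference> %s: %d draws x %d statistics\n",
              x$kind, nrow(x$stats), ncol(x$stats)))
  invisible(x)
}

#' Estimate parameters from observed statistics with an ABC reference
#'
#' Runs the rejection step and the log-scale local-linear regression
#' adjustment, summarizing only the reference's target parameters
#' (divergence times for stage 1, effective sizes for stage 2).
#'
#' @param ref An [abc_reference()].
#' @param observed Named numeric vector of observed summary statistics.
#' @param top_k Retained simulations (default 500).
#' @return An `abc_posterior`.
#' @export
abc_estimate <- function(ref, observed, top_k = 500) {
  rej <- abc_reject(ref, observed, top_k)
  if (ref$kind == "stage1") {
    rej$params <- rej$params[TIME_PARAMS]
  }
  regression_adjust(rej)
}

#' Validate an ABC experiment with pseudo-observed datasets
#'
#' Draws `n_pods` parameter sets from the priors, simulates data under
#' each, runs the full rejection + regression pipeline against `ref`, and
#' scores the reliability of the estimates: per-parameter R-squared,
#' relative bias, relative RMSE, coverage of the nominal 90% equal-tailed
#' credible interval, and the factor-2 fraction.
#'
#' @param ref An [abc_reference()].
#' @param n_pods Number of pseudo-observed datasets (default 100; fewer
#'   than 10 triggers a warning as the metrics become unstable).
#' @param top_k Retained simulations per pod (default 500).
#' @param seed Optional integer seed.
#' @return A `validation_report` tibble (see [validation_metrics()]) with
#'   attributes `truth`, `est`, `lo90`, `hi90` (pods x parameters).
#' @export
validate_with_pods <- function(ref, n_pods = 100, top_k = 500,
                               seed = NULL) {
  if (n_pods < 10) warn("Fewer than 10 pods: validation metrics are unstable.")
  if (!is.null(seed)) set.seed(seed)
  g <- ref$generation_time
  if (ref$kind == "stage1") {
    batch <- stage1_batch(ref$priors, ref$cfg, n_pods, ref$loci, g)
    truth <- as.matrix(batch$params[TIME_PARAMS])
  } else {
    batch <- stage2_batch(ref$priors, ref$cfg, n_pods, ref$loci$locus, g,
                          ref$fixed_times)
    truth <- as.matrix(batch$params)
  }
  P <- ncol(truth)
  est <- lo <- hi <- matrix(NA_real_, n_pods, P,
                            dimnames = list(NULL, colnames(truth)))
  for (i in seq_len(n_pods)) {
    post <- abc_estimate(ref, batch$stats[i, ], top_k)
    s <- post$summary
    stopifnot(identical(s$parameter, colnames(truth)))
    est[i, ] <- s$mean
    lo[i, ] <- s$ci90_lower
    hi[i, ] <- s$ci90_upper
  }
  out <- validation_metrics(truth, est, lo, hi)
  attr(out, "truth") <- truth
  attr(out, "est") <- est
  attr(out, "lo90") <- lo
  attr(out, "hi90") <- hi
  out
}

#' Stage 1: divergence-time estimation from combined mtDNA + NRY data
#'
#' @param observed Named vector of combined summary statistics (prefixes
#'   `mt_`/`nry_`), e.g. from [summarize_stats()] on each locus.
#' @param priors A [prior_spec()].
#' @param cfg A [sample_config()].
#' @param n_draws Reference-table size.
#' @param top_k Retained simulations.
#' @param generation_time Years per generation.
#' @param seed Optional integer seed.
#' @param ref Optional pre-built stage-1 [abc_reference()] to reuse.
#' @return List with `posterior` (`abc_posterior` for `T1..T6`) and `ref`.
#' @export
run_stage1 <- function(observed, priors = prior_spec(),
                       cfg = sample_config(), n_draws = 50000,
                       top_k = 500, generation_time = 25, seed = NULL,
                       ref = NULL) {
  if (is.null(ref)) {
    ref <- abc_reference("stage1", priors, cfg, n_draws,
                         generation_time = generation_time, seed = seed)
  }
  list(posterior = abc_estimate(ref, observed, top_k), ref = ref)
}

#' Stage 2: sex-specific effective-size estimation for one locus
#'
#' @param locus A [locus_spec()]: `"mtDNA"` estimates female sizes,
#'   `"NRY"` male sizes.
#' @param fixed_times Named `T1..T6` divergence times in years (typically
#'   the stage-1 posterior means).
#' @inheritParams run_stage1
#' @return List with `posterior` (`abc_posterior` for the 13 sizes) and
#'   `ref`.
#' @export
run_stage2 <- function(observed, locus, fixed_times,
                       priors = prior_spec(), cfg = sample_config(),
                       n_draws = 50000, top_k = 500,
                       generation_time = 25, seed = NULL, ref = NULL) {
  if (is.null(ref)) {
    ref <- abc_reference("stage2", priors, cfg, n_draws, locus = locus,
                         fixed_times = fixed_times,
                         generation_time = generation_time, seed = seed)
  }
  list(posterior = abc_estimate(ref, observed, top_k), ref = ref)
}
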