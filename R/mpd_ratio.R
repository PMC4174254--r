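#' Ratio of paternal to maternal mean pairwise differences, with a
#' resampling null
#'
#' The observed statistic for a group is `mpd_NRY(group) / mpd_mt(group)`.
#' To detect group-specific deviations from the dataset-wide relationship
#' between the two loci, the null distribution for a group of size
#' `N_group` is obtained by drawing `N_group` individuals at random
#' (without replacement) from the full sample universe and recomputing the
#' ratio; the two-sided empirical p-value uses the add-one correction
#' `p = min(1, 2 * min(P(null <= obs), P(null >= obs)))`.
#'
#' @param nry,mt [hap_matrix()] objects over the same sample universe
#'   (matched by sample id).
#' @param groups Named list of sample-id vectors, or a `sample_table` plus
#'   `by` column from which groups are formed.
#' @param by Grouping column when `groups` is a metadata table.
#' @param reps Null resampling draws per group size (default 10000).
#' @param seed Optional integer seed.
#' @return A tibble with one row per group: `group`, `n`, `mpd_nry`,
#'   `mpd_mt`, `ratio`, `p_value`, and the null mean/quantiles.
#' @export
mpd_ratio_resample <- function(nry, mt, groups, by = "region",
                               reps = 10000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  common <- intersect(sample_ids(nry), sample_ids(mt))
  if (!setequal(sample_ids(nry), sample_ids(mt))) {
    abort("NRY and mtDNA matrices must cover the same sample universe.")
  }
  if (inherits(groups, "sample_table") || is.data.frame(groups)) {
    groups <- split(groups$sample_id, groups[[by]])
  }
  d_nry <- hap_distances(nry)[common, common]
  d_mt <- hap_distances(mt)[common, common]
  n_tot <- length(common)
  mpd_of <- function(d, idx) sum(d[idx, idx]) / (length(idx) * (length(idx) - 1))
  purrr::map_dfr(names(groups), function(gname) {
    ids <- intersect(groups[[gname]], common)
    k <- length(ids)
    if (k < 2) {
      warn(paste0("Group ", gname, " has fewer than 2 samples; skipped."))
      return(NULL)
    }
    mpd_mt_g <- mpd_of(d_mt, ids)
    if (mpd_mt_g == 0) {
      abort(paste0("Undefined ratio: mpd_mt is 0 in group ", gname, "."))
    }
    obs <- mpd_of(d_nry, ids) / mpd_mt_g
    null <- vapply(seq_len(reps), function(r) {
      idx <- sample.int(n_tot, k)
      den <- mpd_of(d_mt, idx)
      if (den == 0) return(NA_real_)
      mpd_of(d_nry, idx) / den
    }, 0)
    null <- null[is.finite(null)]
    p_lo <- (1 + sum(null <= obs + 1e-12)) / (length(null) + 1)
    p_hi <- (1 + sum(null >= obs - 1e-12)) / (length(null) + 1)
    tibble::tibble(
      group = gname, n = k,
      mpd_nry = mpd_of(d_nry, ids), mpd_mt = mpd_mt_g, ratio = obs,
      null_mean = mean(null),
      null_lo = unname(quantile(null, 0.025)),
      null_hi = unname(quantile(null, 0.975)),
      p_value = min(1, 2 * min(p_lo, p_hi))
    )
  })
}
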