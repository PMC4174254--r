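#' Sequential nearest-haplotype imputation for a non-recombining locus
#'
#' Complete linkage on a non-recombining locus means a missing call can be
#' copied from the closest haplotype. All sites with no missing data form
#' the initial reference set; remaining sites are processed in increasing
#' order of missing count (ties by genomic position). For every sample
#' missing at the current site, the Hamming distance to every sample
#' observed at that site is computed over the current reference set, and
#' the allele of the minimum-distance donor is copied. Ties among equally
#' close donors are broken by majority allele, then by the allele of the
#' donor earliest in sample order. After a site is completed it joins the
#' reference set, so later sites see previously imputed calls.
#'
#' @param m A [hap_matrix()] with at least one missing-free site.
#' @return A list of class `imputation_result`: `matrix` (the completed,
#'   missing-free [hap_matrix()]), `fill_log` (tibble: `position`,
#'   `sample_id`, `allele`, `donor`, `distance`), and
#'   `n_reference_sites` (size of the initial reference set).
#' @export
impute_missing <- function(m) {
  g <- m$geno
  n <- nrow(g)
  miss_per_site <- colSums(is.na(g))
  if (!any(miss_per_site > 0)) {
    return(structure(
      list(matrix = m,
           fill_log = tibble::tibble(position = integer(),
                                     sample_id = character(),
                                     allele = integer(), donor = character(),
                                     distance = numeric()),
           n_reference_sites = ncol(g)),
      class = "imputation_result"))
  }
  complete <- which(miss_per_site == 0)
  if (!length(complete)) {
    abort("Imputation requires at least one site with no missing data.")
  }
  if (any(miss_per_site == n)) {
    abort("Unimputable: some site is missing in every sample.")
  }
  # pairwise mismatch counts over the growing reference set
  a <- g[, complete, drop = FALSE]
  b <- 1L - a
  D <- a %*% t(b) + b %*% t(a)
  order_sites <- setdiff(order(miss_per_site, m$sites$position),
                         complete)
  ids <- rownames(g)
  log_rows <- vector("list", length(order_sites))
  for (k in seq_along(order_sites)) {
    s <- order_sites[k]
    col <- g[, s]
    mis <- which(is.na(col))
    obs <- which(!is.na(col))
    filled <- integer(length(mis))
    donors <- character(length(mis))
    dists <- numeric(length(mis))
    for (t in seq_along(mis)) {
      i <- mis[t]
      dvec <- D[i, obs]
      nearest <- obs[dvec == min(dvec)]
      alleles <- col[nearest]
      mean_a <- mean(alleles)
      allele <- if (mean_a > 0.5) 1L else if (mean_a < 0.5) 0L else
        col[nearest[1]]  # exact tie: earliest donor in sample order
      filled[t] <- allele
      donors[t] <- ids[nearest[which(alleles == allele)[1]]]
      dists[t] <- min(dvec)
    }
    col[mis] <- filled
    g[, s] <- col
    # site joins the reference set: update pairwise distances
    D <- D + outer(col, 1L - col) + outer(1L - col, col)
    log_rows[[k]] <- tibble::tibble(
      position = m$sites$position[s], sample_id = ids[mis],
      allele = filled, donor = donors, distance = dists
    )
  }
  out <- m
  out$geno <- g
  structure(
    list(matrix = out, fill_log = dplyr::bind_rows(log_rows),
         n_reference_sites = length(complete)),
    class = "imputation_result"
  )
}

#' @export
print.imputation_result <- function(x, ...) {
  cat(sprintf("<imputation_result> %d calls imputed (%d reference sites)\n",
              nrow(x$fill_log), x$n_reference_sites))
  invisible(x)
}

#' @method tidy imputation_result
#' @export
tidy.imputation_result <- function(x, ...) x$fill_log

# Draw per-sample missing counts emulating the skewed empirical
# distribution of missing calls (mean 122, range 9-1173 out of 2276
# sites), rescaled to a matrix of S sites and an overall fraction.
default_missing_counts <- function(n, S, fraction) {
  lo <- max(1L, round(9 * S / 2276))
  hi <- min(S - 1L, round(1173 * S / 2276))
  counts <- stats::rlnorm(n, meanlog = log(80), sdlog = 0.9)
  target <- fraction * n * S
  counts <- counts * target / sum(counts)
  pmin(pmax(round(counts), lo), hi)
}

#' Mask-and-revalidate accuracy assessment of the imputation
#'
#' Randomly deletes a fraction of the known alleles of a complete matrix
#' (optionally following a supplied per-sample missing-count distribution,
#' resampled and rescaled to the matrix dimensions), re-imputes them, and
#' scores the fraction of imputed alleles matching the truth.
#'
#' @param m A complete (missing-free) [hap_matrix()].
#' @param fraction Fraction of cells to mask, in (0, 1); default 0.0254.
#' @param per_sample_counts Optional integer vector of per-sample missing
#'   counts to resample; `NULL` places masks uniformly at random, `"empirical"`
#'   uses a skewed distribution emulating real capture data (see Details).
#' @param reps Number of replicates (default 1000).
#' @param seed Integer seed (results are deterministic given the seed).
#' @return A list of class `masking_report`: `accuracy` (mean over
#'   replicates), `per_replicate` (tibble with `rep`, `n_masked`,
#'   `accuracy`), `fraction`, `reps`.
#' @export
mask_and_validate <- function(m, fraction = 0.0254,
                              per_sample_counts = NULL, reps = 1000,
                              seed = 1L) {
  if (fraction <= 0 || fraction >= 1) {
    abort("`fraction` must be strictly between 0 and 1.")
  }
  if (anyNA(m$geno)) abort("Masking requires a complete matrix.")
  set.seed(seed)
  g0 <- m$geno
  n <- nrow(g0); S <- ncol(g0)
  acc <- numeric(reps)
  n_masked <- integer(reps)
  for (r in seq_len(reps)) {
    if (is.null(per_sample_counts)) {
      total <- round(fraction * n * S)
      cells <- sample.int(n * S, total)
      mask <- matrix(FALSE, n, S)
      mask[cells] <- TRUE
    } else {
      counts <- if (identical(per_sample_counts, "empirical")) {
        default_missing_counts(n, S, fraction)
      } else {
        cnt <- sample(per_sample_counts, n, replace = TRUE)
        tgt <- fraction * n * S
        pmin(pmax(round(cnt * tgt / sum(cnt)), 1L), S - 1L)
      }
      mask <- matrix(FALSE, n, S)
      for (i in seq_len(n)) {
        mask[i, sample.int(S, counts[i])] <- TRUE
      }
    }
    # keep the problem well-posed: at least one observed call per site and
    # at least one fully observed site
    full_cols <- which(colSums(mask) == n)
    for (s in full_cols) mask[sample.int(n, 1), s] <- FALSE
    if (all(colSums(mask) > 0)) {
      s_min <- which.min(colSums(mask))
      mask[, s_min] <- FALSE
    }
    gm <- g0
    gm[mask] <- NA_integer_
    mm <- m
    mm$geno <- gm
    res <- impute_missing(mm)
    acc[r] <- mean(res$matrix$geno[mask] == g0[mask])
    n_masked[r] <- sum(mask)
  }
  structure(
    list(accuracy = mean(acc),
         per_replicate = tibble::tibble(rep = seq_len(reps),
                                        n_masked = n_masked,
                                        accuracy = acc),
         fraction = fraction, reps = reps),
    class = "masking_report"
  )
}

#' @export
print.masking_report <- function(x, ...) {
  cat(sprintf(
    "<masking_report> %d replicates at %.2f%% masking: accuracy %.4f\n",
    x$reps, 100 * x$fraction, x$accuracy))
  invisible(x)
}

#' @method glance masking_report
#' @export
glance.masking_report <- function(x, ...) {
  tibble::tibble(reps = x$reps, fraction = x$fraction,
                 accuracy = x$accuracy,
                 accuracy_sd = sd(x$per_replicate$accuracy))
}
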