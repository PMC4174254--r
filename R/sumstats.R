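# Summary-statistic vector machinery shared by the observed-data path and
# the simulator's fast path. Per locus the vector holds, in fixed order:
# per-region S, mpd and Tajima's D (6 regions each), pairwise Phi-ST for
# the 15 region pairs, and the two variance components of a two-level
# AMOVA of Africa versus pooled non-Africa. Undefined entries (e.g. D when
# S = 0, or statistics of an unsampled region) are NaN sentinels, excluded
# from ABC distances by masking.

region_tag <- function(x) gsub(" ", "", x)

stat_names <- function() {
  rg <- region_tag(DEME_ORDER)
  pairs <- utils::combn(rg, 2)
  c(paste0("S_", rg), paste0("mpd_", rg), paste0("D_", rg),
    paste0("phist_", pairs[1, ], "_", pairs[2, ]),
    "amova_among", "amova_within")
}

# Two-level AMOVA components from pair sums, vectorised across
# simulations: w1/w2 within-population pair sums, b between; n1/n2 sizes.
.amova2_vec <- function(w1, w2, b, n1, n2) {
  N <- n1 + n2
  ssd_t <- (w1 + w2 + b) / N
  ssd_wp <- w1 / n1 + w2 / n2
  ssd_ap <- ssd_t - ssd_wp
  sigma_c <- ssd_wp / (N - 2)
  n_prime <- N - (n1^2 + n2^2) / N
  sigma_a <- (ssd_ap - sigma_c) / n_prime
  list(sigma_a = sigma_a, sigma_c = sigma_c,
       phi = sigma_a / (sigma_a + sigma_c))
}

# Convert raw sufficient statistics (n_sims x 27: S[6], W[6], B[15]) to
# the summary-statistic matrix (n_sims x 35).
raw_to_stats <- function(raw, nsam) {
  raw <- rbind(raw)
  n_sims <- nrow(raw)
  S <- raw[, 1:6, drop = FALSE]
  W <- raw[, 7:12, drop = FALSE]
  B <- raw[, 13:27, drop = FALSE]
  mpd <- matrix(NaN, n_sims, 6)
  D <- matrix(NaN, n_sims, 6)
  for (r in 1:6) {
    n_r <- nsam[r]
    if (n_r >= 2) {
      mpd[, r] <- W[, r] / (n_r * (n_r - 1) / 2)
      D[, r] <- tajimas_d_value(S[, r], mpd[, r], n_r)
    } else {
      S[, r] <- NaN
    }
  }
  phi <- matrix(NaN, n_sims, 15)
  k <- 0L
  for (r in 1:5) {
    for (s in (r + 1):6) {
      k <- k + 1L
      n1 <- nsam[r]; n2 <- nsam[s]
      if (n1 >= 1 && n2 >= 1 && n1 + n2 >= 3) {
        cmp <- .amova2_vec(W[, r], W[, s], B[, k], n1, n2)
        phi[, k] <- cmp$phi
      }
    }
  }
  # Africa (deme 1) versus pooled non-Africa (demes 2..6)
  n_a <- nsam[1]
  n_b <- sum(nsam[2:6])
  w_b <- rowSums(W[, 2:6, drop = FALSE])
  b_within_nonafr <- 0
  b_afr <- 0
  k <- 0L
  for (r in 1:5) {
    for (s in (r + 1):6) {
      k <- k + 1L
      if (r == 1) b_afr <- b_afr + B[, k]
      else b_within_nonafr <- b_within_nonafr + B[, k]
    }
  }
  grp <- .amova2_vec(W[, 1], w_b + b_within_nonafr, b_afr, n_a, n_b)
  out <- cbind(S, mpd, D, phi, grp$sigma_a, grp$sigma_c)
  colnames(out) <- stat_names()
  out[!is.finite(out)] <- NaN
  out
}

#' Summary-statistic vector of observed haplotype data
#'
#' Computes the per-region diversity statistics (segregating sites, mean
#' pairwise differences, Tajima's D), all pairwise regional Phi-ST values,
#' and the Africa-versus-non-Africa AMOVA variance components, in the
#' fixed ordering used by the ABC machinery. Undefined entries are NaN.
#'
#' @param m A [hap_matrix()].
#' @param regions Character vector of region labels aligned with the
#'   samples (labels outside the six model regions are dropped).
#' @return Named numeric vector of 35 statistics.
#' @export
summarize_stats <- function(m, regions) {
  stopifnot(length(regions) == nrow(m$geno))
  keep <- regions %in% DEME_ORDER
  m <- m[keep, ]
  regions <- regions[keep]
  d <- hap_distances(m)
  g <- m$geno
  nsam <- vapply(DEME_ORDER, function(r) sum(regions == r), 0L)
  idx <- lapply(DEME_ORDER, function(r) which(regions == r))
  raw <- numeric(27)
  for (r in 1:6) {
    i <- idx[[r]]
    if (length(i) >= 1) {
      sub <- g[i, , drop = FALSE]
      n0 <- colSums(sub == 0L, na.rm = TRUE)
      n1 <- colSums(sub == 1L, na.rm = TRUE)
      raw[r] <- sum(n0 > 0 & n1 > 0)
      raw[6 + r] <- sum(d[i, i]) / 2
    }
  }
  k <- 0L
  for (r in 1:5) {
    for (s in (r + 1):6) {
      k <- k + 1L
      raw[12 + k] <- sum(d[idx[[r]], idx[[s]]])
    }
  }
  stats <- raw_to_stats(matrix(raw, 1), nsam)
  setNames(as.numeric(stats), colnames(stats))
}

#' Simulate summary-statistic vectors under the demographic model
#'
#' Fast path for ABC: simulates one genealogy (per locus) per parameter
#' row and returns the summary-statistic matrix without constructing
#' haplotype matrices. Mutations are Poisson on branches under infinite
#' sites.
#'
#' @param params Tibble of parameter draws (columns `T1..T6` in years plus
#'   the 13 size parameters), e.g. from [draw_parameters()].
#' @param cfg A [sample_config()].
#' @param locus A [locus_spec()].
#' @param generation_time Years per generation.
#' @param seed Optional integer seed.
#' @return Matrix with one row per parameter draw and the 35 named
#'   summary statistics as columns.
#' @export
simulate_sumstats <- function(params, cfg = sample_config(), locus,
                              generation_time = 25, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pm <- params_to_matrix(params, generation_time)
  mu_gen <- locus_mu_gen(locus, generation_time)
  raw <- sim_raw_batch_cpp(pm, unname(cfg), mu_gen)
  raw_to_stats(raw, unname(cfg))
}
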