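# Tajima's constants for sample size n: a1, a2, b1, b2, c1, c2, e1, e2.
tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

# Tajima's D from segregating sites and mean pairwise differences;
# undefined (NA) when S = 0.
tajimas_d_value <- function(S, mpd, n) {
  k <- tajima_constants(n)
  v <- k$e1 * S + k$e2 * S * (S - 1)
  ifelse(S > 0, (mpd - S / k$a1) / sqrt(v), NA_real_)
}

#' Pairwise difference matrix
#'
#' Hamming distances (counts of differing sites) between all sample pairs,
#' with pairwise deletion over missing calls and no rescaling.
#'
#' @param m A [hap_matrix()].
#' @return A symmetric integer-valued matrix with sample ids as dimnames.
#' @export
hap_distances <- function(m) {
  g <- m$geno
  obs <- !is.na(g)
  p <- g; p[!obs] <- 0L
  q <- (1L - g); q[!obs] <- 0L
  d <- p %*% t(q) + q %*% t(p)
  dimnames(d) <- list(rownames(g), rownames(g))
  d
}

#' Diversity summary statistics for a set of haplotypes
#'
#' Computes the classical battery of within-group diversity statistics:
#' haplotype diversity `H = n/(n-1) * (1 - sum p_i^2)`, number of
#' segregating sites `S`, mean number of pairwise differences `mpd` with
#' its standard error from the no-recombination total variance
#' `b1*mpd + b2*mpd^2`, per-site nucleotide diversity `pi = mpd / L`,
#' Watterson's `theta_S = S / a_n` (per locus and per site), and Tajima's
#' `D = (mpd - theta_S) / sqrt(e1*S + e2*S*(S-1))`. `D` is reported as `NA`
#' (undefined), not 0, when `S = 0`.
#'
#' @param m A [hap_matrix()] (2 or more samples). Pairwise comparisons use
#'   pairwise deletion over non-missing sites.
#' @param L Callable locus length in bp used to scale `pi` (defaults to the
#'   number of sites in `m`).
#' @return A one-row tibble with columns `n`, `H`, `S`, `mpd`, `mpd_se`,
#'   `pi`, `pi_se`, `theta_s`, `theta_s_site`, `tajimas_d`.
#' @export
#' @examples
#' m <- hap_matrix(rbind(a = c(0,0,0), b = c(0,0,1),
#'                       c = c(0,1,1), d = c(1,1,1)), position = 1:3)
#' diversity_stats(m, L = 6)
diversity_stats <- function(m, L = NULL) {
  g <- m$geno
  n <- nrow(g)
  if (n < 2) abort("Need at least two samples.")
  L <- L %||% ncol(g)
  # segregating sites: columns with both alleles observed
  n0 <- colSums(g == 0L, na.rm = TRUE)
  n1 <- colSums(g == 1L, na.rm = TRUE)
  S <- sum(n0 > 0 & n1 > 0)
  d <- hap_distances(m)
  mpd <- sum(d) / (n * (n - 1))
  hap_key <- apply(g, 1, paste0, collapse = "")
  p_i <- as.numeric(table(hap_key)) / n
  H <- n / (n - 1) * (1 - sum(p_i^2))
  k <- tajima_constants(n)
  mpd_var <- k$b1 * mpd + k$b2 * mpd^2
  tibble::tibble(
    n = n, H = H, S = S,
    mpd = mpd, mpd_se = sqrt(mpd_var),
    pi = mpd / L, pi_se = sqrt(mpd_var) / L,
    theta_s = S / k$a1, theta_s_site = S / (k$a1 * L),
    tajimas_d = tajimas_d_value(S, mpd, n)
  )
}

#' Diversity statistics by group
#'
#' @param m A [hap_matrix()].
#' @param groups Character vector of group labels aligned with the samples
#'   of `m` (or a `sample_table`, in which case `by` selects the column).
#' @param by Grouping column when `groups` is a metadata table.
#' @param L Callable length for the `pi` scaling.
#' @return A tibble with one row per group (groups with fewer than 2
#'   samples are skipped with a warning).
#' @export
diversity_by <- function(m, groups, by = "region", L = NULL) {
  if (inherits(groups, "sample_table") || is.data.frame(groups)) {
    groups <- align_metadata(m, groups)[[by]]
  }
  stopifnot(length(groups) == nrow(m$geno))
  keep <- split(seq_along(groups), groups)
  small <- names(keep)[lengths(keep) < 2]
  if (length(small)) {
    warn(paste0("Skipping group(s) with n < 2: ",
                paste(small, collapse = ", ")))
    keep <- keep[lengths(keep) >= 2]
  }
  purrr::map_dfr(names(keep), function(gname) {
    dplyr::bind_cols(tibble::tibble(group = gname),
                     diversity_stats(m[keep[[gname]], ], L = L))
  })
}
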