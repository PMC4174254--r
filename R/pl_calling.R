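#' Call haploid genotypes from PL likelihood triples
#'
#' PL scores are normalized PHRED-scaled genotype likelihoods for the three
#' diploid genotypes (0/0, 0/1, 1/1); lower is more likely, and the minimum
#' of a normalized triple is 0. On a haploid locus a confident call requires
#' the two homozygote likelihoods to be well separated and the heterozygote
#' (an impossible genotype, indicating mapping or sequencing artefacts) to
#' be clearly disfavoured. A sample/site is called `N` (missing) when
#' * `|PL(1/1) - PL(0/0)| < min_diff`, or
#' * the heterozygote is the most likely genotype
#'   (`PL(0/1) < min(PL(0/0), PL(1/1))`), or
#' * `PL(0/1) - min(PL(0/0), PL(1/1)) < min_diff`;
#' otherwise the allele of the lower homozygote PL is called. A difference
#' of 30 PHRED units means a 1000-fold likelihood ratio.
#'
#' @param records Tibble of PL records with columns `position`, `sample_id`,
#'   `pl_ref`, `pl_het`, `pl_alt` (PHRED-scaled, non-negative). Every
#'   (position, sample) pair must appear exactly once.
#' @param min_diff Minimum PHRED difference for a confident call
#'   (default 30).
#' @param ref,alt Optional per-position allele lookup (tibble with columns
#'   `position`, `ref`, `alt`).
#' @param locus Locus label of the result.
#' @return A [hap_matrix()] over all samples and positions present in
#'   `records`.
#' @export
#' @examples
#' recs <- tibble::tibble(
#'   position = c(10L, 10L), sample_id = c("a", "b"),
#'   pl_ref = c(0, 0), pl_het = c(50, 60), pl_alt = c(40, 20)
#' )
#' call_genotypes_from_pl(recs)$geno  # a -> 0, b -> N
call_genotypes_from_pl <- function(records, min_diff = 30,
                                   ref = NULL, alt = NULL,
                                   locus = "NRY") {
  pl <- cbind(records$pl_ref, records$pl_het, records$pl_alt)
  if (any(pl < 0, na.rm = TRUE) || anyNA(pl)) {
    abort("PL scores must be present and non-negative.")
  }
  call <- pl_call_vec(records$pl_ref, records$pl_het, records$pl_alt,
                      min_diff)
  samples <- unique(records$sample_id)
  positions <- sort(unique(records$position))
  i <- match(records$sample_id, samples)
  j <- match(records$position, positions)
  if (anyDuplicated(cbind(i, j))) {
    abort("Duplicate (position, sample) PL records.")
  }
  g <- matrix(NA_integer_, length(samples), length(positions),
              dimnames = list(samples, NULL))
  g[cbind(i, j)] <- call
  if (any(tabulate(j, length(positions)) < length(samples))) {
    abort("Every (site, sample) pair needs exactly one PL record.")
  }
  ref_a <- alt_a <- NULL
  if (!is.null(ref)) {
    ref_a <- ref$ref[match(positions, ref$position)]
    alt_a <- ref$alt[match(positions, ref$position)]
  }
  hap_matrix(g, position = positions, ref = ref_a, alt = alt_a,
             locus = locus)
}

# Vectorised application of the three threshold clauses.
pl_call_vec <- function(pl00, pl01, pl11, min_diff) {
  best_hom <- pmin(pl00, pl11)
  n_call <- abs(pl11 - pl00) < min_diff |
    pl01 < best_hom |
    (pl01 - best_hom) < min_diff
  out <- ifelse(pl00 <= pl11, 0L, 1L)
  out[n_call] <- NA_integer_
  out
}
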