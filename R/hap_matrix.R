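#' Haplotype matrix of biallelic sites
#'
#' The central substrate of the package: a samples x sites matrix of haploid
#' genotype codes, 0 for the reference allele, 1 for the alternative allele
#' and `NA` for missing calls ("N"). Every site is biallelic among the
#' non-missing calls, positions are strictly increasing 1-based coordinates.
#'
#' @param geno Integer matrix (samples x sites) with entries 0, 1 or `NA`;
#'   row names are taken as sample identifiers.
#' @param position Integer vector of 1-based site coordinates, strictly
#'   increasing, one per column of `geno`.
#' @param ref,alt Character vectors of reference/alternative alleles, one per
#'   site (defaults `"A"`/`"G"` placeholders for simulated loci).
#' @param locus Locus label, e.g. `"mtDNA"`, `"NRY"` or `"synthetic"`.
#'
#' @return An object of class `hap_matrix`: a list with elements `geno`
#'   (integer matrix), `sites` (tibble of `position`, `ref`, `alt`) and
#'   `locus`.
#' @export
#' @examples
#' m <- hap_matrix(rbind(h1 = c(0L, 0L), h2 = c(1L, NA)), position = c(5L, 9L))
#' m
hap_matrix <- function(geno, position, ref = NULL, alt = NULL,
                       locus = "synthetic") {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (is.null(rownames(geno))) {
    rownames(geno) <- paste0("s", seq_len(nrow(geno)))
  }
  position <- as.integer(position)
  if (length(position) != ncol(geno)) {
    abort("`position` must have one entry per genotype column.")
  }
  if (ncol(geno) > 1 && any(diff(position) <= 0)) {
    abort("Site positions must be strictly increasing.")
  }
  if (anyDuplicated(rownames(geno))) {
    abort("Sample identifiers must be unique.")
  }
  bad <- !(geno %in% c(0L, 1L, NA_integer_))
  if (any(bad)) abort("Genotype codes must be 0, 1 or NA.")
  if (is.null(ref)) ref <- rep("A", ncol(geno))
  if (is.null(alt)) alt <- rep("G", ncol(geno))
  structure(
    list(
      geno = geno,
      sites = tibble::tibble(position = position,
                             ref = as.character(ref),
                             alt = as.character(alt)),
      locus = locus
    ),
    class = "hap_matrix"
  )
}

#' @export
dim.hap_matrix <- function(x) dim(x$geno)

#' @export
print.hap_matrix <- function(x, ...) {
  n_missing <- sum(is.na(x$geno))
  cat(sprintf(
    "<hap_matrix> %s: %d samples x %d sites (%.2f%% missing)\n",
    x$locus, nrow(x$geno), ncol(x$geno),
    if (length(x$geno)) 100 * n_missing / length(x$geno) else 0
  ))
  invisible(x)
}

#' @export
`==.hap_matrix` <- function(e1, e2) {
  identical(unclass(e1$geno), unclass(e2$geno)) &&
    isTRUE(all.equal(e1$sites, e2$sites)) &&
    identical(e1$locus, e2$locus)
}

#' Sample identifiers of a haplotype matrix
#' @param m A [hap_matrix()].
#' @return Character vector of sample ids.
#' @export
sample_ids <- function(m) rownames(m$geno)

#' Subset a haplotype matrix
#'
#' @param x A [hap_matrix()].
#' @param i Sample index (names, logical or integer).
#' @param j Site index (logical or integer).
#' @param ... Unused.
#' @return A [hap_matrix()] restricted to the selected samples/sites.
#' @export
`[.hap_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$geno))
  if (missing(j)) j <- seq_len(ncol(x$geno))
  hap_matrix(x$geno[i, j, drop = FALSE],
             position = x$sites$position[j],
             ref = x$sites$ref[j], alt = x$sites$alt[j],
             locus = x$locus)
}

#' Convert a haplotype matrix to a tidy tibble
#'
#' One row per (sample, site) cell; missing calls are `NA`.
#'
#' @param x A [hap_matrix()].
#' @param ... Unused.
#' @return A tibble with columns `sample_id`, `position`, `allele`.
#' @method tidy hap_matrix
#' @export
tidy.hap_matrix <- function(x, ...) {
  tibble::tibble(
    sample_id = rep(rownames(x$geno), times = ncol(x$geno)),
    position = rep(x$sites$position, each = nrow(x$geno)),
    allele = as.integer(x$geno)
  )
}

#' @method glance hap_matrix
#' @export
glance.hap_matrix <- function(x, ...) {
  tibble::tibble(
    locus = x$locus,
    n_samples = nrow(x$geno),
    n_sites = ncol(x$geno),
    prop_missing = if (length(x$geno)) mean(is.na(x$geno)) else 0
  )
}
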