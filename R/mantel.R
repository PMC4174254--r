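#' Mantel test between two distance matrices
#'
#' Pearson correlation of the off-diagonal upper triangles, with a
#' one-sided permutation p-value obtained by jointly permuting the rows and
#' columns of the second matrix (delegated to `vegan::mantel`).
#'
#' @param d1,d2 Symmetric distance matrices with matching labels
#'   (dimnames); `d2` is reordered to `d1`'s labels.
#' @param reps Number of permutations (default 1000).
#' @param seed Optional integer seed.
#' @return A one-row tibble with `r`, `p_value`, `n`, `reps`.
#' @export
mantel_test <- function(d1, d2, reps = 1000, seed = NULL) {
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  lab <- rownames(d1)
  if (is.null(lab) || is.null(rownames(d2))) {
    abort("Both matrices need labels (dimnames).")
  }
  if (!setequal(lab, rownames(d2))) {
    abort("Matrices must share the same label set.")
  }
  if (length(lab) < 4) abort("Need at least 4 labels for a Mantel test.")
  d2 <- d2[lab, lab]
  if (sd(d1[lower.tri(d1)]) == 0 || sd(d2[lower.tri(d2)]) == 0) {
    abort("Undefined correlation: constant distance matrix.")
  }
  if (!is.null(seed)) set.seed(seed)
  fit <- vegan::mantel(stats::as.dist(d1), stats::as.dist(d2),
                       method = "pearson", permutations = reps)
  tibble::tibble(r = unname(fit$statistic), p_value = fit$signif,
                 n = length(lab), reps = reps)
}

#' Great-circle distances between groups
#'
#' Haversine distances in km (Earth radius 6371 km) between group centroid
#' coordinates. Groups containing no sample with coordinates are excluded
#' with a warning.
#'
#' @param meta A `sample_table` (see [read_sample_metadata()]).
#' @param by Grouping column, default `"population"`.
#' @return A symmetric matrix of distances in km, labelled by group.
#' @export
great_circle_distances <- function(meta, by = "population") {
  ok <- meta[meta$has_coords, ]
  dropped <- setdiff(unique(meta[[by]]), unique(ok[[by]]))
  if (length(dropped)) {
    warn(paste0("Excluding group(s) without coordinates: ",
                paste(dropped, collapse = ", ")))
  }
  cen <- ok |>
    dplyr::group_by(.data[[by]]) |>
    dplyr::summarise(lon = mean(.data$longitude),
                     lat = mean(.data$latitude), .groups = "drop")
  pts <- as.matrix(cen[, c("lon", "lat")])
  d <- geosphere::distm(pts, fun = function(p1, p2) {
    geosphere::distHaversine(p1, p2, r = 6371)
  })
  dimnames(d) <- list(cen[[by]], cen[[by]])
  d
}
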