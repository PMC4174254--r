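# Sum of squared distances between/within index sets, from a matrix of
# squared pairwise distances (here: pairwise difference counts).
.sum_within <- function(d2, idx) sum(d2[idx, idx]) / 2

# Two-level variance components from pre-aggregated pair sums.
# w: vector of within-population pair sums; n: population sizes;
# total_pairsum: sum over ALL pairs (within + between).
amova2_components <- function(w, n, total_pairsum) {
  N <- sum(n)
  P <- length(n)
  ssd_t <- total_pairsum / N
  ssd_wp <- sum(w / n)
  ssd_ap <- ssd_t - ssd_wp
  df_ap <- P - 1
  df_wp <- N - P
  sigma_c <- ssd_wp / df_wp
  n_prime <- (N - sum(n^2) / N) / (P - 1)
  sigma_a <- (ssd_ap / df_ap - sigma_c) / n_prime
  list(ssd_t = ssd_t, ssd_ap = ssd_ap, ssd_wp = ssd_wp,
       df_ap = df_ap, df_wp = df_wp,
       sigma_a = sigma_a, sigma_c = sigma_c,
       phi_st = sigma_a / (sigma_a + sigma_c))
}

amova2_from_d2 <- function(d2, pop) {
  sp <- split(seq_along(pop), pop)
  w <- vapply(sp, function(i) .sum_within(d2, i), 0)
  amova2_components(w, lengths(sp), sum(d2) / 2)
}

amova3_from_d2 <- function(d2, pop, grp) {
  sp <- split(seq_along(pop), pop)
  n_p <- lengths(sp)
  pop_grp <- vapply(sp, function(i) as.character(grp[i[1]]), "")
  if (any(vapply(sp, function(i) length(unique(grp[i])), 0L) > 1)) {
    abort("Populations must nest cleanly within groups.")
  }
  sg <- split(seq_along(pop), grp)
  n_g <- lengths(sg)
  G <- length(sg)
  P <- length(sp)
  N <- sum(n_p)
  if (any(table(pop_grp) < 2)) {
    abort("Stratum error: every group needs at least two populations in a 3-level design.")
  }
  ssd_t <- sum(d2) / 2 / N
  ssd_wp <- sum(vapply(sp, function(i) .sum_within(d2, i), 0) / n_p)
  ssd_group_tot <- sum(vapply(sg, function(i) .sum_within(d2, i), 0) / n_g)
  ssd_ag <- ssd_t - ssd_group_tot
  ssd_apwg <- ssd_group_tot - ssd_wp
  df_ag <- G - 1
  df_ap <- P - G
  df_wp <- N - P
  # expected-mean-square coefficients (unequal sizes)
  sum_np2_by_g <- vapply(names(sg), function(gn) {
    sum(n_p[pop_grp == gn]^2) / n_g[gn]
  }, 0)
  n_coef <- (N - sum(sum_np2_by_g)) / df_ap
  n_coef2 <- (sum(sum_np2_by_g) - sum(n_p^2) / N) / df_ag
  n_coef3 <- (N - sum(n_g^2) / N) / df_ag
  sigma_c <- ssd_wp / df_wp
  sigma_b <- (ssd_apwg / df_ap - sigma_c) / n_coef
  sigma_a <- (ssd_ag / df_ag - sigma_c - n_coef2 * sigma_b) / n_coef3
  tot <- sigma_a + sigma_b + sigma_c
  list(ssd_t = ssd_t, ssd_ag = ssd_ag, ssd_apwg = ssd_apwg,
       ssd_wp = ssd_wp, df_ag = df_ag, df_ap = df_ap, df_wp = df_wp,
       sigma_a = sigma_a, sigma_b = sigma_b, sigma_c = sigma_c,
       phi_st = (sigma_a + sigma_b) / tot,
       phi_ct = sigma_a / tot,
       phi_sc = sigma_b / (sigma_b + sigma_c))
}

#' Analysis of molecular variance (AMOVA)
#'
#' Distance-based AMOVA with squared inter-individual distance equal to the
#' pairwise difference count. The two-level design partitions variance
#' among and within populations; the three-level design adds groups of
#' populations (e.g. regions) above populations. Negative variance
#' components are retained, not clamped. Significance is assessed by
#' permutation: individuals among populations (whole dataset) for
#' `phi_st`, individuals among populations within their group for
#' `phi_sc`, and whole populations among groups for `phi_ct`.
#'
#' @param m A [hap_matrix()], or a precomputed squared-distance matrix.
#' @param population Character/factor of population labels per sample.
#' @param group Optional group labels per sample; supplying them selects
#'   the three-level design.
#' @param n_perm Number of permutations (default 1000; 0 disables tests).
#' @param seed Optional integer seed for the permutations.
#' @return An object of class `amova_result`; see [tidy.amova_result()].
#' @export
amova <- function(m, population, group = NULL, n_perm = 1000, seed = NULL) {
  d2 <- if (inherits(m, "hap_matrix")) hap_distances(m) else as.matrix(m)
  population <- as.character(population)
  stopifnot(nrow(d2) == length(population))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(group)) {
    res <- amova2_from_d2(d2, population)
    perm_p <- NA_real_
    if (n_perm > 0) {
      obs <- res$phi_st
      hits <- 0L
      for (b in seq_len(n_perm)) {
        pp <- sample(population)
        if (amova2_from_d2(d2, pp)$phi_st >= obs - 1e-12) hits <- hits + 1L
      }
      perm_p <- (hits + 1) / (n_perm + 1)
    }
    comp <- c(res$sigma_a, res$sigma_c)
    tab <- tibble::tibble(
      source = c("Among populations", "Within populations"),
      df = c(res$df_ap, res$df_wp),
      SSD = c(res$ssd_ap, res$ssd_wp),
      MSD = c(res$ssd_ap / res$df_ap, res$ssd_wp / res$df_wp),
      variance = comp,
      percent = 100 * comp / sum(comp)
    )
    phi <- tibble::tibble(statistic = "phi_st", value = res$phi_st,
                          p_value = perm_p)
    design <- "2-level"
  } else {
    group <- as.character(group)
    res <- amova3_from_d2(d2, population, group)
    phi_p <- c(phi_st = NA_real_, phi_sc = NA_real_, phi_ct = NA_real_)
    if (n_perm > 0) {
      hits <- c(phi_st = 0L, phi_sc = 0L, phi_ct = 0L)
      pops <- unique(population)
      pop_of <- setNames(vapply(pops, function(p) {
        group[match(p, population)]
      }, ""), pops)
      for (b in seq_len(n_perm)) {
        # phi_st: individuals over the whole dataset
        pp <- sample(population)
        r1 <- try(amova3_from_d2(d2, pp, group), silent = TRUE)
        # phi_sc: individuals among populations within groups
        ps <- population
        for (gn in unique(group)) {
          i <- which(group == gn)
          ps[i] <- population[sample(i)]
        }
        r2 <- amova3_from_d2(d2, ps, group)
        # phi_ct: whole populations among groups
        g_perm <- setNames(sample(unname(pop_of)), names(pop_of))
        r3 <- try(amova3_from_d2(d2, population, unname(g_perm[population])),
                  silent = TRUE)
        if (!inherits(r1, "try-error") && r1$phi_st >= res$phi_st - 1e-12)
          hits["phi_st"] <- hits["phi_st"] + 1L
        if (r2$phi_sc >= res$phi_sc - 1e-12)
          hits["phi_sc"] <- hits["phi_sc"] + 1L
        if (!inherits(r3, "try-error") && r3$phi_ct >= res$phi_ct - 1e-12)
          hits["phi_ct"] <- hits["phi_ct"] + 1L
      }
      phi_p <- (hits + 1) / (n_perm + 1)
    }
    comp <- c(res$sigma_a, res$sigma_b, res$sigma_c)
    tab <- tibble::tibble(
      source = c("Among groups", "Among populations within groups",
                 "Within populations"),
      df = c(res$df_ag, res$df_ap, res$df_wp),
      SSD = c(res$ssd_ag, res$ssd_apwg, res$ssd_wp),
      MSD = c(res$ssd_ag / res$df_ag, res$ssd_apwg / res$df_ap,
              res$ssd_wp / res$df_wp),
      variance = comp,
      percent = 100 * comp / sum(comp)
    )
    phi <- tibble::tibble(
      statistic = c("phi_st", "phi_sc", "phi_ct"),
      value = c(res$phi_st, res$phi_sc, res$phi_ct),
      p_value = unname(phi_p[c("phi_st", "phi_sc", "phi_ct")])
    )
    design <- "3-level"
  }
  structure(list(table = tab, phi = phi, design = design, n_perm = n_perm),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("<amova_result>", x$design, "design\n")
  print(as.data.frame(x$table), row.names = FALSE, digits = 4)
  print(as.data.frame(x$phi), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Tidy an AMOVA result
#' @param x An `amova_result`.
#' @param ... Unused.
#' @return The variance-decomposition tibble (`source`, `df`, `SSD`, `MSD`,
#'   `variance`, `percent`).
#' @method tidy amova_result
#' @export
tidy.amova_result <- function(x, ...) x$table

#' @method glance amova_result
#' @export
glance.amova_result <- function(x, ...) {
  out <- tidyr::pivot_wider(x$phi, names_from = "statistic",
                            values_from = c("value", "p_value"))
  dplyr::bind_cols(tibble::tibble(design = x$design, n_perm = x$n_perm), out)
}

#' Pairwise Phi-ST between populations
#'
#' For every population pair, Phi-ST is the among-population variance
#' fraction of a two-level AMOVA restricted to the pair; significance by
#' permuting individuals between the two populations. Negative estimates
#' are retained. Populations with fewer than 2 samples are excluded with a
#' warning.
#'
#' @param m A [hap_matrix()] or a squared-distance matrix.
#' @param population Population labels per sample.
#' @param n_perm Permutations per pair (default 1000; 0 disables).
#' @param seed Optional integer seed.
#' @return A list of class `phist_result`: `phi` and `p` (symmetric
#'   matrices), plus a long-format tibble via [tidy()].
#' @export
pairwise_phist <- function(m, population, n_perm = 1000, seed = NULL) {
  d2 <- if (inherits(m, "hap_matrix")) hap_distances(m) else as.matrix(m)
  population <- as.character(population)
  if (!is.null(seed)) set.seed(seed)
  tab <- table(population)
  small <- names(tab)[tab < 2]
  if (length(small)) {
    warn(paste0("Excluding population(s) with n < 2: ",
                paste(small, collapse = ", ")))
  }
  pops <- sort(names(tab)[tab >= 2])
  if (length(pops) < 2) abort("Need at least two populations with n >= 2.")
  k <- length(pops)
  phi <- matrix(0, k, k, dimnames = list(pops, pops))
  pv <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      idx <- which(population %in% c(pops[a], pops[b]))
      dd <- d2[idx, idx]
      lab <- population[idx]
      obs <- amova2_from_d2(dd, lab)$phi_st
      phi[a, b] <- phi[b, a] <- obs
      if (n_perm > 0) {
        hits <- 0L
        for (r in seq_len(n_perm)) {
          if (amova2_from_d2(dd, sample(lab))$phi_st >= obs - 1e-12)
            hits <- hits + 1L
        }
        pv[a, b] <- pv[b, a] <- (hits + 1) / (n_perm + 1)
      }
    }
  }
  structure(list(phi = phi, p = pv, n_perm = n_perm),
            class = "phist_result")
}

#' @export
print.phist_result <- function(x, ...) {
  cat("<phist_result>", nrow(x$phi), "populations\n")
  print(round(x$phi, 4))
  invisible(x)
}

#' Tidy pairwise Phi-ST results into long format
#' @param x A `phist_result`.
#' @param ... Unused.
#' @return Tibble with columns `pop1`, `pop2`, `phi_st`, `p_value`.
#' @method tidy phist_result
#' @export
tidy.phist_result <- function(x, ...) {
  pops <- rownames(x$phi)
  idx <- which(upper.tri(x$phi), arr.ind = TRUE)
  tibble::tibble(
    pop1 = pops[idx[, 1]], pop2 = pops[idx[, 2]],
    phi_st = x$phi[idx], p_value = x$p[idx]
  )
}
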