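# Convert a biallelic haplotype matrix to a phangorn phyDat object;
# missing calls become fully ambiguous ("?").
as_phydat <- function(m) {
  g <- matrix(as.character(m$geno), nrow(m$geno), ncol(m$geno),
              dimnames = dimnames(m$geno))
  g[is.na(g)] <- "?"
  phangorn::phyDat(g, type = "USER", levels = c("0", "1"), ambiguity = "?")
}

#' Build a maximum-parsimony tree for a haplotype matrix
#'
#' For more than 8 samples: neighbour-joining start tree from Hamming
#' distances followed by nearest-neighbour-interchange hill-climbing that
#' minimises the total parsimony length (heuristic, deterministic given
#' `seed`). For 8 or fewer samples the search is exhaustive over all
#' unrooted topologies, so the returned length is the global minimum.
#'
#' @param m A [hap_matrix()] with at least 3 samples; an imputed (missing-
#'   free) matrix is preferred, otherwise missing calls are treated as
#'   fully ambiguous.
#' @param seed Integer seed for the heuristic search.
#' @return An unrooted `phylo` tree with tip labels equal to the sample
#'   ids and attribute `pscore` (total parsimony length).
#' @export
build_parsimony_tree <- function(m, seed = 1L) {
  n <- nrow(m$geno)
  if (n < 3) abort("Need at least 3 samples to build a tree.")
  pd <- as_phydat(m)
  if (n <= 8) {
    trees <- phangorn::allTrees(n, rooted = FALSE,
                                tip.label = sample_ids(m))
    scores <- vapply(trees, function(tr) {
      sum(fitch_counts(tr, m)$min_changes)
    }, 0)
    best <- trees[[which.min(scores)]]
    attr(best, "pscore") <- min(scores)
    return(best)
  }
  set.seed(seed)
  d <- hap_distances(m)
  start <- ape::nj(stats::as.dist(d))
  start <- ape::unroot(start)
  fit <- phangorn::optim.parsimony(start, pd, method = "fitch",
                                   rearrangements = "NNI", trace = 0)
  attr(fit, "pscore") <- phangorn::parsimony(fit, pd)
  fit
}

# Root an unrooted binary tree on the edge to its first tip so that every
# internal node has exactly two children (Fitch needs a binary rooted
# traversal; the parsimony score is invariant to this rooting).
root_for_fitch <- function(tree) {
  tr <- ape::unroot(tree)
  tr <- ape::root(tr, outgroup = tr$tip.label[1], resolve.root = TRUE)
  ape::reorder.phylo(tr, "postorder")
}

#' Per-site parsimony change counts (two-state Fitch)
#'
#' Counts, for every site, the minimum number of state changes on the tree
#' (Fitch parsimony for the two alleles; missing calls are fully
#' ambiguous), and classifies each change as terminal (on a branch incident
#' to a leaf) or internal using one canonical most-parsimonious
#' reconstruction: down-pass state sets, then a pre-order pass keeping the
#' parental state where possible and preferring allele 0 on ties.
#'
#' @param tree A `phylo` whose tip labels equal the matrix sample ids.
#' @param m A [hap_matrix()].
#' @return A tibble with one row per site: `position`, `min_changes`,
#'   `n_terminal`, `n_internal`, `all_terminal` (invariant sites, having no
#'   changes, get `all_terminal = FALSE`).
#' @export
fitch_counts <- function(tree, m) {
  if (!setequal(tree$tip.label, sample_ids(m))) {
    abort("Tree leaves and matrix samples do not match.")
  }
  tr <- root_for_fitch(tree)
  n_tip <- length(tr$tip.label)
  n_node <- n_tip + tr$Nnode
  S <- ncol(m$geno)
  g <- m$geno[match(tr$tip.label, sample_ids(m)), , drop = FALSE]
  # state sets as bitmasks: 1 = {0}, 2 = {1}, 3 = {0,1}
  sets <- matrix(3L, n_node, S)
  sets[1:n_tip, ] <- ifelse(is.na(g), 3L, g + 1L)
  changes <- integer(S)
  edge <- tr$edge  # postorder: children before parents
  kids <- split(edge[, 2], edge[, 1])
  node_order <- unique(edge[, 1])  # postorder parents
  for (v in node_order) {
    ch <- kids[[as.character(v)]]
    s <- sets[ch[1], ]
    for (w in ch[-1]) {
      inter <- bitwAnd(s, sets[w, ])
      un <- bitwOr(s, sets[w, ])
      hit <- inter == 0L
      changes <- changes + hit
      s <- ifelse(hit, un, inter)
    }
    sets[v, ] <- s
  }
  # canonical reconstruction: root prefers 0, children keep parent state
  state <- matrix(0L, n_node, S)
  root <- node_order[length(node_order)]
  state[root, ] <- ifelse(bitwAnd(sets[root, ], 1L) > 0L, 0L, 1L)
  n_term <- integer(S)
  n_int <- integer(S)
  for (i in rev(seq_len(nrow(edge)))) {  # preorder: parents before children
    p <- edge[i, 1]; v <- edge[i, 2]
    pstate <- state[p, ]
    pbit <- bitwShiftL(1L, pstate)  # 1 for state 0, 2 for state 1
    keep <- bitwAnd(sets[v, ], pbit) > 0L
    vstate <- ifelse(keep, pstate,
                     ifelse(bitwAnd(sets[v, ], 1L) > 0L, 0L, 1L))
    state[v, ] <- vstate
    chg <- vstate != pstate
    if (v <= n_tip) n_term <- n_term + chg else n_int <- n_int + chg
  }
  tibble::tibble(
    position = m$sites$position,
    min_changes = as.integer(changes),
    n_terminal = n_term,
    n_internal = n_int,
    all_terminal = changes > 0L & n_int == 0L
  )
}

#' Remove recurrent (homoplastic) sites
#'
#' Quality-control filter for non-recombining loci: sites inferred to have
#' mutated more than twice on the parsimony tree, with every change on a
#' terminal branch, are characteristic of sequencing error and removed.
#' Sites with any change on an internal branch are retained regardless of
#' the change count.
#'
#' @param m A [hap_matrix()].
#' @param profiles Per-site change profiles from [fitch_counts()]; must
#'   cover every site of `m`.
#' @param max_changes Retention threshold (default 2: sites with more than
#'   two changes, all terminal, are removed).
#' @return The filtered [hap_matrix()], with attribute `removal_report`: a
#'   tibble of all sites with their change counts and removal flags.
#' @export
filter_recurrent_sites <- function(m, profiles, max_changes = 2L) {
  if (!setequal(profiles$position, m$sites$position)) {
    abort("Profiles must cover exactly the sites of the matrix.")
  }
  profiles <- profiles[match(m$sites$position, profiles$position), ]
  removed <- profiles$min_changes > max_changes & profiles$all_terminal
  report <- dplyr::mutate(profiles, removed = removed)
  out <- m[, !removed]
  attr(out, "removal_report") <- report
  attr(out, "n_removed") <- sum(removed)
  out
}
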