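#' Simulate a genealogy under the serial-founder model
#'
#' Reverse-time structured coalescent with six regional demes and no
#' migration after divergence; exponential within-branch growth epochs are
#' handled by exact inversion of the integrated coalescence intensity.
#'
#' @param model A [demographic_model()].
#' @param cfg A [sample_config()] of per-region haploid sample counts.
#' @param seed Optional integer seed.
#' @return An object of class `genealogy`: list with `parent` (1-based
#'   parent index per node, `NA` at the root), `node_time` (generations),
#'   `leaf_region` (region label per leaf) and `n_leaves`. Leaves come
#'   first, ordered by region. Use [as_phylo()] for an `ape` tree.
#' @export
simulate_genealogy <- function(model, cfg = sample_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  prow <- model_to_param_row(model)
  res <- sim_genealogy_cpp(prow[1:6], prow[7:19], unname(cfg))
  parent <- res$parent + 1L
  parent[parent == 0L] <- NA_integer_
  structure(
    list(parent = parent, node_time = res$node_time,
         leaf_region = DEME_ORDER[res$leaf_deme + 1L],
         n_leaves = res$n_leaves,
         generation_time = model$generation_time),
    class = "genealogy"
  )
}

#' @export
print.genealogy <- function(x, ...) {
  cat(sprintf("<genealogy> %d leaves, TMRCA %.1f generations\n",
              x$n_leaves, max(x$node_time)))
  invisible(x)
}

#' Time to the most recent common ancestor, in generations
#' @param gen A `genealogy`.
#' @return Numeric scalar.
#' @export
tmrca <- function(gen) max(gen$node_time)

#' Total branch length of a genealogy, in generations
#' @param gen A `genealogy`.
#' @return Numeric scalar.
#' @export
total_branch_length <- function(gen) {
  p <- gen$parent
  sum(gen$node_time[p[!is.na(p)]] - gen$node_time[!is.na(p)])
}

#' Convert a genealogy to an ape phylo tree
#'
#' @param gen A `genealogy`.
#' @return An object of class `phylo` with branch lengths in generations
#'   and tip labels `<region>_<i>`.
#' @export
as_phylo <- function(gen) {
  n <- gen$n_leaves
  if (n < 2) abort("Cannot build a phylo tree from a single leaf.")
  n_nodes <- length(gen$parent)
  root <- which(is.na(gen$parent))
  # ape numbering: tips 1..n unchanged, root = n+1, other internals after
  internal <- setdiff((n + 1L):n_nodes, root)
  new_id <- integer(n_nodes)
  new_id[1:n] <- 1:n
  new_id[root] <- n + 1L
  new_id[internal] <- seq_along(internal) + n + 1L
  child <- which(!is.na(gen$parent))
  edge <- cbind(new_id[gen$parent[child]], new_id[child])
  edge_len <- gen$node_time[gen$parent[child]] - gen$node_time[child]
  tip_lab <- paste0(gsub(" ", "", gen$leaf_region), "_", seq_len(n))
  tr <- list(edge = edge, edge.length = edge_len, tip.label = tip_lab,
             Nnode = n_nodes - n)
  class(tr) <- "phylo"
  attr(tr, "order") <- NULL
  ape::reorder.phylo(tr, "cladewise")
}

# Logical matrix: desc[v, leaf] — is `leaf` below node v?
descendant_leaves <- function(gen) {
  n <- gen$n_leaves
  n_nodes <- length(gen$parent)
  desc <- matrix(FALSE, n_nodes, n)
  desc[cbind(1:n, 1:n)] <- TRUE
  ord <- order(gen$node_time)
  for (v in ord) {
    p <- gen$parent[v]
    if (!is.na(p)) desc[p, ] <- desc[p, ] | desc[v, ]
  }
  desc
}

#' Drop infinite-sites mutations onto a genealogy
#'
#' Per partition, the mutation count is Poisson with mean total branch
#' length (generations) times `length * rate * generation_time`; mutations
#' are placed on branches proportional to branch length and assigned
#' distinct uniformly-drawn site positions (infinite-sites: no homoplasy).
#'
#' @param gen A `genealogy` from [simulate_genealogy()].
#' @param locus A [locus_spec()].
#' @param generation_time Years per generation (defaults to the value
#'   stored in `gen`).
#' @param seed Optional integer seed.
#' @return A [hap_matrix()]; column positions are 1-based within the
#'   concatenated partitions. The derived (mutant) allele is coded 1.
#' @export
drop_mutations <- function(gen, locus, generation_time = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- generation_time %||% gen$generation_time
  n <- gen$n_leaves
  child <- which(!is.na(gen$parent))
  len <- gen$node_time[gen$parent[child]] - gen$node_time[child]
  desc <- descendant_leaves(gen)
  offset <- cumsum(c(0, locus$length))
  cols <- list()
  pos <- list()
  for (p in seq_len(nrow(locus))) {
    mu_gen <- locus$rate[p] * g  # per site per generation
    m_per_branch <- rpois(length(child), len * mu_gen * locus$length[p])
    total <- sum(m_per_branch)
    if (total == 0) next
    if (total > locus$length[p]) {
      abort("More mutations than sites in a partition; rates too high for infinite sites.")
    }
    which_branch <- rep(seq_along(child), m_per_branch)
    site_pos <- sort(sample.int(locus$length[p], total)) + offset[p]
    cols[[p]] <- t(desc[child[which_branch], seq_len(n), drop = FALSE])
    pos[[p]] <- site_pos
  }
  if (!length(cols)) {
    geno <- matrix(integer(), n, 0)
  } else {
    geno <- do.call(cbind, cols) * 1L
  }
  rownames(geno) <- paste0(gsub(" ", "", gen$leaf_region), "_", seq_len(n))
  hap_matrix(geno, position = unlist(pos) %||% integer(),
             locus = attr(locus, "locus") %||% "synthetic")
}

#' Simulate a haplotype matrix in one step
#'
#' @inheritParams simulate_genealogy
#' @inheritParams drop_mutations
#' @return A [hap_matrix()].
#' @export
simulate_matrix <- function(model, cfg = sample_config(), locus,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gen <- simulate_genealogy(model, cfg)
  drop_mutations(gen, locus, model$generation_time)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
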