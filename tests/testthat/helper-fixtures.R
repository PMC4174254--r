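# Shared fixtures for the test suite: everything is generated in code.

# Random biallelic haplotype matrix (optionally with missing calls).
rand_hap_matrix <- function(n, S, miss_frac = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- matrix(rbinom(n * S, 1, runif(S, 0.1, 0.9)[rep(1:S, each = n)]),
              n, S)
  if (miss_frac > 0) {
    g[sample.int(n * S, round(miss_frac * n * S))] <- NA_integer_
  }
  rownames(g) <- sprintf("s%02d", seq_len(n))
  hap_matrix(g, position = sort(sample.int(S * 10, S)))
}

# Single-deme constant-size model: all sizes N, split times far enough in
# the past (in generations * g years) that no epoch boundary is reached by
# the sampled deme's coalescences in practice.
const_model <- function(N, g = 25) {
  demographic_model(
    times = c(T1 = 6e8, T2 = 5e8, T3 = 4e8, T4 = 3e8, T5 = 2e8, T6 = 1e8) * g,
    n_anc_africa = N, n_ooa = N,
    n_anc = c(Oceania = N, Europe = N, `Central Asia` = N,
              `East Asia` = N, America = N),
    n_cur = c(Africa = N, Oceania = N, Europe = N, `Central Asia` = N,
              `East Asia` = N, America = N),
    generation_time = g
  )
}

# Minimal locus with an arbitrary per-year rate (bypasses the stock
# mtDNA/NRY presets).
toy_locus <- function(length, rate, label = "synthetic") {
  out <- tibble::tibble(partition = "toy", length = length, rate = rate)
  attr(out, "locus") <- label
  class(out) <- c("locus_spec", class(out))
  out
}

# Exhaustive minimum-change count for one site pattern on a tree: brute
# force over all internal-node state assignments (independent oracle for
# Fitch parsimony).
brute_force_changes <- function(tree, states) {
  tr <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tr$tip.label)
  n_internal <- tr$Nnode
  edge <- tr$edge
  best <- Inf
  for (code in 0:(2^n_internal - 1)) {
    assign <- as.integer(intToBits(code))[seq_len(n_internal)]
    full <- c(states[match(tr$tip.label, names(states))], assign)
    chg <- sum(full[edge[, 1]] != full[edge[, 2]])
    best <- min(best, chg)
  }
  best
}

expect_close <- function(x, y, tol) expect_lt(abs(x - y), tol)
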