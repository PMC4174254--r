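test_that("three samples give the unique unrooted topology", {
  m <- rand_hap_matrix(3, 6, seed = 1)
  tr <- build_parsimony_tree(m)
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, sample_ids(m))
  expect_equal(length(tr$tip.label), 3L)
})

test_that("a perfect phylogeny has parsimony length equal to its site count", {
  # nested clades: each site is a single mutation on one branch
  g <- rbind(s1 = c(1L, 1L, 1L, 0L, 0L),
             s2 = c(1L, 1L, 0L, 0L, 0L),
             s3 = c(1L, 0L, 0L, 1L, 0L),
             s4 = c(0L, 0L, 0L, 0L, 1L),
             s5 = c(0L, 0L, 0L, 0L, 0L))
  m <- hap_matrix(g, position = 1:5)
  tr <- build_parsimony_tree(m)
  expect_equal(attr(tr, "pscore"), 5)
  expect_true(all(fitch_counts(tr, m)$min_changes == 1L))
})

test_that("the exhaustive search equals the phangorn oracle on 8 leaves", {
  for (seed in 1:3) {
    m <- rand_hap_matrix(8, 12, seed = seed)
    tr <- build_parsimony_tree(m)
    pd <- phangorn::phyDat(
      matrix(as.character(m$geno), 8, 12,
             dimnames = dimnames(m$geno)),
      type = "USER", levels = c("0", "1"))
    all_tr <- phangorn::allTrees(8, tip.label = sample_ids(m))
    oracle_min <- min(vapply(all_tr, phangorn::parsimony, 0, data = pd))
    expect_equal(attr(tr, "pscore"), oracle_min)
  }
})

test_that("heuristic search is deterministic and scores match phangorn", {
  m <- rand_hap_matrix(15, 40, seed = 12)
  tr1 <- build_parsimony_tree(m, seed = 7)
  tr2 <- build_parsimony_tree(m, seed = 7)
  expect_equal(ape::write.tree(tr1), ape::write.tree(tr2))
  pd <- phangorn::phyDat(
    matrix(as.character(m$geno), 15, 40, dimnames = dimnames(m$geno)),
    type = "USER", levels = c("0", "1"))
  expect_equal(sum(fitch_counts(tr1, m)$min_changes),
               phangorn::parsimony(tr1, pd))
  expect_error(build_parsimony_tree(m[1:2, ]), "at least 3")
})

test_that("Fitch counts match hand-enumerated patterns on a quartet", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  m <- hap_matrix(rbind(A = c(0L, 0L, 0L), B = c(0L, 1L, 0L),
                        C = c(1L, 0L, 0L), D = c(1L, 1L, 0L)),
                  position = 1:3)
  fc <- fitch_counts(tr, m)
  expect_equal(fc$min_changes, c(1L, 2L, 0L))
  expect_false(fc$all_terminal[3])
  expect_error(fitch_counts(tr, rand_hap_matrix(4, 3, seed = 1)),
               "do not match")
})

test_that("Fitch counts equal the brute-force minimum on random trees", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(6:8, 1)
    tr <- ape::rtree(n, tip.label = paste0("t", 1:n))
    g <- matrix(rbinom(n * 5, 1, 0.5), n,
                dimnames = list(paste0("t", 1:n), NULL))
    m <- hap_matrix(g, position = 1:5)
    fc <- fitch_counts(tr, m)
    for (s in 1:5) {
      expect_equal(fc$min_changes[s],
                   brute_force_changes(tr, setNames(g[, s], rownames(g))))
    }
    # the canonical reconstruction realises the minimum change count
    expect_equal(fc$n_terminal + fc$n_internal, fc$min_changes)
  }
})

test_that("the recurrent-site filter removes exactly the flagged sites", {
  m <- rand_hap_matrix(6, 4, seed = 5)
  profiles <- tibble::tibble(
    position = m$sites$position,
    min_changes = c(3L, 3L, 2L, 1L),
    n_terminal = c(3L, 2L, 2L, 1L),
    n_internal = c(0L, 1L, 0L, 0L),
    all_terminal = c(TRUE, FALSE, TRUE, FALSE)
  )
  out <- filter_recurrent_sites(m, profiles)
  # removed: >2 changes AND all terminal (site 1 only); a site with an
  # internal change or exactly 2 changes is retained
  expect_equal(out$sites$position, m$sites$position[2:4])
  expect_equal(attr(out, "n_removed"), 1L)
  expect_equal(sum(attr(out, "removal_report")$removed), 1L)
})

test_that("filtering is idempotent", {
  m <- rand_hap_matrix(10, 25, seed = 17)
  tr <- build_parsimony_tree(m, seed = 1)
  out1 <- filter_recurrent_sites(m, fitch_counts(tr, m))
  out2 <- filter_recurrent_sites(out1, fitch_counts(tr, out1))
  expect_equal(attr(out2, "n_removed"), 0L)
  expect_true(out2 == out1)
})
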