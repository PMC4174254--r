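test_that("pairwise coalescence times match the constant-size closed form", {
  N <- 800
  m <- const_model(N)
  cfg <- sample_config(c(Africa = 2))
  set.seed(1)
  t2 <- replicate(4000, tmrca(simulate_genealogy(m, cfg)))
  se <- sd(t2) / sqrt(length(t2))
  expect_close(mean(t2), N, 3 * se)
})

test_that("TMRCA of a larger sample matches 2N(1 - 1/n)", {
  N <- 500
  m <- const_model(N)
  cfg <- sample_config(c(Africa = 10))
  set.seed(2)
  tm <- replicate(4000, tmrca(simulate_genealogy(m, cfg)))
  se <- sd(tm) / sqrt(length(tm))
  expect_close(mean(tm), 2 * N * (1 - 1 / 10), 3 * se)
})

test_that("segregating sites match Watterson's expectation", {
  N <- 1000
  m <- const_model(N)
  cfg <- sample_config(c(Africa = 10))
  loc <- toy_locus(50000, 1e-8)
  theta <- 2 * N * 50000 * 1e-8 * 25
  set.seed(3)
  S <- replicate(2000, ncol(simulate_matrix(m, cfg, loc)$geno))
  se <- sd(S) / sqrt(length(S))
  expect_close(mean(S), theta * sum(1 / (1:9)), 3 * se)
})

test_that("a single sampled lineage never coalesces", {
  gen <- simulate_genealogy(const_model(100), sample_config(c(Africa = 1)),
                            seed = 1)
  expect_equal(gen$n_leaves, 1L)
  expect_equal(tmrca(gen), 0)
})

test_that("a vanishing mutation rate yields an empty matrix", {
  gen <- simulate_genealogy(const_model(100), sample_config(c(Africa = 5)),
                            seed = 4)
  m <- drop_mutations(gen, toy_locus(100, 1e-300), seed = 1)
  expect_equal(ncol(m$geno), 0L)
})

test_that("mean pairwise differences scale linearly with mutation rate", {
  N <- 500
  m <- const_model(N)
  cfg <- sample_config(c(Africa = 8))
  mpd_at <- function(rate, seed) {
    set.seed(seed)
    x <- replicate(1500, {
      mm <- simulate_matrix(m, cfg, toy_locus(20000, rate))
      sum(hap_distances(mm)) / (8 * 7)
    })
    c(mean(x), sd(x) / sqrt(length(x)))
  }
  a <- mpd_at(2e-8, 5)
  b <- mpd_at(4e-8, 6)
  expect_close(b[1], 2 * a[1], 3 * sqrt((2 * a[2])^2 + b[2]^2))
})

test_that("near-zero split times degenerate to panmixia across regions", {
  N <- 400
  g <- 25
  m <- demographic_model(
    times = c(T1 = 60, T2 = 50, T3 = 40, T4 = 30, T5 = 20, T6 = 10) * g / 10,
    n_anc_africa = N, n_ooa = N,
    n_anc = c(Oceania = N, Europe = N, `Central Asia` = N,
              `East Asia` = N, America = N),
    n_cur = c(Africa = N, Oceania = N, Europe = N, `Central Asia` = N,
              `East Asia` = N, America = N))
  cfg <- sample_config(c(Africa = 10, Oceania = 10, Europe = 10,
                         `Central Asia` = 10, `East Asia` = 10,
                         America = 10))
  pars <- tibble::as_tibble(as.list(setNames(
    c(tidy(m)$value[1:6], model_to_param_row(m)[7:19]),
    c(paste0("T", 1:6), unidem:::SIZE_PARAMS))))
  st <- simulate_sumstats(pars[rep(1, 300), ], cfg, toy_locus(5e4, 2e-8),
                          seed = 7)
  phis <- st[, grep("^phist_", colnames(st))]
  expect_close(mean(phis, na.rm = TRUE), 0, 0.02)
})

test_that("parameter draws respect the prior supports and time ordering", {
  pr <- prior_spec()
  d <- draw_parameters(pr, 10000, seed = 9)
  expect_true(all(d$T2 > d$T3))
  expect_true(all(d$T1 > d$T2 & d$T3 > d$T4 & d$T4 > d$T5 & d$T5 > d$T6))
  expect_true(all(d$T6 >= 10000 & d$T6 <= 20000))
  expect_true(all(d$N_anc_Africa >= 1 & d$N_anc_Africa <= 1e4))
  expect_true(all(d$N_cur_Africa >= 1e2 & d$N_cur_Africa <= 2e5))
  d2 <- draw_parameters(pr, 10000, seed = 9)
  expect_equal(d, d2)
})

test_that("the fast summary path is deterministic given the seed", {
  pars <- draw_parameters(prior_spec(), 50, seed = 3)
  s1 <- simulate_sumstats(pars, sample_config(), locus_spec("NRY"), seed = 5)
  s2 <- simulate_sumstats(pars, sample_config(), locus_spec("NRY"), seed = 5)
  expect_identical(s1, s2)
})

test_that("the matrix path and the fast path agree on summary statistics", {
  # simulate matrices, summarize them, and compare the distribution of
  # mpd to the fast path under the same model
  m <- default_model("NRY")
  cfg <- sample_config(c(Africa = 12, Oceania = 4, Europe = 10,
                         `Central Asia` = 15, `East Asia` = 15,
                         America = 5))
  pars <- draw_parameters(prior_spec(), 1, seed = 1)
  pars[1, ] <- as.list(setNames(
    c(unname(tidy(m)$value[1:6]), model_to_param_row(m)[7:19]),
    c(paste0("T", 1:6), unidem:::SIZE_PARAMS)))
  fast <- simulate_sumstats(pars[rep(1, 400), ], cfg, locus_spec("NRY"),
                            seed = 11)
  set.seed(12)
  slow <- t(replicate(60, {
    mm <- simulate_matrix(m, cfg, locus_spec("NRY"))
    regions <- sub("_[0-9]+$", "", sample_ids(mm))
    regions <- c(Africa = "Africa", Oceania = "Oceania", Europe = "Europe",
                 CentralAsia = "Central Asia", EastAsia = "East Asia",
                 America = "America")[regions]
    summarize_stats(mm, unname(regions))
  }))
  for (stat in c("mpd_Africa", "S_EastAsia", "phist_Africa_Oceania")) {
    se <- sqrt(sd(fast[, stat], na.rm = TRUE)^2 / 400 +
                 sd(slow[, stat], na.rm = TRUE)^2 / 60)
    expect_close(mean(slow[, stat], na.rm = TRUE),
                 mean(fast[, stat], na.rm = TRUE), 3.5 * se)
  }
})

test_that("model construction rejects invalid time orderings", {
  expect_error(demographic_model(
    times = c(T1 = 1e5, T2 = 9e4, T3 = 9.5e4, T4 = 5e4, T5 = 3e4, T6 = 1e4),
    n_anc_africa = 10, n_ooa = 10,
    n_anc = c(Oceania = 10, Europe = 10, `Central Asia` = 10,
              `East Asia` = 10, America = 10),
    n_cur = c(Africa = 100, Oceania = 100, Europe = 100,
              `Central Asia` = 100, `East Asia` = 100, America = 100)),
    "T1 > T2")
  expect_error(locus_spec("NRY", nry_rate = 0), "positive")
  expect_error(sample_config(c(Africa = 0)), "at least one")
})
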