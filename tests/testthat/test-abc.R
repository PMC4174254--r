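make_toy_ref <- function(n = 500, seed = 1) {
  set.seed(seed)
  theta <- runif(n, 1, 100)
  s <- cbind(stat1 = theta + rnorm(n), stat2 = rnorm(n))
  list(params = tibble::tibble(theta = theta), stats = s)
}

test_that("rejection retains a planted zero-distance cluster exactly", {
  set.seed(2)
  obs <- c(stat1 = 5, stat2 = -3)
  far <- matrix(rnorm(900 * 2, mean = 50), ncol = 2,
                dimnames = list(NULL, names(obs)))
  near <- matrix(rep(obs, each = 100), ncol = 2,
                 dimnames = list(NULL, names(obs)))
  ref <- list(params = tibble::tibble(theta = c(rep(1, 100), rep(2, 900))),
              stats = rbind(near, far))
  rej <- abc_reject(ref, obs, top_k = 100)
  expect_setequal(rej$index, 1:100)
  expect_true(all(rej$distances == 0))
  rej2 <- abc_reject(ref, obs, top_k = 150)
  expect_true(all(1:100 %in% rej2$index))
})

test_that("an observed vector equal to a reference row has distance zero and top weight", {
  ref <- make_toy_ref()
  obs <- ref$stats[17, ]
  rej <- abc_reject(ref, obs, top_k = 50)
  expect_equal(rej$index[1], 17L)
  expect_equal(rej$distances[1], 0)
  expect_equal(which.max(rej$weights), 1L)
})

test_that("top_k larger than the table truncates with a warning", {
  ref <- make_toy_ref(n = 30)
  expect_warning(rej <- abc_reject(ref, ref$stats[1, ], top_k = 100),
                 "exceeds")
  expect_equal(length(rej$index), 30L)
  expect_true(all(rej$weights >= 0))
})

test_that("uninformative statistics leave the retained prior unadjusted", {
  set.seed(3)
  n <- 200
  ref <- list(params = tibble::tibble(theta = runif(n, 1, 10)),
              stats = matrix(1, n, 2,
                             dimnames = list(NULL, c("a", "b"))))
  expect_error(suppressWarnings(abc_reject(ref, c(a = 1, b = 1), top_k = n)),
               "No usable")
  # constant columns are unusable; a single noisy uninformative column
  ref$stats <- cbind(a = rnorm(n))
  rej <- abc_reject(ref, c(a = 0), top_k = n)
  expect_warning(post <- regression_adjust(rej), NA)
  # adjustment regresses on noise only; the weighted mean must stay close
  # to the prior mean of the retained draws
  expect_close(post$summary$mean,
               weighted.mean(rej$params$theta, rej$weights), 1.5)
})

test_that("a perfectly linear statistic collapses the adjusted posterior", {
  set.seed(4)
  theta <- runif(300, 5, 50)
  ref <- list(params = tibble::tibble(theta = theta),
              stats = cbind(s = 2 * theta))
  obs <- c(s = 2 * 20)
  rej <- abc_reject(ref, obs, top_k = 100)
  post <- regression_adjust(rej, transform = "none")
  expect_true(all(abs(post$draws - 20) < 1e-8))
  expect_close(post$summary$mean, 20, 1e-8)
  # on the log scale the same holds for log-linear statistics
  ref_log <- list(params = tibble::tibble(theta = theta),
                  stats = cbind(s = log(theta)))
  post_log <- regression_adjust(abc_reject(ref_log, c(s = log(20)), 100))
  expect_close(post_log$summary$mean, 20, 1e-6)
})

test_that("validation metrics are exact for stub estimators", {
  set.seed(5)
  truth <- matrix(runif(200, 10, 100), 100, 2,
                  dimnames = list(NULL, c("p1", "p2")))
  # oracle estimator: returns the truth, intervals covering it
  vm <- validation_metrics(truth, truth, truth * 0.9, truth * 1.1)
  expect_equal(vm$r2, c(1, 1))
  expect_equal(vm$bias, c(0, 0))
  expect_equal(vm$rmse, c(0, 0))
  expect_equal(vm$coverage, c(1, 1))
  expect_equal(vm$factor2, c(1, 1))
  # doubling estimator: bias exactly 1, factor-2 boundary inclusive
  vm2 <- validation_metrics(truth, 2 * truth, truth * 3, truth * 4)
  expect_equal(vm2$bias, c(1, 1))
  expect_equal(vm2$rmse, c(1, 1))
  expect_equal(vm2$factor2, c(1, 1))
  expect_equal(vm2$coverage, c(0, 0))
  g <- glance(vm2)
  expect_equal(g$abs_bias, 1)
  expect_equal(g$factor2, 1)
})

test_that("weighted posterior summaries behave on a known sample", {
  x <- c(1, 2, 3, 4, 100)
  w <- c(1, 1, 1, 1, 0.0001)
  hpd <- unidem:::weighted_hpd(x, w, 0.75)
  expect_true(hpd[1] >= 1 && hpd[2] <= 4)
  q <- unidem:::weighted_quantile(x, rep(1, 5), c(0, 1))
  expect_equal(q, c(1, 100))
})

test_that("the ABC stages are deterministic given a seed", {
  pr <- prior_spec()
  cfg <- sample_config(c(Africa = 20, Oceania = 5, Europe = 10,
                         `Central Asia` = 10, `East Asia` = 10,
                         America = 5))
  ref1 <- abc_reference("stage1", pr, cfg, 300, seed = 8)
  ref2 <- abc_reference("stage1", pr, cfg, 300, seed = 8)
  expect_equal(ref1$stats, ref2$stats)
  expect_equal(ref1$params, ref2$params)
  obs <- ref1$stats[5, ]
  # 60 retained rows cannot support ~70 regressors: the adjustment falls
  # back to the rejection posterior, which must still be deterministic
  p1 <- suppressWarnings(abc_estimate(ref1, obs, top_k = 60))
  p2 <- suppressWarnings(abc_estimate(ref2, obs, top_k = 60))
  expect_equal(p1$summary, p2$summary)
  expect_equal(p1$summary$parameter, paste0("T", 1:6))
})

test_that("a planted two-fold size difference between loci is recovered", {
  pr <- prior_spec()
  cfg <- sample_config(c(Africa = 30, Oceania = 8, Europe = 20,
                         `Central Asia` = 30, `East Asia` = 30,
                         America = 8))
  times <- c(T1 = 107067, T2 = 74916, T3 = 63210, T4 = 49280,
             T5 = 36700, T6 = 15828)
  ref_mt <- abc_reference("stage2", pr, cfg, 8000,
                          locus = locus_spec("mtDNA"),
                          fixed_times = times, seed = 21)
  ref_nry <- abc_reference("stage2", pr, cfg, 8000,
                           locus = locus_spec("NRY"),
                           fixed_times = times, seed = 22)
  truth_m <- tidy(default_model("NRY"))
  truth_nry <- setNames(truth_m$value, truth_m$parameter)
  sizes_nry <- truth_nry[unidem:::SIZE_PARAMS]
  sizes_mt <- 2 * sizes_nry  # female sizes planted at twice the male sizes
  par_tbl <- function(sizes) {
    dplyr::bind_cols(tibble::as_tibble(as.list(times)),
                     tibble::as_tibble(as.list(sizes)))
  }
  n_pods <- 30
  cur <- paste0("N_cur_", c("Africa", "Oceania", "Europe", "CentralAsia",
                            "EastAsia", "America"))
  set.seed(23)
  stats_mt <- simulate_sumstats(par_tbl(sizes_mt)[rep(1, n_pods), ], cfg,
                                locus_spec("mtDNA"))
  stats_nry <- simulate_sumstats(par_tbl(sizes_nry)[rep(1, n_pods), ], cfg,
                                 locus_spec("NRY"))
  wins <- vapply(seq_len(n_pods), function(i) {
    est_f <- abc_estimate(ref_mt, stats_mt[i, ], top_k = 300)$summary
    est_m <- abc_estimate(ref_nry, stats_nry[i, ], top_k = 300)$summary
    ratio <- est_f$mean[match(cur, est_f$parameter)] /
      est_m$mean[match(cur, est_m$parameter)]
    exp(mean(log(ratio))) > 1
  }, TRUE)
  expect_gte(mean(wins), 0.9)
})

test_that("a larger reference table does not worsen divergence-time RMSE", {
  pr <- prior_spec()
  cfg <- sample_config(c(Africa = 30, Oceania = 6, Europe = 25,
                         `Central Asia` = 45, `East Asia` = 50,
                         America = 8))
  ref_small <- abc_reference("stage1", pr, cfg, 4000, seed = 41)
  ref_large <- abc_reference("stage1", pr, cfg, 20000, seed = 42)
  v_small <- validate_with_pods(ref_small, n_pods = 25, top_k = 200,
                                seed = 43)
  v_large <- validate_with_pods(ref_large, n_pods = 25, top_k = 200,
                                seed = 43)
  expect_lte(mean(v_large$rmse), mean(v_small$rmse) + 0.05)
})
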