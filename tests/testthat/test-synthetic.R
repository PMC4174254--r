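test_that("the default synthetic study reproduces the design constants", {
  out <- generate_study(study_config(), withr::local_tempdir(), seed = 5)
  meta <- out$metadata
  expect_equal(nrow(meta), 511L)
  expect_equal(sort(unique(meta$region)),
               sort(c("Africa", "Central Asia", "East Asia", "Europe",
                      "Oceania", "America")))
  expect_equal(length(unique(meta$population)), 44L)
  counts <- table(meta$region)
  expect_equal(unname(counts[c("Africa", "Central Asia", "East Asia",
                               "Europe", "Oceania", "America")]),
               c(85L, 146L, 162L, 79L, 17L, 22L),
               ignore_attr = TRUE)
  frac <- mean(is.na(out$nry_masked$geno))
  expect_close(frac, 0.0254, 0.003)
  # truth matrix is complete and matches the masked one where observed
  obs <- !is.na(out$nry_masked$geno)
  expect_false(anyNA(out$nry_truth$geno))
  expect_equal(out$nry_masked$geno[obs], out$nry_truth$geno[obs])
  expect_true(all(file.exists(unlist(out$paths))))
})

test_that("the generated fileset is byte-identical under the same seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  o1 <- generate_study(study_config(), d1, seed = 11)
  o2 <- generate_study(study_config(), d2, seed = 11)
  for (nm in names(o1$paths)) {
    expect_identical(readLines(o1$paths[[nm]]), readLines(o2$paths[[nm]]),
                     label = nm)
  }
})

test_that("zero missingness makes the masked and truth tables identical", {
  cfg <- sample_config(c(Africa = 10, Oceania = 3, Europe = 5,
                         `Central Asia` = 5, `East Asia` = 5, America = 3))
  sc <- study_config(cfg = cfg, missing_fraction = 0)
  out <- generate_study(sc, withr::local_tempdir(), seed = 3)
  expect_identical(readLines(out$paths$nry_vcf),
                   sub("nry_variants_truth", "nry_variants",
                       readLines(out$paths$nry_truth_vcf)))
})

test_that("the mtDNA FASTA round-trips to the simulated matrix", {
  cfg <- sample_config(c(Africa = 8, Oceania = 2, Europe = 4,
                         `Central Asia` = 4, `East Asia` = 4, America = 2))
  out <- generate_study(study_config(cfg = cfg), withr::local_tempdir(),
                        seed = 7)
  aln <- read_fasta_alignment(out$paths$mtdna_fasta)
  m <- extract_biallelic_sites(aln)
  truth <- out$mt
  # singleton-free? no — but every simulated variable site must reappear
  expect_equal(m$sites$position, truth$sites$position)
  # genotype codes may flip polarity (majority-ref recoding); compare the
  # partition of samples each site induces
  same_or_flipped <- vapply(seq_len(ncol(m$geno)), function(j) {
    a <- m$geno[, j]; b <- truth$geno[, j]
    all(a == b) || all(a == 1L - b)
  }, TRUE)
  expect_true(all(same_or_flipped))
})

test_that("per-sample missing counts follow the configured skewed profile", {
  set.seed(9)
  n <- 300; S <- 2000; frac <- 0.0254
  lo <- round(9 * S / 2276); hi <- round(1173 * S / 2276)
  for (i in 1:20) {
    cnt <- unidem:::default_missing_counts(n, S, frac)
    expect_true(all(cnt >= lo - 1 & cnt <= hi + 1))
    expect_close(sum(cnt) / (n * S), frac, 0.004)
  }
})

test_that("worked fixtures are stable and serializable", {
  fx1 <- worked_fixture()
  fx2 <- worked_fixture()
  expect_equal(names(fx1), c("tajima4", "impute3", "phist22"))
  expect_equal(fx1, fx2)
  expect_equal(unname(fx1$tajima4$matrix$geno),
               rbind(c(0L, 0L, 0L), c(0L, 0L, 1L), c(0L, 1L, 1L),
                     c(1L, 1L, 1L)))
  d <- withr::local_tempdir()
  worked_fixture(d)
  expect_equal(sort(list.files(d)),
               sort(c("tajima4.tsv", "tajima4_expected.json",
                      "impute3.tsv", "impute3_expected.json",
                      "phist22.tsv", "phist22_expected.json")))
})

test_that("generated data flow through QC, imputation and statistics", {
  cfg <- sample_config(c(Africa = 17, Oceania = 4, Europe = 16,
                         `Central Asia` = 29, `East Asia` = 32,
                         America = 5))
  out <- generate_study(study_config(cfg = cfg), withr::local_tempdir(),
                        seed = 13)
  nry <- impute_missing(read_variant_table(out$paths$nry_vcf))$matrix
  meta <- read_sample_metadata(out$paths$metadata)
  div <- diversity_by(nry, meta, by = "region")
  expect_equal(nrow(div), 6L)
  expect_true(all(div$S > 0))
  # matrix-path mpd consistent with the fast-path expectation
  truth_m <- tidy(default_model("NRY"))
  pars <- dplyr::bind_cols(
    tibble::as_tibble(as.list(setNames(truth_m$value[1:6],
                                       paste0("T", 1:6)))),
    tibble::as_tibble(as.list(setNames(
      truth_m$value[match(unidem:::SIZE_PARAMS, truth_m$parameter)],
      unidem:::SIZE_PARAMS))))
  fast <- simulate_sumstats(pars[rep(1, 400), ], cfg, locus_spec("NRY"),
                            seed = 14)
  obs_mpd <- div$mpd[div$group == "Africa"]
  fast_mpd <- fast[, "mpd_Africa"]
  expect_close(obs_mpd, mean(fast_mpd), 3.5 * sd(fast_mpd))
})
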