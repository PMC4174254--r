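#' Run the end-to-end uniparental analysis pipeline
#'
#' Orchestrates QC, imputation, the homoplasy filter, diversity and
#' differentiation statistics, and (optionally) the two ABC stages, with
#' all intermediate state on disk as plain-text files for auditability.
#' Stages: (1) read or synthesize inputs; (2) extract biallelic mtDNA
#' sites from the alignment; (3) impute NRY missing calls; (4) remove
#' recurrent (homoplastic) NRY sites; (5) per-region diversity report,
#' AMOVA reports, mpd-ratio resampling, Mantel tests; (6) divergence-time
#' and effective-size ABC estimates, optionally with pod validation.
#'
#' @param config Named list; recognized entries (all have defaults):
#'   `synthetic` (logical, default TRUE), `study` (a [study_config()]),
#'   `paths` (list `mtdna_fasta`, `nry_vcf`, `metadata` when
#'   `synthetic = FALSE`), `run_abc` (default FALSE), `abc_n_draws`,
#'   `abc_top_k`, `abc_n_pods` (0 disables validation), `stat_perms`,
#'   `mpd_reps`, `mantel_reps`, `generation_time`, `seed`.
#' @param out_dir Output directory for reports and the manifest.
#' @return A list of report tibbles (`diversity`, `amova`, `mantel`,
#'   `divergence_times`, `sizes`, `validation`) plus `manifest`.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile()) {
  t_start <- Sys.time()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- utils::modifyList(list(
    synthetic = TRUE, study = study_config(), paths = NULL,
    run_abc = FALSE, abc_n_draws = 5000, abc_top_k = 200, abc_n_pods = 0,
    stat_perms = 200, mpd_reps = 2000, mantel_reps = 1000,
    generation_time = 25, seed = 1L
  ), config)
  set.seed(cfg$seed)
  timings <- list()
  tick <- function(label, t0) {
    timings[[label]] <<- round(as.numeric(Sys.time() - t0, units = "secs"), 2)
  }

  # stage 1: inputs
  t0 <- Sys.time()
  if (cfg$synthetic) {
    study <- generate_study(cfg$study, file.path(out_dir, "inputs"),
                            seed = cfg$seed)
    paths <- study$paths
  } else {
    paths <- cfg$paths
    if (is.null(paths)) abort("Stage input: non-synthetic runs need `paths`.")
  }
  meta <- read_sample_metadata(paths$metadata)
  aln <- read_fasta_alignment(paths$mtdna_fasta)
  nry_raw <- read_variant_table(paths$nry_vcf)
  tick("inputs", t0)

  # stage 2: mtDNA QC
  t0 <- Sys.time()
  mt <- extract_biallelic_sites(aln, locus = "mtDNA")
  tick("qc", t0)

  # stage 3: NRY imputation
  t0 <- Sys.time()
  imp <- impute_missing(nry_raw)
  nry <- imp$matrix
  readr::write_tsv(imp$fill_log, file.path(out_dir, "imputation_log.tsv"))
  tick("imputation", t0)

  # stage 4: homoplasy filter
  t0 <- Sys.time()
  tree <- build_parsimony_tree(nry, seed = cfg$seed)
  profiles <- fitch_counts(tree, nry)
  nry_f <- filter_recurrent_sites(nry, profiles)
  ape::write.tree(tree, file.path(out_dir, "nry_parsimony.nwk"))
  readr::write_tsv(attr(nry_f, "removal_report"),
                   file.path(out_dir, "homoplasy_report.tsv"))
  tick("homoplasy_filter", t0)

  # stage 5: statistics
  t0 <- Sys.time()
  meta_m <- align_metadata(nry_f, meta)
  L_mt <- sum(locus_spec("mtDNA")$length)
  L_nry <- locus_spec("NRY")$length
  div <- dplyr::bind_rows(
    dplyr::mutate(diversity_by(mt, meta_m$region, L = L_mt),
                  locus = "mtDNA", .before = 1),
    dplyr::mutate(diversity_by(nry_f, meta_m$region, L = L_nry),
                  locus = "NRY", .before = 1)
  )
  ratio <- mpd_ratio_resample(nry_f, mt, meta, by = "region",
                              reps = cfg$mpd_reps)
  div_report <- dplyr::left_join(
    div, dplyr::select(ratio, "group", "ratio", "p_value"), by = "group")
  readr::write_tsv(div_report, file.path(out_dir, "diversity_report.tsv"))

  amova_rep <- purrr::map_dfr(
    list(list(m = nry_f, locus = "NRY"), list(m = mt, locus = "mtDNA")),
    function(it) {
      a3 <- amova(it$m, meta_m$population, meta_m$region,
                  n_perm = cfg$stat_perms)
      a2 <- amova(it$m, meta_m$population, n_perm = cfg$stat_perms)
      dplyr::bind_rows(
        dplyr::mutate(tidy(a3), locus = it$locus, design = "3-level",
                      .before = 1),
        dplyr::mutate(tidy(a2), locus = it$locus, design = "2-level",
                      .before = 1)
      )
    })
  readr::write_tsv(amova_rep, file.path(out_dir, "amova_report.tsv"))

  geo <- great_circle_distances(meta, by = "population")
  mantel_rep <- purrr::map_dfr(
    list(list(m = nry_f, locus = "NRY"), list(m = mt, locus = "mtDNA")),
    function(it) {
      ph <- pairwise_phist(it$m, meta_m$population, n_perm = 0)
      common <- intersect(rownames(ph$phi), rownames(geo))
      dplyr::mutate(
        mantel_test(ph$phi[common, common], geo[common, common],
                    reps = cfg$mantel_reps),
        locus = it$locus, .before = 1)
    })
  readr::write_tsv(mantel_rep, file.path(out_dir, "mantel_report.tsv"))
  tick("statistics", t0)

  # stage 6: ABC
  times_rep <- sizes_rep <- valid_rep <- NULL
  if (isTRUE(cfg$run_abc)) {
    t0 <- Sys.time()
    obs_mt <- summarize_stats(mt, meta_m$region)
    obs_nry <- summarize_stats(nry_f, meta_m$region)
    obs_comb <- c(setNames(obs_mt, paste0("mt_", names(obs_mt))),
                  setNames(obs_nry, paste0("nry_", names(obs_nry))))
    counts <- sample_config(table(meta_m$region))
    s1 <- run_stage1(obs_comb, cfg = counts, n_draws = cfg$abc_n_draws,
                     top_k = cfg$abc_top_k,
                     generation_time = cfg$generation_time)
    times_rep <- dplyr::mutate(tidy(s1$posterior), stage = "stage1",
                               .before = 1)
    t_means <- setNames(times_rep$mean, times_rep$parameter)
    sizes_rep <- purrr::map_dfr(c("mtDNA", "NRY"), function(lc) {
      obs <- if (lc == "mtDNA") obs_mt else obs_nry
      s2 <- run_stage2(obs, locus_spec(lc), t_means, cfg = counts,
                       n_draws = cfg$abc_n_draws, top_k = cfg$abc_top_k,
                       generation_time = cfg$generation_time)
      dplyr::mutate(tidy(s2$posterior), locus = lc, .before = 1)
    })
    readr::write_tsv(times_rep, file.path(out_dir, "divergence_times.tsv"))
    readr::write_tsv(sizes_rep, file.path(out_dir, "effective_sizes.tsv"))
    if (cfg$abc_n_pods > 0) {
      valid_rep <- validate_with_pods(s1$ref, n_pods = cfg$abc_n_pods,
                                      top_k = cfg$abc_top_k)
      readr::write_tsv(valid_rep, file.path(out_dir, "validation.tsv"))
    }
    tick("abc", t0)
  }

  manifest <- list(
    package = "unidem",
    version = as.character(utils::packageVersion("unidem")),
    r_version = R.version.string,
    seed = cfg$seed,
    generation_time = cfg$generation_time,
    n_samples = nrow(meta_m),
    n_sites = list(mtDNA = ncol(mt$geno), NRY = ncol(nry_f$geno),
                   NRY_removed = attr(nry_f, "n_removed")),
    timings_sec = timings,
    total_sec = round(as.numeric(Sys.time() - t_start, units = "secs"), 2)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  list(diversity = div_report, amova = amova_rep, mantel = mantel_rep,
       divergence_times = times_rep, sizes = sizes_rep,
       validation = valid_rep, manifest = manifest)
}
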