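# Synthetic study generator: produces a complete HGDP-like input set
# (mtDNA alignment, NRY variant tables with realistic missingness, sample
# metadata with coordinates, true parameters) so that every pipeline stage
# can be exercised without any download.

#' Synthetic population gazetteer
#'
#' A fixed table of 44 synthetic populations across the six model regions
#' (population counts 10/7/15/5/2/5 for Africa, Central Asia, East Asia,
#' Europe, Oceania, America), with invented coordinates placed inside
#' plausible regional bounding boxes. Populations are labels only — the
#' demographic model is panmictic within regions — but they give the
#' AMOVA/Phi-ST/Mantel code paths realistic strata. Entirely synthetic;
#' not real HGDP populations or locations.
#'
#' @return A tibble with columns `population`, `region`, `latitude`,
#'   `longitude`.
#' @export
population_gazetteer <- function() {
  boxes <- list(
    "Africa" = c(lat0 = -25, lat1 = 15, lon0 = -10, lon1 = 40, n = 10),
    "Central Asia" = c(lat0 = 25, lat1 = 45, lon0 = 55, lon1 = 80, n = 7),
    "East Asia" = c(lat0 = 20, lat1 = 45, lon0 = 95, lon1 = 130, n = 15),
    "Europe" = c(lat0 = 38, lat1 = 60, lon0 = -8, lon1 = 30, n = 5),
    "Oceania" = c(lat0 = -8, lat1 = -3, lon0 = 142, lon1 = 152, n = 2),
    "America" = c(lat0 = -15, lat1 = 30, lon0 = -100, lon1 = -50, n = 5)
  )
  purrr::map_dfr(names(boxes), function(rg) {
    b <- boxes[[rg]]
    k <- b[["n"]]
    # deterministic low-discrepancy placement inside the box
    f <- (seq_len(k) - 0.5) / k
    tibble::tibble(
      population = sprintf("%s_P%02d", region_tag(rg), seq_len(k)),
      region = rg,
      latitude = b[["lat0"]] + f * (b[["lat1"]] - b[["lat0"]]),
      longitude = b[["lon0"]] + rev(f) * (b[["lon1"]] - b[["lon0"]])
    )
  })
}

#' Synthetic study configuration
#'
#' Defaults reproduce the study design: 511 male samples over six regions
#' (Africa 85, Central Asia 146, East Asia 162, Europe 79, Oceania 17,
#' America 22) in 44 populations, mtDNA and NRY loci simulated under the
#' serial-founder model with the [default_model()] parameter point
#' estimates as truth, and NRY missingness of 2.54% overall following a
#' skewed per-sample distribution (mean 122, range 9-1,173 per 2,276
#' sites, rescaled to the realized matrix width).
#'
#' @param cfg A [sample_config()].
#' @param model_nry,model_mt True [demographic_model()]s (male and female
#'   sizes respectively).
#' @param missing_fraction Overall NRY missingness fraction.
#' @param nry_rate NRY mutation-rate choice.
#' @return A list of class `study_config`.
#' @export
study_config <- function(cfg = sample_config(),
                         model_nry = default_model("NRY"),
                         model_mt = default_model("mtDNA"),
                         missing_fraction = 0.0254,
                         nry_rate = "avg") {
  if (missing_fraction < 0 || missing_fraction >= 1) {
    abort("`missing_fraction` must be in [0, 1).")
  }
  structure(
    list(cfg = cfg, model_nry = model_nry, model_mt = model_mt,
         missing_fraction = missing_fraction, nry_rate = nry_rate),
    class = "study_config"
  )
}

# Deterministic arbitrary mtDNA-like reference sequence (independent of
# the user's RNG state).
reference_sequence <- function(L) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(16569L)
  sample(c("A", "C", "G", "T"), L, replace = TRUE)
}

# Next base in a fixed cycle: the alternative allele at a site.
other_base <- function(b) {
  c(A = "G", C = "T", G = "A", T = "C")[b]
}

#' Generate a complete synthetic study
#'
#' Simulates mtDNA and NRY haplotype data under the configured true
#' models, assigns samples to populations, applies the configured NRY
#' missingness, and writes the full input fileset: mtDNA FASTA (mutations
#' substituted into a fixed arbitrary reference), NRY VCF with missing
#' calls, complete truth VCF, metadata TSV, and a truth-parameters JSON.
#'
#' @param config A [study_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed; the fileset is byte-identical given the seed.
#' @return Invisibly, a list with the file `paths` and the in-memory
#'   objects (`mt`, `nry_masked`, `nry_truth`, `metadata`).
#' @export
generate_study <- function(config = study_config(), out_dir = tempfile(),
                           seed = 1L) {
  set.seed(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- config$cfg
  gaz <- population_gazetteer()

  # sample sheet: round-robin assignment of samples to populations
  meta <- purrr::map_dfr(DEME_ORDER, function(rg) {
    n <- cfg[[rg]]
    if (n == 0) return(NULL)
    pops <- gaz$population[gaz$region == rg]
    tibble::tibble(
      sample_id = sprintf("%s%03d", region_tag(rg), seq_len(n)),
      sex = "M",
      population = pops[((seq_len(n) - 1) %% length(pops)) + 1],
      region = rg
    )
  })
  meta <- dplyr::left_join(meta, gaz, by = c("population", "region"))
  meta$excluded_flag <- FALSE
  meta <- sample_table(meta)

  g <- config$model_mt$generation_time
  mt <- simulate_matrix(config$model_mt, cfg, locus_spec("mtDNA"))
  nry <- simulate_matrix(config$model_nry, cfg,
                         locus_spec("NRY", nry_rate = config$nry_rate))
  rownames(mt$geno) <- meta$sample_id
  rownames(nry$geno) <- meta$sample_id
  mt$locus <- "mtDNA"
  nry$locus <- "NRY"

  # substitute mtDNA mutations into the fixed reference string
  L_mt <- sum(locus_spec("mtDNA")$length)
  ref_seq <- reference_sequence(L_mt)
  mt$sites$ref <- ref_seq[mt$sites$position]
  mt$sites$alt <- unname(other_base(mt$sites$ref))
  seqs <- vapply(seq_len(nrow(mt$geno)), function(i) {
    s <- ref_seq
    alt_at <- mt$sites$position[mt$geno[i, ] == 1L]
    s[alt_at] <- mt$sites$alt[mt$geno[i, ] == 1L]
    paste0(s, collapse = "")
  }, "")
  aln <- hap_alignment(meta$sample_id, seqs)

  # NRY missingness: skewed per-sample counts, overall fraction as set
  nry_masked <- nry
  if (config$missing_fraction > 0 && ncol(nry$geno) > 1) {
    n <- nrow(nry$geno); S <- ncol(nry$geno)
    counts <- default_missing_counts(n, S, config$missing_fraction)
    for (i in seq_len(n)) {
      nry_masked$geno[i, sample.int(S, counts[i])] <- NA_integer_
    }
    # keep at least one fully observed site so imputation is well posed
    if (all(colSums(is.na(nry_masked$geno)) > 0)) {
      s_min <- which.min(colSums(is.na(nry_masked$geno)))
      nry_masked$geno[, s_min] <- nry$geno[, s_min]
    }
  }

  paths <- list(
    mtdna_fasta = file.path(out_dir, "mtdna_alignment.fasta"),
    nry_vcf = file.path(out_dir, "nry_variants.vcf"),
    nry_truth_vcf = file.path(out_dir, "nry_variants_truth.vcf"),
    metadata = file.path(out_dir, "samples.tsv"),
    truth_json = file.path(out_dir, "truth_parameters.json")
  )
  write_fasta_alignment(aln, paths$mtdna_fasta)
  write_variant_table(nry_masked, paths$nry_vcf, "vcf")
  write_variant_table(nry, paths$nry_truth_vcf, "vcf")
  write_sample_metadata(meta, paths$metadata)
  jsonlite::write_json(
    list(seed = seed,
         model_nry = setNames(as.list(tidy(config$model_nry)$value),
                              tidy(config$model_nry)$parameter),
         model_mt = setNames(as.list(tidy(config$model_mt)$value),
                             tidy(config$model_mt)$parameter),
         generation_time = g,
         missing_fraction = config$missing_fraction),
    paths$truth_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(paths = paths, mt = mt, nry_masked = nry_masked,
                 nry_truth = nry, metadata = meta, alignment = aln))
}

#' Hand-checkable worked fixtures
#'
#' Tiny datasets used throughout the documentation and tests, with their
#' expected outputs:
#' * `tajima4` — the four-haplotype diversity toy `{000, 001, 011, 111}`
#'   (`L = 6`): `S = 3`, `mpd = 10/6`, `H = 1`, `theta_S = 18/11`,
#'   `D = 0.1676...`
#' * `impute3` — three reference haplotypes `{000, 110, 111}` plus a
#'   target site where the third sample is missing; the nearest donor is
#'   h2, so the imputed allele is 1.
#' * `phist22` — two populations of two haplotypes with within-population
#'   variation: variance components `sigma2_within = 0.5`,
#'   `sigma2_among = 0.75`, `Phi_ST = 0.6`.
#'
#' @param out_dir Optional directory; when given, each fixture is written
#'   as a TSV variant table plus a JSON of expected values.
#' @return Named list of fixtures, each with `matrix` ([hap_matrix()]),
#'   `expected` (named list), and auxiliary fields.
#' @export
worked_fixture <- function(out_dir = NULL) {
  tajima4 <- hap_matrix(
    rbind(a = c(0L, 0L, 0L), b = c(0L, 0L, 1L),
          c = c(0L, 1L, 1L), d = c(1L, 1L, 1L)),
    position = 1:3)
  impute3 <- hap_matrix(
    rbind(h1 = c(0L, 0L, 0L, 0L), h2 = c(1L, 1L, 0L, 1L),
          h3 = c(1L, 1L, 1L, NA)),
    position = 1:4)
  phist22 <- hap_matrix(
    rbind(a1 = c(0L, 0L, 0L), a2 = c(0L, 0L, 1L),
          b1 = c(1L, 1L, 0L), b2 = c(1L, 1L, 1L)),
    position = 1:3)
  fx <- list(
    tajima4 = list(
      matrix = tajima4, L = 6,
      expected = list(S = 3, mpd = 10 / 6, H = 1, theta_s = 18 / 11,
                      pi = 10 / 36)),
    impute3 = list(
      matrix = impute3,
      expected = list(sample = "h3", position = 4L, allele = 1L)),
    phist22 = list(
      matrix = phist22, population = c("A", "A", "B", "B"),
      expected = list(sigma_within = 0.5, sigma_among = 0.75,
                      phi_st = 0.6))
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(fx)) {
      write_variant_table(fx[[nm]]$matrix,
                          file.path(out_dir, paste0(nm, ".tsv")), "tsv")
      jsonlite::write_json(fx[[nm]]$expected,
                           file.path(out_dir, paste0(nm, "_expected.json")),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
  }
  fx
}
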