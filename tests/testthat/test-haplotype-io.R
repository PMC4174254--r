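test_that("FASTA reading upper-cases, preserves order, and round-trips", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", "acgtAC", ">s2", "AAC", "CAC", ">s3", "GGGTTT"), path)
  aln <- read_fasta_alignment(path)
  expect_equal(aln$sample_ids, c("s1", "s2", "s3"))
  expect_equal(paste0(aln$seq[1, ], collapse = ""), "ACGTAC")
  expect_equal(paste0(aln$seq[2, ], collapse = ""), "AACCAC")
  out <- withr::local_tempfile(fileext = ".fasta")
  write_fasta_alignment(aln, out)
  expect_equal(read_fasta_alignment(out), aln)
})

test_that("malformed FASTA inputs are rejected", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGTACGTAC", ">b", "ACGTACGTACG"), path)
  expect_error(read_fasta_alignment(path), "shape")
  writeLines("ACGT", path)
  expect_error(read_fasta_alignment(path), "FASTA")
})

test_that("biallelic extraction drops invariant and multi-allelic columns", {
  # col1 invariant; col2 biallelic; col3 tri-allelic; col4 biallelic with a
  # missing call; cols 5-6 invariant
  aln <- hap_alignment(c("s1", "s2", "s3", "s4"),
                       c("AAAACC", "AAGNCC", "AGTGCC", "AAAGCC"))
  m <- extract_biallelic_sites(aln)
  expect_equal(m$sites$position, c(2L, 4L))
  expect_equal(attr(m, "n_multiallelic"), 1L)
  expect_equal(attr(m, "n_invariant"), 3L)
  # col4: majority base G is ref, A is alt, N missing
  expect_equal(unname(m$geno[, 2]), c(1L, NA, 0L, 0L))
  # gaps and IUPAC ambiguity codes are treated as missing
  aln2 <- hap_alignment(c("x", "y", "z"), c("A-R", "GCA", "GTA"))
  m2 <- extract_biallelic_sites(aln2)
  expect_equal(m2$sites$position, c(1L, 2L))
  expect_equal(unname(m2$geno[, 1]), c(1L, 0L, 0L))
  expect_equal(unname(m2$geno[, 2]), c(NA, 0L, 1L))
  # identical sequences: no variable sites, not an error
  m3 <- extract_biallelic_sites(hap_alignment(c("a", "b"), c("ACG", "ACG")))
  expect_equal(ncol(m3$geno), 0L)
})

test_that("majority-allele ties resolve to the alphabetically smaller base", {
  aln <- hap_alignment(c("s1", "s2", "s3", "s4"), c("G", "G", "A", "A"))
  m <- extract_biallelic_sites(aln)
  expect_equal(m$sites$ref, "A")
  expect_equal(m$sites$alt, "G")
  expect_equal(unname(m$geno[, 1]), c(1L, 1L, 0L, 0L))
})

test_that("PL-based calling applies the three confidence clauses", {
  recs <- tibble::tibble(
    position = 1:4, sample_id = "s",
    pl_ref = c(0, 0, 30, 0),
    pl_het = c(50, 60, 0, 10),
    pl_alt = c(40, 20, 40, 100)
  )
  m <- call_genotypes_from_pl(recs)
  # clear homozygote ref; homozygote gap 20 < 30; het most likely;
  # het within 30 of the best homozygote
  expect_equal(unname(m$geno["s", ]), c(0L, NA, NA, NA))
  # alt call when PL(1/1) is the low homozygote
  ralt <- tibble::tibble(position = 1L, sample_id = "s",
                         pl_ref = 90, pl_het = 45, pl_alt = 0)
  expect_equal(unname(call_genotypes_from_pl(ralt)$geno[1, 1]), 1L)
  expect_error(
    call_genotypes_from_pl(dplyr::mutate(recs, pl_ref = -1)),
    "non-negative")
})

test_that("PL calling is permutation-equivariant in records", {
  set.seed(5)
  recs <- tidyr::expand_grid(position = 1:6, sample_id = letters[1:4]) |>
    dplyr::mutate(pl_ref = sample(0:80, 24, TRUE),
                  pl_het = sample(0:80, 24, TRUE),
                  pl_alt = sample(0:80, 24, TRUE))
  m1 <- call_genotypes_from_pl(recs)
  m2 <- call_genotypes_from_pl(recs[sample.int(nrow(recs)), ])
  expect_equal(m1$geno[rownames(m2$geno), ], m2$geno)
  expect_equal(m1$sites, m2$sites)
})

test_that("metadata reading validates the region vocabulary", {
  path <- withr::local_tempfile(fileext = ".tsv")
  tab <- tibble::tibble(
    sample_id = c("a", "b", "c"), sex = "M",
    population = c("P1", "P1", "P2"),
    region = c("Africa", "Europe", "ME/NA"),
    latitude = c(1.5, NA, 30), longitude = c(10, 2, 40),
    excluded_flag = c(FALSE, FALSE, TRUE)
  )
  readr::write_tsv(tab, path)
  meta <- read_sample_metadata(path)
  expect_s3_class(meta, "sample_table")
  expect_equal(nrow(meta), 3)
  # missing coordinates: retained but flagged for geographic exclusion
  expect_equal(meta$has_coords, c(TRUE, FALSE, TRUE))
  readr::write_tsv(dplyr::mutate(tab, region = "Atlantis"), path)
  expect_error(read_sample_metadata(path), "Unknown region")
  readr::write_tsv(dplyr::mutate(tab, sample_id = "a"), path)
  expect_error(read_sample_metadata(path), "Duplicate")
})

test_that("variant tables round-trip through VCF and TSV", {
  m <- rand_hap_matrix(6, 9, miss_frac = 0.2, seed = 3)
  m$locus <- "NRY"
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_variant_table(m, vcf, "vcf")
  m2 <- read_variant_table(vcf)
  expect_true(m == m2)
  # missing calls are written as "."
  body <- readLines(vcf)
  body <- body[!startsWith(body, "#")]
  expect_true(any(grepl("\t\\.", body)))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_variant_table(m, tsv, "tsv")
  m3 <- read_variant_table(tsv)
  expect_equal(m3$geno, m$geno)
  expect_equal(m3$sites, m$sites)
  # empty matrix: header-only VCF, still readable
  e <- m[, integer(0)]
  write_variant_table(e, vcf, "vcf")
  expect_equal(ncol(read_variant_table(vcf)$geno), 0L)
})

test_that("the haploid VCF dialect is read identically by vcfR", {
  skip_if_not_installed("vcfR")
  m <- rand_hap_matrix(5, 7, miss_frac = 0.15, seed = 11)
  m$locus <- "NRY"
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_variant_table(m, vcf, "vcf")
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  gt <- vcfR::extract.gt(v)
  gt_int <- suppressWarnings(matrix(as.integer(gt), nrow(gt), ncol(gt)))
  expect_equal(unname(t(gt_int)), unname(m$geno))
  expect_equal(as.integer(vcfR::getPOS(v)), m$sites$position)
})
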