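#' Write a haplotype matrix to a variant table
#'
#' Two plain-text formats are supported:
#' * `"vcf"`: VCF v4.2 haploid dialect — one record per site, 1-based `POS`,
#'   single `ALT`, and a haploid `GT` field per sample (`0`, `1`, or `.` for
#'   missing).
#' * `"tsv"`: wide table with `position`, `ref`, `alt` and one column per
#'   sample (`0`/`1`/`N`).
#'
#' [read_variant_table()] inverts either format exactly.
#'
#' @param m A [hap_matrix()].
#' @param path Output path.
#' @param format `"vcf"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(m, path, format = c("vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "vcf") {
    gt <- t(m$geno)
    gt_chr <- matrix(as.character(gt), nrow(gt), ncol(gt))
    gt_chr[is.na(gt)] <- "."
    header <- c(
      "##fileformat=VCFv4.2",
      "##source=unidem",
      paste0("##contig=<ID=", m$locus, ">"),
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Haploid genotype\">",
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
              "INFO", "FORMAT", sample_ids(m)), collapse = "\t")
    )
    body <- if (ncol(m$geno)) {
      paste(m$locus, m$sites$position, ".", m$sites$ref, m$sites$alt,
            ".", "PASS", ".", "GT",
            apply(gt_chr, 1, paste, collapse = "\t"), sep = "\t")
    } else character()
    writeLines(c(header, body), path)
  } else {
    gt <- t(m$geno)
    gt_chr <- matrix(as.character(gt), nrow(gt), ncol(gt),
                     dimnames = list(NULL, sample_ids(m)))
    gt_chr[is.na(gt)] <- "N"
    tab <- dplyr::bind_cols(
      tibble::tibble(position = m$sites$position,
                     ref = m$sites$ref, alt = m$sites$alt),
      tibble::as_tibble(gt_chr)
    )
    readr::write_tsv(tab, path)
  }
  invisible(path)
}

#' Read a variant table written by [write_variant_table()]
#'
#' @param path Path to a `.vcf` or wide `.tsv` variant table.
#' @param format `"auto"` sniffs the first line; otherwise `"vcf"`/`"tsv"`.
#' @return A [hap_matrix()].
#' @export
read_variant_table <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1)
    format <- if (startsWith(first, "##fileformat=VCF")) "vcf" else "tsv"
  }
  if (format == "vcf") {
    lines <- readLines(path)
    hdr <- lines[startsWith(lines, "#")]
    body <- lines[!startsWith(lines, "#")]
    col_line <- hdr[startsWith(hdr, "#CHROM")]
    if (!length(col_line)) abort("VCF missing #CHROM header line.")
    cols <- strsplit(sub("^#", "", col_line), "\t")[[1]]
    samples <- cols[-(1:9)]
    if (!length(body)) {
      g <- matrix(integer(), length(samples), 0,
                  dimnames = list(samples, NULL))
      return(hap_matrix(g, position = integer(), ref = character(),
                        alt = character(), locus = "NRY"))
    }
    fields <- strsplit(body, "\t", fixed = TRUE)
    rec <- do.call(rbind, fields)
    gt <- rec[, -(1:9), drop = FALSE]
    gt[gt == "."] <- NA
    g <- t(matrix(as.integer(gt), nrow(gt), ncol(gt)))
    rownames(g) <- samples
    hap_matrix(g, position = as.integer(rec[, 2]), ref = rec[, 4],
               alt = rec[, 5], locus = rec[1, 1])
  } else {
    tab <- readr::read_tsv(path, col_types = readr::cols(
      position = readr::col_integer(),
      ref = readr::col_character(),
      alt = readr::col_character(),
      .default = readr::col_character()
    ))
    samples <- setdiff(names(tab), c("position", "ref", "alt"))
    gt <- as.matrix(tab[samples])
    gt[gt == "N"] <- NA
    g <- t(matrix(as.integer(gt), nrow(gt), ncol(gt)))
    rownames(g) <- samples
    hap_matrix(g, position = tab$position, ref = tab$ref, alt = tab$alt,
               locus = "NRY")
  }
}
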