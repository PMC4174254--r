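#' Read a FASTA alignment
#'
#' Reads an aligned FASTA file into a `hap_alignment`: an ordered set of
#' equal-length, upper-cased sequences. Record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return A `hap_alignment`: list with `sample_ids` (character) and `seq`
#'   (character matrix, samples x alignment columns).
#' @export
read_fasta_alignment <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  first <- readLines(path, n = 1, warn = FALSE)
  if (!length(first) || !startsWith(first, ">")) {
    abort("Not a FASTA file (no '>' header found).")
  }
  seqs <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) abort(paste0("FASTA format error: ",
                                     conditionMessage(e))))
  if (!length(seqs)) abort("FASTA format error: empty file.")
  ids <- sub("\\s.*$", "", names(seqs))
  hap_alignment(ids, toupper(as.character(seqs)))
}

#' Construct an alignment object
#'
#' @param sample_ids Unique sample identifiers.
#' @param sequences Character vector of equal-length sequences.
#' @return A `hap_alignment`.
#' @export
hap_alignment <- function(sample_ids, sequences) {
  sequences <- toupper(sequences)
  lens <- nchar(sequences)
  if (length(unique(lens)) > 1) {
    abort(sprintf(
      "Alignment shape error: sequence lengths differ (%s).",
      paste(unique(lens), collapse = ", ")
    ))
  }
  if (anyDuplicated(sample_ids)) abort("Duplicate sample ids in alignment.")
  seq_mat <- matrix(unlist(strsplit(sequences, "", fixed = TRUE)),
                    nrow = length(sequences), byrow = TRUE)
  rownames(seq_mat) <- sample_ids
  structure(list(sample_ids = sample_ids, seq = seq_mat),
            class = "hap_alignment")
}

#' @export
print.hap_alignment <- function(x, ...) {
  cat(sprintf("<hap_alignment> %d sequences x %d columns\n",
              nrow(x$seq), ncol(x$seq)))
  invisible(x)
}

#' @export
dim.hap_alignment <- function(x) dim(x$seq)

#' Write an alignment to FASTA
#'
#' @param aln A `hap_alignment`.
#' @param path Output file path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(aln, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(aln$sample_ids)) {
    s <- paste0(aln$seq[i, ], collapse = "")
    chunks <- substring(s, seq(1, nchar(s), width),
                        pmin(seq(1, nchar(s), width) + width - 1L, nchar(s)))
    writeLines(c(paste0(">", aln$sample_ids[i]), chunks), con)
  }
  invisible(path)
}

# Bases treated as valid allele calls; everything else (gaps, N, IUPAC
# ambiguity codes) is collapsed to missing.
.ACGT <- c("A", "C", "G", "T")

#' Extract biallelic variable sites from an alignment
#'
#' Drops invariant columns and columns with more than two distinct called
#' bases (multi-allelic). Gaps (`-`), `N` and IUPAC ambiguity codes are all
#' treated as missing. At each retained column the majority base becomes the
#' reference allele (code 0) and the minority base the alternative (code 1);
#' ties are broken towards the alphabetically smaller base. All downstream
#' statistics are invariant to this polarity choice.
#'
#' @param aln A `hap_alignment`.
#' @param locus Locus label for the resulting matrix.
#' @return A [hap_matrix()] with attributes `n_multiallelic` and
#'   `n_invariant`: counts of dropped columns of each kind. Zero variable
#'   biallelic columns yields an empty (0-site) matrix, not an error.
#' @export
extract_biallelic_sites <- function(aln, locus = "mtDNA") {
  if (!nrow(aln$seq)) abort("Empty alignment.")
  S <- ncol(aln$seq)
  keep <- logical(S)
  n_multi <- 0L
  n_invar <- 0L
  geno <- vector("list", S)
  ref <- character(S)
  alt <- character(S)
  for (j in seq_len(S)) {
    col <- aln$seq[, j]
    col[!(col %in% .ACGT)] <- NA_character_
    tab <- table(col)
    if (length(tab) > 2L) {
      n_multi <- n_multi + 1L
    } else if (length(tab) < 2L) {
      n_invar <- n_invar + 1L
    } else {
      # majority base = ref; alphabetical tie-break (table() is sorted by
      # base, so which.max picks the alphabetically first on ties)
      ref_base <- names(tab)[which.max(tab)]
      alt_base <- setdiff(names(tab), ref_base)
      keep[j] <- TRUE
      ref[j] <- ref_base
      alt[j] <- alt_base
      geno[[j]] <- ifelse(is.na(col), NA_integer_,
                          ifelse(col == ref_base, 0L, 1L))
    }
  }
  idx <- which(keep)
  g <- if (length(idx)) do.call(cbind, geno[idx]) else
    matrix(integer(), nrow = nrow(aln$seq), ncol = 0)
  rownames(g) <- aln$sample_ids
  m <- hap_matrix(g, position = idx, ref = ref[idx], alt = alt[idx],
                  locus = locus)
  attr(m, "n_multiallelic") <- n_multi
  attr(m, "n_invariant") <- n_invar
  m
}
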