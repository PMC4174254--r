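#' Read sample metadata
#'
#' Reads a tab-separated metadata table with the fixed header
#' `sample_id, sex, population, region, latitude, longitude, excluded_flag`.
#' Regions must come from the fixed vocabulary (Africa, America,
#' Central Asia, East Asia, Europe, ME/NA, Oceania). Samples lacking
#' coordinates are retained but flagged, and are excluded later from
#' geographic analyses.
#'
#' @param path Path to a TSV file.
#' @return A tibble (class `sample_table`) with typed columns and a logical
#'   `has_coords` column.
#' @export
read_sample_metadata <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    sex = readr::col_character(),
    population = readr::col_character(),
    region = readr::col_character(),
    latitude = readr::col_double(),
    longitude = readr::col_double(),
    excluded_flag = readr::col_logical()
  ))
  required <- c("sample_id", "sex", "population", "region",
                "latitude", "longitude", "excluded_flag")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    abort(paste0("Metadata is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  sample_table(tab)
}

#' Construct / validate a sample table
#'
#' @param tab Data frame with the metadata columns (see
#'   [read_sample_metadata()]).
#' @return A validated tibble with class `sample_table`.
#' @export
sample_table <- function(tab) {
  tab <- tibble::as_tibble(tab)
  if (anyDuplicated(tab$sample_id)) {
    abort("Duplicate sample_id in metadata.")
  }
  bad <- setdiff(unique(tab$region), REGIONS_ALL)
  if (length(bad)) {
    abort(paste0("Unknown region(s): ", paste(bad, collapse = ", "),
                 ". Allowed: ", paste(REGIONS_ALL, collapse = ", ")))
  }
  tab$has_coords <- !is.na(tab$latitude) & !is.na(tab$longitude)
  class(tab) <- c("sample_table", class(tab))
  tab
}

#' Write sample metadata to TSV
#' @param tab A `sample_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(tab, path) {
  cols <- c("sample_id", "sex", "population", "region",
            "latitude", "longitude", "excluded_flag")
  readr::write_tsv(tab[cols], path)
  invisible(path)
}

# Match metadata rows to the samples of a haplotype matrix (order of m).
align_metadata <- function(m, meta) {
  idx <- match(sample_ids(m), meta$sample_id)
  if (anyNA(idx)) {
    abort(paste0("Samples absent from metadata: ",
                 paste(head(sample_ids(m)[is.na(idx)], 5), collapse = ", ")))
  }
  meta[idx, ]
}
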