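# Readers and writers for the package's plain-text and TIFF interfaces.
# Tabular outputs are TSV (UTF-8, header row, '.' decimal) with a provenance
# comment header; nested results are JSON.

#' Read a table of per-core IHC observations
#'
#' CSV with header: `tumor_id`, `core_id`, `marker`, `compartment`,
#' `quantity`, `intensity`, optionally `grade`.
#'
#' @param path CSV file path.
#' @return Tibble of core observations.
#' @export
read_core_observations <- function(path) {
  out <- readr::read_csv(path,
    show_col_types = FALSE, comment = "#",
    col_types = readr::cols(
      tumor_id = readr::col_character(),
      core_id = readr::col_integer(),
      marker = readr::col_character(),
      compartment = readr::col_character(),
      quantity = readr::col_integer(),
      intensity = readr::col_integer(),
      .default = readr::col_guess()
    )
  )
  out
}

#' Read a qPCR Ct table
#'
#' CSV with header: `condition`, `gene`, `replicate`, `ct`.
#'
#' @param path CSV file path.
#' @return Tibble of Ct records.
#' @export
read_ct_table <- function(path) {
  readr::read_csv(path,
    show_col_types = FALSE, comment = "#",
    col_types = readr::cols(
      condition = readr::col_character(),
      gene = readr::col_character(),
      replicate = readr::col_integer(),
      ct = readr::col_double()
    )
  )
}

#' Read a gene-by-sample expression matrix
#'
#' TSV with genes as rows, samples as columns, first column = gene symbol.
#'
#' @param path TSV file path.
#' @return Numeric matrix with gene rownames.
#' @export
read_expression_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  mat <- as.matrix(df[, -1])
  rownames(mat) <- df[[1]]
  storage.mode(mat) <- "double"
  mat
}

#' Write a gene-by-sample expression matrix as TSV
#'
#' @param mat Numeric matrix with gene rownames.
#' @param path Output TSV path.
#' @param ... Passed to [write_tsv_provenance()].
#' @export
write_expression_tsv <- function(mat, path, ...) {
  df <- tibble::as_tibble(mat, rownames = "gene")
  write_tsv_provenance(df, path, ...)
}

#' Write a tibble as TSV with a provenance header
#'
#' Prepends comment lines recording the package version, the seed and a
#' hash of the parameter list, so every output records how it was made.
#'
#' @param df Data frame.
#' @param path Output path.
#' @param seed Seed recorded in the header (optional).
#' @param params Parameter list recorded as a hash (optional).
#' @export
write_tsv_provenance <- function(df, path, seed = NULL, params = NULL) {
  header <- provenance_lines(seed, params)
  writeLines(header, path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

provenance_lines <- function(seed = NULL, params = NULL) {
  c(
    paste0("# yaptaz ", as.character(utils::packageVersion("yaptaz"))),
    if (!is.null(seed)) paste0("# seed: ", seed),
    if (!is.null(params)) paste0("# config_hash: ", rlang::hash(params))
  )
}

#' Write a two-channel field as a 16-bit TIFF
#'
#' Channel 1 = DAPI, channel 2 = stain, stored as two pages scaled by
#' `max_intensity` into the 16-bit range.
#'
#' @param field List with `dapi` and `stain` matrices (e.g. from
#'   [simulate_if_field()]).
#' @param path Output TIFF path.
#' @param max_intensity Intensity mapped to the 16-bit maximum.
#' @export
write_field_tiff <- function(field, path, max_intensity = 1024) {
  pages <- list(
    pmin(field$dapi / max_intensity, 1),
    pmin(field$stain / max_intensity, 1)
  )
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a two-channel field TIFF
#'
#' @param path TIFF path written by [write_field_tiff()].
#' @param max_intensity Scale used at write time.
#' @return List with `dapi` and `stain` matrices.
#' @export
read_field_tiff <- function(path, max_intensity = 1024) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) < 2) rlang::abort("expected a two-page (two-channel) TIFF")
  list(
    dapi = pages[[1]] * max_intensity,
    stain = pages[[2]] * max_intensity
  )
}

#' Write a binary mask as an 8-bit TIFF (0/255)
#'
#' @param mask Logical matrix.
#' @param path Output TIFF path.
#' @export
write_mask_tiff <- function(mask, path) {
  tiff::writeTIFF(mask * 1, path, bits.per.sample = 8L)
  invisible(path)
}
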