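#' Read and write the package's plain-CSV interchange formats
#'
#' Genotype panels are CSV with rows = accessions, first column `accession`,
#' one column per marker, empty cells = missing. Marker maps are
#' `marker, chrom, pos_bp` (1-based bp). Phenotype tables are
#' `accession, subspecies, SSvR, SStR_NL, SStR_CW, RSStR_CW`. LnP(D) tables
#' are `K, rep, lnpd`. Percent values are serialised with 4 decimal places so
#' repeated runs are byte-stable.
#'
#' @param path File path.
#' @return A tibble of the corresponding shape.
#' @name coldmap-io
NULL

#' @rdname coldmap-io
#' @export
read_genotypes <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    accession = readr::col_character(),
    .default = readr::col_character()))
}

#' @rdname coldmap-io
#' @export
read_marker_map <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    marker = readr::col_character(),
    chrom = readr::col_integer(),
    pos_bp = readr::col_double()))
}

#' @rdname coldmap-io
#' @export
read_phenotypes <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    accession = readr::col_character(),
    subspecies = readr::col_character(),
    .default = readr::col_double()))
}

#' @rdname coldmap-io
#' @export
read_lnpd <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    K = readr::col_integer(),
    rep = readr::col_character(),
    lnpd = readr::col_double()))
}

#' @rdname coldmap-io
#' @param x Tibble to write.
#' @export
write_stage_csv <- function(x, path) {
  num <- vapply(x, is.numeric, logical(1))
  x[num] <- lapply(x[num], function(v) round(v, 4))
  x[vapply(x, is.list, logical(1))] <- NULL
  readr::write_csv(x, path, na = "")
  invisible(path)
}
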