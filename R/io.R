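# Plain-text writers/readers for the standard exchange formats: spectra as
# wide CSV (sample id, then one column per wavelength), counts as TSV
# (genes x samples), occurrences as CSV, trees as Newick via ape.

#' Write spectra to a wide CSV (one column per wavelength)
#' @param spectra long spectra tibble on a common grid.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(spectra, path) {
  m <- spectra_matrix(spectra)
  df <- data.frame(sample = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read spectra from a wide CSV into the long form
#' @param path CSV with column `sample` then one column per wavelength.
#' @param meta optional sample metadata; parsed from sample ids otherwise.
#' @return long spectra tibble.
#' @export
read_spectra_csv <- function(path, meta = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (is.null(meta)) meta <- parse_sample_labels(df$sample)
  tidyr::pivot_longer(df, -"sample", names_to = "wavelength",
                      values_to = "reflectance") |>
    dplyr::mutate(wavelength = as.numeric(.data$wavelength)) |>
    dplyr::left_join(meta, by = "sample") |>
    dplyr::select("sample", "species", "morph", "wavelength", "reflectance")
}

#' Write a counts table to TSV (genes x samples)
#' @param counts counts tibble (`gene` + samples).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a counts TSV (genes x samples)
#' @param path TSV with a `gene` column and one column per sample.
#' @return counts tibble.
#' @export
read_counts_tsv <- function(path) {
  tibble::as_tibble(utils::read.delim(path, check.names = FALSE))
}

#' Write an occurrence table to CSV
#' @param occ occurrence tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_occurrences_csv <- function(occ, path) {
  utils::write.csv(occ, path, row.names = FALSE)
  invisible(path)
}

#' Read an occurrence CSV
#' @param path CSV with `species`, `morph` (or `color`), coordinates and
#'   `bio*` columns.
#' @return occurrence tibble.
#' @export
read_occurrences_csv <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path))
  if (!"morph" %in% names(df) && "color" %in% names(df)) {
    names(df)[names(df) == "color"] <- "morph"
  }
  df
}

#' Write a tree (with supports) to Newick
#' @param tree an `ape::phylo`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
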