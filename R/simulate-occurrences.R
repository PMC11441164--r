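#' Simulate an occurrence table with bioclimatic variables
#'
#' Draws per-record climate variables independently from normal
#' distributions whose means can differ by (species, morph) cell, emulating
#' morph-specific climate niche shifts. Coordinates are drawn uniformly over
#' a rectangle so that pixel-level deduplication can be exercised.
#'
#' @param n_per_cell records per (species, morph) cell, either a single
#'   count (>= 3) or a named vector like `c(A_blue = 30, ...)`.
#' @param n_variables number of climate variables (columns `bio01`...).
#' @param means optional tibble (`species`, `morph`, `variable`, `mean`)
#'   overriding the default mean of 0 for specific cells/variables.
#' @param sds per-variable standard deviations (recycled; all > 0).
#' @param lat_range,lon_range sampling rectangle for coordinates.
#' @param seed integer seed.
#'
#' @return list with `occurrences` (tibble: `record`, `species`, `morph`,
#'   `lat`, `lon`, `bio01..`) and `truth` (tibble per variable and morph:
#'   `variable`, `morph`, `delta` = mean(species A) - mean(species B),
#'   `divergent` = `delta != 0`).
#' @export
simulate_occurrences <- function(n_per_cell = 30,
                                 n_variables = 19,
                                 means = NULL,
                                 sds = 1,
                                 lat_range = c(35, 45),
                                 lon_range = c(-10, 5),
                                 seed = NULL) {
  sds <- rep_len(sds, n_variables)
  if (any(sds <= 0)) abort("`sds` must be > 0.")
  cells <- tidyr::expand_grid(species = c("A", "B"), morph = c("blue", "orange"))
  if (length(n_per_cell) == 1) {
    cells$n <- n_per_cell
  } else {
    key <- paste(cells$species, cells$morph, sep = "_")
    if (!all(key %in% names(n_per_cell))) {
      abort("named `n_per_cell` must cover all four species_morph cells.")
    }
    cells$n <- as.numeric(n_per_cell[key])
  }
  if (any(cells$n < 3)) abort("each cell needs at least 3 records.")

  vars <- sprintf("bio%02d", seq_len(n_variables))
  mean_mat <- matrix(0, nrow = 4, ncol = n_variables,
                     dimnames = list(paste(cells$species, cells$morph, sep = "_"),
                                     vars))
  if (!is.null(means)) {
    for (i in seq_len(nrow(means))) {
      mean_mat[paste(means$species[i], means$morph[i], sep = "_"),
               means$variable[i]] <- means$mean[i]
    }
  }

  with_seed(seed, {
    rows <- purrr::pmap(cells, function(species, morph, n) {
      cell <- paste(species, morph, sep = "_")
      clim <- vapply(seq_len(n_variables), function(v) {
        rnorm(n, mean = mean_mat[cell, v], sd = sds[v])
      }, numeric(n))
      colnames(clim) <- vars
      dplyr::bind_cols(
        tibble::tibble(species = species, morph = morph,
                       lat = runif(n, lat_range[1], lat_range[2]),
                       lon = runif(n, lon_range[1], lon_range[2])),
        tibble::as_tibble(clim)
      )
    })
    occ <- dplyr::bind_rows(rows)
    occ <- dplyr::mutate(occ, record = sprintf("occ%04d", dplyr::row_number()),
                         .before = 1)

    truth <- tidyr::expand_grid(variable = vars, morph = c("blue", "orange")) |>
      dplyr::mutate(
        delta = purrr::map2_dbl(.data$variable, .data$morph, function(v, m) {
          mean_mat[paste("A", m, sep = "_"), v] -
            mean_mat[paste("B", m, sep = "_"), v]
        }),
        divergent = .data$delta != 0
      )
    list(occurrences = occ, truth = truth)
  })
}
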