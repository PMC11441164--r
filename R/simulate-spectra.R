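#' Simulate petal reflectance spectra for a two-species, two-morph design
#'
#' Generates one reflectance curve per sample as a shared smooth base
#' template plus a morph-specific template scaled by `color_effect`, a
#' species-specific template scaled by `species_effect`, and iid Gaussian
#' noise. The orange morph template carries two Gaussian bumps below 450 nm
#' so that, for positive `color_effect`, orange curves show the double UV
#' reflectance peak absent from blue curves.
#'
#' @param n_per_group number of samples per (species, morph) cell (>= 2).
#' @param wavelengths strictly increasing wavelength grid in nm.
#' @param color_effect amplitude (reflectance units) of the morph templates.
#' @param species_effect amplitude of the species template (added for
#'   species A, subtracted for species B).
#' @param noise_sd per-wavelength residual standard deviation.
#' @param seed integer seed; the global RNG state is left untouched.
#'
#' @return A long tibble with columns `sample`, `species`, `morph`,
#'   `wavelength`, `reflectance` (percent units, clipped at 0).
#' @export
#'
#' @examples
#' sp <- simulate_spectra(n_per_group = 3, noise_sd = 0, seed = 1)
#' dplyr::count(sp, species, morph)
simulate_spectra <- function(n_per_group = 20,
                             wavelengths = 300:700,
                             color_effect = 30,
                             species_effect = 5,
                             noise_sd = 2,
                             seed = NULL) {
  if (length(wavelengths) < 3 || any(diff(wavelengths) <= 0)) {
    abort("`wavelengths` must be a strictly increasing grid.")
  }
  if (color_effect < 0 || species_effect < 0) {
    abort("effect amplitudes must be >= 0.")
  }
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (n_per_group < 2) abort("`n_per_group` must be >= 2.")

  wl <- as.numeric(wavelengths)
  base <- 15 + 25 * stats::plogis((wl - 550) / 40)
  templates <- list(
    # two local maxima below 450 nm plus a long-wavelength shoulder
    orange = gaussian_bump(wl, 350, 15) + gaussian_bump(wl, 420, 12) +
      0.8 * gaussian_bump(wl, 620, 45),
    # single broad visible bump, no UV maxima
    blue = gaussian_bump(wl, 460, 35) + 0.4 * gaussian_bump(wl, 680, 50)
  )
  species_template <- gaussian_bump(wl, 550, 80)

  design <- tidyr::expand_grid(species = c("A", "B"),
                               morph = c("blue", "orange"),
                               rep = seq_len(n_per_group))

  with_seed(seed, {
    curves <- purrr::pmap(design, function(species, morph, rep) {
      mu <- base + color_effect * templates[[morph]] +
        species_effect * species_template * (if (species == "A") 1 else -1)
      pmax(mu + rnorm(length(wl), sd = noise_sd), 0)
    })
    design |>
      dplyr::mutate(sample = sprintf("%s_%s_%02d", .data$species,
                                     .data$morph, .data$rep),
                    reflectance = curves) |>
      dplyr::select("sample", "species", "morph", "reflectance") |>
      tidyr::unnest_longer("reflectance") |>
      dplyr::mutate(wavelength = rep(wl, times = nrow(design)),
                    .before = "reflectance")
  })
}
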