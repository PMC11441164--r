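#' Resample reflectance curves onto a common wavelength grid
#'
#' Linearly interpolates each sample's curve onto `wavelengths` and clips
#' negative interpolated values at 0. Input grids need not be sorted; each
#' curve must cover the full target range.
#'
#' @param spectra long tibble with columns `sample`, `wavelength`,
#'   `reflectance` (label columns such as `species`/`morph` are carried
#'   through).
#' @param wavelengths strictly increasing target grid (default 300-700 nm
#'   at 1 nm, the instrument range).
#' @return a long tibble on the common grid.
#' @export
resample_spectra <- function(spectra, wavelengths = 300:700) {
  if (any(diff(wavelengths) <= 0)) abort("target grid must be strictly increasing.")
  labels <- dplyr::distinct(
    spectra, dplyr::across(dplyr::any_of(c("sample", "species", "morph"))))
  spectra |>
    dplyr::group_by(.data$sample) |>
    dplyr::group_modify(function(df, key) {
      o <- order(df$wavelength)
      wl <- df$wavelength[o]
      if (min(wl) > min(wavelengths) || max(wl) < max(wavelengths)) {
        abort(sprintf("curve for sample '%s' does not cover the target range.",
                      key$sample))
      }
      y <- stats::approx(wl, df$reflectance[o], xout = wavelengths)$y
      tibble::tibble(wavelength = as.numeric(wavelengths),
                     reflectance = pmax(y, 0))
    }) |>
    dplyr::ungroup() |>
    dplyr::left_join(labels, by = "sample") |>
    dplyr::select(dplyr::any_of(c("sample", "species", "morph")),
                  "wavelength", "reflectance")
}

# sample x wavelength matrix from the long form
spectra_matrix <- function(spectra) {
  wide <- tidyr::pivot_wider(
    dplyr::select(spectra, "sample", "wavelength", "reflectance"),
    names_from = "wavelength", values_from = "reflectance")
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$sample
  if (anyNA(m)) abort("spectra do not share a common wavelength grid; resample first.")
  m
}

#' Euclidean distance matrix between reflectance curves
#'
#' `d_ij = sqrt(sum_wl (R_i - R_j)^2)`, the Euclidean distance based on the
#' difference in reflectance at each wavelength.
#'
#' @param spectra long spectra tibble on a common grid.
#' @return a symmetric matrix with zero diagonal, sample ids as dimnames.
#' @export
spectra_distances <- function(spectra) {
  m <- spectra_matrix(spectra)
  as.matrix(stats::dist(m, method = "euclidean"))
}

#' Distance-based permutational MANOVA (one factor)
#'
#' Partitions the total sum of squared distances into between- and
#' within-group components and assesses the pseudo-F statistic by free
#' permutation of the group labels. When the number of distinct label
#' arrangements is at most `exact_limit` the null distribution is
#' enumerated exactly and `p = #[F >= F_obs] / N_total` (the identity
#' arrangement counts); otherwise `p = (#[F_perm >= F_obs] + 1) /
#' (n_permutations + 1)`.
#'
#' @param d symmetric distance matrix (or `dist`).
#' @param groups group labels, length `nrow(d)`; at least 2 groups with at
#'   least 2 members each.
#' @param n_permutations Monte Carlo permutations (default 9999).
#' @param seed integer seed for the permutations.
#' @param exact_limit enumerate exactly when the count of distinct
#'   arrangements is at most this (default 10000).
#' @return an object of class `permanova` with fields `pseudo_F`, `R2`,
#'   `p_value`, `n_permutations`, `method` (`"exact"`/`"monte_carlo"`),
#'   `SS_between`, `SS_within`, `SS_total`, `df_between`, `df_within`,
#'   `degenerate`.
#' @export
#'
#' @examples
#' d <- spectra_distances(simulate_spectra(n_per_group = 3, seed = 1))
#' labs <- parse_sample_labels(rownames(d))
#' permanova(d, labs$morph, n_permutations = 199, seed = 1)
permanova <- function(d, groups, n_permutations = 9999, seed = NULL,
                      exact_limit = 10000) {
  d <- as.matrix(d)
  groups <- as.character(groups)
  n <- nrow(d)
  if (length(groups) != n) abort("`groups` must match the distance matrix size.")
  sizes <- table(groups)
  if (length(sizes) < 2) abort("need at least 2 groups.")
  if (any(sizes < 2)) abort("every group needs at least 2 members (singleton group).")
  a <- length(sizes)

  d2 <- d^2
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within_of <- function(g) {
    z <- 0
    for (lev in unique(g)) {
      idx <- which(g == lev)
      z <- z + sum(d2[idx, idx]) / (2 * length(idx))
    }
    z
  }
  f_of <- function(ssw) {
    ((ss_total - ssw) / (a - 1)) / (ssw / (n - a))
  }
  ssw_obs <- ss_within_of(groups)
  ssb_obs <- ss_total - ssw_obs

  if (ss_total <= .Machine$double.eps) {
    return(new_permanova(NA_real_, NA_real_, NA_real_, 0L, "degenerate",
                         ssb_obs, ssw_obs, ss_total, a - 1L, n - a,
                         degenerate = TRUE))
  }
  f_obs <- f_of(ssw_obs)

  n_distinct <- exp(lgamma(n + 1) - sum(lgamma(sizes + 1)))
  tol <- 1e-12 * max(1, abs(f_obs))
  if (n_distinct <= exact_limit) {
    assignments <- enumerate_assignments(groups)
    f_all <- vapply(assignments, function(g) f_of(ss_within_of(g)), numeric(1))
    p <- mean(f_all >= f_obs - tol)
    method <- "exact"
    nperm <- length(f_all)
  } else {
    p <- with_seed(seed, {
      hits <- 0L
      for (b in seq_len(n_permutations)) {
        g <- groups[sample.int(n)]
        if (f_of(ss_within_of(g)) >= f_obs - tol) hits <- hits + 1L
      }
      (hits + 1) / (n_permutations + 1)
    })
    method <- "monte_carlo"
    nperm <- n_permutations
  }
  new_permanova(f_obs, ssb_obs / ss_total, p, nperm, method,
                ssb_obs, ssw_obs, ss_total, a - 1L, n - a, degenerate = FALSE)
}

new_permanova <- function(f, r2, p, nperm, method, ssb, ssw, sst,
                          dfb, dfw, degenerate) {
  structure(list(pseudo_F = f, R2 = r2, p_value = p, n_permutations = nperm,
                 method = method, SS_between = ssb, SS_within = ssw,
                 SS_total = sst, df_between = dfb, df_within = dfw,
                 degenerate = degenerate),
            class = "permanova")
}

# All distinct assignments of the multiset of labels to positions.
enumerate_assignments <- function(groups) {
  n <- length(groups)
  levs <- sort(unique(groups))
  sizes <- as.integer(table(factor(groups, levels = levs)))
  out <- list()
  recurse <- function(avail, assignment, level) {
    if (level == length(levs)) {
      assignment[avail] <- levs[level]
      out[[length(out) + 1]] <<- assignment
      return(invisible())
    }
    picks <- combn(avail, sizes[level], simplify = FALSE)
    for (pk in picks) {
      a2 <- assignment
      a2[pk] <- levs[level]
      recurse(setdiff(avail, pk), a2, level + 1)
    }
  }
  recurse(seq_len(n), character(n), 1)
  out
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf(
    "Permutational MANOVA (%s, %d permutations)\n  pseudo-F = %.4g, R2 = %.4g, p = %.4g\n  SS between/within/total = %.4g / %.4g / %.4g\n",
    x$method, x$n_permutations, x$pseudo_F, x$R2, x$p_value,
    x$SS_between, x$SS_within, x$SS_total))
  if (x$degenerate) cat("  [degenerate: all distances zero]\n")
  invisible(x)
}

#' @export
tidy.permanova <- function(x, ...) {
  tibble::tibble(
    term = c("between", "within", "total"),
    df = c(x$df_between, x$df_within, x$df_between + x$df_within),
    sum_of_squares = c(x$SS_between, x$SS_within, x$SS_total),
    pseudo_F = c(x$pseudo_F, NA, NA),
    R2 = c(x$R2, 1 - x$R2, 1),
    p_value = c(x$p_value, NA, NA)
  )
}

#' @export
glance.permanova <- function(x, ...) {
  tibble::tibble(pseudo_F = x$pseudo_F, R2 = x$R2, p_value = x$p_value,
                 n_permutations = x$n_permutations, method = x$method,
                 degenerate = x$degenerate)
}

#' Compare spectral variance partitioning by morph versus by species
#'
#' Runs the permutational MANOVA twice on the same distance matrix -- once
#' grouping samples by color morph, once by species -- and reports both R2
#' values, their ratio, and for each factor the ratio of mean between-group
#' to mean within-group distance.
#'
#' @param spectra long spectra tibble with `species` and `morph` labels,
#'   both factors fully crossed.
#' @inheritParams permanova
#' @return a tibble with one row per factor (`morph`, `species`):
#'   `pseudo_F`, `R2`, `p_value`, `mean_between`, `mean_within`,
#'   `between_within_ratio`, plus attribute `R2_ratio` (morph over species).
#' @export
compare_partitions <- function(spectra, n_permutations = 9999, seed = NULL) {
  labels <- dplyr::distinct(spectra, .data$sample, .data$species, .data$morph)
  if (dplyr::n_distinct(labels$species) < 2 || dplyr::n_distinct(labels$morph) < 2 ||
      nrow(dplyr::distinct(labels, .data$species, .data$morph)) < 4) {
    abort("need both species and both morphs in a full species x morph design.")
  }
  d <- spectra_distances(spectra)
  labels <- labels[match(rownames(d), labels$sample), ]
  res <- purrr::map(list(morph = labels$morph, species = labels$species),
                    function(g) permanova(d, g, n_permutations, seed = seed))
  ratios <- purrr::map(list(morph = labels$morph, species = labels$species),
                       function(g) {
    same <- outer(g, g, "==")
    ut <- upper.tri(d)
    c(between = mean(d[ut & !same]), within = mean(d[ut & same]))
  })
  out <- tibble::tibble(
    factor = c("morph", "species"),
    pseudo_F = unname(purrr::map_dbl(res, "pseudo_F")),
    R2 = unname(purrr::map_dbl(res, "R2")),
    p_value = unname(purrr::map_dbl(res, "p_value")),
    mean_between = unname(purrr::map_dbl(ratios, "between")),
    mean_within = unname(purrr::map_dbl(ratios, "within")),
    between_within_ratio = .data$mean_between / .data$mean_within
  )
  attr(out, "R2_ratio") <- out$R2[out$factor == "morph"] /
    out$R2[out$factor == "species"]
  attr(out, "permanova") <- res
  out
}

#' Locate inflection points of a group mean reflectance curve
#'
#' Computes the mean curve of a morph, smooths it with a centered moving
#' average, and returns the wavelengths at which the discrete second
#' difference changes sign, ordered by decreasing magnitude of the first
#' derivative (the "primary" inflection points first).
#'
#' @param spectra long spectra tibble.
#' @param morph morph label whose mean curve is analysed.
#' @param window moving-average window in grid steps (odd, >= 3; default 11,
#'   i.e. 11 nm on a 1-nm grid).
#' @return tibble with columns `wavelength` and `slope`, strongest first;
#'   zero rows for a flat or linear curve.
#' @export
inflection_points <- function(spectra, morph, window = 11) {
  if (window < 3 || window %% 2 == 0) abort("`window` must be odd and >= 3.")
  grp <- spectra[spectra$morph == morph, ]
  if (nrow(grp) == 0) abort(sprintf("morph '%s' not present.", morph))
  curve <- grp |>
    dplyr::group_by(.data$wavelength) |>
    dplyr::summarise(reflectance = mean(.data$reflectance), .groups = "drop") |>
    dplyr::arrange(.data$wavelength)
  y <- stats::filter(curve$reflectance, rep(1 / window, window), sides = 2)
  keep <- !is.na(y)
  y <- as.numeric(y[keep])
  wl <- curve$wavelength[keep]
  if (length(y) < 5) return(tibble::tibble(wavelength = numeric(), slope = numeric()))
  d2 <- diff(y, differences = 2)
  # sign changes of the second difference; exact zeros (symmetric curves)
  # are skipped so a +0- pattern still counts as one crossing
  s <- sign(round(d2, 12))
  nz <- which(s != 0)
  if (length(nz) < 2) {
    return(tibble::tibble(wavelength = numeric(), slope = numeric()))
  }
  flips <- which(s[nz[-length(nz)]] * s[nz[-1]] < 0)
  if (length(flips) == 0) {
    return(tibble::tibble(wavelength = numeric(), slope = numeric()))
  }
  a <- nz[flips] + 1L       # curvature point indices flanking the crossing
  b <- nz[flips + 1L] + 1L
  mid <- (wl[a] + wl[b]) / 2
  slope <- (y[b] - y[a]) / (wl[b] - wl[a])
  ord <- order(abs(slope), decreasing = TRUE)
  tibble::tibble(wavelength = mid[ord], slope = slope[ord])
}
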