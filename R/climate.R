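#' Filter and deduplicate occurrence records
#'
#' Drops records with any missing climate value, then removes duplicate
#' occurrences of the same species and morph within one raster pixel
#' (keeping the first by input order). Pixels are indexed on a regular
#' lat/lon grid at `resolution` degrees (default 30 arc-seconds, the
#' highest-resolution BIOCLIM grid).
#'
#' @param occ occurrence tibble with `species`, `morph`, `lat`, `lon` and
#'   climate columns `bio*`.
#' @param resolution pixel size in degrees (default `30 / 3600`).
#' @param dedupe deduplicate within pixels (needs coordinates).
#' @return the filtered tibble.
#' @export
filter_occurrences <- function(occ, resolution = 30 / 3600, dedupe = TRUE) {
  clim_cols <- grep("^bio", names(occ), value = TRUE)
  if (length(clim_cols) == 0) abort("no climate columns (bio*) found.")
  out <- occ[complete.cases(occ[clim_cols]), , drop = FALSE]
  if (dedupe) {
    if (!all(c("lat", "lon") %in% names(out)) || anyNA(out$lat) || anyNA(out$lon)) {
      abort("deduplication needs complete `lat`/`lon` coordinates.")
    }
    px <- paste(out$species, out$morph,
                floor(out$lon / resolution), floor(out$lat / resolution))
    out <- out[!duplicated(px), , drop = FALSE]
  }
  out
}

#' Univariate climate contrasts among the four species x morph cells
#'
#' For each climate variable, the four pairwise contrasts of interest --
#' the within-species color contrasts and the between-species same-color
#' contrasts -- tested two-sided (Mann-Whitney by default, Welch t as an
#' option), with Bonferroni correction across the variables within each
#' contrast family.
#'
#' @param occ filtered occurrence tibble.
#' @param method `"wilcox"` (default) or `"welch"`.
#' @param alpha family significance level (default 0.05).
#' @return tibble `variable`, `contrast`, `statistic`, `p_value`, `p_adj`,
#'   `significant`; empty cells yield a skipped, flagged row.
#' @export
univariate_morph_tests <- function(occ, method = c("wilcox", "welch"),
                                   alpha = 0.05) {
  method <- match.arg(method)
  clim_cols <- grep("^bio", names(occ), value = TRUE)
  contrasts <- list(
    color_within_A = list(occ$species == "A" & occ$morph == "blue",
                          occ$species == "A" & occ$morph == "orange"),
    color_within_B = list(occ$species == "B" & occ$morph == "blue",
                          occ$species == "B" & occ$morph == "orange"),
    species_within_blue = list(occ$species == "A" & occ$morph == "blue",
                               occ$species == "B" & occ$morph == "blue"),
    species_within_orange = list(occ$species == "A" & occ$morph == "orange",
                                 occ$species == "B" & occ$morph == "orange")
  )
  out <- purrr::imap(contrasts, function(sel, cname) {
    if (sum(sel[[1]]) < 3 || sum(sel[[2]]) < 3) {
      warn(sprintf("contrast %s skipped: empty or tiny cell.", cname))
      return(tibble::tibble(variable = clim_cols, contrast = cname,
                            statistic = NA_real_, p_value = NA_real_))
    }
    purrr::map(clim_cols, function(v) {
      a <- occ[[v]][sel[[1]]]; b <- occ[[v]][sel[[2]]]
      if (method == "wilcox") {
        ht <- suppressWarnings(wilcox.test(a, b))
      } else {
        ht <- stats::t.test(a, b)
      }
      tibble::tibble(variable = v, contrast = cname,
                     statistic = unname(ht$statistic), p_value = ht$p.value)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  out |>
    dplyr::group_by(.data$contrast) |>
    dplyr::mutate(p_adj = pmin(1, .data$p_value * dplyr::n()),
                  significant = !is.na(.data$p_adj) & .data$p_adj < alpha) |>
    dplyr::ungroup()
}

#' Classify morph climate differences as parallel or opposing
#'
#' For variables whose within-species color contrast is significant in both
#' species, compares the sign of (mean orange - mean blue) per species:
#' same sign is `parallel`, opposite is `opposing`, an exact zero is
#' `tied`.
#'
#' @param occ filtered occurrence tibble.
#' @param variables climate variables to classify (e.g. those significant
#'   in both species from [univariate_morph_tests()]).
#' @return tibble `variable`, `delta_A`, `delta_B`, `direction`.
#' @export
classify_direction <- function(occ, variables) {
  purrr::map(variables, function(v) {
    d <- vapply(c("A", "B"), function(sp) {
      mean(occ[[v]][occ$species == sp & occ$morph == "orange"]) -
        mean(occ[[v]][occ$species == sp & occ$morph == "blue"])
    }, numeric(1))
    dir <- if (any(d == 0)) "tied" else if (prod(sign(d)) > 0) "parallel" else "opposing"
    tibble::tibble(variable = v, delta_A = d[["A"]], delta_B = d[["B"]],
                   direction = dir)
  }) |> dplyr::bind_rows()
}

#' AIC-best logistic model of morph from climate variables
#'
#' Fits color ~ subset logistic regressions on z-scored predictors for one
#' species, exhaustively over all subsets up to `k_max` variables (or
#' bidirectional stepwise when the exhaustive search would exceed
#' `max_models`), and ranks the winning model's predictors by absolute
#' standardized coefficient. Complete separation is detected and reported
#' rather than returning a diverged fit.
#'
#' @param occ filtered occurrence tibble.
#' @param species species to model.
#' @param k_max maximum number of predictors (default 5).
#' @param max_models exhaustive-search budget (default 20000 fits).
#' @return list with `model_terms` (ranked by |coefficient|),
#'   `coefficients` (tibble `term`, `estimate`), `aic`, `separation`
#'   (flag), `n`, `method` (`"exhaustive"`/`"stepwise"`).
#' @export
select_logistic_model <- function(occ, species, k_max = 5, max_models = 20000) {
  sub <- occ[occ$species == species, , drop = FALSE]
  clim_cols <- grep("^bio", names(sub), value = TRUE)
  if (dplyr::n_distinct(sub$morph) != 2) {
    abort(sprintf("species %s does not have both colors.", species))
  }
  y <- as.integer(sub$morph == "orange")
  x <- scale(as.matrix(sub[clim_cols]))
  if (any(!is.finite(x))) abort("non-finite predictor after standardization.")
  n <- length(y)

  fit_subset <- function(cols) {
    xm <- cbind(`(Intercept)` = 1, x[, cols, drop = FALSE])
    fit <- suppressWarnings(glm.fit(xm, y, family = binomial()))
    aic <- fit$deviance + 2 * ncol(xm)
    mu <- fit$fitted.values
    separated <- all(mu > 1 - 1e-6 | mu < 1e-6) ||
      any(abs(fit$coefficients[-1]) > 15)
    list(aic = aic, coef = fit$coefficients, separated = separated)
  }

  n_models <- sum(choose(length(clim_cols), 0:k_max))
  if (n_models <= max_models) {
    best <- NULL
    for (k in 0:k_max) {
      for (cols in combn(clim_cols, k, simplify = FALSE)) {
        f <- fit_subset(cols)
        if (is.null(best) || f$aic < best$aic) {
          best <- f
          best$terms <- cols
        }
      }
    }
    method <- "exhaustive"
  } else {
    dat <- data.frame(y = y, x)
    null_fit <- stats::glm(y ~ 1, data = dat, family = binomial())
    scope <- stats::as.formula(paste("~", paste(clim_cols, collapse = "+")))
    step_fit <- suppressWarnings(
      stats::step(null_fit, scope = list(lower = ~1, upper = scope),
                  direction = "both", trace = 0,
                  steps = 2 * k_max))
    terms <- setdiff(names(stats::coef(step_fit)), "(Intercept)")
    terms <- head(terms, k_max)
    best <- fit_subset(terms)
    best$terms <- terms
    method <- "stepwise"
  }

  beta <- best$coef[setdiff(names(best$coef), "(Intercept)")]
  ranked <- names(sort(abs(beta), decreasing = TRUE))
  list(
    model_terms = ranked,
    coefficients = tibble::tibble(term = names(best$coef),
                                  estimate = unname(best$coef)),
    aic = best$aic,
    separation = best$separated,
    n = n,
    method = method
  )
}

#' Monte Carlo color-randomization test of climate niche divergence
#'
#' For each climate variable and each color `c`, the observed divergence is
#' `D_c = |mean(v | species A, c) - mean(v | species B, c)|`. The null
#' distribution randomizes color labels within each species independently
#' (preserving per-species color counts) and recomputes `D_c`. When the
#' number of distinct within-species label arrangements is at most
#' `exact_limit`, the null is enumerated exactly and
#' `p = #[D_null >= D_obs] / N_total`; otherwise
#' `p = (#[D_perm >= D_obs] + 1) / (n_permutations + 1)`.
#'
#' @param occ filtered occurrence tibble with all four cells populated.
#' @param n_permutations Monte Carlo permutations (default 9999; refused
#'   below 99).
#' @param seed integer seed.
#' @param alpha per-variable significance level (default 0.05).
#' @param standardize divide the divergence by the pooled SD (optional
#'   variant; default FALSE, plain difference of means).
#' @param bonferroni apply Bonferroni across variables to the significance
#'   flags (default FALSE, matching per-variable reporting).
#' @param exact_limit enumerate exactly when the arrangement count is at
#'   most this (default 10000).
#' @return a tibble of class `divergence_result`: `variable`, `morph`,
#'   `observed`, `p_value`, `significant`, `n_permutations`, `method`;
#'   attribute `summary` counts significant variables per morph.
#' @export
mc_divergence <- function(occ, n_permutations = 9999, seed = NULL,
                          alpha = 0.05, standardize = FALSE,
                          bonferroni = FALSE, exact_limit = 10000) {
  if (n_permutations < 99) abort("`n_permutations` must be at least 99.")
  clim_cols <- grep("^bio", names(occ), value = TRUE)
  cells <- table(occ$species, occ$morph)
  if (!all(dim(cells) == c(2, 2)) || any(cells == 0)) {
    abort("all four species x morph cells must be populated.")
  }
  sp_idx <- list(A = which(occ$species == "A"), B = which(occ$species == "B"))
  k_orange <- vapply(sp_idx, function(i) sum(occ$morph[i] == "orange"), 0)

  vals <- as.matrix(occ[clim_cols])
  pooled_sd <- if (standardize) {
    vapply(seq_along(clim_cols), function(v) {
      sqrt(mean(tapply(vals[, v], paste(occ$species, occ$morph), var)))
    }, numeric(1))
  } else {
    rep(1, length(clim_cols))
  }

  # divergence per variable for one assignment of orange members per species
  d_of <- function(orangeA, orangeB) {
    dA_o <- colMeans(vals[orangeA, , drop = FALSE])
    dA_b <- colMeans(vals[setdiff(sp_idx$A, orangeA), , drop = FALSE])
    dB_o <- colMeans(vals[orangeB, , drop = FALSE])
    dB_b <- colMeans(vals[setdiff(sp_idx$B, orangeB), , drop = FALSE])
    rbind(blue = abs(dA_b - dB_b) / pooled_sd,
          orange = abs(dA_o - dB_o) / pooled_sd)
  }
  obs_orangeA <- sp_idx$A[occ$morph[sp_idx$A] == "orange"]
  obs_orangeB <- sp_idx$B[occ$morph[sp_idx$B] == "orange"]
  d_obs <- d_of(obs_orangeA, obs_orangeB)

  n_arr <- choose(length(sp_idx$A), k_orange["A"]) *
    choose(length(sp_idx$B), k_orange["B"])
  tol <- 1e-12
  if (n_arr <= exact_limit) {
    combsA <- combn(sp_idx$A, k_orange["A"], simplify = FALSE)
    combsB <- combn(sp_idx$B, k_orange["B"], simplify = FALSE)
    ge <- d_obs * 0
    for (ca in combsA) {
      for (cb in combsB) {
        ge <- ge + (d_of(ca, cb) >= d_obs - tol)
      }
    }
    p <- ge / n_arr
    method <- "exact"
    nperm <- n_arr
  } else {
    p <- with_seed(seed, {
      ge <- d_obs * 0
      for (b in seq_len(n_permutations)) {
        ca <- sample(sp_idx$A, k_orange["A"])
        cb <- sample(sp_idx$B, k_orange["B"])
        ge <- ge + (d_of(ca, cb) >= d_obs - tol)
      }
      (ge + 1) / (n_permutations + 1)
    })
    method <- "monte_carlo"
    nperm <- n_permutations
  }

  thr <- if (bonferroni) alpha / length(clim_cols) else alpha
  out <- purrr::map(c("blue", "orange"), function(mo) {
    tibble::tibble(variable = clim_cols, morph = mo,
                   observed = d_obs[mo, ], p_value = p[mo, ],
                   significant = p[mo, ] <= thr,
                   n_permutations = nperm, method = method)
  }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$variable, .data$morph)
  class(out) <- c("divergence_result", class(out))
  attr(out, "summary") <- out |>
    dplyr::group_by(.data$morph) |>
    dplyr::summarise(n_significant = sum(.data$significant), .groups = "drop")
  attr(out, "alpha") <- alpha
  out
}
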