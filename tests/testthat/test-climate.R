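test_that("occurrence filtering drops incomplete records and pixel duplicates", {
  occ <- tibble::tibble(
    record = paste0("r", 1:5),
    species = c("A", "A", "A", "A", "B"),
    morph = c("blue", "blue", "orange", "blue", "blue"),
    lat = c(40.0001, 40.0002, 40.0001, 41, 40.0001),
    lon = c(-5.0001, -5.0002, -5.0001, -5, -5.0001),
    bio01 = c(1, 2, 3, NA, 5), bio02 = 1:5
  )
  out <- filter_occurrences(occ)
  # r4 dropped (missing value); r2 deduplicated against r1 (same pixel,
  # species, morph); r3 kept (other color); r5 kept (other species)
  expect_setequal(out$record, c("r1", "r3", "r5"))

  nocoord <- dplyr::select(occ, -"lat")
  expect_error(filter_occurrences(nocoord), "lat")
  expect_identical(nrow(filter_occurrences(occ, dedupe = FALSE)), 4L)
})

test_that("univariate contrasts find planted shifts and respect symmetry", {
  means <- tibble::tibble(species = "B", morph = "orange",
                          variable = c("bio01", "bio02"), mean = 3)
  occ <- simulate_occurrences(n_per_cell = 30, n_variables = 4,
                              means = means, seed = 8)$occurrences
  ut <- univariate_morph_tests(occ)
  sig_b <- ut[ut$contrast == "color_within_B" & ut$significant, ]
  expect_setequal(sig_b$variable, c("bio01", "bio02"))
  expect_false(any(ut$significant[ut$contrast == "color_within_A"]))
  sig_or <- ut[ut$contrast == "species_within_orange" & ut$significant, ]
  expect_setequal(sig_or$variable, c("bio01", "bio02"))

  swapped <- dplyr::mutate(occ, species = ifelse(species == "A", "B", "A"))
  ut_sw <- univariate_morph_tests(swapped)
  expect_equal(ut_sw$p_value[ut_sw$contrast == "color_within_A"],
               ut$p_value[ut$contrast == "color_within_B"])
})

test_that("direction classification separates parallel from opposing shifts", {
  means <- dplyr::bind_rows(
    tibble::tibble(species = c("A", "B"), morph = "orange",
                   variable = "bio01", mean = c(-2, -2)),   # parallel (lower)
    tibble::tibble(species = c("A", "B"), morph = "orange",
                   variable = "bio02", mean = c(2, -2))     # opposing
  )
  occ <- simulate_occurrences(n_per_cell = 50, n_variables = 3,
                              means = means, seed = 9)$occurrences
  dc <- classify_direction(occ, c("bio01", "bio02"))
  expect_identical(dc$direction[dc$variable == "bio01"], "parallel")
  expect_identical(dc$direction[dc$variable == "bio02"], "opposing")

  flat <- occ
  flat$bio03 <- 1
  expect_identical(classify_direction(flat, "bio03")$direction, "tied")
})

test_that("logistic selection finds the informative variable and flags separation", {
  means <- tibble::tibble(species = "A", morph = "orange",
                          variable = "bio03", mean = 3)
  occ <- simulate_occurrences(n_per_cell = 100, n_variables = 10,
                              means = means, seed = 10)$occurrences
  fit <- select_logistic_model(occ, "A", k_max = 2)
  expect_identical(fit$model_terms[1], "bio03")
  expect_identical(fit$method, "exhaustive")
  expect_false(fit$separation)

  sep <- occ
  sep$bio01 <- ifelse(sep$morph == "orange", 10, -10) + rnorm(nrow(sep), sd = 0.01)
  fit_sep <- select_logistic_model(sep, "A", k_max = 1)
  expect_true(fit_sep$separation)
})

test_that("all-noise predictors rarely beat the intercept-only model", {
  # with a couple of noise predictors the chance that the best subset
  # improves AIC by > 2 is the chance a chi-square(1) exceeds 4, per
  # predictor; at 3 predictors the intercept stays within 2 AIC ~87% of
  # the time
  set.seed(12)
  within2 <- vapply(1:40, function(i) {
    occ <- simulate_occurrences(n_per_cell = 30, n_variables = 3,
                                seed = 1000 + i)$occurrences
    fit <- select_logistic_model(occ, "A", k_max = 3)
    dat <- occ[occ$species == "A", ]
    null_aic <- stats::glm(I(morph == "orange") ~ 1, family = binomial(),
                           data = dat)$aic
    (null_aic - fit$aic) <= 2
  }, logical(1))
  expect_gte(mean(within2), 0.7)
})

test_that("divergence test reproduces the enumerable toy case", {
  occ <- tibble::tibble(
    record = paste0("r", 1:12),
    species = rep(c("A", "B"), each = 6),
    morph = rep(rep(c("blue", "orange"), each = 3), 2),
    lat = 40, lon = -5,
    bio01 = c(rep(0, 6), 0, 0, 0, 5, 5, 5)
  )
  dv <- mc_divergence(occ, n_permutations = 999)
  expect_identical(dv$method[1], "exact")
  expect_equal(dv$p_value[dv$morph == "orange"], 1 / 20)
  expect_equal(dv$p_value[dv$morph == "blue"], 1)
  expect_error(mc_divergence(occ, n_permutations = 50), "99")
})

test_that("divergence p-values are shift invariant and scale equivariant", {
  means <- tibble::tibble(species = "B", morph = "orange",
                          variable = "bio01", mean = 2)
  occ <- simulate_occurrences(n_per_cell = 6, n_variables = 2,
                              means = means, seed = 13)$occurrences
  base <- mc_divergence(occ, n_permutations = 999, seed = 1)
  shifted <- dplyr::mutate(occ, bio01 = bio01 + 100, bio02 = bio02 + 100)
  sh <- mc_divergence(shifted, n_permutations = 999, seed = 1)
  expect_equal(sh$p_value, base$p_value)
  scaled <- dplyr::mutate(occ, bio01 = bio01 * 7, bio02 = bio02 * 7)
  sc <- mc_divergence(scaled, n_permutations = 999, seed = 1)
  expect_equal(sc$p_value, base$p_value)
  expect_equal(sc$observed, base$observed * 7)
})

test_that("monte-carlo divergence p agrees with exact enumeration", {
  means <- tibble::tibble(species = "B", morph = "orange",
                          variable = "bio01", mean = 1.5)
  occ <- simulate_occurrences(n_per_cell = 4, n_variables = 1,
                              means = means, seed = 14)$occurrences
  ex <- mc_divergence(occ, n_permutations = 999)
  expect_identical(ex$method[1], "exact")
  mc <- mc_divergence(occ, n_permutations = 9999, seed = 2, exact_limit = 1)
  for (i in 1:2) {
    se <- sqrt(ex$p_value[i] * (1 - ex$p_value[i]) / 9999)
    expect_lt(abs(mc$p_value[i] - ex$p_value[i]), 2 * se + 2e-4)
  }
})

test_that("planted 15-of-19 orange divergence is recovered", {
  means <- tibble::tibble(species = "B", morph = "orange",
                          variable = sprintf("bio%02d", 1:15), mean = 3)
  occ <- simulate_occurrences(n_per_cell = 40, means = means,
                              seed = 5)$occurrences
  dv <- mc_divergence(filter_occurrences(occ), n_permutations = 999, seed = 1)
  summ <- attr(dv, "summary")
  expect_identical(summ$n_significant[summ$morph == "orange"], 15L)
  expect_lte(summ$n_significant[summ$morph == "blue"], 1L)
})
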