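test_that("cpm matches its definition and is depth invariant", {
  m <- matrix(c(10, 0, 5, 20), nrow = 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  out <- cpm(m, lib_sizes = c(1e6, 1e6))
  expect_equal(out$s1[out$gene == "g1"], 10)

  set.seed(1)
  r <- matrix(rpois(20, 40), nrow = 5,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  brute <- r
  for (s in 1:4) brute[, s] <- r[, s] / sum(r[, s]) * 1e6
  expect_equal(as.matrix(cpm(r)[-1]), brute, ignore_attr = TRUE)

  doubled <- r; doubled[, 2] <- r[, 2] * 2
  expect_equal(cpm(doubled)$s2, cpm(r)$s2)
})

test_that("low-expression filter applies the CPM > 1 in >= 4 samples rule", {
  m <- rbind(kept = c(2, 2, 2, 2, 0), dropped = c(2, 2, 2, 0, 0),
             silent = c(0, 0, 0, 0, 0))
  colnames(m) <- paste0("s", 1:5)
  out <- filter_low_expression(m, lib_sizes = rep(1e6, 5))
  expect_identical(out$gene, "kept")
  expect_identical(
    filter_low_expression(m, min_samples = 0, lib_sizes = rep(1e6, 5))$gene,
    rownames(m))
  expect_warning(filter_low_expression(m, min_cpm = 10, lib_sizes = rep(1e6, 5)),
                 "every gene")
})

test_that("TMM factors behave per the trimmed mean-of-ratios construction", {
  set.seed(2)
  base <- matrix(rpois(4000, 60), ncol = 4,
                 dimnames = list(paste0("g", 1:1000), paste0("s", 1:4)))
  expect_equal(unname(tmm_norm_factors(cbind(base[, 1], base[, 1],
                                             base[, 1]))), rep(1, 3))

  two <- cbind(s1 = base[, 1], s2 = 2 * base[, 1])
  f <- tmm_norm_factors(two, lib_sizes = c(1e6, 1e6))
  expect_equal(unname(f), c(2^(-0.5), 2^(0.5)), tolerance = 1e-9)

  f_all <- tmm_norm_factors(base)
  expect_equal(unname(tmm_norm_factors(base * 5)), unname(f_all),
               tolerance = 1e-9)
  expect_equal(exp(mean(log(f_all))), 1, tolerance = 1e-12)
  perm <- sample(nrow(base))
  expect_equal(unname(tmm_norm_factors(base[perm, ])), unname(f_all),
               tolerance = 1e-9)
})

test_that("TMM agrees with the edgeR reference implementation", {
  set.seed(8)
  m <- matrix(rnbinom(4000 * 6, mu = runif(4000 * 6, 2, 400), size = 5),
              ncol = 6, dimnames = list(paste0("g", 1:4000), paste0("s", 1:6)))
  expect_equal(unname(tmm_norm_factors(m)),
               unname(edgeR::calcNormFactors(m)), tolerance = 1e-3)
})

test_that("common dispersion is recovered by method of moments", {
  meta <- tibble::tibble(sample = paste0("s", 1:20), species = "A",
                         morph = rep(c("blue", "orange"), each = 10))
  pois <- simulate_counts(n_genes = 2000, n_per_group = 10, dispersion = 0,
                          de_fraction = 0, libsize_factor_range = c(1, 1),
                          seed = 5)
  expect_lt(abs(estimate_dispersion(pois$counts, pois$meta)), 0.02)

  nb <- simulate_counts(n_genes = 2000, n_per_group = 10, dispersion = 0.1,
                        de_fraction = 0, libsize_factor_range = c(1, 1),
                        seed = 6)
  expect_lt(abs(estimate_dispersion(nb$counts, nb$meta) - 0.1), 0.03)

  tiny <- matrix(c(10, 10, 11, 11), nrow = 1,
                 dimnames = list("g1", meta$sample[1:4]))
  expect_gte(estimate_dispersion(tiny, meta[1:4, ],
                                 lib_sizes = rep(1, 4)), 0)
})

test_that("NB exact test: symmetric null, binomial limit, planted recovery", {
  expect_equal(nb_exact_pvalue(10, 10, 5, 5, 0.1), 1)
  expect_equal(nb_exact_pvalue(1, 3, 1, 1, 0), brute_binomial_p(1, 4, 1, 1),
               tolerance = 1e-14)

  sim <- simulate_counts(n_genes = 1000, n_per_group = 10, dispersion = 0.1,
                         de_fraction = 0.05, planted_log2fc = 3,
                         orange_specific_genes = 2, seed = 17)
  de <- de_exact_test(filter_low_expression(sim$counts), sim$meta)
  planted <- de$gene %in% sim$truth$gene
  expect_gte(sum(de$deg & planted) / nrow(sim$truth), 0.9)
  expect_identical(sum(de$deg & !planted), 0L)
  # planted direction is recovered
  merged <- dplyr::inner_join(tibble::as_tibble(de), sim$truth, by = "gene")
  expect_true(all(sign(merged$log2fc.x[merged$deg]) ==
                    sign(merged$log2fc.y[merged$deg])))
})

test_that("BH adjustment matches the hand examples and is monotone", {
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(3)
  p <- runif(50)
  q <- bh_fdr(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_true(all(q >= p - 1e-12))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("Mann-Whitney fallback gives exact small-sample p-values", {
  m <- rbind(g1 = c(1, 2, 3, 4, 5, 6), g2 = rep(2, 6))
  colnames(m) <- paste0("s", 1:6)
  meta <- tibble::tibble(sample = colnames(m), species = "A",
                         morph = rep(c("blue", "orange"), each = 3))
  out <- mann_whitney_de(m, meta)
  expect_equal(out$statistic[out$gene == "g1"], 0)
  expect_equal(out$p_value[out$gene == "g1"], 0.1)
  expect_equal(out$p_value[out$gene == "g2"], 1)
  expect_error(mann_whitney_de(m, meta, genes = "nope"), "nope")
})

test_that("direction bias chi-square matches the hand computation", {
  de <- tibble::tibble(gene = paste0("g", 1:100),
                       deg = TRUE,
                       direction = rep(c("O>B", "B>O"), c(75, 25)))
  r <- direction_bias_test(de)
  expect_equal(r$chisq, 25)
  expect_equal(r$p_value, stats::pchisq(25, 1, lower.tail = FALSE))
  expect_equal(r$ratio, 3)

  even <- tibble::tibble(gene = "g", deg = TRUE,
                         direction = rep(c("O>B", "B>O"), 5))
  expect_equal(direction_bias_test(even)$chisq, 0)
  none <- tibble::tibble(gene = "g", deg = FALSE, direction = "O>B")
  expect_warning(r0 <- direction_bias_test(none), "no DEGs")
  expect_true(is.na(r0$chisq))
})

test_that("isotig selection applies the four criteria then presence", {
  base <- tidyr::expand_grid(gene = "G", sample = paste0("s", 1:8)) |>
    dplyr::mutate(ambiguity_frac = 0.05, mapped_reads = 500,
                  cds_length = 900, expression = 10)
  one <- dplyr::mutate(base, isotig = "iso1")
  expect_identical(select_isotig(one)$isotig, "iso1")

  # iso_a survives in 8 samples, iso_b only in 5 (fails read cutoff in 3)
  two <- dplyr::bind_rows(
    dplyr::mutate(base, isotig = "iso_a"),
    dplyr::mutate(base, isotig = "iso_b",
                  mapped_reads = c(rep(500, 5), rep(50, 3)))
  )
  pick <- select_isotig(two)
  expect_identical(pick$isotig, "iso_a")
  expect_identical(pick$n_samples, 8L)
  expect_false(pick$tie)

  # equal survival: lexicographic tie-break, flagged
  tie <- dplyr::bind_rows(
    dplyr::mutate(base[1:6, ], isotig = "isoB"),
    dplyr::mutate(base[1:6, ], isotig = "isoA")
  )
  pick_tie <- select_isotig(tie)
  expect_identical(pick_tie$isotig, "isoA")
  expect_true(pick_tie$tie)

  # everything eliminated: pre-filter presence leader, flagged
  gone <- dplyr::mutate(two, ambiguity_frac = 0.9)
  pick_fb <- select_isotig(gone)
  expect_true(pick_fb$fallback)
})
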