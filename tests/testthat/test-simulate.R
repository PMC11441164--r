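test_that("generators are pure functions of their seed", {
  set.seed(999)
  before <- .Random.seed
  s1 <- simulate_spectra(n_per_group = 3, seed = 4)
  expect_identical(before, .Random.seed)
  expect_identical(s1, simulate_spectra(n_per_group = 3, seed = 4))

  c1 <- simulate_counts(n_genes = 50, n_per_group = 3, seed = 4)
  expect_identical(c1, simulate_counts(n_genes = 50, n_per_group = 3, seed = 4))

  meta <- make_cell_meta(3)
  a1 <- simulate_alignment(meta, length_codons = 30, n_color_ns = 2, seed = 4)
  expect_identical(a1, simulate_alignment(meta, length_codons = 30,
                                          n_color_ns = 2, seed = 4))

  t1 <- simulate_tree("ancestral_polymorphism", seed = 4)
  expect_identical(ape::write.tree(t1),
                   ape::write.tree(simulate_tree("ancestral_polymorphism",
                                                 seed = 4)))

  o1 <- simulate_occurrences(n_per_cell = 4, n_variables = 3, seed = 4)
  expect_identical(o1, simulate_occurrences(n_per_cell = 4, n_variables = 3,
                                            seed = 4))
})

test_that("zero-effect spectra are identical and orange gains UV peaks", {
  flat <- simulate_spectra(n_per_group = 2, color_effect = 0,
                           species_effect = 0, noise_sd = 0, seed = 1)
  by_wl <- tapply(flat$reflectance, flat$wavelength, function(v) diff(range(v)))
  expect_true(all(by_wl == 0))

  sp <- simulate_spectra(n_per_group = 5, color_effect = 30,
                         species_effect = 5, noise_sd = 0, seed = 1)
  uv_maxima <- function(morph) {
    mu <- sp |>
      dplyr::filter(.data$morph == !!morph) |>
      dplyr::group_by(wavelength) |>
      dplyr::summarise(y = mean(reflectance), .groups = "drop")
    y <- mu$y
    interior <- which(diff(sign(diff(y))) == -2) + 1
    sum(mu$wavelength[interior] < 450)
  }
  expect_identical(uv_maxima("orange"), 2L)
  expect_identical(uv_maxima("blue"), 0L)
})

test_that("count generator plants the requested DE structure", {
  sim <- simulate_counts(n_genes = 1000, de_fraction = 0.05,
                         planted_log2fc = 3, dispersion = 0.1,
                         n_per_group = 10, orange_specific_genes = 0, seed = 7)
  expect_identical(nrow(sim$truth), 50L)
  expect_true(all(abs(abs(sim$truth$log2fc) - 3) < 1e-12))

  none <- simulate_counts(n_genes = 100, de_fraction = 0, seed = 1)
  expect_identical(nrow(none$truth), 0L)

  os <- simulate_counts(n_genes = 500, de_fraction = 0.02,
                        orange_specific_genes = 2, n_per_group = 20, seed = 3)
  os_genes <- os$truth$gene[os$truth$type == "orange_specific"]
  expect_length(os_genes, 2)
  m <- as.matrix(os$counts[-1])
  blue_cols <- os$meta$morph == "blue"
  expect_true(all(rowMeans(m[match(os_genes, os$counts$gene), blue_cols]) < 0.5))

  expect_warning(simulate_counts(n_genes = 10, de_fraction = 0.01, seed = 1),
                 "planting none")
})

test_that("dispersion zero gives Poisson-like counts and means track baselines", {
  sim <- simulate_counts(n_genes = 400, n_per_group = 50, dispersion = 0,
                         de_fraction = 0, libsize_factor_range = c(1, 1),
                         baseline_log2_range = c(5, 5), seed = 11)
  m <- as.matrix(sim$counts[-1])
  ratio <- apply(m, 1, var) / rowMeans(m)
  expect_lt(abs(mean(ratio) - 1), 0.05)
  # marginal means match the specified baseline within 3 SE at n = 100
  mu <- 2^5
  se <- sqrt(mu / ncol(m))
  expect_true(mean(abs(rowMeans(m) - mu) <= 3 * se) > 0.95)
})

test_that("alignment generator plants stop-free disjoint SNPs", {
  meta <- make_cell_meta(4)
  sim <- simulate_alignment(meta, length_codons = 100, n_color_ns = 13,
                            n_color_syn = 2, n_species_ns = 3,
                            ambiguity_rate = 0, seed = 3)
  color_ns <- sim$truth[sim$truth$class == "color" &
                          sim$truth$effect == "nonsynonymous", ]
  expect_identical(nrow(color_ns), 13L)
  expect_false(anyDuplicated(sim$truth$codon) > 0)
  prots <- vapply(sim$alignment$seqs, translate_cds, character(1))
  internal <- substr(prots, 1, nchar(prots) - 1)
  expect_false(any(grepl("*", internal, fixed = TRUE)))

  plain <- simulate_alignment(meta, length_codons = 20, n_color_ns = 0,
                              seed = 5)
  expect_identical(length(unique(plain$alignment$seqs)), 1L)
  expect_error(simulate_alignment(meta, length_codons = 5, n_color_ns = 10),
               "exceed")
})

test_that("tree topologies encode the four hypotheses", {
  meta <- parse_sample_labels(simulate_tree("convergence", seed = 1)$tip.label)
  orange <- meta$sample[meta$morph == "orange"]
  conv <- simulate_tree("convergence", seed = 1)
  expect_false(is_monophyletic(conv, orange)$is_monophyletic)
  for (h in c("introgression", "ancestral_polymorphism", "non_monophyly")) {
    tr <- simulate_tree(h, seed = 2)
    expect_true(is_monophyletic(tr, orange)$is_monophyletic)
  }
  ap <- simulate_scenario_trees("ancestral_polymorphism", seed = 3)
  meta_c <- parse_sample_labels(ap$combined$tip.label)
  for (sp in c("A", "B")) {
    expect_true(is_monophyletic(ap$combined,
                                meta_c$sample[meta_c$species == sp])$is_monophyletic)
  }
  expect_error(simulate_tree("hybrid_swarm"), "arg")
})

test_that("occurrence truth lists exactly the planted shifts", {
  null_occ <- simulate_occurrences(n_per_cell = 5, n_variables = 4, seed = 2)
  expect_false(any(null_occ$truth$divergent))

  means <- tibble::tibble(species = "B", morph = "orange",
                          variable = sprintf("bio%02d", 1:15), mean = 3)
  shifted <- simulate_occurrences(n_per_cell = 5, means = means, seed = 2)
  tr <- shifted$truth
  expect_identical(sum(tr$divergent[tr$morph == "orange"]), 15L)
  expect_identical(sum(tr$divergent[tr$morph == "blue"]), 0L)
  expect_error(simulate_occurrences(n_per_cell = 5, sds = 0), "> 0")
})
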