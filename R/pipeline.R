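#' Simulate a complete study under one evolutionary scenario
#'
#' Generates all five input kinds -- spectra, per-species count matrices,
#' per-gene coding alignments, gene trees plus a combined tree, and an
#' occurrence table -- with the planted structure each hypothesis implies:
#'
#' * `ancestral_polymorphism`: shared color SNPs and expression pattern,
#'   cross-species orange clade at color genes, species monophyly in the
#'   combined tree, no interspecific fertility.
#' * `introgression`: as above but with interspecific fertility.
#' * `convergence`: species-private color SNPs and DEG sets, no
#'   cross-species orange clade, no fertility.
#' * `non_monophyly`: shared signal, orange clade at every locus including
#'   the combined tree, fertility.
#'
#' @param hypothesis scenario to generate.
#' @param seed integer seed driving every generator.
#' @param n_per_group RNA-seq samples per morph within each species.
#' @param n_genes genes per species count matrix.
#' @param n_tips_per_cell tree tips per species x morph cell.
#' @param n_occ occurrence records per species x morph cell.
#' @param focal_genes ids of the two orange-specific color genes.
#' @return a list with elements `hypothesis`, `spectra`, `counts` (named
#'   list per species: `counts`, `meta`, `truth`), `alignments` (named list
#'   of [coding_alignment()]), `snp_truth`, `trees` (list `gene_trees`,
#'   `combined`), `occurrences`, `occurrence_truth`, `crosses`.
#' @export
simulate_study <- function(hypothesis = c("ancestral_polymorphism",
                                          "convergence", "introgression",
                                          "non_monophyly"),
                           seed = 1,
                           n_per_group = 10,
                           n_genes = 1000,
                           n_tips_per_cell = 3,
                           n_occ = 40,
                           focal_genes = c("DFR2", "BZ12")) {
  hypothesis <- match.arg(hypothesis)
  shared <- hypothesis != "convergence"
  seeds <- as.integer(seed) + 0:19  # one sub-seed per generator call

  spectra <- simulate_spectra(n_per_group = 20, color_effect = 30,
                              species_effect = 5, noise_sd = 2,
                              seed = seeds[1])

  counts <- purrr::imap(list(A = seeds[2], B = seeds[3]), function(s, sp) {
    sim <- simulate_counts(n_genes = n_genes, n_per_group = n_per_group,
                           orange_specific_genes = 2, species = sp, seed = s)
    # the two orange-specific paralogues are the focal color genes; under
    # convergence each species recruits a different pair of genes
    os <- sim$truth$gene[sim$truth$type == "orange_specific"]
    new_names <- if (shared) focal_genes else paste0(focal_genes, "_", sp)
    idx <- match(os, sim$counts$gene)
    sim$counts$gene[idx] <- new_names
    sim$truth$gene[match(os, sim$truth$gene)] <- new_names
    sim
  })

  tree_meta <- tidyr::expand_grid(species = c("A", "B"),
                                  morph = c("blue", "orange"),
                                  rep = seq_len(4)) |>
    dplyr::mutate(sample = sprintf("%s_%s_%02d", .data$species, .data$morph,
                                   .data$rep)) |>
    dplyr::select("sample", "species", "morph")

  alignments <- purrr::imap(
    setNames(seq_along(focal_genes), focal_genes),
    function(i, g) {
      simulate_alignment(tree_meta, gene = g, length_codons = 150,
                         n_color_ns = if (i == 1) 13 else 5,
                         n_color_syn = 2, n_species_ns = 3,
                         shared_color_snps = shared, seed = seeds[3 + i])
    })

  trees <- simulate_scenario_trees(hypothesis, genes = c(focal_genes, "F3pH",
                                                         "ANS"),
                                   color_genes = focal_genes,
                                   n_tips_per_cell = n_tips_per_cell,
                                   seed = seeds[6])

  # orange morphs diverge between species for 15 of 19 variables
  shift_vars <- sprintf("bio%02d", 1:15)
  occ_means <- tibble::tibble(species = "B", morph = "orange",
                              variable = shift_vars, mean = 3)
  occ <- simulate_occurrences(n_per_cell = n_occ, means = occ_means,
                              seed = seeds[7])

  fertile <- hypothesis %in% c("introgression", "non_monophyly")
  crosses <- tibble::tibble(
    type = c("interspecific", "interspecific", "intraspecific",
             "intraspecific"),
    direction = c("AxB", "BxA", "AxA", "BxB"),
    n_pollinations = c(27, 26, 97, 575),
    n_fruits = c(if (fertile) c(5, 4) else c(0, 0), 97, 275)
  )

  list(hypothesis = hypothesis, spectra = spectra, counts = counts,
       alignments = purrr::map(alignments, "alignment"),
       snp_truth = purrr::map(alignments, "truth"),
       trees = trees, occurrences = occ$occurrences,
       occurrence_truth = occ$truth, crosses = crosses,
       focal_genes = focal_genes)
}

#' Run the full multiscale analysis on a simulated or assembled study
#'
#' Executes every pipeline stage: spectral variance partitioning, per-
#' species differential expression at the conservative thresholds, color-
#' and species-differentiating SNP detection, monophyly evaluation, the
#' Monte Carlo climate divergence test, evidence aggregation and hypothesis
#' scoring.
#'
#' @param study a list shaped like the output of [simulate_study()].
#' @param n_permutations permutations for the spectra PERMANOVA and the
#'   climate Monte Carlo test.
#' @param seed integer seed for the permutation draws.
#' @param snp_cutoff frequency-difference cutoff for SNP calls.
#' @param min_support bootstrap gate for monophyly calls.
#' @return a list with `partitions`, `de` (per species), `snps` (per
#'   species, per gene), `phylo_evidence`, `divergence`, `evidence`,
#'   `assessment` (tibble of verdicts), `verdict` (the consistent
#'   hypotheses).
#' @export
run_study <- function(study, n_permutations = 999, seed = 1,
                      snp_cutoff = 0.75, min_support = 70) {
  partitions <- compare_partitions(study$spectra,
                                   n_permutations = n_permutations,
                                   seed = seed)

  de <- purrr::map(study$counts, function(cc) {
    filtered <- filter_low_expression(cc$counts)
    de_exact_test(filtered, cc$meta)
  })

  # per-species SNP reports, each computed on the species' own samples
  snps <- purrr::map(setNames(c("A", "B"), c("A", "B")), function(sp) {
    purrr::map(study$alignments, function(aln) {
      keep <- aln$meta$sample[aln$meta$species == sp]
      sub <- coding_alignment(aln$gene, aln$seqs[keep],
                              aln$meta[aln$meta$species == sp, ])
      color_differentiating_snps(sub, cutoff = snp_cutoff)
    })
  })

  phylo_evidence <- topology_evidence(study$trees$gene_trees,
                                      study$trees$combined,
                                      min_support = min_support)

  occ <- filter_occurrences(study$occurrences)
  divergence <- mc_divergence(occ, n_permutations = max(999, n_permutations),
                              seed = seed)

  evidence <- build_evidence(phylo_evidence, de, snps, study$crosses,
                             focal_genes = study$focal_genes)
  assessment <- score_hypotheses(evidence)
  list(partitions = partitions, de = de, snps = snps,
       phylo_evidence = phylo_evidence, divergence = divergence,
       evidence = evidence, assessment = assessment,
       verdict = assessment$hypothesis[assessment$verdict == "consistent"])
}
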