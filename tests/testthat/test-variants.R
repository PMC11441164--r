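toy_alignment <- function() {
  # 4 codons x 8 samples; column 4 (codon 2, pos 1) separates morphs
  meta <- make_cell_meta(2)
  codons <- purrr::map(seq_len(nrow(meta)), function(i) {
    base <- c("ATG", "AAA", "GAA", "CCC")
    if (meta$morph[i] == "orange") base[2] <- "GAA"  # Lys -> Glu
    base
  })
  names(codons) <- meta$sample
  alignment_from_codons(codons, meta)
}

test_that("allele frequencies count unambiguous calls only", {
  aln <- toy_alignment()
  fr <- site_allele_frequencies(aln, "morph")
  col1 <- fr[fr$column == 1, ]
  expect_true(all(col1$A == 2 * 2))  # every sample starts ATG

  # orange T,T,N,A at one column: denominator 3, freq 2/3
  meta <- make_cell_meta(1) |>
    dplyr::bind_rows(tibble::tibble(sample = c("A_orange_02", "B_orange_02"),
                                    species = c("A", "B"),
                                    morph = "orange"))
  codons <- purrr::map(seq_len(nrow(meta)), function(i) c("ATG", "GCA"))
  names(codons) <- meta$sample
  seqs <- vapply(codons, paste, collapse = "", FUN.VALUE = character(1))
  substr(seqs["A_orange_01"], 4, 4) <- "T"
  substr(seqs["B_orange_01"], 4, 4) <- "T"
  substr(seqs["A_orange_02"], 4, 4) <- "N"
  aln2 <- coding_alignment("toy2", seqs, meta)
  fr2 <- site_allele_frequencies(aln2, "morph")
  or4 <- fr2[fr2$column == 4 & fr2$group == "orange", ]
  expect_equal(or4$n_unambiguous, 3)
  expect_equal(or4$T / or4$n_unambiguous, 2 / 3)
})

test_that("codon effect classification follows the standard genetic code", {
  aln <- toy_alignment()
  # GAA -> GAG at codon 3 position 3: synonymous Glu
  syn <- classify_snp_effect(aln, 9, "G")
  expect_identical(syn$effect, "synonymous")
  # AAA -> GAA at codon 2 position 1 (blue majority background varies):
  ns <- classify_snp_effect(aln, 4, "C")
  expect_identical(ns$effect, "nonsynonymous")
  # substitution creating a stop: GAA -> TAA
  stopch <- classify_snp_effect(aln, 7, "T")
  expect_identical(stopch$effect, "nonsynonymous")
  expect_true(stopch$nonsense)
})

test_that("frequency-difference cutoff is inclusive at 0.75", {
  meta <- parse_sample_labels(c(sprintf("A_blue_%02d", 1:2),
                                sprintf("B_blue_%02d", 1:2),
                                sprintf("A_orange_%02d", 1:50),
                                sprintf("B_orange_%02d", 1:50)))
  make_aln <- function(n_alt) {
    codons <- purrr::map(seq_len(nrow(meta)), function(i) c("ATG", "AAA"))
    names(codons) <- meta$sample
    seqs <- vapply(codons, paste, collapse = "", FUN.VALUE = character(1))
    orange <- which(meta$morph == "orange")
    for (i in orange[seq_len(n_alt)]) substr(seqs[i], 4, 4) <- "G"
    coding_alignment("cut", seqs, meta)
  }
  at_cutoff <- color_differentiating_snps(make_aln(75))   # diff exactly 0.75
  expect_identical(nrow(at_cutoff), 1L)
  below <- color_differentiating_snps(make_aln(74))       # diff 0.74
  expect_identical(nrow(below), 0L)
})

test_that("planted color SNPs are recovered exactly with zero false calls", {
  meta <- make_cell_meta(4)
  sim <- simulate_alignment(meta, length_codons = 150, n_color_ns = 13,
                            n_color_syn = 2, n_species_ns = 3,
                            ambiguity_rate = 0, seed = 3)
  snps <- color_differentiating_snps(sim$alignment, cutoff = 0.75)
  ns <- snps[snps$effect == "nonsynonymous", ]
  expect_identical(nrow(ns), 13L)
  truth_ns <- sim$truth[sim$truth$class == "color" &
                          sim$truth$effect == "nonsynonymous", ]
  expect_setequal(ns$column, truth_ns$column)
  syn <- snps[snps$effect == "synonymous", ]
  expect_identical(nrow(syn), 2L)

  sp <- species_differentiating_snps(sim$alignment, cutoff = 0.75)
  expect_setequal(sp$column,
                  sim$truth$column[sim$truth$class == "species"])

  # effect classification agrees with whole-protein translation (Biostrings)
  blue_seq <- sim$alignment$seqs[[which(meta$morph == "blue")[1]]]
  orange_seq <- sim$alignment$seqs[[which(meta$morph == "orange")[1]]]
  p_blue <- as.character(Biostrings::translate(Biostrings::DNAString(blue_seq)))
  p_orange <- as.character(Biostrings::translate(Biostrings::DNAString(orange_seq)))
  aa_diff <- which(strsplit(p_blue, "")[[1]] != strsplit(p_orange, "")[[1]])
  expect_setequal(ns$codon, aa_diff)
})

test_that("ambiguity reduces denominators but spares strong signal", {
  meta <- make_cell_meta(6)
  sim <- simulate_alignment(meta, length_codons = 120, n_color_ns = 10,
                            ambiguity_rate = 0.05, seed = 9)
  snps <- color_differentiating_snps(sim$alignment, cutoff = 0.75)
  ns_cols <- snps$column[snps$effect == "nonsynonymous"]
  truth_cols <- sim$truth$column[sim$truth$effect == "nonsynonymous"]
  expect_true(all(ns_cols %in% truth_cols))
  expect_gte(length(ns_cols), 9)
})

test_that("fixed color differences require fixation in both species", {
  meta <- make_cell_meta(3)
  sim <- simulate_alignment(meta, length_codons = 60, n_color_ns = 4, seed = 2)
  fx <- fixed_color_differences(sim$alignment)
  planted_cols <- sim$truth$column
  expect_setequal(fx$column, planted_cols)

  # one discordant orange sample breaks fixation at that column
  aln <- sim$alignment
  col <- planted_cols[1]
  ref <- sim$truth$ref[sim$truth$column == col]
  discordant <- aln$meta$sample[aln$meta$morph == "orange"][1]
  substr(aln$seqs[[discordant]], col, col) <- ref
  fx2 <- fixed_color_differences(aln)
  expect_false(col %in% fx2$column)

  # fixation is a color-only definition: swapping species labels changes nothing
  swapped <- aln
  swapped$meta$species <- ifelse(swapped$meta$species == "A", "B", "A")
  expect_equal(fixed_color_differences(swapped)$column, fx2$column)
})

test_that("SNP reports are invariant under sample reordering", {
  meta <- make_cell_meta(3)
  sim <- simulate_alignment(meta, length_codons = 90, n_color_ns = 5,
                            n_species_ns = 2, seed = 12)
  aln <- sim$alignment
  perm <- sample(length(aln$seqs))
  shuffled <- coding_alignment(aln$gene, aln$seqs[perm],
                               aln$meta[perm, ])
  expect_equal(color_differentiating_snps(aln)$column,
               color_differentiating_snps(shuffled)$column)
})

test_that("FASTA round trip preserves the alignment", {
  meta <- make_cell_meta(2)
  sim <- simulate_alignment(meta, length_codons = 30, n_color_ns = 2, seed = 1)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_alignment_fasta(sim$alignment, path)
  back <- read_alignment_fasta(path, gene = sim$alignment$gene)
  expect_identical(back$seqs, sim$alignment$seqs)
})
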