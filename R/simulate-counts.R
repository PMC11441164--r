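#' Simulate an RNA-seq count matrix with planted differential expression
#'
#' Draws negative-binomial counts for two color morphs of one species.
#' A fraction `de_fraction` of genes is planted as differentially expressed
#' with a symmetric mean ratio of `2^planted_log2fc` between morphs; the
#' first `orange_specific_genes` of those emulate orange-specific paralogues
#' whose baseline mean in blue petals is below 0.5 counts (near-undetectable)
#' while expression in orange is substantial.
#'
#' @param n_genes number of genes.
#' @param n_per_group samples per morph.
#' @param baseline_log2_range range (log2 scale) of baseline mean expression;
#'   gene means are `2^U(baseline_log2_range)`.
#' @param dispersion negative-binomial dispersion phi >= 0; 0 gives Poisson
#'   counts.
#' @param de_fraction fraction of genes planted as differentially expressed.
#' @param planted_log2fc absolute log2 fold change planted between morphs
#'   (sign alternates between planted genes; orange-specific genes are
#'   always orange > blue).
#' @param orange_specific_genes number of planted genes (taken from the DE
#'   budget) given the orange-specific near-zero-in-blue pattern.
#' @param libsize_factor_range range of per-sample library size multipliers.
#' @param species species label used in sample names and metadata.
#' @param seed integer seed.
#'
#' @return A list with elements `counts` (tibble, `gene` + one column per
#'   sample), `meta` (tibble `sample`, `species`, `morph`) and `truth`
#'   (tibble of planted genes: `gene`, `log2fc` signed orange vs blue,
#'   `type` in `shift`/`orange_specific`).
#' @export
simulate_counts <- function(n_genes = 1000,
                            n_per_group = 10,
                            baseline_log2_range = c(3, 8),
                            dispersion = 0.1,
                            de_fraction = 0.05,
                            planted_log2fc = 3,
                            orange_specific_genes = 2,
                            libsize_factor_range = c(0.7, 1.4),
                            species = "A",
                            seed = NULL) {
  if (de_fraction < 0 || de_fraction > 1) abort("`de_fraction` must be in [0, 1].")
  if (dispersion < 0) abort("`dispersion` must be >= 0.")
  if (any(libsize_factor_range <= 0)) abort("library size factors must be > 0.")

  n_de <- round(de_fraction * n_genes)
  if (de_fraction > 0 && n_de < 1) {
    warn("`de_fraction` too small for any planted gene; planting none.")
    n_de <- 0L
  }
  n_orange_specific <- min(orange_specific_genes, n_de)

  with_seed(seed, {
    genes <- sprintf("gene%04d", seq_len(n_genes))
    mu0 <- 2^runif(n_genes, baseline_log2_range[1], baseline_log2_range[2])

    de_idx <- if (n_de > 0) sort(sample.int(n_genes, n_de)) else integer(0)
    os_idx <- head(de_idx, n_orange_specific)
    shift_idx <- setdiff(de_idx, os_idx)
    sign_vec <- rep_len(c(1, -1), length(shift_idx))

    mu_blue <- mu_orange <- mu0
    mu_blue[shift_idx] <- mu0[shift_idx] * 2^(-sign_vec * planted_log2fc / 2)
    mu_orange[shift_idx] <- mu0[shift_idx] * 2^(sign_vec * planted_log2fc / 2)
    # orange-specific paralogues: essentially silent in blue petals
    mu_blue[os_idx] <- 0.05
    mu_orange[os_idx] <- pmax(mu0[os_idx], 2^mean(baseline_log2_range))

    meta <- tibble::tibble(
      sample = c(sprintf("%s_blue_%02d", species, seq_len(n_per_group)),
                 sprintf("%s_orange_%02d", species, seq_len(n_per_group))),
      species = species,
      morph = rep(c("blue", "orange"), each = n_per_group)
    )
    sf <- runif(nrow(meta), libsize_factor_range[1], libsize_factor_range[2])

    draw <- function(mu) {
      if (dispersion == 0) rpois(length(mu), mu) else {
        rnbinom(length(mu), mu = mu, size = 1 / dispersion)
      }
    }
    mat <- vapply(seq_len(nrow(meta)), function(s) {
      mu <- if (meta$morph[s] == "blue") mu_blue else mu_orange
      draw(mu * sf[s])
    }, numeric(n_genes))
    dimnames(mat) <- list(genes, meta$sample)

    truth <- tibble::tibble(
      gene = genes[de_idx],
      log2fc = log2(mu_orange[de_idx] / mu_blue[de_idx]),
      type = ifelse(de_idx %in% os_idx, "orange_specific", "shift")
    )
    list(counts = counts_as_tibble(mat), meta = meta, truth = truth)
  })
}
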