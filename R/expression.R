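#' Counts per million
#'
#' `CPM_gs = count_gs / (lib_size_s * norm_factor_s) * 1e6`.
#'
#' @param counts counts tibble (`gene` column + samples) or matrix.
#' @param norm_factors optional per-sample normalization factors (named or
#'   in column order; default 1).
#' @param lib_sizes optional per-sample library sizes (default column sums).
#' @return a tibble of the same shape as `counts`.
#' @export
cpm <- function(counts, norm_factors = NULL, lib_sizes = NULL) {
  m <- as_counts_matrix(counts)
  lib <- resolve_per_sample(lib_sizes, m, colSums(m), "lib_sizes")
  nf <- resolve_per_sample(norm_factors, m, rep(1, ncol(m)), "norm_factors")
  if (any(lib * nf <= 0)) abort("effective library sizes must be > 0.")
  counts_as_tibble(sweep(m, 2, lib * nf, "/") * 1e6)
}

resolve_per_sample <- function(x, m, default, what) {
  if (is.null(x)) return(default)
  if (!is.null(names(x))) {
    if (!all(colnames(m) %in% names(x))) {
      abort(sprintf("`%s` must name every sample.", what))
    }
    x <- x[colnames(m)]
  }
  if (length(x) != ncol(m)) abort(sprintf("`%s` has the wrong length.", what))
  as.numeric(x)
}

#' Filter genes by minimum expression
#'
#' Keeps genes with CPM strictly greater than `min_cpm` in at least
#' `min_samples` samples ("more than one count per million in a minimum of
#' four samples"), preserving gene order.
#'
#' @inheritParams cpm
#' @param min_cpm CPM threshold (strict `>`).
#' @param min_samples minimum number of samples exceeding the threshold.
#' @return the filtered counts tibble.
#' @export
filter_low_expression <- function(counts, min_cpm = 1, min_samples = 4,
                                  norm_factors = NULL, lib_sizes = NULL) {
  if (min_cpm < 0 || min_samples < 0) abort("thresholds must be >= 0.")
  m <- as_counts_matrix(counts)
  cpm_m <- as_counts_matrix(cpm(m, norm_factors, lib_sizes))
  keep <- rowSums(cpm_m > min_cpm) >= min_samples
  if (!any(keep)) warn("expression filter removed every gene.")
  counts_as_tibble(m[keep, , drop = FALSE])
}

#' TMM normalization factors (trimmed mean of M-values)
#'
#' The reference sample is the one whose upper-quartile CPM is closest to
#' the mean upper quartile. For each sample, gene-wise log2 expression
#' ratios to the reference (M) and average log2 abundances (A) are computed
#' over genes positive in both, doubly trimmed (30% of M, 5% of A from each
#' tail by default), and the factor is 2 to the precision-weighted mean of
#' the retained M values. Factors are rescaled to a geometric mean of 1.
#'
#' @inheritParams cpm
#' @param trim_m fraction of M values trimmed from each tail.
#' @param trim_a fraction of A values trimmed from each tail.
#' @return named numeric vector of per-sample factors (geometric mean 1).
#' @export
tmm_norm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05,
                             lib_sizes = NULL) {
  m <- as_counts_matrix(counts)
  if (ncol(m) < 2) abort("TMM needs at least 2 samples.")
  lib <- resolve_per_sample(lib_sizes, m, colSums(m), "lib_sizes")

  uq <- vapply(seq_len(ncol(m)), function(s) {
    quantile(m[, s], 0.75, names = FALSE) / lib[s]
  }, numeric(1))
  ref <- which.min(abs(uq - mean(uq)))

  f <- vapply(seq_len(ncol(m)), function(s) {
    obs <- m[, s]; refc <- m[, ref]
    pos <- obs > 0 & refc > 0
    if (!any(pos)) {
      warn(sprintf("sample '%s' shares no positive gene with the reference; factor 1.",
                   colnames(m)[s]))
      return(1)
    }
    obs <- obs[pos]; refc <- refc[pos]
    p_obs <- obs / lib[s]; p_ref <- refc / lib[ref]
    M <- log2(p_obs / p_ref)
    A <- 0.5 * log2(p_obs * p_ref)
    w <- (lib[s] - obs) / (lib[s] * obs) + (lib[ref] - refc) / (lib[ref] * refc)
    # degenerate weights (single-gene libraries) fall back to equal weighting
    w[w <= 0] <- max(w[w > 0], 1e-6)
    n <- length(M)
    loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
    rkM <- rank(M, ties.method = "first")
    rkA <- rank(A, ties.method = "first")
    keep <- rkM >= loM & rkM <= hiM & rkA >= loA & rkA <= hiA
    if (!any(keep)) return(1)
    2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
  }, numeric(1))

  f <- f / exp(mean(log(f)))
  setNames(f, colnames(m))
}

#' Method-of-moments common dispersion estimate
#'
#' Counts are scaled to a common effective library size; for each gene and
#' group with mean above `min_mean`, `phi = (s^2 - m) / m^2` is computed and
#' the average over eligible (gene, group) cells, floored at 0, is returned.
#'
#' @inheritParams cpm
#' @param meta sample metadata tibble (`sample`, `morph` used as group).
#' @param group_col metadata column defining the two groups.
#' @param min_mean minimum scaled group mean for a gene to contribute.
#' @return a single dispersion estimate `phi >= 0`.
#' @export
estimate_dispersion <- function(counts, meta, group_col = "morph",
                                norm_factors = NULL, lib_sizes = NULL,
                                min_mean = 5) {
  m <- as_counts_matrix(counts)
  meta <- check_meta(meta, samples = colnames(m))
  groups <- meta[[group_col]]
  lib <- resolve_per_sample(lib_sizes, m, colSums(m), "lib_sizes")
  nf <- resolve_per_sample(norm_factors, m, rep(1, ncol(m)), "norm_factors")
  eff <- lib * nf
  scaled <- sweep(m, 2, exp(mean(log(eff))) / eff, "*")

  phis <- c()
  for (g in unique(groups)) {
    sub <- scaled[, groups == g, drop = FALSE]
    if (ncol(sub) < 2) abort("need >= 2 samples per group.")
    mu <- rowMeans(sub)
    s2 <- apply(sub, 1, var)
    ok <- mu > min_mean
    phis <- c(phis, pmax(0, (s2[ok] - mu[ok]) / mu[ok]^2))
  }
  if (length(phis) == 0) {
    warn("no gene exceeded `min_mean`; returning dispersion 0.")
    return(0)
  }
  max(0, mean(phis))
}

#' Conditional negative-binomial exact test p-value for two group sums
#'
#' Under a common per-sample mean, the two group sums are negative binomial
#' with sizes `n1/phi` and `n2/phi` (Poisson when `phi = 0`). Conditional on
#' their total, the two-sided p-value is the summed probability of all
#' splits as likely or less likely than the observed one.
#'
#' @param sum1,sum2 the two group sums (non-negative integers).
#' @param n1,n2 number of samples in each group.
#' @param phi common dispersion (>= 0).
#' @return p-value in (0, 1].
#' @export
nb_exact_pvalue <- function(sum1, sum2, n1, n2, phi = 0) {
  if (phi < 0) abort("`phi` must be >= 0.")
  total <- sum1 + sum2
  if (total == 0) return(1)
  s <- 0:total
  mu <- total / (n1 + n2)
  logp <- if (phi == 0) {
    dpois(s, n1 * mu, log = TRUE) + dpois(total - s, n2 * mu, log = TRUE)
  } else {
    dnbinom(s, size = n1 / phi, mu = n1 * mu, log = TRUE) +
      dnbinom(total - s, size = n2 / phi, mu = n2 * mu, log = TRUE)
  }
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  p_obs <- pr[sum1 + 1]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-10)]))
}

#' Differential expression between color morphs by NB exact test
#'
#' TMM-normalizes the (filtered) counts, estimates a single common
#' dispersion unless one is supplied, scales counts to a common effective
#' library size, and applies the conditional negative-binomial exact test
#' per gene. Log2 fold changes (orange vs blue) are computed from group
#' mean CPM with a prior count of 0.5 so orange-specific genes get large
#' but finite values. FDR is Benjamini-Hochberg; a gene is flagged as a DEG
#' when `fdr < fdr_threshold` and `|log2fc| > lfc_threshold` (defaults are
#' the conservative thresholds FDR < 1e-5 and |log2FC| > 1).
#'
#' @inheritParams estimate_dispersion
#' @param dispersion optional common dispersion; estimated when NULL.
#' @param fdr_threshold FDR cutoff for the DEG flag.
#' @param lfc_threshold absolute log2 fold-change cutoff (strict `>`).
#' @return a tibble of class `de_result`: `gene`, `mean_blue`,
#'   `mean_orange` (group mean CPM), `log2fc`, `p_value`, `fdr`, `deg`,
#'   `direction` (`"O>B"`/`"B>O"`).
#' @export
de_exact_test <- function(counts, meta, group_col = "morph",
                          dispersion = NULL, norm_factors = NULL,
                          lib_sizes = NULL,
                          fdr_threshold = 1e-5, lfc_threshold = 1) {
  m <- as_counts_matrix(counts)
  meta <- check_meta(meta, samples = colnames(m))
  groups <- meta[[group_col]]
  levs <- sort(unique(groups))
  if (length(levs) != 2) abort("exact test needs exactly 2 groups.")
  if (!all(c("blue", "orange") %in% levs) && group_col == "morph") {
    abort("morph groups must be 'blue' and 'orange'.")
  }

  lib <- resolve_per_sample(lib_sizes, m, colSums(m), "lib_sizes")
  if (is.null(norm_factors)) {
    norm_factors <- tmm_norm_factors(m, lib_sizes = lib)
  }
  nf <- resolve_per_sample(norm_factors, m, rep(1, ncol(m)), "norm_factors")
  eff <- lib * nf
  if (is.null(dispersion)) {
    dispersion <- estimate_dispersion(m, meta, group_col,
                                      norm_factors = nf, lib_sizes = lib)
  }

  common <- exp(mean(log(eff)))
  pseudo <- sweep(m, 2, common / eff, "*")
  is_o <- groups == "orange" | groups == levs[2]
  g1 <- !is_o; g2 <- is_o
  n1 <- sum(g1); n2 <- sum(g2)
  sum1 <- round(rowSums(pseudo[, g1, drop = FALSE]))
  sum2 <- round(rowSums(pseudo[, g2, drop = FALSE]))

  p <- vapply(seq_len(nrow(m)), function(i) {
    nb_exact_pvalue(sum1[i], sum2[i], n1, n2, dispersion)
  }, numeric(1))

  cpm_m <- sweep(m, 2, eff, "/") * 1e6
  mean1 <- rowMeans(cpm_m[, g1, drop = FALSE])
  mean2 <- rowMeans(cpm_m[, g2, drop = FALSE])
  log2fc <- log2((mean2 + 0.5) / (mean1 + 0.5))
  fdr <- bh_fdr(p)

  out <- tibble::tibble(
    gene = rownames(m),
    mean_blue = mean1, mean_orange = mean2,
    log2fc = log2fc, p_value = p, fdr = fdr,
    deg = fdr < fdr_threshold & abs(log2fc) > lfc_threshold,
    direction = ifelse(log2fc >= 0, "O>B", "B>O")
  )
  class(out) <- c("de_result", class(out))
  attr(out, "dispersion") <- dispersion
  attr(out, "norm_factors") <- nf
  attr(out, "thresholds") <- c(fdr = fdr_threshold, lfc = lfc_threshold)
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (monotone, capped at 1).
#'
#' @param p vector of p-values in \code{[0, 1]}.
#' @return adjusted q-values.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1].")
  p.adjust(p, method = "BH")
}

#' Mann-Whitney U test fallback for low-expression genes
#'
#' Two-sided rank-sum test per gene on normalized expression values, exact
#' when group sizes are small and there are no ties, with the normal
#' approximation (tie-corrected) otherwise. Reported separately from the
#' exact-test FDR pool.
#'
#' @param expr expression tibble (`gene` + samples; e.g. TMM-scale CPM).
#' @param meta sample metadata tibble.
#' @param genes optional subset of genes to test.
#' @param group_col metadata column defining the two groups.
#' @return tibble `gene`, `statistic` (U), `p_value`.
#' @export
mann_whitney_de <- function(expr, meta, genes = NULL, group_col = "morph") {
  m <- as_counts_matrix(expr)
  meta <- check_meta(meta, samples = colnames(m))
  groups <- meta[[group_col]]
  levs <- sort(unique(groups))
  if (length(levs) != 2) abort("need exactly 2 groups.")
  if (min(table(groups)) < 3) abort("need >= 3 samples per group.")
  if (!is.null(genes)) {
    missing_g <- setdiff(genes, rownames(m))
    if (length(missing_g) > 0) {
      abort(paste0("gene(s) not found: ", paste(missing_g, collapse = ", ")))
    }
    m <- m[genes, , drop = FALSE]
  }
  res <- purrr::map(seq_len(nrow(m)), function(i) {
    x <- m[i, groups == levs[1]]
    y <- m[i, groups == levs[2]]
    if (length(unique(c(x, y))) == 1) {
      return(c(statistic = length(x) * length(y) / 2, p_value = 1))
    }
    wt <- suppressWarnings(wilcox.test(x, y, exact = NULL, correct = TRUE))
    c(statistic = unname(wt$statistic), p_value = wt$p.value)
  })
  tibble::tibble(
    gene = rownames(m),
    statistic = purrr::map_dbl(res, "statistic"),
    p_value = purrr::map_dbl(res, "p_value")
  )
}

#' Chi-square test of direction bias among DEGs
#'
#' Goodness-of-fit of the O>B / B>O DEG counts against a 50:50 split,
#' with the count ratio (max over min).
#'
#' @param de a `de_result` tibble from [de_exact_test()].
#' @return tibble `n_o_gt_b`, `n_b_gt_o`, `ratio`, `chisq`, `df`, `p_value`.
#' @export
direction_bias_test <- function(de) {
  degs <- de[de$deg, ]
  n_ob <- sum(degs$direction == "O>B")
  n_bo <- sum(degs$direction == "B>O")
  if (n_ob + n_bo == 0) {
    warn("no DEGs; direction bias undefined.")
    return(tibble::tibble(n_o_gt_b = 0L, n_b_gt_o = 0L, ratio = NA_real_,
                          chisq = NA_real_, df = 1L, p_value = NA_real_))
  }
  n <- n_ob + n_bo
  chisq <- (n_ob - n / 2)^2 / (n / 2) + (n_bo - n / 2)^2 / (n / 2)
  tibble::tibble(
    n_o_gt_b = n_ob, n_b_gt_o = n_bo,
    ratio = max(n_ob, n_bo) / max(1L, min(n_ob, n_bo)),
    chisq = chisq, df = 1L,
    p_value = pchisq(chisq, df = 1, lower.tail = FALSE)
  )
}

#' Select one representative isotig per gene
#'
#' Applies the four sample-level criteria as successive filters -- (1) CDS
#' ambiguity fraction below `max_ambiguity`, (2) more than `min_reads`
#' mapped reads, (3) the longest CDS among remaining candidates in that
#' sample, (4) the highest expression among remaining candidates -- then
#' picks the isotig present in the most samples after filtering. Ties are
#' broken by lexicographic isotig id and flagged.
#'
#' @param candidates tibble with columns `gene`, `isotig`, `sample`,
#'   `ambiguity_frac`, `mapped_reads`, `cds_length`, `expression`.
#' @param max_ambiguity ambiguity-fraction cutoff (strict `<`; default 0.20).
#' @param min_reads mapped-read cutoff (strict `>`; default 100).
#' @return tibble per gene: `gene`, `isotig`, `n_samples`, `tie`,
#'   `fallback` (TRUE when every candidate was eliminated and the
#'   pre-filter presence leader was returned).
#' @export
select_isotig <- function(candidates, max_ambiguity = 0.20, min_reads = 100) {
  need <- c("gene", "isotig", "sample", "ambiguity_frac", "mapped_reads",
            "cds_length", "expression")
  missing_cols <- setdiff(need, names(candidates))
  if (length(missing_cols) > 0) {
    abort(paste0("`candidates` missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  candidates |>
    dplyr::group_by(.data$gene) |>
    dplyr::group_modify(function(df, key) {
      kept <- dplyr::filter(df, .data$ambiguity_frac < max_ambiguity,
                            .data$mapped_reads > min_reads)
      if (nrow(kept) > 0) {
        kept <- kept |>
          dplyr::group_by(.data$sample) |>
          dplyr::filter(.data$cds_length == max(.data$cds_length)) |>
          dplyr::filter(.data$expression == max(.data$expression)) |>
          dplyr::ungroup()
      }
      fallback <- nrow(kept) == 0
      pool <- if (fallback) df else kept
      presence <- pool |>
        dplyr::count(.data$isotig, name = "n_samples") |>
        dplyr::arrange(dplyr::desc(.data$n_samples), .data$isotig)
      tie <- sum(presence$n_samples == presence$n_samples[1]) > 1
      tibble::tibble(isotig = presence$isotig[1],
                     n_samples = presence$n_samples[1],
                     tie = tie, fallback = fallback)
    }) |>
    dplyr::ungroup()
}
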