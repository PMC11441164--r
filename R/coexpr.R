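#' Kendall rank correlation with exact small-sample p-value
#'
#' Computes tau-b (tie-corrected) and a two-sided p-value: exact by
#' enumeration of the null distribution of concordances (via the classic
#' inversion-count recursion) when `n <= 8` and there are no ties, and by
#' the tie-corrected normal approximation otherwise.
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @return tibble `tau`, `p_value`, `n`, `method`; `tau` is `NA` (flagged
#'   by `method = "degenerate"`) when either vector is constant.
#' @export
kendall_tau <- function(x, y) {
  n <- length(x)
  if (length(y) != n) abort("`x` and `y` must have equal length.")
  if (n < 4) abort("need at least 4 observations.")
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    return(tibble::tibble(tau = NA_real_, p_value = NA_real_, n = n,
                          method = "degenerate"))
  }
  sgn <- function(v) sign(outer(v, v, "-"))
  sx <- sgn(x); sy <- sgn(y)
  ut <- upper.tri(sx)
  tt <- sum((sx * sy)[ut])           # C - D
  has_ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  npairs <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  denom <- sqrt((npairs - sum(tx * (tx - 1) / 2)) *
                (npairs - sum(ty * (ty - 1) / 2)))
  tau <- tt / denom

  if (!has_ties && n <= 8) {
    w <- inversion_counts(n)          # counts for 0..npairs inversions
    t_vals <- npairs - 2 * (0:npairs)
    p <- sum(w[abs(t_vals) >= abs(tt) - 1e-9]) / sum(w)
    method <- "exact"
  } else {
    xt <- as.numeric(tx); yt <- as.numeric(ty)
    v0 <- n * (n - 1) * (2 * n + 5)
    vt <- sum(xt * (xt - 1) * (2 * xt + 5))
    vu <- sum(yt * (yt - 1) * (2 * yt + 5))
    v1 <- sum(xt * (xt - 1)) * sum(yt * (yt - 1)) / (2 * n * (n - 1))
    v2 <- sum(xt * (xt - 1) * (xt - 2)) * sum(yt * (yt - 1) * (yt - 2)) /
      (9 * n * (n - 1) * (n - 2))
    vv <- (v0 - vt - vu) / 18 + v1 + v2
    p <- 2 * pnorm(-abs(tt) / sqrt(vv))
    p <- min(1, p)
    method <- "normal"
  }
  tibble::tibble(tau = tau, p_value = p, n = n, method = method)
}

# Number of permutations of 1..n with k inversions, k = 0..choose(n,2).
inversion_counts <- function(n) {
  w <- 1
  for (k in 2:n) {
    nw <- numeric(length(w) + k - 1)
    for (j in 0:(k - 1)) {
      idx <- seq_along(w) + j
      nw[idx] <- nw[idx] + w
    }
    w <- nw
  }
  w
}

#' Pairwise expression correlations within species
#'
#' All pairwise Kendall correlations among a gene set, computed separately
#' within each species on normalized expression values. Significance is
#' declared at `p <= alpha` (the threshold interpretation of a
#' "Bonferroni corrected p-value of 0.001"); set `divide_alpha = TRUE` to
#' use `alpha / n_pairs` instead. Every pair is reported.
#'
#' @param expr expression tibble (`gene` + samples; TMM-scale CPM).
#' @param meta sample metadata tibble.
#' @param genes gene ids to correlate (>= 2; all must be present).
#' @param species optional species subset (default: all in `meta`).
#' @param alpha significance threshold on the p-value.
#' @param divide_alpha divide `alpha` by the number of pairs.
#' @return tibble `species`, `gene1`, `gene2`, `n`, `tau`, `p_value`,
#'   `significant`.
#' @export
correlate_expression <- function(expr, meta, genes, species = NULL,
                                 alpha = 0.001, divide_alpha = FALSE) {
  m <- as_counts_matrix(expr)
  meta <- check_meta(meta, samples = colnames(m))
  missing_g <- setdiff(genes, rownames(m))
  if (length(missing_g) > 0) {
    abort(paste0("gene(s) absent from expression matrix: ",
                 paste(missing_g, collapse = ", ")))
  }
  if (length(genes) < 2) {
    return(tibble::tibble(species = character(), gene1 = character(),
                          gene2 = character(), n = integer(), tau = numeric(),
                          p_value = numeric(), significant = logical()))
  }
  if (is.null(species)) species <- unique(meta$species)
  pairs <- combn(sort(genes), 2, simplify = FALSE)
  thr <- if (divide_alpha) alpha / length(pairs) else alpha
  purrr::map(species, function(sp) {
    cols <- meta$sample[meta$species == sp]
    purrr::map(pairs, function(pr) {
      kt <- kendall_tau(m[pr[1], cols], m[pr[2], cols])
      tibble::tibble(species = sp, gene1 = pr[1], gene2 = pr[2],
                     n = kt$n, tau = kt$tau, p_value = kt$p_value,
                     significant = !is.na(kt$p_value) & kt$p_value <= thr)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
}
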