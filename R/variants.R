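#' Per-column allele frequencies by group
#'
#' Counts bases per alignment column within each group, over samples with
#' an unambiguous call (not `N`, not `-`; other IUPAC ambiguity codes are
#' treated as `N`). Columns with fewer than 2 unambiguous samples in any
#' group are flagged uncallable.
#'
#' @param aln a [coding_alignment()].
#' @param grouping `"morph"` (color) or `"species"`.
#' @return tibble: `column`, `group`, `A`, `C`, `G`, `T`, `n_unambiguous`,
#'   `callable` (per column, TRUE when every group has >= 2 unambiguous
#'   calls).
#' @export
site_allele_frequencies <- function(aln, grouping = c("morph", "species")) {
  grouping <- match.arg(grouping)
  mat <- alignment_matrix(aln)
  groups <- aln$meta[[grouping]]
  if (any(table(groups) == 0)) abort("empty group.")
  levs <- sort(unique(groups))
  bases <- c("A", "C", "G", "T")
  out <- purrr::map(levs, function(g) {
    sub <- mat[groups == g, , drop = FALSE]
    cnt <- vapply(bases, function(b) colSums(sub == b), numeric(ncol(sub)))
    tibble::tibble(column = seq_len(ncol(sub)), group = g,
                   A = cnt[, "A"], C = cnt[, "C"], G = cnt[, "G"],
                   T = cnt[, "T"],
                   n_unambiguous = rowSums(cnt))
  }) |> dplyr::bind_rows()
  callable <- out |>
    dplyr::group_by(.data$column) |>
    dplyr::summarise(callable = all(.data$n_unambiguous >= 2), .groups = "drop")
  dplyr::left_join(out, callable, by = "column") |>
    dplyr::arrange(.data$column, .data$group)
}

# Majority (modal) unambiguous base per column; NA when no unambiguous call.
majority_bases <- function(mat) {
  bases <- c("A", "C", "G", "T")
  cnt <- vapply(bases, function(b) colSums(mat == b), numeric(ncol(mat)))
  idx <- max.col(cnt, ties.method = "first")
  out <- bases[idx]
  out[rowSums(cnt) == 0] <- NA_character_
  out
}

#' Classify the coding effect of a substitution
#'
#' Translates the majority codon containing `column` with and without the
#' alternate base substituted, using the standard genetic code.
#'
#' @param aln a [coding_alignment()].
#' @param column 1-based alignment column.
#' @param alt alternate base.
#' @return list with `effect` (`"synonymous"`/`"nonsynonymous"`),
#'   `nonsense` (TRUE when the alternate codon is a stop), `ref_codon`,
#'   `alt_codon`, `codon` (1-based codon index), or `NULL` when the codon
#'   is uncallable (contains a gap or `N` in the majority background).
#' @export
classify_snp_effect <- function(aln, column, alt) {
  mat <- alignment_matrix(aln)
  maj <- majority_bases(mat)
  pos_in_cds <- column - aln$offset
  if (pos_in_cds < 1) abort("column precedes the reading frame offset.")
  codon_idx <- (pos_in_cds - 1) %/% 3 + 1
  cols <- aln$offset + (codon_idx - 1) * 3 + 1:3
  codon <- maj[cols]
  if (anyNA(codon)) return(NULL)
  ref_codon <- paste(codon, collapse = "")
  within <- pos_in_cds - (codon_idx - 1) * 3
  alt_codon <- ref_codon
  substr(alt_codon, within, within) <- alt
  ref_aa <- translate_codon(ref_codon)
  alt_aa <- translate_codon(alt_codon)
  if (ref_aa == "X" || alt_aa == "X") return(NULL)
  list(
    effect = if (ref_aa == alt_aa) "synonymous" else "nonsynonymous",
    nonsense = alt_aa == "*",
    ref_codon = ref_codon, alt_codon = alt_codon, codon = codon_idx
  )
}

# Shared engine for the frequency-difference SNP callers.
call_differentiating_snps <- function(aln, grouping, cutoff) {
  mat <- alignment_matrix(aln)
  groups <- aln$meta[[grouping]]
  levs <- sort(unique(groups))
  if (length(levs) != 2) abort(sprintf("need exactly 2 %s groups.", grouping))
  bases <- c("A", "C", "G", "T")
  maj <- majority_bases(mat)

  cnt <- lapply(levs, function(g) {
    sub <- mat[groups == g, , drop = FALSE]
    vapply(bases, function(b) colSums(sub == b), numeric(ncol(sub)))
  })
  names(cnt) <- levs
  n1 <- rowSums(cnt[[1]]); n2 <- rowSums(cnt[[2]])
  callable_col <- n1 >= 2 & n2 >= 2

  recs <- list()
  for (col in which(callable_col)) {
    ref <- maj[col]
    if (is.na(ref)) next
    for (alt in setdiff(bases, ref)) {
      f1 <- cnt[[1]][col, alt] / n1[col]
      f2 <- cnt[[2]][col, alt] / n2[col]
      if (f1 == 0 && f2 == 0) next
      diff <- abs(f2 - f1)
      if (diff >= cutoff) {
        eff <- classify_snp_effect(aln, col, alt)
        recs[[length(recs) + 1]] <- tibble::tibble(
          gene = aln$gene, column = col,
          codon = if (is.null(eff)) NA_integer_ else eff$codon,
          ref = ref, alt = alt,
          effect = if (is.null(eff)) "uncallable" else eff$effect,
          nonsense = if (is.null(eff)) NA else eff$nonsense,
          freq_1 = f1, freq_2 = f2, freq_diff = diff
        )
      }
    }
  }
  out <- if (length(recs) == 0) {
    tibble::tibble(gene = character(), column = integer(), codon = integer(),
                   ref = character(), alt = character(), effect = character(),
                   nonsense = logical(), freq_1 = numeric(), freq_2 = numeric(),
                   freq_diff = numeric())
  } else {
    dplyr::bind_rows(recs)
  }
  names(out)[names(out) == "freq_1"] <- paste0("freq_", levs[1])
  names(out)[names(out) == "freq_2"] <- paste0("freq_", levs[2])
  attr(out, "n_callable_codons") <- sum(tapply(callable_col,
    (seq_along(callable_col) - aln$offset - 1) %/% 3, all), na.rm = TRUE)
  out
}

#' Color-differentiating SNPs
#'
#' Columns where the absolute alternate-allele frequency difference between
#' the blue and orange groups is at least `cutoff` (inclusive; frequencies
#' over unambiguous calls only), with codon-aware effect classification.
#' The per-gene nonsynonymous SNP rate (NS count over callable codons) is
#' attached as attribute `ns_rate`.
#'
#' @param aln a [coding_alignment()].
#' @param cutoff frequency-difference cutoff (default 0.75).
#' @return tibble of SNP records with `class = "color"`.
#' @export
color_differentiating_snps <- function(aln, cutoff = 0.75) {
  out <- call_differentiating_snps(aln, "morph", cutoff)
  out$class <- rep("color", nrow(out))
  n_codons <- attr(out, "n_callable_codons")
  attr(out, "ns_rate") <- if (n_codons > 0) {
    sum(out$effect == "nonsynonymous") / n_codons
  } else {
    NA_real_
  }
  out
}

#' Species-differentiating SNPs
#'
#' Same frequency-difference rule as [color_differentiating_snps()] with
#' samples grouped by species.
#'
#' @inheritParams color_differentiating_snps
#' @return tibble of SNP records with `class = "species"`.
#' @export
species_differentiating_snps <- function(aln, cutoff = 0.75) {
  out <- call_differentiating_snps(aln, "species", cutoff)
  out$class <- rep("species", nrow(out))
  out
}

#' Completely fixed color differences
#'
#' Columns where every unambiguous blue sample of both species carries one
#' base and every unambiguous orange sample carries another.
#'
#' @param aln a [coding_alignment()] containing all four species x morph
#'   cells.
#' @return tibble of SNP records with `class = "fixed-color"`.
#' @export
fixed_color_differences <- function(aln) {
  cells <- dplyr::distinct(aln$meta, .data$species, .data$morph)
  if (nrow(cells) < 4) abort("all four species x morph cells must be present.")
  mat <- alignment_matrix(aln)
  morph <- aln$meta$morph
  bases <- c("A", "C", "G", "T")
  blue <- mat[morph == "blue", , drop = FALSE]
  orange <- mat[morph == "orange", , drop = FALSE]
  one_base <- function(sub, col) {
    x <- sub[, col]
    x <- x[x %in% bases]
    if (length(x) < 2) return(NA_character_)
    u <- unique(x)
    if (length(u) == 1) u else NA_character_
  }
  recs <- list()
  for (col in seq_len(ncol(mat))) {
    b <- one_base(blue, col)
    o <- one_base(orange, col)
    if (is.na(b) || is.na(o) || b == o) next
    eff <- classify_snp_effect(aln, col, o)
    recs[[length(recs) + 1]] <- tibble::tibble(
      gene = aln$gene, column = col,
      codon = if (is.null(eff)) NA_integer_ else eff$codon,
      ref = b, alt = o,
      effect = if (is.null(eff)) "uncallable" else eff$effect,
      nonsense = if (is.null(eff)) NA else eff$nonsense,
      freq_blue = 0, freq_orange = 1, freq_diff = 1,
      class = "fixed-color"
    )
  }
  if (length(recs) == 0) {
    return(tibble::tibble(gene = character(), column = integer(),
                          codon = integer(), ref = character(),
                          alt = character(), effect = character(),
                          nonsense = logical(), freq_blue = numeric(),
                          freq_orange = numeric(), freq_diff = numeric(),
                          class = character()))
  }
  dplyr::bind_rows(recs)
}
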