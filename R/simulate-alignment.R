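#' Simulate an in-frame coding alignment with planted SNPs
#'
#' Builds an ancestral coding sequence free of internal stop codons, then
#' plants single-base substitutions at disjoint codon sites: color
#' nonsynonymous sites (alternate base carried by every orange sample, amino
#' acid changed), color synonymous sites (alternate base carried by orange,
#' amino acid preserved) and species nonsynonymous sites (alternate base
#' carried by every species-B sample). Ambiguity (`N`) is applied after
#' planting, uniformly at random over sample-by-position cells.
#'
#' @param meta sample metadata tibble (`sample`, `species`, `morph`)
#'   covering both species and both morphs.
#' @param gene gene id for the alignment and truth records.
#' @param length_codons alignment length in codons.
#' @param n_color_ns number of planted color-differentiating nonsynonymous
#'   sites.
#' @param n_color_syn number of planted color-differentiating synonymous
#'   sites.
#' @param n_species_ns number of planted species-differentiating
#'   nonsynonymous sites.
#' @param ambiguity_rate fraction of sample-site base calls replaced by `N`.
#' @param shared_color_snps if TRUE (default) the color sites are shared by
#'   both species (orange samples of both species carry the alternate); if
#'   FALSE each species receives its own private set of `n_color_ns` color
#'   nonsynonymous sites, emulating convergent origins.
#' @param seed integer seed.
#'
#' @return list with `alignment` (a [coding_alignment()]) and `truth`
#'   (tibble: `gene`, `codon`, `column` 1-based nucleotide column, `ref`,
#'   `alt`, `effect`, `class`, `species`).
#' @export
simulate_alignment <- function(meta,
                               gene = "DFR2",
                               length_codons = 150,
                               n_color_ns = 13,
                               n_color_syn = 0,
                               n_species_ns = 0,
                               ambiguity_rate = 0,
                               shared_color_snps = TRUE,
                               seed = NULL) {
  meta <- check_meta(meta)
  if (ambiguity_rate < 0 || ambiguity_rate >= 1) {
    abort("`ambiguity_rate` must be in [0, 1).")
  }
  n_color_sets <- if (shared_color_snps) 1L else 2L
  n_sites <- n_color_ns * n_color_sets + n_color_syn + n_species_ns
  if (n_sites > length_codons) {
    abort("planted SNP counts exceed available codon sites.")
  }

  bases <- c("A", "C", "G", "T")
  non_stop <- names(GENETIC_CODE_STD)[GENETIC_CODE_STD != "*"]

  # All single-base substitutions of a codon, annotated with effect.
  codon_subs <- function(codon) {
    ref_aa <- GENETIC_CODE_STD[[codon]]
    out <- list()
    for (pos in 1:3) {
      for (alt in setdiff(bases, substr(codon, pos, pos))) {
        new <- codon
        substr(new, pos, pos) <- alt
        new_aa <- GENETIC_CODE_STD[[new]]
        if (new_aa == "*") next  # never plant nonsense changes
        out[[length(out) + 1]] <- list(
          pos = pos, ref = substr(codon, pos, pos), alt = alt,
          effect = if (new_aa == ref_aa) "synonymous" else "nonsynonymous",
          new_codon = new
        )
      }
    }
    out
  }

  with_seed(seed, {
    anc <- sample(non_stop, length_codons, replace = TRUE)
    sites <- sample.int(length_codons, n_sites)
    classes <- c(
      rep("color_ns", n_color_ns * n_color_sets),
      rep("color_syn", n_color_syn),
      rep("species_ns", n_species_ns)
    )
    site_species <- rep(NA_character_, n_sites)
    if (!shared_color_snps && n_color_ns > 0) {
      site_species[seq_len(2 * n_color_ns)] <- rep(c("A", "B"), each = n_color_ns)
    }

    seq_mat <- matrix(rep(anc, each = nrow(meta)), nrow = nrow(meta),
                      dimnames = list(meta$sample, NULL))
    truth <- vector("list", n_sites)
    for (k in seq_len(n_sites)) {
      want <- if (classes[k] == "color_syn") "synonymous" else "nonsynonymous"
      # resample the ancestral codon until it offers a substitution of the
      # wanted effect (e.g. ATG/TGG have no synonymous neighbour)
      repeat {
        subs <- codon_subs(anc[sites[k]])
        subs <- subs[vapply(subs, function(s) s$effect == want, logical(1))]
        if (length(subs) > 0) break
        anc[sites[k]] <- sample(non_stop, 1)
        seq_mat[, sites[k]] <- anc[sites[k]]
      }
      ch <- subs[[sample.int(length(subs), 1)]]
      carriers <- switch(
        classes[k],
        color_ns = ,
        color_syn = if (is.na(site_species[k])) {
          meta$morph == "orange"
        } else {
          meta$morph == "orange" & meta$species == site_species[k]
        },
        species_ns = meta$species == "B"
      )
      seq_mat[carriers, sites[k]] <- ch$new_codon
      truth[[k]] <- tibble::tibble(
        gene = gene,
        codon = sites[k],
        column = (sites[k] - 1) * 3 + ch$pos,
        ref = ch$ref, alt = ch$alt,
        effect = ch$effect,
        class = if (classes[k] == "species_ns") "species" else "color",
        species = site_species[k]
      )
    }

    seqs <- apply(seq_mat, 1, paste, collapse = "")
    if (ambiguity_rate > 0) {
      nt <- nchar(seqs[[1]])
      for (i in seq_along(seqs)) {
        hit <- which(runif(nt) < ambiguity_rate)
        if (length(hit) > 0) {
          s <- strsplit(seqs[[i]], "")[[1]]
          s[hit] <- "N"
          seqs[[i]] <- paste(s, collapse = "")
        }
      }
    }

    truth <- if (n_sites == 0) {
      tibble::tibble(gene = character(), codon = integer(), column = numeric(),
                     ref = character(), alt = character(), effect = character(),
                     class = character(), species = character())
    } else {
      dplyr::arrange(dplyr::bind_rows(truth), .data$column)
    }
    list(alignment = coding_alignment(gene, seqs, meta), truth = truth)
  })
}
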