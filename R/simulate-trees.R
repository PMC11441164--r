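#' Simulate a labeled gene tree under one of four evolutionary hypotheses
#'
#' Builds a Newick topology from the template implied by each hypothesis for
#' a color locus, with tips named `species_morph_nn`, uniform random branch
#' lengths and bootstrap supports of 100 on internal nodes:
#' * `convergence`: each species forms a clade containing its own blue and
#'   orange tips, so orange tips of the two species are not jointly
#'   monophyletic.
#' * `introgression` / `ancestral_polymorphism`: the orange tips of both
#'   species form a single clade.
#' * `non_monophyly`: the same cross-species orange clade, arising because
#'   the species themselves are not reciprocally monophyletic (this
#'   topology applies to all loci, not just color loci).
#'
#' @param hypothesis one of `convergence`, `introgression`,
#'   `ancestral_polymorphism`, `non_monophyly`.
#' @param n_tips_per_cell tips per (species, morph) cell (>= 2).
#' @param seed integer seed; a fixed seed gives an identical Newick string.
#' @return an `ape::phylo` tree with `node.label` bootstrap supports.
#' @export
simulate_tree <- function(hypothesis = c("convergence", "introgression",
                                         "ancestral_polymorphism",
                                         "non_monophyly"),
                          n_tips_per_cell = 3,
                          seed = NULL) {
  hypothesis <- match.arg(hypothesis)
  if (n_tips_per_cell < 2) abort("`n_tips_per_cell` must be >= 2.")
  template <- if (hypothesis == "convergence") "species" else "orange_clade"
  simulate_topology(template, n_tips_per_cell, seed)
}

# template: "species" = ((A_blue, A_orange), (B_blue, B_orange));
# "orange_clade" = ((A_blue, (A_orange, B_orange)), B_blue)
simulate_topology <- function(template, n_tips_per_cell, seed = NULL) {
  cell_tips <- function(species, morph) {
    sprintf("%s_%s_%02d", species, morph, seq_len(n_tips_per_cell))
  }
  with_seed(seed, {
    bl <- function() sprintf("%.4f", runif(1, 0.01, 0.1))
    ladder <- function(tips) {
      out <- sprintf("%s:%s", tips[1], bl())
      for (t in tips[-1]) {
        out <- sprintf("(%s:%s,%s)100:%s", t, bl(), out, bl())
      }
      out
    }
    cl <- list(
      Ab = ladder(cell_tips("A", "blue")),
      Ao = ladder(cell_tips("A", "orange")),
      Bb = ladder(cell_tips("B", "blue")),
      Bo = ladder(cell_tips("B", "orange"))
    )
    nwk <- if (template == "species") {
      sprintf("((%s,%s)100:%s,(%s,%s)100:%s);",
              cl$Ab, cl$Ao, bl(), cl$Bb, cl$Bo, bl())
    } else {
      sprintf("((%s,(%s,%s)100:%s)100:%s,%s);",
              cl$Ab, cl$Ao, cl$Bo, bl(), bl(), cl$Bb)
    }
    ape::read.tree(text = nwk)
  })
}

#' Simulate the full set of gene trees plus a combined tree for a scenario
#'
#' Color loci follow the hypothesis-specific topology from
#' [simulate_tree()]; non-color loci and the combined (all-loci) tree follow
#' the species topology except under `non_monophyly`, where every locus and
#' the combined tree show the cross-species orange clade.
#'
#' @inheritParams simulate_tree
#' @param genes character vector of gene ids.
#' @param color_genes subset of `genes` treated as color loci.
#' @return list with `gene_trees` (named list of `phylo`) and `combined`
#'   (`phylo`).
#' @export
simulate_scenario_trees <- function(hypothesis,
                                    genes = c("DFR2", "BZ12", "F3pH", "ANS"),
                                    color_genes = c("DFR2", "BZ12"),
                                    n_tips_per_cell = 3,
                                    seed = NULL) {
  hypothesis <- match.arg(hypothesis, c("convergence", "introgression",
                                        "ancestral_polymorphism",
                                        "non_monophyly"))
  with_seed(seed, {
    gene_trees <- purrr::map(setNames(genes, genes), function(g) {
      template <- if (hypothesis == "non_monophyly") {
        "orange_clade"
      } else if (g %in% color_genes) {
        if (hypothesis == "convergence") "species" else "orange_clade"
      } else {
        "species"
      }
      simulate_topology(template, n_tips_per_cell)
    })
    combined_template <- if (hypothesis == "non_monophyly") "orange_clade" else "species"
    combined <- simulate_topology(combined_template, n_tips_per_cell)
    list(gene_trees = gene_trees, combined = combined)
  })
}
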