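#' Construct an evidence profile for the four hypotheses
#'
#' Six tri-state evidence fields (TRUE / FALSE / NA for unknown) feeding
#' the rule table in [score_hypotheses()].
#'
#' @param orange_monophyly_color_genes are the orange samples of both
#'   species monophyletic at the color gene(s)?
#' @param species_monophyly_combined are the species reciprocally
#'   monophyletic in the combined (all-loci) tree?
#' @param within_species_color_monophyly are the color morphs monophyletic
#'   within each species?
#' @param interspecific_fertility did interspecific crosses produce any
#'   fruit?
#' @param shared_color_ns_snps are the color-differentiating nonsynonymous
#'   SNP sets of the focal gene(s) identical across the two species?
#' @param shared_expression_pattern are the focal genes differentially
#'   expressed in the same direction in both species?
#' @return a named logical vector of class `evidence_profile`.
#' @export
evidence_profile <- function(orange_monophyly_color_genes = NA,
                             species_monophyly_combined = NA,
                             within_species_color_monophyly = NA,
                             interspecific_fertility = NA,
                             shared_color_ns_snps = NA,
                             shared_expression_pattern = NA) {
  out <- c(
    orange_monophyly_color_genes = orange_monophyly_color_genes,
    species_monophyly_combined = species_monophyly_combined,
    within_species_color_monophyly = within_species_color_monophyly,
    interspecific_fertility = interspecific_fertility,
    shared_color_ns_snps = shared_color_ns_snps,
    shared_expression_pattern = shared_expression_pattern
  )
  if (!is.logical(out)) abort("evidence fields must be logical (TRUE/FALSE/NA).")
  class(out) <- "evidence_profile"
  out
}

# requirement table: each hypothesis requires the named fields to have the
# given values; a contradicted requirement marks the hypothesis
# inconsistent, an unknown one (unless already inconsistent) indeterminate.
hypothesis_rules <- function() {
  list(
    convergence = c(orange_monophyly_color_genes = FALSE,
                    shared_color_ns_snps = FALSE),
    introgression = c(orange_monophyly_color_genes = TRUE,
                      interspecific_fertility = TRUE),
    ancestral_polymorphism = c(orange_monophyly_color_genes = TRUE,
                               species_monophyly_combined = TRUE),
    non_monophyly = c(orange_monophyly_color_genes = TRUE,
                      species_monophyly_combined = FALSE)
  )
}

#' Score the four evolutionary hypotheses against an evidence profile
#'
#' Applies the rule table: convergence requires separate orange origins (no
#' cross-species orange monophyly at color genes and no shared color NS
#' SNP set); introgression requires the cross-species orange clade plus
#' interspecific fertility; ancestral polymorphism requires the orange
#' clade plus reciprocally monophyletic species in the combined tree;
#' species non-monophyly requires the orange clade at all loci, i.e. with
#' the combined tree not recovering species monophyly. Any requirement
#' contradicted by the evidence makes the hypothesis `inconsistent`; an
#' unknown requirement (without a contradiction) makes it `indeterminate`;
#' otherwise it is `consistent`.
#'
#' @param profile an [evidence_profile()].
#' @return tibble `hypothesis`, `verdict`, `triggers` (list column of the
#'   violated or unknown evidence fields).
#' @export
score_hypotheses <- function(profile) {
  if (!inherits(profile, "evidence_profile")) {
    profile <- do.call(evidence_profile, as.list(profile))
  }
  purrr::imap(hypothesis_rules(), function(req, hyp) {
    vals <- unclass(profile)[names(req)]
    violated <- !is.na(vals) & vals != req
    unknown <- is.na(vals)
    verdict <- if (any(violated)) {
      "inconsistent"
    } else if (any(unknown)) {
      "indeterminate"
    } else {
      "consistent"
    }
    triggers <- names(req)[if (any(violated)) violated else unknown]
    tibble::tibble(hypothesis = hyp, verdict = verdict,
                   triggers = list(triggers))
  }) |> dplyr::bind_rows()
}

#' Build an evidence profile from module outputs
#'
#' Aggregates the phylogenetic evidence table, per-species differential
#' expression results, per-species color SNP reports and a crossing summary
#' into the six tri-state evidence fields. A missing (`NULL`) input leaves
#' the corresponding field(s) unknown.
#'
#' @param phylo_evidence output of [topology_evidence()].
#' @param de_by_species named list (species -> `de_result`) of
#'   within-species blue/orange DE tables.
#' @param snps_by_species named list (species -> named list of per-gene SNP
#'   tibbles from [color_differentiating_snps()]).
#' @param crosses crossing summary tibble with columns `type`
#'   (`"interspecific"`/`"intraspecific"`), `n_pollinations`, `n_fruits`.
#' @param focal_genes genes expected to drive the color shift (must appear
#'   in the DE tables and SNP reports).
#' @return an [evidence_profile()].
#' @export
build_evidence <- function(phylo_evidence = NULL, de_by_species = NULL,
                           snps_by_species = NULL, crosses = NULL,
                           focal_genes = c("DFR2", "BZ12")) {
  orange_mono <- species_mono <- within_color <- NA
  if (!is.null(phylo_evidence)) {
    focal <- phylo_evidence[phylo_evidence$tree %in% focal_genes &
                              phylo_evidence$query == "orange_cross_species", ]
    if (nrow(focal) > 0) {
      orange_mono <- all(focal$is_monophyletic & focal$supported)
    }
    comb_sp <- phylo_evidence[phylo_evidence$tree == "combined" &
                                grepl("^species_", phylo_evidence$query), ]
    if (nrow(comb_sp) > 0) {
      species_mono <- all(comb_sp$is_monophyletic & comb_sp$supported)
    }
    comb_col <- phylo_evidence[phylo_evidence$tree == "combined" &
                                 grepl("within_", phylo_evidence$query), ]
    if (nrow(comb_col) > 0) {
      within_color <- all(comb_col$is_monophyletic)
    }
  }

  fertility <- NA
  if (!is.null(crosses)) {
    inter <- crosses[crosses$type == "interspecific", ]
    if (nrow(inter) > 0) fertility <- sum(inter$n_fruits) > 0
  }

  shared_snps <- NA
  if (!is.null(snps_by_species) && length(snps_by_species) == 2) {
    shared_snps <- all(vapply(focal_genes, function(g) {
      keys <- lapply(snps_by_species, function(sp) {
        snp <- sp[[g]]
        if (is.null(snp)) return(NULL)
        ns <- snp[snp$effect == "nonsynonymous", ]
        sort(paste(ns$column, ns$alt))
      })
      if (any(vapply(keys, is.null, logical(1)))) return(NA)
      identical(keys[[1]], keys[[2]])
    }, logical(1)))
  }

  shared_expr <- NA
  if (!is.null(de_by_species) && length(de_by_species) == 2) {
    shared_expr <- all(vapply(focal_genes, function(g) {
      rows <- lapply(de_by_species, function(de) de[de$gene == g, ])
      if (any(vapply(rows, nrow, integer(1)) == 0)) return(NA)
      all(vapply(rows, function(r) r$deg, logical(1))) &&
        length(unique(vapply(rows, function(r) r$direction, character(1)))) == 1
    }, logical(1)))
  }

  evidence_profile(
    orange_monophyly_color_genes = orange_mono,
    species_monophyly_combined = species_mono,
    within_species_color_monophyly = within_color,
    interspecific_fertility = fertility,
    shared_color_ns_snps = shared_snps,
    shared_expression_pattern = shared_expr
  )
}
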