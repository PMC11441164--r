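#' Read a Newick tree with bootstrap supports and tip labels
#'
#' Parses a Newick string or file with `ape`, keeping internal-node labels
#' as bootstrap supports, and joins tip metadata either from `meta` or from
#' the `species_morph_nn` tip-naming convention.
#'
#' @param source a file path or a Newick string (detected by the presence
#'   of a parenthesis).
#' @param meta optional tip metadata tibble (`sample`, `species`, `morph`);
#'   every tip must be covered.
#' @return an `ape::phylo` with attribute `tip_meta`.
#' @export
read_labeled_tree <- function(source, meta = NULL) {
  tree <- suppressWarnings(
    if (grepl("(", source, fixed = TRUE)) {
      tryCatch(ape::read.tree(text = source), error = function(e) NULL)
    } else {
      tryCatch(ape::read.tree(source), error = function(e) NULL)
    }
  )
  if (is.null(tree)) abort("malformed Newick input.")
  if (is.null(meta)) {
    meta <- parse_sample_labels(tree$tip.label)
  } else {
    meta <- check_meta(meta, samples = tree$tip.label)
  }
  attr(tree, "tip_meta") <- meta
  tree
}

tree_tip_meta <- function(tree) {
  meta <- attr(tree, "tip_meta")
  if (is.null(meta)) meta <- parse_sample_labels(tree$tip.label)
  meta
}

node_support <- function(tree, node) {
  if (is.null(tree$node.label)) return(NA_real_)
  lbl <- tree$node.label[node - ape::Ntip(tree)]
  suppressWarnings(as.numeric(lbl))
}

# Tip-index sets descending from every internal node of a rooted tree.
node_descendants <- function(tree) {
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  desc <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) desc[[i]] <- i
  # postorder guarantees children are visited before parents
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(edge))) {
    parent <- edge[i, 1]; child <- edge[i, 2]
    desc[[parent]] <- c(desc[[parent]], desc[[child]])
  }
  desc
}

#' Test monophyly of a tip set with bootstrap gating
#'
#' With an outgroup the tree is rooted on it and the query is monophyletic
#' when some node's descendant tips equal it exactly (rooted-clade method);
#' without one, the query is monophyletic when some bipartition of the
#' unrooted tree separates exactly the query from the remaining tips
#' (unrooted-bipartition method). A polytomy whose descendants equal the
#' query counts. The clade is "supported" when its node's bootstrap value
#' is at least `min_support`.
#'
#' @param tree an `ape::phylo`.
#' @param tips character vector of queried tip labels (nonempty subset).
#' @param min_support bootstrap threshold (default 0; the reporting
#'   convention in this literature is 70).
#' @param outgroup optional tip label(s) to root on.
#' @return tibble `is_monophyletic`, `support`, `supported`, `method`,
#'   `degenerate` (TRUE when the query covers all tips).
#' @export
is_monophyletic <- function(tree, tips, min_support = 0, outgroup = NULL) {
  if (length(tips) == 0) abort("`tips` must be nonempty.")
  missing_t <- setdiff(tips, tree$tip.label)
  if (length(missing_t) > 0) {
    abort(paste0("tip(s) not in tree: ", paste(missing_t, collapse = ", ")))
  }
  ntip <- ape::Ntip(tree)
  if (length(unique(tips)) == ntip) {
    return(tibble::tibble(is_monophyletic = TRUE, support = NA_real_,
                          supported = NA, method = "degenerate",
                          degenerate = TRUE))
  }
  if (!is.null(outgroup)) {
    if (any(outgroup %in% tips)) {
      abort("outgroup must be disjoint from the queried tips.")
    }
    work <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
    method <- "rooted-clade"
    complement_ok <- FALSE
  } else {
    work <- tree
    method <- "unrooted-bipartition"
    complement_ok <- TRUE
  }
  query <- sort(match(tips, work$tip.label))
  desc <- node_descendants(work)
  found_node <- NA_integer_
  for (node in (ape::Ntip(work) + 1):(ape::Ntip(work) + work$Nnode)) {
    dn <- sort(desc[[node]])
    if (identical(dn, query)) {
      found_node <- node
      break
    }
    if (complement_ok &&
        identical(dn, sort(setdiff(seq_len(ape::Ntip(work)), query)))) {
      found_node <- node
      break
    }
  }
  mono <- !is.na(found_node)
  sup <- if (mono) node_support(work, found_node) else NA_real_
  tibble::tibble(
    is_monophyletic = mono,
    support = sup,
    supported = if (mono) !is.na(sup) && sup >= min_support else NA,
    method = method,
    degenerate = FALSE
  )
}

#' Topological evidence table for the hypothesis rules
#'
#' For each gene tree: is the cross-species orange tip set monophyletic,
#' and are the orange tips within each species monophyletic. For the
#' combined tree: are the two species reciprocally monophyletic, and are
#' the color morphs monophyletic within each species. All queries carry
#' their supporting-node bootstrap and a `supported` flag at
#' `min_support`.
#'
#' @param gene_trees named list of `ape::phylo` gene trees.
#' @param combined the combined (all-loci) `ape::phylo` tree.
#' @param min_support bootstrap gate (default 70, the reporting
#'   convention).
#' @return tibble `tree` (gene id or `"combined"`), `query`,
#'   `is_monophyletic`, `support`, `supported`.
#' @export
topology_evidence <- function(gene_trees, combined, min_support = 70) {
  eval_query <- function(tree, label, query_tips, query_name) {
    r <- is_monophyletic(tree, query_tips, min_support = min_support)
    tibble::tibble(tree = label, query = query_name,
                   is_monophyletic = r$is_monophyletic,
                   support = r$support, supported = r$supported)
  }
  per_gene <- purrr::imap(gene_trees, function(tr, g) {
    meta <- tree_tip_meta(tr)
    dplyr::bind_rows(
      eval_query(tr, g, meta$sample[meta$morph == "orange"],
                 "orange_cross_species"),
      purrr::map(unique(meta$species), function(sp) {
        eval_query(tr, g,
                   meta$sample[meta$morph == "orange" & meta$species == sp],
                   paste0("orange_within_", sp))
      }) |> dplyr::bind_rows()
    )
  }) |> dplyr::bind_rows()

  meta_c <- tree_tip_meta(combined)
  comb <- dplyr::bind_rows(
    purrr::map(unique(meta_c$species), function(sp) {
      eval_query(combined, "combined", meta_c$sample[meta_c$species == sp],
                 paste0("species_", sp))
    }) |> dplyr::bind_rows(),
    purrr::map(unique(meta_c$species), function(sp) {
      purrr::map(unique(meta_c$morph), function(mo) {
        eval_query(combined, "combined",
                   meta_c$sample[meta_c$species == sp & meta_c$morph == mo],
                   paste0(mo, "_within_", sp))
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
  )
  dplyr::bind_rows(per_gene, comb)
}
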