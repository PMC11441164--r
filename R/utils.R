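#' @importFrom rlang %||% .data abort warn
#' @importFrom stats aggregate dnbinom dpois median pchisq pnorm quantile
#'   rbinom rnbinom rnorm rpois runif sd setNames var wilcox.test glm.fit
#'   binomial p.adjust complete.cases
#' @importFrom utils combn head
NULL

# Evaluate expr with a temporary RNG state. The caller's .Random.seed is
# restored afterwards so generators are pure functions of their arguments.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number or NULL.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Coerce a counts input (tibble with `gene` column, data.frame, or matrix)
# to an integer-like matrix with gene rownames.
as_counts_matrix <- function(counts) {
  if (is.matrix(counts)) {
    if (is.null(rownames(counts))) {
      rownames(counts) <- paste0("gene", seq_len(nrow(counts)))
    }
    return(counts)
  }
  if (!is.data.frame(counts)) {
    abort("`counts` must be a data frame with a `gene` column or a matrix.")
  }
  if (!"gene" %in% names(counts)) {
    abort("`counts` data frame must contain a `gene` column.")
  }
  m <- as.matrix(counts[setdiff(names(counts), "gene")])
  rownames(m) <- counts$gene
  storage.mode(m) <- "double"
  m
}

counts_as_tibble <- function(m) {
  tibble::as_tibble(as.data.frame(m), rownames = "gene")
}

check_meta <- function(meta, samples = NULL) {
  need <- c("sample", "species", "morph")
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols) > 0) {
    abort(paste0("`meta` is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!is.null(samples)) {
    unmatched <- setdiff(samples, meta$sample)
    if (length(unmatched) > 0) {
      abort(paste0("samples absent from `meta`: ",
                   paste(head(unmatched, 5), collapse = ", ")))
    }
    meta <- meta[match(samples, meta$sample), , drop = FALSE]
  }
  meta
}

gaussian_bump <- function(x, center, width) {
  exp(-0.5 * ((x - center) / width)^2)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
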