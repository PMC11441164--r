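#' Construct a per-gene coding alignment
#'
#' A light container for an in-frame coding-sequence alignment of per-sample
#' consensus sequences, with the (species, morph) labels used by the SNP
#' callers.
#'
#' @param gene gene identifier.
#' @param seqs named character vector of aligned sequences over
#'   `A,C,G,T,N,-` (names are sample ids), all the same length.
#' @param meta sample metadata tibble with columns `sample`, `species`,
#'   `morph`; must cover every sequence.
#' @param offset reading-frame offset in nucleotides (default 0).
#'
#' @return An object of class `coding_alignment`.
#' @export
coding_alignment <- function(gene, seqs, meta, offset = 0) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    abort("`seqs` must be uniquely named by sample id.")
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1) abort("aligned sequences must share one length.")
  if ((lens[1] - offset) %% 3 != 0) {
    abort("alignment length minus `offset` must be divisible by 3.")
  }
  meta <- check_meta(meta, samples = names(seqs))
  structure(
    list(gene = gene, seqs = toupper(seqs), meta = meta, offset = offset),
    class = "coding_alignment"
  )
}

#' @export
print.coding_alignment <- function(x, ...) {
  cat(sprintf("<coding_alignment> gene %s: %d samples x %d nt (offset %d)\n",
              x$gene, length(x$seqs), nchar(x$seqs[[1]]), x$offset))
  invisible(x)
}

# sample x column character matrix of the aligned bases
alignment_matrix <- function(aln) {
  t(vapply(aln$seqs, function(s) strsplit(s, "")[[1]],
           character(nchar(aln$seqs[[1]]))))
}

#' Read a coding alignment from a FASTA file
#'
#' Sample ids are the FASTA headers; labels are joined from `meta` or, when
#' `meta` is NULL, parsed from the `species_morph_nn` naming convention.
#'
#' @param path FASTA file with one aligned sequence per sample.
#' @param gene gene id (defaults to the file name without extension).
#' @param meta optional sample metadata tibble.
#' @param offset reading-frame offset.
#' @return a [coding_alignment()].
#' @export
read_alignment_fasta <- function(path, gene = NULL, meta = NULL, offset = 0) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) abort("no FASTA headers found.")
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, collapse = "",
                 FUN.VALUE = character(1))
  names(seqs) <- ids
  if (is.null(meta)) meta <- parse_sample_labels(ids)
  if (is.null(gene)) gene <- sub("\\.[^.]*$", "", basename(path))
  coding_alignment(gene, seqs, meta, offset = offset)
}

#' Write a coding alignment to a FASTA file
#'
#' @param aln a [coding_alignment()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(aln, path) {
  writeLines(paste0(">", names(aln$seqs), "\n", unname(aln$seqs)), path)
  invisible(path)
}

#' Parse (species, morph) labels from `species_morph_nn` sample ids
#'
#' @param samples character vector of sample ids such as `A_orange_01`.
#' @return a tibble with columns `sample`, `species`, `morph`.
#' @export
parse_sample_labels <- function(samples) {
  parts <- strsplit(samples, "_", fixed = TRUE)
  bad <- lengths(parts) < 2
  if (any(bad)) {
    abort(paste0("cannot parse labels from sample id(s): ",
                 paste(samples[bad], collapse = ", ")))
  }
  tibble::tibble(
    sample = samples,
    species = vapply(parts, `[[`, character(1), 1),
    morph = vapply(parts, `[[`, character(1), 2)
  )
}
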