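# Shared fixtures and independent oracles, built in code at test time.

make_cell_meta <- function(n_per_cell = 4) {
  parse_sample_labels(c(
    sprintf("A_blue_%02d", seq_len(n_per_cell)),
    sprintf("A_orange_%02d", seq_len(n_per_cell)),
    sprintf("B_blue_%02d", seq_len(n_per_cell)),
    sprintf("B_orange_%02d", seq_len(n_per_cell))
  ))
}

# build a coding_alignment from per-sample codon vectors
alignment_from_codons <- function(codon_list, meta, gene = "toy") {
  seqs <- vapply(codon_list, paste, collapse = "", FUN.VALUE = character(1))
  coding_alignment(gene, seqs, meta)
}

# brute-force Euclidean distance between curve matrices
brute_distance <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d[i, j] <- sqrt(sum((m[i, ] - m[j, ])^2))
    }
  }
  d
}

# brute-force two-sided Kendall p over all permutations of y's ranks
brute_kendall_p <- function(x, y) {
  n <- length(x)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  tau_of <- function(a, b) {
    s <- sign(outer(a, a, "-")) * sign(outer(b, b, "-"))
    sum(s[upper.tri(s)])
  }
  t_obs <- tau_of(x, y)
  t_all <- vapply(perms(seq_len(n)), function(p) tau_of(x, y[p]), numeric(1))
  mean(abs(t_all) >= abs(t_obs) - 1e-9)
}

# brute-force conditional binomial two-sided p for group sums at phi = 0
brute_binomial_p <- function(s1, total, n1, n2) {
  pr <- stats::dbinom(0:total, total, n1 / (n1 + n2))
  sum(pr[pr <= pr[s1 + 1] * (1 + 1e-10)])
}
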