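# Small in-code fixtures shared across test files.

# cytosine table from a compact spec: one row per site
ct <- function(chrom, pos, strand = "+", context = "CG", m, n) {
  cytosine_table(chrom = rep_len(chrom, length(pos)), pos = pos,
                 strand = rep_len(strand, length(pos)),
                 context = rep_len(context, length(pos)), m = m, n = n)
}

# single region
rg <- function(chrom, start, end, strand = "+", label = "r1", kind = "other") {
  region_set(chrom = chrom, start = start, end = end, strand = strand,
             label = label, kind = kind)
}

# two-sample set from parallel count vectors at shared sites
two_sample_set <- function(pos, m1, n1, m2, n2, context = "CHG",
                           chrom = "Chr1", strand = "+") {
  sample_set(list(
    s1 = ct(chrom, pos, strand, context, m1, n1),
    s2 = ct(chrom, pos, strand, context, m2, n2)))
}

# independent brute-force oracle for the two-sample margin-fixed null:
# enumerate k = methylated reads landing in sample 1
oracle_two_sample_p <- function(m1, n1, m2, n2) {
  M <- m1 + m2; N <- n1 + n2
  stat <- function(k) {
    mm <- c(k, M - k); nn <- c(n1, n2)
    e1 <- nn * M / N; e2 <- nn * (N - M) / N
    sqrt(sum(((mm - e1) / N)^2 + ((nn - mm - e2) / N)^2) / 4)
  }
  ks <- max(0, M - n2):min(M, n1)
  probs <- choose(n1, ks) * choose(n2, M - ks) / choose(N, M)
  obs <- stat(m1)
  sum(probs[vapply(ks, stat, numeric(1)) >= obs - 1e-12])
}

# minimal DMC table for collapse tests
fake_dmcs <- function(pos, chrom = "Chr1") {
  data.table::data.table(chrom = chrom, pos = as.integer(pos),
                         strand = "+", context = "CG",
                         is_dmc = TRUE)
}
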