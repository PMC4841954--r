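# Shared toy fixtures, built in code.

# 4-haplotype toy panel with two segregating sites (pos 6 and 10) and two
# 2-sequence groups; every expected value in the tests was computed by
# brute force over its 6 sequence pairs and 3 distinct haplotypes.
toy_alignment <- function() {
  seqs <- c(seq1 = "AAAAAAAAAA", seq2 = "AAAAAAAAAT",
            seq3 = "AAAAATAAAT", seq4 = "AAAAATAAAT")
  groups <- c(seq1 = "X", seq2 = "X", seq3 = "Y", seq4 = "Y")
  haplotype_alignment(seqs, groups)
}

# random small alignment for property tests (resolved bases only)
random_alignment <- function(n, L, n_groups = 1L) {
  mat <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE,
                       prob = c(0.55, 0.25, 0.15, 0.05)),
                nrow = n,
                dimnames = list(sprintf("s%d", seq_len(n)), NULL))
  grp <- sprintf("g%d", rep_len(seq_len(n_groups), n))
  haplotype_alignment(mat, setNames(grp, rownames(mat)))
}

# brute-force mean pairwise difference (the oracle the fast column-count
# implementation is checked against)
brute_pi_total <- function(aln) {
  mat <- aln$mat
  keep <- colSums(mat == "N" | mat == "-") == 0L
  mat <- mat[, keep, drop = FALSE]
  n <- nrow(mat)
  tot <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      tot <- tot + sum(mat[i, ] != mat[j, ])
    }
  }
  tot / choose(n, 2)
}

# bisulfite toy sample: counts chosen by hand
toy_bisulfite_sample <- function(id = "s1", breed = "B1",
                                 pos = c(10L, 20L, 30L),
                                 meth = c(2L, 4L, 6L),
                                 unmeth = c(8L, 6L, 4L)) {
  rec <- data.frame(chrom = "locus", pos = pos, strand = "+",
                    meth = meth, unmeth = unmeth, context = "CpG",
                    stringsAsFactors = FALSE)
  methylome_sample(id, breed, "bisulfite", rec)
}

# phased-read table (0-based positions, internal shape)
toy_reads <- function(snp_pos = 50L, alleles = c("A", "G"),
                      n_ref = 10L, n_alt = 8L, cpg_pos = c(40L, 60L)) {
  rows <- list()
  rid <- 0L
  for (k in seq_len(n_ref + n_alt)) {
    rid <- rid + 1L
    al <- if (k <= n_ref) alleles[1L] else alleles[2L]
    rows[[rid]] <- data.frame(
      read_id = sprintf("r%03d", rid), chrom = "locus",
      snp_pos = snp_pos, allele = al, cpg_pos = cpg_pos,
      call = rep("M", length(cpg_pos)), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

toy_het <- function(snp_pos = 50L, ref = "A", alt = "G") {
  data.frame(chrom = "locus", pos = snp_pos, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}
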