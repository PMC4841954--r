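# Column-wise allele counting shared by the diversity estimators: a
# 4 x L matrix of base counts per column (vectorised; per-column table()
# calls are far too slow for simulation-scale panels).
base_counts <- function(mat) {
  rbind(A = colSums(mat == "A"), C = colSums(mat == "C"),
        G = colSums(mat == "G"), T = colSums(mat == "T"))
}

# per-column mean pairwise difference from a base-count matrix:
# (#discordant pairs) / C(n,2); n_eff = resolved bases per column
column_pi_vec <- function(cnt, n = NULL) {
  n_eff <- if (is.null(n)) colSums(cnt) else rep(n, ncol(cnt))
  pairs <- choose(n_eff, 2)
  out <- numeric(ncol(cnt))
  ok <- pairs > 0
  out[ok] <- (pairs[ok] - colSums(choose(cnt, 2))[ok]) / pairs[ok]
  out
}

# harmonic numbers a1 = sum 1/i and a2 = sum 1/i^2, i = 1..n-1
harmonic_a1 <- function(n) sum(1 / seq_len(n - 1L))
harmonic_a2 <- function(n) sum(1 / seq_len(n - 1L)^2)

# mean pairwise difference contributed by one column with allele counts ct
# among n sequences: (#discordant pairs) / C(n,2)
column_pi <- function(ct, n) {
  (choose(n, 2) - sum(choose(ct, 2))) / choose(n, 2)
}

#' Diversity statistics for a haplotype panel
#'
#' Computes the classical sequence-panel summaries: number of segregating
#' sites S, nucleotide diversity (pi, mean pairwise differences), Watterson's
#' theta, and haplotype diversity Hd with the n/(n-1) small-sample
#' correction. Columns containing N or "-" are excluded (complete deletion)
#' by default; `missing = "pairwise"` uses, per column, all sequences with a
#' resolved base there.
#'
#' @param aln a [haplotype_alignment()].
#' @param group optional group label; statistics are computed on that
#'   subpopulation only.
#' @param missing `"complete"` (default) or `"pairwise"` column handling.
#' @return Object of class `diversity_stats`: list with `n`, `L`
#'   (alignment length), `L_used` (columns used), `S`, `pi_total`,
#'   `pi_site`, `theta_w_total`, `theta_w_site` and `Hd`.
#' @export
diversity_stats <- function(aln, group = NULL,
                            missing = c("complete", "pairwise")) {
  missing <- match.arg(missing)
  aln <- aln_subset(aln, group)
  n <- nrow(aln$mat)
  if (n < 2L) stop("need at least 2 sequences")
  cols <- if (missing == "complete") complete_columns(aln$mat) else
    seq_len(ncol(aln$mat))
  L_used <- length(cols)
  if (L_used == 0L) stop("no usable alignment columns after site filtering")
  cnt <- base_counts(aln$mat[, cols, drop = FALSE])
  a1 <- harmonic_a1(n)
  S <- sum(colSums(cnt > 0L) > 1L)
  pi_total <- if (missing == "complete") {
    sum(column_pi_vec(cnt, n))
  } else {
    sum(column_pi_vec(cnt))
  }
  theta_w_total <- S / a1
  # haplotype diversity over complete columns only (haplotypes need full data)
  cols <- complete_columns(aln$mat)
  if (length(cols)) {
    haps <- apply(aln$mat[, cols, drop = FALSE], 1L, paste, collapse = "")
    f <- table(haps) / n
    Hd <- (n / (n - 1)) * (1 - sum(f^2))
  } else {
    Hd <- NA_real_
  }
  out <- list(n = n, L = aln$L, L_used = L_used, S = S,
              pi_total = pi_total, pi_site = pi_total / L_used,
              theta_w_total = theta_w_total,
              theta_w_site = theta_w_total / L_used, Hd = Hd)
  class(out) <- "diversity_stats"
  out
}

#' @export
print.diversity_stats <- function(x, ...) {
  cat("Diversity statistics (n =", x$n, ", sites used =", x$L_used, "of",
      x$L, ")\n")
  cat(sprintf("  S = %d\n  pi      = %.6g total, %.6g per site\n", x$S,
              x$pi_total, x$pi_site))
  cat(sprintf("  theta_w = %.6g total, %.6g per site\n  Hd      = %.4f\n",
              x$theta_w_total, x$theta_w_site, x$Hd))
  invisible(x)
}
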