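# 2x2 chi-square without continuity correction, closed form
# chi2 = N (ad - bc)^2 / (r1 r2 c1 c2); zero-margin tables give chi2 = 0,
# p = 1 (no evidence of difference), never NaN.
chisq2x2 <- function(a, b, c, d) {
  N <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  denom <- as.numeric(r1) * r2 * c1 * c2
  chi2 <- ifelse(denom == 0, 0, N * (a * d - b * c)^2 / denom)
  p <- ifelse(chi2 == 0, 1, pchisq(chi2, df = 1L, lower.tail = FALSE))
  list(chi2 = chi2, p = p)
}

#' Call differential methylation sites between two samples
#'
#' Per CpG shared by both bisulfite samples and passing the coverage gate,
#' tests the 2x2 table (methylated/unmethylated x sample) with a 1-df
#' chi-square (no continuity correction). Raw p values drive the
#' significance call; a Benjamini-Hochberg column is appended for reference
#' when `adjust = TRUE`.
#'
#' @param sample_a,sample_b bisulfite [methylome_sample()] objects.
#' @param min_cov both totals must reach this depth for a site to be tested.
#' @param alpha significance level on the raw p value.
#' @param adjust append a BH-adjusted column `p_bh`.
#' @return data.frame of class `dms_result`: columns `pos`, `meth_a`,
#'   `unmeth_a`, `meth_b`, `unmeth_b`, `level_a`, `level_b`, `chi2`, `p`,
#'   `significant` (and optionally `p_bh`). Attributes record the sample
#'   ids and parameters.
#' @export
call_dms <- function(sample_a, sample_b, min_cov = 10L, alpha = 0.05,
                     adjust = FALSE) {
  if (sample_a$mode != "bisulfite" || sample_b$mode != "bisulfite") {
    stop("DMS calling needs two bisulfite samples")
  }
  ra <- sample_a$records; rb <- sample_b$records
  key_a <- paste(ra$chrom, ra$pos, ra$strand)
  key_b <- paste(rb$chrom, rb$pos, rb$strand)
  common <- intersect(key_a, key_b)
  ia <- match(common, key_a); ib <- match(common, key_b)
  tot_a <- ra$meth[ia] + ra$unmeth[ia]
  tot_b <- rb$meth[ib] + rb$unmeth[ib]
  keep <- tot_a >= min_cov & tot_b >= min_cov
  ia <- ia[keep]; ib <- ib[keep]
  ts <- chisq2x2(ra$meth[ia], ra$unmeth[ia], rb$meth[ib], rb$unmeth[ib])
  out <- data.frame(
    chrom = ra$chrom[ia], pos = ra$pos[ia], strand = ra$strand[ia],
    meth_a = ra$meth[ia], unmeth_a = ra$unmeth[ia],
    meth_b = rb$meth[ib], unmeth_b = rb$unmeth[ib],
    level_a = ra$meth[ia] / (ra$meth[ia] + ra$unmeth[ia]),
    level_b = rb$meth[ib] / (rb$meth[ib] + rb$unmeth[ib]),
    chi2 = ts$chi2, p = ts$p,
    significant = ts$p < alpha,
    stringsAsFactors = FALSE
  )
  if (adjust) out$p_bh <- p.adjust(out$p, method = "BH")
  attr(out, "sample_a") <- sample_a$id
  attr(out, "sample_b") <- sample_b$id
  attr(out, "min_cov") <- min_cov
  attr(out, "alpha") <- alpha
  class(out) <- c("dms_result", "data.frame")
  out
}
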