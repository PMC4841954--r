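#' Sliding-window diversity / differentiation scan
#'
#' Computes a statistic per window over an aligned panel anchored at a
#' genomic position. Alignment column `j` (1-based) maps to 0-based genomic
#' position `aln_start + j - 1`; a window \[start, end) covers the columns
#' whose positions fall inside it.
#'
#' @param aln a [haplotype_alignment()].
#' @param windows data.frame from [make_windows()].
#' @param statistic one of `"pi"` (nucleotide diversity), `"fst"`
#'   (Hudson Fst between `pop_a` and `pop_b`) or `"theta_pi_ratio"`
#'   (pi of `pop_a` / pi of `pop_b`, NA where the denominator is 0).
#' @param pop_a,pop_b group labels; for `"pi"`, `pop_a` optionally restricts
#'   to one group.
#' @param aln_start 0-based genomic position of alignment column 1.
#' @param min_sites windows with fewer usable columns get value NA.
#' @param per_site divide pi by the number of usable columns (default TRUE);
#'   FALSE reports the per-window total.
#' @return data.frame of class `window_track`: `windows` plus columns
#'   `sites_used` and `value`; attributes `statistic`, `width`, `step`
#'   record the scan metadata.
#' @export
window_scan <- function(aln, windows,
                        statistic = c("pi", "fst", "theta_pi_ratio"),
                        pop_a = NULL, pop_b = NULL, aln_start = 0L,
                        min_sites = 1L, per_site = TRUE) {
  statistic <- match.arg(statistic)
  if (statistic != "pi" && (is.null(pop_a) || is.null(pop_b))) {
    stop("statistic '", statistic, "' needs pop_a and pop_b")
  }
  pos <- aln_start + seq_len(aln$L) - 1L   # 0-based position per column
  values <- numeric(nrow(windows))
  sites <- integer(nrow(windows))
  win_pi <- function(mat, cols) {
    usable <- intersect(cols, complete_columns(mat))
    tot <- if (length(usable)) {
      sum(column_pi_vec(base_counts(mat[, usable, drop = FALSE]),
                        nrow(mat)))
    } else 0
    list(pi = if (per_site && length(usable)) tot / length(usable) else tot,
         used = length(usable))
  }
  for (w in seq_len(nrow(windows))) {
    cols <- which(pos >= windows$start[w] & pos < windows$end[w])
    if (statistic == "pi") {
      mat <- if (is.null(pop_a)) aln$mat else
        aln$mat[aln$groups == pop_a, , drop = FALSE]
      r <- win_pi(mat, cols)
      sites[w] <- r$used
      values[w] <- if (r$used >= min_sites) r$pi else NA_real_
    } else if (statistic == "theta_pi_ratio") {
      ra <- win_pi(aln$mat[aln$groups == pop_a, , drop = FALSE], cols)
      rb <- win_pi(aln$mat[aln$groups == pop_b, , drop = FALSE], cols)
      sites[w] <- min(ra$used, rb$used)
      values[w] <- if (sites[w] < min_sites || rb$pi == 0) NA_real_ else
        ra$pi / rb$pi
    } else {
      ma <- aln$mat[aln$groups == pop_a, , drop = FALSE]
      mb <- aln$mat[aln$groups == pop_b, , drop = FALSE]
      usable <- intersect(cols, complete_columns(rbind(ma, mb)))
      sites[w] <- length(usable)
      if (length(usable) < min_sites) {
        values[w] <- NA_real_
      } else {
        ps <- pair_diff_sums(ma[, usable, drop = FALSE],
                             mb[, usable, drop = FALSE])
        hw <- (ps$hw_a + ps$hw_b) / 2
        values[w] <- if (ps$hb == 0) NA_real_ else 1 - hw / ps$hb
      }
    }
  }
  out <- windows
  out$sites_used <- sites
  out$value <- values
  attr(out, "statistic") <- statistic
  attr(out, "width") <- if (nrow(windows)) max(windows$end - windows$start) else NA
  attr(out, "step") <- if (nrow(windows) > 1L)
    windows$start[2L] - windows$start[1L] else NA
  attr(out, "populations") <- c(pop_a, pop_b)
  class(out) <- c("window_track", "data.frame")
  out
}

#' Z-test for outlier windows against a genome background
#'
#' Screens window statistics against a genome-wide background distribution
#' summarised by its mean and standard deviation:
#' z = (value - mean) / sd, with the normal tail probability for the chosen
#' side. The default side `"greater"` suits a screen for elevated diversity.
#'
#' @param window_value numeric vector of window statistics.
#' @param genome_mean,genome_sd background mean and standard deviation
#'   (sd must be > 0).
#' @param side `"greater"`, `"less"` or `"two_sided"`.
#' @return data.frame with columns `value`, `z`, `p`.
#' @export
z_outlier_test <- function(window_value, genome_mean, genome_sd,
                           side = c("greater", "less", "two_sided")) {
  side <- match.arg(side)
  if (!is.finite(genome_sd) || genome_sd <= 0) {
    stop("genome_sd must be > 0")
  }
  z <- (window_value - genome_mean) / genome_sd
  p <- switch(side,
    greater = pnorm(z, lower.tail = FALSE),
    less = pnorm(z),
    two_sided = 2 * pnorm(abs(z), lower.tail = FALSE)
  )
  data.frame(value = window_value, z = z, p = p)
}
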