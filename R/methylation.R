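#' Methylome sample container
#'
#' Wraps one sample's methylation evidence together with its breed label and
#' assay mode. Bisulfite samples carry per-CpG methylated/unmethylated
#' counts (a `cytosine_report`); MeDIP samples carry per-position mapped
#' read counts. The two modes use different level definitions (fraction vs
#' raw count) and are never mixed in one comparison.
#'
#' @param id sample identifier.
#' @param breed breed / group label.
#' @param mode `"bisulfite"` or `"medip"`.
#' @param records for bisulfite: a `cytosine_report` data.frame (columns
#'   `chrom`, `pos`, `strand`, `meth`, `unmeth`, `context`); for medip: a
#'   data.frame with columns `pos` and `count`.
#' @return Object of class `methylome_sample`.
#' @export
methylome_sample <- function(id, breed, mode = c("bisulfite", "medip"),
                             records) {
  mode <- match.arg(mode)
  need <- if (mode == "bisulfite") c("pos", "meth", "unmeth") else
    c("pos", "count")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    stop("records for mode '", mode, "' need column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  key <- if ("strand" %in% names(records)) {
    paste(records$pos, records$strand)
  } else {
    records$pos
  }
  if (anyDuplicated(key)) stop("duplicate positions in records")
  obj <- list(id = id, breed = breed, mode = mode, records = records)
  class(obj) <- "methylome_sample"
  obj
}

#' @export
print.methylome_sample <- function(x, ...) {
  cat(sprintf("methylome_sample '%s' (%s, %s): %d sites\n",
              x$id, x$breed, x$mode, nrow(x$records)))
  invisible(x)
}

#' Per-site methylation levels
#'
#' Bisulfite: level = methylated / total reads at the site, `NA` below the
#' coverage gate. MeDIP: the mapped read count itself serves as an
#' (unnormalized, unitless) relative level.
#'
#' @param sample a [methylome_sample()].
#' @param min_cov minimum total reads for a bisulfite level to be defined.
#' @return data.frame with columns `pos`, `level` and (bisulfite) `coverage`.
#' @export
site_levels <- function(sample, min_cov = 5L) {
  r <- sample$records
  if (sample$mode == "medip") {
    return(data.frame(pos = r$pos, level = as.numeric(r$count)))
  }
  total <- r$meth + r$unmeth
  level <- ifelse(total >= min_cov, r$meth / total, NA_real_)
  data.frame(pos = r$pos, level = level, coverage = total)
}

#' Mean methylation level in a region
#'
#' Unweighted mean of defined site levels inside the half-open interval,
#' plus (bisulfite) a coverage-weighted mean: pooled methylated reads over
#' pooled total reads of the sites passing the coverage gate.
#'
#' @param sample a [methylome_sample()].
#' @param region a [genomic_interval()] (0-based half-open).
#' @param min_cov per-site coverage gate (bisulfite).
#' @param min_sites fewer defined sites than this gives `NA` means.
#' @return Object of class `region_methylation`: list with `region`,
#'   `mean_level`, `weighted_mean` (bisulfite only), `site_count`, `mode`
#'   and a `reason` when undefined.
#' @export
region_mean_level <- function(sample, region, min_cov = 5L, min_sites = 1L) {
  sl <- site_levels(sample, min_cov)
  inside <- sl$pos >= region$start & sl$pos < region$end
  sl <- sl[inside & !is.na(sl$level), , drop = FALSE]
  out <- list(region = region, mode = sample$mode, sample = sample$id,
              site_count = nrow(sl))
  if (nrow(sl) < min_sites) {
    out$mean_level <- NA_real_
    out$weighted_mean <- NA_real_
    out$reason <- sprintf("only %d defined site(s), min_sites = %d",
                          nrow(sl), min_sites)
  } else {
    out$mean_level <- mean(sl$level)
    if (sample$mode == "bisulfite") {
      r <- sample$records
      tot <- r$meth + r$unmeth
      use <- r$pos >= region$start & r$pos < region$end & tot >= min_cov
      out$weighted_mean <- sum(r$meth[use]) / sum(tot[use])
    } else {
      out$weighted_mean <- NA_real_
    }
  }
  class(out) <- "region_methylation"
  out
}

#' @export
print.region_methylation <- function(x, ...) {
  cat(sprintf("region [%d, %d) %s: ", x$region$start, x$region$end, x$mode))
  if (is.na(x$mean_level)) {
    cat("NA (", x$reason, ")\n", sep = "")
  } else {
    cat(sprintf("mean level %.4f over %d sites", x$mean_level, x$site_count))
    if (!is.na(x$weighted_mean)) {
      cat(sprintf(" (coverage-weighted %.4f)", x$weighted_mean))
    }
    cat("\n")
  }
  invisible(x)
}

#' Bisulfite conversion rate from an unmethylated control
#'
#' Estimates the C-to-T conversion efficiency on a contig assumed fully
#' unmethylated (typically the mitochondrial genome), over all cytosine
#' contexts: rate = converted (unmethylated) calls / total calls.
#'
#' @param control_records a `cytosine_report` data.frame for the control
#'   contig.
#' @param warn_below warn when the rate falls below this threshold.
#' @return Numeric conversion rate in \[0, 1\].
#' @export
conversion_rate <- function(control_records, warn_below = 0.98) {
  total <- sum(control_records$meth) + sum(control_records$unmeth)
  if (total == 0) stop("control records have zero total coverage")
  rate <- sum(control_records$unmeth) / total
  if (rate < warn_below) {
    warning(sprintf("low bisulfite conversion rate: %.4f < %.2f",
                    rate, warn_below))
  }
  rate
}

#' Correct methylation levels for incomplete conversion
#'
#' Optional correction (not applied by default anywhere):
#' corrected = max(0, (level - (1 - rate)) / rate).
#'
#' @param level raw level(s) in \[0, 1\].
#' @param rate conversion rate from [conversion_rate()].
#' @return Corrected level(s).
#' @export
conversion_adjust <- function(level, rate) {
  pmax(0, (level - (1 - rate)) / rate)
}

#' Group comparison of methylation levels
#'
#' Dispatches the comparison the design calls for: Welch's t-test for two
#' groups (pooled-variance Student by `var_equal = TRUE`), one-way ANOVA or
#' pairwise t-tests with Bonferroni correction for more than two groups,
#' and additive two-way ANOVA (no interaction) for a crossed tissue x breed
#' layout.
#'
#' @param values for one-way designs: a named list of numeric vectors (one
#'   per group); for `"anova_two_way"`: a data.frame with columns `value`,
#'   `factor_a`, `factor_b`.
#' @param design `"auto"` (t-test for 2 groups, one-way ANOVA otherwise),
#'   `"t_test"`, `"anova_one_way"`, `"pairwise_t_bonferroni"` or
#'   `"anova_two_way"`.
#' @param var_equal use pooled-variance t-tests (default FALSE = Welch).
#' @return Object of class `group_comparison`: list with `test`,
#'   `statistic`, `p` and, for pairwise mode, matrices `p_raw` and `p_adj`
#'   (Bonferroni, m = choose(groups, 2)); for two-way, per-factor p values.
#' @export
group_comparison <- function(values,
                             design = c("auto", "t_test", "anova_one_way",
                                        "pairwise_t_bonferroni",
                                        "anova_two_way"),
                             var_equal = FALSE) {
  design <- match.arg(design)
  if (design == "anova_two_way") {
    stopifnot(is.data.frame(values),
              all(c("value", "factor_a", "factor_b") %in% names(values)))
    fit <- aov(value ~ factor_a + factor_b,
               data = transform(values, factor_a = factor(factor_a),
                                factor_b = factor(factor_b)))
    tab <- anova(fit)
    out <- list(test = "anova_two_way",
                statistic = setNames(tab[["F value"]][1:2],
                                     c("factor_a", "factor_b")),
                p = setNames(tab[["Pr(>F)"]][1:2],
                             c("factor_a", "factor_b")))
    class(out) <- "group_comparison"
    return(out)
  }
  stopifnot(is.list(values), !is.null(names(values)))
  sizes <- vapply(values, length, integer(1))
  if (any(sizes < 2L)) {
    stop("group(s) with fewer than 2 values: ",
         paste(names(values)[sizes < 2L], collapse = ", "))
  }
  k <- length(values)
  if (design == "auto") design <- if (k == 2L) "t_test" else "anova_one_way"
  if (design == "t_test") {
    if (k != 2L) stop("t_test needs exactly 2 groups")
    tt <- t.test(values[[1L]], values[[2L]], var.equal = var_equal)
    out <- list(test = if (var_equal) "t_test_student" else "t_test_welch",
                statistic = unname(tt$statistic), p = tt$p.value)
  } else if (design == "anova_one_way") {
    df <- data.frame(value = unlist(values, use.names = FALSE),
                     group = factor(rep(names(values), sizes)))
    tab <- anova(aov(value ~ group, data = df))
    out <- list(test = "anova_one_way",
                statistic = tab[["F value"]][1L], p = tab[["Pr(>F)"]][1L])
  } else { # pairwise_t_bonferroni
    pairs <- utils::combn(names(values), 2L)
    m <- ncol(pairs)
    p_raw <- p_adj <- stat <- matrix(NA_real_, k, k,
                                     dimnames = list(names(values),
                                                     names(values)))
    for (q in seq_len(m)) {
      a <- pairs[1L, q]; b <- pairs[2L, q]
      tt <- t.test(values[[a]], values[[b]], var.equal = var_equal)
      p_raw[a, b] <- p_raw[b, a] <- tt$p.value
      stat[a, b] <- stat[b, a] <- unname(tt$statistic)
      p_adj[a, b] <- p_adj[b, a] <- min(1, m * tt$p.value)
    }
    out <- list(test = "pairwise_t_bonferroni", statistic = stat,
                p = p_raw, p_raw = p_raw, p_adj = p_adj, m = m)
  }
  class(out) <- "group_comparison"
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("group_comparison:", x$test, "\n")
  if (is.matrix(x$p)) {
    cat("adjusted p-values (Bonferroni, m =", x$m, "):\n")
    print(round(x$p_adj, 4))
  } else {
    stat <- paste(sprintf("%.4g", x$statistic), collapse = ", ")
    pv <- paste(sprintf("%.4g", x$p), collapse = ", ")
    cat("  statistic:", stat, "\n  p:", pv, "\n")
  }
  invisible(x)
}

#' Compare region methylation across samples by breed
#'
#' Convenience wrapper for the per-region workflow: pools the defined
#' per-site levels inside the region for each breed and runs
#' [group_comparison()] on the per-breed site-level distributions. Samples
#' of different assay modes are refused because bisulfite fractions and
#' MeDIP read counts are not comparable.
#'
#' @param samples list of [methylome_sample()] objects.
#' @param region a [genomic_interval()].
#' @param design passed to [group_comparison()].
#' @param min_cov per-site coverage gate (bisulfite).
#' @return A `group_comparison`, with the per-breed site-level vectors
#'   attached as attribute `levels`.
#' @export
compare_region_methylation <- function(samples, region, design = "auto",
                                       min_cov = 5L) {
  modes <- unique(vapply(samples, function(s) s$mode, character(1)))
  if (length(modes) > 1L) {
    stop("refusing to compare samples of different modes: ",
         paste(modes, collapse = " vs "))
  }
  breeds <- vapply(samples, function(s) s$breed, character(1))
  by_breed <- lapply(split(samples, breeds), function(ss) {
    unlist(lapply(ss, function(s) {
      site <- site_levels(s, min_cov)
      vals <- site$level[site$pos >= region$start & site$pos < region$end]
      vals[!is.na(vals)]
    }), use.names = FALSE)
  })
  out <- group_comparison(by_breed, design)
  attr(out, "levels") <- by_breed
  out
}
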