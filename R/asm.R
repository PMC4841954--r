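#' Read a phased bisulfite read table
#'
#' The phasing contract is a TSV with header columns `read_id`, `chrom`,
#' `snp_pos`, `allele`, `cpg_pos`, `call`: one row per CpG call on a read
#' that uniquely covers a heterozygous SNP. `call` is `M`/`methylated` or
#' `U`/`unmethylated`. Positions are 1-based in the file and converted to
#' the internal 0-based convention.
#'
#' @param path TSV path.
#' @return data.frame with columns `read_id`, `chrom`, `snp_pos`,
#'   `allele`, `cpg_pos`, `call` (`"M"`/`"U"`), 0-based positions.
#' @export
read_phased_reads <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  need <- c("read_id", "chrom", "snp_pos", "allele", "cpg_pos", "call")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("phased-read table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df$snp_pos <- as.integer(df$snp_pos) - 1L
  df$cpg_pos <- as.integer(df$cpg_pos) - 1L
  df$call <- normalize_call(df$call)
  df
}

normalize_call <- function(x) {
  out <- ifelse(toupper(substr(x, 1L, 1L)) == "M", "M",
                ifelse(toupper(substr(x, 1L, 1L)) == "U", "U", NA))
  if (anyNA(out)) stop("methylation calls must be M/methylated or ",
                       "U/unmethylated")
  out
}

# SNP classes whose alleles bisulfite conversion confounds: C/T for reads
# on the plus strand and G/A for reads on the minus strand (an unmethylated
# C is read as T, and as A on the reverse complement), so such
# polymorphisms cannot be phased from bisulfite reads of that strand.
is_bisulfite_confounded <- function(ref, alt, strand = "+") {
  pair <- paste(pmin(ref, alt), pmax(ref, alt))
  ifelse(strand == "-", pair == "A G", pair == "C T")
}

#' Phase reads by heterozygous SNP allele
#'
#' Divides bisulfite reads covering a heterozygous SNP into reference- and
#' alternate-allele groups. SNPs whose alleles are confounded by bisulfite
#' conversion (C/T, G/A) are excluded; reads carrying neither declared
#' allele are dropped; reads anchoring more than one SNP with conflicting
#' allele-group assignments are dropped with a warning. All exclusions are
#' counted in the audit.
#'
#' @param reads data.frame from [read_phased_reads()] (or of that shape,
#'   0-based positions).
#' @param het_snps data.frame from [read_het_vcf()]: `chrom`, `pos`
#'   (0-based), `ref`, `alt`; biallelic SNPs only. An optional `strand`
#'   column (default `"+"`) selects which confounded class applies (C/T on
#'   plus, G/A on minus).
#' @return list with `groups` (named by "chrom:pos", each holding `chrom`,
#'   `snp_pos`, `ref`, `alt` and `calls`, a data.frame of per-read CpG
#'   calls labelled `allele_group` = "ref"/"alt") and `audit` (counts of
#'   SNPs excluded as confounded, reads dropped for carrying neither
#'   allele, and reads dropped for conflicting anchors).
#' @export
phase_reads <- function(reads, het_snps) {
  audit <- list(n_snps_input = nrow(het_snps), n_snps_confounded = 0L,
                n_reads_dropped_allele = 0L, n_reads_conflicting = 0L)
  strand <- if ("strand" %in% names(het_snps)) het_snps$strand else "+"
  conf <- is_bisulfite_confounded(het_snps$ref, het_snps$alt, strand)
  audit$n_snps_confounded <- sum(conf)
  het <- het_snps[!conf, , drop = FALSE]
  groups <- list()
  if (nrow(het) == 0L || nrow(reads) == 0L) {
    return(list(groups = groups, audit = audit))
  }
  reads$call <- normalize_call(reads$call)
  snp_key <- paste(reads$chrom, reads$snp_pos, sep = ":")
  het_key <- paste(het$chrom, het$pos, sep = ":")
  keep <- snp_key %in% het_key
  reads <- reads[keep, , drop = FALSE]
  snp_key <- snp_key[keep]
  idx <- match(snp_key, het_key)
  grp <- ifelse(reads$allele == het$ref[idx], "ref",
                ifelse(reads$allele == het$alt[idx], "alt", NA))
  bad_reads <- unique(reads$read_id[is.na(grp)])
  audit$n_reads_dropped_allele <- length(bad_reads)
  ok <- !(reads$read_id %in% bad_reads)
  reads <- reads[ok, , drop = FALSE]
  grp <- grp[ok]; snp_key <- snp_key[ok]
  # conflicting anchors: one read assigned to different allele groups
  ass <- unique(data.frame(read_id = reads$read_id, grp = grp,
                           stringsAsFactors = FALSE))
  conflict <- names(which(table(ass$read_id) > 1L))
  if (length(conflict)) {
    warning(length(conflict), " read(s) dropped: conflicting allele ",
            "assignments across anchoring SNPs")
    audit$n_reads_conflicting <- length(conflict)
    ok <- !(reads$read_id %in% conflict)
    reads <- reads[ok, , drop = FALSE]
    grp <- grp[ok]; snp_key <- snp_key[ok]
  }
  for (key in unique(snp_key)) {
    sel <- snp_key == key
    hrow <- het[het_key == key, ][1L, ]
    groups[[key]] <- list(
      chrom = hrow$chrom, snp_pos = hrow$pos,
      ref = hrow$ref, alt = hrow$alt,
      calls = data.frame(read_id = reads$read_id[sel],
                         allele_group = grp[sel],
                         cpg_pos = reads$cpg_pos[sel],
                         call = reads$call[sel],
                         stringsAsFactors = FALSE)
    )
  }
  list(groups = groups, audit = audit)
}

#' Build per-allele methylation tracks for one phased SNP
#'
#' Aggregates per-read CpG calls into per-allele methylated/total counts and
#' levels. A CpG enters the shared track only when both alleles reach the
#' per-allele coverage gate.
#'
#' @param group one element of `phase_reads()$groups`.
#' @param min_cov_allele minimum reads per allele per CpG.
#' @return Object of class `allele_tracks`: list with `chrom`, `snp_pos`,
#'   `ref`, `alt`, `cpg_pos` (ordered), and per-allele vectors `ref_meth`,
#'   `ref_total`, `ref_level`, `alt_meth`, `alt_total`, `alt_level`.
#' @export
allele_tracks <- function(group, min_cov_allele = 5L) {
  calls <- group$calls
  agg <- function(side) {
    sub <- calls[calls$allele_group == side, , drop = FALSE]
    if (nrow(sub) == 0L) {
      return(data.frame(cpg_pos = integer(), meth = integer(),
                        total = integer()))
    }
    tot <- tapply(sub$call, sub$cpg_pos, length)
    met <- tapply(sub$call == "M", sub$cpg_pos, sum)
    data.frame(cpg_pos = as.integer(names(tot)),
               meth = as.integer(met), total = as.integer(tot))
  }
  r <- agg("ref"); a <- agg("alt")
  shared <- intersect(r$cpg_pos[r$total >= min_cov_allele],
                      a$cpg_pos[a$total >= min_cov_allele])
  shared <- sort(shared)
  ir <- match(shared, r$cpg_pos); ia <- match(shared, a$cpg_pos)
  out <- list(chrom = group$chrom, snp_pos = group$snp_pos,
              ref = group$ref, alt = group$alt, cpg_pos = shared,
              ref_meth = r$meth[ir], ref_total = r$total[ir],
              ref_level = r$meth[ir] / r$total[ir],
              alt_meth = a$meth[ia], alt_total = a$total[ia],
              alt_level = a$meth[ia] / a$total[ia])
  class(out) <- "allele_tracks"
  out
}

#' Scan allele tracks with a 5-CpG sliding window
#'
#' Slides a window of `window_cpgs` consecutive shared CpGs (step 1 CpG) and
#' flags candidate windows where the allele mean levels differ by fold
#' change >= `fold_min` and absolute difference >= `diff_min` (both
#' thresholds inclusive). A window whose smaller mean is 0 passes the fold
#' criterion (infinite fold); the absolute-difference criterion still
#' applies.
#'
#' @param tracks an [allele_tracks()] object.
#' @param window_cpgs CpGs per window (default 5).
#' @param step step in CpGs between window starts.
#' @param fold_min,diff_min candidate thresholds (defaults 2.0 and 0.3).
#' @return data.frame with one row per window: `idx_start`, `idx_end`
#'   (indices into `tracks$cpg_pos`), `cpg_start`, `cpg_end` (0-based
#'   positions), `level_ref`, `level_alt`, `fold`, `diff`, `candidate`.
#'   Zero rows when the shared track is shorter than `window_cpgs`.
#' @export
asm_window_scan <- function(tracks, window_cpgs = 5L, step = 1L,
                            fold_min = 2.0, diff_min = 0.3) {
  m <- length(tracks$cpg_pos)
  empty <- data.frame(idx_start = integer(), idx_end = integer(),
                      cpg_start = integer(), cpg_end = integer(),
                      level_ref = numeric(), level_alt = numeric(),
                      fold = numeric(), diff = numeric(),
                      candidate = logical())
  if (m < window_cpgs) return(empty)
  starts <- seq.int(1L, m - window_cpgs + 1L, by = step)
  rows <- lapply(starts, function(i) {
    idx <- i:(i + window_cpgs - 1L)
    a <- mean(tracks$ref_level[idx])
    b <- mean(tracks$alt_level[idx])
    lo <- min(a, b); hi <- max(a, b)
    fold <- if (lo == 0) Inf else hi / lo
    data.frame(idx_start = i, idx_end = idx[window_cpgs],
               cpg_start = tracks$cpg_pos[i],
               cpg_end = tracks$cpg_pos[idx[window_cpgs]],
               level_ref = a, level_alt = b, fold = fold,
               diff = abs(a - b),
               candidate = (fold >= fold_min) & (abs(a - b) >= diff_min))
  })
  do.call(rbind, rows)
}

#' Merge candidate windows and t-test the merged regions
#'
#' Overlapping candidate windows (sharing at least one CpG) are merged into
#' maximal regions; each region is tested with a paired t-test of the
#' per-CpG level pairs (ref vs alt) across its CpGs, and kept when
#' p < `alpha`. Regions with fewer than 2 CpG pairs cannot be tested and are
#' dropped. Degenerate regions whose paired differences are exactly
#' constant get p = 0 when the constant is nonzero and p = 1 otherwise.
#'
#' @param candidates window table from [asm_window_scan()].
#' @param tracks the [allele_tracks()] the windows came from.
#' @param alpha region-level significance threshold.
#' @return data.frame of class `asm_regions`: `chrom`, `start`, `end`
#'   (0-based half-open, first to one-past-last CpG), `snp_pos`, `n_cpg`,
#'   `level_ref`, `level_alt`, `fold`, `diff`, `t`, `p`.
#' @export
merge_and_test <- function(candidates, tracks, alpha = 0.05) {
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), snp_pos = integer(),
                      n_cpg = integer(), level_ref = numeric(),
                      level_alt = numeric(), fold = numeric(),
                      diff = numeric(), t = numeric(), p = numeric(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("asm_regions", "data.frame")
  cand <- candidates[candidates$candidate, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  cand <- cand[order(cand$idx_start), , drop = FALSE]
  # merge index ranges that share at least one CpG
  merged <- list(c(cand$idx_start[1L], cand$idx_end[1L]))
  for (i in seq_len(nrow(cand))[-1L]) {
    last <- merged[[length(merged)]]
    if (cand$idx_start[i] <= last[2L]) {
      merged[[length(merged)]][2L] <- max(last[2L], cand$idx_end[i])
    } else {
      merged[[length(merged) + 1L]] <- c(cand$idx_start[i], cand$idx_end[i])
    }
  }
  rows <- lapply(merged, function(rg) {
    idx <- rg[1L]:rg[2L]
    if (length(idx) < 2L) return(NULL)
    ref <- tracks$ref_level[idx]; alt <- tracks$alt_level[idx]
    d <- ref - alt
    if (sd(d) == 0) {
      tstat <- NA_real_
      p <- if (mean(d) != 0) 0 else 1
    } else {
      tt <- t.test(ref, alt, paired = TRUE)
      tstat <- unname(tt$statistic)
      p <- tt$p.value
    }
    data.frame(chrom = tracks$chrom,
               start = tracks$cpg_pos[rg[1L]],
               end = tracks$cpg_pos[rg[2L]] + 1L,
               snp_pos = tracks$snp_pos, n_cpg = length(idx),
               level_ref = mean(ref), level_alt = mean(alt),
               fold = if (min(mean(ref), mean(alt)) == 0) Inf else
                 max(mean(ref), mean(alt)) / min(mean(ref), mean(alt)),
               diff = abs(mean(ref) - mean(alt)),
               t = tstat, p = p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out <- out[!is.na(out$p) & out$p < alpha, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("asm_regions", "data.frame")
  out
}

#' Call allele-specific methylation regions end to end
#'
#' Composes the full procedure: phase reads by heterozygous SNP, build
#' per-allele CpG tracks, scan with the 5-CpG window (fold change >= 2 and
#' absolute difference >= 0.3), merge overlapping candidate windows, and
#' keep merged regions whose paired t-test is significant. SNPs whose
#' shared track is shorter than one window are skipped and counted.
#'
#' @param reads phased-read table (data.frame, or a TSV path for
#'   [read_phased_reads()]).
#' @param het_snps het-SNP table (data.frame, or a VCF path for
#'   [read_het_vcf()]).
#' @param min_cov_allele per-allele per-CpG coverage gate.
#' @param window_cpgs,fold_min,diff_min window-stage parameters.
#' @param alpha region-stage significance threshold.
#' @return Object of class `asm_call`: list with `regions` (an
#'   `asm_regions` data.frame over all SNPs, sorted), `audit` (per-stage
#'   counters) and `tracks` (per-SNP [allele_tracks()]).
#' @export
call_asm <- function(reads, het_snps, min_cov_allele = 5L,
                     window_cpgs = 5L, fold_min = 2.0, diff_min = 0.3,
                     alpha = 0.05) {
  if (is.character(reads)) reads <- read_phased_reads(reads)
  if (is.character(het_snps)) het_snps <- read_het_vcf(het_snps)
  ph <- phase_reads(reads, het_snps)
  audit <- ph$audit
  audit$n_snps_skipped_few_cpgs <- 0L
  audit$n_windows_tested <- 0L
  audit$n_candidate_windows <- 0L
  all_regions <- list()
  tracks_list <- list()
  for (key in names(ph$groups)) {
    tr <- allele_tracks(ph$groups[[key]], min_cov_allele)
    tracks_list[[key]] <- tr
    if (length(tr$cpg_pos) < window_cpgs) {
      audit$n_snps_skipped_few_cpgs <- audit$n_snps_skipped_few_cpgs + 1L
      next
    }
    win <- asm_window_scan(tr, window_cpgs, step = 1L, fold_min, diff_min)
    audit$n_windows_tested <- audit$n_windows_tested + nrow(win)
    audit$n_candidate_windows <- audit$n_candidate_windows +
      sum(win$candidate)
    reg <- merge_and_test(win, tr, alpha)
    if (nrow(reg)) all_regions[[key]] <- reg
  }
  regions <- if (length(all_regions)) {
    r <- do.call(rbind, all_regions)
    r <- r[order(r$chrom, r$start), , drop = FALSE]
    rownames(r) <- NULL
    class(r) <- c("asm_regions", "data.frame")
    r
  } else {
    merge_and_test(asm_window_scan(
      structure(list(cpg_pos = integer()), class = "allele_tracks"),
      window_cpgs), NULL, alpha)
  }
  audit$n_regions <- nrow(regions)
  out <- list(regions = regions, audit = audit, tracks = tracks_list)
  class(out) <- "asm_call"
  out
}

#' @export
print.asm_call <- function(x, ...) {
  cat("ASM call:", nrow(x$regions), "region(s)\n")
  a <- x$audit
  cat(sprintf(paste0("  SNPs: %d in, %d excluded (bisulfite-confounded), ",
                     "%d skipped (<1 window of shared CpGs)\n"),
              a$n_snps_input, a$n_snps_confounded,
              a$n_snps_skipped_few_cpgs))
  cat(sprintf("  reads dropped: %d (unmatched allele), %d (conflicting)\n",
              a$n_reads_dropped_allele, a$n_reads_conflicting))
  cat(sprintf("  windows: %d tested, %d candidates\n",
              a$n_windows_tested, a$n_candidate_windows))
  if (nrow(x$regions)) print(as.data.frame(x$regions))
  invisible(x)
}
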