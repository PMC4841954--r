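make_pair <- function(meth_a, unmeth_a, meth_b, unmeth_b, pos = 100L) {
  a <- toy_bisulfite_sample("a", "b1", pos = pos, meth = meth_a,
                            unmeth = unmeth_a)
  b <- toy_bisulfite_sample("b", "b2", pos = pos, meth = meth_b,
                            unmeth = unmeth_b)
  list(a = a, b = b)
}

test_that("DMS chi-square matches the closed 2x2 form and chisq.test", {
  p <- make_pair(30L, 0L, 0L, 30L)
  dms <- call_dms(p$a, p$b, min_cov = 10L)
  expect_equal(dms$chi2, 60)
  expect_lt(dms$p, 1e-13)
  expect_true(dms$significant)
  # independent route: stats::chisq.test without continuity correction
  ct <- stats::chisq.test(matrix(c(30, 0, 0, 30), 2), correct = FALSE)
  expect_equal(dms$chi2, unname(ct$statistic))
  expect_equal(dms$p, ct$p.value)

  same <- make_pair(15L, 15L, 15L, 15L)
  d2 <- call_dms(same$a, same$b)
  expect_equal(d2$chi2, 0)
  expect_equal(d2$p, 1)
  expect_false(d2$significant)
})

test_that("DMS calling gates on coverage and handles degenerate margins", {
  low <- make_pair(3L, 2L, 2L, 3L)
  expect_equal(nrow(call_dms(low$a, low$b, min_cov = 10L)), 0L)
  expect_equal(nrow(call_dms(low$a, low$b, min_cov = 5L)), 1L)

  # zero margin: both samples fully methylated -> chi2 = 0, p = 1, no NaN
  full <- make_pair(30L, 0L, 30L, 0L)
  d <- call_dms(full$a, full$b)
  expect_equal(d$chi2, 0)
  expect_equal(d$p, 1)

  med <- methylome_sample("m", "B", "medip",
                          data.frame(pos = 1L, count = 5L))
  expect_error(call_dms(med, full$a), "bisulfite")

  # BH column is optional and never smaller than honest raw p ordering
  many <- make_pair(c(30L, 10L), c(0L, 20L), c(0L, 12L), c(30L, 18L),
                    pos = c(100L, 200L))
  db <- call_dms(many$a, many$b, adjust = TRUE)
  expect_true(all(db$p_bh >= db$p))
})

test_that("read phasing partitions by allele and audits exclusions", {
  ph <- phase_reads(toy_reads(n_ref = 10L, n_alt = 8L), toy_het())
  grp <- ph$groups[["locus:50"]]
  expect_equal(sum(grp$calls$allele_group == "ref") / 2, 10)  # 2 CpGs/read
  expect_equal(sum(grp$calls$allele_group == "alt") / 2, 8)
  expect_equal(ph$audit$n_reads_dropped_allele, 0L)

  # C/T SNP on the plus strand is bisulfite-confounded
  ph_ct <- phase_reads(toy_reads(alleles = c("C", "T")),
                       toy_het(ref = "C", alt = "T"))
  expect_equal(ph_ct$audit$n_snps_confounded, 1L)
  expect_equal(length(ph_ct$groups), 0L)
  # G/A is confounded only for minus-strand reads
  het_minus <- cbind(toy_het(ref = "G", alt = "A"), strand = "-")
  expect_equal(phase_reads(toy_reads(alleles = c("G", "A")),
                           het_minus)$audit$n_snps_confounded, 1L)

  # a read carrying neither declared allele is dropped and counted
  reads <- toy_reads(n_ref = 3L, n_alt = 3L)
  reads$allele[reads$read_id == "r001"] <- "T"
  ph2 <- phase_reads(reads, toy_het())
  expect_equal(ph2$audit$n_reads_dropped_allele, 1L)
  expect_false("r001" %in% ph2$groups[["locus:50"]]$calls$read_id)

  # conflicting anchors across two SNPs -> dropped with warning
  r1 <- toy_reads(snp_pos = 50L, n_ref = 2L, n_alt = 0L)
  r2 <- toy_reads(snp_pos = 80L, n_ref = 0L, n_alt = 2L)
  r2$read_id <- r1$read_id  # same reads, opposite assignment
  het2 <- rbind(toy_het(50L), toy_het(80L))
  expect_warning(ph3 <- phase_reads(rbind(r1, r2), het2), "conflicting")
  expect_equal(ph3$audit$n_reads_conflicting, 2L)
})

test_that("allele tracks aggregate reads and enforce the shared-CpG gate", {
  calls <- data.frame(
    read_id = rep(sprintf("r%d", 1:10), each = 1L),
    allele_group = rep(c("ref", "alt"), each = 5L),
    cpg_pos = rep(40L, 10L),
    call = c("M", "M", "M", "M", "U",  # ref: 4/5
             "U", "U", "U", "M", "U"), # alt: 1/5
    stringsAsFactors = FALSE)
  grp <- list(chrom = "locus", snp_pos = 50L, ref = "A", alt = "G",
              calls = calls)
  tr <- allele_tracks(grp, min_cov_allele = 5L)
  expect_equal(tr$ref_level, 0.8)
  expect_equal(tr$alt_level, 0.2)

  # a CpG covered by ref reads only is excluded from the shared track
  calls2 <- rbind(calls, data.frame(read_id = "r11", allele_group = "ref",
                                    cpg_pos = 60L, call = "M"))
  tr2 <- allele_tracks(list(chrom = "locus", snp_pos = 50L, ref = "A",
                            alt = "G", calls = calls2), min_cov_allele = 1L)
  expect_equal(tr2$cpg_pos, 40L)

  # aggregation equals a brute-force recount over the read list
  set.seed(3)
  big <- data.frame(
    read_id = sprintf("r%d", 1:400),
    allele_group = sample(c("ref", "alt"), 400, TRUE),
    cpg_pos = sample(c(10L, 20L, 30L), 400, TRUE),
    call = sample(c("M", "U"), 400, TRUE), stringsAsFactors = FALSE)
  tr3 <- allele_tracks(list(chrom = "c", snp_pos = 5L, ref = "A",
                            alt = "G", calls = big), min_cov_allele = 1L)
  for (k in seq_along(tr3$cpg_pos)) {
    sub <- big[big$cpg_pos == tr3$cpg_pos[k] & big$allele_group == "ref", ]
    expect_equal(tr3$ref_meth[k], sum(sub$call == "M"))
    expect_equal(tr3$ref_total[k], nrow(sub))
  }
})

test_that("the 5-CpG window applies inclusive fold and difference thresholds", {
  mk_tracks <- function(ref, alt) {
    structure(list(chrom = "c", snp_pos = 0L, ref = "A", alt = "G",
                   cpg_pos = seq_along(ref) * 10L,
                   ref_level = ref, alt_level = alt,
                   ref_meth = rep(1L, length(ref)),
                   ref_total = rep(1L, length(ref)),
                   alt_meth = rep(1L, length(ref)),
                   alt_total = rep(1L, length(ref))),
              class = "allele_tracks")
  }
  pass <- asm_window_scan(mk_tracks(rep(0.8, 5), rep(0.2, 5)))
  expect_equal(pass$fold, 4)
  expect_equal(pass$diff, 0.6)
  expect_true(pass$candidate)

  reject <- asm_window_scan(mk_tracks(rep(0.5, 5), rep(0.35, 5)))
  expect_false(reject$candidate)

  boundary <- asm_window_scan(mk_tracks(rep(0.6, 5), rep(0.3, 5)))
  expect_true(boundary$candidate)  # thresholds are inclusive

  # a zero mean passes the fold criterion but still needs the difference
  zero_pass <- asm_window_scan(mk_tracks(rep(0.4, 5), rep(0, 5)))
  expect_equal(zero_pass$fold, Inf)
  expect_true(zero_pass$candidate)
  zero_fail <- asm_window_scan(mk_tracks(rep(0.2, 5), rep(0, 5)))
  expect_false(zero_fail$candidate)

  # track shorter than a window yields no rows
  expect_equal(nrow(asm_window_scan(mk_tracks(rep(0.8, 4), rep(0.2, 4)))),
               0L)
})

test_that("candidate windows merge into maximal regions and t-test them", {
  ref <- c(0.9, 0.85, 0.95, 0.9, 0.8, 0.88, 0.92)
  alt <- c(0.1, 0.2, 0.15, 0.1, 0.2, 0.12, 0.18)
  tracks <- structure(list(chrom = "c", snp_pos = 0L, ref = "A", alt = "G",
                           cpg_pos = seq_along(ref) * 10L,
                           ref_level = ref, alt_level = alt),
                      class = "allele_tracks")
  win <- asm_window_scan(tracks)  # windows 1-5, 2-6, 3-7, all candidates
  expect_equal(nrow(win), 3L)
  reg <- merge_and_test(win, tracks, alpha = 0.05)
  expect_equal(nrow(reg), 1L)  # overlapping windows -> one region 1-7
  expect_equal(reg$n_cpg, 7L)
  expect_equal(c(reg$start, reg$end), c(10L, 71L))
  expect_lt(reg$p, 0.001)
  # statistic equals an independent paired-t computation
  d <- ref - alt
  t_manual <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(reg$t, t_manual)

  # non-overlapping candidates stay separate regions
  win2 <- data.frame(idx_start = c(1L, 3L, 10L), idx_end = c(5L, 7L, 14L),
                     cpg_start = 0L, cpg_end = 0L, level_ref = 0.9,
                     level_alt = 0.1, fold = 9, diff = 0.8,
                     candidate = TRUE)
  tracks2 <- structure(list(chrom = "c", snp_pos = 0L, ref = "A",
                            alt = "G", cpg_pos = (1:14) * 10L,
                            ref_level = rep(0.9, 14),
                            alt_level = c(rep(0.1, 7), rep(0.1, 7))),
                       class = "allele_tracks")
  tracks2$ref_level <- tracks2$ref_level + seq(-0.01, 0.01, length.out = 14)
  reg2 <- merge_and_test(win2, tracks2, alpha = 0.05)
  expect_equal(nrow(reg2), 2L)
  expect_equal(reg2$n_cpg, c(7L, 5L))

  # merging is idempotent: re-merging merged ranges changes nothing
  win3 <- data.frame(idx_start = c(1L, 10L), idx_end = c(7L, 14L),
                     cpg_start = 0L, cpg_end = 0L, level_ref = 0.9,
                     level_alt = 0.1, fold = 9, diff = 0.8,
                     candidate = TRUE)
  reg3 <- merge_and_test(win3, tracks2, alpha = 0.05)
  expect_equal(reg3[c("start", "end", "n_cpg")],
               reg2[c("start", "end", "n_cpg")])
})

test_that("the end-to-end ASM caller recovers a planted region", {
  cpg <- seq(100L, 170L, by = 10L)
  cfg <- bisulfite_sim_config(
    cpg_pos = cpg, levels = rbind(s1 = rep(0.5, 8)),
    asm = list(snp_pos = 135L, ref = "A", alt = "G",
               level_ref = rep(0.85, 8), level_alt = rep(0.15, 8),
               mean_cov_allele = 20, read_len_cpgs = 5L))
  sim <- sim_bisulfite(cfg, seed = 7)
  res <- call_asm(sim$reads, sim$het_snps)
  expect_equal(nrow(res$regions), 1L)
  expect_lt(res$regions$start, 170L)
  expect_gt(res$regions$end, 100L)
  expect_gte(res$regions$fold, 2)
  expect_gte(res$regions$diff, 0.3)
  expect_lt(res$regions$p, 0.05)

  # equal allele levels -> no regions
  cfg0 <- bisulfite_sim_config(
    cpg_pos = cpg, levels = rbind(s1 = rep(0.5, 8)),
    asm = list(snp_pos = 135L, ref = "A", alt = "G",
               level_ref = rep(0.5, 8), level_alt = rep(0.5, 8)))
  sim0 <- sim_bisulfite(cfg0, seed = 8)
  expect_equal(nrow(call_asm(sim0$reads, sim0$het_snps)$regions), 0L)

  # a C/T-only dataset yields nothing but an audited exclusion
  cfg_ct <- bisulfite_sim_config(
    cpg_pos = cpg, levels = rbind(s1 = rep(0.5, 8)),
    asm = list(snp_pos = 135L, ref = "C", alt = "T",
               level_ref = rep(0.85, 8), level_alt = rep(0.15, 8)))
  sim_ct <- sim_bisulfite(cfg_ct, seed = 9)
  res_ct <- call_asm(sim_ct$reads, sim_ct$het_snps)
  expect_equal(nrow(res_ct$regions), 0L)
  expect_equal(res_ct$audit$n_snps_confounded, 1L)
})

test_that("ASM file contracts round-trip through TSV and VCF", {
  cpg <- seq(100L, 170L, by = 10L)
  cfg <- bisulfite_sim_config(
    cpg_pos = cpg, levels = rbind(s1 = rep(0.5, 8)),
    asm = list(snp_pos = 135L, ref = "A", alt = "G",
               level_ref = rep(0.9, 8), level_alt = rep(0.1, 8)))
  dir <- tempfile()
  sim <- sim_bisulfite(cfg, seed = 11, out_dir = dir)
  res_file <- call_asm(file.path(dir, "reads.tsv"),
                       file.path(dir, "het.vcf"))
  res_mem <- call_asm(sim$reads, sim$het_snps)
  expect_equal(res_file$regions, res_mem$regions)
  het <- read_het_vcf(file.path(dir, "het.vcf"))
  expect_equal(het$pos, 135L)  # 1-based in file, 0-based internally
  expect_equal(het$ref, "A")
})
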