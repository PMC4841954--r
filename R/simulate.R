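#' Simulate a neutral coalescent haplotype panel
#'
#' Standard single-population neutral coalescent without recombination:
#' while k lineages remain, an exponential waiting time with rate
#' choose(k, 2) (time in units of 2N generations) precedes a uniformly
#' chosen pairwise coalescence. Mutations are Poisson with mean
#' theta_locus * T_total / 2 (theta_locus = theta_site * L, T_total the
#' total tree length), placed on branches proportionally to length and at
#' distinct sites (infinite sites on a finite grid). Under this model
#' E\[pi\] = theta_locus and E\[S\] = theta_locus * a1(n).
#'
#' @param n sample size (>= 2).
#' @param L number of sites (>= 1).
#' @param theta_site per-site population mutation rate (> 0).
#' @param seed RNG seed; identical seeds give identical panels.
#' @return list with `aln` (a [haplotype_alignment()], single group
#'   "pop1"), `tree` (the true genealogy as an `ape` `phylo`),
#'   `n_mutations` and `positions` (0-based mutated sites).
#' @export
sim_coalescent <- function(n, L, theta_site, seed = NULL) {
  stopifnot(n >= 2L, L >= 1L, theta_site > 0)
  with_seed(seed, {
    # node: list(children = list or NULL, label, height)
    active <- lapply(seq_len(n), function(i) {
      list(label = sprintf("hap%d", i), height = 0, tips = i)
    })
    t <- 0
    while (length(active) > 1L) {
      k <- length(active)
      t <- t + rexp(1L, rate = choose(k, 2))
      pair <- sample.int(k, 2L)
      node <- list(children = active[pair], height = t,
                   tips = c(active[[pair[1L]]]$tips,
                            active[[pair[2L]]]$tips))
      active <- c(active[-pair], list(node))
    }
    root <- active[[1L]]
    # collect branches (tip set + length) and emit newick
    branches <- list()
    newick <- function(node, parent_height) {
      len <- parent_height - node$height
      lab <- if (is.null(node$children)) {
        node$label
      } else {
        paste0("(", newick(node$children[[1L]], node$height), ",",
               newick(node$children[[2L]], node$height), ")")
      }
      branches[[length(branches) + 1L]] <<- list(tips = node$tips,
                                                 len = len)
      paste0(lab, ":", format(len, digits = 12))
    }
    inner <- if (is.null(root$children)) root$label else
      paste0("(", newick(root$children[[1L]], root$height), ",",
             newick(root$children[[2L]], root$height), ")")
    tree <- ape::read.tree(text = paste0(inner, ";"))
    total_len <- sum(vapply(branches, `[[`, numeric(1), "len"))
    n_mut <- rpois(1L, theta_site * L * total_len / 2)
    if (n_mut > L) {
      stop("mutation count ", n_mut, " exceeds the ", L,
           " available sites; increase L or decrease theta_site")
    }
    positions <- sort(sample.int(L, n_mut))
    mat <- matrix("A", nrow = n, ncol = L,
                  dimnames = list(sprintf("hap%d", seq_len(n)), NULL))
    if (n_mut > 0L) {
      lens <- vapply(branches, `[[`, numeric(1), "len")
      which_branch <- sample.int(length(branches), n_mut, replace = TRUE,
                                 prob = lens)
      for (m in seq_len(n_mut)) {
        tips <- branches[[which_branch[m]]]$tips
        mat[tips, positions[m]] <- "T"
      }
    }
    groups <- setNames(rep("pop1", n), rownames(mat))
    list(aln = haplotype_alignment(mat, groups), tree = tree,
         n_mutations = n_mut, positions = positions - 1L)
  })
}

#' Simulate two diverged populations (Balding-Nichols model)
#'
#' Per locus, an ancestral allele frequency p is drawn from `p_range`
#' uniformly and each population's frequency from
#' Beta(p(1-F)/F, (1-p)(1-F)/F); haplotype alleles are Bernoulli draws.
#' The expectation of Hudson's Fst over loci is the divergence parameter F,
#' which makes the generator a closed-form calibration target for the
#' differentiation estimator.
#'
#' @param n_a,n_b haplotypes per population.
#' @param loci number of unlinked biallelic loci (one alignment column
#'   each).
#' @param F divergence parameter, 0 < F < 1.
#' @param p_range range of the uniform ancestral frequency distribution.
#' @param labels group labels for the two populations.
#' @param seed RNG seed.
#' @return list with `aln` (a [haplotype_alignment()] with the two groups),
#'   `true_f = F` and the per-locus population frequencies `freq_a`,
#'   `freq_b`.
#' @export
sim_two_pop <- function(n_a = 25L, n_b = 25L, loci = 200L, F = 0.2,
                        p_range = c(0.05, 0.95),
                        labels = c("popA", "popB"), seed = NULL) {
  stopifnot(F > 0, F < 1, loci >= 1L, n_a >= 2L, n_b >= 2L)
  with_seed(seed, {
    p <- runif(loci, p_range[1L], p_range[2L])
    shape_scale <- (1 - F) / F
    fa <- rbeta(loci, p * shape_scale, (1 - p) * shape_scale)
    fb <- rbeta(loci, p * shape_scale, (1 - p) * shape_scale)
    draw <- function(nh, freq) {
      m <- matrix("A", nrow = nh, ncol = loci)
      for (j in seq_len(loci)) {
        m[rbinom(nh, 1L, freq[j]) == 1L, j] <- "T"
      }
      m
    }
    mat <- rbind(draw(n_a, fa), draw(n_b, fb))
    ids <- c(sprintf("%s_h%d", labels[1L], seq_len(n_a)),
             sprintf("%s_h%d", labels[2L], seq_len(n_b)))
    rownames(mat) <- ids
    groups <- setNames(rep(labels, c(n_a, n_b)), ids)
    list(aln = haplotype_alignment(mat, groups), true_f = F,
         freq_a = fa, freq_b = fb)
  })
}

#' Bisulfite simulation configuration
#'
#' Defines the study conditions the bisulfite read simulator emulates:
#' single-base methylomes as per-CpG binomial counts (with conversion
#' failure inflating apparent levels of unmethylated cytosines), and, when
#' `asm` is set, phased reads around a heterozygous SNP with per-allele
#' methylation levels.
#'
#' @param chrom contig name.
#' @param cpg_pos 0-based CpG positions.
#' @param levels matrix of true levels, rows = samples (rownames = sample
#'   ids), columns = CpGs.
#' @param breeds breed label per sample (defaults to the sample id).
#' @param mean_cov mean Poisson coverage per CpG per sample.
#' @param conversion_rate bisulfite conversion rate in (0.9, 1\].
#' @param planted_dms 0-based positions planted as truly differential
#'   (recorded in the truth table; the levels matrix must encode the
#'   difference).
#' @param asm NULL, or a list with `snp_pos` (0-based), `ref`, `alt`,
#'   `level_ref`, `level_alt` (per shared CpG), `mean_cov_allele`,
#'   `read_len_cpgs`; the CpGs of the allele tracks are `cpg_pos`.
#' @return list of class `bisulfite_sim_config`.
#' @export
bisulfite_sim_config <- function(chrom = "locus", cpg_pos, levels,
                                 breeds = NULL, mean_cov = 30,
                                 conversion_rate = 1.0,
                                 planted_dms = integer(), asm = NULL) {
  stopifnot(is.matrix(levels), ncol(levels) == length(cpg_pos),
            all(levels >= 0 & levels <= 1),
            conversion_rate > 0.9, conversion_rate <= 1)
  if (is.null(rownames(levels))) {
    rownames(levels) <- sprintf("sample%d", seq_len(nrow(levels)))
  }
  if (is.null(breeds)) breeds <- rownames(levels)
  if (!is.null(asm)) {
    need <- c("snp_pos", "ref", "alt", "level_ref", "level_alt")
    stopifnot(all(need %in% names(asm)),
              length(asm$level_ref) == length(cpg_pos),
              length(asm$level_alt) == length(cpg_pos))
    if (length(cpg_pos) < 5L) {
      stop("a planted ASM track needs at least 5 CpGs ",
           "(one full sliding window)")
    }
    if (is.null(asm$mean_cov_allele)) asm$mean_cov_allele <- 20
    if (is.null(asm$read_len_cpgs)) asm$read_len_cpgs <- 5L
  }
  out <- list(chrom = chrom, cpg_pos = as.integer(cpg_pos),
              levels = levels, breeds = breeds, mean_cov = mean_cov,
              conversion_rate = conversion_rate,
              planted_dms = as.integer(planted_dms), asm = asm)
  class(out) <- "bisulfite_sim_config"
  out
}

#' Simulate bisulfite methylomes (and optionally phased ASM reads)
#'
#' Per CpG and sample: coverage ~ Poisson(mean_cov) and methylated calls ~
#' Binomial(coverage, level + (1 - level) * (1 - conversion_rate)) -- the
#' second term models conversion failure on unmethylated cytosines. When
#' the configuration carries an `asm` block, phased reads are emitted: each
#' read carries the SNP allele and a contiguous run of CpG calls drawn from
#' that allele's levels.
#'
#' @param cfg a [bisulfite_sim_config()].
#' @param seed RNG seed.
#' @param out_dir optional directory; when given, writes one cytosine
#'   report per sample, `reads.tsv` + `het.vcf` (ASM mode) and truth TSVs.
#' @return list with `samples` (list of [methylome_sample()]), `reads`
#'   (phased-read data.frame or NULL), `het_snps` (data.frame or NULL) and
#'   `truth` (list with `dms` positions and `asm` interval).
#' @export
sim_bisulfite <- function(cfg, seed = NULL, out_dir = NULL) {
  stopifnot(inherits(cfg, "bisulfite_sim_config"))
  with_seed(seed, {
    n_cpg <- length(cfg$cpg_pos)
    fail <- 1 - cfg$conversion_rate
    samples <- list()
    for (s in rownames(cfg$levels)) {
      cov <- rpois(n_cpg, cfg$mean_cov)
      p_obs <- cfg$levels[s, ] + (1 - cfg$levels[s, ]) * fail
      meth <- rbinom(n_cpg, cov, p_obs)
      rec <- data.frame(chrom = cfg$chrom, pos = cfg$cpg_pos,
                        strand = "+", meth = meth, unmeth = cov - meth,
                        context = "CpG", stringsAsFactors = FALSE)
      class(rec) <- c("cytosine_report", "data.frame")
      samples[[s]] <- methylome_sample(s, cfg$breeds[match(
        s, rownames(cfg$levels))], "bisulfite", rec)
    }
    reads <- NULL; het <- NULL; asm_truth <- NULL
    if (!is.null(cfg$asm)) {
      a <- cfg$asm
      rl <- min(a$read_len_cpgs, n_cpg)
      rows <- list()
      rid <- 0L
      for (side in c("ref", "alt")) {
        lv <- if (side == "ref") a$level_ref else a$level_alt
        p_obs <- lv + (1 - lv) * fail
        n_reads <- rpois(1L, a$mean_cov_allele * n_cpg / rl)
        starts <- sample.int(n_cpg - rl + 1L, n_reads, replace = TRUE)
        for (r in seq_len(n_reads)) {
          rid <- rid + 1L
          idx <- starts[r]:(starts[r] + rl - 1L)
          calls <- ifelse(rbinom(length(idx), 1L, p_obs[idx]) == 1L,
                          "M", "U")
          rows[[rid]] <- data.frame(
            read_id = sprintf("read%05d", rid), chrom = cfg$chrom,
            snp_pos = a$snp_pos,
            allele = if (side == "ref") a$ref else a$alt,
            cpg_pos = cfg$cpg_pos[idx], call = calls,
            stringsAsFactors = FALSE)
        }
      }
      reads <- do.call(rbind, rows)
      het <- data.frame(chrom = cfg$chrom, pos = a$snp_pos, ref = a$ref,
                        alt = a$alt, stringsAsFactors = FALSE)
      asm_truth <- data.frame(
        chrom = cfg$chrom, start = min(cfg$cpg_pos),
        end = max(cfg$cpg_pos) + 1L,
        mean_diff = mean(abs(a$level_ref - a$level_alt)))
    }
    truth <- list(dms = cfg$planted_dms, asm = asm_truth)
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      for (s in names(samples)) {
        write_cytosine_report(samples[[s]]$records,
                              file.path(out_dir, paste0(s, ".cov.tsv")))
      }
      if (!is.null(reads)) {
        out_reads <- transform(reads, snp_pos = snp_pos + 1L,
                               cpg_pos = cpg_pos + 1L)
        write.table(out_reads, file.path(out_dir, "reads.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        write_het_vcf(het, file.path(out_dir, "het.vcf"))
      }
      if (length(truth$dms)) {
        write.table(data.frame(pos = truth$dms),
                    file.path(out_dir, "truth_dms.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
      }
      if (!is.null(asm_truth)) {
        write.table(asm_truth, file.path(out_dir, "truth_asm.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    list(samples = samples, reads = reads, het_snps = het, truth = truth)
  })
}

#' Write a minimal sites-only VCF of heterozygous SNPs
#'
#' @param het data.frame with columns `chrom`, `pos` (0-based), `ref`,
#'   `alt`.
#' @param path output path (plain text VCF 4.2).
#' @return `path`, invisibly.
#' @export
write_het_vcf <- function(het, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##contig=<ID=", unique(het$chrom)[1L], ">"),
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(het)) {
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
                       het$chrom, het$pos + 1L, het$ref, het$alt), con)
  }
  invisible(path)
}

#' Simulate a genome-background window distribution
#'
#' Draws normal window values standing in for a genome-wide background scan
#' (the input of [z_outlier_test()]).
#'
#' @param n_windows number of windows.
#' @param mean,sd background parameters (sd > 0).
#' @param seed RNG seed.
#' @param path optional TSV output (columns window, value).
#' @return data.frame with columns `window`, `value`.
#' @export
sim_window_background <- function(n_windows, mean, sd, seed = NULL,
                                  path = NULL) {
  stopifnot(sd > 0, n_windows >= 0)
  with_seed(seed, {
    out <- data.frame(window = seq_len(n_windows),
                      value = rnorm(n_windows, mean, sd))
    if (!is.null(path)) {
      write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    out
  })
}

#' Allele counts at eight SNPs of the porcine H19 3' region
#'
#' The published survey of the 3' region of the porcine *H19* long
#' non-coding gene: per-position, per-breed-group allele counts at eight
#' SNPs (transcript coordinates, TSS = 1) across six domestic groups --
#' North China (NC, n = 23), Central China (CC, 42), Jianghai (JH, 29),
#' South China (SC, 84), Southwest China (SW, 23), European (EU, 33) --
#' and two wild groups, Sichuan wild boar (WB.S, 3) and Tibetan wild boar
#' (TB, 27). Shipped as a plain-text table and parsed with
#' [read_genotype_count_table()].
#'
#' @return A `genotype_count_table` with classes and group sizes attached.
#' @export
h19_snp_table <- function() {
  path <- system.file("extdata", "h19_snp_counts.tsv", package = "popmeth",
                      mustWork = TRUE)
  classes <- c(NC = "domestic", CC = "domestic", JH = "domestic",
               SC = "domestic", SW = "domestic", EU = "domestic",
               WB.S = "wild", TB = "wild")
  n <- c(NC = 23L, CC = 42L, JH = 29L, SC = 84L, SW = 23L, EU = 33L,
         WB.S = 3L, TB = 27L)
  read_genotype_count_table(path, classes, n)
}
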