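test_that("diversity statistics match brute-force values on the toy panel", {
  aln <- toy_alignment()
  d <- diversity_stats(aln)
  expect_equal(d$S, 2L)
  expect_equal(d$pi_total, 7 / 6)
  expect_equal(d$theta_w_total, 2 / (1 + 1 / 2 + 1 / 3))
  expect_equal(d$Hd, (4 / 3) * (1 - 6 / 16))
  expect_equal(d$pi_site, (7 / 6) / 10)

  mono <- haplotype_alignment(c(a = "ACGT", b = "ACGT", c = "ACGT"),
                              setNames(rep("g", 3), c("a", "b", "c")))
  dm <- diversity_stats(mono)
  expect_equal(c(dm$S, dm$pi_total, dm$Hd), c(0, 0, 0))
})

test_that("Watterson's theta uses the harmonic-sum normaliser", {
  # n = 10, L = 100, exactly 5 segregating sites (one singleton each)
  mat <- matrix("A", 10, 100, dimnames = list(sprintf("s%d", 1:10), NULL))
  for (j in 1:5) mat[j, j * 10] <- "G"
  aln <- haplotype_alignment(mat, setNames(rep("g", 10), rownames(mat)))
  a1 <- sum(1 / 1:9)
  expect_equal(a1, 2.828968, tolerance = 1e-6)
  d <- diversity_stats(aln)
  expect_equal(d$S, 5L)
  expect_equal(d$theta_w_site, 5 / (a1 * 100))
})

test_that("column-count pi equals brute-force pairwise and frequency forms", {
  set.seed(11)
  for (rep in 1:100) {
    n <- sample(3:10, 1)
    L <- sample(5:50, 1)
    aln <- random_alignment(n, L)
    d <- diversity_stats(aln)
    expect_equal(d$pi_total, brute_pi_total(aln))
    # frequency form: sum over sites of (n/(n-1)) * (1 - sum p_a^2)
    freq_pi <- sum(apply(aln$mat, 2, function(col) {
      p <- table(col) / n
      (n / (n - 1)) * (1 - sum(p^2))
    }))
    expect_equal(d$pi_total, freq_pi)
  }
})

test_that("complete deletion drops columns with N or gaps", {
  aln <- haplotype_alignment(c(a = "ACGTN", b = "ACGT-", c = "ATGTA"),
                             setNames(rep("g", 3), c("a", "b", "c")))
  d <- diversity_stats(aln)
  expect_equal(d$L_used, 4L)  # column 5 excluded
  expect_equal(d$S, 1L)
})

test_that("Tajima's D reproduces the independently derived toy value", {
  aln <- toy_alignment()
  expect_equal(as.numeric(tajimas_d(aln)), 0.5915801398995606,
               tolerance = 1e-9)
  k <- attr(tajimas_d(aln), "constants")
  expect_equal(k$a1, 11 / 6)
  expect_equal(k$e1, (5 / 9 - 6 / 11) / (11 / 6))

  mono <- haplotype_alignment(c(a = "AAAA", b = "AAAA"),
                              c(a = "g", b = "g"))
  expect_true(is.na(tajimas_d(mono)))
  expect_equal(attr(tajimas_d(mono), "reason"), "no segregating sites")
})

test_that("Fu & Li star statistics reproduce the constants-oracle values", {
  aln <- toy_alignment()
  fl <- fu_li_star_tests(aln)
  expect_equal(fl$eta, 2L)
  expect_equal(fl$eta_s, 1L)  # the terminal A carried only by seq1
  # frozen from an independent evaluation of the published constants
  expect_equal(fl$d_star, 0.5915801398995606, tolerance = 1e-9)
  expect_equal(fl$f_star, 0.2621652030966655, tolerance = 1e-9)

  mono <- haplotype_alignment(c(a = "AAAA", b = "AAAA", c = "AAAA"),
                              setNames(rep("g", 3), c("a", "b", "c")))
  expect_true(is.na(fu_li_star_tests(mono)$d_star))
})

test_that("Fay & Wu's H weights derived-frequency classes correctly", {
  aln <- toy_alignment()
  h <- fay_wu_h(aln, rep("A", 10))
  # derived counts {2, 3}: theta_H = (2*4 + 2*9)/12 = 26/12, pi = 14/12
  expect_equal(as.numeric(h), -1.0)
  expect_equal(attr(h, "theta_h"), 26 / 12)

  # a single singleton site: theta_H = 2/12, H = pi - 1/6
  one <- haplotype_alignment(
    c(a = "AAAT", b = "AAAA", c = "AAAA", d = "AAAA"),
    setNames(rep("g", 4), c("a", "b", "c", "d")))
  h1 <- fay_wu_h(one, rep("A", 4))
  expect_equal(as.numeric(h1), 0.5 - 1 / 6)

  # ancestral allele absent from the sample -> skipped with warning
  expect_warning(h2 <- fay_wu_h(aln, c(rep("A", 5), "C", rep("A", 4))),
                 "skipped")
  mono <- haplotype_alignment(c(a = "AAAA", b = "AAAA"),
                              c(a = "g", b = "g"))
  expect_true(is.na(fay_wu_h(mono, rep("A", 4))))
})

test_that("Hudson's Fst matches the brute-force toy value and bounds", {
  aln <- toy_alignment()
  f <- hudson_fst(aln, "X", "Y")
  expect_equal(f$hw, 0.5)
  expect_equal(f$hb, 1.5)
  expect_equal(f$fst, 2 / 3)

  # fixed difference between the groups -> Fst = 1
  fixed <- haplotype_alignment(
    c(a = "AAAA", b = "AAAA", c = "TTTT", d = "TTTT"),
    c(a = "X", b = "X", c = "Y", d = "Y"))
  expect_equal(hudson_fst(fixed, "X", "Y")$fst, 1)

  # no between-group variation -> NA with reason
  same <- haplotype_alignment(
    c(a = "AAAA", b = "AAAA", c = "AAAA", d = "AAAA"),
    c(a = "X", b = "X", c = "Y", d = "Y"))
  fs <- hudson_fst(same, "X", "Y")
  expect_true(is.na(fs$fst))
  expect_match(attr(fs$fst, "reason"), "no between-group")
})

test_that("Fst on split halves of one population is near 0 and <= 1", {
  # two groups sampled from the same coalescent population: expectation 0
  # (literal duplication carries the finite-sample bias -1/(n-1))
  r <- sim_coalescent(40, 2000, 10 / 2000, seed = 99)
  ids <- r$aln$ids
  groups <- setNames(rep(c("u", "v"), each = 20), ids)
  aln <- haplotype_alignment(r$aln$mat, groups)
  f <- hudson_fst(aln, "u", "v")
  expect_lt(abs(f$fst), 0.15)
  expect_lte(f$fst, 1)
})

test_that("net distances match the toy brute force and vanish on identity", {
  aln <- toy_alignment()
  dm <- net_distance_matrix(aln)
  expect_equal(dm["X", "Y"], 0.10)
  expect_true(isSymmetric(unclass(dm)))
  expect_equal(diag(unclass(dm)), setNames(c(0, 0), c("X", "Y")))

  ident <- haplotype_alignment(
    c(a = "ACGT", b = "ACGT", c = "ACGT", d = "ACGT"),
    c(a = "X", b = "X", c = "Y", d = "Y"))
  expect_equal(net_distance_matrix(ident)["X", "Y"], 0)

  one <- haplotype_alignment(c(a = "ACGT", b = "ACGT"),
                             c(a = "X", b = "X"))
  expect_error(net_distance_matrix(one), "2 groups")
})

test_that("neighbor joining recovers additive trees and handles ties", {
  # additive 4-taxon tree ((A,B),(C,D)): dAB = 3, dCD = 7, internal 1
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- 3; d["C", "D"] <- 7
  d["A", "C"] <- 5; d["A", "D"] <- 6
  d["B", "C"] <- 6; d["B", "D"] <- 7
  d <- d + t(d)
  tr <- nj_tree(d)
  # the split {A,B} | {C,D} must be present
  parts <- ape::prop.part(ape::unroot(tr))
  tipsets <- lapply(parts, function(p) sort(attr(parts, "labels")[p]))
  expect_true(any(vapply(tipsets, identical, logical(1), c("A", "B"))) ||
              any(vapply(tipsets, identical, logical(1), c("C", "D"))))
  # additive distances are reproduced exactly on the tree
  expect_equal(as.matrix(ape::cophenetic.phylo(tr))[rownames(d), colnames(d)],
               d, tolerance = 1e-8)

  # equal distances: deterministic under the label-order tie rule
  eq <- matrix(1, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(eq) <- 0
  t1 <- ape::write.tree(nj_tree(eq))
  t2 <- ape::write.tree(nj_tree(eq))
  expect_identical(t1, t2)

  asym <- d; asym[1, 2] <- 99
  expect_error(nj_tree(asym), "symmetric")
})

test_that("negative NJ branch lengths are clamped with compensation", {
  set.seed(5)
  for (i in 1:10) {
    labs <- letters[1:5]
    m <- matrix(runif(25, 0.1, 1), 5, 5, dimnames = list(labs, labs))
    m <- (m + t(m)) / 2; diag(m) <- 0
    tr <- nj_tree(m)
    expect_true(all(tr$edge.length >= 0))
  }
})

test_that("window tiling follows the width/step arithmetic", {
  region <- genomic_interval("chrH19", 0, 2608, "gene_body")
  w <- make_windows(region, 1000, 300)
  expect_equal(w$start, seq(0, 2400, by = 300))
  expect_equal(w$end[1:6], seq(0, 1500, by = 300) + 1000)
  expect_equal(w$end[7:9], rep(2608L, 3))
  expect_equal(w$partial, c(rep(FALSE, 6), rep(TRUE, 3)))

  short <- make_windows(genomic_interval("c", 0, 500), 1000, 300)
  expect_equal(nrow(short), 2L)  # starts 0 and 300, both partial
  expect_true(all(short$partial))

  tile <- make_windows(genomic_interval("c", 0, 3000), 1000, 1000)
  expect_equal(tile$start, c(0, 1000, 2000))
  expect_false(any(tile$partial))
  expect_error(make_windows(region, 0, 300))
  expect_error(make_windows(region, 1000, 1200))
})

test_that("window scans agree with whole-region estimates", {
  aln <- toy_alignment()
  # one window covering everything equals the unwindowed statistic
  wins <- make_windows(genomic_interval("c", 0, 10), 10, 10)
  tr <- window_scan(aln, wins, "pi")
  expect_equal(tr$value, diversity_stats(aln)$pi_site)
  expect_equal(tr$sites_used, 10L)

  trf <- window_scan(aln, wins, "fst", pop_a = "X", pop_b = "Y")
  expect_equal(trf$value, hudson_fst(aln, "X", "Y")$fst)

  # monomorphic window -> pi = 0; window with variation only in X -> ratio NA
  wins2 <- make_windows(genomic_interval("c", 0, 10), 5, 5)
  tr2 <- window_scan(aln, wins2, "pi")
  expect_equal(tr2$value[1], 0)
  ratio <- window_scan(aln, wins2, "theta_pi_ratio",
                       pop_a = "X", pop_b = "Y")
  expect_true(is.na(ratio$value[1]))  # pi_Y = 0 in window 1

  # overlapping windows double-count sites
  over <- window_scan(aln, make_windows(genomic_interval("c", 0, 10), 6, 2),
                      "pi")
  expect_gte(sum(over$sites_used), 10L)
})

test_that("the outlier Z-test matches normal-tail arithmetic", {
  expect_equal(z_outlier_test(0.5, 0.5, 0.1)$p, 0.5)
  expect_equal(z_outlier_test(0.5, 0.5, 0.1)$z, 0)
  two <- z_outlier_test(1.96, 0, 1, side = "two_sided")
  expect_equal(two$p, 0.05, tolerance = 1e-3)
  below <- z_outlier_test(-1, 0, 1, side = "greater")
  expect_gt(below$p, 0.5)
  expect_error(z_outlier_test(1, 0, 0), "genome_sd")
})

test_that("site sharing classification partitions positions", {
  tab <- h19_snp_table()
  cl <- classify_site_sharing(tab)
  expect_equal(cl$by_pos$class[cl$by_pos$pos == 1818], "domestic_only")
  expect_equal(cl$by_pos$class[cl$by_pos$pos == 2020], "shared")
  expect_equal(sum(cl$summary), nrow(cl$by_pos))

  tab$class <- NA_character_
  expect_error(classify_site_sharing(tab), "class")
})
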