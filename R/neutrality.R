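# eta (minimal mutation count, = S under infinite sites) and eta_s
# (singletons: alleles carried by exactly one sequence at a segregating
# site), from a base-count matrix
eta_counts <- function(cnt) {
  k <- colSums(cnt > 0L)
  seg <- k > 1L
  list(eta = sum(k[seg] - 1L),
       eta_s = sum(cnt[, seg, drop = FALSE] == 1L))
}

tajima_constants <- function(n) {
  a1 <- harmonic_a1(n); a2 <- harmonic_a2(n)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = e1, e2 = e2)
}

na_stat <- function(reason) structure(NA_real_, reason = reason)

#' Tajima's D
#'
#' Normalized difference between the pairwise (pi) and segregating-site
#' (Watterson) estimates of the population mutation rate, with the 1989
#' variance constants. Approximately zero under neutral equilibrium.
#'
#' @param aln a [haplotype_alignment()].
#' @param group optional group label to subset.
#' @return Numeric D, with the constants used attached as attribute
#'   `constants`; `NA` with attribute `reason` when there are no
#'   segregating sites.
#' @export
tajimas_d <- function(aln, group = NULL) {
  aln <- aln_subset(aln, group)
  d <- diversity_stats(aln)
  if (d$S == 0L) return(na_stat("no segregating sites"))
  k <- tajima_constants(d$n)
  D <- (d$pi_total - d$S / k$a1) /
    sqrt(k$e1 * d$S + k$e2 * d$S * (d$S - 1))
  structure(D, constants = k)
}

fu_li_constants <- function(n) {
  a <- harmonic_a1(n); b <- harmonic_a2(n)
  an1 <- a + 1 / n  # a_{n+1}
  cn <- 2 * (n * a - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    (2 / (n - 1)) * (1.5 - (2 * an1 - 3) / (n - 2) - 1 / n)
  vD <- ((n / (n - 1))^2 * b + a^2 * dn -
           2 * (n * a * (a + 1)) / (n - 1)^2) / (a^2 + b)
  uD <- (n / (n - 1)) * (a - n / (n - 1)) - vD
  vF <- (dn + 2 * (n^2 + n + 3) / (9 * n * (n - 1)) -
           (2 / (n - 1)) * (4 * b - 6 + 8 / n)) / (a^2 + b)
  uF <- ((n / (n - 1) + (n + 1) / (3 * (n - 1)) - 4 / (n * (n - 1)) +
            2 * (n + 1) / (n - 1)^2 * (an1 - 2 * n / (n + 1))) / a) - vF
  list(a = a, b = b, cn = cn, dn = dn, uD = uD, vD = vD, uF = uF, vF = vF)
}

#' Fu and Li's D* and F* (no outgroup)
#'
#' Star variants of the Fu & Li (1993) tests, contrasting the singleton
#' count with total polymorphism; the F* variance uses the corrected
#' constants of Simonsen et al. (1995). A singleton is an allele observed
#' in exactly one sequence at a segregating site.
#'
#' @param aln a [haplotype_alignment()].
#' @param group optional group label to subset.
#' @return list with `d_star`, `f_star`, `eta`, `eta_s` and the variance
#'   `constants`; statistics are `NA` with a `reason` attribute when the
#'   panel is monomorphic.
#' @export
fu_li_star_tests <- function(aln, group = NULL) {
  aln <- aln_subset(aln, group)
  n <- nrow(aln$mat)
  if (n < 3L) stop("Fu & Li star statistics need n >= 3")
  cols <- complete_columns(aln$mat)
  cnt <- base_counts(aln$mat[, cols, drop = FALSE])
  et <- eta_counts(cnt)
  if (et$eta == 0L) {
    return(list(d_star = na_stat("no segregating sites"),
                f_star = na_stat("no segregating sites"),
                eta = 0L, eta_s = 0L, constants = NULL))
  }
  k <- fu_li_constants(n)
  eta <- et$eta; eta_s <- et$eta_s
  d_star <- ((n / (n - 1)) * eta - k$a * eta_s) /
    sqrt(k$uD * eta + k$vD * eta^2)
  pi_total <- sum(column_pi_vec(cnt, n))
  f_star <- (pi_total - ((n - 1) / n) * eta_s) /
    sqrt(k$uF * eta + k$vF * eta^2)
  list(d_star = d_star, f_star = f_star, eta = et$eta, eta_s = et$eta_s,
       constants = k)
}

#' Fay and Wu's H
#'
#' Unnormalized H = pi - theta_H, where theta_H weights segregating sites by
#' the square of their derived-allele count. Requires a declared ancestral
#' base per site; segregating sites whose ancestral allele is not present in
#' the sample are skipped with a warning.
#'
#' @param aln a [haplotype_alignment()].
#' @param ancestral character vector of length `L` giving the ancestral base
#'   per alignment column (NA allowed at monomorphic columns).
#' @param group optional group label to subset.
#' @return Numeric H (attribute `theta_h` carries theta_H); `NA` with a
#'   `reason` attribute when monomorphic or when all sites were skipped.
#' @export
fay_wu_h <- function(aln, ancestral, group = NULL) {
  aln <- aln_subset(aln, group)
  n <- nrow(aln$mat)
  if (length(ancestral) != aln$L) {
    stop("ancestral must have one base per alignment column (length L)")
  }
  cols <- complete_columns(aln$mat)
  seg <- cols[vapply(cols, function(j) {
    length(unique(aln$mat[, j])) > 1L
  }, logical(1))]
  if (length(seg) == 0L) return(na_stat("no segregating sites"))
  theta_h <- 0
  pi_total <- 0
  skipped <- 0L
  for (j in seg) {
    ct <- table(aln$mat[, j])
    anc <- toupper(ancestral[j])
    if (is.na(anc) || !(anc %in% names(ct))) {
      skipped <- skipped + 1L
      next
    }
    derived <- ct[names(ct) != anc]
    theta_h <- theta_h + sum(2 * derived^2) / (n * (n - 1))
    pi_total <- pi_total + column_pi(ct, n)
  }
  if (skipped > 0L) {
    warning(skipped, " segregating site(s) skipped: ancestral allele ",
            "absent from the sample")
  }
  if (skipped == length(seg)) return(na_stat("all sites skipped"))
  structure(pi_total - theta_h, theta_h = theta_h)
}

#' All neutrality statistics at once
#'
#' @param aln a [haplotype_alignment()].
#' @param ancestral optional ancestral base per column; when supplied,
#'   Fay and Wu's H is included.
#' @param group optional group label to subset.
#' @return Object of class `neutrality_result`: list with `tajima_d`,
#'   `fu_li_d_star`, `fu_li_f_star`, `fay_wu_h` (NA with reason when not
#'   computable), `eta`, `eta_s` and the constant sets used.
#' @export
neutrality_stats <- function(aln, ancestral = NULL, group = NULL) {
  fl <- fu_li_star_tests(aln, group)
  out <- list(
    tajima_d = tajimas_d(aln, group),
    fu_li_d_star = fl$d_star,
    fu_li_f_star = fl$f_star,
    fay_wu_h = if (is.null(ancestral)) {
      na_stat("no ancestral states supplied")
    } else {
      fay_wu_h(aln, ancestral, group)
    },
    eta = fl$eta, eta_s = fl$eta_s,
    constants = list(tajima = attr(tajimas_d(aln, group), "constants"),
                     fu_li = fl$constants)
  )
  class(out) <- "neutrality_result"
  out
}

#' @export
print.neutrality_result <- function(x, ...) {
  fmt <- function(v) {
    if (is.na(v)) paste0("NA (", attr(v, "reason"), ")") else sprintf("%.4f", v)
  }
  cat("Neutrality tests:\n")
  cat("  Tajima's D   :", fmt(x$tajima_d), "\n")
  cat("  Fu & Li's D* :", fmt(x$fu_li_d_star), "\n")
  cat("  Fu & Li's F* :", fmt(x$fu_li_f_star), "\n")
  cat("  Fay & Wu's H :", fmt(x$fay_wu_h), "\n")
  invisible(x)
}
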