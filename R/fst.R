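# per-column within-group mean pairwise difference and cross-group mean
# difference, computed from allele counts (complete deletion across the
# rows in use)
pair_diff_sums <- function(mat_a, mat_b) {
  mat <- rbind(mat_a, mat_b)
  cols <- complete_columns(mat)
  na <- nrow(mat_a); nb <- nrow(mat_b)
  if (length(cols) == 0L) {
    return(list(hw_a = 0, hw_b = 0, hb = 0, L_used = 0L))
  }
  ca <- base_counts(mat_a[, cols, drop = FALSE])
  cb <- base_counts(mat_b[, cols, drop = FALSE])
  hw_a <- if (na >= 2L) sum(column_pi_vec(ca, na)) else 0
  hw_b <- if (nb >= 2L) sum(column_pi_vec(cb, nb)) else 0
  hb <- sum((na * nb - colSums(ca * cb)) / (na * nb))
  list(hw_a = hw_a, hw_b = hw_b, hb = hb, L_used = length(cols))
}

#' Hudson's Fst between two populations
#'
#' Fst = 1 - Hw/Hb where Hw is the unweighted mean of the two within-group
#' mean pairwise difference counts and Hb the mean difference over all
#' cross-group pairs. Columns containing N or "-" in either group are
#' excluded.
#'
#' @param aln a [haplotype_alignment()] with group labels.
#' @param pop_a,pop_b group labels to compare (each needs >= 2 sequences).
#' @return Object of class `fst_result`: list with `pop_a`, `pop_b`,
#'   `n_a`, `n_b`, `hw`, `hb`, `fst` (NA with reason when `hb` is 0) and
#'   `L_used`.
#' @export
hudson_fst <- function(aln, pop_a, pop_b) {
  sub_a <- aln_subset(aln, pop_a)
  sub_b <- aln_subset(aln, pop_b)
  ps <- pair_diff_sums(sub_a$mat, sub_b$mat)
  hw <- (ps$hw_a + ps$hw_b) / 2
  fst <- if (ps$hb == 0) {
    na_stat("no between-group variation")
  } else {
    1 - hw / ps$hb
  }
  out <- list(pop_a = pop_a, pop_b = pop_b,
              n_a = nrow(sub_a$mat), n_b = nrow(sub_b$mat),
              hw = hw, hb = ps$hb, fst = fst, L_used = ps$L_used)
  class(out) <- "fst_result"
  out
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("Hudson Fst(%s, %s): ", x$pop_a, x$pop_b))
  if (is.na(x$fst)) {
    cat("NA (", attr(x$fst, "reason"), ")\n", sep = "")
  } else {
    cat(sprintf("%.4f  (Hw = %.4f, Hb = %.4f, n = %d + %d)\n",
                x$fst, x$hw, x$hb, x$n_a, x$n_b))
  }
  invisible(x)
}

#' Net (Nei's dA) distance matrix between groups
#'
#' Per-site net divergence d_net(X, Y) = d_XY - (d_X + d_Y)/2, where d_XY is
#' the mean per-site cross-pair difference and d_X, d_Y the within-group
#' means. Negative values (within-diversity exceeding between) are reported,
#' not clamped. Groups with a single sequence get within-distance 0 with a
#' warning.
#'
#' @param aln a [haplotype_alignment()] with >= 2 groups.
#' @return Symmetric numeric matrix of class `dist_matrix` (zero diagonal),
#'   labelled by group.
#' @export
net_distance_matrix <- function(aln) {
  grps <- sort(unique(unname(aln$groups)))
  if (length(grps) < 2L) stop("net distance needs at least 2 groups")
  singletons <- grps[vapply(grps, function(g) sum(aln$groups == g) < 2L,
                            logical(1))]
  if (length(singletons)) {
    warning("group(s) with a single sequence use within-distance 0: ",
            paste(singletons, collapse = ", "))
  }
  m <- matrix(0, length(grps), length(grps), dimnames = list(grps, grps))
  for (i in seq_along(grps)) {
    for (j in seq_along(grps)) {
      if (j <= i) next
      ma <- aln$mat[aln$groups == grps[i], , drop = FALSE]
      mb <- aln$mat[aln$groups == grps[j], , drop = FALSE]
      ps <- pair_diff_sums(ma, mb)
      if (ps$L_used == 0L) stop("no usable columns between groups ",
                                grps[i], " and ", grps[j])
      d_x <- if (nrow(ma) >= 2L) ps$hw_a else 0
      d_y <- if (nrow(mb) >= 2L) ps$hw_b else 0
      d_net <- (ps$hb - (d_x + d_y) / 2) / ps$L_used
      m[i, j] <- m[j, i] <- d_net
    }
  }
  class(m) <- c("dist_matrix", class(m))
  m
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (Q-criterion). Labels are sorted
#' lexicographically before joining so ties resolve deterministically.
#' Negative branch lengths are clamped to zero with the excess moved to the
#' sister branch, preserving path lengths through the parent node.
#'
#' @param dm symmetric numeric matrix with labelled rows/columns (e.g. from
#'   [net_distance_matrix()]); 2 labels give a single midpoint-split edge.
#' @return An `ape` `phylo` tree (unrooted for >= 3 labels).
#' @export
nj_tree <- function(dm) {
  dm <- unclass(dm)
  if (!isSymmetric(unname(dm), tol = 1e-8)) {
    stop("distance matrix must be symmetric")
  }
  labs <- sort(rownames(dm))
  dm <- dm[labs, labs]
  if (length(labs) < 2L) stop("need at least 2 labels")
  if (length(labs) == 2L) {
    half <- dm[1L, 2L] / 2
    txt <- sprintf("(%s:%g,%s:%g);", labs[1L], half, labs[2L], half)
    return(ape::read.tree(text = txt))
  }
  tr <- ape::nj(as.dist(dm))
  clamp_negative_branches(tr)
}

# move negative edge lengths onto the sister edge (same parent), keeping
# parent-to-descendant path lengths unchanged
clamp_negative_branches <- function(tr) {
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    parent <- tr$edge[e, 1L]
    sibs <- which(tr$edge[, 1L] == parent & seq_len(nrow(tr$edge)) != e)
    excess <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    if (length(sibs)) {
      tr$edge.length[sibs[1L]] <- tr$edge.length[sibs[1L]] + excess
    }
  }
  tr
}
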