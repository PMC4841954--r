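#' Classify SNP sharing between domestic and wild groups
#'
#' A position is polymorphic within a class (domestic or wild) when any
#' group of that class segregates two alleles there (minor count >= 1).
#' Positions are then classified `domestic_only`, `wild_only`, `shared`
#' (polymorphic in both classes) or `monomorphic`.
#'
#' @param table a `genotype_count_table` from
#'   [read_genotype_count_table()] or [h19_snp_table()]; every group must
#'   carry a declared class.
#' @return Object of class `sharing_classification`: list with `by_pos`
#'   (data.frame pos, class) and `summary` (named counts over the four
#'   classes).
#' @export
classify_site_sharing <- function(table) {
  if (any(is.na(table$class))) {
    stop("every group needs a declared class (domestic/wild)")
  }
  poly <- !is.na(table$allele2) & table$count2 >= 1L
  by_pos <- do.call(rbind, lapply(split(seq_len(nrow(table)), table$pos),
    function(idx) {
      dom <- any(poly[idx] & table$class[idx] == "domestic")
      wld <- any(poly[idx] & table$class[idx] == "wild")
      cls <- if (dom && wld) "shared" else if (dom) "domestic_only" else
        if (wld) "wild_only" else "monomorphic"
      data.frame(pos = table$pos[idx[1L]], class = cls,
                 stringsAsFactors = FALSE)
    }))
  by_pos <- by_pos[order(by_pos$pos), , drop = FALSE]
  rownames(by_pos) <- NULL
  lev <- c("domestic_only", "wild_only", "shared", "monomorphic")
  summary <- table(factor(by_pos$class, levels = lev))
  out <- list(by_pos = by_pos, summary = setNames(as.integer(summary), lev))
  class(out) <- "sharing_classification"
  out
}

#' @export
print.sharing_classification <- function(x, ...) {
  cat("SNP sharing classification of", nrow(x$by_pos), "positions:\n")
  for (cl in names(x$summary)) {
    cat(sprintf("  %-14s %d\n", cl, x$summary[[cl]]))
  }
  invisible(x)
}
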