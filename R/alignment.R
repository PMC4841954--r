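#' Haplotype alignment
#'
#' Container for an equal-length panel of haplotype sequences with a
#' population label per sequence. This is the substrate of every diversity
#' statistic in the package. Bases are stored uppercase over the alphabet
#' `A, C, G, T, N, -`; other IUPAC ambiguity codes are rejected because the
#' diversity statistics assume resolved bases.
#'
#' @param seqs character vector of sequences (equal lengths), named by
#'   sequence id, or a character matrix (rows = sequences).
#' @param groups named character vector mapping sequence id to group label;
#'   every id must be present.
#' @param classes optional named character vector mapping group label to a
#'   class such as `"domestic"` or `"wild"`.
#' @return Object of class `haplotype_alignment`: a list with elements
#'   `ids`, `groups`, `classes`, `mat` (character matrix, rows = sequences)
#'   and `L` (alignment length).
#' @export
haplotype_alignment <- function(seqs, groups, classes = NULL) {
  if (is.matrix(seqs)) {
    mat <- seqs
    ids <- rownames(mat)
  } else {
    ids <- names(seqs)
    if (is.null(ids)) ids <- sprintf("seq%d", seq_along(seqs))
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1L) {
      bad <- ids[which(lens != lens[1L])[1L]]
      stop("unequal sequence lengths: record '", bad, "' has length ",
           nchar(seqs[bad]), ", expected ", lens[1L])
    }
    mat <- do.call(rbind, strsplit(toupper(seqs), ""))
    rownames(mat) <- ids
  }
  mat[] <- toupper(mat)
  bad <- setdiff(unique(as.vector(mat)), c("A", "C", "G", "T", "N", "-"))
  if (length(bad)) {
    stop("disallowed characters in alignment: ", paste(bad, collapse = ", "),
         " (ambiguity codes other than N are rejected)")
  }
  if (nrow(mat) < 2L) stop("an alignment needs at least 2 sequences")
  missing_ids <- setdiff(ids, names(groups))
  if (length(missing_ids)) {
    stop("sequence id(s) missing from population map: ",
         paste(missing_ids, collapse = ", "))
  }
  obj <- list(ids = ids, groups = groups[ids], classes = classes,
              mat = mat, L = ncol(mat))
  class(obj) <- "haplotype_alignment"
  obj
}

#' @export
print.haplotype_alignment <- function(x, ...) {
  cat("haplotype_alignment: n =", nrow(x$mat), "sequences, L =", x$L, "sites\n")
  cat("groups:", paste(sprintf("%s (%d)", names(table(x$groups)),
                               table(x$groups)), collapse = ", "), "\n")
  invisible(x)
}

#' Subset an alignment to one population
#'
#' @param aln a [haplotype_alignment()].
#' @param group group label to keep; `NULL` keeps all sequences.
#' @return A `haplotype_alignment` of the selected sequences.
#' @export
aln_subset <- function(aln, group = NULL) {
  if (is.null(group)) return(aln)
  keep <- names(aln$groups)[aln$groups %in% group]
  if (length(keep) < 2L) {
    stop("group '", paste(group, collapse = "/"),
         "' has fewer than 2 sequences")
  }
  haplotype_alignment(aln$mat[keep, , drop = FALSE], aln$groups[keep],
                      aln$classes)
}

# Columns usable under complete deletion: no N and no gap anywhere.
complete_columns <- function(mat) {
  which(colSums(mat == "N" | mat == "-") == 0L)
}
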