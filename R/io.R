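#' Read an aligned FASTA panel with a population map
#'
#' Reads one-record-per-haplotype aligned FASTA (equal lengths required) and
#' attaches group labels from a population map.
#'
#' @param path FASTA file of aligned sequences.
#' @param popmap_path TSV without header: columns id, group and optionally
#'   class (e.g. domestic / wild).
#' @return A [haplotype_alignment()].
#' @export
read_fasta_alignment <- function(path, popmap_path) {
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  lens <- Biostrings::width(ss)
  if (length(unique(lens)) > 1L) {
    bad <- ids[which(lens != max(lens))[1L]]
    stop("unequal sequence lengths in ", path, ": record '", bad,
         "' has length ", lens[ids == bad][1L])
  }
  seqs <- setNames(toupper(as.character(ss)), ids)
  pm <- read_popmap(popmap_path)
  haplotype_alignment(seqs, pm$groups, pm$classes)
}

#' Read a population map
#'
#' @param path TSV without header: id, group and optional class column.
#' @return list with `groups` (named id -> group) and `classes`
#'   (named group -> class, or NULL).
#' @export
read_popmap <- function(path) {
  pm <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(pm) < 2L) stop("popmap needs at least two columns (id, group)")
  groups <- setNames(as.character(pm[[2L]]), as.character(pm[[1L]]))
  classes <- NULL
  if (ncol(pm) >= 3L) {
    cl <- unique(data.frame(group = pm[[2L]], class = pm[[3L]],
                            stringsAsFactors = FALSE))
    if (anyDuplicated(cl$group)) {
      stop("popmap assigns more than one class to a group")
    }
    classes <- setNames(cl$class, cl$group)
  }
  list(groups = groups, classes = classes)
}

#' Write an alignment back to FASTA
#'
#' @param aln a [haplotype_alignment()].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(aln, path) {
  seqs <- apply(aln$mat, 1L, paste, collapse = "")
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- aln$ids
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a per-CpG cytosine report
#'
#' Bismark-cytosine-report-like TSV without header: chrom, 1-based position,
#' strand, methylated count, unmethylated count, context. Positions are
#' converted to the package's internal 0-based convention.
#'
#' @param path TSV path.
#' @return data.frame of class `cytosine_report`, sorted by (chrom, pos),
#'   with columns `chrom`, `pos` (0-based), `strand`, `meth`, `unmeth`,
#'   `context`.
#' @export
read_cytosine_report <- function(path) {
  raw <- tryCatch(
    read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
               col.names = c("chrom", "pos", "strand", "meth", "unmeth",
                             "context"),
               colClasses = c("character", "character", "character",
                              "character", "character", "character")),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e))) NULL else stop(e)
    })
  if (is.null(raw) || nrow(raw) == 0L) {
    out <- data.frame(chrom = character(), pos = integer(),
                      strand = character(), meth = integer(),
                      unmeth = integer(), context = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("cytosine_report", "data.frame")
    return(out)
  }
  num <- function(col, name) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) | v != floor(v) | (name != "pos" & v < 0) |
                   (name == "pos" & v < 1))
    if (length(bad)) {
      stop("invalid ", name, " in ", path, " at line ", bad[1L], ": '",
           raw[[col]][bad[1L]], "'")
    }
    as.integer(v)
  }
  out <- data.frame(
    chrom = raw$chrom,
    pos = num("pos", "pos") - 1L,          # file is 1-based, internal 0-based
    strand = raw$strand,
    meth = num("meth", "meth_count"),
    unmeth = num("unmeth", "unmeth_count"),
    context = raw$context,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cytosine_report", "data.frame")
  out
}

#' Write a cytosine report
#'
#' Inverse of [read_cytosine_report()]; positions are written 1-based.
#'
#' @param records a `cytosine_report` data.frame (0-based positions).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_cytosine_report <- function(records, path) {
  out <- data.frame(chrom = records$chrom, pos = records$pos + 1L,
                    strand = records$strand, meth = records$meth,
                    unmeth = records$unmeth, context = records$context)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a per-group genotype count table
#'
#' Parses a TSV of per-position, per-group genotype cells in the style of a
#' published SNP survey: a header line `pos<TAB>group1<TAB>group2...`, then
#' one row per position with cells either a single fixed allele (`"C"`) or
#' `"C/T(80/4)"` meaning allele C observed 80 times and allele T 4 times.
#' Positions are transcript coordinates (TSS = 1) and are kept as given --
#' they are never mixed with the package's 0-based genomic coordinates.
#'
#' @param path TSV path.
#' @param group_classes named character vector group -> class
#'   ("domestic" or "wild").
#' @param group_n optional named integer vector group -> number of
#'   chromosomes sampled; when given, cells whose counts do not sum to it
#'   raise a warning naming the cell.
#' @return data.frame of class `genotype_count_table` in long form: columns
#'   `pos`, `group`, `class`, `allele1`, `allele2`, `count1`, `count2`
#'   (`allele2`/`count2` are NA/0 for monomorphic cells).
#' @export
read_genotype_count_table <- function(path, group_classes, group_n = NULL) {
  tab <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "#")
  groups <- setdiff(names(tab), "pos")
  rows <- list()
  for (i in seq_len(nrow(tab))) {
    for (g in groups) {
      cell <- gsub("\\s", "", as.character(tab[i, g]))
      m <- regmatches(cell,
        regexec("^([ACGT])/([ACGT])\\(([0-9]+)/([0-9]+)\\)$", cell))[[1L]]
      if (length(m) == 5L) {
        row <- data.frame(pos = tab$pos[i], group = g,
                          allele1 = m[2L], allele2 = m[3L],
                          count1 = as.integer(m[4L]),
                          count2 = as.integer(m[5L]),
                          stringsAsFactors = FALSE)
      } else if (grepl("^[ACGT]$", cell)) {
        row <- data.frame(pos = tab$pos[i], group = g,
                          allele1 = cell, allele2 = NA_character_,
                          count1 = NA_integer_, count2 = 0L,
                          stringsAsFactors = FALSE)
      } else {
        stop("cannot parse genotype cell '", cell, "' (pos ", tab$pos[i],
             ", group ", g, ")")
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  missing_cls <- setdiff(unique(out$group), names(group_classes))
  if (length(missing_cls)) {
    stop("group(s) without a declared class: ",
         paste(missing_cls, collapse = ", "))
  }
  out$class <- unname(group_classes[out$group])
  if (!is.null(group_n)) {
    # monomorphic cells: all n copies carry allele1
    mono <- is.na(out$allele2)
    out$count1[mono] <- unname(group_n[out$group[mono]])
    tot <- out$count1 + out$count2
    bad <- which(tot != unname(group_n[out$group]))
    for (b in bad) {
      warning("counts at pos ", out$pos[b], " group ", out$group[b],
              " sum to ", tot[b], ", expected n = ",
              group_n[out$group[b]])
    }
  }
  out <- out[, c("pos", "group", "class", "allele1", "allele2",
                 "count1", "count2")]
  attr(out, "group_n") <- group_n
  class(out) <- c("genotype_count_table", "data.frame")
  out
}

#' Read heterozygous SNPs from a VCF
#'
#' Consumes only biallelic SNP records (single-base REF and ALT). Positions
#' are converted to the internal 0-based convention.
#'
#' @param path VCF 4.x file (uncompressed or bgzipped).
#' @return data.frame with columns `chrom`, `pos` (0-based), `ref`, `alt`.
#' @export
read_het_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)  # single record comes back as vector
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      stringsAsFactors = FALSE))
  }
  keep <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  fix <- fix[keep, , drop = FALSE]
  data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS) - 1L,
             ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
}

#' Write a tree in Newick format
#'
#' @param tree an `ape` `phylo` object (e.g. from [nj_tree()]).
#' @param path output path; the string is terminated by ";".
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo' object")
  ape::write.tree(tree, file = path)
  invisible(path)
}
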