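#' Genomic interval
#'
#' Half-open, 0-based interval \[start, end). All internal coordinates in the
#' package are 0-based half-open; file formats keep their own convention
#' (BED 0-based, VCF and cytosine reports 1-based) with conversion at the
#' read/write boundary only.
#'
#' @param chrom chromosome / contig name.
#' @param start 0-based inclusive start, `0 <= start < end`.
#' @param end exclusive end.
#' @param label optional interval name.
#' @return A one-row data.frame of class `genomic_interval` with columns
#'   `chrom`, `start`, `end`, `label`.
#' @export
genomic_interval <- function(chrom, start, end, label = NA_character_) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start >= end) {
    stop("invalid interval [", start, ", ", end, "): need 0 <= start < end")
  }
  out <- data.frame(chrom = as.character(chrom), start = start, end = end,
                    label = as.character(label), stringsAsFactors = FALSE)
  class(out) <- c("genomic_interval", "data.frame")
  out
}

#' Interval length
#' @param x a `genomic_interval`.
#' @return `end - start`.
#' @export
interval_length <- function(x) x$end - x$start

#' Tile a region into sliding windows
#'
#' Windows start at `region$start + k * step` for `k = 0, 1, ...` while the
#' start lies inside the region; each window ends at
#' `min(start + width, region$end)`. Terminal windows shorter than `width`
#' are emitted and flagged `partial` rather than dropped.
#'
#' @param region a [genomic_interval()].
#' @param width window width in bp (> 0).
#' @param step step between window starts, `0 < step <= width`.
#' @return data.frame with columns `chrom`, `start`, `end`, `label`,
#'   `partial` (one row per window, 0-based half-open).
#' @export
make_windows <- function(region, width, step) {
  width <- as.integer(width); step <- as.integer(step)
  if (is.na(width) || width <= 0L) stop("width must be > 0")
  if (is.na(step) || step <= 0L || step > width) stop("need 0 < step <= width")
  starts <- seq.int(region$start, region$end - 1L, by = step)
  ends <- pmin(starts + width, region$end)
  data.frame(
    chrom = region$chrom,
    start = starts,
    end = ends,
    label = sprintf("win%d", seq_along(starts)),
    partial = (ends - starts) < width,
    stringsAsFactors = FALSE
  )
}

#' Write intervals with scores as BED
#'
#' Writes 0-based half-open BED with columns chrom, start, end, name and any
#' additional score columns appended after the name. `NA` scores are written
#' as ".".
#'
#' @param intervals data.frame with columns `chrom`, `start`, `end` and
#'   optionally `label`; any further numeric columns are written as scores.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  if (nrow(intervals) > 0 && any(intervals$start >= intervals$end)) {
    stop("BED intervals must satisfy start < end")
  }
  if (any(intervals$start < 0)) stop("BED intervals must have start >= 0")
  name <- if ("label" %in% names(intervals)) intervals$label else
    sprintf("iv%d", seq_len(nrow(intervals)))
  extra <- setdiff(names(intervals), c("chrom", "start", "end", "label", "partial"))
  out <- data.frame(chrom = intervals$chrom, start = intervals$start,
                    end = intervals$end, name = name,
                    stringsAsFactors = FALSE)
  for (col in extra) out[[col]] <- intervals[[col]]
  df <- as.data.frame(lapply(out, function(x) ifelse(is.na(x), ".", as.character(x))),
                      stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
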