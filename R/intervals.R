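#' Read a BED interval track
#'
#' Reads a BED3+ file (0-based half-open intervals) into a queryable track.
#' Point membership is evaluated against 1-based genomic positions, so a BED
#' interval `start end` contains position `pos` iff `start < pos <= end`.
#' Intervals with `start >= end` are skipped with a warning; input need not
#' be sorted.
#'
#' @param path Path to a BED file (no header; at least chrom, start, end).
#' @return An object of class `interval_track`: a tibble of intervals with
#'   columns `chrom`, `start`, `end` (BED coordinates), reduced to a sorted,
#'   non-overlapping union per chromosome.
#' @seealso [in_track()] for point-membership queries.
#' @export
read_interval_track <- function(path) {
  if (!file.exists(path)) abort(paste0("BED file not found: ", path))
  raw <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end"),
                           colClasses = c("character", "numeric", "numeric"),
                           fill = FALSE)[, 1:3]
  interval_track(as_tibble(raw))
}

#' Build an interval track from a tibble of BED intervals
#'
#' @param intervals Tibble with columns `chrom`, `start`, `end` in BED
#'   (0-based half-open) coordinates.
#' @return An `interval_track` object (reduced union of the input intervals).
#' @export
interval_track <- function(intervals) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  bad <- intervals$start >= intervals$end
  if (any(bad)) {
    warn(paste0("skipping ", sum(bad), " interval(s) with start >= end"))
    intervals <- intervals[!bad, , drop = FALSE]
  }
  if (nrow(intervals) == 0) {
    out <- tibble(chrom = character(), start = numeric(), end = numeric())
    return(structure(out, class = c("interval_track", class(out))))
  }
  # union per chromosome in 1-based closed coordinates, stored back as BED
  reduced <- intervals %>%
    group_by(.data$chrom) %>%
    group_modify(function(df, key) {
      ir <- IRanges::reduce(IRanges::IRanges(start = df$start + 1, end = df$end))
      tibble(start = IRanges::start(ir) - 1, end = as.numeric(IRanges::end(ir)))
    }) %>%
    ungroup() %>%
    arrange(.data$chrom, .data$start)
  structure(reduced, class = c("interval_track", class(reduced)))
}

#' Point membership in an interval track
#'
#' @param track An `interval_track`.
#' @param chrom Character vector of chromosome names.
#' @param pos Numeric vector of 1-based positions (recycled against `chrom`).
#' @return Logical vector: `TRUE` where (chrom, pos) falls inside the track.
#' @export
#' @examples
#' trk <- interval_track(tibble::tibble(chrom = "chr1", start = 99, end = 200))
#' in_track(trk, "chr1", c(99, 100, 200, 201))
in_track <- function(track, chrom, pos) {
  stopifnot(inherits(track, "interval_track"))
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n)
  pos <- rep_len(pos, n)
  out <- logical(n)
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    iv <- track[track$chrom == ch, , drop = FALSE]
    if (nrow(iv) == 0) next
    q <- IRanges::IRanges(start = pos[sel], width = 1)
    s <- IRanges::IRanges(start = iv$start + 1, end = iv$end)
    out[sel] <- IRanges::overlapsAny(q, s)
  }
  out
}

#' Total genomic length covered by a track
#'
#' @param track An `interval_track`.
#' @return Total covered length in bases (intervals are already disjoint).
#' @export
track_coverage <- function(track) {
  stopifnot(inherits(track, "interval_track"))
  sum(track$end - track$start)
}

#' Write an interval track to BED3
#'
#' @param track An `interval_track` (or tibble with chrom/start/end in BED
#'   coordinates).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interval_track <- function(track, path) {
  utils::write.table(track[, c("chrom", "start", "end")], path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
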