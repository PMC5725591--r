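#' Read a BED repeat mask
#'
#' Reads a BED3+ file (0-based, half-open intervals) into a normalised
#' region mask: intervals are converted to 1-based closed coordinates,
#' sorted and merged per chromosome. For a BED interval `(s, e)` the
#' 1-based positions `s+1 .. e` are inside the mask and `e+1` is not.
#'
#' @param path BED file path.
#' @return object of class `region_mask` wrapping a
#'   [GenomicRanges::GRanges] of the merged intervals.
#' @export
read_region_mask <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "extra")[1:3],
                           colClasses = c("character", "integer", "integer"),
                           fill = TRUE)
  if (any(bed$start >= bed$end)) {
    i <- which(bed$start >= bed$end)[1]
    stopf("BED interval with start >= end at line %d (%s %d %d)",
          i, bed$chrom[i], bed$start[i], bed$end[i])
  }
  region_mask(bed$chrom, bed$start, bed$end)
}

#' Construct a region mask from 0-based half-open intervals
#'
#' @param chrom chromosome names.
#' @param start,end 0-based half-open interval bounds (`start < end`).
#' @return object of class `region_mask`.
#' @export
region_mask <- function(chrom = character(), start = integer(), end = integer()) {
  stopifnot(length(chrom) == length(start), length(start) == length(end),
            all(start < end))
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  gr <- GenomicRanges::reduce(GenomicRanges::sort(gr))
  structure(list(ranges = gr), class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("<region_mask> %d merged intervals, %d bases on %d sequences\n",
              length(x$ranges), sum(IRanges::width(x$ranges)),
              length(GenomicRanges::seqnames(GenomicRanges::seqinfo(x$ranges)))))
  invisible(x)
}

#' Test 1-based positions for mask membership
#'
#' @param mask a `region_mask`.
#' @param chrom chromosome names (recycled against `pos`).
#' @param pos 1-based positions.
#' @return logical vector.
#' @export
in_mask <- function(mask, chrom, pos) {
  stopifnot(inherits(mask, "region_mask"))
  if (length(mask$ranges) == 0) return(rep(FALSE, length(pos)))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  GenomicRanges::countOverlaps(q, mask$ranges) > 0
}

# total masked bases per chromosome as a data frame (0-based half-open again)
mask_as_bed <- function(mask) {
  gr <- mask$ranges
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Write a region mask as BED3
#'
#' @param mask a `region_mask`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_region_mask <- function(mask, path) {
  bed <- mask_as_bed(mask)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
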