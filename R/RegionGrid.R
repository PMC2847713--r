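#' Tile a genomic span with fixed-width windows
#'
#' Builds the non-overlapping window layout used by all region-level tallies:
#' half-open windows of \code{window_bp} base pairs anchored at
#' \code{span_start}. The number of windows is
#' \code{ceiling((span_end - span_start)/window_bp)}; the last window may be
#' shorter. The packaged non-pseudoautosomal X layout spans 148.8 Mb, giving
#' 744 windows at 200 kb and 372 at 400 kb.
#'
#' @param span_start,span_end numeric, 0-based half-open span in bp.
#' @param window_bp window width in bp (> 0).
#' @param chrom chromosome label attached to the grid.
#' @return a [RegionGrid-class].
#' @examples
#' length(makeWindows(0, 148.8e6, 200e3))  # 744
#' length(makeWindows(0, 148.8e6, 400e3))  # 372
#' @export
makeWindows <- function(span_start, span_end, window_bp, chrom = "X") {
  if (!is.numeric(window_bp) || length(window_bp) != 1L || window_bp <= 0)
    stop("window_bp must be a single positive number")
  if (span_end <= span_start)
    stop("span_end must exceed span_start")
  new("RegionGrid", chrom = chrom, spanStart = as.numeric(span_start),
      spanEnd = as.numeric(span_end), windowBp = as.numeric(window_bp))
}

#' @describeIn makeWindows number of windows in the grid.
#' @param x a RegionGrid.
#' @export
setMethod("length", "RegionGrid", function(x) {
  as.integer(ceiling((x@spanEnd - x@spanStart) / x@windowBp))
})

#' @describeIn RegionGrid-class 0-based window start positions.
#' @export
setMethod("windowStarts", "RegionGrid", function(grid) {
  grid@spanStart + (seq_len(length(grid)) - 1) * grid@windowBp
})

#' @describeIn RegionGrid-class half-open window end positions (the last is
#'   clipped to the span end).
#' @export
setMethod("windowEnds", "RegionGrid", function(grid) {
  pmin(windowStarts(grid) + grid@windowBp, grid@spanEnd)
})

#' @describeIn RegionGrid-class map 0-based positions to 1-based window
#'   indices; positions outside the span give NA. A position exactly on a
#'   window boundary belongs to the right-hand window.
#' @export
setMethod("assignWindow", "RegionGrid", function(grid, pos) {
  idx <- floor((pos - grid@spanStart) / grid@windowBp) + 1
  idx[pos < grid@spanStart | pos >= grid@spanEnd] <- NA
  as.integer(idx)
})

setMethod("show", "RegionGrid", function(object) {
  cat(sprintf("RegionGrid on %s: %d windows of %g bp over [%g, %g)\n",
              object@chrom, length(object), object@windowBp,
              object@spanStart, object@spanEnd))
})

#' Coerce a RegionGrid to GRanges
#'
#' Windows are returned 1-based closed, the GenomicRanges convention.
#'
#' @param grid a [RegionGrid-class].
#' @return a \code{GRanges} with one range per window.
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @export
gridAsGRanges <- function(grid) {
  GenomicRanges::GRanges(grid@chrom,
                         IRanges::IRanges(start = windowStarts(grid) + 1,
                                          end = windowEnds(grid)))
}

setMethod("show", "DemographySurface", function(object) {
  cat(sprintf("DemographySurface [%s]: %d x %d cells over N_f/N in [%g, %g], m_f/m in [%g, %g]\n",
              object@kind, length(object@xAxis), length(object@yAxis),
              min(object@xAxis), max(object@xAxis),
              min(object@yAxis), max(object@yAxis)))
})

#' @describeIn DemographySurface-class extract the cell matrix
#'   (rows = N_f/N axis, columns = m_f/m axis).
#' @param x a DemographySurface.
#' @param ... ignored.
#' @export
setMethod("as.matrix", "DemographySurface", function(x, ...) {
  m <- x@cells
  dimnames(m) <- list(format(x@xAxis), format(x@yAxis))
  m
})
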