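#' @rdname HaplotypePanel-class
#' @param x a HaplotypePanel.
#' @export
setGeneric("alleleMat", function(x) standardGeneric("alleleMat"))

#' @rdname HaplotypePanel-class
#' @export
setGeneric("markerInfo", function(x) standardGeneric("markerInfo"))

#' @rdname HaplotypePanel-class
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' @rdname HaplotypePanel-class
#' @export
setGeneric("chromType", function(x) standardGeneric("chromType"))

#' @rdname RegionGrid-class
#' @param grid a RegionGrid.
#' @export
setGeneric("windowStarts", function(grid) standardGeneric("windowStarts"))

#' @rdname RegionGrid-class
#' @export
setGeneric("windowEnds", function(grid) standardGeneric("windowEnds"))

#' @rdname RegionGrid-class
#' @param pos numeric vector of 0-based bp positions.
#' @export
setGeneric("assignWindow", function(grid, pos) standardGeneric("assignWindow"))
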