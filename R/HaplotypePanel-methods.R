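#' @describeIn HaplotypePanel-class the markers x copies 0/1 allele matrix.
#' @export
setMethod("alleleMat", "HaplotypePanel", function(x) {
  SummarizedExperiment::assay(x, "alleles")
})

#' @describeIn HaplotypePanel-class the marker table as a data.frame.
#' @export
setMethod("markerInfo", "HaplotypePanel", function(x) {
  as.data.frame(SummarizedExperiment::rowData(x))
})

#' @describeIn HaplotypePanel-class one row per sample (not per copy):
#'   sample_id, sex, population, region, ploidy on this panel.
#' @export
setMethod("sampleInfo", "HaplotypePanel", function(x) {
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  first <- !duplicated(cd$sample_id)
  out <- cd[first, c("sample_id", "sex", "population", "region"), drop = FALSE]
  out$ploidy <- as.integer(table(cd$sample_id)[out$sample_id])
  rownames(out) <- NULL
  out
})

#' @describeIn HaplotypePanel-class "X" or "autosome".
#' @export
setMethod("chromType", "HaplotypePanel", function(x) {
  S4Vectors::metadata(x)$chrom_type
})

setMethod("show", "HaplotypePanel", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat(sprintf("HaplotypePanel (%s): %d markers x %d chromosome copies\n",
              chromType(object), nrow(object), ncol(object)))
  cat(sprintf("  %d samples, %d populations, %d regions\n",
              length(unique(cd$sample_id)), length(unique(cd$population)),
              length(unique(cd$region))))
})

#' Restrict a panel to selected populations or markers
#'
#' Whole samples (all their chromosome copies) are kept so ploidy invariants
#' hold on the subset.
#'
#' @param x a [HaplotypePanel-class].
#' @param populations character vector of population labels to keep.
#' @return a HaplotypePanel.
#' @export
subsetPopulations <- function(x, populations) {
  cd <- SummarizedExperiment::colData(x)
  missing_pop <- setdiff(populations, unique(cd$population))
  if (length(missing_pop))
    stop("population(s) not in panel: ", paste(missing_pop, collapse = ", "))
  x[, cd$population %in% populations]
}

#' @rdname subsetPopulations
#' @param idx integer or logical index over markers (rows).
#' @export
subsetMarkers <- function(x, idx) {
  x[idx, ]
}

#' Number of chromosome copies per population
#'
#' @param x a [HaplotypePanel-class].
#' @return named integer vector.
#' @export
copiesPerPopulation <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  tab <- table(cd$population)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}
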