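#' @import methods
#' @importFrom S4Vectors DataFrame metadata SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

#' HaplotypePanel: phased haplotypes with sample and marker annotation
#'
#' A \code{HaplotypePanel} holds a phased biallelic SNP haplotype matrix as a
#' \linkS4class{SummarizedExperiment}: markers are rows, chromosome copies are
#' columns. The single assay \code{"alleles"} is an integer matrix of 0/1
#' (\code{NA} = missing). Column metadata carries, per chromosome copy, the
#' sample it came from, its copy index, and the sample's sex, population and
#' continental region. Row metadata carries the marker table: id, chromosome,
#' 0-based bp position, cM position, the two alleles, the ancestral state and a
#' genic flag.
#'
#' For X panels males contribute exactly one column and females two; autosomal
#' panels have two columns per sample. The panel kind is stored in
#' \code{metadata(x)$chrom_type} (\code{"X"} or \code{"autosome"}).
#'
#' @slot ... inherited from \code{SummarizedExperiment}.
#' @seealso [HaplotypePanel()] for the constructor, [alleleMat()],
#'   [markerInfo()], [sampleInfo()], [chromType()].
#' @export
setClass("HaplotypePanel", contains = "SummarizedExperiment")

.ANC_STATES <- c("allele0", "allele1", "unknown")

setValidity("HaplotypePanel", function(object) {
  msg <- character()
  if (!"alleles" %in% SummarizedExperiment::assayNames(object))
    return("assay 'alleles' is required")
  al <- SummarizedExperiment::assay(object, "alleles")
  if (!all(al %in% c(0L, 1L, NA)))
    msg <- c(msg, "allele matrix must contain only 0, 1 or NA")
  ct <- S4Vectors::metadata(object)$chrom_type
  if (is.null(ct) || !ct %in% c("X", "autosome"))
    msg <- c(msg, "metadata chrom_type must be 'X' or 'autosome'")
  cd <- SummarizedExperiment::colData(object)
  need_cd <- c("sample_id", "copy", "sex", "population", "region")
  if (!all(need_cd %in% colnames(cd))) {
    msg <- c(msg, paste("colData must have columns:", paste(need_cd, collapse = ", ")))
  } else {
    if (!all(cd$sex %in% c("female", "male")))
      msg <- c(msg, "sex must be 'female' or 'male'")
    cp <- table(cd$sample_id)
    sex1 <- cd$sex[match(names(cp), cd$sample_id)]
    if (identical(ct, "X")) {
      bad <- (sex1 == "male" & cp != 1L) | (sex1 == "female" & cp != 2L)
      if (any(bad))
        msg <- c(msg, paste0("X panel ploidy violated for sample(s): ",
                             paste(names(cp)[bad], collapse = ", ")))
    } else if (identical(ct, "autosome")) {
      if (any(cp != 2L))
        msg <- c(msg, paste0("autosomal panel must have 2 copies per sample; offending: ",
                             paste(names(cp)[cp != 2L], collapse = ", ")))
    }
  }
  rd <- SummarizedExperiment::rowData(object)
  need_rd <- c("marker_id", "chrom", "pos_bp", "pos_cM", "allele0", "allele1",
               "anc_state", "genic")
  if (!all(need_rd %in% colnames(rd))) {
    msg <- c(msg, paste("rowData must have columns:", paste(need_rd, collapse = ", ")))
  } else {
    if (any(rd$pos_bp < 0)) msg <- c(msg, "pos_bp must be >= 0")
    if (!all(rd$anc_state %in% .ANC_STATES))
      msg <- c(msg, "anc_state must be allele0/allele1/unknown")
    o <- order(rd$chrom, rd$pos_bp)
    if (!identical(o, seq_len(nrow(rd))))
      msg <- c(msg, "markers must be sorted by (chrom, pos_bp)")
    for (ch in unique(rd$chrom)) {
      cm <- rd$pos_cM[rd$chrom == ch]
      cm <- cm[!is.na(cm)]
      if (length(cm) > 1L && any(diff(cm) < 0))
        msg <- c(msg, sprintf("pos_cM must be non-decreasing within chrom %s", ch))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a HaplotypePanel
#'
#' @param alleles integer matrix of 0/1 (NA allowed), markers x chromosome
#'   copies.
#' @param markers data.frame with columns \code{marker_id}, \code{chrom},
#'   \code{pos_bp} (0-based), and optionally \code{pos_cM}, \code{allele0},
#'   \code{allele1}, \code{anc_state}, \code{genic}. Missing optional columns
#'   are filled with defaults (1 cM/Mb positions, A/G alleles, unknown
#'   ancestral state, non-genic).
#' @param copies data.frame with one row per column of \code{alleles}:
#'   \code{sample_id}, \code{copy}, \code{sex}, \code{population},
#'   \code{region}.
#' @param chrom_type \code{"X"} or \code{"autosome"}.
#' @return A [HaplotypePanel-class] object.
#' @examples
#' al <- matrix(c(0L, 1L, 1L, 0L, 1L, 1L), nrow = 2)
#' mk <- data.frame(marker_id = c("m1", "m2"), chrom = "X", pos_bp = c(100, 200))
#' cp <- data.frame(sample_id = c("f1", "f1", "m1"), copy = c(1, 2, 1),
#'                  sex = c("female", "female", "male"),
#'                  population = "pop1", region = "r1")
#' HaplotypePanel(al, mk, cp, "X")
#' @export
HaplotypePanel <- function(alleles, markers, copies, chrom_type = c("autosome", "X")) {
  chrom_type <- match.arg(chrom_type)
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  markers <- as.data.frame(markers)
  if (is.null(markers$pos_cM)) markers$pos_cM <- markers$pos_bp * 1e-6
  if (is.null(markers$allele0)) markers$allele0 <- "A"
  if (is.null(markers$allele1)) markers$allele1 <- "G"
  if (is.null(markers$anc_state)) markers$anc_state <- "unknown"
  if (is.null(markers$genic)) markers$genic <- FALSE
  markers$pos_bp <- as.numeric(markers$pos_bp)
  copies <- as.data.frame(copies)
  rownames(alleles) <- markers$marker_id
  colnames(alleles) <- paste(copies$sample_id, copies$copy, sep = "_")
  se <- SummarizedExperiment(
    assays = SimpleList(alleles = alleles),
    rowData = DataFrame(markers),
    colData = DataFrame(copies, row.names = colnames(alleles)),
    metadata = list(chrom_type = chrom_type)
  )
  new("HaplotypePanel", se)
}

#' RegionGrid: non-overlapping fixed-width genomic windows
#'
#' Tiles the half-open span \code{[span_start, span_end)} with windows of
#' width \code{window_bp}; the last window may be shorter. Coordinates are
#' 0-based half-open throughout. A position maps to window
#' \code{floor((pos - span_start)/window_bp) + 1}, so a marker sitting exactly
#' on a boundary belongs to the right-hand window.
#'
#' @slot chrom chromosome label.
#' @slot spanStart,spanEnd numeric, half-open span in bp.
#' @slot windowBp numeric window width in bp.
#' @export
setClass("RegionGrid",
         representation(chrom = "character", spanStart = "numeric",
                        spanEnd = "numeric", windowBp = "numeric"))

setValidity("RegionGrid", function(object) {
  msg <- character()
  if (object@spanEnd <= object@spanStart) msg <- c(msg, "span_end must exceed span_start")
  if (object@windowBp <= 0) msg <- c(msg, "window width must be positive")
  if (length(msg)) msg else TRUE
})

#' DemographySurface: a grid of values over (N_f/N, m_f/m)
#'
#' Holds one matrix over the demographic grid: \code{cells[i, j]} is the value
#' at \code{x_axis[i]} (female share of effective size, N_f/N) and
#' \code{y_axis[j]} (female share of migration, m_f/m). \code{kind} says what
#' the cells are: \code{"snp_count"}, \code{"region_count"} or
#' \code{"p_value"}.
#'
#' @slot xAxis,yAxis numeric axes (default grids run 0.01..0.99 by 0.01).
#' @slot cells numeric matrix, \code{length(xAxis)} x \code{length(yAxis)}.
#' @slot kind character, one of snp_count/region_count/p_value.
#' @export
setClass("DemographySurface",
         representation(xAxis = "numeric", yAxis = "numeric",
                        cells = "matrix", kind = "character"))

setValidity("DemographySurface", function(object) {
  msg <- character()
  if (!identical(dim(object@cells), c(length(object@xAxis), length(object@yAxis))))
    msg <- c(msg, "cells must be length(xAxis) x length(yAxis)")
  if (!object@kind %in% c("snp_count", "region_count", "p_value"))
    msg <- c(msg, "kind must be snp_count, region_count or p_value")
  if (object@kind == "p_value") {
    v <- object@cells[!is.na(object@cells)]
    if (length(v) && (min(v) < 0 || max(v) > 1))
      msg <- c(msg, "p-values must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})
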