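#' Load a phased haplotype panel from VCF plus metadata tables
#'
#' Reads a phased biallelic VCF (via \pkg{vcfR}) together with a sample table
#' and optional gene intervals and genetic map, and assembles a
#' [HaplotypePanel-class]. Internal coordinates are 0-based half-open;
#' the VCF's 1-based POS is shifted at this boundary.
#'
#' Genotype handling: on X panels a male may be encoded haploid (\code{"1"})
#' or phased/homozygous diploid (\code{"1|1"}, \code{"1/1"}); both collapse to
#' one haplotype column. A heterozygous male X genotype is an error naming the
#' sample and site. Heterozygous unphased diploid genotypes (\code{"0/1"}) are
#' errors; homozygous unphased genotypes are accepted since their phase is
#' unambiguous. Missing genotypes become NA and are excluded site-wise from
#' frequency denominators downstream.
#'
#' @param vcf_path path to a VCF with phased GT (plain text or gz).
#' @param sample_table_path TSV with columns \code{sample}, \code{sex},
#'   \code{population}, \code{region}.
#' @param bed_path optional BED file (0-based half-open) of gene intervals;
#'   markers falling inside any interval are flagged genic.
#' @param map_path optional 2-column TSV (bp, cM); marker cM positions are
#'   linearly interpolated (constant beyond the map ends). Without a map,
#'   1 cM/Mb is assumed.
#' @param chrom_type \code{"autosome"} or \code{"X"}.
#' @return a [HaplotypePanel-class].
#' @importFrom vcfR read.vcfR
#' @importFrom stats approx
#' @importFrom utils read.table write.table
#' @export
loadPanel <- function(vcf_path, sample_table_path, bed_path = NULL,
                      map_path = NULL, chrom_type = c("autosome", "X")) {
  chrom_type <- match.arg(chrom_type)
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- v@gt
  fmt <- strsplit(gt[, "FORMAT"], ":")
  gt_field <- vapply(fmt, function(f) match("GT", f), integer(1))
  if (any(is.na(gt_field))) stop("VCF records without GT field")
  samples <- colnames(gt)[-1]

  st <- read.table(sample_table_path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  need <- c("sample", "sex", "population", "region")
  if (!all(need %in% colnames(st)))
    stop("sample table must have columns: ", paste(need, collapse = ", "))
  absent <- setdiff(samples, st$sample)
  if (length(absent))
    stop("VCF sample(s) absent from sample table: ", paste(absent, collapse = ", "))
  st <- st[match(samples, st$sample), ]

  if (any(as.character(fix$ALT) == "" | is.na(fix$ALT) | grepl(",", fix$ALT)))
    stop("VCF must be biallelic with a single ALT allele at every site")

  pos_bp <- as.numeric(fix$POS) - 1
  n_mark <- nrow(fix)
  cols <- list()
  copies <- list()
  for (j in seq_along(samples)) {
    raw <- gt[, samples[j]]
    gt_str <- vapply(seq_len(n_mark), function(i) {
      strsplit(raw[i], ":", fixed = TRUE)[[1]][gt_field[i]]
    }, character(1))
    parsed <- .parse_gt(gt_str, samples[j], st$sex[j], chrom_type, fix)
    for (k in seq_len(ncol(parsed))) {
      cols[[length(cols) + 1L]] <- parsed[, k]
      copies[[length(copies) + 1L]] <- data.frame(
        sample_id = samples[j], copy = k, sex = st$sex[j],
        population = st$population[j], region = st$region[j],
        stringsAsFactors = FALSE)
    }
  }
  alleles <- do.call(cbind, cols)
  copies <- do.call(rbind, copies)

  markers <- data.frame(
    marker_id = ifelse(is.na(fix$ID) | fix$ID == ".",
                       paste0(fix$CHROM, "_", fix$POS), fix$ID),
    chrom = fix$CHROM, pos_bp = pos_bp,
    allele0 = fix$REF, allele1 = fix$ALT,
    anc_state = "unknown", genic = FALSE, stringsAsFactors = FALSE)

  if (!is.null(map_path)) {
    mp <- read.table(map_path, header = TRUE, sep = "\t")
    markers$pos_cM <- stats::approx(mp[[1]], mp[[2]], xout = markers$pos_bp,
                                    rule = 2, ties = "ordered")$y
  } else {
    markers$pos_cM <- markers$pos_bp * 1e-6
  }

  if (!is.null(bed_path)) {
    bed <- read.table(bed_path, header = FALSE, sep = "\t",
                      stringsAsFactors = FALSE)[, 1:3]
    colnames(bed) <- c("chrom", "start", "end")
    markers$genic <- .flag_genic(markers$chrom, markers$pos_bp, bed)
  }

  o <- order(markers$chrom, markers$pos_bp)
  HaplotypePanel(alleles[o, , drop = FALSE], markers[o, , drop = FALSE],
                 copies, chrom_type)
}

# one sample's GT strings -> matrix with 1 (haploid male X) or 2 columns
.parse_gt <- function(gt_str, sample_id, sex, chrom_type, fix) {
  hap_male <- chrom_type == "X" && sex == "male"
  a1 <- a2 <- rep(NA_integer_, length(gt_str))
  single <- !grepl("[|/]", gt_str)
  sep2 <- !single
  al <- function(ch) ifelse(ch %in% c("0", "1"), as.integer(ch), NA_integer_)
  if (any(single)) a1[single] <- a2[single] <- al(gt_str[single])
  if (any(sep2)) {
    parts <- strsplit(gt_str[sep2], "[|/]")
    a1[sep2] <- al(vapply(parts, `[`, character(1), 1))
    a2[sep2] <- al(vapply(parts, `[`, character(1), 2))
    het <- which(sep2)[!is.na(a1[sep2]) & !is.na(a2[sep2]) & a1[sep2] != a2[sep2]]
    if (hap_male && length(het))
      stop(sprintf("heterozygous male X genotype for sample %s at %s:%s",
                   sample_id, fix$CHROM[het[1]], fix$POS[het[1]]))
    unph <- grepl("/", gt_str) & sep2
    bad <- which(unph & !is.na(a1) & !is.na(a2) & a1 != a2)
    if (length(bad))
      stop(sprintf("unphased heterozygous genotype for sample %s at %s:%s",
                   sample_id, fix$CHROM[bad[1]], fix$POS[bad[1]]))
  }
  if (hap_male) matrix(a1, ncol = 1) else cbind(a1, a2)
}

#' @importFrom GenomicRanges GRanges findOverlaps
#' @importFrom IRanges IRanges
.flag_genic <- function(chrom, pos_bp, bed) {
  ok <- bed$end > bed$start
  bed <- bed[ok, , drop = FALSE]
  if (!nrow(bed)) return(rep(FALSE, length(pos_bp)))
  # shift both to 1-based closed; marker is a point
  mk <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos_bp + 1, pos_bp + 1))
  gn <- GenomicRanges::GRanges(bed$chrom, IRanges::IRanges(bed$start + 1, bed$end))
  hits <- GenomicRanges::findOverlaps(mk, gn)
  out <- rep(FALSE, length(pos_bp))
  out[unique(S4Vectors::queryHits(hits))] <- TRUE
  out
}

#' Write a panel back to VCF and companion tables
#'
#' Emits \code{<prefix>.vcf} (phased GT; haploid male columns on X),
#' \code{<prefix>.samples.tsv}, \code{<prefix>.genic.bed} (one 1-bp interval
#' per genic marker), \code{<prefix>.map.tsv} (bp, cM at every marker) and
#' \code{<prefix>.anc.tsv} (marker_id, ancestral base, for markers with a
#' known ancestral state). Re-loading with [loadPanel()] plus
#' [assignAncestralAlleles()] reproduces the panel exactly.
#'
#' @param panel a [HaplotypePanel-class].
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return invisibly, the named vector of written paths.
#' @export
writePanelFiles <- function(panel, dir, prefix = "panel") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mk <- markerInfo(panel)
  cd <- as.data.frame(SummarizedExperiment::colData(panel))
  al <- alleleMat(panel)
  si <- sampleInfo(panel)

  gt_cols <- vapply(si$sample_id, function(s) {
    idx <- which(cd$sample_id == s)
    if (length(idx) == 1L) {
      g <- as.character(al[, idx])
      g[is.na(g)] <- "."
      g
    } else {
      g1 <- as.character(al[, idx[1]]); g2 <- as.character(al[, idx[2]])
      g1[is.na(g1)] <- "."; g2[is.na(g2)] <- "."
      paste0(g1, "|", g2)
    }
  }, character(nrow(mk)))
  if (is.null(dim(gt_cols))) gt_cols <- matrix(gt_cols, nrow = nrow(mk))

  body <- cbind(mk$chrom, format(mk$pos_bp + 1, scientific = FALSE, trim = TRUE),
                mk$marker_id, mk$allele0, mk$allele1, ".", "PASS", ".", "GT",
                gt_cols)
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", si$sample_id), collapse = "\t"))
  paths <- c(vcf = file.path(dir, paste0(prefix, ".vcf")),
             samples = file.path(dir, paste0(prefix, ".samples.tsv")),
             bed = file.path(dir, paste0(prefix, ".genic.bed")),
             map = file.path(dir, paste0(prefix, ".map.tsv")),
             anc = file.path(dir, paste0(prefix, ".anc.tsv")))
  writeLines(c(header, apply(body, 1, paste, collapse = "\t")), paths["vcf"])

  write.table(data.frame(sample = si$sample_id, sex = si$sex,
                         population = si$population, region = si$region),
              paths["samples"], sep = "\t", quote = FALSE, row.names = FALSE)

  gb <- mk[mk$genic, , drop = FALSE]
  bed_df <- data.frame(chrom = gb$chrom,
                       start = format(gb$pos_bp, scientific = FALSE, trim = TRUE),
                       end = format(gb$pos_bp + 1, scientific = FALSE, trim = TRUE))
  write.table(bed_df, paths["bed"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)

  write.table(data.frame(bp = mk$pos_bp, cM = mk$pos_cM), paths["map"],
              sep = "\t", quote = FALSE, row.names = FALSE)

  known <- mk$anc_state != "unknown"
  anc_base <- ifelse(mk$anc_state == "allele0", mk$allele0, mk$allele1)
  write.table(data.frame(marker_id = mk$marker_id[known],
                         ancestral = anc_base[known]),
              paths["anc"], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Read a per-site score track
#'
#' Tab-delimited with columns \code{chrom}, \code{pos_bp} (0-based),
#' \code{score} — the format used to import externally computed statistics
#' (for example composite likelihood ratio scores) for window aggregation.
#'
#' @param path TSV path.
#' @return data.frame with chrom, pos_bp, score.
#' @export
readScoreTrack <- function(path) {
  x <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("chrom", "pos_bp", "score") %in% colnames(x)))
    stop("score track needs columns chrom, pos_bp, score")
  x
}

#' Read outgroup genotypes
#'
#' Tab-delimited with column \code{marker_id} followed by one column per
#' outgroup individual holding diploid base genotypes like \code{"A/A"}
#' (\code{"./."} = missing).
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
readOutgroup <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write a DemographySurface as a TSV matrix
#'
#' @param surface a [DemographySurface-class].
#' @param path output TSV; rows are N_f/N values (first column), columns are
#'   m_f/m values (header).
#' @export
writeSurface <- function(surface, path) {
  m <- as.matrix(surface)
  df <- data.frame(nf_ratio = rownames(m), m, check.names = FALSE)
  colnames(df) <- c("nf_ratio", colnames(m))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
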