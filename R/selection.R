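#' Extended haplotype homozygosity curve around a core marker
#'
#' EHH at flanking distance d is the probability that two random haplotypes
#' carrying the core allele are identical at every marker from the core out
#' to d: EHH(d) = sum_h n_h (n_h - 1) / (n_c (n_c - 1)) over the haplotype
#' classes h extending the core allele, computed separately in each
#' direction. EHH is 1 at the core and non-increasing with |offset|.
#'
#' @param panel a [HaplotypePanel-class] (phased).
#' @param populations population label(s) defining the group scanned.
#' @param core_marker marker id or row index.
#' @param partition "derived", "ancestral" (requires an assigned ancestral
#'   state) or "all" (no allele partition, as used cross-population).
#' @return data.frame with offset_bp, offset_cM (signed), ehh; NULL when
#'   fewer than 2 haplotypes carry the core allele.
#' @export
ehhCurve <- function(panel, populations, core_marker,
                     partition = c("derived", "ancestral", "all")) {
  partition <- match.arg(partition)
  w <- .ehh_setup(panel, populations, core_marker, partition)
  if (is.null(w)) return(NULL)
  left <- .ehh_side(w$al, w$core, -1L)
  right <- .ehh_side(w$al, w$core, +1L)
  mk <- markerInfo(panel)
  seg <- function(idx, e) data.frame(
    offset_bp = mk$pos_bp[idx] - mk$pos_bp[w$core],
    offset_cM = mk$pos_cM[idx] - mk$pos_cM[w$core], ehh = e)
  out <- rbind(seg(rev(left$idx), rev(left$ehh)),
               data.frame(offset_bp = 0, offset_cM = 0, ehh = 1),
               seg(right$idx, right$ehh))
  rownames(out) <- NULL
  attr(out, "core_marker") <- mk$marker_id[w$core]
  attr(out, "partition") <- partition
  attr(out, "n_core") <- ncol(w$al)
  out
}

# haplotype columns carrying the core allele (partitioned), NA-free coding
.ehh_setup <- function(panel, populations, core_marker, partition) {
  mk <- markerInfo(panel)
  core <- if (is.character(core_marker)) match(core_marker, mk$marker_id)
          else as.integer(core_marker)
  if (is.na(core) || core < 1 || core > nrow(mk)) stop("core marker not found")
  cd <- as.data.frame(SummarizedExperiment::colData(panel))
  cols <- which(cd$population %in% populations)
  if (!length(cols)) stop("no haplotypes in the requested population(s)")
  al <- alleleMat(panel)[, cols, drop = FALSE]
  if (partition != "all") {
    anc <- mk$anc_state[core]
    if (!anc %in% c("allele0", "allele1"))
      stop("core marker has no assigned ancestral state")
    derived <- if (anc == "allele0") 1L else 0L
    want <- if (partition == "derived") derived else 1L - derived
    al <- al[, !is.na(al[core, ]) & al[core, ] == want, drop = FALSE]
  } else {
    al <- al[, !is.na(al[core, ]), drop = FALSE]
  }
  if (ncol(al) < 2) return(NULL)
  al[is.na(al)] <- 2L  # missing breaks haplotype identity conservatively
  list(al = al, core = core)
}

# full EHH values along one side (dir = -1 left, +1 right)
.ehh_side <- function(al, core, dir) {
  n_mark <- nrow(al)
  n_c <- ncol(al)
  if (core + dir < 1L || core + dir > n_mark)
    return(list(idx = integer(), ehh = numeric()))
  idx <- if (dir > 0) seq(core + 1L, n_mark) else seq(core - 1L, 1L)
  g <- rep(1L, n_c)
  ehh <- numeric(length(idx))
  for (j in seq_along(idx)) {
    key <- g * 3L + al[idx[j], ]
    g <- match(key, unique(key))
    tab <- tabulate(g)
    ehh[j] <- sum(tab * (tab - 1)) / (n_c * (n_c - 1))
  }
  list(idx = idx, ehh = ehh)
}

#' Integrated EHH (iHH)
#'
#' Trapezoidal integral of an EHH curve over genetic distance (cM) from the
#' core out to the first marker where EHH drops below \code{cutoff}, summed
#' over both directions. The integral is undefined (NA) when EHH is still at
#' or above the cutoff at the last marker on either side — scores cannot be
#' computed for cores too close to the chromosome ends.
#'
#' @param curve data.frame from [ehhCurve()].
#' @param cutoff EHH truncation value (default 0.1).
#' @return numeric iHH in cM, or NA.
#' @export
ihh <- function(curve, cutoff = 0.1) {
  if (is.null(curve)) return(NA_real_)
  side_area <- function(cm, e) {
    o <- order(cm)
    cm <- cm[o]; e <- e[o]
    k <- which(e < cutoff)[1]
    if (is.na(k)) return(NA_real_)
    if (k == 1L) return(0)
    sum((e[seq_len(k - 1)] + e[2:k]) / 2 * diff(cm[1:k]))
  }
  right <- curve$offset_cM >= 0
  left <- curve$offset_cM <= 0
  a_r <- side_area(curve$offset_cM[right], curve$ehh[right])
  a_l <- side_area(-curve$offset_cM[left], curve$ehh[left])
  a_r + a_l
}

# fast one-sided integral with early stopping; NA if cutoff never reached
.ihh_walk <- function(al, cm, core, dir, cutoff) {
  n_mark <- nrow(al)
  n_c <- ncol(al)
  if (n_c < 2) return(NA_real_)
  if ((dir > 0 && core >= n_mark) || (dir < 0 && core <= 1L)) return(NA_real_)
  g <- rep(1L, n_c)
  prev_e <- 1
  prev_cm <- cm[core]
  area <- 0
  i <- core
  repeat {
    i <- i + dir
    key <- g * 3L + al[i, ]
    g <- match(key, unique(key))
    tab <- tabulate(g)
    e <- sum(tab * (tab - 1)) / (n_c * (n_c - 1))
    d <- abs(cm[i] - prev_cm)
    area <- area + (prev_e + e) / 2 * d
    if (e < cutoff) return(area)
    if ((dir > 0 && i >= n_mark) || (dir < 0 && i <= 1L)) return(NA_real_)
    prev_e <- e
    prev_cm <- cm[i]
  }
}

.ihh_both <- function(al, cm, core, cutoff) {
  a <- .ihh_walk(al, cm, core, +1L, cutoff)
  if (is.na(a)) return(NA_real_)
  b <- .ihh_walk(al, cm, core, -1L, cutoff)
  if (is.na(b)) return(NA_real_)
  a + b
}

#' iHS scan: per-marker integrated haplotype scores
#'
#' For every marker with an assigned ancestral state and both alleles present
#' at least twice, computes iHH separately for the ancestral- and
#' derived-allele haplotype classes and the raw score
#' iHS = ln(iHH_ancestral / iHH_derived). Markers are grouped by observed
#' derived-allele count (optionally 2\% frequency bins) and a marker is
#' flagged high when its score deviates from its frequency-group mean by
#' \code{flag_deviation} or more — an absolute-deviation rule, not an SD
#' standardization.
#'
#' @param panel a [HaplotypePanel-class] with ancestral states assigned.
#' @param populations population label(s) of the scanned group.
#' @param cutoff EHH truncation (default 0.1).
#' @param flag_deviation absolute deviation from the frequency-group mean at
#'   or above which a marker is flagged (default 2).
#' @param freq_bins "exact" observed derived-allele counts (default) or
#'   "binned" 2\% derived-frequency bins for sparse data.
#' @return data.frame: marker_id, pos_bp, derived_count, derived_freq, ihs,
#'   group_mean, deviation, high. Markers without a defined score carry NA.
#' @export
ihsScan <- function(panel, populations, cutoff = 0.1, flag_deviation = 2,
                    freq_bins = c("exact", "binned")) {
  freq_bins <- match.arg(freq_bins)
  mk <- markerInfo(panel)
  cd <- as.data.frame(SummarizedExperiment::colData(panel))
  cols <- which(cd$population %in% populations)
  al <- alleleMat(panel)[, cols, drop = FALSE]
  aln <- al; aln[is.na(aln)] <- 2L
  cm <- mk$pos_cM
  n_mark <- nrow(mk)

  ihs <- rep(NA_real_, n_mark)
  dcount <- rep(NA_integer_, n_mark)
  dfreq <- rep(NA_real_, n_mark)
  for (i in seq_len(n_mark)) {
    anc <- mk$anc_state[i]
    if (!anc %in% c("allele0", "allele1")) next
    derived <- if (anc == "allele0") 1L else 0L
    obs <- al[i, ]
    ok <- !is.na(obs)
    nd <- sum(obs[ok] == derived)
    na_ <- sum(ok) - nd
    dcount[i] <- nd
    dfreq[i] <- nd / sum(ok)
    if (nd < 2 || na_ < 2) next
    der_cols <- which(ok & obs == derived)
    anc_cols <- which(ok & obs != derived)
    ihh_d <- .ihh_both(aln[, der_cols, drop = FALSE], cm, i, cutoff)
    ihh_a <- .ihh_both(aln[, anc_cols, drop = FALSE], cm, i, cutoff)
    if (is.na(ihh_d) || is.na(ihh_a) || ihh_d == 0 || ihh_a == 0) next
    ihs[i] <- log(ihh_a / ihh_d)
  }

  grp <- if (freq_bins == "exact") as.character(dcount)
         else as.character(floor(dfreq * 50) / 50)
  scored <- !is.na(ihs)
  gmean <- rep(NA_real_, n_mark)
  if (any(scored)) {
    means <- tapply(ihs[scored], grp[scored], mean)
    gmean[scored] <- means[grp[scored]]
  }
  deviation <- abs(ihs - gmean)
  data.frame(marker_id = mk$marker_id, pos_bp = mk$pos_bp,
             derived_count = dcount, derived_freq = dfreq, ihs = ihs,
             group_mean = gmean, deviation = deviation,
             high = !is.na(deviation) & deviation >= flag_deviation,
             row.names = NULL)
}

#' XP-EHH scan: cross-population extended haplotype homozygosity
#'
#' Per core marker, integrates the unpartitioned EHH (all haplotypes, no
#' allele split) within each of two groups, with the same cutoff and boundary
#' rules as iHS, and takes raw XP-EHH = ln(iHH_A / iHH_B). Raw scores are
#' standardized chromosome-wide to mean 0 and unit variance. Positive scores
#' indicate longer haplotypes (a harder sweep) in group A.
#'
#' @param panel a [HaplotypePanel-class].
#' @param popsA,popsB population label(s) of the test and reference groups.
#' @param cutoff EHH truncation (default 0.1).
#' @return data.frame: marker_id, pos_bp, ihh_A, ihh_B, xpehh_raw, xpehh_std.
#' @export
xpehhScan <- function(panel, popsA, popsB, cutoff = 0.1) {
  mk <- markerInfo(panel)
  cd <- as.data.frame(SummarizedExperiment::colData(panel))
  colsA <- which(cd$population %in% popsA)
  colsB <- which(cd$population %in% popsB)
  if (length(colsA) < 2 || length(colsB) < 2)
    stop("both groups need at least 2 haplotypes")
  alA <- alleleMat(panel)[, colsA, drop = FALSE]; alA[is.na(alA)] <- 2L
  alB <- alleleMat(panel)[, colsB, drop = FALSE]; alB[is.na(alB)] <- 2L
  cm <- mk$pos_cM
  n_mark <- nrow(mk)
  ihh_A <- ihh_B <- rep(NA_real_, n_mark)
  for (i in seq_len(n_mark)) {
    a <- .ihh_both(alA, cm, i, cutoff)
    if (is.na(a) || a == 0) next
    b <- .ihh_both(alB, cm, i, cutoff)
    if (is.na(b) || b == 0) next
    ihh_A[i] <- a; ihh_B[i] <- b
  }
  raw <- log(ihh_A / ihh_B)
  std <- (raw - mean(raw, na.rm = TRUE)) / stats::sd(raw, na.rm = TRUE)
  data.frame(marker_id = mk$marker_id, pos_bp = mk$pos_bp,
             ihh_A = ihh_A, ihh_B = ihh_B, xpehh_raw = raw, xpehh_std = std,
             row.names = NULL)
}

#' Aggregate per-marker scores into fixed-width regions
#'
#' \code{ihs_ratio}: the fraction of scored markers in a window that are
#' flagged (the region-level iHS). \code{mean}: the average score, missing
#' where no marker is scored (the region-level CLR rule). \code{mean_zero_fill}:
#' as \code{mean} but empty windows score 0 (the region-level XP-EHH rule).
#' Ranks are assigned over non-missing windows, 1 = highest, ties broken by
#' smaller start coordinate.
#'
#' @param scores data.frame with pos_bp and \code{value} column (and
#'   \code{high} flag for mode ihs_ratio).
#' @param grid a [RegionGrid-class].
#' @param mode "ihs_ratio", "mean" or "mean_zero_fill".
#' @param value_col,flag_col column names holding scores and flags.
#' @return data.frame: window, start_bp, n_snps_scored, score, rank.
#' @export
regionizeScores <- function(scores, grid,
                            mode = c("ihs_ratio", "mean", "mean_zero_fill"),
                            value_col = "value", flag_col = "high") {
  mode <- match.arg(mode)
  v <- scores[[value_col]]
  win <- assignWindow(grid, scores$pos_bp)
  scored <- !is.na(v) & !is.na(win)
  nw <- length(grid)
  n_scored <- tabulate(win[scored], nbins = nw)
  score <- rep(NA_real_, nw)
  if (mode == "ihs_ratio") {
    fl <- scores[[flag_col]]
    n_high <- tabulate(win[scored & fl], nbins = nw)
    score[n_scored > 0] <- n_high[n_scored > 0] / n_scored[n_scored > 0]
  } else {
    sums <- rep(0, nw)
    agg <- tapply(v[scored], win[scored], sum)
    sums[as.integer(names(agg))] <- agg
    score[n_scored > 0] <- sums[n_scored > 0] / n_scored[n_scored > 0]
    if (mode == "mean_zero_fill") score[n_scored == 0] <- 0
  }
  out <- data.frame(window = seq_len(nw), start_bp = windowStarts(grid),
                    n_snps_scored = n_scored, score = score)
  out$rank <- NA_integer_
  sc <- !is.na(out$score)
  ord <- order(-out$score[sc], out$start_bp[sc])
  out$rank[which(sc)[ord]] <- seq_len(sum(sc))
  out
}

#' Top-k regions by aggregated score
#'
#' @param region_scores data.frame from [regionizeScores()].
#' @param k number of regions (default 10); if fewer windows are scored, all
#'   are returned with a message.
#' @return the k highest-scoring rows, rank 1 first; ties broken by smaller
#'   start coordinate.
#' @export
topRegions <- function(region_scores, k = 10) {
  sc <- region_scores[!is.na(region_scores$score), , drop = FALSE]
  if (!nrow(sc)) stop("no scored windows")
  if (k > nrow(sc)) {
    message("only ", nrow(sc), " scored windows; returning all")
    k <- nrow(sc)
  }
  sc <- sc[order(sc$rank), , drop = FALSE]
  head(sc, k)
}

#' Empirical percentile test for a set of consecutive scores
#'
#' Compares the mean of the k scores in \code{[from, to]} with the means of
#' every other k-length run of consecutive scores (sliding, overlapping, the
#' tested run excluded). The percentile is the fraction of other runs with
#' strictly smaller mean; the run is flagged elevated when the percentile
#' exceeds \code{level} (default 0.95).
#'
#' @param scores ordered numeric vector (one score per unit, e.g. region).
#' @param from,to 1-based inclusive index range of the tested run.
#' @param level flag threshold on the percentile.
#' @return list with mean, percentile, elevated, n_other.
#' @export
empiricalWindowTest <- function(scores, from, to, level = 0.95) {
  n <- length(scores)
  k <- to - from + 1
  stopifnot(from >= 1, to >= from)
  if (k >= n) stop("tested run must be shorter than the score list")
  target <- mean(scores[from:to])
  starts <- setdiff(seq_len(n - k + 1), from)
  cs <- c(0, cumsum(scores))
  others <- (cs[starts + k] - cs[starts]) / k
  pct <- mean(others < target)
  list(mean = target, percentile = pct, elevated = pct > level,
       n_other = length(others))
}

#' Haplotype heterozygosity ratio track
#'
#' Slides a window of \code{window_snps} consecutive markers along the
#' panel; within each window the multi-SNP haplotype heterozygosity
#' H = 1 - sum p_h^2 is computed in each population from the observed window
#' haplotype frequencies, and the ratio H_popB / H_popA is placed at the
#' window's center marker. The ratio is NA where H_popA = 0.
#'
#' @param panel a [HaplotypePanel-class].
#' @param popA reference population (denominator).
#' @param popB test population (numerator).
#' @param window_snps markers per haplotype window (default 5, >= 2).
#' @param unbiased apply the n/(n-1) small-sample correction to each H.
#' @return data.frame: center_marker, pos_bp, H_A, H_B, ratio.
#' @export
hapHetRatio <- function(panel, popA, popB, window_snps = 5, unbiased = FALSE) {
  stopifnot(window_snps >= 2)
  mk <- markerInfo(panel)
  n_mark <- nrow(mk)
  if (n_mark < window_snps) stop("panel has fewer markers than the window")
  cd <- as.data.frame(SummarizedExperiment::colData(panel))
  het <- function(cols, from) {
    sub <- alleleMat(panel)[from:(from + window_snps - 1), cols, drop = FALSE]
    complete <- colSums(is.na(sub)) == 0
    sub <- sub[, complete, drop = FALSE]
    n <- ncol(sub)
    if (n < 2) return(NA_real_)
    keys <- apply(sub, 2, paste, collapse = "")
    p <- as.numeric(table(keys)) / n
    h <- 1 - sum(p^2)
    if (unbiased) h * n / (n - 1) else h
  }
  colsA <- which(cd$population == popA)
  colsB <- which(cd$population == popB)
  if (!length(colsA) || !length(colsB)) stop("population not in panel")
  starts <- seq_len(n_mark - window_snps + 1)
  center <- starts + (window_snps - 1) %/% 2
  H_A <- vapply(starts, function(s) het(colsA, s), numeric(1))
  H_B <- vapply(starts, function(s) het(colsB, s), numeric(1))
  ratio <- ifelse(!is.na(H_A) & H_A > 0, H_B / H_A, NA_real_)
  data.frame(center_marker = mk$marker_id[center], pos_bp = mk$pos_bp[center],
             H_A = H_A, H_B = H_B, ratio = ratio, row.names = NULL)
}
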