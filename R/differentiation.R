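#' Per-population allele-1 frequencies
#'
#' Counts chromosome copies directly, so on X panels males contribute one copy
#' and females two. Missing genotypes are excluded site-wise from the
#' denominator; a site with zero non-missing copies gets frequency NA.
#'
#' @param panel a [HaplotypePanel-class].
#' @param population population label.
#' @return data.frame with marker_id, p (allele-1 frequency), n (non-missing
#'   copies).
#' @export
populationFrequencies <- function(panel, population) {
  cd <- as.data.frame(SummarizedExperiment::colData(panel))
  if (!population %in% cd$population)
    stop("population not in panel: ", population)
  al <- alleleMat(panel)[, cd$population == population, drop = FALSE]
  n <- rowSums(!is.na(al))
  p <- rowSums(al, na.rm = TRUE) / n
  p[n == 0] <- NA_real_
  data.frame(marker_id = markerInfo(panel)$marker_id, p = p, n = n,
             row.names = NULL)
}

# Hudson's pairwise estimator per site from sample frequencies and copy
# counts, ratio form; here the per-site ratio, clipped to [0, 1].
.hudson_site <- function(p1, n1, p2, n2) {
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  fst <- num / den
  fst[den == 0] <- NA_real_
  pmin(pmax(fst, 0), 1)
}

# haploid-count Weir-Cockerham theta per site (ANOVA form, two populations)
.wc_site <- function(p1, n1, p2, n2) {
  r <- 2
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  msp <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / (r - 1)
  msg <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (n1 - 1 + n2 - 1)
  nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
  theta <- (msp - msg) / (msp + (nc - 1) * msg)
  theta[msp + (nc - 1) * msg == 0] <- NA_real_
  pmin(pmax(theta, 0), 1)
}

#' Per-marker differentiation scan between two populations
#'
#' \code{delta} is the absolute allele frequency difference |p_A - p_B|;
#' \code{hudson_fst} is Hudson's pairwise estimator from the two sample
#' frequencies and copy counts, clipped to [0, 1]; \code{wc_fst} is the
#' haploid-count Weir-Cockerham estimator. Sites with an undefined frequency
#' in either population get NA.
#'
#' @param panel a [HaplotypePanel-class].
#' @param popA,popB population labels.
#' @param measure "delta", "hudson_fst" or "wc_fst".
#' @return data.frame with marker_id, chrom, pos_bp, p_A, p_B, n_A, n_B,
#'   value.
#' @export
deltaScan <- function(panel, popA, popB,
                      measure = c("delta", "hudson_fst", "wc_fst")) {
  measure <- match.arg(measure)
  fa <- populationFrequencies(panel, popA)
  fb <- populationFrequencies(panel, popB)
  mk <- markerInfo(panel)
  value <- switch(measure,
    delta = abs(fa$p - fb$p),
    hudson_fst = .hudson_site(fa$p, fa$n, fb$p, fb$n),
    wc_fst = .wc_site(fa$p, fa$n, fb$p, fb$n))
  data.frame(marker_id = mk$marker_id, chrom = mk$chrom, pos_bp = mk$pos_bp,
             p_A = fa$p, p_B = fb$p, n_A = fa$n, n_B = fb$n,
             value = value, row.names = NULL)
}

#' Genome-wide Hudson Fst (ratio of averages)
#'
#' Multi-locus Hudson estimator: per-site numerators and denominators are
#' averaged separately before the ratio is taken, the form that is unbiased
#' for the island-model differentiation parameter.
#'
#' @inheritParams deltaScan
#' @return a single Fst estimate.
#' @export
hudsonFstGenomewide <- function(panel, popA, popB) {
  fa <- populationFrequencies(panel, popA)
  fb <- populationFrequencies(panel, popB)
  ok <- !is.na(fa$p) & !is.na(fb$p) & fa$n > 1 & fb$n > 1
  num <- (fa$p - fb$p)^2 - fa$p * (1 - fa$p) / (fa$n - 1) -
         fb$p * (1 - fb$p) / (fb$n - 1)
  den <- fa$p * (1 - fb$p) + fb$p * (1 - fa$p)
  sum(num[ok]) / sum(den[ok])
}

#' Call high-differentiation SNPs and regions
#'
#' A marker is "high" when its value strictly exceeds \code{threshold}; a
#' window of the grid is a high region when it contains at least one high
#' marker.
#'
#' @param values data.frame from [deltaScan()] (needs pos_bp and value).
#' @param grid a [RegionGrid-class]; markers outside the span are dropped
#'   from region tallies (but still counted as SNPs).
#' @param threshold strict threshold (default 0.9).
#' @return list with \code{n_high_snps}, \code{n_high_regions},
#'   \code{per_region} (window, n_snps, n_high), and \code{calls} (the input
#'   with \code{high} flag and \code{window} index).
#' @export
callHighDeltaRegions <- function(values, grid, threshold = 0.9) {
  v <- values$value
  high <- !is.na(v) & v > threshold
  win <- assignWindow(grid, values$pos_bp)
  keep <- !is.na(win) & !is.na(v)
  n_snps <- tabulate(win[keep], nbins = length(grid))
  n_high <- tabulate(win[keep & high], nbins = length(grid))
  values$high <- high
  values$window <- win
  list(n_high_snps = sum(high),
       n_high_regions = sum(n_high > 0),
       per_region = data.frame(window = seq_len(length(grid)),
                               n_snps = n_snps, n_high = n_high),
       calls = values)
}

#' Assign ancestral alleles from outgroup genotypes
#'
#' A marker whose outgroup individuals are all (non-missing) fixed for one
#' base gets that base as ancestral; markers polymorphic or entirely missing
#' in the outgroup stay unknown. An optional override table (columns
#' \code{marker_id}, \code{ancestral}) then sets the state for its rows, e.g.
#' from an external database; an override base that is not one of the
#' marker's two alleles is an error.
#'
#' @param panel a [HaplotypePanel-class].
#' @param outgroup data.frame from [readOutgroup()]: marker_id plus one
#'   column per outgroup individual of "A/A"-style genotypes ("./." missing).
#' @param override optional data.frame (marker_id, ancestral).
#' @return the panel with rowData \code{anc_state} filled in.
#' @export
assignAncestralAlleles <- function(panel, outgroup, override = NULL) {
  mk <- markerInfo(panel)
  state <- mk$anc_state
  idx <- match(mk$marker_id, outgroup$marker_id)
  gcols <- setdiff(colnames(outgroup), "marker_id")
  for (i in which(!is.na(idx))) {
    gts <- unlist(strsplit(as.character(outgroup[idx[i], gcols]), "/"))
    gts <- gts[!gts %in% c(".", "", NA)]
    u <- unique(gts)
    if (length(u) == 1L) {
      state[i] <- if (u == mk$allele0[i]) "allele0"
                  else if (u == mk$allele1[i]) "allele1"
                  else "unknown"
    } else state[i] <- "unknown"
  }
  if (!is.null(override)) {
    oi <- match(mk$marker_id, override$marker_id)
    for (i in which(!is.na(oi))) {
      base <- override$ancestral[oi[i]]
      if (base == mk$allele0[i]) state[i] <- "allele0"
      else if (base == mk$allele1[i]) state[i] <- "allele1"
      else stop(sprintf("override ancestral allele %s for %s is not among the marker's alleles",
                        base, mk$marker_id[i]))
    }
  }
  SummarizedExperiment::rowData(panel)$anc_state <- state
  panel
}

#' Chi-square comparison of two proportions
#'
#' Builds the 2x2 success/failure table for k1/n1 vs k2/n2 and applies the
#' chi-square test, without Yates continuity correction by default.
#'
#' @param k1,n1,k2,n2 counts.
#' @param correct apply Yates correction.
#' @return list with statistic, p_value, table.
#' @importFrom stats chisq.test
#' @export
proportionChisq <- function(k1, n1, k2, n2, correct = FALSE) {
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE)
  if (all(rowSums(tab) > 0) && any(colSums(tab) == 0)) {
    # identical degenerate proportions (e.g. both 0%): no association
    return(list(statistic = 0, p_value = 1, table = tab))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(ct$statistic), p_value = unname(ct$p.value),
       table = tab)
}

#' Characterize high-delta SNPs: genic content, derived-allele direction, MAF
#'
#' Summarizes a set of per-marker calls: the genic fraction among high
#' markers; per population, the count of high markers whose derived allele
#' (relative to the assigned ancestral state) has frequency at or above
#' \code{derived_high_threshold} in that population, with unknown-ancestral
#' markers excluded from the denominator; genic enrichment per delta-decile
#' bin relative to the panel-wide genic fraction; a genic x low-MAF x high
#' cross-tabulation; and a chi-square comparing the genic proportion among
#' high vs non-high markers.
#'
#' @param calls data.frame with columns value, high, genic, anc_state, p_A,
#'   p_B (as produced by [deltaScan()] + [callHighDeltaRegions()] joined with
#'   marker annotation; see [highDeltaCalls()]).
#' @param popA,popB population labels for reporting.
#' @param derived_high_threshold derived frequency at/above which a marker
#'   counts as derived-high in a population (default 0.9).
#' @param maf_threshold low-MAF cut (default 0.1), on the copy-weighted
#'   pooled frequency of the two populations.
#' @param correct Yates correction for the chi-square.
#' @return list with n_high, genic_fraction_high, derived_high (data.frame),
#'   decile_enrichment (data.frame), crosstab (table), genic_vs_high_chisq.
#' @export
classifyHighDelta <- function(calls, popA = "popA", popB = "popB",
                              derived_high_threshold = 0.9,
                              maf_threshold = 0.1, correct = FALSE) {
  ok <- !is.na(calls$value)
  calls <- calls[ok, , drop = FALSE]
  high <- calls$high
  n_high <- sum(high)

  genic_fraction_high <- if (n_high > 0) mean(calls$genic[high]) else NA_real_

  known <- calls$anc_state %in% c("allele0", "allele1")
  denom <- sum(high & known)
  derived_freq <- function(p, anc) ifelse(anc == "allele0", p, 1 - p)
  dh <- function(p) {
    if (denom == 0) return(c(count = NA_real_, fraction = NA_real_))
    dfq <- derived_freq(p, calls$anc_state)[high & known]
    cnt <- sum(dfq >= derived_high_threshold)
    c(count = cnt, fraction = cnt / denom)
  }
  a <- dh(calls$p_A); b <- dh(calls$p_B)
  derived_high <- data.frame(
    population = c(popA, popB),
    count = c(a["count"], b["count"]),
    denom = denom,
    fraction = c(a["fraction"], b["fraction"]), row.names = NULL)

  panel_genic <- mean(calls$genic)
  bin <- cut(calls$value, breaks = seq(0, 1, 0.1), right = FALSE,
             include.lowest = FALSE)
  bin[calls$value == 1] <- "[0.9,1)"  # top bin is closed at 1
  bin[calls$value == 0] <- "[0,0.1)"
  n_bin <- as.vector(table(bin))
  g_bin <- as.vector(tapply(calls$genic, bin, sum, default = 0))
  decile <- data.frame(bin = levels(bin), n = n_bin, n_genic = g_bin,
                       genic_fraction = ifelse(n_bin > 0, g_bin / n_bin, NA),
                       row.names = NULL)
  decile$enrichment <- decile$genic_fraction / panel_genic

  pooled <- (calls$p_A * calls$n_A + calls$p_B * calls$n_B) /
            (calls$n_A + calls$n_B)
  maf <- pmin(pooled, 1 - pooled)
  crosstab <- table(genic = calls$genic, low_maf = maf <= maf_threshold,
                    high = high)

  chisq <- if (n_high > 0 && n_high < nrow(calls)) {
    proportionChisq(sum(calls$genic[high]), n_high,
                    sum(calls$genic[!high]), sum(!high), correct = correct)
  } else NULL

  list(n_high = n_high, genic_fraction_high = genic_fraction_high,
       panel_genic_fraction = panel_genic, derived_high = derived_high,
       decile_enrichment = decile, crosstab = crosstab,
       genic_vs_high_chisq = chisq)
}

#' Build the calls table for [classifyHighDelta()] from a panel scan
#'
#' Convenience wrapper: runs [deltaScan()], flags high markers against a
#' grid, and joins the genic and ancestral-state marker annotation.
#'
#' @inheritParams deltaScan
#' @inheritParams callHighDeltaRegions
#' @return the \code{calls} data.frame with genic and anc_state columns.
#' @export
highDeltaCalls <- function(panel, popA, popB, grid, threshold = 0.9,
                           measure = "delta") {
  sc <- deltaScan(panel, popA, popB, measure = measure)
  out <- callHighDeltaRegions(sc, grid, threshold)$calls
  mk <- markerInfo(panel)
  out$genic <- mk$genic[match(out$marker_id, mk$marker_id)]
  out$anc_state <- mk$anc_state[match(out$marker_id, mk$marker_id)]
  out
}
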