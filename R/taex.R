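#' Combined demographic term c = (1 + m_f/m)/(2 - N_f/N)
#'
#' The single quantity through which the female share of effective size
#' (\code{x}) and of migration (\code{y}) enter the X/autosome
#' differentiation relation; all (x, y) pairs with equal c produce identical
#' transformed values, which is what draws the diagonal bands on the
#' demographic grid.
#'
#' @param x N_f/N in (0, 1).
#' @param y m_f/m in (0, 1).
#' @return c = (1 + y)/(2 - x).
#' @examples
#' combinedFactor(0.5, 0.5)  # 1
#' combinedFactor(0.8, 0.2)  # 1, same band
#' @export
combinedFactor <- function(x, y) {
  if (any(x <= 0 | x >= 1) || any(y <= 0 | y >= 1))
    stop("x and y must lie in (0, 1)")
  (1 + y) / (2 - x)
}

#' Transform autosomal differentiation values to expected X-linked (TA/EX)
#'
#' Applies the linearized island-model map elementwise: with
#' F' = v/(1 - v) and multiplier M = (4/3)/c(x, y), each value becomes
#' v' = M F'/(1 + M F'). 0 and 1 are fixed points and the output depends on
#' (x, y) only through the combined term c.
#'
#' @param values numeric vector in [0, 1] (delta or Fst values).
#' @param x,y demographic shares in (0, 1).
#' @return transformed values, order preserved.
#' @examples
#' transformAutosomal(0.5, 0.5, 0.5)  # 4/7
#' @export
transformAutosomal <- function(values, x, y) {
  if (any(values < 0 | values > 1, na.rm = TRUE))
    stop("values must lie in [0, 1]")
  M <- (4 / 3) / combinedFactor(x, y)
  .taex_apply(values, M)
}

.taex_apply <- function(values, M) {
  vp <- values / (1 - values)
  out <- M * vp / (1 + M * vp)
  out[values >= 1] <- 1
  out
}

# inverse image of the strict threshold t under the map with multiplier M:
# v' > t  <=>  v > u
.taex_inverse_threshold <- function(t, M) {
  tp <- t / (1 - t) / M
  tp / (1 + tp)
}

.wilcox_p <- function(a, b, alternative) {
  comb <- c(a, b)
  if (length(unique(comb)) == 1L) {
    warning("all-constant inputs to rank test; p-value set to 1")
    return(1)
  }
  if ((length(a) + length(b) <= 20) && !any(duplicated(comb))) {
    return(stats::wilcox.test(a, b, alternative = alternative,
                              exact = TRUE)$p.value)
  }
  .mw_approx_p(a, b, alternative)
}

# Mann-Whitney normal approximation with tie correction and continuity
# correction; identical formulas to the large-sample path of
# stats::wilcox.test, reimplemented for speed in the grid loop.
.mw_approx_p <- function(a, b, alternative) {
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  z <- U - n1 * n2 / 2
  ties <- rle(sort(r))$lengths
  sigma <- sqrt((n1 * n2 / 12) *
                ((n1 + n2 + 1) -
                 sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1))))
  corr <- switch(alternative, two.sided = sign(z) * 0.5, greater = 0.5,
                 less = -0.5)
  z <- (z - corr) / sigma
  switch(alternative,
         two.sided = min(1, 2 * min(stats::pnorm(z),
                                    stats::pnorm(z, lower.tail = FALSE))),
         greater = stats::pnorm(z, lower.tail = FALSE),
         less = stats::pnorm(z))
}

#' Demographic grid scan: TA/EX tallies and Wilcoxon surfaces
#'
#' For every (N_f/N, m_f/m) cell of the grid, transforms the autosomal value
#' list through the island-model map and records (i) the number of
#' transformed values strictly above \code{threshold}, (ii) the number of
#' autosomal windows containing at least one such value, and (iii) the
#' rank-sum (Mann-Whitney) p-value comparing the full transformed list to the
#' observed X-linked list (tie-corrected normal approximation with continuity
#' correction; exact enumeration for tie-free combined n <= 20). Cells with
#' equal combined term c share one computation, so equal-c cells are
#' bit-identical.
#'
#' @param auto_values numeric vector of autosomal per-marker values in [0, 1].
#' @param auto_pos_bp positions (0-based bp) aligned to \code{auto_values},
#'   used for the region tallies.
#' @param observed_x numeric vector of observed X-linked values.
#' @param grid a [RegionGrid-class] over the autosomal span.
#' @param threshold strict high-value threshold (default 0.9).
#' @param side "two_sided" (default) or "one_sided" (alternative: transformed
#'   values greater than observed).
#' @param x_axis,y_axis demographic grids (default 0.01..0.99 step 0.01,
#'   9,801 cells).
#' @return list with \code{snp_count}, \code{region_count}, \code{p_value}
#'   ([DemographySurface-class] each), plus \code{n_auto}, \code{n_x}.
#' @importFrom stats wilcox.test
#' @export
demographyGridScan <- function(auto_values, auto_pos_bp, observed_x, grid,
                               threshold = 0.9,
                               side = c("two_sided", "one_sided"),
                               x_axis = seq(0.01, 0.99, by = 0.01),
                               y_axis = seq(0.01, 0.99, by = 0.01)) {
  side <- match.arg(side)
  alternative <- if (side == "two_sided") "two.sided" else "greater"
  keep <- !is.na(auto_values)
  auto_values <- auto_values[keep]
  auto_pos_bp <- auto_pos_bp[keep]
  observed_x <- observed_x[!is.na(observed_x)]
  if (!length(observed_x)) stop("observed X value list is empty")

  win <- assignWindow(grid, auto_pos_bp)
  win_max <- tapply(auto_values, win, max)

  cmat <- outer(x_axis, y_axis, combinedFactor)
  ckey <- signif(cmat, 12)
  uc <- unique(as.vector(ckey))

  snp <- region <- pval <- numeric(length(uc))
  for (i in seq_along(uc)) {
    M <- (4 / 3) / uc[i]
    u <- .taex_inverse_threshold(threshold, M)
    snp[i] <- sum(auto_values > u)
    region[i] <- sum(win_max > u)
    pval[i] <- .wilcox_p(.taex_apply(auto_values, M), observed_x, alternative)
  }
  idx <- match(as.vector(ckey), uc)
  shape <- function(v, kind) {
    new("DemographySurface", xAxis = x_axis, yAxis = y_axis,
        cells = matrix(v[idx], length(x_axis), length(y_axis)), kind = kind)
  }
  list(snp_count = shape(snp, "snp_count"),
       region_count = shape(region, "region_count"),
       p_value = shape(pval, "p_value"),
       n_auto = length(auto_values), n_x = length(observed_x))
}

#' Cells whose TA/EX high count matches the X observation proportionally
#'
#' A cell "matches" when its high-count proportion (count over the autosomal
#' list length) is at least the observed X proportion — proportions rather
#' than absolute counts, since the autosomal and X marker panels differ in
#' size.
#'
#' @param count_surface a snp_count or region_count
#'   [DemographySurface-class].
#' @param n_auto_total autosomal list size (SNPs or regions).
#' @param x_count observed X high count.
#' @param n_x_total X list size.
#' @return logical matrix over the grid.
#' @export
cellsMatchingX <- function(count_surface, n_auto_total, x_count, n_x_total) {
  count_surface@cells / n_auto_total >= x_count / n_x_total
}
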