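#' Pair male X chromosomes into pseudofemales
#'
#' Randomly pairs male X haplotypes within each population (without
#' replacement) into synthetic diploid "pseudofemale" records, so diploid
#' analyses can use the male chromosomes. Each population contributes
#' floor(n_males/2) pseudofemales; a leftover male is dropped (with a
#' message). Fully determined by \code{seed}.
#'
#' @param panel an X [HaplotypePanel-class].
#' @param seed integer seed.
#' @return list with \code{panel} (females + pseudofemales, all diploid) and
#'   \code{pairs} (data.frame: pseudofemale id, the two source males,
#'   population).
#' @export
makePseudofemales <- function(panel, seed = 1) {
  if (chromType(panel) != "X") stop("pseudofemales are an X-panel construction")
  set.seed(seed)
  cd <- as.data.frame(SummarizedExperiment::colData(panel))
  al <- alleleMat(panel)
  keep_cols <- which(cd$sex == "female")
  new_cols <- list(); new_cd <- list(); pairs <- list()
  for (pop in unique(cd$population)) {
    males <- which(cd$population == pop & cd$sex == "male")
    if (length(males) < 2) {
      if (length(males) == 1)
        message("population ", pop, " has a single male; no pseudofemale formed")
      next
    }
    perm <- sample(males)
    n_pf <- length(males) %/% 2L
    if (length(males) %% 2L == 1L)
      message("population ", pop, ": one unpaired male dropped")
    for (k in seq_len(n_pf)) {
      m1 <- perm[2 * k - 1]; m2 <- perm[2 * k]
      pf_id <- sprintf("PF_%s_%d", pop, k)
      new_cols[[length(new_cols) + 1L]] <- al[, m1]
      new_cols[[length(new_cols) + 1L]] <- al[, m2]
      new_cd[[length(new_cd) + 1L]] <- data.frame(
        sample_id = pf_id, copy = 1:2, sex = "female",
        population = pop, region = cd$region[m1], stringsAsFactors = FALSE)
      pairs[[length(pairs) + 1L]] <- data.frame(
        pseudofemale = pf_id, male1 = cd$sample_id[m1],
        male2 = cd$sample_id[m2], population = pop, stringsAsFactors = FALSE)
    }
  }
  alleles <- cbind(al[, keep_cols, drop = FALSE],
                   if (length(new_cols)) do.call(cbind, new_cols))
  copies <- rbind(cd[keep_cols, c("sample_id", "copy", "sex", "population",
                                  "region")],
                  if (length(new_cd)) do.call(rbind, new_cd))
  list(panel = HaplotypePanel(alleles, markerInfo(panel), copies, "X"),
       pairs = if (length(pairs)) do.call(rbind, pairs) else
         data.frame(pseudofemale = character(), male1 = character(),
                    male2 = character(), population = character()))
}

# Per-locus sums of squares for one stratum of units.
# Haplotypic 0/1 data: SS_l = n1 (n - n1) / n.
# Diploid dosage data with indicator distance (differing dosages):
# SS_l = (n^2 - sum_c n_c^2) / (2 n) over dosage classes {0, 1, 2}.
.ss_locus <- function(X, idx, mode) {
  sub <- X[idx, , drop = FALSE]
  if (mode == "haplotypic") {
    n <- colSums(!is.na(sub))
    n1 <- colSums(sub, na.rm = TRUE)
    ss <- n1 * (n - n1) / n
  } else {
    n <- colSums(!is.na(sub))
    s2 <- numeric(ncol(sub))
    for (c_val in 0:2) s2 <- s2 + colSums(sub == c_val, na.rm = TRUE)^2
    ss <- (n^2 - s2) / (2 * n)
  }
  ss[n == 0] <- 0
  ss
}

# units-by-loci matrix and unit labels for a panel under a given mode
.amova_units <- function(panel, mode) {
  cd <- as.data.frame(SummarizedExperiment::colData(panel))
  al <- alleleMat(panel)
  if (mode == "haplotypic") {
    list(X = t(al), population = cd$population, region = cd$region)
  } else {
    si <- sampleInfo(panel)
    if (any(si$ploidy != 2L))
      stop("diploid AMOVA needs two copies per sample; pair males first ",
           "(makePseudofemales)")
    dos <- vapply(si$sample_id, function(s) {
      idx <- which(cd$sample_id == s)
      rowSums(al[, idx, drop = FALSE])
    }, numeric(nrow(al)))
    list(X = t(dos), population = si$population, region = si$region)
  }
}

.amova_core <- function(ss_w, ss_g, ss_t, pop, region, n_units) {
  N <- n_units
  pops <- unique(pop)
  P <- length(pops)
  groups <- unique(region)
  G <- length(groups)
  n_p <- as.numeric(table(pop)[pops])
  n_g <- as.numeric(table(region)[groups])
  pop_group <- region[match(pops, pop)]

  SSD_w <- sum(ss_w); SSD_ap <- sum(ss_g) - sum(ss_w)
  SSD_ag <- sum(ss_t) - sum(ss_g)
  df_w <- N - P; df_ap <- P - G; df_ag <- G - 1

  MS_w <- SSD_w / df_w
  sigma_c <- MS_w
  if (G > 1) {
    sum_np2_over_ng <- sum(vapply(groups, function(g) {
      sum(n_p[pop_group == g]^2) / n_g[groups == g]
    }, numeric(1)))
    n2 <- (sum_np2_over_ng - sum(n_p^2) / N) / df_ag
    n3 <- (N - sum(n_g^2) / N) / df_ag
    MS_ag <- SSD_ag / df_ag
    if (df_ap > 0) {
      n1 <- (N - sum_np2_over_ng) / df_ap
      MS_ap <- SSD_ap / df_ap
      sigma_b <- (MS_ap - sigma_c) / n1
    } else {
      sigma_b <- 0  # one population per region: no among-pop stratum
    }
    sigma_a <- (MS_ag - sigma_c - n2 * sigma_b) / n3
    comp <- c(among_regions = sigma_a, among_pops_within_regions = sigma_b,
              within_pops = sigma_c)
  } else {
    n0 <- (N - sum(n_p^2) / N) / df_ap
    MS_ap <- SSD_ap / df_ap
    sigma_b <- (MS_ap - sigma_c) / n0
    comp <- c(among_pops_within_regions = sigma_b, within_pops = sigma_c)
  }
  comp[comp < 0] <- 0
  100 * comp / sum(comp)
}

#' AMOVA: hierarchical variance components from a haplotype panel
#'
#' Excoffier-Quattro-Smouse nested analysis of molecular variance on pairwise
#' differences. In haplotypic mode the units are chromosome copies and the
#' distance is the count of differing loci; in diploid mode the units are
#' individuals and the distance counts loci with differing allele dosage
#' (phase ignored). Hierarchy is samples within populations within
#' continental regions; with a single region the analysis is two-level. Loci
#' are first filtered to those polymorphic within the analyzed group.
#' Negative variance components are truncated to zero before conversion to
#' percentages.
#'
#' @param panel a [HaplotypePanel-class] (subset to the grouping of interest
#'   first, e.g. with [subsetPopulations()]).
#' @param mode "haplotypic" or "diploid".
#' @return list with \code{components} (percent of total variance),
#'   \code{n_loci_used}, \code{n_units}, \code{mode}, \code{levels}.
#' @export
amova <- function(panel, mode = c("haplotypic", "diploid")) {
  mode <- match.arg(mode)
  u <- .amova_units(panel, mode)
  if (length(unique(u$population)) < 2) stop("need at least 2 populations")
  poly <- .polymorphic_loci(u$X)
  if (!any(poly)) stop("no polymorphic loci within the analyzed group")
  X <- u$X[, poly, drop = FALSE]
  ss <- .amova_ss(X, u$population, u$region, mode)
  comp <- .amova_core(ss$w, ss$g, ss$t, u$population, u$region, nrow(X))
  list(components = comp, n_loci_used = sum(poly), n_units = nrow(X),
       mode = mode, levels = length(comp))
}

.polymorphic_loci <- function(X) {
  apply(X, 2, function(v) length(unique(v[!is.na(v)])) > 1)
}

# per-locus SS vectors: within pops (summed over pops), within regions,
# total
.amova_ss <- function(X, pop, region, mode) {
  L <- ncol(X)
  w <- numeric(L); g <- numeric(L)
  for (p in unique(pop)) w <- w + .ss_locus(X, pop == p, mode)
  for (r in unique(region)) g <- g + .ss_locus(X, region == r, mode)
  t <- .ss_locus(X, rep(TRUE, nrow(X)), mode)
  list(w = w, g = g, t = t)
}

#' AMOVA with bootstrap confidence intervals over loci
#'
#' Resamples loci (with replacement) B times from the polymorphic set,
#' recomputes the variance-component percentages, and reports percentile
#' 2.5/97.5 bounds around the point estimate.
#'
#' @inheritParams amova
#' @param B bootstrap replicates (default 20000; reduce for interactive use).
#' @param seed integer seed.
#' @return the [amova()] list plus \code{ci95}, a components x (low, high)
#'   matrix.
#' @importFrom stats quantile
#' @export
amovaBootstrap <- function(panel, mode = c("haplotypic", "diploid"),
                           B = 20000, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(B >= 1)
  u <- .amova_units(panel, mode)
  if (length(unique(u$population)) < 2) stop("need at least 2 populations")
  poly <- .polymorphic_loci(u$X)
  if (!any(poly)) stop("no polymorphic loci within the analyzed group")
  X <- u$X[, poly, drop = FALSE]
  ss <- .amova_ss(X, u$population, u$region, mode)
  point <- .amova_core(ss$w, ss$g, ss$t, u$population, u$region, nrow(X))
  set.seed(seed)
  L <- ncol(X)
  boot <- matrix(NA_real_, B, length(point))
  for (b in seq_len(B)) {
    idx <- sample.int(L, L, replace = TRUE)
    boot[b, ] <- .amova_core(ss$w[idx], ss$g[idx], ss$t[idx],
                             u$population, u$region, nrow(X))
  }
  ci <- t(apply(boot, 2, stats::quantile, probs = c(0.025, 0.975)))
  dimnames(ci) <- list(names(point), c("low", "high"))
  list(components = point, ci95 = ci, n_loci_used = L, n_units = nrow(X),
       mode = mode, levels = length(point), B = B)
}
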