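#' Expected X-linked differentiation under the sex-structured island model
#'
#' Maps autosomal differentiation to its X-linked expectation given the female
#' share of the effective population size (\code{x} = N_f/N) and of the total
#' migration rate (\code{y} = m_f/m). Demography enters only through the
#' combined term c = (1 + y)/(2 - x): writing F' = F/(1 - F), the linearized
#' island-model relation is F'_X = M F'_A with multiplier
#' M(x, y) = (4/3) (2 - x)/(1 + y) = (4/3)/c. At x = y = 0.5 this reduces to
#' the classic 4/3 X/autosome ratio.
#'
#' @param F_A autosomal differentiation value(s) in [0, 1].
#' @param x female proportion of the effective population size, in (0, 1).
#' @param y female proportion of the total migration rate, in (0, 1).
#' @return expected X-linked differentiation, same length as \code{F_A};
#'   F_A = 1 is a fixed point.
#' @examples
#' expectedXDifferentiation(0.10, 0.5, 0.5)  # 4/31
#' @export
expectedXDifferentiation <- function(F_A, x, y) {
  if (any(F_A < 0 | F_A > 1)) stop("F_A must lie in [0, 1]")
  if (x <= 0 || x >= 1 || y <= 0 || y >= 1) stop("x and y must lie in (0, 1)")
  M <- (4 / 3) * (2 - x) / (1 + y)
  out <- ifelse(F_A >= 1, 1, {
    Fp <- F_A / (1 - F_A)
    M * Fp / (1 + M * Fp)
  })
  out
}

#' Simulation configuration for the sex-structured island model
#'
#' Returns a validated config list for [simulateDataset()]. Defaults describe
#' the packaged study conditions: 2 continental regions of 3 populations each,
#' 2,000 autosomal and 500 X-linked loci at 20-kb spacing, autosomal island
#' differentiation F_A = 0.10, balanced demography (N_f/N = m_f/m = 0.5),
#' 25 females + 25 males per population, 16 founder haplotypes per population,
#' founder switching at 1e-5 /bp (100-kb mean segments), allele flips at
#' 0.002 /site, outgroup fixed for the ancestral allele with probability 0.8,
#' and gene intervals covering about 32% of markers.
#'
#' @param n_regions,pops_per_region hierarchy of population labels.
#' @param n_auto_loci,n_x_loci marker counts per panel.
#' @param fst_auto autosomal island-model differentiation F_A in (0, 1).
#' @param nf_ratio,mf_ratio N_f/N and m_f/m in (0, 1).
#' @param females_per_pop,males_per_pop diploid sample sizes per population.
#' @param founder_count founder haplotypes per population (>= 1).
#' @param switch_rate founder-copying switch rate per bp.
#' @param flip_rate per-site allele flip (mutation) rate.
#' @param outgroup_fixed_prob probability the outgroup pair is fixed for the
#'   ancestral allele at a marker (else it is polymorphic).
#' @param genic_fraction_target target fraction of markers inside genes.
#' @param region_fst_share fraction of total differentiation placed among
#'   regions (0 = flat island model; populations exchangeable).
#' @param marker_spacing_bp distance between consecutive markers.
#' @param seed integer seed; fully determines the output.
#' @return a list of class \code{"simConfig"}.
#' @export
simConfig <- function(n_regions = 2, pops_per_region = 3,
                      n_auto_loci = 2000, n_x_loci = 500,
                      fst_auto = 0.10, nf_ratio = 0.5, mf_ratio = 0.5,
                      females_per_pop = 25, males_per_pop = 25,
                      founder_count = 16, switch_rate = 1e-5,
                      flip_rate = 0.002, outgroup_fixed_prob = 0.8,
                      genic_fraction_target = 0.32, region_fst_share = 0,
                      marker_spacing_bp = 20e3, seed = 1) {
  stopifnot(n_regions >= 1, pops_per_region >= 1, n_auto_loci >= 1,
            n_x_loci >= 1, founder_count >= 1)
  if (fst_auto <= 0 || fst_auto >= 1) stop("fst_auto must lie in (0, 1)")
  if (nf_ratio <= 0 || nf_ratio >= 1 || mf_ratio <= 0 || mf_ratio >= 1)
    stop("nf_ratio and mf_ratio must lie in (0, 1)")
  if (flip_rate < 0 || flip_rate >= 0.5) stop("flip_rate must lie in [0, 0.5)")
  if (outgroup_fixed_prob < 0 || outgroup_fixed_prob > 1)
    stop("outgroup_fixed_prob must lie in [0, 1]")
  if (region_fst_share < 0 || region_fst_share >= 1)
    stop("region_fst_share must lie in [0, 1)")
  cfg <- as.list(environment())
  class(cfg) <- "simConfig"
  cfg
}

# Balding-Nichols draw: population frequencies around ancestral p with
# differentiation F; F -> 0 degenerates to q = p.
.bn_draw <- function(p, F) {
  if (F < 1e-12) return(p)
  a <- p * (1 - F) / F
  b <- (1 - p) * (1 - F) / F
  stats::rbeta(length(p), a, b)
}

# founder-copying haplotypes for one population:
# founder pool carries allele 1 at site l in round(K*q_l) of K founders, so
# the pool frequency matches the drawn population frequency up to 1/(2K);
# haplotypes copy founders, switching at exponential bp distances.
.copy_haplotypes <- function(q, pos_bp, n_hap, K, switch_rate, flip_rate) {
  L <- length(q)
  fmat <- matrix(0L, K, L)
  n1 <- round(K * q)
  for (l in seq_len(L)) if (n1[l] > 0)
    fmat[sample.int(K, n1[l]), l] <- 1L
  gaps <- diff(pos_bp)
  p_switch <- 1 - exp(-switch_rate * gaps)
  f <- sample.int(K, n_hap, replace = TRUE)
  out <- matrix(0L, n_hap, L)
  out[, 1] <- fmat[cbind(f, 1L)]
  for (l in 2:L) {
    sw <- stats::rbinom(n_hap, 1L, p_switch[l - 1]) == 1L
    if (any(sw)) f[sw] <- sample.int(K, sum(sw), replace = TRUE)
    out[, l] <- fmat[cbind(f, l)]
  }
  if (flip_rate > 0) {
    flips <- matrix(stats::rbinom(n_hap * L, 1L, flip_rate), n_hap, L)
    out <- (out + flips) %% 2L
  }
  out
}

.sim_panel <- function(cfg, n_loci, F_target, chrom, chrom_type) {
  n_pops <- cfg$n_regions * cfg$pops_per_region
  pops <- paste0("R", rep(seq_len(cfg$n_regions), each = cfg$pops_per_region),
                 "P", rep(seq_len(cfg$pops_per_region), cfg$n_regions))
  regions <- paste0("R", rep(seq_len(cfg$n_regions), each = cfg$pops_per_region))

  pos_bp <- round((seq_len(n_loci) - 0.5) * cfg$marker_spacing_bp)
  p_anc <- stats::runif(n_loci, 0.05, 0.95)

  # optional hierarchical split of differentiation into region + population
  F_r <- cfg$region_fst_share * F_target
  F_w <- if (F_r > 0) (F_target - F_r) / (1 - F_r) else F_target
  qmat <- matrix(0, n_loci, n_pops, dimnames = list(NULL, pops))
  for (r in seq_len(cfg$n_regions)) {
    p_region <- if (F_r > 0) .bn_draw(p_anc, F_r) else p_anc
    for (k in seq_len(cfg$pops_per_region)) {
      j <- (r - 1) * cfg$pops_per_region + k
      qmat[, j] <- .bn_draw(p_region, F_w)
    }
  }

  n_per_pop_x <- cfg$females_per_pop * 2 + cfg$males_per_pop
  n_per_pop_a <- (cfg$females_per_pop + cfg$males_per_pop) * 2
  n_hap <- if (chrom_type == "X") n_per_pop_x else n_per_pop_a

  hap_blocks <- copies <- vector("list", n_pops)
  for (j in seq_len(n_pops)) {
    hap <- .copy_haplotypes(qmat[, j], pos_bp, n_hap, cfg$founder_count,
                            cfg$switch_rate, cfg$flip_rate)
    hap_blocks[[j]] <- t(hap)  # markers x copies
    sex <- c(rep("female", cfg$females_per_pop), rep("male", cfg$males_per_pop))
    ids <- paste0(pops[j], "_", c(paste0("F", seq_len(cfg$females_per_pop)),
                                  paste0("M", seq_len(cfg$males_per_pop))))
    cp_per <- if (chrom_type == "X") ifelse(sex == "female", 2L, 1L)
              else rep(2L, length(sex))
    copies[[j]] <- data.frame(
      sample_id = rep(ids, cp_per),
      copy = unlist(lapply(cp_per, seq_len)),
      sex = rep(sex, cp_per),
      population = pops[j], region = regions[j],
      stringsAsFactors = FALSE)
  }
  alleles <- do.call(cbind, hap_blocks)
  copies <- do.call(rbind, copies)

  markers <- data.frame(
    marker_id = paste0(chrom, "_", pos_bp + 1),
    chrom = chrom, pos_bp = pos_bp, pos_cM = pos_bp * 1e-6,
    allele0 = "A", allele1 = "G", anc_state = "allele0",
    genic = FALSE, stringsAsFactors = FALSE)

  # random gene intervals sized to cover about the target marker fraction
  span <- n_loci * cfg$marker_spacing_bp
  gene_len <- 40e3
  n_genes <- max(1L, round(cfg$genic_fraction_target * span / gene_len))
  g_start <- sort(stats::runif(n_genes, 0, span - gene_len))
  genic <- vapply(markers$pos_bp, function(b)
    any(b >= g_start & b < g_start + gene_len), logical(1))
  markers$genic <- genic
  genes <- data.frame(chrom = chrom, start = round(g_start),
                      end = round(g_start + gene_len))

  # diploid outgroup pair: fixed ancestral with prob outgroup_fixed_prob,
  # else one individual heterozygous
  fixed <- stats::runif(n_loci) < cfg$outgroup_fixed_prob
  og <- data.frame(marker_id = markers$marker_id,
                   out1 = ifelse(fixed, "A/A", "A/G"),
                   out2 = "A/A", stringsAsFactors = FALSE)

  list(panel = HaplotypePanel(alleles, markers, copies, chrom_type),
       truth_p = p_anc, truth_q = qmat, genes = genes, outgroup = og)
}

#' Simulate a matched X / autosome dataset under sex-structured demography
#'
#' Draws, per locus, an ancestral frequency p ~ Uniform(0.05, 0.95) and
#' per-population frequencies from the Balding-Nichols equilibrium
#' Beta(p(1-F)/F, (1-p)(1-F)/F), with F = \code{fst_auto} for autosomal loci
#' and F = [expectedXDifferentiation()] of \code{fst_auto} at
#' (\code{nf_ratio}, \code{mf_ratio}) for X loci. Haplotypes are built by
#' founder copying so panels carry realistic haplotype structure with tunable
#' EHH decay; founder pools are matched to the drawn frequencies so Hudson Fst
#' recovers the generative F. Males receive one X haplotype, females two.
#'
#' @param cfg a [simConfig()] list.
#' @return a list with elements \code{x_panel}, \code{auto_panel}
#'   ([HaplotypePanel-class]), \code{truth} (ancestral and per-population
#'   frequencies and the F values used), \code{outgroup} (per-marker diploid
#'   outgroup genotypes for both panels), and \code{genes} (the gene
#'   intervals used for genic flags, BED-style 0-based half-open).
#' @export
simulateDataset <- function(cfg) {
  stopifnot(inherits(cfg, "simConfig"))
  set.seed(cfg$seed)
  F_X <- expectedXDifferentiation(cfg$fst_auto, cfg$nf_ratio, cfg$mf_ratio)
  auto <- .sim_panel(cfg, cfg$n_auto_loci, cfg$fst_auto, "A1", "autosome")
  x <- .sim_panel(cfg, cfg$n_x_loci, F_X, "X", "X")
  list(
    x_panel = x$panel, auto_panel = auto$panel,
    truth = list(F_A = cfg$fst_auto, F_X = F_X,
                 nf_ratio = cfg$nf_ratio, mf_ratio = cfg$mf_ratio,
                 auto_p = auto$truth_p, auto_q = auto$truth_q,
                 x_p = x$truth_p, x_q = x$truth_q),
    outgroup = rbind(auto$outgroup, x$outgroup),
    genes = rbind(auto$genes, x$genes)
  )
}

#' Write simulator output as the standard file set
#'
#' Emits, per panel, the VCF/sample/BED/map files read by [loadPanel()], plus
#' the outgroup TSV and a truth TSV of per-locus generative frequencies.
#'
#' @param sim output of [simulateDataset()].
#' @param dir output directory.
#' @return invisibly, a named list of written paths.
#' @export
writeSimFiles <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  px <- writePanelFiles(sim$x_panel, dir, "x")
  pa <- writePanelFiles(sim$auto_panel, dir, "auto")
  og_path <- file.path(dir, "outgroup.tsv")
  write.table(sim$outgroup, og_path, sep = "\t", quote = FALSE, row.names = FALSE)
  genes_path <- file.path(dir, "genes.bed")
  write.table(sim$genes, genes_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  truth <- data.frame(
    marker_id = c(markerInfo(sim$auto_panel)$marker_id,
                  markerInfo(sim$x_panel)$marker_id),
    p_anc = c(sim$truth$auto_p, sim$truth$x_p),
    rbind(sim$truth$auto_q, sim$truth$x_q))
  truth_path <- file.path(dir, "truth.tsv")
  write.table(truth, truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(x = px, auto = pa, outgroup = og_path, genes = genes_path,
                 truth = truth_path))
}

#' Plant a selective-sweep haplotype signature
#'
#' Rewrites a fraction of one population's haplotypes so they carry the
#' derived allele at a focal marker on a long shared haplotype: each carrier
#' copies one of \code{carrier_founders} template haplotypes over a tract
#' around the core and keeps its own background outside the tract. Tract
#' half-lengths are \code{min_tract_bp} plus an Exponential(\code{tract_rate})
#' distance per side, mimicking recombination onto the background. With one
#' founder all carriers are identical across their shared tract.
#'
#' @param panel a [HaplotypePanel-class].
#' @param focal_marker marker id or row index; must be polymorphic in the
#'   target population.
#' @param population target population label.
#' @param carrier_fraction share of the population's haplotypes made carriers,
#'   in (0, 1].
#' @param carrier_founders number of template haplotypes (>= 1).
#' @param tract_rate per-bp decay rate of the shared tract (default 5e-6,
#'   mean 200-kb one-sided tract).
#' @param min_tract_bp minimum shared tract per side around the core.
#' @param seed optional integer seed.
#' @return the modified [HaplotypePanel-class].
#' @export
plantSweep <- function(panel, focal_marker, population, carrier_fraction = 0.8,
                       carrier_founders = 2, tract_rate = 5e-6,
                       min_tract_bp = 50e3, seed = NULL) {
  if (carrier_fraction <= 0 || carrier_fraction > 1)
    stop("carrier_fraction must lie in (0, 1]")
  stopifnot(carrier_founders >= 1)
  if (!is.null(seed)) set.seed(seed)
  mk <- markerInfo(panel)
  row <- if (is.character(focal_marker)) match(focal_marker, mk$marker_id)
         else as.integer(focal_marker)
  if (is.na(row) || row < 1 || row > nrow(mk)) stop("focal marker not found")
  cd <- as.data.frame(SummarizedExperiment::colData(panel))
  cols <- which(cd$population == population)
  if (!length(cols)) stop("population not in panel: ", population)
  al <- alleleMat(panel)
  core <- al[row, cols]
  if (length(unique(core[!is.na(core)])) < 2)
    stop("focal marker is monomorphic in population ", population)

  n_car <- max(1L, round(carrier_fraction * length(cols)))
  carriers <- sample(cols, n_car)
  templates <- al[, carriers[seq_len(min(carrier_founders, n_car))], drop = FALSE]
  templates[row, ] <- 1L

  pos <- mk$pos_bp
  for (i in seq_along(carriers)) {
    t_idx <- sample.int(ncol(templates), 1L)
    dl <- min_tract_bp + stats::rexp(1, tract_rate)
    dr <- min_tract_bp + stats::rexp(1, tract_rate)
    in_tract <- pos >= pos[row] - dl & pos <= pos[row] + dr
    al[in_tract, carriers[i]] <- templates[in_tract, t_idx]
  }
  al[row, carriers] <- 1L
  SummarizedExperiment::assay(panel, "alleles") <- al
  panel
}
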