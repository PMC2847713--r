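# Independent oracles used by several test files.

# AMOVA from an explicit pairwise squared-distance matrix:
# SSD(S) = sum_{i<j in S} d_ij / |S|, then the nested ANOVA solution.
brute_amova_dist <- function(D, pop, region) {
  ssd <- function(idx) sum(D[idx, idx]) / (2 * length(idx))
  N <- nrow(D)
  pops <- unique(pop); P <- length(pops)
  groups <- unique(region); G <- length(groups)
  SSD_t <- ssd(seq_len(N))
  SSD_w <- sum(vapply(pops, function(p) ssd(which(pop == p)), numeric(1)))
  SSD_g <- sum(vapply(groups, function(g) ssd(which(region == g)), numeric(1)))
  n_p <- as.numeric(table(pop)[pops])
  n_g <- as.numeric(table(region)[groups])
  pg <- region[match(pops, pop)]
  sigma_c <- SSD_w / (N - P)
  if (G > 1) {
    s1 <- sum(vapply(groups, function(g) sum(n_p[pg == g]^2) / n_g[groups == g],
                     numeric(1)))
    n1 <- (N - s1) / (P - G)
    n2 <- (s1 - sum(n_p^2) / N) / (G - 1)
    n3 <- (N - sum(n_g^2) / N) / (G - 1)
    sigma_b <- ((SSD_g - SSD_w) / (P - G) - sigma_c) / n1
    sigma_a <- ((SSD_t - SSD_g) / (G - 1) - sigma_c - n2 * sigma_b) / n3
    comp <- c(sigma_a, sigma_b, sigma_c)
  } else {
    n0 <- (N - sum(n_p^2) / N) / (P - 1)
    sigma_b <- ((SSD_t - SSD_w) / (P - 1) - sigma_c) / n0
    comp <- c(sigma_b, sigma_c)
  }
  comp[comp < 0] <- 0
  100 * comp / sum(comp)
}

# 0/1 haplotype data: squared Euclidean distance equals the count of
# differing loci
brute_amova <- function(X, pop, region) {
  brute_amova_dist(as.matrix(dist(X))^2, pop, region)
}

# panel where the 4 haplotypes carrying allele 1 at the core (marker 2)
# extend as patterns {B, B, C, D} over the two right-flank markers
bbcd_panel <- function() {
  al <- matrix(c(
    0L, 0L, 0L, 0L,   # marker 1 (left flank, all identical)
    1L, 1L, 1L, 1L,   # marker 2 (core)
    0L, 0L, 1L, 1L,   # marker 3
    0L, 0L, 0L, 1L),  # marker 4
    nrow = 4, byrow = TRUE)
  samples <- data.frame(sample_id = c("s1", "s2"), sex = "female",
                        population = "p", region = "r")
  toy_panel(al, c(0, 1e5, 2e5, 3e5), samples, anc_state = "allele0")
}
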