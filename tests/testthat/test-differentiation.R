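test_that("X frequencies count males once", {
  # females 0|1 and 1|1, male 1 -> p = 4/5
  p <- toy_x_panel()
  fq <- populationFrequencies(p, "pop1")
  expect_equal(fq$p, rep(4 / 5, 3))
  expect_equal(fq$n, rep(5L, 3))
})

test_that("monomorphic and all-missing sites behave as specified", {
  samples <- data.frame(sample_id = c("s1", "s2"), sex = "female",
                        population = "p", region = "r")
  al <- matrix(c(1L, 0L, NA, 1L, 0L, NA, 1L, 0L, NA, 1L, 0L, NA), nrow = 3)
  pan <- toy_panel(al, c(10, 20, 30), samples)
  fq <- populationFrequencies(pan, "p")
  expect_equal(fq$p[1:2], c(1, 0))
  expect_true(is.na(fq$p[3]))
  expect_equal(fq$n[3], 0L)
})

test_that("delta is the absolute frequency difference", {
  hapA <- matrix(c(0L, 1L, 0L), 3, 4)   # popA: p = 0, 1, 0
  hapB <- matrix(c(1L, 1L, 0L), 3, 4)   # popB: p = 1, 1, 0
  pan <- two_pop_panel(hapA, hapB)
  sc <- deltaScan(pan, "popA", "popB")
  expect_equal(sc$value, c(1, 0, 0))
  # symmetry
  expect_equal(deltaScan(pan, "popB", "popA")$value, sc$value)
  # arithmetic example on explicit frequencies: 20 copies per pop
  hapA2 <- rbind(c(rep(1L, 19), 0L))          # p = 0.95
  hapB2 <- rbind(c(1L, rep(0L, 19)))          # p = 0.05
  pan2 <- two_pop_panel(matrix(hapA2, 1), matrix(hapB2, 1))
  expect_equal(deltaScan(pan2, "popA", "popB")$value, 0.90)
})

test_that("Hudson Fst is clipped, 1 for fixed differences, ~0 for equality", {
  hapA <- matrix(c(0L, 1L), 2, 6)
  hapB <- matrix(c(1L, 1L), 2, 6)
  pan <- two_pop_panel(hapA, hapB)
  fst <- deltaScan(pan, "popA", "popB", "hudson_fst")$value
  expect_equal(fst[1], 1)      # fixed difference
  expect_true(is.na(fst[2]))   # both fixed for the same allele: undefined
  set.seed(2)
  hapC <- matrix(rbinom(5 * 20, 1, 0.4), 5, 20)
  pan2 <- two_pop_panel(hapC, hapC)
  v <- deltaScan(pan2, "popA", "popB", "hudson_fst")$value
  expect_true(all(v >= 0 & v <= 1, na.rm = TRUE))
  expect_true(all(v[!is.na(v)] == 0))  # equal freqs, corrections clipped at 0
})

test_that("high-delta calling is strict and region tallies match a recount", {
  grid <- makeWindows(0, 10e3, 2e3)
  vals <- data.frame(pos_bp = c(100, 500, 2500, 4100, 9900),
                     value = c(0.91, 0.95, 0.9, 0.2, 0.99))
  out <- callHighDeltaRegions(vals, grid, threshold = 0.9)
  # 0.9 exactly at the threshold is NOT high
  expect_equal(out$n_high_snps, 3L)
  # two high SNPs share window 1; 0.99 sits in window 5
  expect_equal(out$n_high_regions, 2L)
  expect_equal(out$per_region$n_high, c(2L, 0L, 0L, 0L, 1L))

  # brute-force recount oracle on random values
  set.seed(7)
  vals2 <- data.frame(pos_bp = sort(sample(0:9999, 10)),
                      value = round(runif(10), 2))
  out2 <- callHighDeltaRegions(vals2, grid, threshold = 0.5)
  brute_high <- 0L
  brute_regions <- rep(0L, 5)
  for (i in seq_len(nrow(vals2))) {
    if (vals2$value[i] > 0.5) {
      brute_high <- brute_high + 1L
      w <- floor(vals2$pos_bp[i] / 2000) + 1
      brute_regions[w] <- brute_regions[w] + 1L
    }
  }
  expect_equal(out2$n_high_snps, brute_high)
  expect_equal(out2$n_high_regions, sum(brute_regions > 0))
  expect_equal(out2$per_region$n_high, brute_regions)
  # invariants
  expect_lte(out2$n_high_regions, out2$n_high_snps)
  expect_lte(out2$n_high_regions, length(grid))
})

test_that("ancestral states follow the fixed-outgroup rule with overrides", {
  samples <- data.frame(sample_id = "s1", sex = "female",
                        population = "p", region = "r")
  pan <- toy_panel(matrix(c(0L, 1L), 4, 2), c(10, 20, 30, 40), samples)
  og <- data.frame(marker_id = c("m1", "m2", "m3"),
                   out1 = c("A/A", "A/G", "./."),
                   out2 = c("A/A", "A/A", "./."))
  pan <- assignAncestralAlleles(pan, og)
  st <- markerInfo(pan)$anc_state
  expect_equal(st, c("allele0", "unknown", "unknown", "unknown"))
  # fixed for the alternate allele
  og2 <- data.frame(marker_id = "m4", out1 = "G/G", out2 = "G/G")
  pan <- assignAncestralAlleles(pan, og2)
  expect_equal(markerInfo(pan)$anc_state[4], "allele1")
  # override fills in a missing call
  pan <- assignAncestralAlleles(
    pan, og, override = data.frame(marker_id = "m3", ancestral = "G"))
  expect_equal(markerInfo(pan)$anc_state[3], "allele1")
  expect_error(assignAncestralAlleles(
    pan, og, override = data.frame(marker_id = "m3", ancestral = "T")),
    "not among")
})

test_that("classification reproduces the printed derived-high fractions", {
  # 159 high-delta markers, ancestral known everywhere; derived frequency
  # >= 0.9 in popA for exactly 26 and in popB for exactly 133
  n_high <- 159
  calls <- data.frame(
    value = rep(0.95, n_high), high = TRUE, genic = rep(c(TRUE, FALSE), length.out = n_high),
    anc_state = "allele0",
    p_A = c(rep(0.95, 26), rep(0.03, 133)),
    p_B = c(rep(0.02, 26), rep(0.97, 133)),
    n_A = 100, n_B = 100)
  low <- data.frame(value = rep(0.1, 40), high = FALSE, genic = FALSE,
                    anc_state = "allele0", p_A = 0.5, p_B = 0.45,
                    n_A = 100, n_B = 100)
  s <- classifyHighDelta(rbind(calls, low), "Yoruba", "Han")
  dh <- s$derived_high
  expect_equal(dh$count[dh$population == "Yoruba"], 26)
  expect_equal(dh$denom[1], 159)
  expect_equal(round(100 * dh$fraction[dh$population == "Yoruba"], 1), 16.4)
  expect_equal(dh$count[dh$population == "Han"], 133)
})

test_that("empty high set yields absent fractions, not zeros", {
  calls <- data.frame(value = runif(10, 0, 0.5), high = FALSE, genic = TRUE,
                      anc_state = "allele0", p_A = 0.4, p_B = 0.5,
                      n_A = 10, n_B = 10)
  s <- classifyHighDelta(calls)
  expect_equal(s$n_high, 0L)
  expect_true(is.na(s$genic_fraction_high))
  expect_true(all(is.na(s$derived_high$fraction)))
})

test_that("all-genic high set gives genic fraction 1 and the cross-tab matches brute force", {
  set.seed(31)
  n <- 60
  calls <- data.frame(
    value = runif(n), genic = runif(n) < 0.4, anc_state = "allele0",
    p_A = runif(n), p_B = runif(n), n_A = 50, n_B = 30)
  calls$high <- calls$value > 0.7
  s <- classifyHighDelta(calls)
  # brute-force cross-tab
  pooled <- (calls$p_A * 50 + calls$p_B * 30) / 80
  maf <- pmin(pooled, 1 - pooled)
  for (g in c(FALSE, TRUE)) for (l in c(FALSE, TRUE)) for (h in c(FALSE, TRUE)) {
    expect_equal(
      unname(s$crosstab[as.character(g), as.character(l), as.character(h)]),
      sum(calls$genic == g & (maf <= 0.1) == l & calls$high == h))
  }
  # brute-force decile check
  for (b in seq_len(10)) {
    lo <- (b - 1) / 10; hi <- b / 10
    inbin <- calls$value >= lo & (calls$value < hi | (b == 10 & calls$value <= 1))
    expect_equal(s$decile_enrichment$n[b], sum(inbin))
    expect_equal(s$decile_enrichment$n_genic[b], sum(calls$genic[inbin]))
  }
  calls2 <- calls
  calls2$genic[calls2$high] <- TRUE
  expect_equal(classifyHighDelta(calls2)$genic_fraction_high, 1)
})

test_that("chi-square on identical proportions is 0 with p = 1", {
  r <- proportionChisq(5, 10, 50, 100)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  # degenerate: both groups all failures
  r2 <- proportionChisq(0, 10, 0, 20)
  expect_equal(r2$statistic, 0)
  expect_equal(r2$p_value, 1)
})

test_that("X carries proportionally more high-delta SNPs than autosomes when M > 1", {
  wins <- 0L
  for (seed in 1:20) {
    cfg <- simConfig(n_regions = 2, pops_per_region = 1, n_auto_loci = 1200,
                     n_x_loci = 1200, females_per_pop = 25, males_per_pop = 25,
                     fst_auto = 0.2, seed = seed)
    sim <- simulateDataset(cfg)
    thr <- 0.7
    px <- mean(deltaScan(sim$x_panel, "R1P1", "R2P1")$value > thr, na.rm = TRUE)
    pa <- mean(deltaScan(sim$auto_panel, "R1P1", "R2P1")$value > thr, na.rm = TRUE)
    if (px > pa) wins <- wins + 1L
  }
  expect_gte(wins, 15L)
})
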