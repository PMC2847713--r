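test_that("EHH matches hand enumeration on the 4-haplotype toy", {
  cv <- ehhCurve(bbcd_panel(), "p", 2, "derived")
  expect_equal(cv$ehh[cv$offset_bp == 0], 1)
  # marker 3: classes {B,B} and {C,D-prefix}: 2 identical pairs of 12 -> 1/3
  expect_equal(cv$ehh[cv$offset_bp == 1e5], 1 / 3)
  # marker 4: classes sizes {2,1,1}: EHH = 2*1 / (4*3) = 1/6
  expect_equal(cv$ehh[cv$offset_bp == 2e5], 1 / 6)
  # left flank: all identical -> EHH stays 1
  expect_equal(cv$ehh[cv$offset_bp == -1e5], 1)
  expect_equal(attr(cv, "n_core"), 4L)
})

test_that("EHH is 1 at the core, 0 past full diversification, non-increasing", {
  al <- matrix(c(1L, 1L, 1L, 1L,
                 0L, 1L, 0L, 1L,
                 0L, 0L, 1L, 1L,
                 0L, 1L, 1L, 0L), nrow = 4, byrow = TRUE)
  samples <- data.frame(sample_id = c("s1", "s2"), sex = "female",
                        population = "p", region = "r")
  pan <- toy_panel(al, c(0, 100, 200, 300), samples, anc_state = "allele0")
  cv <- ehhCurve(pan, "p", 1, "all")
  # all 4 distinct after marker 3 -> EHH 0 from there on
  expect_equal(cv$ehh[cv$offset_bp == 200], 0)
  expect_equal(cv$ehh[cv$offset_bp == 300], 0)
  # property: non-increasing with |offset| on random panels
  set.seed(10)
  for (rep in 1:5) {
    al2 <- matrix(rbinom(8 * 20, 1, 0.5), nrow = 8)
    s2 <- data.frame(sample_id = paste0("s", 1:10), sex = "female",
                     population = "p", region = "r")
    p2 <- toy_panel(al2, 1:8 * 100, s2)
    cv2 <- ehhCurve(p2, "p", 4, "all")
    right <- cv2$ehh[cv2$offset_bp >= 0]
    left <- rev(cv2$ehh[cv2$offset_bp <= 0])
    expect_true(all(diff(right) <= 1e-12))
    expect_true(all(diff(left) <= 1e-12))
  }
})

test_that("ehhCurve returns NULL below 2 core haplotypes", {
  pan <- bbcd_panel()
  expect_null(ehhCurve(pan, "p", 2, "ancestral"))  # no ancestral carriers
})

test_that("iHH trapezoid integration and boundary rules match hand arithmetic", {
  # symmetric curve: each side 0.1 cM at EHH 1 then drop to 0.05
  cv <- data.frame(offset_bp = c(-2e5, -1e5, 0, 1e5, 2e5),
                   offset_cM = c(-0.2, -0.1, 0, 0.1, 0.2),
                   ehh = c(0.05, 1, 1, 1, 0.05))
  # one-sided area = 0.1 + (1 + 0.05)/2 * 0.1 = 0.1525
  expect_equal(ihh(cv, cutoff = 0.1), 2 * 0.1525)

  # below cutoff at the first flanking marker on both sides: still defined
  cv2 <- data.frame(offset_bp = c(-1e5, 0, 1e5),
                    offset_cM = c(-0.1, 0, 0.1), ehh = c(0.05, 1, 0.05))
  expect_equal(ihh(cv2, cutoff = 0.1), 2 * (1 + 0.05) / 2 * 0.1)

  # cutoff never reached on the right side: absent
  cv3 <- data.frame(offset_bp = c(-1e5, 0, 1e5),
                    offset_cM = c(-0.1, 0, 0.1), ehh = c(0.05, 1, 0.5))
  expect_true(is.na(ihh(cv3, cutoff = 0.1)))
  expect_true(is.na(ihh(NULL)))
})

test_that("mirror-symmetric decay gives raw iHS 0; lone frequency groups never flag", {
  # derived and ancestral classes with identical extension patterns
  al <- matrix(c(
    0L, 1L, 0L, 1L,  # left flank
    1L, 1L, 0L, 0L,  # core: 2 derived, 2 ancestral
    0L, 1L, 0L, 1L,  # right flank 1
    1L, 0L, 1L, 0L), # right flank 2
    nrow = 4, byrow = TRUE)
  samples <- data.frame(sample_id = c("s1", "s2"), sex = "female",
                        population = "p", region = "r")
  pan <- toy_panel(al, c(0, 1e5, 2e5, 3e5), samples, anc_state = "allele0")
  sc <- ihsScan(pan, "p")
  expect_equal(sc$ihs[2], 0)
  # its frequency group has a single member: deviation 0, never high
  expect_equal(sc$deviation[2], 0)
  expect_false(sc$high[2])
})

test_that("relabelling derived/ancestral negates raw iHS", {
  set.seed(55)
  cfg <- simConfig(n_regions = 1, pops_per_region = 1, n_auto_loci = 5,
                   n_x_loci = 80, females_per_pop = 12, males_per_pop = 12,
                   seed = 55)
  sim <- simulateDataset(cfg)
  pan <- sim$x_panel
  SummarizedExperiment::rowData(pan)$anc_state <- "allele0"
  sc0 <- ihsScan(pan, "R1P1")
  flipped <- pan
  SummarizedExperiment::rowData(flipped)$anc_state <- "allele1"
  sc1 <- ihsScan(flipped, "R1P1")
  ok <- !is.na(sc0$ihs) & !is.na(sc1$ihs)
  expect_gt(sum(ok), 5)
  expect_equal(sc1$ihs[ok], -sc0$ihs[ok])
})

test_that("XP-EHH is 0 for identical panels and antisymmetric under swap", {
  cfg <- simConfig(n_regions = 1, pops_per_region = 2, n_auto_loci = 5,
                   n_x_loci = 100, females_per_pop = 10, males_per_pop = 10,
                   seed = 61)
  sim <- simulateDataset(cfg)
  pan <- sim$x_panel
  # identical groups: compare a population to itself
  same <- xpehhScan(pan, "R1P1", "R1P1")
  expect_true(all(same$xpehh_raw[!is.na(same$xpehh_raw)] == 0))
  ab <- xpehhScan(pan, "R1P1", "R1P2")
  ba <- xpehhScan(pan, "R1P2", "R1P1")
  ok <- !is.na(ab$xpehh_raw) & !is.na(ba$xpehh_raw)
  expect_gt(sum(ok), 10)
  expect_equal(ab$xpehh_raw[ok], -ba$xpehh_raw[ok])
})

test_that("region aggregation matches brute force and conserves counts", {
  grid <- makeWindows(0, 10e3, 1e3)
  set.seed(71)
  sc <- data.frame(pos_bp = sort(sample(0:9999, 50)),
                   value = rnorm(50), high = runif(50) < 0.3)
  sc$value[c(3, 17)] <- NA
  for (mode in c("mean", "mean_zero_fill", "ihs_ratio")) {
    rg <- regionizeScores(sc, grid, mode)
    for (w in 1:10) {
      inw <- !is.na(sc$value) & floor(sc$pos_bp / 1000) + 1 == w
      expect_equal(rg$n_snps_scored[w], sum(inw))
      want <- if (mode == "ihs_ratio") {
        if (sum(inw)) sum(sc$high[inw]) / sum(inw) else NA_real_
      } else if (sum(inw)) mean(sc$value[inw])
        else if (mode == "mean_zero_fill") 0 else NA_real_
      expect_equal(rg$score[w], want)
    }
    expect_equal(sum(rg$n_snps_scored), sum(!is.na(sc$value)))
  }
  # spot checks from the window rules
  rg2 <- regionizeScores(data.frame(pos_bp = c(100, 200, 5000),
                                    value = c(1, 1, 1),
                                    high = c(TRUE, FALSE, FALSE)),
                         grid, "ihs_ratio")
  expect_equal(rg2$score[1], 0.5)
  expect_true(is.na(rg2$score[2]))
  rg3 <- regionizeScores(data.frame(pos_bp = 100, value = 2, high = FALSE),
                         grid, "mean_zero_fill")
  expect_equal(rg3$score[2:10], rep(0, 9))
})

test_that("top regions rank by score then position", {
  rg <- regionizeScores(
    data.frame(pos_bp = c(100, 1100, 2100), value = c(0.5, 0.9, 0.1),
               high = FALSE),
    makeWindows(0, 3e3, 1e3), "mean")
  top <- topRegions(rg, 2)
  expect_equal(top$window, c(2L, 1L))
  expect_equal(top$rank, 1:2)
  # ties resolve to the earlier window
  rg2 <- regionizeScores(
    data.frame(pos_bp = c(100, 1100, 2100), value = c(0.7, 0.7, 0.7),
               high = FALSE),
    makeWindows(0, 3e3, 1e3), "mean")
  expect_equal(topRegions(rg2, 3)$window, 1:3)
  expect_message(topRegions(rg2, 10), "returning all")
})

test_that("empirical window test agrees with exhaustive enumeration", {
  # unique maximum run
  s <- c(0, 1, 0, 10, 10, 0, 1, 0)
  r <- empiricalWindowTest(s, 4, 5)
  expect_equal(r$percentile, 1)
  expect_true(r$elevated)
  # constant scores: nothing is below
  rc <- empiricalWindowTest(rep(2, 10), 3, 5)
  expect_equal(rc$percentile, 0)
  expect_false(rc$elevated)
  expect_error(empiricalWindowTest(1:5, 1, 5), "shorter")

  set.seed(81)
  sc <- rnorm(50)
  from <- 13; to <- 16; k <- 4
  r2 <- empiricalWindowTest(sc, from, to)
  target <- mean(sc[from:to])
  others <- vapply(setdiff(1:(50 - k + 1), from),
                   function(s0) mean(sc[s0:(s0 + k - 1)]), numeric(1))
  expect_equal(r2$percentile, mean(others < target))
  expect_equal(r2$n_other, length(others))

  # k = 1 reduces to a per-score strict rank percentile
  r3 <- empiricalWindowTest(sc, 20, 20)
  expect_equal(r3$percentile, mean(sc[-20] < sc[20]))
})

test_that("haplotype heterozygosity ratio follows the closed forms", {
  set.seed(91)
  hap <- matrix(rbinom(8 * 10, 1, 0.5), 8, 10)
  pan <- two_pop_panel(hap, hap, regions = c("r1", "r1"))
  hr <- hapHetRatio(pan, "popA", "popB", window_snps = 5)
  # identical haplotype sets: ratio 1 wherever defined
  expect_true(all(hr$ratio[!is.na(hr$ratio)] == 1))
  expect_equal(nrow(hr), 8 - 5 + 1)
  expect_equal(hr$pos_bp[1], 3000)   # centered on the third marker

  # popB monomorphic for the window haplotype -> ratio 0
  hapB <- matrix(0L, 8, 10)
  panB <- two_pop_panel(hap, hapB, regions = c("r1", "r1"))
  hrB <- hapHetRatio(panB, "popA", "popB")
  expect_true(all(hrB$ratio[!is.na(hrB$ratio)] == 0))

  # k equally frequent window haplotypes: H = 1 - 1/k
  k <- 4
  block <- matrix(c(0L, 0L, 0L, 0L, 0L,
                    1L, 0L, 0L, 0L, 0L,
                    0L, 1L, 0L, 0L, 0L,
                    1L, 1L, 0L, 0L, 0L), nrow = 5)
  hapK <- block[, rep(1:4, each = 2)]
  panK <- two_pop_panel(hapK, hapK, regions = c("r1", "r1"))
  hrK <- hapHetRatio(panK, "popA", "popB")
  expect_equal(hrK$H_A, 1 - 1 / k)
  # ratio undefined where the reference heterozygosity is 0
  hrZ <- hapHetRatio(panB, "popB", "popA")
  expect_true(all(is.na(hrZ$ratio)))
})
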