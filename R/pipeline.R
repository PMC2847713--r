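#' Run the full analysis pipeline from one config
#'
#' Orchestrates simulate -> diff -> taex -> amova -> selscan -> report as a
#' reproducible run: a YAML config supplies every stage's parameters, a
#' single global seed is expanded into per-stage seeds by a fixed scheme
#' (stage i uses \code{seed + 1000 * i}; simulate is stage 0, the AMOVA
#' bootstrap stage 3), all stage outputs are TSV files under \code{out_dir},
#' and a run log echoes the config, the seeds and the locus counts after
#' each filter. Identical config and seed give byte-identical outputs.
#'
#' Recognized config keys (stages run only if their key is present):
#' \describe{
#'   \item{seed, out_dir}{global seed and output directory.}
#'   \item{simulate}{overrides for [simConfig()].}
#'   \item{diff}{\code{pair} (two population labels), \code{measure},
#'     \code{threshold} (default 0.9), \code{window_bp} (default 200000).}
#'   \item{taex}{\code{threshold}, \code{side}, \code{grid_step} (default
#'     0.01).}
#'   \item{amova}{\code{mode}, \code{bootstrap} (replicates, default 200).}
#'   \item{selscan}{\code{test} (ihs/xpehh/track), \code{groupA},
#'     \code{groupB} (population vectors), \code{window_bp} (default 400000),
#'     \code{track_path} for test = track, \code{top_k} (default 10).}
#'   \item{report}{\code{true} to write the summary table.}
#' }
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @return invisibly, a list of stage results.
#' @export
runPipeline <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(cfg$out_dir)) stop("config missing field: out_dir")
  if (is.null(cfg$seed)) stop("config missing field: seed")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  logf("hapXscan pipeline run")
  logf("seed: %d", cfg$seed)
  logf("config: %s", gsub("\n", " | ", yaml::as.yaml(cfg)))
  res <- list()
  tsv <- function(df, name) {
    write.table(df, file.path(cfg$out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }

  if (is.null(cfg$simulate)) stop("config missing field: simulate")
  sim_args <- cfg$simulate
  sim_args$seed <- cfg$seed
  sc <- do.call(simConfig, sim_args)
  sim <- .stage("simulate", function() simulateDataset(sc))
  writeSimFiles(sim, file.path(cfg$out_dir, "simulated"))
  logf("simulate: %d autosomal + %d X loci, %d populations",
       sc$n_auto_loci, sc$n_x_loci, sc$n_regions * sc$pops_per_region)
  res$simulate <- sim

  x_mk <- markerInfo(sim$x_panel)
  a_mk <- markerInfo(sim$auto_panel)

  if (!is.null(cfg$diff)) {
    d <- cfg$diff
    if (is.null(d$pair)) stop("diff stage missing field: pair")
    thr <- d$threshold %||% 0.9
    wbp <- d$window_bp %||% 200000
    measure <- d$measure %||% "delta"
    res$diff <- .stage("diff", function() {
      grids <- list(
        x = makeWindows(0, max(x_mk$pos_bp) + 1, wbp, chrom = "X"),
        auto = makeWindows(0, max(a_mk$pos_bp) + 1, wbp, chrom = "A1"))
      out <- lapply(c(x = "x_panel", auto = "auto_panel"), function(p) {
        pan <- assignAncestralAlleles(sim[[p]], sim$outgroup)
        calls <- highDeltaCalls(pan, d$pair[1], d$pair[2],
                                grids[[if (p == "x_panel") "x" else "auto"]],
                                threshold = thr, measure = measure)
        list(calls = calls,
             tallies = callHighDeltaRegions(
               calls, grids[[if (p == "x_panel") "x" else "auto"]], thr),
             summary = classifyHighDelta(calls, d$pair[1], d$pair[2]))
      })
      tsv(out$x$calls, "diff_x_persnp.tsv")
      tsv(out$auto$calls, "diff_auto_persnp.tsv")
      tsv(out$x$tallies$per_region, "diff_x_regions.tsv")
      tsv(out$auto$tallies$per_region, "diff_auto_regions.tsv")
      out
    })
    logf("diff: X high SNPs %d / regions %d; autosomal high SNPs %d / regions %d",
         res$diff$x$tallies$n_high_snps, res$diff$x$tallies$n_high_regions,
         res$diff$auto$tallies$n_high_snps, res$diff$auto$tallies$n_high_regions)
  }

  if (!is.null(cfg$taex)) {
    if (is.null(res$diff)) stop("taex stage requires the diff stage")
    t <- cfg$taex
    step <- t$grid_step %||% 0.01
    axis <- seq(0.01, 0.99, by = step)
    res$taex <- .stage("taex", function() {
      surf <- demographyGridScan(
        res$diff$auto$calls$value, res$diff$auto$calls$pos_bp,
        res$diff$x$calls$value,
        makeWindows(0, max(a_mk$pos_bp) + 1, cfg$diff$window_bp %||% 200000,
                    chrom = "A1"),
        threshold = t$threshold %||% 0.9,
        side = t$side %||% "two_sided", x_axis = axis, y_axis = axis)
      writeSurface(surf$snp_count, file.path(cfg$out_dir, "taex_snp_count.tsv"))
      writeSurface(surf$region_count,
                   file.path(cfg$out_dir, "taex_region_count.tsv"))
      writeSurface(surf$p_value, file.path(cfg$out_dir, "taex_p_value.tsv"))
      surf
    })
    logf("taex: %d x %d grid over %d autosomal / %d X values",
         length(axis), length(axis), res$taex$n_auto, res$taex$n_x)
  }

  if (!is.null(cfg$amova)) {
    a <- cfg$amova
    mode <- a$mode %||% "haplotypic"
    B <- a$bootstrap %||% 200
    res$amova <- .stage("amova", function() {
      run1 <- function(panel) {
        pan <- panel
        if (mode == "diploid" && chromType(panel) == "X")
          pan <- makePseudofemales(panel, seed = cfg$seed + 3000)$panel
        amovaBootstrap(pan, mode = mode, B = B, seed = cfg$seed + 3000)
      }
      out <- list(x = run1(sim$x_panel), auto = run1(sim$auto_panel))
      rows <- do.call(rbind, lapply(names(out), function(nm) {
        r <- out[[nm]]
        data.frame(panel = nm, component = names(r$components),
                   percent = unname(r$components),
                   ci_low = r$ci95[, "low"], ci_high = r$ci95[, "high"],
                   n_loci_used = r$n_loci_used, row.names = NULL)
      }))
      tsv(rows, "amova.tsv")
      out
    })
    logf("amova (%s, B=%d): X loci used %d, autosomal loci used %d",
         mode, B, res$amova$x$n_loci_used, res$amova$auto$n_loci_used)
  }

  if (!is.null(cfg$selscan)) {
    s <- cfg$selscan
    wbp <- s$window_bp %||% 400000
    test <- s$test %||% "xpehh"
    res$selscan <- .stage("selscan", function() {
      grid <- makeWindows(0, max(x_mk$pos_bp) + 1, wbp, chrom = "X")
      pan <- assignAncestralAlleles(sim$x_panel, sim$outgroup)
      out <- switch(test,
        ihs = {
          scan <- ihsScan(pan, s$groupA)
          scan$value <- scan$ihs
          regionizeScores(scan, grid, "ihs_ratio")
        },
        xpehh = {
          scan <- xpehhScan(pan, s$groupA, s$groupB)
          scan$value <- scan$xpehh_std
          regionizeScores(scan, grid, "mean_zero_fill")
        },
        track = {
          tr <- readScoreTrack(s$track_path)
          tr$value <- tr$score
          regionizeScores(tr, grid, "mean")
        },
        stop("unknown selscan test: ", test))
      tsv(out, paste0("selscan_", test, "_regions.tsv"))
      top <- topRegions(out, s$top_k %||% 10)
      tsv(top, paste0("selscan_", test, "_top.tsv"))
      list(regions = out, top = top)
    })
    logf("selscan (%s): %d windows scored, top score %.4f", test,
         sum(!is.na(res$selscan$regions$score)), res$selscan$top$score[1])
  }

  if (isTRUE(cfg$report)) {
    rows <- data.frame(key = character(), value = character())
    add <- function(k, v) rbind(rows, data.frame(key = k, value = as.character(v)))
    rows <- add("seed", cfg$seed)
    if (!is.null(res$diff)) {
      rows <- add("x_high_snps", res$diff$x$tallies$n_high_snps)
      rows <- add("x_high_regions", res$diff$x$tallies$n_high_regions)
      rows <- add("auto_high_snps", res$diff$auto$tallies$n_high_snps)
      rows <- add("auto_high_regions", res$diff$auto$tallies$n_high_regions)
    }
    if (!is.null(res$amova)) {
      rows <- add("x_within_pct", res$amova$x$components[["within_pops"]])
      rows <- add("auto_within_pct", res$amova$auto$components[["within_pops"]])
    }
    tsv(rows, "report.tsv")
    logf("report written")
  }
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.stage <- function(name, fn) {
  tryCatch(fn(), error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}
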