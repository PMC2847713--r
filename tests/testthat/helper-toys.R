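# In-code fixtures shared across tests.

# Small panel from explicit pieces. `samples` is a data.frame with
# sample_id, sex, population, region; copies are expanded by ploidy rule.
toy_panel <- function(alleles, pos_bp, samples, chrom_type = "autosome",
                      chrom = if (chrom_type == "X") "X" else "A1",
                      pos_cM = NULL, anc_state = "unknown", genic = FALSE) {
  ploidy <- if (chrom_type == "X") ifelse(samples$sex == "male", 1L, 2L)
            else rep(2L, nrow(samples))
  copies <- data.frame(
    sample_id = rep(samples$sample_id, ploidy),
    copy = unlist(lapply(ploidy, seq_len)),
    sex = rep(samples$sex, ploidy),
    population = rep(samples$population, ploidy),
    region = rep(samples$region, ploidy))
  markers <- data.frame(
    marker_id = paste0("m", seq_along(pos_bp)), chrom = chrom,
    pos_bp = pos_bp,
    pos_cM = if (is.null(pos_cM)) pos_bp * 1e-6 else pos_cM,
    allele0 = "A", allele1 = "G", anc_state = anc_state, genic = genic)
  HaplotypePanel(alleles, markers, copies, chrom_type)
}

# X panel: 2 females (0|1 and 1|1) + 1 male (1) at every site
toy_x_panel <- function(n_markers = 3) {
  samples <- data.frame(sample_id = c("f1", "f2", "m1"),
                        sex = c("female", "female", "male"),
                        population = "pop1", region = "r1")
  al <- matrix(rep(c(0L, 1L, 1L, 1L, 1L), each = n_markers),
               nrow = n_markers)
  toy_panel(al, seq_len(n_markers) * 1000, samples, chrom_type = "X")
}

# two-population diploid panel from per-population haplotype matrices
# (markers x copies each), 1 sample per 2 copies, all female
two_pop_panel <- function(hapA, hapB, chrom_type = "autosome",
                          regions = c("r1", "r2"), pos_bp = NULL) {
  nA <- ncol(hapA) / 2; nB <- ncol(hapB) / 2
  samples <- data.frame(
    sample_id = c(paste0("a", seq_len(nA)), paste0("b", seq_len(nB))),
    sex = "female",
    population = rep(c("popA", "popB"), c(nA, nB)),
    region = rep(regions, c(nA, nB)))
  if (is.null(pos_bp)) pos_bp <- seq_len(nrow(hapA)) * 1000
  toy_panel(cbind(hapA, hapB), pos_bp, samples, chrom_type)
}

write_toy_vcf <- function(path, rows, samples) {
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, rows), path)
}

write_toy_samples <- function(path, df) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
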