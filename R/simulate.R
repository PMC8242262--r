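#' Configuration for the synthetic multi-omic generator
#'
#' The generator plants a ground truth that mirrors the statistical structure
#' of the study system: alternating A/B compartment blocks; LADs
#' concentrated in B; G9a/GLP-sensitive regions (GSRs) covering most of A
#' plus a minority of B; paired-condition H3K9me2 tracks with the mark
#' erased by `erasure_depth` inside GSRs in the treated condition; DamID
#' log-ratios positive over LADs with treated-condition lamina loss at
#' GSR/LAD overlaps; Hi-C matrices with power-law distance decay times an
#' A/B checkerboard of tunable contrast (stronger in the treated condition);
#' and a gene table with up-regulation and promoter ATAC gain concentrated
#' in GSRs. Defaults are chosen once as desk-scale study conditions.
#'
#' @param seed RNG seed (integer).
#' @param n_chroms number of chromosomes (default 2).
#' @param chrom_len_bp chromosome length (default 20 Mb).
#' @param chip_bin_bp ChIP/ATAC/DamID track bin (default 1 kb).
#' @param hic_bin_bp Hi-C matrix bin (default 40 kb).
#' @param compartment_block_bp A/B block size (default 2 Mb).
#' @param frac_lad_in_B fraction of B covered by LADs; A-side LAD bp is
#'   scaled so LADs make up the complementary share (default 0.8).
#' @param gsr_frac_of_A fraction of A covered by GSRs (default 0.6).
#' @param gsr_frac_of_B minority fraction of B covered by GSRs (default 0.1).
#' @param erasure_depth H3K9me2 loss inside GSRs, treated condition
#'   (default 1).
#' @param noise_sd Gaussian noise SD per ChIP bin (default 0.3).
#' @param checkerboard_contrast Hi-C same-compartment enrichment factor
#'   kappa, control condition (default 1.5).
#' @param contrast_treated kappa for the treated condition (default 1.7,
#'   i.e. stronger compartmentalization after treatment).
#' @param decay_exponent power-law distance-decay exponent (default 1).
#' @param hic_depth expected count at one-bin separation (default 500).
#' @param hic_lognorm_sd SD of multiplicative log-normal Hi-C noise
#'   (default 0.2).
#' @param hic_masked_frac fraction of Hi-C bins zeroed to emulate
#'   unmappable bins (default 0.02).
#' @param n_genes number of genes (default 2000).
#' @param frac_de_up_in_gsr probability that a GSR gene is up-regulated
#'   (default 0.3).
#' @param frac_de_up_bg up-regulation probability outside GSRs
#'   (default 0.02).
#' @param frac_de_down down-regulation probability everywhere
#'   (default 0.06).
#' @param gene_density_ratio_A gene-density ratio A:B (default 3).
#' @param damid_noise_sd DamID noise SD (default 0.3).
#' @param gsr_ilad_detach mild DamID decrease over GSR/iLAD in the treated
#'   condition (default 0.3).
#' @param atac_fold_up promoter ATAC fold increase for up-regulated genes
#'   (default 2).
#' @return A validated list of class `SimConfig`.
#' @export
sim_config <- function(seed = 1, n_chroms = 2, chrom_len_bp = 2e7,
                       chip_bin_bp = 1000, hic_bin_bp = 40000,
                       compartment_block_bp = 2e6,
                       frac_lad_in_B = 0.8, gsr_frac_of_A = 0.6,
                       gsr_frac_of_B = 0.1, erasure_depth = 1,
                       noise_sd = 0.3, checkerboard_contrast = 1.5,
                       contrast_treated = 1.7, decay_exponent = 1,
                       hic_depth = 500, hic_lognorm_sd = 0.2,
                       hic_masked_frac = 0.02, n_genes = 2000,
                       frac_de_up_in_gsr = 0.3, frac_de_up_bg = 0.02,
                       frac_de_down = 0.06, gene_density_ratio_A = 3,
                       damid_noise_sd = 0.3, gsr_ilad_detach = 0.3,
                       atac_fold_up = 2) {
  cfg <- as.list(environment())
  fr <- c("frac_lad_in_B", "gsr_frac_of_A", "gsr_frac_of_B",
          "frac_de_up_in_gsr", "frac_de_up_bg", "frac_de_down",
          "hic_masked_frac")
  for (f in fr) if (cfg[[f]] < 0 || cfg[[f]] > 1)
    stop(f, " must be in [0, 1]")
  if (cfg$checkerboard_contrast < 1) stop("checkerboard_contrast must be >= 1")
  if (cfg$contrast_treated < cfg$checkerboard_contrast)
    stop("contrast_treated must be >= checkerboard_contrast")
  if (cfg$noise_sd <= 0) stop("noise_sd must be positive")
  if (cfg$erasure_depth < 0) stop("erasure_depth must be non-negative")
  if (abs(cfg$seed) >= 2^31 - 20) stop("seed too large")
  if (cfg$n_chroms < 1 || cfg$n_genes < 1) stop("need at least 1 chromosome and gene")
  if (cfg$hic_bin_bp %% cfg$chip_bin_bp != 0)
    stop("hic_bin_bp must be a multiple of chip_bin_bp")
  structure(cfg, class = "SimConfig")
}

## a random contiguous sub-interval covering `frac` of [s, e)
sub_block <- function(s, e, frac) {
  len <- (e - s) * frac
  if (len <= 0) return(NULL)
  start <- s + stats::runif(1, 0, (e - s) - len)
  c(floor(start), floor(start) + round(len))
}

#' Generate the synthetic multi-omic dataset with planted truth
#'
#' All randomness is seeded from `config$seed` with fixed per-component
#' offsets, so identical configs give byte-identical outputs.
#'
#' @param config a [sim_config()].
#' @return A list of class `SyntheticTruth`: layouts, planted
#'   `compartments`, `lads`, `lads_treated`, `gsrs` ([domain_set()]s),
#'   per-condition `chip_*`, `atac_*`, `damid_*` tracks, `hic_control` /
#'   `hic_treated` ([contact_matrix()]s), `genes` (`GeneTable` with planted
#'   `section` labels), `spikein` counts, and the `config`.
#' @export
simulate_multiomics <- function(config = sim_config()) {
  stopifnot(inherits(config, "SimConfig"))
  cfg <- config
  lens <- stats::setNames(rep(cfg$chrom_len_bp, cfg$n_chroms),
                          paste0("chr", seq_len(cfg$n_chroms)))
  layout <- genome_layout(lens, cfg$chip_bin_bp)
  layout_hic <- genome_layout(lens, cfg$hic_bin_bp)

  ## (i) alternating A/B blocks; odd chromosomes start with A, even with B
  rows <- list()
  for (ci in seq_len(cfg$n_chroms)) {
    chrom <- names(lens)[ci]
    starts <- seq(0, lens[[chrom]] - 1, by = cfg$compartment_block_bp)
    ends <- pmin(starts + cfg$compartment_block_bp, lens[[chrom]])
    first <- if (ci %% 2 == 1) c("A", "B") else c("B", "A")
    lab <- rep_len(first, length(starts))
    rows[[chrom]] <- data.frame(chrom = chrom, start = starts, end = ends, label = lab)
  }
  df <- do.call(rbind, rows)
  compartments <- domain_set(df$chrom, df$start, df$end, df$label, layout)
  a_blocks <- compartments[compartments$label == "A", , drop = FALSE]
  b_blocks <- compartments[compartments$label == "B", , drop = FALSE]

  ## (ii) LADs: frac_lad_in_B of each B block; A-side LAD bp sized so the
  ## A share of total LAD bp is (1 - frac_lad_in_B)
  set.seed(cfg$seed + 1)
  a_frac <- cfg$frac_lad_in_B * (1 - cfg$frac_lad_in_B) /
    max(cfg$frac_lad_in_B, 1e-9) *
    (sum(b_blocks$end - b_blocks$start) / max(sum(a_blocks$end - a_blocks$start), 1))
  lad_rows <- list()
  for (k in seq_len(nrow(b_blocks))) {
    sb <- sub_block(b_blocks$start[k], b_blocks$end[k], cfg$frac_lad_in_B)
    if (!is.null(sb)) lad_rows[[length(lad_rows) + 1]] <-
        data.frame(chrom = b_blocks$chrom[k], start = sb[1], end = sb[2])
  }
  for (k in seq_len(nrow(a_blocks))) {
    sb <- sub_block(a_blocks$start[k], a_blocks$end[k], min(a_frac, 1))
    if (!is.null(sb)) lad_rows[[length(lad_rows) + 1]] <-
        data.frame(chrom = a_blocks$chrom[k], start = sb[1], end = sb[2])
  }
  ldf <- do.call(rbind, lad_rows)
  lads <- domain_set(ldf$chrom, ldf$start, ldf$end, "LAD", layout)

  ## (iii) GSRs: gsr_frac_of_A of each A block plus gsr_frac_of_B of each B
  set.seed(cfg$seed + 2)
  gsr_rows <- list()
  for (k in seq_len(nrow(a_blocks))) {
    sb <- sub_block(a_blocks$start[k], a_blocks$end[k], cfg$gsr_frac_of_A)
    if (!is.null(sb) && sb[2] - sb[1] >= 50000)
      gsr_rows[[length(gsr_rows) + 1]] <-
        data.frame(chrom = a_blocks$chrom[k], start = sb[1], end = sb[2])
  }
  for (k in seq_len(nrow(b_blocks))) {
    sb <- sub_block(b_blocks$start[k], b_blocks$end[k], cfg$gsr_frac_of_B)
    if (!is.null(sb) && sb[2] - sb[1] >= 50000)
      gsr_rows[[length(gsr_rows) + 1]] <-
        data.frame(chrom = b_blocks$chrom[k], start = sb[1], end = sb[2])
  }
  gdf <- do.call(rbind, gsr_rows)
  gsrs <- domain_set(gdf$chrom, gdf$start, gdf$end, "GSR", layout)

  ## (iv) H3K9me2 tracks: base level higher in B; treated loses
  ## erasure_depth inside GSRs; fresh noise per condition
  set.seed(cfg$seed + 3)
  in_b <- domains_indicator(b_blocks_ds(compartments), layout)
  in_gsr <- domains_indicator(gsrs, layout)
  base <- track_map(in_b, function(x) 1 + x)  # A: 1, B: 2
  chip_control <- track_map(base, function(x) x + stats::rnorm(length(x), 0, cfg$noise_sd))
  chip_treated <- track_map2(base, in_gsr, function(x, g)
    x - cfg$erasure_depth * g)
  chip_treated <- track_map(chip_treated, function(x)
    x + stats::rnorm(length(x), 0, cfg$noise_sd))

  ## (v) Hi-C per condition
  hic_control <- simulate_hic(layout_hic, compartments, cfg$checkerboard_contrast,
                              cfg, seed = cfg$seed + 4)
  hic_treated <- simulate_hic(layout_hic, compartments, cfg$contrast_treated,
                              cfg, seed = cfg$seed + 5)

  ## (vi) DamID: +1 over LADs, -1 elsewhere; treated loses lamina contact
  ## over GSR/LAD entirely and detaches mildly over GSR/iLAD
  set.seed(cfg$seed + 6)
  in_lad <- domains_indicator(lads, layout)
  damid_control <- track_map(in_lad, function(x)
    2 * x - 1 + stats::rnorm(length(x), 0, cfg$damid_noise_sd))
  lads_treated <- domains_setdiff(lads, gsrs, "LAD")
  in_lad_t <- domains_indicator(lads_treated, layout)
  gsr_ilad <- domains_setdiff(gsrs, lads)
  in_gsr_ilad <- domains_indicator(gsr_ilad, layout)
  damid_treated <- track_map2(in_lad_t, in_gsr_ilad, function(x, g)
    2 * x - 1 - cfg$gsr_ilad_detach * g)
  damid_treated <- track_map(damid_treated, function(x)
    x + stats::rnorm(length(x), 0, cfg$damid_noise_sd))

  ## (vii) genes: density-weighted placement (A richer than B), DE
  ## concentrated in GSRs, promoter ATAC raised for up genes
  set.seed(cfg$seed + 7)
  comp_df <- as.data.frame(compartments)
  wts <- (comp_df$end - comp_df$start) *
    ifelse(comp_df$label == "A", cfg$gene_density_ratio_A, 1)
  blk <- sample(nrow(comp_df), cfg$n_genes, replace = TRUE, prob = wts)
  pos <- floor(stats::runif(cfg$n_genes, comp_df$start[blk], comp_df$end[blk] - 1))
  strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  glen <- pmax(2000, floor(stats::rlnorm(cfg$n_genes, log(20000), 0.6)))
  chrom <- comp_df$chrom[blk]
  start <- ifelse(strand == "+", pos, pmax(pos - glen, 0))
  end <- ifelse(strand == "+", pmin(pos + glen, lens[chrom] - 1), pos)
  base_mean <- stats::rlnorm(cfg$n_genes, 3, 1.5)
  in_gsr_gene <- !is.na(locate_label(gsrs, chrom, pos))
  p_up <- ifelse(in_gsr_gene, cfg$frac_de_up_in_gsr, cfg$frac_de_up_bg)
  u <- stats::runif(cfg$n_genes)
  status <- ifelse(u < p_up, "up",
                   ifelse(u < p_up + cfg$frac_de_down, "down", "unchanged"))
  lfc <- stats::rnorm(cfg$n_genes, 0, 0.3)
  n_up <- sum(status == "up"); n_dn <- sum(status == "down")
  lfc[status == "up"] <- 1.2 + abs(stats::rnorm(n_up, 0, 0.8))
  lfc[status == "down"] <- -(1.2 + abs(stats::rnorm(n_dn, 0, 0.8)))
  padj <- stats::runif(cfg$n_genes, 0.1, 1)
  padj[status != "unchanged"] <- stats::runif(n_up + n_dn, 0, 0.04)
  gene_df <- data.frame(
    id = sprintf("gene%04d", seq_len(cfg$n_genes)),
    chrom = chrom, start = start, end = end, strand = strand,
    base_mean = base_mean, log2fc = lfc, padj = padj,
    stringsAsFactors = FALSE)
  genes <- make_gene_table(gene_df, layout)
  sections <- build_sections(gsrs, lads)
  genes$section <- locate_label(sections, genes$chrom, genes$tss)
  genes$cluster_truth <- match(genes$section,
                               c("GSRs/iLADs", "GSRs/LADs",
                                 "non-GSRs/iLADs", "non-GSRs/LADs"))

  set.seed(cfg$seed + 8)
  atac_control <- binned_track(layout, 1)
  atac_control <- track_map(atac_control, function(x)
    x + stats::rnorm(length(x), 0, 0.1))
  atac_base <- binned_track(layout, 1)
  up_genes <- which(status == "up")
  for (i in up_genes) {
    ch <- chrom[i]
    b0 <- max(floor((pos[i] - 2500) / cfg$chip_bin_bp) + 1L, 1L)
    b1 <- min(floor((pos[i] + 2499) / cfg$chip_bin_bp) + 1L,
              n_bins(layout, ch)[[1]])
    atac_base$values[[ch]][b0:b1] <- cfg$atac_fold_up
  }
  atac_treated <- track_map(atac_base, function(x)
    x + stats::rnorm(length(x), 0, 0.1))

  spikein <- data.frame(
    sample = c("input", "control", "treated"),
    reads_exogenous = c(1e6, 1e6, 1e6),
    reads_endogenous = c(4e6, 4e6, 4e6))

  structure(list(
    layout = layout, layout_hic = layout_hic,
    compartments = compartments, lads = lads, lads_treated = lads_treated,
    gsrs = gsrs, sections = sections,
    chip_control = chip_control, chip_treated = chip_treated,
    atac_control = atac_control, atac_treated = atac_treated,
    damid_control = damid_control, damid_treated = damid_treated,
    hic_control = hic_control, hic_treated = hic_treated,
    genes = genes, spikein = spikein, config = cfg
  ), class = "SyntheticTruth")
}

b_blocks_ds <- function(compartments) {
  domains_with_label(compartments, "B")
}

#' Simulate one condition's Hi-C contact matrices
#'
#' Expected counts are `depth * (d + 1)^(-alpha)` times
#' `kappa^(+1)` for same-compartment and `kappa^(-1)` for cross-compartment
#' bin pairs, with multiplicative log-normal noise (mean-corrected),
#' symmetrization, and Poisson sampling. A small fraction of bins is zeroed
#' to emulate unmappable regions.
#'
#' @param layout_hic [genome_layout()] at Hi-C resolution.
#' @param compartments A/B [domain_set()].
#' @param kappa checkerboard contrast (>= 1).
#' @param cfg a [sim_config()] (depth, decay, noise, masked fraction).
#' @param seed RNG seed for this matrix.
#' @return A raw [contact_matrix()].
#' @export
simulate_hic <- function(layout_hic, compartments, kappa, cfg, seed) {
  set.seed(seed)
  lab <- bin_labels(compartments, layout_hic)
  mats <- lapply(layout_hic$chroms, function(chrom) {
    n <- n_bins(layout_hic, chrom)[[1]]
    is_a <- lab[[chrom]] == "A"
    same <- outer(is_a, is_a, `==`)
    d <- abs(outer(seq_len(n), seq_len(n), `-`))
    E <- cfg$hic_depth * (d + 1)^(-cfg$decay_exponent) *
      ifelse(same, kappa, 1 / kappa)
    noise <- matrix(stats::rlnorm(n * n, -cfg$hic_lognorm_sd^2 / 2,
                                  cfg$hic_lognorm_sd), n, n)
    E <- E * noise
    E[lower.tri(E)] <- t(E)[lower.tri(E)]
    counts <- matrix(0, n, n)
    ut <- upper.tri(counts, diag = TRUE)
    counts[ut] <- stats::rpois(sum(ut), E[ut])
    counts[lower.tri(counts)] <- t(counts)[lower.tri(counts)]
    n_mask <- floor(cfg$hic_masked_frac * n)
    if (n_mask > 0) {
      mb <- sample(n, n_mask)
      counts[mb, ] <- 0
      counts[, mb] <- 0
    }
    counts
  })
  names(mats) <- layout_hic$chroms
  contact_matrix(layout_hic, mats, flag = "raw")
}

#' Write a synthetic dataset as standard-format fixture files
#'
#' Emits every format the pipeline reads: bedGraph tracks, BED interval
#' sets, contact triples, gene and spike-in TSVs, plus a `truth.json` with
#' the config and planted coverage fractions. Output is deterministic given
#' the truth object.
#'
#' @param truth a `SyntheticTruth` from [simulate_multiomics()].
#' @param dir output directory (created if absent).
#' @return Named character vector of written paths, invisibly.
#' @export
write_fixture <- function(truth, dir) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_bedgraph(truth$chip_control, p("chip_control.bedgraph"))
  write_bedgraph(truth$chip_treated, p("chip_treated.bedgraph"))
  write_bedgraph(truth$atac_control, p("atac_control.bedgraph"))
  write_bedgraph(truth$atac_treated, p("atac_treated.bedgraph"))
  write_bedgraph(truth$damid_control, p("damid_control.bedgraph"))
  write_bedgraph(truth$damid_treated, p("damid_treated.bedgraph"))
  write_bed(truth$gsrs, p("gsrs.bed"))
  write_bed(truth$lads, p("lads_control.bed"))
  write_bed(truth$lads_treated, p("lads_treated.bed"))
  write_bed(truth$compartments, p("compartments.bed"))
  write_contacts(truth$hic_control, p("hic_control.tsv"))
  write_contacts(truth$hic_treated, p("hic_treated.tsv"))
  write_gene_table(truth$genes, p("genes.tsv"))
  utils::write.table(truth$spikein, p("spikein_counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth_json <- list(
    config = unclass(truth$config),
    chrom_lengths = as.list(truth$layout$lengths),
    coverage = list(
      gsr = genome_coverage(truth$gsrs),
      lad_control = genome_coverage(truth$lads),
      lad_treated = genome_coverage(truth$lads_treated),
      compartment_A = genome_coverage(domains_with_label(truth$compartments, "A"))))
  jsonlite::write_json(truth_json, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files <- c("chip_control.bedgraph", "chip_treated.bedgraph",
             "atac_control.bedgraph", "atac_treated.bedgraph",
             "damid_control.bedgraph", "damid_treated.bedgraph",
             "gsrs.bed", "lads_control.bed", "lads_treated.bed",
             "compartments.bed", "hic_control.tsv", "hic_treated.tsv",
             "genes.tsv", "spikein_counts.tsv", "truth.json")
  invisible(stats::setNames(file.path(dir, files), files))
}
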