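REPORT_SCHEMA_VERSION <- "1.0"

#' Run the full pipeline on a synthetic (or supplied) dataset
#'
#' Executes the stages in order: spike-in normalization (tracks scaled to
#' the control sample's spike-in factor), GSR calling, LAD calling and
#' switch classification, Hi-C compartment statistics per condition, and
#' gene-centric integration, and collects the study's summary quantities
#' into a structured report.
#'
#' @param config a [sim_config()] (the dataset is generated with
#'   [simulate_multiomics()]) or a `SyntheticTruth` object.
#' @param gsr_par a [gsr_params()].
#' @param lad_par a [lad_params()].
#' @param n_quantiles saddle quantiles (default 5).
#' @param saddle_bin_bp resolution at which the saddle is computed; counts
#'   and PC1 are re-binned. Default 240 kb, the closest multiple of the
#'   default 40-kb matrix bin to the classic 250-kb saddle resolution.
#' @param out_dir optional directory: intermediate standard-format files and
#'   `report.json` are written there.
#' @return A list of class `RunReport` (schema-versioned; all fractions in
#'   `[0, 1]`).
#' @export
run_all <- function(config, gsr_par = gsr_params(), lad_par = lad_params(),
                    n_quantiles = 5, saddle_bin_bp = 240000, out_dir = NULL) {
  truth <- if (inherits(config, "SyntheticTruth")) config
           else simulate_multiomics(config)
  cfg <- truth$config

  ## --- spike-in normalization (relative to the control sample) ---
  rho <- stats::setNames(
    mapply(spikein_scale_factor, truth$spikein$reads_exogenous,
           truth$spikein$reads_endogenous),
    truth$spikein$sample)
  chip_control <- apply_spikein(truth$chip_control, rho[["control"]] / rho[["control"]])
  chip_treated <- apply_spikein(truth$chip_treated, rho[["treated"]] / rho[["control"]])

  ## --- LAD calling per condition + switching ---
  lads_control <- call_lads(truth$damid_control, lad_par)
  lads_treated <- call_lads(truth$damid_treated, lad_par)
  switches <- classify_switches(lads_control, lads_treated)
  switch_assoc <- switch_expression_association(switches, truth$genes, strict = FALSE)

  ## --- GSR calling (sections use control-condition LADs) ---
  gsr_call <- call_gsrs(chip_control, chip_treated, lads_control, gsr_par)
  gsrs <- gsr_call$gsr_domains
  diff <- difference_track(chip_treated, chip_control)

  ## --- Hi-C ---
  gd <- gene_density_track(truth$genes, truth$layout_hic)
  oe_control <- observed_over_expected(truth$hic_control)
  oe_treated <- observed_over_expected(truth$hic_treated)
  pc_control <- compartment_pc1(truth$hic_control, gd)
  pc_treated <- compartment_pc1(truth$hic_treated, gd)
  strength_control <- compartmentalization_strength(oe_control, pc_control$pc1)
  strength_treated <- compartmentalization_strength(oe_treated, pc_treated$pc1)
  sad_control <- saddle(
    observed_over_expected(rebin_contacts(truth$hic_control, saddle_bin_bp)),
    rebin_track(pc_control$pc1, saddle_bin_bp), n_quantiles)
  sad_treated <- saddle(
    observed_over_expected(rebin_contacts(truth$hic_treated, saddle_bin_bp)),
    rebin_track(pc_treated$pc1, saddle_bin_bp), n_quantiles)
  cs_control <- interaction_score(oe_control, gsr_call$sections)
  cs_treated <- interaction_score(oe_treated, gsr_call$sections)
  cs_median <- function(cs) vapply(cs, function(tr)
    stats::median(track_values(tr), na.rm = TRUE), 0)

  ## --- gene-centric integration ---
  expressed <- filter_expressed(truth$genes)
  assays <- list(
    chip = list(control = chip_control, treated = chip_treated,
                combine = "log2ratio"),
    pc1 = list(control = pc_control$pc1, treated = pc_treated$pc1,
               combine = "difference"),
    damid = list(control = truth$damid_control, treated = truth$damid_treated,
                 combine = "difference"),
    atac = list(control = truth$atac_control, treated = truth$atac_treated,
                combine = "log2ratio"))
  features <- promoter_features(expressed, assays)
  clusters <- kmeans_clusters(features, k = 4, seed = cfg$seed + 10)
  clus_expr <- cluster_expression_test(clusters, expressed)
  clus_sec <- cluster_section_proportions(clusters, expressed, gsr_call$sections)
  de <- de_summary(truth$genes)

  ## --- section and coverage fractions ---
  sec_frac <- vapply(
    stats::setNames(nm = sort(unique(gsr_call$sections$label))),
    function(lb) genome_coverage(domains_with_label(gsr_call$sections, lb)), 0)
  sec_frac <- sec_frac / sum(sec_frac)
  switch_frac <- vapply(
    stats::setNames(nm = sort(unique(switches$label))),
    function(lb) genome_coverage(domains_with_label(switches, lb)), 0)
  ab_control <- pc_control$ab
  gsr_fraction <- genome_coverage(gsrs)
  gsr_in_ilad <- if (nrow(gsrs)) 1 - overlap_fraction(gsrs, lads_control) else NA_real_
  gsr_in_a <- if (nrow(gsrs) && nrow(ab_control))
    overlap_fraction(gsrs, domains_with_label(ab_control, "A")) else NA_real_

  report <- structure(list(
    schema_version = REPORT_SCHEMA_VERSION,
    seed = cfg$seed,
    parameters = list(sim = unclass(cfg), gsr = unclass(gsr_par),
                      lad = unclass(lad_par)),
    gsr = list(
      genome_fraction = gsr_fraction,
      fraction_in_ilad = gsr_in_ilad,
      fraction_in_A = gsr_in_a,
      n_domains = nrow(gsrs),
      threshold_used = gsr_call$threshold_used,
      empirical_fdr = gsr_call$empirical_fdr_at_threshold),
    sections = as.list(sec_frac),
    lad = list(
      coverage_control = genome_coverage(lads_control),
      coverage_treated = genome_coverage(lads_treated),
      switch_fractions = as.list(switch_frac),
      p_loss_vs_stable_lad = switch_assoc$p_loss_vs_stable_lad,
      p_gain_vs_stable_ilad = switch_assoc$p_gain_vs_stable_ilad),
    hic = list(
      strength_control = as.list(strength_control),
      strength_treated = as.list(strength_treated),
      strength_median_control = stats::median(strength_control, na.rm = TRUE),
      strength_median_treated = stats::median(strength_treated, na.rm = TRUE),
      saddle_control = sad_control$mean,
      saddle_treated = sad_treated$mean,
      interaction_score_median_control = as.list(cs_median(cs_control)),
      interaction_score_median_treated = as.list(cs_median(cs_treated))),
    genes = list(
      n_total = nrow(truth$genes),
      n_expressed = nrow(expressed),
      de_counts = as.list(de$counts),
      pct_up = de$pct_up,
      pct_down = de$pct_down,
      cluster_centers = clusters$centers,
      cluster_sizes = clusters$sizes,
      cluster_assignment = clusters$assignment,
      cluster_expression = clus_expr,
      cluster_sections = clus_sec)
  ), class = "RunReport")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fixture(truth, file.path(out_dir, "data"))
    write_bed(gsrs, file.path(out_dir, "gsrs_called.bed"))
    write_bed(gsr_call$sections, file.path(out_dir, "sections.bed"))
    write_bed(lads_control, file.path(out_dir, "lads_called_control.bed"))
    write_bed(lads_treated, file.path(out_dir, "lads_called_treated.bed"))
    write_bed(switches, file.path(out_dir, "lad_switches.bed"))
    write_bedgraph(gsr_call$t_track, file.path(out_dir, "t_statistic.bedgraph"))
    write_bedgraph(pc_control$pc1, file.path(out_dir, "pc1_control.bedgraph"))
    write_bedgraph(pc_treated$pc1, file.path(out_dir, "pc1_treated.bedgraph"))
    write_report(report, file.path(out_dir, "report.json"))
  }
  report
}

#' Serialize a run report to JSON
#'
#' Deterministic serialization: identical reports produce byte-identical
#' files.
#'
#' @param report a `RunReport`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "RunReport"))
  jsonlite::write_json(prepare_json(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

prepare_json <- function(x) {
  if (is.matrix(x)) return(apply(x, 1, as.list, simplify = FALSE))
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(unclass(x), prepare_json))
  x
}

#' Numeric diff between two run reports
#'
#' @param a,b `RunReport`s with identical schema versions.
#' @param tol differences at or below this absolute size are ignored
#'   (default 0: report every difference).
#' @return Data frame with columns `key`, `a`, `b`, `delta` for every
#'   numeric leaf that differs; zero rows when the reports agree.
#' @export
compare_reports <- function(a, b, tol = 0) {
  stopifnot(inherits(a, "RunReport"), inherits(b, "RunReport"))
  if (!identical(a$schema_version, b$schema_version))
    stop("schema version mismatch: ", a$schema_version, " vs ", b$schema_version)
  fa <- flatten_numeric(a)
  fb <- flatten_numeric(b)
  keys <- union(names(fa), names(fb))
  rows <- lapply(keys, function(k) {
    va <- if (k %in% names(fa)) fa[[k]] else NA_real_
    vb <- if (k %in% names(fb)) fb[[k]] else NA_real_
    d <- vb - va
    differs <- if (is.na(va) || is.na(vb)) !identical(is.na(va), is.na(vb))
               else abs(d) > tol
    if (!isTRUE(differs)) return(NULL)
    data.frame(key = k, a = va, b = vb, delta = d)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(data.frame(key = character(), a = numeric(), b = numeric(),
                      delta = numeric()))
  do.call(rbind, rows)
}

flatten_numeric <- function(x, prefix = "") {
  out <- list()
  if (is.data.frame(x)) x <- as.list(x)
  if (is.list(x)) {
    nms <- names(x)
    if (is.null(nms)) nms <- seq_along(x)
    for (i in seq_along(x)) {
      out <- c(out, flatten_numeric(x[[i]], paste0(prefix, nms[i], ".")))
    }
  } else if (is.numeric(x)) {
    v <- as.numeric(x)
    nms <- names(x)
    if (length(v) == 1 && is.null(nms)) {
      out[[substr(prefix, 1, nchar(prefix) - 1)]] <- v
    } else {
      if (is.null(nms)) nms <- seq_along(v)
      for (i in seq_along(v)) out[[paste0(prefix, nms[i])]] <- v[i]
    }
  }
  out
}
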