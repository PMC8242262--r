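#' Parameters for the DamID LAD caller
#'
#' A transparent smoothed-threshold segmentation: smooth the Lamin B1 DamID
#' log2 ratio, keep runs above the threshold, merge nearby runs, drop short
#' ones. Defaults: 120-kb smoothing window, threshold 0 (positive log-ratio =
#' lamina-associated), minimum LAD 100 kb, merge gap 40 kb.
#'
#' @param smooth_window_bp smoothing window (bp).
#' @param call_threshold threshold on the smoothed log2 ratio; bins strictly
#'   above it are LAD candidates.
#' @param min_lad_bp minimum retained LAD length (bp).
#' @param merge_gap_bp gaps shorter than this are closed (bp).
#' @return A list of class `LadParams`.
#' @export
lad_params <- function(smooth_window_bp = 120000, call_threshold = 0,
                       min_lad_bp = 100000, merge_gap_bp = 40000) {
  stopifnot(smooth_window_bp > 0, min_lad_bp > 0, merge_gap_bp > 0)
  structure(list(smooth_window_bp = smooth_window_bp,
                 call_threshold = call_threshold,
                 min_lad_bp = min_lad_bp, merge_gap_bp = merge_gap_bp),
            class = "LadParams")
}

#' Call LADs from a DamID log-ratio track
#'
#' @param damid a [binned_track()] of Lamin B1 DamID log2 ratios.
#' @param params a [lad_params()].
#' @return A [domain_set()] of LADs (label `"LAD"`).
#' @export
call_lads <- function(damid, params = lad_params()) {
  stopifnot(inherits(damid, "BinnedTrack"), inherits(params, "LadParams"))
  if (all(is.na(unlist(damid$values)))) stop("all-masked DamID track")
  sm <- moving_average(damid, params$smooth_window_bp)
  segment_domains(sm, params$call_threshold,
                  min_domain_bp = params$min_lad_bp,
                  merge_gap_bp = params$merge_gap_bp, label = "LAD")
}

#' Classify LAD switching between two conditions
#'
#' Base-pair-level set logic between condition-a and condition-b LAD calls:
#' `stable-LAD` = a and b; `loss` = a only (LAD to iLAD); `gain` = b only
#' (iLAD to LAD); `stable-iLAD` = neither. The four labels tile the genome.
#'
#' @param lads_a,lads_b [domain_set()]s on the same layout.
#' @return A [domain_set()] of class `LadSwitch` with the four labels.
#' @export
classify_switches <- function(lads_a, lads_b) {
  stopifnot(inherits(lads_a, "DomainSet"), inherits(lads_b, "DomainSet"))
  layout <- domain_layout(lads_a)
  if (!same_genome(layout, domain_layout(lads_b)))
    stop("LAD sets are on different genomes")
  genome <- genome_domains(layout)
  out <- domains_rbind(
    domains_intersect(lads_a, lads_b, "stable-LAD"),
    domains_setdiff(lads_a, lads_b, "loss"),
    domains_setdiff(lads_b, lads_a, "gain"),
    domains_setdiff(domains_setdiff(genome, lads_a), lads_b, "stable-iLAD"))
  class(out) <- c("LadSwitch", class(out))
  out
}

#' Expression changes of genes in LAD-switch classes
#'
#' Genes are assigned to switch classes by TSS position. Loss-class genes are
#' compared against stable-LAD genes and gain-class genes against
#' stable-iLAD genes with two-sided Wilcoxon rank-sum tests on log2 fold
#' change. When every value in a comparison is identical (fully tied), the
#' p-value is reported as 1.
#'
#' @param switch a `LadSwitch` from [classify_switches()].
#' @param genes a `GeneTable` (see [make_gene_table()]).
#' @param strict error when a class holds fewer than 2 genes (default);
#'   with `strict = FALSE` the affected comparison reports `NA` instead
#'   (useful in pipelines where a condition may have produced no switches of
#'   one kind).
#' @return A list with `distributions` (named list of log2fc vectors per
#'   class), `p_loss_vs_stable_lad`, `p_gain_vs_stable_ilad`, and `n` per
#'   class.
#' @export
switch_expression_association <- function(switch, genes, strict = TRUE) {
  stopifnot(inherits(switch, "DomainSet"), inherits(genes, "GeneTable"))
  cls <- locate_label(switch, genes$chrom, genes$tss)
  classes <- c("stable-LAD", "stable-iLAD", "loss", "gain")
  dist <- lapply(stats::setNames(classes, classes),
                 function(cl) genes$log2fc[!is.na(cls) & cls == cl])
  n <- vapply(dist, length, 0L)
  short <- classes[n < 2]
  if (length(short) && strict)
    stop("class with fewer than 2 genes: ", paste(short, collapse = ", "))
  p_of <- function(a, b) if (length(dist[[a]]) < 2 || length(dist[[b]]) < 2)
    NA_real_ else safe_wilcox(dist[[a]], dist[[b]])
  list(distributions = dist,
       p_loss_vs_stable_lad = p_of("loss", "stable-LAD"),
       p_gain_vs_stable_ilad = p_of("gain", "stable-iLAD"),
       n = n)
}

## two-sided rank-sum robust to full ties (p = 1 when all values identical)
safe_wilcox <- function(x, y) {
  if (length(unique(c(x, y))) == 1L) return(1)
  suppressWarnings(stats::wilcox.test(x, y, exact = FALSE)$p.value)
}
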