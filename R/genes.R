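#' Build a gene table with TSS and differential-expression flags
#'
#' The TSS is the annotated start for `+`-strand genes and the annotated end
#' for `-`-strand genes (0-based). The DE flag applies the standard
#' thresholds: up = `log2fc > lfc_cut` and `padj < padj_cut`; down
#' symmetric; everything else unchanged.
#'
#' @param df data frame with columns `id`, `chrom`, `start`, `end`,
#'   `strand`, `base_mean`, `log2fc`, `padj` (extra columns are kept).
#' @param layout a [genome_layout()]; genes must lie inside it.
#' @param lfc_cut absolute log2 fold-change threshold (default 1).
#' @param padj_cut adjusted-p threshold (default 0.05).
#' @return A data frame of class `GeneTable` with added `tss` and `de_flag`
#'   columns and the layout as an attribute.
#' @export
make_gene_table <- function(df, layout, lfc_cut = 1, padj_cut = 0.05) {
  stopifnot(inherits(layout, "GenomeLayout"))
  need <- c("id", "chrom", "start", "end", "strand", "base_mean", "log2fc", "padj")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("gene table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$id)) stop("duplicate gene ids")
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  bad <- !df$chrom %in% layout$chroms
  if (any(bad)) stop("unknown chromosome: ", paste(unique(df$chrom[bad]), collapse = ", "))
  if (any(df$base_mean < 0)) stop("base_mean must be non-negative")
  df$tss <- ifelse(df$strand == "+", df$start, df$end)
  out_of_range <- df$tss < 0 | df$tss >= layout$lengths[df$chrom]
  if (any(out_of_range))
    stop("TSS outside chromosome for gene(s): ",
         paste(utils::head(df$id[out_of_range], 3), collapse = ", "))
  sig <- !is.na(df$padj) & df$padj < padj_cut
  df$de_flag <- ifelse(sig & df$log2fc > lfc_cut, "up",
                       ifelse(sig & df$log2fc < -lfc_cut, "down", "unchanged"))
  structure(df, layout = layout, class = c("GeneTable", "data.frame"))
}

#' Filter to expressed genes
#'
#' Removes genes whose expression baseline (`base_mean`) is below the cutoff;
#' genes exactly at the cutoff are kept.
#'
#' @param genes a `GeneTable`.
#' @param base_mean_min expression cutoff (default 10.30).
#' @return The filtered `GeneTable`.
#' @export
filter_expressed <- function(genes, base_mean_min = 10.30) {
  stopifnot(inherits(genes, "GeneTable"))
  out <- genes[genes$base_mean >= base_mean_min, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Promoter-level chromatin feature changes per gene
#'
#' For each gene and assay, the mean unmasked signal in a window centered on
#' the TSS is computed per condition and combined per the assay's
#' convention: `"log2ratio"` gives `log2((treated + pc) / (control + pc))`
#' (ChIP, ATAC) and `"difference"` gives `treated - control` (PC1, DamID).
#' Genes with a missing value in any column are dropped (count in attribute
#' `n_dropped`).
#'
#' @param genes a `GeneTable` (typically after [filter_expressed()]).
#' @param assays named list; each element is
#'   `list(control = track, treated = track, combine = "log2ratio"|"difference")`.
#' @param promoter_window_bp TSS-centered window width (default 5000, i.e.
#'   +/- 2.5 kb).
#' @param pseudocount pseudocount for log2 ratios (default 1).
#' @return A numeric matrix (class `GeneFeatureMatrix`) with one row per
#'   retained gene (rownames = gene ids) and one `d_<assay>` column per
#'   assay.
#' @export
promoter_features <- function(genes, assays, promoter_window_bp = 5000,
                              pseudocount = 1) {
  stopifnot(inherits(genes, "GeneTable"), is.list(assays), length(assays) > 0)
  half <- promoter_window_bp / 2
  feat <- sapply(names(assays), function(a) {
    spec <- assays[[a]]
    combine <- match.arg(spec$combine, c("log2ratio", "difference"))
    vapply(seq_len(nrow(genes)), function(i) {
      ctl <- region_mean(spec$control, genes$chrom[i],
                         genes$tss[i] - half, genes$tss[i] + half)
      trt <- region_mean(spec$treated, genes$chrom[i],
                         genes$tss[i] - half, genes$tss[i] + half)
      if (is.na(ctl) || is.na(trt)) return(NA_real_)
      if (combine == "log2ratio")
        log2((trt + pseudocount) / (ctl + pseudocount))
      else trt - ctl
    }, 0)
  })
  feat <- matrix(feat, nrow = nrow(genes),
                 dimnames = list(genes$id, paste0("d_", names(assays))))
  keep <- stats::complete.cases(feat)
  out <- feat[keep, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!keep)
  class(out) <- c("GeneFeatureMatrix", class(out))
  out
}

#' K-means clustering of gene-centric feature changes
#'
#' Columns are z-scored before clustering (mixed units: log2 ratios and
#' differences); Lloyd's algorithm with `n_init` seeded restarts keeps the
#' result deterministic given the seed. Clusters are relabeled in canonical
#' order (descending mean of the `relabel_by` column, by default `d_pc1`
#' when present) so cluster identities are stable across runs.
#'
#' @param features a matrix from [promoter_features()].
#' @param k number of clusters (default 4).
#' @param seed RNG seed (default 1234).
#' @param n_init number of random restarts (default 20).
#' @param relabel_by column used for canonical ordering; default `d_pc1` if
#'   present else the first column.
#' @return A list of class `ClusterResult`: `assignment` (named integer
#'   vector), `centers` (cluster means in original units), `centers_z`,
#'   `sizes`, `k`, `seed`, `tot_withinss`.
#' @export
kmeans_clusters <- function(features, k = 4, seed = 1234, n_init = 20,
                            relabel_by = NULL) {
  stopifnot(is.matrix(features), nrow(features) >= 1)
  if (k > nrow(features)) stop("k exceeds the number of genes")
  sds <- apply(features, 2, stats::sd)
  sds[sds == 0 | is.na(sds)] <- 1
  z <- scale(features, center = colMeans(features), scale = sds)
  set.seed(seed)
  km <- suppressWarnings(stats::kmeans(z, centers = k, nstart = n_init,
                                       iter.max = 100, algorithm = "Lloyd"))
  if (is.null(relabel_by))
    relabel_by <- if ("d_pc1" %in% colnames(features)) "d_pc1" else colnames(features)[1]
  centers_raw <- apply(features, 2, function(col) tapply(col, km$cluster, mean))
  if (k == 1) centers_raw <- matrix(centers_raw, nrow = 1,
                                    dimnames = list("1", colnames(features)))
  ord <- order(-centers_raw[, relabel_by])
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  assignment <- stats::setNames(relabel[km$cluster], rownames(features))
  centers <- centers_raw[ord, , drop = FALSE]
  rownames(centers) <- seq_len(k)
  structure(list(assignment = assignment, centers = centers,
                 centers_z = km$centers[ord, , drop = FALSE],
                 sizes = as.integer(table(factor(assignment, levels = seq_len(k)))),
                 k = k, seed = seed, tot_withinss = km$tot.withinss),
            class = "ClusterResult")
}

#' Expression-change test per cluster
#'
#' Two-sided Wilcoxon rank-sum of each cluster's log2 fold changes against
#' all other clustered genes.
#'
#' @param clusters a `ClusterResult`.
#' @param genes a `GeneTable` containing the clustered gene ids.
#' @return Data frame with one row per cluster: `cluster`, `n`,
#'   `median_log2fc`, `p_value`.
#' @export
cluster_expression_test <- function(clusters, genes) {
  stopifnot(inherits(clusters, "ClusterResult"), inherits(genes, "GeneTable"))
  lfc <- stats::setNames(genes$log2fc, genes$id)[names(clusters$assignment)]
  if (anyNA(lfc)) stop("clustered genes missing from the gene table")
  do.call(rbind, lapply(seq_len(clusters$k), function(cl) {
    inx <- clusters$assignment == cl
    data.frame(cluster = cl, n = sum(inx),
               median_log2fc = stats::median(lfc[inx]),
               p_value = safe_wilcox(lfc[inx], lfc[!inx]))
  }))
}

#' Genome-section composition of each cluster
#'
#' Assigns each clustered gene to the section containing its TSS and returns
#' per-cluster fractions over the section labels (rows sum to 1; genes whose
#' TSS falls outside every section are dropped).
#'
#' @param clusters a `ClusterResult`.
#' @param genes a `GeneTable`.
#' @param sections a [domain_set()] (e.g. from [build_sections()]).
#' @return Matrix of fractions, clusters x section labels.
#' @export
cluster_section_proportions <- function(clusters, genes, sections) {
  stopifnot(inherits(clusters, "ClusterResult"), inherits(genes, "GeneTable"),
            inherits(sections, "DomainSet"))
  idx <- match(names(clusters$assignment), genes$id)
  sec <- locate_label(sections, genes$chrom[idx], genes$tss[idx])
  labs <- sort(unique(sections$label))
  ok <- !is.na(sec)
  tab <- table(factor(clusters$assignment[ok], levels = seq_len(clusters$k)),
               factor(sec[ok], levels = labs))
  prop <- prop.table(tab, margin = 1)
  out <- matrix(as.numeric(prop), nrow = clusters$k,
                dimnames = list(seq_len(clusters$k), labs))
  out
}

#' Differential-expression summary
#'
#' @param genes a `GeneTable`.
#' @return A list: `counts` (up/down/unchanged), `pct_up`, `pct_down`
#'   (percentages of changed genes; `NA` when nothing changed).
#' @export
de_summary <- function(genes) {
  stopifnot(inherits(genes, "GeneTable"))
  counts <- table(factor(genes$de_flag, levels = c("up", "down", "unchanged")))
  changed <- counts[["up"]] + counts[["down"]]
  list(counts = c(up = counts[["up"]], down = counts[["down"]],
                  unchanged = counts[["unchanged"]]),
       pct_up = if (changed > 0) 100 * counts[["up"]] / changed else NA_real_,
       pct_down = if (changed > 0) 100 * counts[["down"]] / changed else NA_real_)
}

#' Gene-density track (TSS counts per bin)
#'
#' @param genes a `GeneTable`.
#' @param layout the target [genome_layout()] (e.g. the Hi-C layout).
#' @return A [binned_track()] of TSS counts.
#' @export
gene_density_track <- function(genes, layout) {
  stopifnot(inherits(genes, "GeneTable"), inherits(layout, "GenomeLayout"))
  vals <- lapply(layout$chroms, function(chrom) {
    n <- n_bins(layout, chrom)[[1]]
    tss <- genes$tss[genes$chrom == chrom]
    counts <- tabulate(floor(tss / layout$bin_bp) + 1L, nbins = n)
    as.numeric(counts)
  })
  names(vals) <- layout$chroms
  binned_track(layout, vals)
}
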