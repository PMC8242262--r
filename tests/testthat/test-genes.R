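make_genes <- function(layout, n = 10, tss = NULL, strand = "+",
                       base_mean = 100, log2fc = 0, padj = 1) {
  if (is.null(tss)) tss <- seq(5000, by = 10000, length.out = n)
  df <- data.frame(id = sprintf("g%03d", seq_len(n)), chrom = layout$chroms[1],
                   start = tss, end = tss + 2000,
                   strand = rep_len(strand, n),
                   base_mean = rep_len(base_mean, n),
                   log2fc = rep_len(log2fc, n), padj = rep_len(padj, n))
  df$start <- ifelse(df$strand == "+", tss, tss - 2000)
  df$end <- ifelse(df$strand == "+", tss + 2000, tss)
  make_gene_table(df, layout)
}

test_that("expression filter keeps the boundary value", {
  layout <- tiny_layout(2e5, 1000)
  g <- make_genes(layout, 10, base_mean = c(10.30, 0, 10.29, 10.31, 50, 5,
                                            11, 9, 10.3, 100))
  kept <- filter_expressed(g)
  expect_equal(nrow(kept), 6)
  expect_true(all(kept$base_mean >= 10.30))
  expect_true("g001" %in% kept$id)  # exactly 10.30 is kept
})

test_that("promoter features follow window, strand and column conventions", {
  layout <- genome_layout(c(chr1 = 1e5), 1000)
  g <- make_genes(layout, 3, tss = c(10000, 50000, 90000),
                  strand = c("+", "-", "+"))
  # minus-strand gene: TSS is the annotated end coordinate
  expect_equal(g$tss[2], g$end[2])

  same <- binned_track(layout, 2)
  feats <- promoter_features(g, list(
    chip = list(control = same, treated = same, combine = "log2ratio"),
    pc1 = list(control = same, treated = same, combine = "difference")))
  expect_equal(unname(feats[, "d_chip"]), rep(0, 3))
  expect_equal(unname(feats[, "d_pc1"]), rep(0, 3))

  # planted promoter doubling: log2 ratio with vanishing pseudocount is 1
  ctl <- binned_track(layout, 1)
  trt_v <- rep(1, 100)
  trt_v[48:53] <- 2  # covers gene 2's promoter (TSS 50000 +/- 2.5 kb)
  trt <- binned_track(layout, list(chr1 = trt_v))
  f2 <- promoter_features(g, list(atac = list(control = ctl, treated = trt,
                                              combine = "log2ratio")),
                          pseudocount = 1e-9)
  expect_equal(unname(f2[2, "d_atac"]), 1, tolerance = 1e-6)
  expect_equal(unname(f2[1, "d_atac"]), 0, tolerance = 1e-6)

  # brute-force window scan oracle (difference convention)
  set.seed(5)
  v <- rnorm(100)
  noisy <- binned_track(layout, list(chr1 = v))
  f3 <- promoter_features(g, list(x = list(control = ctl, treated = noisy,
                                           combine = "difference")))
  for (i in 1:3) {
    bins <- (floor((g$tss[i] - 2500) / 1000)):(floor((g$tss[i] + 2500 - 1) / 1000))
    w <- pmin((bins + 1) * 1000, g$tss[i] + 2500) - pmax(bins * 1000, g$tss[i] - 2500)
    expect_equal(unname(f3[i, "d_x"]),
                 sum(v[bins + 1] * w) / sum(w) - 1, tolerance = 1e-12)
  }
})

test_that("k-means recovers planted blobs deterministically", {
  skip_if_not_installed("mclust")
  set.seed(99)
  centers <- rbind(c(0, 0, 0, 0), c(3, 0, 0, 0), c(0, 3, 0, 0), c(3, 3, 3, 0))
  truth_lab <- rep(1:4, each = 50)
  x <- centers[truth_lab, ] + matrix(rnorm(200 * 4, 0, 0.1), 200, 4)
  colnames(x) <- c("d_chip", "d_pc1", "d_damid", "d_atac")
  rownames(x) <- sprintf("g%03d", 1:200)
  res <- kmeans_clusters(x, k = 4, seed = 7)
  expect_gte(mclust::adjustedRandIndex(res$assignment, truth_lab), 0.99)

  # bit-for-bit reproducibility given (seed, n_init)
  res2 <- kmeans_clusters(x, k = 4, seed = 7)
  expect_identical(res$assignment, res2$assignment)
  expect_identical(res$centers, res2$centers)

  # canonical labels ordered by descending mean d_pc1
  expect_true(all(diff(res$centers[, "d_pc1"]) <= 0))

  # duplicating every row leaves centroids unchanged
  xx <- rbind(x, x)
  rownames(xx) <- sprintf("g%03d", 1:400)
  res_dup <- kmeans_clusters(xx, k = 4, seed = 7)
  expect_equal(sort(res_dup$centers[, "d_chip"]), sort(res$centers[, "d_chip"]),
               tolerance = 1e-6)

  # k = 1: single cluster at the column means
  res1 <- kmeans_clusters(x, k = 1, seed = 7)
  expect_equal(unname(res1$centers[1, ]), unname(colMeans(x)))
  expect_error(kmeans_clusters(x[1:3, ], k = 4), "exceeds")

  # standardization makes clustering invariant to per-column rescaling
  y <- x
  y[, 1] <- y[, 1] * 50 + 7
  res_y <- kmeans_clusters(y, k = 4, seed = 7)
  expect_gte(mclust::adjustedRandIndex(res$assignment, res_y$assignment), 0.999)
})

test_that("cluster expression tests flag shifted clusters", {
  layout <- tiny_layout(1e7, 1000)
  n <- 400
  tss <- seq(5000, by = 20000, length.out = n)
  set.seed(17)
  lab <- rep(1:4, each = 100)
  hits <- 0
  for (s in 1:20) {
    lfc <- rnorm(n, 0, 0.5) + ifelse(lab == 2, 1, 0)
    df <- data.frame(id = sprintf("g%03d", 1:n), chrom = "chr1", start = tss,
                     end = tss + 1000, strand = "+", base_mean = 100,
                     log2fc = lfc, padj = 1)
    genes <- make_gene_table(df, layout)
    clus <- structure(list(assignment = setNames(lab, genes$id), k = 4),
                      class = "ClusterResult")
    res <- cluster_expression_test(clus, genes)
    if (res$p_value[res$cluster == 2] < 1e-6) hits <- hits + 1
  }
  expect_gte(hits, 19)

  # identical fold changes: every p-value is 1
  df0 <- data.frame(id = sprintf("g%03d", 1:n), chrom = "chr1", start = tss,
                    end = tss + 1000, strand = "+", base_mean = 100,
                    log2fc = 0.2, padj = 1)
  genes0 <- make_gene_table(df0, layout)
  clus <- structure(list(assignment = setNames(lab, genes0$id), k = 4),
                    class = "ClusterResult")
  expect_equal(cluster_expression_test(clus, genes0)$p_value, rep(1, 4))
})

test_that("cluster section proportions are TSS-based and sum to one", {
  layout <- tiny_layout(1e5, 1000)
  sections <- domain_set("chr1", c(0, 50000), c(50000, 1e5),
                         c("GSRs/iLADs", "non-GSRs/LADs"), layout)
  g <- make_genes(layout, 8, tss = c(1e4, 2e4, 3e4, 4e4, 6e4, 7e4, 8e4, 9e4))
  clus <- structure(list(assignment = setNames(c(1, 1, 1, 1, 2, 2, 2, 1), g$id),
                         k = 2), class = "ClusterResult")
  prop <- cluster_section_proportions(clus, g, sections)
  expect_equal(rowSums(prop), c(`1` = 1, `2` = 1), tolerance = 1e-12)
  expect_equal(prop["1", "GSRs/iLADs"], 0.8)
  expect_equal(prop["2", "non-GSRs/LADs"], 1.0)
})

test_that("DE summaries report percentages of changed genes", {
  layout <- tiny_layout(1e7, 1000)
  n <- 1000
  tss <- seq(5000, by = 5000, length.out = n)
  lfc <- c(rep(2, 484), rep(-2, 226), rep(0, n - 710))
  padj <- c(rep(0.001, 710), rep(0.9, n - 710))
  df <- data.frame(id = sprintf("g%04d", 1:n), chrom = "chr1", start = tss,
                   end = tss + 1000, strand = "+", base_mean = 100,
                   log2fc = lfc, padj = padj)
  g <- make_gene_table(df, layout)
  s <- de_summary(g)
  expect_equal(unname(s$counts[c("up", "down")]), c(484, 226))
  expect_equal(s$pct_up, 100 * 484 / 710, tolerance = 1e-12)
  expect_equal(s$pct_down, 100 * 226 / 710, tolerance = 1e-12)

  g_none <- make_gene_table(transform(df, padj = 0.9), layout)
  expect_true(is.na(de_summary(g_none)$pct_up))
  g_all_up <- make_gene_table(transform(df, log2fc = 2, padj = 0.001), layout)
  expect_equal(de_summary(g_all_up)$pct_up, 100)
})
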