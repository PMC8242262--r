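test_that("difference track is control minus treated (loss positive)", {
  layout <- tiny_layout(5000, 1000)
  ctl <- track_from(layout, chr1 = c(3, 3, 3, 3, 3))
  expect_equal(track_values(difference_track(ctl, ctl)), rep(0, 5))
  trt <- track_map(ctl, function(x) x - 2)
  expect_equal(track_values(difference_track(trt, ctl)), rep(2, 5))
})

test_that("windowed t-statistic matches a per-bin loop oracle", {
  layout <- genome_layout(c(chr1 = 50000), 1000)
  set.seed(7)
  x <- rnorm(50)
  tr <- track_from(layout, chr1 = x)
  for (k_bp in c(4000, 5000, 11000)) {
    got <- t_statistic_track(tr, k_bp)$values$chr1
    expect_equal(got, oracle_t_track(x, k_bp / 1000), tolerance = 1e-12)
  }

  # hand case: window holding (1, 1, 1, 3) -> m = 1.5, s = 1, t = 3
  h <- track_from(tiny_layout(4000, 1000), chr1 = c(1, 1, 1, 3))
  t4 <- t_statistic_track(h, 4000)$values$chr1
  expect_equal(t4[3], 1.5 / (1 / sqrt(4)))

  # zero-variance windows: flat nonzero -> +Inf; flat zero -> masked
  flat <- track_from(tiny_layout(6000, 1000), chr1 = rep(2, 6))
  expect_true(all(t_statistic_track(flat, 3000)$values$chr1 == Inf))
  zero <- track_from(tiny_layout(6000, 1000), chr1 = rep(0, 6))
  expect_true(all(is.na(t_statistic_track(zero, 3000)$values$chr1)))

  # oddness: t(-d) = -t(d)
  neg <- t_statistic_track(track_map(tr, function(v) -v), 5000)$values$chr1
  pos <- t_statistic_track(tr, 5000)$values$chr1
  expect_equal(neg, -pos)

  expect_error(t_statistic_track(binned_track(layout), 5000), "all-masked")
})

test_that("mirrored-null FDR threshold follows tail-count arithmetic", {
  layout <- genome_layout(c(chr1 = 1000 * 1000), 1000)
  # planted tails: 100 bins at +10, 1 bin at -10, remainder inside (-1, 1)
  v <- seq(-0.99, 0.99, length.out = 899)
  v <- c(v, rep(10, 100), -10)
  tr <- track_from(layout, chr1 = v)
  res <- mirrored_null_threshold(tr, fdr_level = 0.05)
  expect_lte(res$threshold, 10)
  expect_lt(res$fdr, 0.05)
  at10 <- which.min(abs(res$curve$cutoff - 10))
  expect_equal(res$curve$fdr[at10], 1 / 100)
  # grid minimality: one step below the threshold the FDR is >= the level
  ix <- which(res$curve$cutoff == res$threshold)
  if (ix > 1) expect_gte(res$curve$fdr[ix - 1], 0.05)

  # exactly mirrored distribution: target unreachable
  set.seed(2)
  v2 <- rnorm(500)
  sym <- track_from(layout, chr1 = c(v2, -v2))
  err <- tryCatch(mirrored_null_threshold(sym, 0.01), error = identity)
  expect_s3_class(err, "gsrkit_fdr_unreachable")
  expect_match(conditionMessage(err), "minimum achievable")
})

test_that("segmentation merges before filtering and matches a bp oracle", {
  layout <- genome_layout(c(chr1 = 200000), 1000)
  v <- rep(0, 200)
  tr0 <- track_from(layout, chr1 = v)
  expect_equal(nrow(segment_domains(tr0, 1)), 0)

  # 30 kb + 5 kb gap + 30 kb -> merged 65-kb domain survives the 50-kb filter
  v <- rep(0, 200); v[11:40] <- 10; v[46:75] <- 10
  got <- segment_domains(track_from(layout, chr1 = v), 1)
  expect_equal(nrow(got), 1)
  expect_equal(c(got$start, got$end), c(10000, 75000))

  # boundary of "no less than 50 kb"
  v <- rep(0, 200); v[1:49] <- 10
  expect_equal(nrow(segment_domains(track_from(layout, chr1 = v), 1)), 0)
  v <- rep(0, 200); v[1:50] <- 10
  expect_equal(nrow(segment_domains(track_from(layout, chr1 = v), 1)), 1)

  # random tracks against the bitmap oracle (small scale)
  small <- genome_layout(c(chr1 = 50000), 1000)
  set.seed(11)
  for (i in 1:10) {
    x <- rnorm(50, sd = 3)
    got <- segment_domains(track_from(small, chr1 = x), 2,
                           min_domain_bp = 5000, merge_gap_bp = 3000)
    want <- oracle_segments(x, 2, 1000, 50000, 5000, 3000)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(cbind(got$start, got$end), unname(want))
    }
  }

  # raising the threshold never enlarges the selected region
  x <- rnorm(200, sd = 3)
  lo <- segment_domains(track_from(layout, chr1 = x), 1, 1000, 1)
  hi <- segment_domains(track_from(layout, chr1 = x), 2, 1000, 1)
  if (nrow(hi) > 0 && nrow(lo) > 0)
    expect_equal(overlap_fraction(hi, lo), 1)
})

test_that("full GSR calling recovers planted domains and is antisymmetric", {
  truth <- simulate_multiomics(sim_config(seed = 5, chrom_len_bp = 6e6))
  call <- call_gsrs(truth$chip_control, truth$chip_treated, truth$lads)
  expect_gte(jaccard_domains(call$gsr_domains, truth$gsrs), 0.9)
  sec_cov <- vapply(unique(call$sections$label), function(lb)
    genome_coverage(domains_with_label(call$sections, lb)), 0)
  expect_equal(sum(sec_cov), 1, tolerance = 1e-9)

  # identical conditions: zero domains, sections reduce to the LAD/iLAD split
  same <- suppressWarnings(
    call_gsrs(truth$chip_control, truth$chip_control, truth$lads))
  expect_equal(nrow(same$gsr_domains), 0)
  expect_setequal(unique(same$sections$label),
                  c("non-GSRs/LADs", "non-GSRs/iLADs"))

  # swapping conditions puts the signal on the opposite tail only
  fixed <- gsr_params(fixed_threshold = 8)
  fwd <- call_gsrs(truth$chip_control, truth$chip_treated, truth$lads, fixed)
  swp <- call_gsrs(truth$chip_treated, truth$chip_control, truth$lads, fixed)
  expect_gt(nrow(fwd$gsr_domains), 0)
  expect_equal(nrow(swp$gsr_domains), 0)
  neg_t <- track_map(swp$t_track, function(x) -x)
  expect_equal(track_values(neg_t), track_values(fwd$t_track))
})

test_that("domain-level difference summaries recover the erasure depth", {
  truth <- simulate_multiomics(sim_config(seed = 6, chrom_len_bp = 6e6))
  d <- difference_track(truth$chip_treated, truth$chip_control)
  st <- domain_level_stats(d, truth$gsrs)
  delta <- truth$config$erasure_depth
  expect_equal(st$median[st$class == "GSR"], delta, tolerance = 0.1)
  expect_equal(st$median[st$class == "non-GSR"], 0, tolerance = 0.1)
  layout <- d$layout
  expect_error(domain_level_stats(d, domain_set(layout = layout, label = character(0))),
               "empty GSR")
  expect_error(domain_level_stats(d, genome_domains(layout)), "outside")
})
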