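test_that("observed/expected normalizes distance decay exactly", {
  # every diagonal constant -> O/E all 1
  n <- 10
  d <- abs(outer(1:n, 1:n, `-`))
  m <- single_chrom_cm(100 / (d + 1))
  oe <- observed_over_expected(m)
  expect_equal(unname(oe$matrices$chr1), matrix(1, n, n), tolerance = 1e-12)

  # scale invariance
  m2 <- single_chrom_cm(2 * (100 / (d + 1)))
  expect_equal(observed_over_expected(m2)$matrices$chr1, oe$matrices$chr1,
               tolerance = 1e-12)

  # 6x6 with hand-set diagonals
  vals <- c(8, 4, 2, 1, 0.5, 0.25)
  mat <- matrix(0, 6, 6)
  for (i in 1:6) for (j in 1:6) mat[i, j] <- vals[abs(i - j) + 1]
  mat[1, 2] <- mat[2, 1] <- 6  # perturb one entry
  cm <- single_chrom_cm(mat)
  oe2 <- observed_over_expected(cm)$matrices$chr1
  exp_d1 <- mean(c(6, rep(4, 4)))
  expect_equal(oe2[1, 2], 6 / exp_d1)
  expect_equal(oe2[3, 4], 4 / exp_d1)
  expect_equal(oe2[1, 4], 1)

  # idempotence: O/E of an O/E matrix is itself
  r <- single_chrom_cm(random_oe_matrix(30, seed = 3))
  once <- observed_over_expected(r)
  twice <- observed_over_expected(once)
  expect_equal(twice$matrices$chr1, once$matrices$chr1, tolerance = 1e-9)
})

test_that("compartment PC1 recovers planted structure and obeys orientation", {
  # permutation-symmetric two-block matrix: equal |pc1| within a block
  n <- 12
  blk <- rep(c(TRUE, FALSE), each = 6)
  mat <- ifelse(outer(blk, blk, `==`), 2, 0.5)
  diag(mat) <- 2
  cm <- single_chrom_cm(mat, flag = "oe")
  gd <- binned_track(cm$layout, list(chr1 = as.numeric(blk)))
  call <- compartment_pc1(cm, gd)
  pc <- call$pc1$values$chr1
  expect_equal(stats::sd(abs(pc)), 0, tolerance = 1e-8)
  expect_true(all(pc[blk] > 0) && all(pc[!blk] < 0))
  expect_setequal(unique(call$ab$label), c("A", "B"))

  # flipping the gene-density track flips every sign
  flipped <- compartment_pc1(cm, track_map(gd, function(x) -x))
  expect_equal(flipped$pc1$values$chr1, -pc)

  # planted checkerboard: >= 95% of bins labeled correctly
  layout_hic <- genome_layout(c(chr1 = 1e7), 40000)
  comps <- alt_compartments(layout_hic, 1e6)
  cfg <- sim_config(seed = 9, chrom_len_bp = 1e7, n_chroms = 1)
  hm <- simulate_hic(layout_hic, comps, 1.5, cfg, seed = 99)
  gd2 <- domains_indicator(domains_with_label(comps, "A"), layout_hic)
  cc <- compartment_pc1(hm, gd2)
  truth_a <- track_values(gd2) > 0
  called_a <- track_values(cc$pc1) > 0
  ok <- !is.na(track_values(cc$pc1))
  expect_gte(mean(truth_a[ok] == called_a[ok]), 0.95)
})

test_that("saddle means equal a brute-force pair loop", {
  # uniform O/E -> all cells 1; saddle difference with itself -> 0
  uni <- single_chrom_cm(matrix(1, 20, 20), flag = "oe")
  pc <- binned_track(uni$layout, list(chr1 = seq(-1, 1, length.out = 20)))
  sad <- saddle(uni, pc, n_quantiles = 4)
  expect_equal(sad$mean, matrix(1, 4, 4))
  expect_equal(saddle_difference(sad, sad), matrix(0, 4, 4))

  # random 8-bin matrix vs explicit double loop, 2 quantiles
  mat <- random_oe_matrix(8, seed = 5)
  cm <- single_chrom_cm(mat, flag = "oe")
  pcv <- c(0.3, -0.2, 0.8, -0.9, 0.1, -0.4, 0.6, -0.1)
  pc2 <- binned_track(cm$layout, list(chr1 = pcv))
  sad2 <- saddle(cm, pc2, n_quantiles = 2, min_sep = 2)
  grp <- ceiling(rank(pcv, ties.method = "first") * 2 / 8)
  sums <- matrix(0, 2, 2); cnt <- matrix(0, 2, 2)
  for (i in 1:8) for (j in 1:8) {
    if (abs(i - j) < 2) next
    sums[grp[i], grp[j]] <- sums[grp[i], grp[j]] + mat[i, j]
    cnt[grp[i], grp[j]] <- cnt[grp[i], grp[j]] + 1
  }
  expect_equal(sad2$mean, sums / cnt, tolerance = 1e-9)
  expect_equal(sad2$mean, t(sad2$mean), tolerance = 1e-9)
})

test_that("compartmentalization strength matches construction arithmetic", {
  # uniform O/E -> strength exactly 1
  uni <- single_chrom_cm(matrix(1, 20, 20), flag = "oe")
  pc <- binned_track(uni$layout, list(chr1 = seq(-1, 1, length.out = 20)))
  expect_equal(unname(compartmentalization_strength(uni, pc)), 1)

  # checkerboard with within-block O/E 2, between-block 0.5 -> 2 / 0.5 = 4
  n <- 20
  blk <- rep(c(TRUE, FALSE), each = 10)
  mat <- ifelse(outer(blk, blk, `==`), 2, 0.5)
  cm <- single_chrom_cm(mat, flag = "oe")
  pcb <- binned_track(cm$layout, list(chr1 = ifelse(blk, 1, -1) * seq(2, 0.1, length.out = n)))
  expect_equal(unname(compartmentalization_strength(cm, pcb)), 4)

  # brute-force oracle on a random matrix
  mat <- random_oe_matrix(60, seed = 8)
  cm <- single_chrom_cm(mat, flag = "oe")
  set.seed(8)
  pcv <- rnorm(60)
  pcr <- binned_track(cm$layout, list(chr1 = pcv))
  got <- unname(compartmentalization_strength(cm, pcr, top_frac = 0.2, min_sep = 2))
  k <- floor(0.2 * 60)
  sa <- order(-pcv)[1:k]; sb <- order(pcv)[1:k]
  aa <- c(); bb <- c(); ab <- c()
  for (i in sa) for (j in sa) if (i < j && abs(i - j) >= 2) aa <- c(aa, mat[i, j])
  for (i in sb) for (j in sb) if (i < j && abs(i - j) >= 2) bb <- c(bb, mat[i, j])
  for (i in sa) for (j in sb) if (abs(i - j) >= 2) ab <- c(ab, mat[i, j])
  expect_equal(got, median(c(aa, bb)) / median(ab), tolerance = 1e-9)

  # invariance under global scaling of raw counts
  d <- abs(outer(1:60, 1:60, `-`))
  raw <- single_chrom_cm(round(1000 / (d + 1) * mat))
  s1 <- compartmentalization_strength(observed_over_expected(raw), pcr)
  raw2 <- single_chrom_cm(3 * round(1000 / (d + 1) * mat))
  s2 <- compartmentalization_strength(observed_over_expected(raw2), pcr)
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("interaction scores equal a double-loop oracle and detect enrichment", {
  layout <- genome_layout(c(chr1 = 1e5), 1000)
  sections <- domain_set("chr1", c(0, 30000, 60000), c(30000, 60000, 1e5),
                         c("s1", "s2", "s1"), layout)
  # uniform O/E -> CS = 1 everywhere
  uni <- single_chrom_cm(matrix(1, 100, 100), flag = "oe")
  cs <- interaction_score(uni, sections)
  expect_equal(unique(stats::na.omit(track_values(cs$s1))), 1)
  expect_equal(unique(stats::na.omit(track_values(cs$s2))), 1)

  # oracle equivalence on a random 100-bin matrix
  mat <- random_oe_matrix(100, seed = 13)
  cm <- single_chrom_cm(mat, flag = "oe")
  cs2 <- interaction_score(cm, sections, min_sep = 2)
  lab <- rep("s1", 100); lab[31:60] <- "s2"
  for (b in c(1, 31, 45, 61, 100)) {
    others <- which(abs(seq_len(100) - b) >= 2)
    same <- others[lab[others] == lab[b]]
    want <- mean(mat[b, same]) / mean(mat[b, others])
    expect_equal(cs2[[lab[b]]]$values$chr1[b], want, tolerance = 1e-9)
  }

  # raising within-section contacts raises that section's median CS
  meds <- vapply(c(1, 1.5, 2.5), function(f) {
    m <- mat
    idx <- which(lab == "s2")
    m[idx, idx] <- m[idx, idx] * f
    median(track_values(interaction_score(single_chrom_cm(m, flag = "oe"),
                                          sections)$s2), na.rm = TRUE)
  }, 0)
  expect_true(all(diff(meds) > 0))
})

test_that("insulation profiles and boundaries match window arithmetic", {
  # uniform matrix -> flat insulation, no boundaries
  uni <- single_chrom_cm(matrix(5, 30, 30))
  ins <- insulation_track(uni, 3000)
  expect_equal(unique(stats::na.omit(ins$values$chr1)), 0)
  expect_equal(nrow(find_boundaries(ins)), 0)

  # two blocks with near-zero inter-block contact: one junction boundary
  n <- 30
  blk <- rep(c(TRUE, FALSE), each = 15)
  two <- ifelse(outer(blk, blk, `==`), 10, 0.01)
  tb <- single_chrom_cm(two)
  ins2 <- insulation_track(tb, 4000)
  bd <- find_boundaries(ins2, min_strength = 0.5)
  expect_equal(nrow(bd), 1)
  expect_true(bd$start <= 15000 && bd$end >= 15000)
  expect_gt(boundary_strength(ins2, bd), 1)

  # 12-bin hand matrix: insulation equals brute-force window means
  mat <- random_oe_matrix(12, seed = 21)
  cm <- single_chrom_cm(round(mat * 10) + 1)
  w <- 2
  ins3 <- insulation_track(cm, 2000)$values$chr1
  raw <- rep(NA_real_, 12)
  for (b in (w + 1):(12 - w))
    raw[b] <- mean(cm$matrices$chr1[(b - w):(b - 1), (b + 1):(b + w)])
  want <- log2(raw / mean(raw, na.rm = TRUE))
  expect_equal(ins3, want, tolerance = 1e-9)
  expect_error(insulation_track(cm, 7000), "exceeds")

  # boundary classification by flanking compartments
  layout <- tb$layout
  ab <- domain_set(c("chr1", "chr1"), c(0, 15000), c(15000, 30000),
                   c("A", "B"), layout)
  expect_equal(classify_boundaries(bd, ab), "A-B")
})

test_that("matrix balancing equalizes row sums", {
  set.seed(4)
  mat <- random_oe_matrix(40) * outer(runif(40, 0.3, 3), runif(40, 0.3, 3))
  mat <- (mat + t(mat)) / 2
  bal <- ice_balance(single_chrom_cm(mat), n_iter = 200)
  rs <- rowSums(bal$matrices$chr1)
  expect_lt(stats::sd(rs) / mean(rs), 1e-6)
})
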