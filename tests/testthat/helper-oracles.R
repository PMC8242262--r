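# Shared fixtures and independent brute-force oracles.

tiny_layout <- function(len = 1e5, bin = 1000, n_chrom = 1) {
  lens <- stats::setNames(rep(len, n_chrom), paste0("chr", seq_len(n_chrom)))
  genome_layout(lens, bin)
}

track_from <- function(layout, ...) {
  vals <- list(...)
  binned_track(layout, vals)
}

# Jaccard index of two interval sets in bp
jaccard_domains <- function(a, b) {
  ga <- GenomicRanges::granges(as_granges(a))
  gb <- GenomicRanges::granges(as_granges(b))
  i <- sum(GenomicRanges::width(GenomicRanges::intersect(ga, gb)))
  u <- sum(GenomicRanges::width(GenomicRanges::reduce(c(ga, gb))))
  i / u
}

# per-bp bitmap of a DomainSet over one chromosome
domain_bitmap <- function(domains, chrom, len) {
  x <- logical(len)
  sub <- as.data.frame(domains)
  sub <- sub[sub$chrom == chrom, , drop = FALSE]
  for (k in seq_len(nrow(sub))) x[(sub$start[k] + 1):sub$end[k]] <- TRUE
  x
}

# random non-overlapping interval set on one small chromosome
random_domains <- function(layout, n = 10, label = "d") {
  len <- layout$lengths[[1]]
  cuts <- sort(sample(seq(0, len, by = 100), 2 * n))
  s <- cuts[seq(1, 2 * n, by = 2)]
  e <- cuts[seq(2, 2 * n, by = 2)]
  keep <- e > s
  domain_set(rep(layout$chroms[1], sum(keep)), s[keep], e[keep], label, layout)
}

# windowed one-sample t by explicit per-bin loops (window k bins, centered
# with the longer side left for even k)
oracle_t_track <- function(x, k) {
  n <- length(x)
  L <- k %/% 2
  R <- k - 1 - L
  vapply(seq_len(n), function(i) {
    w <- x[max(1, i - L):min(n, i + R)]
    w <- w[!is.na(w)]
    if (length(w) < 2) return(NA_real_)
    m <- mean(w)
    s <- stats::sd(w)
    if (s == 0) {
      if (m == 0) return(NA_real_) else return(sign(m) * Inf)
    }
    m / (s / sqrt(length(w)))
  }, 0)
}

# run segmentation by explicit bp bitmap: select, close gaps < merge, drop
# short runs
oracle_segments <- function(values, c, bin_bp, chrom_len, min_bp, merge_bp) {
  sel <- !is.na(values) & values > c
  bp <- logical(chrom_len)
  for (i in which(sel)) {
    s <- (i - 1) * bin_bp + 1
    e <- min(i * bin_bp, chrom_len)
    bp[s:e] <- TRUE
  }
  r <- rle(bp)
  # close internal gaps shorter than merge_bp
  pos <- cumsum(r$lengths)
  for (j in seq_along(r$values)) {
    if (!r$values[j] && j > 1 && j < length(r$values) && r$lengths[j] < merge_bp) {
      bp[(pos[j] - r$lengths[j] + 1):pos[j]] <- TRUE
    }
  }
  r <- rle(bp)
  pos <- cumsum(r$lengths)
  out <- NULL
  for (j in seq_along(r$values)) {
    if (r$values[j] && r$lengths[j] >= min_bp) {
      out <- rbind(out, c(pos[j] - r$lengths[j], pos[j]))
    }
  }
  out
}

# symmetric random positive matrix resembling an O/E field
random_oe_matrix <- function(n, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::rlnorm(n * n, 0, 0.4), n, n)
  (m + t(m)) / 2
}

# contact matrix wrapper on a single synthetic chromosome
single_chrom_cm <- function(mat, bin = 1000, flag = "raw") {
  layout <- genome_layout(c(chr1 = nrow(mat) * bin), bin)
  contact_matrix(layout, list(chr1 = mat), flag = flag)
}

# alternating A/B blocks for Hi-C simulations
alt_compartments <- function(layout, block_bp) {
  rows <- do.call(rbind, lapply(layout$chroms, function(chrom) {
    starts <- seq(0, layout$lengths[[chrom]] - 1, by = block_bp)
    ends <- pmin(starts + block_bp, layout$lengths[[chrom]])
    data.frame(chrom = chrom, start = starts, end = ends,
               label = rep_len(c("A", "B"), length(starts)))
  }))
  domain_set(rows$chrom, rows$start, rows$end, rows$label, layout)
}
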