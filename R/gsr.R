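#' Parameters for the GSR caller
#'
#' Defaults follow the published analysis: 1-kb difference bins, 40-kb
#' window, probe-level FDR 0.01 from the mirrored null, minimum domain length
#' 50 kb, merge gap 10 kb. `fixed_threshold` (|t| = 8 in the original
#' analysis) bypasses the FDR search when supplied.
#'
#' @param diff_bin_bp bin width of the difference track (bp).
#' @param smooth_window_bp window for the moving t-statistic (bp).
#' @param fdr_level target probe-level empirical FDR in (0, 1).
#' @param min_domain_bp minimum retained domain length (bp).
#' @param merge_gap_bp domains closer than this are merged (bp).
#' @param fixed_threshold optional fixed |t| threshold replacing the search.
#' @param grid_step candidate-threshold grid step for the FDR search.
#' @return A list of class `GsrParams`.
#' @export
gsr_params <- function(diff_bin_bp = 1000, smooth_window_bp = 40000,
                       fdr_level = 0.01, min_domain_bp = 50000,
                       merge_gap_bp = 10000, fixed_threshold = NULL,
                       grid_step = 0.1) {
  stopifnot(diff_bin_bp > 0, smooth_window_bp > 0, min_domain_bp > 0,
            merge_gap_bp > 0, grid_step > 0,
            fdr_level > 0, fdr_level < 1)
  structure(list(diff_bin_bp = diff_bin_bp, smooth_window_bp = smooth_window_bp,
                 fdr_level = fdr_level, min_domain_bp = min_domain_bp,
                 merge_gap_bp = merge_gap_bp, fixed_threshold = fixed_threshold,
                 grid_step = grid_step),
            class = "GsrParams")
}

#' Per-bin difference of two condition tracks
#'
#' Returns control minus treated, so loss of signal in the treated condition
#' (e.g. H3K9me2 erased by G9a/GLP inhibition) is positive.
#'
#' @param treated,control [binned_track()]s on the same layout.
#' @return A [binned_track()] of `control - treated`.
#' @export
difference_track <- function(treated, control) {
  track_map2(control, treated, `-`)
}

#' Moving-window one-sample t-statistic of a difference track
#'
#' For each bin, over the centered window: `t = m / (s / sqrt(n))` with `m`
#' the window mean of the difference, `s` the window standard deviation
#' (n - 1 denominator) and `n` the unmasked bin count. This both smooths the
#' per-bin differences and standardizes them against local variability, the
#' windowed-t construction used for broad-domain callers. Bins are masked
#' where `n < 2`, where the unmasked support is below `min_frac` of the
#' window, or where `s = 0` with `m = 0`; a zero-variance window with a
#' non-zero mean reports signed infinity.
#'
#' @param diff a [binned_track()] of per-bin differences.
#' @param window_bp window in bp; multiple of the bin width.
#' @param min_frac minimum unmasked window fraction (default 0.5).
#' @return A [binned_track()] of t-statistics.
#' @export
t_statistic_track <- function(diff, window_bp, min_frac = 0.5) {
  stopifnot(inherits(diff, "BinnedTrack"))
  if (all(is.na(unlist(diff$values)))) stop("all-masked input track")
  k <- check_window(diff$layout, window_bp)
  vals <- lapply(diff$values, function(x) {
    w <- window_sums(x, k)
    n <- w$count
    m <- w$sum / n
    s2 <- pmax((w$sum2 - n * m^2) / (n - 1), 0)
    t <- m / sqrt(s2 / n)
    t[s2 == 0 & m != 0 & n >= 2] <- sign(m[s2 == 0 & m != 0 & n >= 2]) * Inf
    t[s2 == 0 & (is.na(m) | m == 0)] <- NA_real_
    t[n < 2 | n < min_frac * w$width] <- NA_real_
    t
  })
  binned_track(diff$layout, vals)
}

#' Empirical FDR threshold from the mirrored null
#'
#' With signal defined as the positive tail (difference = control - treated,
#' so loss is positive), the negative tail is taken as an empirical null and
#' mirrored: for candidate cutoffs c on a grid,
#' `FDR(c) = #\{t <= -c\} / max(1, #\{t >= c\})`. Returns the smallest c with
#' `FDR(c) < fdr_level` plus the full curve.
#'
#' @param t a [binned_track()] of t-statistics.
#' @param fdr_level target FDR in (0, 1).
#' @param grid_step grid spacing for candidate cutoffs (default 0.1).
#' @return List with `threshold`, `fdr` (empirical FDR at the threshold) and
#'   `curve` (data frame of cutoff and FDR).
#' @export
mirrored_null_threshold <- function(t, fdr_level = 0.01, grid_step = 0.1) {
  stopifnot(inherits(t, "BinnedTrack"))
  tv <- track_values(t)
  tv <- tv[!is.na(tv)]
  fin <- tv[is.finite(tv)]
  if (!any(tv > 0) || !any(tv < 0))
    stop("t-track must contain both positive and negative values")
  cmax <- max(abs(fin))
  grid <- seq(0, cmax, by = grid_step)
  pos <- vapply(grid, function(c) sum(tv >= c), 0)
  neg <- vapply(grid, function(c) sum(tv <= -c), 0)
  fdr <- neg / pmax(1, pos)
  curve <- data.frame(cutoff = grid, fdr = fdr, n_signal = pos, n_null = neg)
  hit <- which(fdr < fdr_level)
  if (!length(hit)) {
    cond <- simpleError(sprintf(
      "FDR target %g unreachable; minimum achievable empirical FDR is %g",
      fdr_level, min(fdr)))
    class(cond) <- c("gsrkit_fdr_unreachable", class(cond))
    attr(cond, "min_fdr") <- min(fdr)
    stop(cond)
  }
  list(threshold = grid[hit[1]], fdr = fdr[hit[1]], curve = curve)
}

#' Segment threshold-exceeding runs into domains
#'
#' Maximal runs of unmasked bins with `t > c` become candidate intervals;
#' intervals separated by less than `merge_gap_bp` are merged (masked gaps
#' count toward the distance), and only then are intervals shorter than
#' `min_domain_bp` dropped. Merge-then-filter lets two sub-minimum runs
#' survive as one domain.
#'
#' @param t a [binned_track()].
#' @param c finite threshold; bins with `t > c` (strict) are selected.
#' @param min_domain_bp minimum retained length in bp.
#' @param merge_gap_bp gaps shorter than this are closed.
#' @param label label for the output intervals.
#' @return A [domain_set()] (possibly empty).
#' @export
segment_domains <- function(t, c, min_domain_bp = 50000, merge_gap_bp = 10000,
                            label = "GSR") {
  stopifnot(inherits(t, "BinnedTrack"), is.finite(c))
  layout <- t$layout
  out <- list()
  for (chrom in layout$chroms) {
    v <- t$values[[chrom]]
    sel <- !is.na(v) & v > c
    if (!any(sel)) next
    r <- rle(sel)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    i0 <- starts[r$values]
    i1 <- ends[r$values]
    s <- (i0 - 1) * layout$bin_bp
    e <- pmin(i1 * layout$bin_bp, layout$lengths[[chrom]])
    # merge gaps < merge_gap_bp (single left-to-right pass reaches fixpoint)
    ms <- s[1]; me <- e[1]
    ks <- numeric(0); ke <- numeric(0)
    for (j in seq_along(s)[-1]) {
      if (s[j] - me < merge_gap_bp) {
        me <- e[j]
      } else {
        ks <- c(ks, ms); ke <- c(ke, me)
        ms <- s[j]; me <- e[j]
      }
    }
    ks <- c(ks, ms); ke <- c(ke, me)
    keep <- (ke - ks) >= min_domain_bp
    if (any(keep))
      out[[chrom]] <- data.frame(chrom = chrom, start = ks[keep], end = ke[keep])
  }
  if (!length(out)) return(domain_set(layout = layout, label = character(0)))
  df <- do.call(rbind, out)
  domain_set(df$chrom, df$start, df$end, label, layout)
}

#' Partition the mappable genome into GSR x LAD sections
#'
#' @param gsrs,lads [domain_set()]s.
#' @param mappable a [domain_set()] of mappable regions; default whole
#'   genome.
#' @return A [domain_set()] with labels `GSRs/LADs`, `GSRs/iLADs`,
#'   `non-GSRs/LADs`, `non-GSRs/iLADs` tiling the mappable genome.
#' @export
build_sections <- function(gsrs, lads, mappable = NULL) {
  layout <- domain_layout(gsrs)
  if (is.null(mappable)) mappable <- genome_domains(layout)
  g <- domains_intersect(gsrs, mappable)
  ng <- domains_setdiff(mappable, gsrs)
  l <- domains_intersect(lads, mappable)
  il <- domains_setdiff(mappable, lads)
  domains_rbind(
    domains_intersect(g, l, "GSRs/LADs"),
    domains_intersect(g, il, "GSRs/iLADs"),
    domains_intersect(ng, l, "non-GSRs/LADs"),
    domains_intersect(ng, il, "non-GSRs/iLADs"))
}

#' Call G9a/GLP-sensitive regions from paired-condition tracks
#'
#' Full caller: per-bin difference (control - treated, so loss is positive),
#' moving-window t-statistic, mirrored-null FDR threshold (or a fixed
#' threshold), run segmentation with merge-then-filter, and the four-section
#' partition of the mappable genome by GSR and LAD status. When the FDR
#' target is unreachable (no real signal tail, e.g. a pure-noise difference),
#' the caller warns and returns zero domains with `threshold_used = Inf`.
#'
#' @param control,treated [binned_track()]s of (spike-in calibrated) signal
#'   on the same layout.
#' @param lads a [domain_set()] of LADs used for the section partition.
#' @param params a [gsr_params()].
#' @return A list of class `GsrCallResult`: `t_track`, `threshold_used`,
#'   `empirical_fdr_at_threshold`, `fdr_curve`, `gsr_domains`, `sections`.
#' @export
call_gsrs <- function(control, treated, lads, params = gsr_params()) {
  stopifnot(inherits(params, "GsrParams"))
  d <- difference_track(treated, control)
  t <- t_statistic_track(d, params$smooth_window_bp)
  curve <- NULL
  tv_all <- track_values(t)
  has_both_tails <- any(tv_all > 0, na.rm = TRUE) && any(tv_all < 0, na.rm = TRUE)
  if (!is.null(params$fixed_threshold)) {
    thr <- abs(params$fixed_threshold)
    tv <- track_values(t)
    fdr <- sum(tv <= -thr, na.rm = TRUE) / max(1, sum(tv >= thr, na.rm = TRUE))
  } else if (!has_both_tails) {
    warning("t-statistic track has no two-sided distribution; ",
            "calling zero domains", call. = FALSE)
    thr <- Inf; fdr <- NA_real_
  } else {
    res <- tryCatch(
      mirrored_null_threshold(t, params$fdr_level, params$grid_step),
      gsrkit_fdr_unreachable = function(e) {
        warning("FDR target unreachable (", conditionMessage(e),
                "); calling zero domains", call. = FALSE)
        NULL
      })
    if (is.null(res)) {
      thr <- Inf; fdr <- NA_real_
    } else {
      thr <- res$threshold; fdr <- res$fdr; curve <- res$curve
    }
  }
  gsrs <- if (is.finite(thr)) {
    segment_domains(t, thr, params$min_domain_bp, params$merge_gap_bp, "GSR")
  } else {
    domain_set(layout = t$layout, label = character(0))
  }
  mappable <- track_mappable(d)
  structure(list(
    t_track = t,
    threshold_used = thr,
    empirical_fdr_at_threshold = fdr,
    fdr_curve = curve,
    gsr_domains = gsrs,
    sections = build_sections(gsrs, lads, mappable)
  ), class = "GsrCallResult")
}

## merged intervals of unmasked bins
track_mappable <- function(track, label = "mappable") {
  layout <- track$layout
  out <- list()
  for (chrom in layout$chroms) {
    sel <- !is.na(track$values[[chrom]])
    if (!any(sel)) next
    r <- rle(sel)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    i0 <- starts[r$values]; i1 <- ends[r$values]
    out[[chrom]] <- data.frame(
      chrom = chrom,
      start = (i0 - 1) * layout$bin_bp,
      end = pmin(i1 * layout$bin_bp, layout$lengths[[chrom]]))
  }
  if (!length(out)) return(domain_set(layout = layout, label = character(0)))
  df <- do.call(rbind, out)
  domain_set(df$chrom, df$start, df$end, label, layout)
}

#' Difference-signal summaries inside and outside called domains
#'
#' @param diff a [binned_track()] of per-bin differences.
#' @param gsrs a non-empty [domain_set()] whose complement (over unmasked
#'   bins) is also non-empty.
#' @return Data frame with one row per class (`GSR`, `non-GSR`): n bins,
#'   median and quartiles of the difference.
#' @export
domain_level_stats <- function(diff, gsrs) {
  stopifnot(inherits(diff, "BinnedTrack"), inherits(gsrs, "DomainSet"))
  if (nrow(gsrs) == 0) stop("empty GSR set")
  ind <- domains_indicator(gsrs, diff$layout)
  d <- track_values(diff)
  inside <- track_values(ind) > 0
  ok <- !is.na(d)
  x_in <- d[ok & inside]
  x_out <- d[ok & !inside]
  if (!length(x_in)) stop("no unmasked bins inside GSRs")
  if (!length(x_out)) stop("no unmasked bins outside GSRs (all-genome GSR set)")
  summarize <- function(x) c(n = length(x), q1 = unname(stats::quantile(x, 0.25)),
                             median = stats::median(x), q3 = unname(stats::quantile(x, 0.75)))
  out <- rbind(GSR = summarize(x_in), `non-GSR` = summarize(x_out))
  data.frame(class = rownames(out), out, row.names = NULL, check.names = FALSE)
}
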