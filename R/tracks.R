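## Windowed statistics on binned tracks. Windows never cross chromosome
## boundaries; masked (NA) bins are excluded from every window sum.

## running (sum, sum of squares, count) over a centered window of k bins.
## Offsets are -floor(k/2) .. k - 1 - floor(k/2), so odd k is symmetric and
## even k extends one bin further to the left. Windows are truncated at the
## chromosome ends.
window_sums <- function(x, k) {
  n <- length(x)
  ok <- !is.na(x)
  x0 <- ifelse(ok, x, 0)
  cs <- cumsum(x0)
  cs2 <- cumsum(x0^2)
  cn <- cumsum(as.numeric(ok))
  L <- k %/% 2
  R <- k - 1L - L
  lo <- pmax(seq_len(n) - L, 1L)
  hi <- pmin(seq_len(n) + R, n)
  at <- function(c, i) ifelse(i >= 1, c[pmax(i, 1)], 0)
  list(sum = cs[hi] - at(cs, lo - 1L),
       sum2 = cs2[hi] - at(cs2, lo - 1L),
       count = cn[hi] - at(cn, lo - 1L),
       width = hi - lo + 1L)
}

check_window <- function(layout, window_bp) {
  if (window_bp < layout$bin_bp)
    stop("window smaller than one bin")
  if (window_bp %% layout$bin_bp != 0)
    stop("window_bp must be a positive multiple of the bin width")
  as.integer(window_bp / layout$bin_bp)
}

#' Moving-average smoothing of a binned track
#'
#' Centered running mean over unmasked bins within a `window_bp` window,
#' computed per chromosome (no smoothing across chromosome boundaries).
#' A bin reports `NA` when fewer than `min_frac` of the in-chromosome window
#' bins are unmasked, so gappy data cannot fabricate signal.
#'
#' @param track a [binned_track()].
#' @param window_bp window size in bp; positive multiple of the bin width.
#' @param min_frac minimum unmasked fraction of the window (default 0.5).
#' @return A smoothed [binned_track()].
#' @export
moving_average <- function(track, window_bp, min_frac = 0.5) {
  stopifnot(inherits(track, "BinnedTrack"))
  k <- check_window(track$layout, window_bp)
  vals <- lapply(track$values, function(x) {
    w <- window_sums(x, k)
    out <- w$sum / w$count
    out[w$count == 0 | w$count < min_frac * w$width] <- NA_real_
    out
  })
  binned_track(track$layout, vals)
}

#' Pearson correlation between two tracks
#'
#' Computed over jointly unmasked bins across all chromosomes.
#'
#' @param a,b [binned_track()]s on the same layout.
#' @return Pearson r.
#' @export
track_correlation <- function(a, b) {
  stopifnot(inherits(a, "BinnedTrack"), inherits(b, "BinnedTrack"))
  if (!same_layout(a$layout, b$layout)) stop("tracks are on different layouts")
  x <- track_values(a)
  y <- track_values(b)
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) stop("fewer than 3 jointly unmasked bins")
  stats::cor(x[ok], y[ok])
}

#' Average signal profile across domain borders
#'
#' For every domain border, extracts the signal from `-flank_bp` to
#' `+flank_bp` and orients it so the domain interior is on the right-hand
#' side of the profile. When `mirror = TRUE` (the default), right borders are
#' reflected before averaging so left and right borders superimpose. Borders
#' whose full flank does not fit inside the chromosome are skipped.
#'
#' @param track a [binned_track()].
#' @param domains a [domain_set()] on the same layout.
#' @param flank_bp flank on each side of the border; multiple of the bin
#'   width.
#' @param mirror reflect right borders before averaging (default `TRUE`).
#' @return A data frame with columns `offset_bp` (bin-center offset from the
#'   border, negative = outside the domain) and `mean` (per-offset mean over
#'   all borders, ignoring masked bins), plus attribute `n_borders`.
#' @export
border_metaprofile <- function(track, domains, flank_bp, mirror = TRUE) {
  stopifnot(inherits(track, "BinnedTrack"), inherits(domains, "DomainSet"))
  layout <- track$layout
  if (!same_layout(layout, domain_layout(domains)))
    stop("track and domains are on different layouts")
  f <- check_window(layout, flank_bp)
  rows <- list()
  for (k in seq_len(nrow(domains))) {
    chrom <- domains$chrom[k]
    v <- track$values[[chrom]]
    n <- length(v)
    for (side in c("left", "right")) {
      border <- if (side == "left") domains$start[k] else domains$end[k]
      b <- round(border / layout$bin_bp)  # bin boundary index (0-based)
      if (b - f < 0 || b + f > n) next
      prof <- v[(b - f + 1):(b + f)]
      if (side == "right" && mirror) prof <- rev(prof)
      rows[[length(rows) + 1L]] <- prof
    }
  }
  if (!length(rows)) stop("no borders with the full flank inside a chromosome")
  mat <- do.call(rbind, rows)
  data.frame(
    offset_bp = (seq_len(2 * f) - f - 0.5) * layout$bin_bp,
    mean = colMeans(mat, na.rm = TRUE)
  ) -> out
  attr(out, "n_borders") <- nrow(mat)
  out
}
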