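#' Genome layout: chromosome sizes plus a bin width
#'
#' The shared coordinate frame for every binned track, interval set, and
#' contact matrix in the package. Coordinates are 0-based half-open (BED
#' convention); bins are anchored at coordinate 0 of each chromosome and the
#' final partial bin is kept, so each chromosome has `ceiling(length / bin_bp)`
#' bins.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp;
#'   names are the chromosome names and must be unique.
#' @param bin_bp bin width in bp (positive scalar).
#' @return An object of class `GenomeLayout`.
#' @examples
#' layout <- genome_layout(c(chr1 = 1e6, chr2 = 5e5), bin_bp = 1000)
#' n_bins(layout)
#' @export
genome_layout <- function(chrom_lengths, bin_bp) {
  if (!is.numeric(chrom_lengths) || length(chrom_lengths) < 1L)
    stop("chrom_lengths must be a non-empty numeric vector")
  nm <- names(chrom_lengths)
  if (is.null(nm) || any(!nzchar(nm)))
    stop("chrom_lengths must be named by chromosome")
  if (anyDuplicated(nm))
    stop("chromosome names must be unique")
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths <= 0))
    stop("chromosome lengths must be positive and finite")
  if (!is.numeric(bin_bp) || length(bin_bp) != 1L || !is.finite(bin_bp) || bin_bp <= 0)
    stop("bin_bp must be a positive scalar")
  structure(
    list(chroms = nm,
         lengths = stats::setNames(as.numeric(chrom_lengths), nm),
         bin_bp = as.numeric(bin_bp)),
    class = "GenomeLayout"
  )
}

#' Number of bins per chromosome
#'
#' @param layout a [genome_layout()].
#' @param chrom optional chromosome name(s); default all.
#' @return Named integer vector of bin counts.
#' @export
n_bins <- function(layout, chrom = NULL) {
  stopifnot(inherits(layout, "GenomeLayout"))
  len <- if (is.null(chrom)) layout$lengths else layout$lengths[chrom]
  if (anyNA(len)) stop("unknown chromosome: ", paste(chrom[!chrom %in% layout$chroms], collapse = ", "))
  stats::setNames(as.integer(ceiling(len / layout$bin_bp)), names(len))
}

#' @export
print.GenomeLayout <- function(x, ...) {
  cat(sprintf("GenomeLayout: %d chromosome(s), bin %g bp, %g bp total\n",
              length(x$chroms), x$bin_bp, sum(x$lengths)))
  invisible(x)
}

same_layout <- function(a, b) {
  same_genome(a, b) && a$bin_bp == b$bin_bp
}

## same chromosomes and lengths; bin width may differ (bp-level interval
## arithmetic does not depend on it)
same_genome <- function(a, b) {
  identical(a$chroms, b$chroms) && isTRUE(all.equal(a$lengths, b$lengths))
}

#' Binned genomic signal track
#'
#' One real value per fixed-width bin per chromosome. Missing / unmappable
#' bins are `NA`; every statistic in the package skips `NA` bins. A track
#' holds ChIP log-ratios, per-bin condition differences, windowed
#' t-statistics, DamID log-ratios, PC1 values, or insulation scores alike.
#'
#' @param layout a [genome_layout()].
#' @param values either `NULL` (all-missing track), a single number recycled
#'   to every bin, or a named list with one numeric vector per chromosome of
#'   exactly the layout's bin count.
#' @return An object of class `BinnedTrack` with elements `layout` and
#'   `values` (named list per chromosome; `NA` = masked).
#' @export
binned_track <- function(layout, values = NULL) {
  stopifnot(inherits(layout, "GenomeLayout"))
  nb <- n_bins(layout)
  if (is.null(values)) {
    values <- lapply(nb, function(n) rep(NA_real_, n))
  } else if (is.numeric(values) && length(values) == 1L) {
    values <- lapply(nb, function(n) rep(as.numeric(values), n))
  } else {
    if (!is.list(values) || !setequal(names(values), layout$chroms))
      stop("values must be a named list with one vector per chromosome")
    values <- values[layout$chroms]
    for (chrom in layout$chroms) {
      v <- values[[chrom]]
      if (!is.numeric(v) || length(v) != nb[[chrom]])
        stop(sprintf("values for %s must be numeric of length %d", chrom, nb[[chrom]]))
      values[[chrom]] <- as.numeric(v)
    }
  }
  structure(list(layout = layout, values = values), class = "BinnedTrack")
}

#' @export
print.BinnedTrack <- function(x, ...) {
  v <- unlist(x$values, use.names = FALSE)
  cat(sprintf("BinnedTrack: %d bins (%g bp), %.1f%% masked\n",
              length(v), x$layout$bin_bp, 100 * mean(is.na(v))))
  invisible(x)
}

#' Flatten a track to a single vector (bins in chromosome order)
#' @param track a [binned_track()].
#' @return Numeric vector; `NA` marks masked bins.
#' @export
track_values <- function(track) {
  stopifnot(inherits(track, "BinnedTrack"))
  unlist(track$values, use.names = FALSE)
}

## elementwise combination of two tracks on the same layout; NA propagates
track_map2 <- function(a, b, f) {
  stopifnot(inherits(a, "BinnedTrack"), inherits(b, "BinnedTrack"))
  if (!same_layout(a$layout, b$layout)) stop("tracks are on different layouts")
  vals <- mapply(function(x, y) {
    out <- f(x, y)
    out[is.na(x) | is.na(y)] <- NA_real_
    out
  }, a$values, b$values, SIMPLIFY = FALSE)
  binned_track(a$layout, vals)
}

track_map <- function(a, f) {
  binned_track(a$layout, lapply(a$values, function(x) {
    out <- f(x)
    out[is.na(x)] <- NA_real_
    out
  }))
}

## per-bin interval [start, end) of bin i (1-based) on a chromosome
bin_bounds <- function(layout, chrom) {
  n <- n_bins(layout, chrom)[[1]]
  start <- (seq_len(n) - 1) * layout$bin_bp
  end <- pmin(start + layout$bin_bp, layout$lengths[[chrom]])
  list(start = start, end = end, width = end - start)
}

#' Mean signal over an arbitrary genomic window
#'
#' Overlap-weighted mean of unmasked bin values over `[start, end)`.
#' Returns `NA` when fewer than `min_frac` of the covered bp are unmasked.
#'
#' @param track a [binned_track()].
#' @param chrom chromosome name.
#' @param start,end 0-based half-open window; clipped to the chromosome.
#' @param min_frac minimum unmasked fraction of the window required for a
#'   value (default 0.5).
#' @return A single number or `NA`.
#' @export
region_mean <- function(track, chrom, start, end, min_frac = 0.5) {
  stopifnot(inherits(track, "BinnedTrack"))
  layout <- track$layout
  if (!chrom %in% layout$chroms) stop("unknown chromosome: ", chrom)
  len <- layout$lengths[[chrom]]
  start <- max(0, start); end <- min(end, len)
  if (end <= start) stop("empty window after clipping")
  bw <- layout$bin_bp
  b0 <- floor(start / bw) + 1L
  b1 <- floor((end - 1) / bw) + 1L
  idx <- b0:b1
  bs <- (idx - 1) * bw
  be <- pmin(bs + bw, len)
  ov <- pmin(end, be) - pmax(start, bs)
  v <- track$values[[chrom]][idx]
  ok <- !is.na(v)
  if (sum(ov[ok]) < min_frac * sum(ov)) return(NA_real_)
  sum(v[ok] * ov[ok]) / sum(ov[ok])
}

#' Rebin a track to a coarser resolution by bp-weighted averaging
#'
#' @param track a [binned_track()].
#' @param new_bin_bp target bin width; must be a positive multiple of the
#'   current bin width.
#' @param min_frac minimum unmasked bp fraction for a coarse bin to get a
#'   value (default 0.5).
#' @return A [binned_track()] on the coarser layout.
#' @export
rebin_track <- function(track, new_bin_bp, min_frac = 0.5) {
  stopifnot(inherits(track, "BinnedTrack"))
  old <- track$layout$bin_bp
  if (new_bin_bp %% old != 0 || new_bin_bp <= 0)
    stop("new_bin_bp must be a positive multiple of the current bin width")
  layout2 <- genome_layout(track$layout$lengths, new_bin_bp)
  fac <- new_bin_bp / old
  vals <- lapply(track$layout$chroms, function(chrom) {
    bb <- bin_bounds(track$layout, chrom)
    grp <- floor(bb$start / new_bin_bp) + 1L
    v <- track$values[[chrom]]
    w <- bb$width
    ok <- !is.na(v)
    tot <- rowsum(w, grp)[, 1]
    win <- rowsum(ifelse(ok, w, 0), grp)[, 1]
    num <- rowsum(ifelse(ok, v * w, 0), grp)[, 1]
    out <- ifelse(win >= min_frac * tot & win > 0, num / win, NA_real_)
    as.numeric(out)
  })
  names(vals) <- track$layout$chroms
  binned_track(layout2, vals)
}
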