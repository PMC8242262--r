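#' Labeled genomic interval set
#'
#' Disjoint 0-based half-open intervals with a text label per interval
#' (GSR, LAD, compartment A/B, genome section, TAD boundary, ...). Intervals
#' are sorted on construction; overlapping intervals sharing a label are
#' rejected.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end numeric vectors, 0-based half-open.
#' @param label character vector (recycled) of interval labels.
#' @param layout a [genome_layout()]; intervals must fit inside it.
#' @return An object of class `DomainSet`: a data frame with columns
#'   `chrom`, `start`, `end`, `label`, plus the layout as an attribute.
#' @export
domain_set <- function(chrom = character(), start = numeric(), end = numeric(),
                       label = "domain", layout = NULL) {
  if (is.null(layout) || !inherits(layout, "GenomeLayout"))
    stop("a GenomeLayout is required")
  n <- max(length(chrom), length(start), length(end), 0L)
  if (length(start) != n || length(end) != n)
    stop("start and end must have equal length")
  chrom <- if (n > 0) rep_len(as.character(chrom), n) else character(0)
  label <- rep_len(as.character(label), n)
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), label = label,
                   stringsAsFactors = FALSE)
  if (n > 0) {
    bad <- !df$chrom %in% layout$chroms
    if (any(bad)) stop("unknown chromosome: ", paste(unique(df$chrom[bad]), collapse = ", "))
    if (any(df$start < 0)) stop("negative interval start")
    if (any(df$end <= df$start)) stop("interval end must exceed start")
    over <- df$end > layout$lengths[df$chrom]
    if (any(over))
      stop(sprintf("interval end %g beyond %s length %g",
                   df$end[which(over)[1]], df$chrom[which(over)[1]],
                   layout$lengths[[df$chrom[which(over)[1]]]]))
    df <- df[order(match(df$chrom, layout$chroms), df$start, df$end), , drop = FALSE]
    rownames(df) <- NULL
    for (lb in unique(df$label)) {
      sub <- df[df$label == lb, , drop = FALSE]
      for (ch in unique(sub$chrom)) {
        s <- sub[sub$chrom == ch, , drop = FALSE]
        if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)]))
          stop(sprintf("overlapping intervals with label '%s' on %s", lb, ch))
      }
    }
  }
  structure(df, layout = layout, class = c("DomainSet", "data.frame"))
}

#' @export
print.DomainSet <- function(x, ...) {
  cat(sprintf("DomainSet: %d interval(s), %g bp, labels: %s\n",
              nrow(x), if (nrow(x)) sum(x$end - x$start) else 0,
              paste(unique(x$label), collapse = ", ")))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}

domain_layout <- function(domains) attr(domains, "layout")

#' Convert a DomainSet to a GRanges object
#' @param domains a [domain_set()].
#' @return A `GRanges` with the labels in `mcols()$label` and seqlengths set.
#' @export
as_granges <- function(domains) {
  stopifnot(inherits(domains, "DomainSet"))
  layout <- domain_layout(domains)
  gr <- GenomicRanges::GRanges(
    seqnames = factor(domains$chrom, levels = layout$chroms),
    ranges = IRanges::IRanges(start = domains$start + 1, end = domains$end),
    label = domains$label,
    seqlengths = stats::setNames(as.integer(layout$lengths), layout$chroms))
  gr
}

granges_to_domains <- function(gr, layout, label = "domain") {
  if (length(gr) == 0)
    return(domain_set(layout = layout, label = character(0)))
  lb <- if (!is.null(gr$label)) gr$label else label
  domain_set(as.character(GenomeInfoDb::seqnames(gr)),
             GenomicRanges::start(gr) - 1, GenomicRanges::end(gr),
             lb, layout)
}

## reduce to a label-free merged range set
reduce_granges <- function(domains) {
  GenomicRanges::reduce(as_granges(domains), ignore.strand = TRUE)
}

#' Fraction of one interval set covered by another
#'
#' `overlap_fraction(a, b)` is (bp of a intersected with b) / (bp of a).
#' Labels are ignored; both sets are merged first.
#'
#' @param a,b [domain_set()]s on the same layout.
#' @return A number in `[0, 1]`.
#' @export
overlap_fraction <- function(a, b) {
  stopifnot(inherits(a, "DomainSet"), inherits(b, "DomainSet"))
  if (!same_genome(domain_layout(a), domain_layout(b)))
    stop("domain sets are on different genomes")
  wa <- sum(GenomicRanges::width(reduce_granges(a)))
  if (wa == 0) stop("set 'a' has zero total length")
  inter <- GenomicRanges::intersect(reduce_granges(a), reduce_granges(b),
                                    ignore.strand = TRUE)
  sum(GenomicRanges::width(inter)) / wa
}

#' Fraction of the genome covered by an interval set
#'
#' @param domains a [domain_set()].
#' @return A number in `[0, 1]` (merged bp over total genome bp).
#' @export
genome_coverage <- function(domains) {
  stopifnot(inherits(domains, "DomainSet"))
  layout <- domain_layout(domains)
  if (nrow(domains) == 0) return(0)
  sum(GenomicRanges::width(reduce_granges(domains))) / sum(layout$lengths)
}

#' Restrict to intervals carrying one label
#' @param domains a [domain_set()].
#' @param label label to keep.
#' @return A [domain_set()].
#' @export
domains_with_label <- function(domains, label) {
  stopifnot(inherits(domains, "DomainSet"))
  sub <- as.data.frame(domains)[domains$label %in% label, , drop = FALSE]
  domain_set(sub$chrom, sub$start, sub$end, sub$label, domain_layout(domains))
}

## set algebra on merged interval sets, returning DomainSets with one label
domains_setdiff <- function(a, b, label = "domain") {
  gr <- GenomicRanges::setdiff(reduce_granges(a), reduce_granges(b),
                               ignore.strand = TRUE)
  granges_to_domains(gr, domain_layout(a), label)
}

domains_intersect <- function(a, b, label = "domain") {
  gr <- GenomicRanges::intersect(reduce_granges(a), reduce_granges(b),
                                 ignore.strand = TRUE)
  granges_to_domains(gr, domain_layout(a), label)
}

domains_union <- function(a, b, label = "domain") {
  gr <- GenomicRanges::reduce(c(reduce_granges(a), reduce_granges(b)))
  granges_to_domains(gr, domain_layout(a), label)
}

## whole-genome DomainSet
genome_domains <- function(layout, label = "genome") {
  domain_set(layout$chroms, rep(0, length(layout$chroms)),
             as.numeric(layout$lengths), label, layout)
}

## bind several DomainSets (distinct labels) into one
domains_rbind <- function(...) {
  parts <- list(...)
  parts <- parts[vapply(parts, nrow, 1L) > 0]
  layout <- domain_layout(list(...)[[1]])
  if (!length(parts)) return(domain_set(layout = layout, label = character(0)))
  df <- do.call(rbind, lapply(parts, as.data.frame))
  domain_set(df$chrom, df$start, df$end, df$label, layout)
}

#' Label lookup for genomic point positions
#'
#' Assigns each (chrom, pos) point the label of the interval containing it,
#' or `NA` when uncovered. Used to place gene TSSs into genome sections or
#' LAD-switch classes.
#'
#' @param domains a [domain_set()].
#' @param chrom,pos vectors of positions (0-based).
#' @return Character vector of labels.
#' @export
locate_label <- function(domains, chrom, pos) {
  stopifnot(inherits(domains, "DomainSet"), length(chrom) == length(pos))
  out <- rep(NA_character_, length(pos))
  if (nrow(domains) == 0 || length(pos) == 0) return(out)
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1, width = 1))
  s <- as_granges(domains)
  hit <- GenomicRanges::findOverlaps(q, s, select = "first")
  ok <- !is.na(hit)
  out[ok] <- domains$label[hit[ok]]
  out
}

## indicator BinnedTrack (1 inside domains, 0 outside) at the layout's bins;
## a bin counts as inside when its midpoint is covered
domains_indicator <- function(domains, layout = domain_layout(domains)) {
  vals <- lapply(layout$chroms, function(chrom) {
    bb <- bin_bounds(layout, chrom)
    mid <- (bb$start + bb$end) / 2
    lab <- locate_label(domains, rep(chrom, length(mid)), floor(mid))
    as.numeric(!is.na(lab))
  })
  names(vals) <- layout$chroms
  binned_track(layout, vals)
}

## majority-overlap label per bin of `layout`; NA where nothing overlaps
bin_labels <- function(domains, layout) {
  lapply_out <- lapply(layout$chroms, function(chrom) {
    n <- n_bins(layout, chrom)[[1]]
    bb <- bin_bounds(layout, chrom)
    lab <- rep(NA_character_, n)
    cover <- rep(0, n)
    sub <- as.data.frame(domains)[domains$chrom == chrom, , drop = FALSE]
    if (nrow(sub)) {
      for (lb in unique(sub$label)) {
        s <- sub[sub$label == lb, , drop = FALSE]
        cov <- rep(0, n)
        for (k in seq_len(nrow(s))) {
          b0 <- floor(s$start[k] / layout$bin_bp) + 1L
          b1 <- floor((s$end[k] - 1) / layout$bin_bp) + 1L
          idx <- b0:b1
          ov <- pmin(s$end[k], bb$end[idx]) - pmax(s$start[k], bb$start[idx])
          cov[idx] <- cov[idx] + ov
        }
        take <- cov > cover
        lab[take] <- lb
        cover[take] <- cov[take]
      }
    }
    lab
  })
  stats::setNames(lapply_out, layout$chroms)
}
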