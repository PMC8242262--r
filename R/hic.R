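#' Per-chromosome cis contact matrix
#'
#' Symmetric non-negative binned contact counts, one square matrix per
#' chromosome, on a shared [genome_layout()]. Bins whose row is entirely
#' zero/NA are treated as masked in every derived statistic.
#'
#' @param layout a [genome_layout()] at the matrix resolution.
#' @param matrices named list (one per chromosome) of square symmetric
#'   matrices of dimension equal to the chromosome's bin count.
#' @param flag one of `"raw"`, `"balanced"`, `"oe"`.
#' @return An object of class `ContactMatrix`.
#' @export
contact_matrix <- function(layout, matrices, flag = c("raw", "balanced", "oe")) {
  stopifnot(inherits(layout, "GenomeLayout"))
  flag <- match.arg(flag)
  if (!is.list(matrices) || !setequal(names(matrices), layout$chroms))
    stop("matrices must be a named list with one matrix per chromosome")
  matrices <- matrices[layout$chroms]
  nb <- n_bins(layout)
  for (chrom in layout$chroms) {
    m <- matrices[[chrom]]
    if (!is.matrix(m) || nrow(m) != nb[[chrom]] || ncol(m) != nb[[chrom]])
      stop(sprintf("matrix for %s must be %d x %d", chrom, nb[[chrom]], nb[[chrom]]))
    fin <- m[is.finite(m)]
    if (length(fin) && flag != "oe" && any(fin < 0))
      stop("contact counts must be non-negative")
    d <- abs(m - t(m))
    scale <- max(abs(fin), 1)
    if (any(d > 1e-9 * scale, na.rm = TRUE))
      stop(sprintf("matrix for %s is not symmetric", chrom))
  }
  structure(list(layout = layout, matrices = matrices, flag = flag),
            class = "ContactMatrix")
}

#' @export
print.ContactMatrix <- function(x, ...) {
  cat(sprintf("ContactMatrix (%s): %d chromosome(s) at %g bp\n",
              x$flag, length(x$layout$chroms), x$layout$bin_bp))
  invisible(x)
}

## masked bins: all-zero or all-NA rows
contact_mask <- function(mat) {
  apply(mat, 1, function(r) all(is.na(r)) || all(r[!is.na(r)] == 0))
}

#' Distance-decay expected profile of a contact matrix
#'
#' `expected(d)` is the mean of unmasked entries at diagonal offset `d`,
#' computed per chromosome.
#'
#' @param m a [contact_matrix()].
#' @return Named list (per chromosome) of numeric vectors, element `d + 1`
#'   holding the expectation at offset `d` bins.
#' @export
expected_by_distance <- function(m) {
  stopifnot(inherits(m, "ContactMatrix"))
  out <- lapply(m$layout$chroms, function(chrom) {
    mat <- m$matrices[[chrom]]
    n <- nrow(mat)
    if (n == 0) stop("empty chromosome: ", chrom)
    mask <- contact_mask(mat)
    vapply(0:(n - 1), function(d) {
      i <- seq_len(n - d)
      ok <- !mask[i] & !mask[i + d]
      if (!any(ok)) return(NA_real_)
      mean(mat[cbind(i[ok], i[ok] + d)], na.rm = TRUE)
    }, 0)
  })
  stats::setNames(out, m$layout$chroms)
}

#' Observed-over-expected contact matrix
#'
#' Divides each entry by the distance expectation of its diagonal; entries in
#' masked bins or with zero/undefined expectation become `NA`.
#'
#' @param m a [contact_matrix()] (raw or balanced).
#' @return A [contact_matrix()] with flag `"oe"`.
#' @export
observed_over_expected <- function(m) {
  stopifnot(inherits(m, "ContactMatrix"))
  expv <- expected_by_distance(m)
  mats <- lapply(m$layout$chroms, function(chrom) {
    mat <- m$matrices[[chrom]]
    n <- nrow(mat)
    mask <- contact_mask(mat)
    E <- matrix(expv[[chrom]][abs(outer(seq_len(n), seq_len(n), `-`)) + 1], n, n)
    oe <- mat / E
    oe[!is.finite(oe)] <- NA_real_
    oe[E == 0] <- NA_real_
    oe[mask, ] <- NA_real_
    oe[, mask] <- NA_real_
    oe
  })
  names(mats) <- m$layout$chroms
  contact_matrix(m$layout, mats, flag = "oe")
}

as_oe <- function(m) if (m$flag == "oe") m else observed_over_expected(m)

#' Simple iterative row/column balancing
#'
#' Vanilla matrix-balancing (ICE-style): repeatedly divide by the outer
#' product of normalized row sums until row sums are uniform over unmasked
#' bins.
#'
#' @param m a raw [contact_matrix()].
#' @param n_iter maximum iterations (default 50).
#' @param tol stop when the coefficient of variation of row sums drops below
#'   this (default 1e-8).
#' @return A [contact_matrix()] with flag `"balanced"`.
#' @export
ice_balance <- function(m, n_iter = 50, tol = 1e-8) {
  stopifnot(inherits(m, "ContactMatrix"))
  mats <- lapply(m$layout$chroms, function(chrom) {
    mat <- m$matrices[[chrom]]
    mask <- contact_mask(mat)
    w <- mat
    for (it in seq_len(n_iter)) {
      rs <- rowSums(w, na.rm = TRUE)
      rs[mask] <- NA
      mu <- mean(rs, na.rm = TRUE)
      if (!is.finite(mu) || mu == 0) break
      b <- rs / mu
      if (stats::sd(b, na.rm = TRUE) < tol) break
      b[!is.finite(b) | b == 0] <- 1
      w <- w / outer(b, b)
    }
    w
  })
  names(mats) <- m$layout$chroms
  contact_matrix(m$layout, mats, flag = "balanced")
}

#' Compartment PC1 and A/B calls from a contact matrix
#'
#' Per chromosome: the O/E matrix is converted to its Pearson correlation
#' matrix over unmasked bins; the leading eigenvector, scaled by the square
#' root of the leading eigenvalue, is the PC1 track. The sign is oriented so
#' that mean gene density over PC1-positive bins exceeds that over
#' PC1-negative bins; A = positive PC1, B = negative.
#'
#' @param m a [contact_matrix()] (raw, balanced, or O/E).
#' @param gene_density a [binned_track()] of gene density (e.g. TSS counts)
#'   on the same layout, used only to orient the sign.
#' @return A list of class `CompartmentCall`: `pc1` ([binned_track()]) and
#'   `ab` ([domain_set()] with labels `A`/`B`).
#' @export
compartment_pc1 <- function(m, gene_density) {
  stopifnot(inherits(m, "ContactMatrix"), inherits(gene_density, "BinnedTrack"))
  if (!same_layout(m$layout, gene_density$layout))
    stop("gene density track is on a different layout")
  oe <- as_oe(m)
  layout <- m$layout
  vals <- list()
  for (chrom in layout$chroms) {
    mat <- oe$matrices[[chrom]]
    n <- nrow(mat)
    u <- which(!contact_mask(m$matrices[[chrom]]))
    if (length(u) < 10) stop("fewer than 10 unmasked bins on ", chrom)
    S <- mat[u, u, drop = FALSE]
    C <- suppressWarnings(stats::cor(S, use = "pairwise.complete.obs"))
    if (any(!is.finite(C)))
      C[!is.finite(C)] <- 0
    if (all(abs(C - C[1, 1]) < 1e-12))
      stop("degenerate correlation matrix on ", chrom)
    eg <- eigen(C, symmetric = TRUE)
    e1 <- eg$vectors[, 1] * sqrt(max(eg$values[1], 0))
    gd <- gene_density$values[[chrom]][u]
    mpos <- mean(gd[e1 > 0], na.rm = TRUE)
    mneg <- mean(gd[e1 < 0], na.rm = TRUE)
    if (is.finite(mpos) && is.finite(mneg) && mpos < mneg) e1 <- -e1
    v <- rep(NA_real_, n)
    v[u] <- e1
    vals[[chrom]] <- v
  }
  pc1 <- binned_track(layout, vals)
  structure(list(pc1 = pc1, ab = pc1_to_ab(pc1)), class = "CompartmentCall")
}

## sign runs of a PC1 track -> A/B DomainSet (zero/NA bins excluded)
pc1_to_ab <- function(pc1) {
  layout <- pc1$layout
  rows <- list()
  for (chrom in layout$chroms) {
    v <- pc1$values[[chrom]]
    state <- ifelse(is.na(v) | v == 0, "none", ifelse(v > 0, "A", "B"))
    r <- rle(state)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values != "none"
    if (!any(keep)) next
    rows[[chrom]] <- data.frame(
      chrom = chrom,
      start = (starts[keep] - 1) * layout$bin_bp,
      end = pmin(ends[keep] * layout$bin_bp, layout$lengths[[chrom]]),
      label = r$values[keep])
  }
  if (!length(rows)) return(domain_set(layout = layout, label = character(0)))
  df <- do.call(rbind, rows)
  domain_set(df$chrom, df$start, df$end, df$label, layout)
}

## per-chromosome list of valid (finite pc1, unmasked) bin indices
pc1_valid_bins <- function(oe, pc1) {
  lapply(stats::setNames(oe$layout$chroms, oe$layout$chroms), function(chrom) {
    v <- pc1$values[[chrom]]
    which(!is.na(v) & !contact_mask(oe$matrices[[chrom]]))
  })
}

#' Saddle enrichment: mean O/E between PC1-ranked bin pairs
#'
#' Bins are ranked genome-wide by PC1 and cut into `n_quantiles` equal-size
#' groups (ties broken by position); cell (p, q) is the mean O/E over all cis
#' pairs with one bin in each group, at separations of at least `min_sep`
#' bins. Quantile 1 is the strongest-B end.
#'
#' @param m_oe an O/E [contact_matrix()] (raw input is converted).
#' @param pc1 a [binned_track()] on the same layout.
#' @param n_quantiles number of PC1 groups (>= 2, default 5).
#' @param min_sep minimum bin separation for pairs (default 2).
#' @return A list of class `SaddleResult`: `mean` (symmetric
#'   `n_quantiles x n_quantiles` matrix), `counts`, `n_quantiles`.
#' @export
saddle <- function(m_oe, pc1, n_quantiles = 5, min_sep = 2) {
  stopifnot(inherits(m_oe, "ContactMatrix"), inherits(pc1, "BinnedTrack"),
            n_quantiles >= 2)
  if (!same_layout(m_oe$layout, pc1$layout)) stop("layout mismatch")
  oe <- as_oe(m_oe)
  valid <- pc1_valid_bins(oe, pc1)
  allpc <- unlist(mapply(function(chrom, idx) pc1$values[[chrom]][idx],
                         names(valid), valid, SIMPLIFY = FALSE))
  ntot <- length(allpc)
  if (ntot < n_quantiles) stop("fewer valid bins than quantiles")
  grp_all <- ceiling(rank(allpc, ties.method = "first") * n_quantiles / ntot)
  sums <- matrix(0, n_quantiles, n_quantiles)
  cnts <- matrix(0, n_quantiles, n_quantiles)
  off <- 0
  for (chrom in names(valid)) {
    idx <- valid[[chrom]]
    if (!length(idx)) next
    g <- grp_all[off + seq_along(idx)]
    off <- off + length(idx)
    mat <- oe$matrices[[chrom]][idx, idx, drop = FALSE]
    sep <- abs(outer(idx, idx, `-`))
    use <- is.finite(mat) & sep >= min_sep
    mat0 <- ifelse(use, mat, 0)
    G <- stats::model.matrix(~ 0 + factor(g, levels = seq_len(n_quantiles)))
    sums <- sums + t(G) %*% mat0 %*% G
    cnts <- cnts + t(G) %*% (use * 1) %*% G
  }
  mean_oe <- ifelse(cnts > 0, sums / cnts, NA_real_)
  dimnames(mean_oe) <- NULL
  structure(list(mean = mean_oe, counts = cnts, n_quantiles = n_quantiles),
            class = "SaddleResult")
}

#' Elementwise difference of two saddle results
#' @param a,b `SaddleResult`s with equal `n_quantiles`.
#' @return Numeric matrix `a$mean - b$mean`.
#' @export
saddle_difference <- function(a, b) {
  stopifnot(inherits(a, "SaddleResult"), inherits(b, "SaddleResult"))
  if (a$n_quantiles != b$n_quantiles) stop("saddle dimensions differ")
  a$mean - b$mean
}

#' Compartmentalization strength per chromosome
#'
#' Strength = `median(AA, BB) / median(AB)` where AA are O/E values between
#' pairs of strong-A bins (top `top_frac` by PC1), BB between strong-B pairs
#' (bottom `top_frac`), and AB between strong-A and strong-B bins; cis pairs
#' at separations of at least `min_sep` bins only.
#'
#' @param m_oe an O/E (or raw) [contact_matrix()].
#' @param pc1 a [binned_track()] on the same layout.
#' @param top_frac fraction of bins in each strong set (default 0.2).
#' @param min_sep minimum bin separation (default 2).
#' @return Named numeric vector, one strength per chromosome.
#' @export
compartmentalization_strength <- function(m_oe, pc1, top_frac = 0.2, min_sep = 2) {
  stopifnot(inherits(m_oe, "ContactMatrix"), inherits(pc1, "BinnedTrack"),
            top_frac > 0, top_frac <= 0.5)
  if (!same_layout(m_oe$layout, pc1$layout)) stop("layout mismatch")
  oe <- as_oe(m_oe)
  valid <- pc1_valid_bins(oe, pc1)
  out <- vapply(names(valid), function(chrom) {
    idx <- valid[[chrom]]
    if (length(idx) < 4) return(NA_real_)
    v <- pc1$values[[chrom]][idx]
    k <- max(1L, floor(top_frac * length(idx)))
    ordv <- order(-v, idx)  # ties broken by bin index
    strongA <- idx[ordv[seq_len(k)]]
    ordv2 <- order(v, idx)
    strongB <- idx[ordv2[seq_len(k)]]
    mat <- oe$matrices[[chrom]]
    pair_vals <- function(set1, set2, within) {
      sub <- mat[set1, set2, drop = FALSE]
      sep <- abs(outer(set1, set2, `-`))
      use <- is.finite(sub) & sep >= min_sep
      if (within) use <- use & outer(set1, set2, `<`)
      sub[use]
    }
    aa <- pair_vals(strongA, strongA, TRUE)
    bb <- pair_vals(strongB, strongB, TRUE)
    ab <- pair_vals(strongA, strongB, FALSE)
    if (!length(ab) || !length(c(aa, bb))) return(NA_real_)
    mab <- stats::median(ab)
    if (mab == 0) stop("median AB contact is zero on ", chrom)
    stats::median(c(aa, bb)) / mab
  }, 0)
  out
}

#' Per-bin interaction score of genome sections
#'
#' For each bin b in section x: `CS = C_x / C_total`, where `C_x` is the mean
#' O/E of b with the other bins of section x on the same chromosome and
#' `C_total` its mean O/E with all other unmasked bins on the chromosome
#' (cis only; pairs closer than `min_sep` bins excluded). Chromosomes where a
#' section has fewer than 2 bins are masked for that section.
#'
#' @param m_oe an O/E (or raw) [contact_matrix()].
#' @param sections a [domain_set()] whose labels define the sections; bins
#'   are labeled by majority overlap.
#' @param min_sep minimum bin separation (default 2).
#' @return Named list of [binned_track()]s, one per section label, with CS
#'   values at that section's bins and `NA` elsewhere.
#' @export
interaction_score <- function(m_oe, sections, min_sep = 2) {
  stopifnot(inherits(m_oe, "ContactMatrix"), inherits(sections, "DomainSet"))
  oe <- as_oe(m_oe)
  layout <- oe$layout
  labels <- bin_labels(sections, layout)
  secs <- sort(unique(sections$label))
  out <- lapply(stats::setNames(secs, secs), function(s) binned_track(layout))
  for (chrom in layout$chroms) {
    mat <- oe$matrices[[chrom]]
    n <- nrow(mat)
    mask <- contact_mask(m_oe$matrices[[chrom]])
    lab <- labels[[chrom]]
    for (s in secs) {
      inset <- which(!mask & !is.na(lab) & lab == s)
      if (length(inset) < 2) next
      vals <- out[[s]]$values[[chrom]]
      for (b in inset) {
        others <- which(!mask & abs(seq_len(n) - b) >= min_sep)
        row <- mat[b, others]
        fin <- is.finite(row)
        if (!any(fin)) next
        c_total <- mean(row[fin])
        same <- others %in% inset
        if (!any(fin & same)) next
        c_x <- mean(row[fin & same])
        if (c_total != 0) vals[b] <- c_x / c_total
      }
      out[[s]]$values[[chrom]] <- vals
    }
  }
  out
}

#' Insulation score along the diagonal
#'
#' For each bin, the mean contact count in the square window spanning
#' `window_bp` upstream x downstream of the bin (the classic
#' insulation-square statistic), log2-normalized to the chromosome mean.
#' Bins whose window does not fit inside the chromosome are masked.
#'
#' @param m a [contact_matrix()] (raw or balanced).
#' @param window_bp square half-width in bp; multiple of the bin width.
#' @return A [binned_track()] of log2 relative insulation.
#' @export
insulation_track <- function(m, window_bp) {
  stopifnot(inherits(m, "ContactMatrix"))
  w <- check_window(m$layout, window_bp)
  vals <- lapply(m$layout$chroms, function(chrom) {
    mat <- m$matrices[[chrom]]
    n <- nrow(mat)
    if (2 * w + 1 > n) stop("window exceeds chromosome ", chrom)
    ins <- rep(NA_real_, n)
    for (b in (w + 1):(n - w)) {
      sub <- mat[(b - w):(b - 1), (b + 1):(b + w), drop = FALSE]
      if (all(is.na(sub))) next
      ins[b] <- mean(sub, na.rm = TRUE)
    }
    mu <- mean(ins[is.finite(ins) & ins > 0])
    out <- log2(ins / mu)
    out[!is.finite(out)] <- NA_real_
    out
  })
  names(vals) <- m$layout$chroms
  binned_track(m$layout, vals)
}

#' Detect insulation boundaries (local minima)
#'
#' Boundaries are local minima of the insulation track whose strength (see
#' [boundary_strength()]) reaches `min_strength`.
#'
#' @param insulation a [binned_track()] from [insulation_track()].
#' @param min_strength minimum boundary strength in log2 units (default 0.1).
#' @return A [domain_set()] of one-bin boundary intervals labeled
#'   `"boundary"`.
#' @export
find_boundaries <- function(insulation, min_strength = 0.1) {
  stopifnot(inherits(insulation, "BinnedTrack"))
  layout <- insulation$layout
  rows <- list()
  for (chrom in layout$chroms) {
    v <- insulation$values[[chrom]]
    mins <- local_minima(v)
    if (!length(mins)) next
    st <- vapply(mins, function(b) minimum_strength(v, b), 0)
    keep <- st >= min_strength
    if (!any(keep)) next
    b <- mins[keep]
    rows[[chrom]] <- data.frame(
      chrom = chrom, start = (b - 1) * layout$bin_bp,
      end = pmin(b * layout$bin_bp, layout$lengths[[chrom]]))
  }
  if (!length(rows)) return(domain_set(layout = layout, label = character(0)))
  df <- do.call(rbind, rows)
  domain_set(df$chrom, df$start, df$end, "boundary", layout)
}

local_minima <- function(v) {
  n <- length(v)
  which(vapply(seq_len(n), function(i) {
    if (is.na(v[i]) || i == 1 || i == n) return(FALSE)
    !is.na(v[i - 1]) && !is.na(v[i + 1]) && v[i] < v[i - 1] && v[i] <= v[i + 1]
  }, TRUE))
}

## depth of the minimum at bin b relative to the nearest flanking maxima:
## mean of the running maxima reached before the profile turns down again
minimum_strength <- function(v, b) {
  climb <- function(dir) {
    best <- v[b]
    i <- b + dir
    while (i >= 1 && i <= length(v) && !is.na(v[i]) && v[i] >= best) {
      best <- v[i]
      i <- i + dir
    }
    best
  }
  mean(c(climb(-1L), climb(1L))) - v[b]
}

#' Strength of given insulation boundaries
#'
#' Strength of a boundary is the depth of its insulation minimum relative to
#' the nearest flanking maxima (mean of the two sides), in log2 units.
#'
#' @param insulation a [binned_track()] from [insulation_track()].
#' @param boundaries a [domain_set()] of boundary intervals (their midpoints
#'   locate the minima).
#' @return Numeric vector, one strength per boundary.
#' @export
boundary_strength <- function(insulation, boundaries) {
  stopifnot(inherits(insulation, "BinnedTrack"), inherits(boundaries, "DomainSet"))
  layout <- insulation$layout
  vapply(seq_len(nrow(boundaries)), function(k) {
    chrom <- boundaries$chrom[k]
    mid <- (boundaries$start[k] + boundaries$end[k]) / 2
    b <- floor(mid / layout$bin_bp) + 1L
    v <- insulation$values[[chrom]]
    if (is.na(v[b])) return(NA_real_)
    minimum_strength(v, b)
  }, 0)
}

#' Classify boundaries by flanking compartment
#'
#' @param boundaries a [domain_set()] of boundaries.
#' @param ab a [domain_set()] with labels `A`/`B`.
#' @param flank_bp how far on each side to read the compartment label
#'   (default one boundary width).
#' @return Character vector per boundary: `"within-A"`, `"within-B"`,
#'   `"A-B"`, or `NA` when a side is unlabeled.
#' @export
classify_boundaries <- function(boundaries, ab, flank_bp = NULL) {
  stopifnot(inherits(boundaries, "DomainSet"), inherits(ab, "DomainSet"))
  vapply(seq_len(nrow(boundaries)), function(k) {
    w <- if (is.null(flank_bp)) boundaries$end[k] - boundaries$start[k] else flank_bp
    left <- locate_label(ab, boundaries$chrom[k], max(boundaries$start[k] - w / 2, 0))
    right <- locate_label(ab, boundaries$chrom[k],
                          min(boundaries$end[k] + w / 2,
                              domain_layout(ab)$lengths[[boundaries$chrom[k]]] - 1))
    if (is.na(left) || is.na(right)) return(NA_character_)
    if (left == right) paste0("within-", left) else "A-B"
  }, "")
}

#' Aggregate a contact matrix to a coarser resolution
#'
#' Counts are summed into the coarser bins (appropriate for raw counts).
#'
#' @param m a raw [contact_matrix()].
#' @param new_bin_bp target resolution; positive multiple of the current one.
#' @return A [contact_matrix()] at the new resolution.
#' @export
rebin_contacts <- function(m, new_bin_bp) {
  stopifnot(inherits(m, "ContactMatrix"))
  old <- m$layout$bin_bp
  if (new_bin_bp %% old != 0 || new_bin_bp <= 0)
    stop("new_bin_bp must be a positive multiple of the current bin width")
  layout2 <- genome_layout(m$layout$lengths, new_bin_bp)
  mats <- lapply(m$layout$chroms, function(chrom) {
    mat <- m$matrices[[chrom]]
    n <- nrow(mat)
    grp <- floor(((seq_len(n) - 1) * old) / new_bin_bp) + 1L
    n2 <- n_bins(layout2, chrom)[[1]]
    G <- matrix(0, n, n2)
    G[cbind(seq_len(n), grp)] <- 1
    m0 <- mat
    m0[is.na(m0)] <- 0
    t(G) %*% m0 %*% G
  })
  names(mats) <- m$layout$chroms
  contact_matrix(layout2, mats, flag = m$flag)
}
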