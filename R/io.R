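## Readers/writers for the plain-text formats at the package boundary:
## 4-column bedGraph for tracks, BED3+label for domains, 4-column triples for
## cis contact matrices, TSV for gene tables. All readers are gzip-transparent
## (gzfile() also reads uncompressed files).

read_body_lines <- function(path) {
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  keep <- !grepl("^\\s*($|#|track\\b|browser\\b)", lines)
  list(lines = lines[keep], lineno = which(keep))
}

parse_columns <- function(path, n_col) {
  body <- read_body_lines(path)
  if (!length(body$lines))
    return(list(fields = matrix(character(), 0, n_col), lineno = integer()))
  fields <- strsplit(trimws(body$lines), "[\t ]+")
  bad <- which(lengths(fields) < n_col)
  if (length(bad))
    stop(sprintf("%s line %d: expected %d columns, found %d",
                 path, body$lineno[bad[1]], n_col, lengths(fields)[bad[1]]))
  mat <- matrix(unlist(lapply(fields, `[`, seq_len(n_col))),
                ncol = n_col, byrow = TRUE)
  list(fields = mat, lineno = body$lineno)
}

num_col <- function(mat, j, path, lineno, what) {
  v <- suppressWarnings(as.numeric(mat[, j]))
  bad <- which(is.na(v) & !is.na(mat[, j]))
  if (length(bad))
    stop(sprintf("%s line %d: malformed %s '%s'", path, lineno[bad[1]], what, mat[bad[1], j]))
  v
}

#' Read a bedGraph file into a binned track
#'
#' Interval values are averaged into fixed-width bins weighted by overlap
#' length; bins with no coverage are masked. Input intervals may be irregular
#' and need not be bin-aligned.
#'
#' @param path bedGraph file (4 columns: chrom, start, end, value); plain or
#'   gzipped.
#' @param layout a [genome_layout()] naming the expected chromosomes.
#' @param bin_bp bin width for the output track; default the layout's.
#' @return A [binned_track()].
#' @export
read_bedgraph <- function(path, layout, bin_bp = layout$bin_bp) {
  stopifnot(inherits(layout, "GenomeLayout"))
  if (bin_bp != layout$bin_bp) layout <- genome_layout(layout$lengths, bin_bp)
  p <- parse_columns(path, 4L)
  track <- binned_track(layout)
  if (!nrow(p$fields)) return(track)
  chrom <- p$fields[, 1]
  unknown <- !chrom %in% layout$chroms
  if (any(unknown))
    stop(sprintf("%s line %d: unknown chromosome '%s'",
                 path, p$lineno[which(unknown)[1]], chrom[which(unknown)[1]]))
  s <- num_col(p$fields, 2, path, p$lineno, "start")
  e <- num_col(p$fields, 3, path, p$lineno, "end")
  v <- num_col(p$fields, 4, path, p$lineno, "value")
  bad <- which(e <= s | s < 0)
  if (length(bad))
    stop(sprintf("%s line %d: invalid interval [%g, %g)", path, p$lineno[bad[1]], s[bad[1]], e[bad[1]]))
  over <- e > layout$lengths[chrom]
  if (any(over))
    stop(sprintf("%s line %d: interval end %g beyond %s length %g",
                 path, p$lineno[which(over)[1]], e[which(over)[1]],
                 chrom[which(over)[1]], layout$lengths[[chrom[which(over)[1]]]]))
  bw <- layout$bin_bp
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    cs <- s[sel]; ce <- e[sel]; cv <- v[sel]
    b0 <- floor(cs / bw)
    b1 <- floor((ce - 1) / bw)
    nspan <- b1 - b0 + 1
    ri <- rep(seq_along(cs), nspan)
    bin <- b0[ri] + sequence(nspan) - 1
    bs <- bin * bw
    be <- pmin(bs + bw, layout$lengths[[ch]])
    ov <- pmin(ce[ri], be) - pmax(cs[ri], bs)
    agg <- rowsum(cbind(ov, ov * cv[ri]), group = bin)
    idx <- as.integer(rownames(agg)) + 1L
    vals <- track$values[[ch]]
    vals[idx] <- agg[, 2] / agg[, 1]
    track$values[[ch]] <- vals
  }
  track
}

#' Write a binned track as bedGraph
#'
#' Masked bins are omitted. Runs of equal-valued adjacent bins are not
#' collapsed, so a written track re-reads to the identical values.
#'
#' @param track a [binned_track()].
#' @param path output file path (gzipped when ending in `.gz`).
#' @param digits significant digits for values (default 6).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, digits = 6) {
  stopifnot(inherits(track, "BinnedTrack"))
  layout <- track$layout
  lines <- character(0)
  for (chrom in layout$chroms) {
    v <- track$values[[chrom]]
    ok <- which(!is.na(v))
    if (!length(ok)) next
    bb <- bin_bounds(layout, chrom)
    lines <- c(lines, sprintf("%s\t%d\t%d\t%s", chrom,
                              as.integer(bb$start[ok]), as.integer(bb$end[ok]),
                              formatC(v[ok], digits = digits, format = "g")))
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a BED file into a DomainSet
#'
#' Expects BED3 or BED4 (chrom, start, end, optional label); 0-based
#' half-open. Overlapping intervals sharing a label are an error.
#'
#' @param path BED file, plain or gzipped.
#' @param layout a [genome_layout()].
#' @param default_label label used when column 4 is absent.
#' @return A [domain_set()].
#' @export
read_bed <- function(path, layout, default_label = "domain") {
  stopifnot(inherits(layout, "GenomeLayout"))
  body <- read_body_lines(path)
  if (!length(body$lines))
    return(domain_set(layout = layout, label = character(0)))
  fields <- strsplit(trimws(body$lines), "[\t ]+")
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop(sprintf("%s line %d: expected at least 3 columns", path, body$lineno[bad[1]]))
  chrom <- vapply(fields, `[`, "", 1)
  s <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2)))
  e <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3)))
  bad <- which(is.na(s) | is.na(e))
  if (length(bad))
    stop(sprintf("%s line %d: malformed coordinates", path, body$lineno[bad[1]]))
  lab <- vapply(fields, function(f) if (length(f) >= 4) f[4] else default_label, "")
  domain_set(chrom, s, e, lab, layout)
}

#' Write a DomainSet as BED
#'
#' @param domains a [domain_set()].
#' @param path output file path (gzipped when ending in `.gz`).
#' @return `path`, invisibly.
#' @export
write_bed <- function(domains, path) {
  stopifnot(inherits(domains, "DomainSet"))
  lines <- if (nrow(domains) == 0) "# empty DomainSet" else
    sprintf("%s\t%d\t%d\t%s", domains$chrom, as.integer(domains$start),
            as.integer(domains$end), domains$label)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read cis contact triples into a ContactMatrix
#'
#' Input is 4 columns: chrom, binA_start, binB_start, count; bin starts must
#' be multiples of the layout bin width. The matrix is symmetrized (each
#' triple fills both (i, j) and (j, i)).
#'
#' @param path triples file, plain or gzipped.
#' @param layout a [genome_layout()] at the matrix resolution.
#' @return A [contact_matrix()] with flag `"raw"`.
#' @export
read_contacts <- function(path, layout) {
  stopifnot(inherits(layout, "GenomeLayout"))
  p <- parse_columns(path, 4L)
  nb <- n_bins(layout)
  mats <- lapply(nb, function(n) matrix(0, n, n))
  if (nrow(p$fields)) {
    chrom <- p$fields[, 1]
    unknown <- !chrom %in% layout$chroms
    if (any(unknown))
      stop(sprintf("%s line %d: unknown chromosome '%s'",
                   path, p$lineno[which(unknown)[1]], chrom[which(unknown)[1]]))
    a <- num_col(p$fields, 2, path, p$lineno, "binA_start")
    b <- num_col(p$fields, 3, path, p$lineno, "binB_start")
    cnt <- num_col(p$fields, 4, path, p$lineno, "count")
    bw <- layout$bin_bp
    if (any(a %% bw != 0 | b %% bw != 0))
      stop("bin starts must be multiples of the layout bin width")
    for (ch in unique(chrom)) {
      sel <- chrom == ch
      i <- a[sel] / bw + 1L
      j <- b[sel] / bw + 1L
      if (any(i > nb[[ch]] | j > nb[[ch]]))
        stop(sprintf("bin start beyond %s in %s", ch, path))
      m <- mats[[ch]]
      m[cbind(i, j)] <- cnt[sel]
      m[cbind(j, i)] <- cnt[sel]
      mats[[ch]] <- m
    }
  }
  contact_matrix(layout, mats, flag = "raw")
}

#' Write a ContactMatrix as upper-triangle contact triples
#'
#' @param m a [contact_matrix()].
#' @param path output file path (gzipped when ending in `.gz`).
#' @param digits significant digits for counts.
#' @return `path`, invisibly.
#' @export
write_contacts <- function(m, path, digits = 6) {
  stopifnot(inherits(m, "ContactMatrix"))
  layout <- m$layout
  bw <- layout$bin_bp
  lines <- character(0)
  for (chrom in layout$chroms) {
    mat <- m$matrices[[chrom]]
    ut <- which(upper.tri(mat, diag = TRUE) & !is.na(mat) & mat != 0, arr.ind = TRUE)
    if (!nrow(ut)) next
    lines <- c(lines, sprintf("%s\t%d\t%d\t%s", chrom,
                              as.integer((ut[, 1] - 1) * bw),
                              as.integer((ut[, 2] - 1) * bw),
                              formatC(mat[ut], digits = digits, format = "g")))
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a gene table TSV
#'
#' Expects a header with at least `id`, `chrom`, `start`, `end`, `strand`,
#' `base_mean`, `log2fc`, `padj`. Differential-expression flags are derived
#' from the stored thresholds via [make_gene_table()].
#'
#' @param path TSV file, plain or gzipped.
#' @param layout a [genome_layout()].
#' @param lfc_cut,padj_cut significance thresholds for the DE flag.
#' @return A `GeneTable` data frame (see [make_gene_table()]).
#' @export
read_gene_table <- function(path, layout, lfc_cut = 1, padj_cut = 0.05) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("id", "chrom", "start", "end", "strand", "base_mean", "log2fc", "padj")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("gene table missing column(s): ", paste(miss, collapse = ", "))
  make_gene_table(df, layout, lfc_cut = lfc_cut, padj_cut = padj_cut)
}

#' Write a gene table TSV
#' @param genes a `GeneTable`.
#' @param path output file path.
#' @param digits significant digits for numeric columns.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path, digits = 6) {
  df <- as.data.frame(genes)
  for (j in names(df)) if (is.numeric(df[[j]]) && !all(df[[j]] == floor(df[[j]]), na.rm = TRUE))
    df[[j]] <- formatC(df[[j]], digits = digits, format = "g")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
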