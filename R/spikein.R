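#' Spike-in scale factor from unique-mapping read counts
#'
#' Exogenous spike-in chromatin (e.g. human HeLa cells mixed into the mouse
#' sample before ChIP) calibrates signal between conditions: the scale factor
#' is the exogenous fraction of unique-mapping reads,
#' rho = exogenous / (exogenous + endogenous). Dividing a sample's coverage by
#' its rho makes conditions quantitatively comparable even under global loss
#' of the mark.
#'
#' @param reads_exogenous unique-mapping read count on the spike-in genome.
#' @param reads_endogenous unique-mapping read count on the target genome.
#' @return rho in (0, 1).
#' @examples
#' spikein_scale_factor(1e6, 4e6)  # 0.2
#' @export
spikein_scale_factor <- function(reads_exogenous, reads_endogenous) {
  if (!is.numeric(reads_exogenous) || !is.numeric(reads_endogenous) ||
      length(reads_exogenous) != 1L || length(reads_endogenous) != 1L)
    stop("read counts must be scalars")
  if (reads_exogenous < 0 || reads_endogenous < 0)
    stop("read counts must be non-negative")
  if (reads_exogenous == 0)
    stop("zero exogenous reads: cannot calibrate")
  reads_exogenous / (reads_exogenous + reads_endogenous)
}

#' Divide a coverage track by a spike-in scale factor
#'
#' @param track a [binned_track()].
#' @param rho positive scale factor (see [spikein_scale_factor()]).
#' @return The scaled track; the mask is unchanged.
#' @export
apply_spikein <- function(track, rho) {
  stopifnot(inherits(track, "BinnedTrack"))
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) || rho <= 0)
    stop("rho must be a positive scalar")
  track_map(track, function(x) x / rho)
}

#' Log2 ratio of IP over input signal
#'
#' @param ip,input [binned_track()]s on the same layout; input must be
#'   non-negative.
#' @param pseudocount added to both numerator and denominator (default 1).
#' @return A [binned_track()] of `log2((ip + pc) / (input + pc))`; bins
#'   masked where either operand is masked.
#' @export
log2_ip_over_input <- function(ip, input, pseudocount = 1) {
  stopifnot(inherits(ip, "BinnedTrack"), inherits(input, "BinnedTrack"))
  if (!is.numeric(pseudocount) || pseudocount <= 0)
    stop("pseudocount must be positive")
  if (any(unlist(input$values) < 0, na.rm = TRUE))
    stop("negative input values")
  track_map2(ip, input, function(x, y) log2((x + pseudocount) / (y + pseudocount)))
}

#' Read a spike-in counts TSV
#'
#' Expects header columns `sample`, `reads_exogenous`, `reads_endogenous`.
#'
#' @param path TSV file.
#' @return Data frame with an added `rho` column.
#' @export
read_spikein_counts <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample", "reads_exogenous", "reads_endogenous")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("spike-in table missing column(s): ", paste(miss, collapse = ", "))
  df$rho <- mapply(spikein_scale_factor, df$reads_exogenous, df$reads_endogenous)
  df
}
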