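# Per-residue score tracks: aggregation of k-mer calls, region calling
# at a score cutoff, peptide expansion, and SPOT reactivity tracks.

#' Aggregate k-mer predictions to a per-residue score track
#'
#' The default aggregation is the fraction of covering k-mers that are
#' predicted positive: `score(i) = positives covering i / k-mers
#' covering i`, 0 for residues covered by no k-mer.  The alternative
#' `"mean_prob"` averages the predicted probabilities of the covering
#' k-mers instead of thresholding them.
#'
#' @param kmers K-mer data frame with columns `start`, `k` and `prob`
#'   (predicted epitope probability).
#' @param L Antigen sequence length.
#' @param kmer_cutoff Probability at or above which a k-mer counts as
#'   positive (default 0.5; used by the `"fraction"` aggregation).
#' @param aggregate `"fraction"` (default) or `"mean_prob"`.
#' @return Numeric score track of length `L`, values in \[0, 1\].
#' @export
residue_scores <- function(kmers, L, kmer_cutoff = 0.5,
                           aggregate = c("fraction", "mean_prob")) {
  aggregate <- match.arg(aggregate)
  s <- kmers$start; e <- kmers$start + kmers$k - 1L
  if (nrow(kmers) && (any(s < 1L) || any(e > L)))
    stop("k-mer outside [1, ", L, "]")
  cover <- numeric(L + 1L); hit <- numeric(L + 1L)
  w <- if (aggregate == "fraction") as.numeric(kmers$prob >= kmer_cutoff)
       else kmers$prob
  # difference-array accumulation of interval coverage
  for (i in seq_len(nrow(kmers))) {
    cover[s[i]] <- cover[s[i]] + 1
    if (e[i] < L) cover[e[i] + 1L] <- cover[e[i] + 1L] - 1
    hit[s[i]] <- hit[s[i]] + w[i]
    if (e[i] < L) hit[e[i] + 1L] <- hit[e[i] + 1L] - w[i]
  }
  cov <- cumsum(cover[seq_len(L)])
  num <- cumsum(hit[seq_len(L)])
  ifelse(cov > 0, num / cov, 0)
}

#' Call epitope regions from a score track
#'
#' Maximal runs of consecutive residues with score at or above the
#' cutoff; runs shorter than `min_length` are discarded.  The default
#' cutoff of 0.2 is the operating point used to classify a sequence as
#' positive; `min_length` 3 matches the smallest k-mer.
#'
#' @param track Numeric per-residue score track in \[0, 1\].
#' @param cutoff Score threshold in \[0, 1\] (default 0.2).
#' @param min_length Minimum region length (default 3).
#' @return Data frame with columns `start`, `end`, `label`
#'   (`"predicted"`) and `mean_score`, sorted by `start`.
#' @export
call_regions <- function(track, cutoff = 0.2, min_length = 3L) {
  check_track(track)
  if (cutoff < 0 || cutoff > 1) stop("cutoff must lie in [0, 1]")
  r <- rle(track >= cutoff)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_length
  out <- data.frame(start = as.integer(starts[keep]),
                    end = as.integer(ends[keep]),
                    label = rep("predicted", sum(keep)),
                    mean_score = vapply(which(keep), function(i)
                      mean(track[starts[i]:ends[i]]), 0))
  out[order(out$start), , drop = FALSE]
}

#' Expand a region towards a synthesis-ready peptide
#'
#' Pads the region by `pad` residues on each side, clamped to
#' \[1, L\]; a 9-residue core with the default pad of 3 becomes a
#' 15-residue peptide.  Never shrinks a region, and re-applying the
#' expansion at the sequence borders is idempotent.
#'
#' @param start,end 1-based inclusive region coordinates.
#' @param L Antigen sequence length.
#' @param pad Residues added to each border (default 3).
#' @return Named integer vector `c(start, end)`.
#' @examples
#' expand_region(11, 19, L = 202)  # 8..22, a 15-mer
#' @export
expand_region <- function(start, end, L, pad = 3L) {
  stopifnot(start >= 1L, start <= end, end <= L, pad >= 0L)
  c(start = max(1L, as.integer(start - pad)),
    end = min(as.integer(L), as.integer(end + pad)))
}

#' Reactivity track from a SPOT peptide array
#'
#' SPOT membranes tile an antigen with overlapping pentadecapeptides
#' frame-shifted by 3 residues.  The reactivity score of residue `i` is
#' the number of reactive spots covering it, scaled so the maximum is
#' exactly 1 (all-zero track if no spot is reactive).
#'
#' @param spots Data frame with columns `start` (1-based spot start) and
#'   `reactive` (logical).
#' @param L Antigen sequence length.
#' @param length Spot peptide length (default 15).
#' @param stride Frame shift between consecutive spots (default 3; spot
#'   starts must be on this lattice).
#' @return Numeric score track of length `L` in \[0, 1\].
#' @export
spot_track <- function(spots, L, length = 15L, stride = 3L) {
  stopifnot(all(c("start", "reactive") %in% names(spots)))
  s <- as.integer(spots$start)
  if (any(s < 1L) || any(s + length - 1L > L))
    stop("spot outside [1, ", L, "]")
  if (any((s - 1L) %% stride != 0L))
    stop("spot starts must lie on the stride-", stride, " lattice")
  raw <- numeric(L)
  for (i in which(as.logical(spots$reactive))) {
    idx <- s[i]:(s[i] + length - 1L)
    raw[idx] <- raw[idx] + 1
  }
  m <- max(raw)
  if (m > 0) raw / m else raw
}

#' Tile an antigen with SPOT peptides
#'
#' @param L Antigen sequence length.
#' @param length Spot length (default 15).
#' @param stride Frame shift (default 3).
#' @return Data frame of spot `start` positions (all non-reactive).
#' @export
spot_tiling <- function(L, length = 15L, stride = 3L) {
  if (L < length) return(data.frame(start = integer(), reactive = logical()))
  data.frame(start = seq.int(1L, L - length + 1L, by = stride),
             reactive = FALSE)
}
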