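# Frame-shifted k-mer decomposition and overlap labeling.
#
# A k-mer inherits a class from the interval annotations of its antigen
# under one of three rules:
#   any_overlap      - a single residue of the class suffices
#   majority         - >= 50% of the k-mer's residues (ties count)
#   full_containment - every residue must belong to the class
# The epitope test takes precedence when both classes reach the bar.

KMER_RULES <- c("majority", "any_overlap", "full_containment")

#' Generate frame-shifted k-mers
#'
#' Enumerates, for every k in `k_min..k_max`, all substrings starting at
#' offsets 1, 1+step, 2*step+1, ... that fit inside the sequence.  For
#' step 1 the total count is `sum over k of max(0, L - k + 1)`.
#'
#' @param a An [antigen()] (or a plain sequence string, in which case
#'   `id` defaults to `"seq"`).
#' @param k_min,k_max Inclusive k-mer length range (default 3 to 15).
#' @param step Frame shift between consecutive offsets (default 1).
#' @return Data frame with columns `antigen_id`, `start` (1-based),
#'   `k`, `sequence`, ordered by `k` then `start`.
#' @examples
#' nrow(generate_kmers(antigen("x", "SYVDLFIRETDFLSLDE")))  # 117
#' @export
generate_kmers <- function(a, k_min = 3L, k_max = 15L, step = 1L) {
  if (is.character(a)) a <- antigen("seq", a)
  stopifnot(k_min >= 1L, k_max >= k_min, step >= 1L)
  L <- nchar(a$sequence)
  pieces <- lapply(seq.int(k_min, k_max), function(k) {
    if (L < k) return(NULL)
    starts <- seq.int(1L, L - k + 1L, by = step)
    data.frame(antigen_id = a$id, start = starts, k = as.integer(k),
               sequence = substring(a$sequence, starts, starts + k - 1L))
  })
  out <- do.call(rbind, pieces)
  if (is.null(out))
    out <- data.frame(antigen_id = character(), start = integer(),
                      k = integer(), sequence = character())
  rownames(out) <- NULL
  out
}

#' Label k-mers against an antigen's annotations
#'
#' Computes, for each k-mer, the fraction of its residues covered by the
#' union of epitope regions (`overlap_fraction`) and by nonepitope
#' regions, and assigns a class under the chosen rule.  Residues covered
#' by neither annotation count toward neither class but stay in the
#' denominator `k`.
#'
#' @param kmers Data frame from [generate_kmers()].
#' @param a The [antigen()] the k-mers came from (supplies the regions).
#' @param rule One of `"majority"` (>= 50% of residues, ties included),
#'   `"any_overlap"` (> 0), `"full_containment"` (= 1).
#' @return `kmers` with columns `overlap_fraction`, `nonepitope_fraction`
#'   and `label` (`"epitope"`, `"nonepitope"` or `"unassigned"`) added.
#' @export
label_kmers <- function(kmers, a, rule = c("majority", "any_overlap",
                                           "full_containment")) {
  rule <- match.arg(rule)
  lab <- residue_labels(a)
  cs_epi <- cumsum(c(0L, lab == "epitope"))
  cs_non <- cumsum(c(0L, lab == "nonepitope"))
  s <- kmers$start; e <- kmers$start + kmers$k - 1L
  if (nrow(kmers) && (any(s < 1L) || any(e > nchar(a$sequence))))
    stop("k-mer outside antigen '", a$id, "'")
  fe <- (cs_epi[e + 1L] - cs_epi[s]) / kmers$k
  fn <- (cs_non[e + 1L] - cs_non[s]) / kmers$k
  hit <- switch(rule,
    majority         = list(fe >= 0.5, fn >= 0.5),
    any_overlap      = list(fe > 0,    fn > 0),
    full_containment = list(fe == 1,   fn == 1))
  label <- rep("unassigned", nrow(kmers))
  label[hit[[2]]] <- "nonepitope"
  label[hit[[1]]] <- "epitope"       # epitope precedence
  kmers$overlap_fraction <- fe
  kmers$nonepitope_fraction <- fn
  kmers$label <- label
  kmers
}

#' Build the labeled k-mer set over an annotated antigen panel
#'
#' Concatenates [generate_kmers()] + [label_kmers()] over all antigens.
#'
#' @param antigens List of annotated [antigen()] objects.
#' @param rule Labeling rule, see [label_kmers()].
#' @param k_min,k_max,step See [generate_kmers()].
#' @param drop_unassigned Drop k-mers labeled `"unassigned"` (default
#'   `FALSE`; training drops them downstream).
#' @return Data frame of labeled k-mers across the panel.
#' @export
build_labeled_set <- function(antigens, rule = "majority",
                              k_min = 3L, k_max = 15L, step = 1L,
                              drop_unassigned = FALSE) {
  antigens <- as_antigen_list(antigens)
  if (!any(vapply(antigens, function(a) nrow(a$regions) > 0L, TRUE)))
    stop("no annotated regions in any antigen; nothing to label")
  out <- do.call(rbind, lapply(antigens, function(a)
    label_kmers(generate_kmers(a, k_min, k_max, step), a, rule)))
  rownames(out) <- NULL
  if (drop_unassigned) out <- out[out$label != "unassigned", , drop = FALSE]
  out
}

# Closed-form k-mer count for stride `step`; used for validation and by
# callers sizing allocations.
kmer_count <- function(L, k_min = 3L, k_max = 15L, step = 1L) {
  ks <- seq.int(k_min, k_max)
  sum(pmax(0L, (L - ks) %/% step + 1L) * (ks <= L))
}
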