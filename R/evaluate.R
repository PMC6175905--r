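# Per-residue evaluation: confusion counts, ROC/AUC, Cohen's kappa,
# cutoff policies, and method-comparison tables.  The evaluation unit
# is the residue: predicted score tracks are compared against
# experimentally mapped epitope regions position by position, with
# every residue outside an epitope region counted as a negative.

truth_vector <- function(a_or_regions, L = NULL) {
  if (inherits(a_or_regions, "antigen")) {
    L <- nchar(a_or_regions$sequence)
    r <- a_or_regions$regions
  } else r <- a_or_regions
  stopifnot(!is.null(L))
  truth <- rep(FALSE, L)
  for (i in which(r$label == "epitope")) truth[r$start[i]:r$end[i]] <- TRUE
  truth
}

#' Residue-level confusion counts
#'
#' @param track Per-residue score track.
#' @param truth An [antigen()] with epitope regions, or a logical
#'   per-residue truth vector.
#' @param cutoff Score at or above which a residue is called positive.
#' @return Named numeric vector `c(tp, fp, tn, fn)`; the four counts sum
#'   to the sequence length.
#' @export
confusion_counts <- function(track, truth, cutoff) {
  if (!is.logical(truth)) truth <- truth_vector(truth)
  if (length(track) != length(truth))
    stop("track length ", length(track),
         " does not match truth length ", length(truth))
  pred <- track >= cutoff
  c(tp = sum(pred & truth), fp = sum(pred & !truth),
    tn = sum(!pred & !truth), fn = sum(!pred & truth))
}

metrics_from_confusion <- function(cc) {
  tp <- cc[["tp"]]; fp <- cc[["fp"]]; tn <- cc[["tn"]]; fn <- cc[["fn"]]
  c(accuracy = (tp + tn) / sum(cc),
    tpr = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    specificity = if (fp + tn > 0) tn / (fp + tn) else NA_real_,
    kappa = cohen_kappa(tp, fp, tn, fn))
}

#' Cohen's kappa from confusion counts
#'
#' `(p_o - p_e) / (1 - p_e)` with the standard marginal chance
#' agreement.
#'
#' @param tp,fp,tn,fn Confusion counts.
#' @return Kappa in \[-1, 1\] (`NA` in the degenerate `p_e = 1` case).
#' @examples
#' cohen_kappa(40, 10, 40, 10)  # 0.6
#' @export
cohen_kappa <- function(tp, fp, tn, fn) {
  n <- tp + fp + tn + fn
  stopifnot(n > 0)
  po <- (tp + tn) / n
  pe <- ((tp + fp) / n) * ((tp + fn) / n) +
    ((tn + fn) / n) * ((tn + fp) / n)
  if (abs(1 - pe) < 1e-15) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' ROC curve and AUC of a score track
#'
#' Sweeps the cutoff over all distinct scores (plus the trivial
#' endpoints) and integrates the curve by the trapezoidal rule; the
#' result equals the pairwise-ranking probability that a random
#' positive residue outscores a random negative one, ties counted 1/2.
#'
#' @param track Per-residue score track.
#' @param truth An [antigen()] with epitope regions, or a logical truth
#'   vector containing at least one positive and one negative.
#' @return List with `curve` (data frame `fpr`, `tpr`, `cutoff`, from
#'   (0,0) to (1,1)) and `auc`.
#' @export
roc_auc <- function(track, truth) {
  if (!is.logical(truth)) truth <- truth_vector(truth)
  stopifnot(length(track) == length(truth))
  n_pos <- sum(truth); n_neg <- sum(!truth)
  if (n_pos == 0L || n_neg == 0L)
    stop("degenerate truth: need at least one positive and one negative")
  cuts <- sort(unique(track), decreasing = TRUE)
  tpr <- vapply(cuts, function(ct) sum(track >= ct & truth) / n_pos, 0)
  fpr <- vapply(cuts, function(ct) sum(track >= ct & !truth) / n_neg, 0)
  curve <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1),
                      cutoff = c(Inf, cuts, -Inf))
  auc <- sum(diff(curve$fpr) * (head(curve$tpr, -1) + curve$tpr[-1]) / 2)
  list(curve = curve, auc = auc)
}

#' Select an operating cutoff under a policy
#'
#' `"max_precision"` returns the cutoff maximizing precision (ties
#' resolved towards higher specificity, then higher sensitivity);
#' `"max_auc_point"` returns the Youden-optimal cutoff maximizing
#' `TPR - FPR`; `"default"` returns `default_cutoff` unchanged.
#'
#' @param track,truth As in [roc_auc()].
#' @param policy One of `"default"`, `"max_precision"`,
#'   `"max_auc_point"`.
#' @param default_cutoff Cutoff returned under the `"default"` policy
#'   (default 0.2).
#' @return The selected cutoff.
#' @export
select_cutoff <- function(track, truth,
                          policy = c("default", "max_precision",
                                     "max_auc_point"),
                          default_cutoff = 0.2) {
  policy <- match.arg(policy)
  if (policy == "default") return(default_cutoff)
  if (!is.logical(truth)) truth <- truth_vector(truth)
  cuts <- sort(unique(track))
  stats <- vapply(cuts, function(ct)
    metrics_from_confusion(confusion_counts(track, truth, ct)),
    metrics_from_confusion(c(tp = 1, fp = 1, tn = 1, fn = 1)))
  if (policy == "max_auc_point") {
    j <- stats["tpr", ] - stats["fpr", ]
    return(cuts[which.max(j)])
  }
  prec <- stats["precision", ]
  prec[is.na(prec)] <- -Inf
  best <- which(prec == max(prec))
  # ties: higher specificity, then higher sensitivity (so a separable
  # track yields a zero-error operating point)
  best <- best[order(-stats["specificity", best],
                     -stats["tpr", best], cuts[best])][1L]
  cuts[best]
}

#' Compare prediction methods on a common antigen panel
#'
#' Builds one metrics row per method and cutoff policy.  Per-antigen
#' metrics (AUC and the confusion-derived rates at the selected cutoff)
#' are averaged across antigens by default; `pool = TRUE` pools all
#' residues into one confusion matrix instead.
#'
#' @param tracks Named list (one element per method) of lists of score
#'   tracks, aligned with `antigens`.
#' @param antigens List of annotated [antigen()] objects supplying the
#'   experimental truth.
#' @param policies Character vector of cutoff policies, see
#'   [select_cutoff()].
#' @param default_cutoffs Named numeric vector: each method's default
#'   operating cutoff (default 0.2 for all).
#' @param pool Pool residues across antigens instead of averaging
#'   per-antigen metrics.
#' @return Data frame with columns `method`, `policy`, `cutoff`, `auc`,
#'   `accuracy`, `tpr`, `fpr`, `precision`, `specificity`, `kappa`.
#' @export
compare_methods <- function(tracks, antigens,
                            policies = c("default", "max_precision",
                                         "max_auc_point"),
                            default_cutoffs = NULL, pool = FALSE) {
  antigens <- as_antigen_list(antigens)
  rows <- list()
  for (method in names(tracks)) {
    trs <- tracks[[method]]
    if (length(trs) != length(antigens))
      stop("method '", method, "': ", length(trs), " tracks for ",
           length(antigens), " antigens")
    dflt <- if (!is.null(default_cutoffs)) default_cutoffs[[method]] else 0.2
    truths <- lapply(antigens, truth_vector)
    for (policy in policies) {
      per <- lapply(seq_along(antigens), function(i) {
        ct <- select_cutoff(trs[[i]], truths[[i]], policy,
                            default_cutoff = dflt)
        list(auc = roc_auc(trs[[i]], truths[[i]])$auc,
             cutoff = ct,
             cc = confusion_counts(trs[[i]], truths[[i]], ct))
      })
      if (pool) {
        cc <- Reduce(`+`, lapply(per, `[[`, "cc"))
        m <- metrics_from_confusion(cc)
      } else {
        m <- rowMeans(vapply(per, function(p)
          metrics_from_confusion(p$cc), metrics_from_confusion(
            c(tp = 1, fp = 1, tn = 1, fn = 1))))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        method = method, policy = policy,
        cutoff = mean(vapply(per, `[[`, 0, "cutoff")),
        auc = mean(vapply(per, `[[`, 0, "auc")),
        accuracy = m[["accuracy"]], tpr = m[["tpr"]], fpr = m[["fpr"]],
        precision = m[["precision"]], specificity = m[["specificity"]],
        kappa = m[["kappa"]])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
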