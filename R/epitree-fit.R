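# The user-facing model: epitree() fits the whole pipeline
# (k-merization -> majority labeling -> 33-attribute featurization ->
# SMOTE rebalancing -> CART tree) on an annotated antigen panel and
# returns a classed object whose predict method produces per-residue
# score tracks and region calls for new antigens.

#' Fit a class-restricted linear B-cell epitope classifier
#'
#' Decomposes the annotated training antigens into frame-shifted k-mers
#' (all lengths `k_min..k_max`, stride `step`), labels each k-mer
#' against the epitope/nonepitope annotations under the chosen overlap
#' rule, describes every labeled k-mer by the 33 physicochemical
#' attributes, rebalances the two classes with SMOTE and grows a CART
#' decision tree.
#'
#' @param antigens List of annotated [antigen()] objects; at least one
#'   must carry epitope regions and one nonepitope (or flanking)
#'   regions.
#' @param rule K-mer labeling rule (default `"majority"`: a k-mer
#'   inherits a class when at least half of its residues are covered by
#'   that class).
#' @param k_min,k_max,step K-mer enumeration parameters (defaults 3,
#'   15, 1).
#' @param smote_percent SMOTE oversampling percent (multiple of 100);
#'   `NULL` (default) picks the multiple that brings the classes
#'   closest to 1:1, 0 disables rebalancing.
#' @param smote_k SMOTE neighbourhood size (default 5).
#' @param include_length Append k-mer length as a 34th attribute
#'   (default `FALSE`: the classifier uses the 33 attributes).
#' @param max_depth,min_leaf,min_split CART stopping parameters
#'   (defaults 12, 5, 10).
#' @param kmer_cutoff Probability at or above which a k-mer counts as
#'   positive when aggregating to residue scores (default 0.5).
#' @param region_cutoff Residue score at or above which region calls
#'   are made (default 0.2).
#' @param seed Optional integer seed (SMOTE interpolation noise).
#' @return Object of class `"epitree"` with components `tree` (the
#'   fitted `"epitree_tree"`), `config`, `n_kmers` (labeled k-mer count
#'   per class before balancing), `n_train` (after balancing) and
#'   `call`.
#' @seealso [predict.epitree()], [epitree_cv()], [simulate_antigens()]
#' @examples
#' panel <- simulate_antigens(12, effect_size = 3, seed = 42)
#' fit <- epitree(panel, seed = 1)
#' fit
#' pred <- predict(fit, panel[1], type = "regions")
#' @export
epitree <- function(antigens, rule = c("majority", "any_overlap",
                                       "full_containment"),
                    k_min = 3L, k_max = 15L, step = 1L,
                    smote_percent = NULL, smote_k = 5L,
                    include_length = FALSE,
                    max_depth = 12L, min_leaf = 5L, min_split = 10L,
                    kmer_cutoff = 0.5, region_cutoff = 0.2,
                    seed = NULL) {
  rule <- match.arg(rule)
  antigens <- as_antigen_list(antigens)
  kmers <- build_labeled_set(antigens, rule, k_min, k_max, step,
                             drop_unassigned = TRUE)
  if (!nrow(kmers)) stop("no labeled k-mers; check the annotations")
  n_kmers <- table(factor(kmers$label, c("epitope", "nonepitope")))
  if (any(n_kmers == 0L))
    stop("training needs both epitope and nonepitope k-mers (got ",
         n_kmers[["epitope"]], " epitope, ", n_kmers[["nonepitope"]],
         " nonepitope)")
  x <- featurize(kmers$sequence, include_length = include_length)
  y <- kmers$label
  if (is.null(smote_percent))
    smote_percent <- parity_percent(min(n_kmers), max(n_kmers))
  if (smote_percent > 0L) {
    bal <- smote(x, y, k_neighbors = smote_k,
                 oversample_percent = smote_percent, seed = seed)
    x <- bal$x; y <- bal$y
  }
  tree <- train_tree(x, y, max_depth = max_depth, min_leaf = min_leaf,
                     min_split = min_split)
  structure(list(
    tree = tree,
    config = list(rule = rule, k_min = k_min, k_max = k_max, step = step,
                  smote_percent = smote_percent, smote_k = smote_k,
                  include_length = include_length, max_depth = max_depth,
                  min_leaf = min_leaf, min_split = min_split,
                  kmer_cutoff = kmer_cutoff,
                  region_cutoff = region_cutoff),
    n_kmers = c(n_kmers), n_train = c(table(y)),
    n_antigens = length(antigens),
    call = match.call()),
    class = "epitree")
}

#' @export
print.epitree <- function(x, ...) {
  cat("Linear B-cell epitope classifier (k-mer decision tree)\n")
  cfg <- x$config
  cat(sprintf("  trained on %d antigen(s): %d epitope / %d nonepitope k-mers (k %d-%d, step %d, %s rule)\n",
              x$n_antigens, x$n_kmers[["epitope"]],
              x$n_kmers[["nonepitope"]], cfg$k_min, cfg$k_max, cfg$step,
              cfg$rule))
  if (cfg$smote_percent > 0)
    cat(sprintf("  SMOTE %d%% (k = %d): %d / %d rows after balancing\n",
                cfg$smote_percent, cfg$smote_k,
                x$n_train[["epitope"]], x$n_train[["nonepitope"]]))
  nd <- x$tree$nodes
  cat(sprintf("  tree: %d nodes (%d leaves), depth %d\n",
              nrow(nd), sum(is.na(nd$attribute)), max(nd$depth)))
  cat(sprintf("  cutoffs: k-mer %.2f, region %.2f\n",
              cfg$kmer_cutoff, cfg$region_cutoff))
  invisible(x)
}

#' @export
summary.epitree <- function(object, ...) {
  nd <- object$tree$nodes
  internal <- nd[!is.na(nd$attribute), , drop = FALSE]
  top <- internal[order(internal$depth), , drop = FALSE]
  top <- head(top, 8L)
  structure(list(fit = object,
                 top_splits = data.frame(
                   depth = top$depth,
                   attribute = object$tree$attributes[top$attribute],
                   threshold = top$threshold,
                   n = top$n_epitope + top$n_other)),
            class = "summary.epitree")
}

#' @export
print.summary.epitree <- function(x, ...) {
  print(x$fit)
  cat("\nFirst decision nodes (by depth):\n")
  print(x$top_splits, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Predict epitopes for new antigens
#'
#' Enumerates the k-mers of each antigen with the training
#' configuration, scores them with the fitted tree, and aggregates to a
#' per-residue score track; `type = "regions"` additionally calls
#' maximal regions at the region cutoff, `type = "kmer"` returns the
#' raw per-k-mer probabilities.
#'
#' @param object An `"epitree"` fit.
#' @param antigens List of [antigen()] objects (annotations not
#'   required).
#' @param type `"track"` (default), `"regions"` or `"kmer"`.
#' @param kmer_cutoff,region_cutoff,min_length Override the fit's
#'   operating cutoffs.
#' @param aggregate Aggregation of k-mer calls to residue scores, see
#'   [residue_scores()].
#' @param ... Unused.
#' @return For `"track"`, a named list of numeric score tracks; for
#'   `"regions"`, a named list of region-call data frames; for
#'   `"kmer"`, a named list of k-mer data frames with a `prob` column.
#' @export
predict.epitree <- function(object, antigens,
                            type = c("track", "regions", "kmer"),
                            kmer_cutoff = NULL, region_cutoff = NULL,
                            min_length = 3L,
                            aggregate = c("fraction", "mean_prob"), ...) {
  type <- match.arg(type)
  aggregate <- match.arg(aggregate)
  antigens <- as_antigen_list(antigens)
  cfg <- object$config
  if (is.null(kmer_cutoff)) kmer_cutoff <- cfg$kmer_cutoff
  if (is.null(region_cutoff)) region_cutoff <- cfg$region_cutoff
  out <- lapply(antigens, function(a) {
    km <- generate_kmers(a, cfg$k_min, cfg$k_max, cfg$step)
    if (!nrow(km)) {
      if (type == "kmer") return(km)
      track <- rep(0, nchar(a$sequence))
      return(if (type == "track") track
             else call_regions(track, region_cutoff, min_length))
    }
    km$prob <- predict_tree(object$tree,
                            featurize(km$sequence,
                                      include_length = cfg$include_length))
    if (type == "kmer") return(km)
    track <- residue_scores(km, nchar(a$sequence), kmer_cutoff, aggregate)
    if (type == "track") track
    else call_regions(track, region_cutoff, min_length)
  })
  names(out) <- names(antigens)
  out
}

#' Plot a predicted score track
#'
#' Base-graphics rendering of the per-residue epitope score (displayed
#' on the 0-100 scale) with annotated epitope regions shaded and the
#' region-calling cutoff drawn as a dashed line.
#'
#' @param x An `"epitree"` fit.
#' @param antigen The [antigen()] to score and draw.
#' @param region_cutoff Cutoff line (default: the fit's).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.epitree <- function(x, antigen, region_cutoff = NULL, ...) {
  stopifnot(inherits(antigen, "antigen"))
  if (is.null(region_cutoff)) region_cutoff <- x$config$region_cutoff
  track <- predict(x, list(antigen))[[1]]
  L <- length(track)
  graphics::plot(seq_len(L), 100 * track, type = "l",
                 xlab = "residue position", ylab = "epitope score (0-100)",
                 ylim = c(0, 100), main = antigen$id, ...)
  r <- antigen$regions
  for (i in which(r$label == "epitope"))
    graphics::rect(r$start[i], 0, r$end[i], 100,
                   col = grDevices::adjustcolor("red", 0.15), border = NA)
  graphics::abline(h = 100 * region_cutoff, lty = 2)
  invisible(track)
}

#' Cross-validate the epitope classifier
#'
#' Splits the antigen panel into folds (all k-mers of one antigen stay
#' in one fold by default, preventing overlap leakage between folds),
#' fits the full pipeline on the training folds — SMOTE is applied
#' inside each training fold only — and evaluates per-residue metrics
#' on the held-out antigens.
#'
#' @param antigens Annotated antigen panel.
#' @param folds Number of folds (default 10).
#' @param group_by_antigen Keep each antigen's k-mers in a single fold
#'   (default `TRUE`).  `FALSE` stratifies k-mer rows instead and
#'   evaluates at the k-mer level.
#' @param seed Integer seed for the fold assignment.
#' @param ... Passed to [epitree()].
#' @return List with `per_fold` (one metrics row per fold: `auc`,
#'   `accuracy`, `tpr`, `fpr`, `precision`, `specificity`, `kappa`) and
#'   `summary` (mean and sd across folds).
#' @export
epitree_cv <- function(antigens, folds = 10L, group_by_antigen = TRUE,
                       seed = NULL, ...) {
  if (folds < 2L) stop("folds must be >= 2")
  antigens <- as_antigen_list(antigens)
  if (!is.null(seed)) set.seed(seed)
  if (group_by_antigen) {
    if (length(antigens) < folds)
      stop("need at least ", folds, " antigens for ", folds,
           " antigen-grouped folds")
    assign <- sample(rep_len(seq_len(folds), length(antigens)))
    per_fold <- lapply(seq_len(folds), function(f) {
      fit <- epitree(antigens[assign != f], ...)
      held <- antigens[assign == f]
      tracks <- predict(fit, held)
      cut <- fit$config$region_cutoff
      m <- vapply(seq_along(held), function(i) {
        cc <- confusion_counts(tracks[[i]], held[[i]], cut)
        truth <- truth_vector(held[[i]])
        auc <- if (any(truth) && !all(truth))
          roc_auc(tracks[[i]], truth)$auc else NA_real_
        c(auc = auc, metrics_from_confusion(cc))
      }, c(auc = 0, metrics_from_confusion(c(tp = 1, fp = 1, tn = 1, fn = 1))))
      rowMeans(m, na.rm = TRUE)
    })
  } else {
    kmers <- build_labeled_set(antigens, drop_unassigned = TRUE)
    x <- featurize(kmers$sequence)
    y <- kmers$label
    assign <- integer(length(y))
    for (cl in unique(y))                      # stratified by class
      assign[y == cl] <- sample(rep_len(seq_len(folds), sum(y == cl)))
    per_fold <- lapply(seq_len(folds), function(f) {
      tr <- assign != f
      dots <- list(...)
      pct <- dots$smote_percent
      if (is.null(pct))
        pct <- parity_percent(min(table(y[tr])), max(table(y[tr])))
      xt <- x[tr, , drop = FALSE]; yt <- y[tr]
      if (pct > 0L) {
        bal <- smote(xt, yt, oversample_percent = pct)
        xt <- bal$x; yt <- bal$y
      }
      tree <- train_tree(xt, yt)
      prob <- predict_tree(tree, x[!tr, , drop = FALSE])
      truth <- y[!tr] == "epitope"
      cc <- c(tp = sum(prob >= 0.5 & truth), fp = sum(prob >= 0.5 & !truth),
              tn = sum(prob < 0.5 & !truth), fn = sum(prob < 0.5 & truth))
      auc <- if (any(truth) && !all(truth)) roc_auc(prob, truth)$auc
             else NA_real_
      c(auc = auc, metrics_from_confusion(cc))
    })
  }
  per_fold <- do.call(rbind, per_fold)
  list(per_fold = as.data.frame(per_fold),
       summary = data.frame(metric = colnames(per_fold),
                            mean = colMeans(per_fold, na.rm = TRUE),
                            sd = apply(per_fold, 2, sd, na.rm = TRUE),
                            row.names = NULL))
}
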