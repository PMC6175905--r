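# CART decision tree for the epitope/nonepitope k-mer classifier.
#
# Binary recursive partitioning on the 33-attribute space, maximizing
# the Gini impurity decrease over all attributes and all candidate
# thresholds (midpoints between sorted distinct values).  Tie-breaking
# is pinned for determinism: lowest attribute index, then lowest
# threshold.  The fitted tree is stored flat (one row per node) and
# serializes to a plain-text format with a bit-exact round trip.

#' Gini impurity of a two-class count vector
#'
#' `1 - p1^2 - p2^2`, ranging from 0 (pure node) to 0.5 (perfect
#' two-class mixture).
#'
#' @param counts Numeric vector of two nonnegative class counts.
#' @return Impurity in \[0, 0.5\].
#' @examples
#' gini(c(10, 0))  # 0
#' gini(c(5, 5))   # 0.5
#' gini(c(3, 1))   # 0.375
#' @export
gini <- function(counts) {
  stopifnot(length(counts) == 2L, all(counts >= 0))
  n <- sum(counts)
  if (n == 0) stop("all-zero class counts")
  1 - sum((counts / n)^2)
}

# Best (attribute, threshold) split of a node by Gini decrease.
# `pos` is a logical class indicator.  Returns NULL when no split with
# positive decrease and both children >= min_leaf exists.
best_split <- function(x, pos, min_leaf) {
  n <- length(pos)
  npos <- sum(pos)
  g_parent <- 1 - (npos / n)^2 - ((n - npos) / n)^2
  best <- NULL
  for (j in seq_len(ncol(x))) {
    xj <- x[, j]
    o <- order(xj)
    v <- xj[o]
    cp <- cumsum(pos[o])
    i <- seq_len(n - 1L)
    ok <- v[i] < v[i + 1L]                    # distinct-value boundaries
    ok <- ok & i >= min_leaf & (n - i) >= min_leaf
    if (!any(ok)) next
    i <- i[ok]
    nl <- i; nr <- n - i
    pl <- cp[i]; pr <- npos - pl
    g_l <- 1 - (pl / nl)^2 - ((nl - pl) / nl)^2
    g_r <- 1 - (pr / nr)^2 - ((nr - pr) / nr)^2
    dec <- g_parent - (nl / n) * g_l - (nr / n) * g_r
    m <- which.max(dec)                       # first max: lowest threshold
    # zero-gain splits are accepted (they can enable deeper informative
    # splits, e.g. on XOR-structured attributes); negative gain cannot
    # occur beyond rounding
    if (dec[m] >= -1e-12 && (is.null(best) || dec[m] > best$decrease)) {
      best <- list(attribute = j,
                   threshold = (v[i[m]] + v[i[m] + 1L]) / 2,
                   decrease = dec[m])
    }
  }
  best
}

#' Train a CART decision tree
#'
#' @param x Numeric feature matrix (named columns).
#' @param y Class labels; the positive class is `"epitope"` when
#'   present, otherwise the first level.
#' @param max_depth Maximum tree depth (root = depth 0; default 12).
#' @param min_leaf Minimum rows in any leaf (default 5).
#' @param min_split Minimum rows for a node to be considered for
#'   splitting (default 10).
#' @return Object of class `"epitree_tree"`: a flat node table plus the
#'   attribute names.  Leaves carry the class counts from which
#'   [predict_tree()] reads the epitope probability.
#' @export
train_tree <- function(x, y, max_depth = 12L, min_leaf = 5L,
                       min_split = 10L) {
  stopifnot(is.matrix(x), nrow(x) >= 2L, nrow(x) == length(y))
  y <- as.character(y)
  positive <- if ("epitope" %in% y) "epitope" else sort(unique(y))[1L]
  pos <- y == positive
  if (all(pos) || !any(pos))
    warning("single-class input; returning a single leaf")
  nodes <- new.env(parent = emptyenv())
  nodes$tab <- list()
  grow <- function(idx, depth) {
    id <- length(nodes$tab) + 1L
    nodes$tab[[id]] <- list()                 # reserve slot (preorder ids)
    n_pos <- sum(pos[idx]); n_neg <- length(idx) - n_pos
    split <- NULL
    if (depth < max_depth && length(idx) >= min_split &&
        n_pos > 0L && n_neg > 0L)
      split <- best_split(x[idx, , drop = FALSE], pos[idx], min_leaf)
    if (is.null(split)) {
      nodes$tab[[id]] <- list(id = id, attribute = NA_integer_,
                              threshold = NA_real_, left = NA_integer_,
                              right = NA_integer_, n_epitope = n_pos,
                              n_other = n_neg, depth = depth)
      return(id)
    }
    go_left <- x[idx, split$attribute] <= split$threshold
    left <- grow(idx[go_left], depth + 1L)
    right <- grow(idx[!go_left], depth + 1L)
    nodes$tab[[id]] <- list(id = id, attribute = split$attribute,
                            threshold = split$threshold, left = left,
                            right = right, n_epitope = n_pos,
                            n_other = n_neg, depth = depth)
    id
  }
  grow(seq_len(nrow(x)), 0L)
  tab <- do.call(rbind, lapply(nodes$tab, as.data.frame))
  structure(list(nodes = tab, attributes = colnames(x),
                 positive = positive),
            class = "epitree_tree")
}

#' Epitope probability from a fitted tree
#'
#' Routes each feature row to its leaf and returns the leaf's epitope
#' class fraction (two rows reaching the same leaf always get the same
#' score).
#'
#' @param tree An `"epitree_tree"` from [train_tree()].
#' @param x Feature matrix over the tree's attribute space.
#' @return Numeric vector of epitope probabilities in \[0, 1\].
#' @export
predict_tree <- function(tree, x) {
  if (is.null(dim(x))) x <- matrix(x, 1L, dimnames = list(NULL, names(x)))
  missing <- setdiff(tree$attributes, colnames(x))
  if (length(missing))
    stop("missing attribute(s): ", paste(missing, collapse = ", "))
  x <- x[, tree$attributes, drop = FALSE]
  nd <- tree$nodes
  node <- rep(1L, nrow(x))
  repeat {
    internal <- !is.na(nd$attribute[node])
    if (!any(internal)) break
    i <- which(internal)
    at <- nd$attribute[node[i]]
    thr <- nd$threshold[node[i]]
    val <- x[cbind(i, at)]
    node[i] <- ifelse(val <= thr, nd$left[node[i]], nd$right[node[i]])
  }
  nd$n_epitope[node] / (nd$n_epitope[node] + nd$n_other[node])
}

#' Serialize / deserialize a fitted tree
#'
#' Plain-text model format, one node per line:
#' `id attribute threshold left right n_epitope n_other depth`, with
#' thresholds printed at full double precision (`%.17g`) so the round
#' trip is bit-exact.
#'
#' @param tree An `"epitree_tree"`.
#' @param path File path.
#' @return `read_tree_model` returns the tree object.
#' @export
write_tree_model <- function(tree, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# epitree decision tree model v1",
               paste0("positive\t", tree$positive),
               paste0("attributes\t", paste(tree$attributes, collapse = "\t")),
               "id\tattribute\tthreshold\tleft\tright\tn_epitope\tn_other\tdepth"),
             con)
  nd <- tree$nodes
  writeLines(sprintf("%d\t%s\t%s\t%s\t%s\t%d\t%d\t%d",
                     nd$id,
                     ifelse(is.na(nd$attribute), "leaf",
                            tree$attributes[nd$attribute]),
                     ifelse(is.na(nd$threshold), ".",
                            sprintf("%.17g", nd$threshold)),
                     ifelse(is.na(nd$left), ".", as.character(nd$left)),
                     ifelse(is.na(nd$right), ".", as.character(nd$right)),
                     nd$n_epitope, nd$n_other, nd$depth),
             con)
  invisible(path)
}

#' @rdname write_tree_model
#' @export
read_tree_model <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  positive <- sub("^positive\t", "", lines[1L])
  attributes <- strsplit(lines[2L], "\t")[[1]][-1L]
  body <- read.delim(text = lines[-(1:2)], stringsAsFactors = FALSE,
                     colClasses = c(threshold = "character"))
  parse_col <- function(v, convert) {
    out <- rep(convert(NA), length(v))
    sel <- v != "."
    out[sel] <- convert(v[sel])
    out
  }
  nd <- data.frame(
    id = body$id,
    attribute = parse_col(ifelse(body$attribute == "leaf", ".",
                                 body$attribute),
                          function(v) match(v, attributes)),
    threshold = parse_col(as.character(body$threshold), as.numeric),
    left = parse_col(as.character(body$left), as.integer),
    right = parse_col(as.character(body$right), as.integer),
    n_epitope = body$n_epitope, n_other = body$n_other,
    depth = body$depth)
  structure(list(nodes = nd, attributes = attributes, positive = positive),
            class = "epitree_tree")
}

#' Random-forest attribute importances
#'
#' Fits a random forest (bootstrap resampling, sqrt(p) attributes per
#' split) on the labeled feature matrix and returns the two classical
#' importance measures: mean decrease in Gini impurity and mean
#' decrease in out-of-bag accuracy under attribute permutation.
#' Computed with the randomForest package.
#'
#' @param x Feature matrix.
#' @param y Class labels.
#' @param n_trees Forest size (default 10000 for stable ranks at desk
#'   scale).
#' @param seed Optional integer seed.
#' @return Data frame with columns `attribute`, `decreased_gini`,
#'   `decreased_accuracy`, ordered by decreasing Gini importance.
#' @export
forest_importance <- function(x, y, n_trees = 10000L, seed = NULL) {
  stopifnot(n_trees >= 1L)
  if (!is.null(seed)) set.seed(seed)
  fit <- randomForest::randomForest(x, factor(y), ntree = n_trees,
                                    importance = TRUE)
  imp <- randomForest::importance(fit)
  out <- data.frame(attribute = rownames(imp),
                    decreased_gini = imp[, "MeanDecreaseGini"],
                    decreased_accuracy = imp[, "MeanDecreaseAccuracy"])
  out <- out[order(-out$decreased_gini), ]
  rownames(out) <- NULL
  out
}
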