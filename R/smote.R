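# SMOTE: synthetic minority oversampling by interpolation between
# minority nearest neighbours (Euclidean distance in the raw feature
# space by default).  Used to rebalance epitope/nonepitope k-mers before
# tree induction; applied to training data only, never to held-out
# folds.

#' Synthetic minority oversampling (SMOTE)
#'
#' For each minority-class row, `oversample_percent / 100` synthetic
#' rows are generated as `x + u * (x_nn - x)` with `u` uniform on
#' \[0, 1\] and `x_nn` drawn from the row's `k_neighbors` nearest
#' minority neighbours (Euclidean distance).  Original rows are
#' unchanged; synthetic rows carry the minority label.
#'
#' @param x Numeric feature matrix.
#' @param y Class label vector (factor or character), length `nrow(x)`.
#' @param k_neighbors Number of minority nearest neighbours (default 5);
#'   must be smaller than the minority class size.
#' @param oversample_percent Integer multiple of 100; 100 doubles the
#'   minority class, 200 triples it, etc.
#' @param scale Z-scale attributes before computing neighbour distances
#'   (interpolation still happens in the raw space).  Default `FALSE`:
#'   the 33 attributes are mostly commensurable percents.
#' @param seed Optional integer seed making the augmentation
#'   deterministic.
#' @return List with `x` (original rows followed by synthetic rows),
#'   `y`, `synthetic` (logical index of the synthetic rows), and
#'   `parent` / `neighbor` (for each synthetic row, the minority-row
#'   indices of the interpolation endpoints).
#' @export
smote <- function(x, y, k_neighbors = 5L, oversample_percent = 100L,
                  scale = FALSE, seed = NULL) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  if (oversample_percent < 100L || oversample_percent %% 100L != 0L)
    stop("oversample_percent must be a positive multiple of 100")
  if (!is.null(seed)) set.seed(seed)
  y <- as.character(y)
  tab <- sort(table(y))
  minority <- names(tab)[1L]
  n_min <- tab[[1L]]
  if (n_min < k_neighbors + 1L)
    stop("minority class (", n_min, " rows) too small for k_neighbors = ",
         k_neighbors)
  xm <- x[y == minority, , drop = FALSE]
  nn <- minority_neighbors(if (scale) scale_cols(xm) else xm, k_neighbors)
  reps <- oversample_percent %/% 100L
  parent <- rep(seq_len(n_min), each = reps)
  pick <- nn[cbind(parent, sample.int(k_neighbors, length(parent),
                                      replace = TRUE))]
  u <- runif(length(parent))
  synth <- xm[parent, , drop = FALSE] +
    u * (xm[pick, , drop = FALSE] - xm[parent, , drop = FALSE])
  list(x = rbind(x, synth),
       y = c(y, rep(minority, nrow(synth))),
       synthetic = c(rep(FALSE, nrow(x)), rep(TRUE, nrow(synth))),
       parent = parent, neighbor = pick)
}

scale_cols <- function(m) {
  s <- apply(m, 2L, sd)
  s[s == 0] <- 1
  sweep(sweep(m, 2L, colMeans(m)), 2L, s, "/")
}

# k nearest neighbours (excluding self) within one matrix, computed
# blockwise so memory stays O(block * n).  Ties broken by row index.
minority_neighbors <- function(m, k) {
  n <- nrow(m)
  sq <- rowSums(m^2)
  block <- max(1L, min(n, 2048L))
  out <- matrix(0L, n, k)
  for (from in seq.int(1L, n, by = block)) {
    to <- min(n, from + block - 1L)
    d2 <- outer(sq[from:to], sq, "+") - 2 * tcrossprod(m[from:to, , drop = FALSE], m)
    for (i in seq.int(from, to)) {
      di <- d2[i - from + 1L, ]
      di[i] <- Inf
      out[i, ] <- order(di)[seq_len(k)]
    }
  }
  out
}

# Oversample percent that brings the minority class closest to parity
# (never above), as a multiple of 100; 0 means already balanced.
parity_percent <- function(n_minority, n_majority) {
  100L * max(0L, (n_majority - n_minority) %/% n_minority)
}
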