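# Independent oracles and fixture builders used across the suite.
# Every oracle is a deliberately naive reimplementation (enumeration,
# brute force, closed form) kept separate from the package code paths
# it checks.

AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_peptide <- function(len) paste(sample(AA, len, replace = TRUE),
                                      collapse = "")

# A small antigen with one planted epitope and nonepitope flanks.
toy_antigen <- function(id = "toy", L = 40L, epi = c(15L, 24L)) {
  r <- regions(c(epi[1], 1L, epi[2] + 1L),
               c(epi[2], epi[1] - 1L, L),
               c("epitope", "nonepitope", "nonepitope"))
  antigen(id, random_peptide(L), r)
}

# Brute-force k-mer enumeration (oracle for the count formula and
# ordering).
enumerate_kmers_oracle <- function(seqstr, k_min, k_max, step) {
  out <- list()
  for (k in k_min:k_max) {
    s <- 1L
    while (s + k - 1L <= nchar(seqstr)) {
      out[[length(out) + 1L]] <- c(start = s, k = k)
      s <- s + step
    }
  }
  out
}

# Pairwise-ranking AUC (ties counted 1/2): brute force over all
# positive/negative pairs.
auc_pairwise_oracle <- function(scores, truth) {
  pos <- scores[truth]; neg <- scores[!truth]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Exhaustive best split by Gini decrease: all attributes, all midpoint
# thresholds, no shortcuts.  Returns NULL if nothing improves.
best_split_oracle <- function(x, pos, min_leaf) {
  gini2 <- function(a, b) { n <- a + b; 1 - (a / n)^2 - (b / n)^2 }
  n <- length(pos)
  parent <- gini2(sum(pos), n - sum(pos))
  best <- NULL
  for (j in seq_len(ncol(x))) {
    vals <- sort(unique(x[, j]))
    if (length(vals) < 2L) next
    for (t in (vals[-length(vals)] + vals[-1]) / 2) {
      l <- x[, j] <= t
      if (sum(l) < min_leaf || sum(!l) < min_leaf) next
      dec <- parent -
        (sum(l) / n) * gini2(sum(pos & l), sum(!pos & l)) -
        (sum(!l) / n) * gini2(sum(pos & !l), sum(!pos & !l))
      if (dec >= -1e-12 && (is.null(best) || dec > best$decrease))
        best <- list(attribute = j, threshold = t, decrease = dec)
    }
  }
  best
}

# Route training rows down a fitted tree, returning the row-index set
# of every node (for per-node oracle comparisons).
node_row_sets <- function(tree, x) {
  nd <- tree$nodes
  sets <- vector("list", nrow(nd))
  walk <- function(id, idx) {
    sets[[id]] <<- idx
    if (is.na(nd$attribute[id])) return(invisible())
    l <- x[idx, nd$attribute[id]] <= nd$threshold[id]
    walk(nd$left[id], idx[l])
    walk(nd$right[id], idx[!l])
  }
  walk(1L, seq_len(nrow(x)))
  sets
}

# Gotoh global affine alignment score (no traceback), matching the
# convention: a gap of length L costs open + L * extend.
align_score_oracle <- function(a, b, sub, open = 10, extend = 0.5) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (j in 2:(m + 1)) Y[1, j] <- -(open + (j - 1) * extend)
  for (i in 2:(n + 1)) X[i, 1] <- -(open + (i - 1) * extend)
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- sub[a[i - 1], b[j - 1]]
    M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
    X[i, j] <- max(M[i - 1, j] - open - extend, X[i - 1, j] - extend)
    Y[i, j] <- max(M[i, j - 1] - open - extend, Y[i, j - 1] - extend)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

getdata_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# Residues covered by at least one positive-labeled k-mer.
positive_residues <- function(kmers) {
  pos <- kmers[kmers$label == "epitope", , drop = FALSE]
  sort(unique(unlist(mapply(function(s, k) s:(s + k - 1L),
                            pos$start, pos$k, SIMPLIFY = FALSE))))
}
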