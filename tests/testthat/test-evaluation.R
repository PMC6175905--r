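test_that("residue-level confusion counts are exact", {
  truth <- rep(FALSE, 10); truth[3:5] <- TRUE
  track <- rep(0, 10); track[4:7] <- 0.9
  cc <- confusion_counts(track, truth, cutoff = 0.5)
  expect_equal(unname(cc), c(2, 2, 5, 1))    # tp fp tn fn
  expect_equal(sum(cc), 10)
  perfect <- as.numeric(truth)
  expect_equal(unname(confusion_counts(perfect, truth, 0.5)[c("fp", "fn")]),
               c(0, 0))
  zero <- confusion_counts(rep(0, 10), truth, 0.5)
  expect_equal(unname(zero[c("tp", "fp")]), c(0, 0))
  expect_error(confusion_counts(rep(0, 9), truth, 0.5), "length")
  # antigen regions work as truth directly
  a <- antigen("cc", paste(rep("A", 10), collapse = ""),
               regions(3, 5, "epitope"))
  expect_identical(confusion_counts(track, a, 0.5), cc)
})

test_that("trapezoidal AUC equals the pairwise-ranking oracle", {
  set.seed(81)
  for (rep in 1:20) {
    n <- sample(20:200, 1)
    truth <- runif(n) < 0.4
    if (!any(truth) || all(truth)) next
    # include heavy ties: scores on a coarse grid
    track <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    expect_equal(roc_auc(track, truth)$auc,
                 auc_pairwise_oracle(track, truth), tolerance = 1e-12)
  }
})

test_that("AUC endpoints and the permutation null behave canonically", {
  truth <- rep(c(TRUE, FALSE), each = 10)
  expect_equal(roc_auc(c(rep(1, 10), rep(0, 10)), truth)$auc, 1)
  expect_equal(roc_auc(c(rep(0, 10), rep(1, 10)), truth)$auc, 0)
  expect_error(roc_auc(runif(5), rep(TRUE, 5)), "degenerate")
  set.seed(82)
  aucs <- replicate(20, roc_auc(runif(1000), rep(c(TRUE, FALSE), 500))$auc)
  expect_true(all(abs(aucs - 0.5) < 0.05))
  # curve structure: starts (0,0), ends (1,1), fpr non-decreasing
  cv <- roc_auc(runif(50), runif(50) < 0.5)$curve
  expect_equal(unlist(cv[1, c("fpr", "tpr")]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(cv[nrow(cv), c("fpr", "tpr")]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(cv$fpr) >= 0))
  expect_true(all(diff(cv$tpr) >= 0))
})

test_that("own AUC agrees with pROC on random tracks", {
  set.seed(83)
  for (rep in 1:5) {
    truth <- runif(120) < 0.5
    track <- runif(120)
    expect_equal(roc_auc(track, truth)$auc,
                 as.numeric(pROC::auc(pROC::roc(truth, track,
                                                quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-10)
  }
})

test_that("cutoff policies optimize what they claim", {
  truth <- rep(c(TRUE, FALSE), each = 10)
  sep <- c(runif(10, 0.8, 1), runif(10, 0, 0.2))
  for (policy in c("max_precision", "max_auc_point")) {
    ct <- select_cutoff(sep, truth, policy)
    cc <- confusion_counts(sep, truth, ct)
    expect_equal(unname(cc[c("fp", "fn")]), c(0, 0), info = policy)
  }
  expect_equal(select_cutoff(sep, truth, "default", default_cutoff = 0.2),
               0.2)
  set.seed(84)
  for (rep in 1:10) {
    track <- runif(40); truth <- runif(40) < 0.5
    if (!any(truth) || all(truth)) next
    cuts <- sort(unique(track))
    prec_at <- function(ct) {
      cc <- confusion_counts(track, truth, ct)
      if (cc[["tp"]] + cc[["fp"]] == 0) -Inf else
        cc[["tp"]] / (cc[["tp"]] + cc[["fp"]])
    }
    ct <- select_cutoff(track, truth, "max_precision")
    expect_equal(prec_at(ct), max(vapply(cuts, prec_at, 0)))
    j_at <- function(ct) {
      cc <- confusion_counts(track, truth, ct)
      cc[["tp"]] / (cc[["tp"]] + cc[["fn"]]) -
        cc[["fp"]] / (cc[["fp"]] + cc[["tn"]])
    }
    ctj <- select_cutoff(track, truth, "max_auc_point")
    expect_equal(j_at(ctj), max(vapply(cuts, j_at, 0)), tolerance = 1e-12)
  }
})

test_that("kappa closed forms and metric identities", {
  expect_equal(cohen_kappa(10, 0, 10, 0), 1)
  expect_equal(cohen_kappa(25, 25, 25, 25), 0)
  expect_equal(cohen_kappa(40, 10, 40, 10), 0.6)
  set.seed(85)
  for (rep in 1:20) {
    cc <- setNames(as.numeric(sample(1:50, 4, replace = TRUE)),
                   c("tp", "fp", "tn", "fn"))
    m <- epitree:::metrics_from_confusion(cc)
    expect_equal(m[["specificity"]], 1 - m[["fpr"]], tolerance = 1e-12)
    expect_equal(m[["tpr"]],
                 1 - cc[["fn"]] / (cc[["tp"]] + cc[["fn"]]),
                 tolerance = 1e-12)
    expect_true(all(m[c("accuracy", "tpr", "fpr", "precision",
                        "specificity")] >= 0 &
                    m[c("accuracy", "tpr", "fpr", "precision",
                        "specificity")] <= 1))
  }
})

test_that("TPR and FPR are non-increasing as the cutoff rises", {
  set.seed(86)
  track <- runif(100); truth <- runif(100) < 0.4
  cuts <- seq(0, 1, by = 0.05)
  stats <- vapply(cuts, function(ct) {
    cc <- confusion_counts(track, truth, ct)
    c(tpr = cc[["tp"]] / (cc[["tp"]] + cc[["fn"]]),
      fpr = cc[["fp"]] / (cc[["fp"]] + cc[["tn"]]))
  }, c(tpr = 0, fpr = 0))
  expect_true(all(diff(stats["tpr", ]) <= 1e-12))
  expect_true(all(diff(stats["fpr", ]) <= 1e-12))
})

test_that("method comparison tables rank an oracle over noise", {
  set.seed(87)
  panel <- lapply(1:3, function(i) toy_antigen(paste0("m", i), L = 60L,
                                               epi = c(21L, 32L)))
  names(panel) <- vapply(panel, `[[`, "", "id")
  oracle <- lapply(panel, function(a) {
    tv <- epitree:::truth_vector(a)
    0.8 * tv + 0.1
  })
  noise <- lapply(panel, function(a) runif(nchar(a$sequence)))
  tab <- compare_methods(list(oracle = oracle, noise = noise), panel)
  expect_identical(nrow(tab), 6L)   # 2 methods x 3 policies
  for (pol in unique(tab$policy)) {
    o <- tab[tab$method == "oracle" & tab$policy == pol, ]
    z <- tab[tab$method == "noise" & tab$policy == pol, ]
    expect_gt(o$auc, z$auc)
    expect_gt(o$accuracy, z$accuracy)
  }
  # a method compared against itself yields identical rows
  tab2 <- compare_methods(list(a = oracle, b = oracle), panel)
  expect_equal(tab2[tab2$method == "a", -1], tab2[tab2$method == "b", -1],
               ignore_attr = TRUE)
  # rank invariance: adding a constant leaves AUC unchanged
  shifted <- lapply(oracle, function(t) t + 0.05)
  t3 <- compare_methods(list(a = oracle, b = shifted), panel,
                        policies = "default")
  expect_equal(t3$auc[1], t3$auc[2])
})
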