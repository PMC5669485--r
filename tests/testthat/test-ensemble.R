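test_that("precision/recall/F follow their defining identities", {
  m <- prf_metrics(c(TP = 5, FP = 5, FN = 0, TN = 10))
  expect_equal(unname(m), c(0.5, 1, 2 * 0.5 * 1 / 1.5))
  expect_warning(m0 <- prf_metrics(c(TP = 0, FP = 0, FN = 3, TN = 5)),
                 "precision undefined")
  expect_equal(unname(m0), c(0, 0, 0))
  set.seed(6)
  for (i in 1:20) {
    cc <- c(TP = sample(0:20, 1), FP = sample(0:20, 1),
            FN = sample(0:20, 1), TN = sample(0:20, 1))
    m <- suppressWarnings(prf_metrics(cc))
    expect_true(all(m >= 0 & m <= 1))
    if (m["P"] + m["R"] > 0) {
      expect_equal(unname(m["F"]),
                   unname(2 * m["P"] * m["R"] / (m["P"] + m["R"])),
                   tolerance = 1e-12)
    }
  }
})

test_that("cosine normalization gives unit diagonals and guards zeros", {
  set.seed(10)
  X <- matrix(stats::rnorm(30), 10, 3)
  K <- tcrossprod(X)
  Kn <- normalize_gram(K)
  expect_equal(unname(diag(Kn)), rep(1, 10))
  expect_true(all(abs(Kn) <= 1 + 1e-12))
  K2 <- rbind(cbind(K, 0), 0)  # an instance with zero self-similarity
  Kn2 <- normalize_gram(K2)
  expect_equal(Kn2[11, ], rep(0, 11))
})

test_that("kernel algebra: symmetry, PSD, composite = fea' + w dstk'", {
  sh <- shared_prep()
  fea_n <- normalize_gram(ppidstk:::feature_gram(sh$prep$features))
  dstk_n <- normalize_gram(tcrossprod(sh$prep$dst_flat))
  for (w in c(0, 0.5, 1)) {
    cfg <- kernel_config(d = sh$cfg$d, k = sh$cfg$k, seed = sh$cfg$seed,
                         w = w)
    K <- gram_matrix(sh$prep, "ckl", cfg)
    expect_equal(K, t(K), ignore_attr = TRUE)
    expect_equal(unname(K), unname(fea_n + w * dstk_n), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(unname(diag(K)), rep(1 + w, nrow(K)), tolerance = 1e-12)
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8)
  }
  for (tag in c("fea", "dstk")) {
    K <- gram_matrix(sh$prep, tag)
    expect_equal(K, t(K), ignore_attr = TRUE)
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8)
    expect_equal(unname(diag(K)), rep(1, nrow(K)), tolerance = 1e-12)
  }
})

test_that("the SVM separates a separable toy set and respects permutations", {
  set.seed(12)
  X <- rbind(matrix(stats::rnorm(40, mean = 2), 20),
             matrix(stats::rnorm(40, mean = -2), 20))
  y <- factor(rep(c("positive", "negative"), each = 20),
              levels = c("negative", "positive"))
  K <- tcrossprod(X)
  fit <- train_svm(K, y, C = 1)
  pred <- predict_svm(fit, K)
  expect_equal(as.character(pred$class), as.character(y))
  # oriented decision values: positives score higher
  expect_gt(mean(pred$score[y == "positive"]),
            mean(pred$score[y == "negative"]))
  # consistent permutation of Gram and labels leaves predictions equivariant
  p <- sample(length(y))
  fit2 <- train_svm(K[p, p], y[p], C = 1)
  pred2 <- predict_svm(fit2, K[, p])
  expect_equal(as.character(pred2$class), as.character(y))
  expect_error(train_svm(K, factor(rep("positive", 40),
                                   levels = c("negative", "positive"))),
               "single class")
})

test_that("stratified folds balance classes and need enough instances", {
  y <- factor(rep(c("negative", "positive"), c(30, 12)),
              levels = c("negative", "positive"))
  f <- ppidstk:::stratified_folds(y, 6, seed = 1)
  expect_equal(sort(unique(f)), 1:6)
  per <- table(f[y == "positive"])
  expect_equal(unname(max(per) - min(per)), 0)
  expect_error(ppidstk:::stratified_folds(y, 13, 1), "need at least")
  # same seed, same assignment
  expect_identical(f, ppidstk:::stratified_folds(y, 6, seed = 1))
})

test_that("cross-validation on a clean corpus reaches ceiling accuracy", {
  sh <- shared_prep()
  reps <- cross_validate(sh$prep, sh$cfg, folds = 5, seed = 1)
  expect_named(reps, c("fea", "dstk", "ckl"))
  for (tag in names(reps)) {
    a <- reps[[tag]]$aggregate
    expect_equal(unname(a["TP"] + a["FP"] + a["FN"] + a["TN"]),
                 length(sh$prep$labels))
    roc <- reps[[tag]]$roc
    expect_true(all(diff(roc$FPR) >= 0))
    expect_true(all(roc$TPR >= 0 & roc$TPR <= 1))
  }
  expect_gte(reps$ckl$aggregate["F"], 0.9)
  expect_gte(reps$ckl$auc, 0.95)
  # same seed reproduces the report exactly
  reps2 <- cross_validate(sh$prep, sh$cfg, folds = 5, seed = 1,
                          kernels = "ckl")
  expect_equal(reps$ckl$aggregate, reps2$ckl$aggregate)
})

test_that("the score-averaging ensemble variant also classifies cleanly", {
  sh <- shared_prep()
  cfg <- kernel_config(d = sh$cfg$d, k = sh$cfg$k, seed = sh$cfg$seed,
                       ensemble_mode = "score_avg")
  reps <- cross_validate(sh$prep, cfg, folds = 5, seed = 1,
                         kernels = c("fea", "dstk", "ckl"))
  expect_gte(reps$ckl$aggregate["F"], 0.9)
})

test_that("reports tabulate per fold and serialize to CSV/JSON", {
  sh <- shared_prep()
  reps <- cross_validate(sh$prep, sh$cfg, folds = 5, seed = 1)
  tab <- report_table(reps, "synthetic")
  expect_equal(nrow(tab), 3 * 6)  # 3 kernels x (5 folds + pooled)
  expect_setequal(names(tab), c("corpus", "kernel", "fold", "TP", "FP",
                                "FN", "TN", "P", "R", "F"))
  pooled <- tab[tab$fold == "all" & tab$kernel == "ckl", ]
  expect_equal(pooled$F, unname(reps$ckl$aggregate["F"]))
  dir <- tempfile()
  paths <- write_results(reps, dir, "synthetic")
  expect_true(all(file.exists(file.path(dir, c("results.csv",
                                               "results.json", "roc.csv")))))
  back <- utils::read.csv(file.path(dir, "results.csv"))
  expect_equal(nrow(back), nrow(tab))
})
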