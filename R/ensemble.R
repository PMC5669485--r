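# Kernel combination and evaluation: per-kernel Gram matrices over
# candidate instances, a max-margin classifier (kernlab SVM on
# precomputed kernels), stratified 10-fold cross-validation and
# precision/recall/F reporting with ROC curves from pooled decision
# values. The composite kernel is the sum of the cosine-normalized
# feature kernel and w times the cosine-normalized DSTK.

#' Kernel configuration
#'
#' @param lambda Tree-kernel decay in (0,1] (default 0.4).
#' @param d Structural dimension of the distributed trees (default 4096).
#' @param k Distributional vector dimension requested from the embedding
#'   builder (default 1024; capped at the co-occurrence rank).
#' @param w Weight of the DSTK term in the composite kernel (default 1).
#' @param C Soft-margin constant of the SVM (default 1).
#' @param normalize Cosine-normalize each component Gram before summing
#'   (default TRUE).
#' @param seed Master seed for the random label store (default 42).
#' @param oov Embedding OOV policy.
#' @param ensemble_mode `"kernel_sum"` (one SVM on the summed Gram,
#'   default) or `"score_avg"` (average the decision values of the two
#'   single-kernel SVMs).
#' @return A `kernel_config` list.
#' @export
kernel_config <- function(lambda = 0.4, d = 4096L, k = 1024L, w = 1,
                          C = 1, normalize = TRUE, seed = 42L,
                          oov = c("zero", "hash"),
                          ensemble_mode = c("kernel_sum", "score_avg")) {
  stopifnot(lambda > 0, lambda <= 1, w >= 0, d >= 1, k >= 1, C > 0)
  structure(list(lambda = lambda, d = as.integer(d), k = as.integer(k),
                 w = w, C = C, normalize = normalize,
                 seed = as.integer(seed), oov = match.arg(oov),
                 ensemble_mode = match.arg(ensemble_mode)),
            class = "kernel_config")
}

#' Prepare all candidate instances of a corpus for kernel computation
#'
#' Enumerates blinded instances, extracts sparse feature vectors,
#' lexicalizes each blinded parse (with the interaction-keyword head
#' override) and computes its flattened DST matrix. Embeddings default to
#' PPMI+SVD vectors built from the corpus itself.
#'
#' @param corpus A `ppi_corpus` with parses attached.
#' @param config A `kernel_config`.
#' @param lexicon Interaction lexicon.
#' @param rules Head-rule table.
#' @param embeddings Optional pre-built `embedding_table`.
#' @param need_trees Require a parse for every instance (default TRUE);
#'   missing parses are a fatal error listing the instances.
#' @return A `ppi_prep`: list with `instances`, `labels` (factor
#'   negative/positive), `features` (list of sparse vectors), `dst_flat`
#'   (n x d*k matrix or NULL), `embeddings`, `config`.
#' @export
prepare_instances <- function(corpus, config = kernel_config(),
                              lexicon = default_lexicon(),
                              rules = default_head_rules(),
                              embeddings = NULL, need_trees = TRUE) {
  instances <- unlist(lapply(corpus, make_instances), recursive = FALSE)
  if (length(instances) == 0) stop("corpus yields no candidate instances")
  labels <- factor(vapply(instances, `[[`, character(1), "label"),
                   levels = c("negative", "positive"))
  features <- lapply(instances, extract_features, lexicon = lexicon)
  dst_flat <- NULL
  if (need_trees) {
    missing <- vapply(instances, function(x) is.na(x$parse), logical(1))
    if (any(missing)) {
      ids <- vapply(instances[missing], function(x)
        paste0(x$sentence_id, ":", x$e1, "-", x$e2), character(1))
      stop("missing parse tree for instance(s): ",
           paste(utils::head(ids, 10), collapse = ", "))
    }
    if (is.null(embeddings)) {
      embeddings <- build_embeddings(corpus, k = config$k, oov = config$oov)
    }
    store <- new_label_store(d = config$d, seed = config$seed)
    dst_flat <- matrix(0, length(instances), config$d * embeddings$k)
    for (i in seq_along(instances)) {
      inst <- instances[[i]]
      toks <- normalize_tokens(inst$tokens)
      kw <- find_interaction_keywords(pos_lemma(toks, lexicon), lexicon)
      lt <- lexicalize(inst$parse, rules,
                       keyword_index = if (length(kw)) kw[1] else NA,
                       tokens = inst$tokens)
      dst_flat[i, ] <- as.numeric(dst_matrix(lt, store, embeddings,
                                             config$lambda)$matrix)
    }
  }
  structure(list(instances = instances, labels = labels,
                 features = features, dst_flat = dst_flat,
                 embeddings = embeddings, config = config),
            class = "ppi_prep")
}

#' Cosine-normalize a Gram matrix
#'
#' `k'(x,y) = k(x,y) / sqrt(k(x,x) k(y,y))`; rows/columns with a zero
#' diagonal become 0.
#'
#' @param K Square kernel matrix.
#' @return Normalized matrix with unit diagonal where defined.
#' @export
normalize_gram <- function(K) {
  dn <- sqrt(pmax(diag(K), 0))
  sc <- ifelse(dn > 0, 1 / dn, 0)
  K * outer(sc, sc)
}

#' Gram matrix over prepared instances
#'
#' `"fea"`: pairwise linear kernel of the sparse feature vectors.
#' `"dstk"`: pairwise Frobenius products of the flattened DST matrices.
#' `"ckl"`: cosine-normalize both components, then `fea' + w * dstk'`.
#' Single kernels are normalized when `config$normalize` is TRUE.
#'
#' @param prep A `ppi_prep`.
#' @param kernel One of `"fea"`, `"dstk"`, `"ckl"`.
#' @param config Defaults to the config stored in `prep`.
#' @return Symmetric PSD matrix with attribute `kernel`.
#' @export
gram_matrix <- function(prep, kernel = c("fea", "dstk", "ckl"),
                        config = prep$config) {
  kernel <- match.arg(kernel)
  raw <- function(tag) {
    if (tag == "fea") return(feature_gram(prep$features))
    if (is.null(prep$dst_flat)) {
      stop("DST matrices were not prepared (need_trees = FALSE?)")
    }
    tcrossprod(prep$dst_flat)
  }
  K <- if (kernel == "ckl") {
    normalize_gram(raw("fea")) + config$w * normalize_gram(raw("dstk"))
  } else {
    K0 <- raw(kernel)
    if (config$normalize) normalize_gram(K0) else K0
  }
  attr(K, "kernel") <- kernel
  K
}

#' Train the max-margin classifier on a precomputed Gram
#'
#' @param K Training Gram matrix (square, over training instances).
#' @param y Factor with levels `negative`, `positive`; both classes must
#'   be present.
#' @param C Soft-margin constant.
#' @return A `ppi_svm`: kernlab model plus bookkeeping.
#' @export
train_svm <- function(K, y, C = 1) {
  y <- factor(y, levels = c("negative", "positive"))
  if (nlevels(droplevels(y)) < 2) {
    stop("training set contains a single class")
  }
  # shrinking heuristics can stall kernlab's SMO on the near-singular
  # Grams that template-heavy corpora produce; disabling them is faster
  # here and does not change the solution
  model <- kernlab::ksvm(kernlab::as.kernelMatrix(K), y, C = C,
                         shrinking = FALSE)
  structure(list(model = model, n_train = nrow(K),
                 sv_index = kernlab::SVindex(model)),
            class = "ppi_svm")
}

#' Predict with a precomputed test-vs-train kernel block
#'
#' Decision values are oriented so that larger means more positive
#' (checked against the model's own class predictions).
#'
#' @param fit A `ppi_svm`.
#' @param K_test_train Matrix of kernel values, test rows x training
#'   columns.
#' @return List with `class` (factor) and `score` (oriented decision
#'   values).
#' @export
predict_svm <- function(fit, K_test_train) {
  if (ncol(K_test_train) != fit$n_train) {
    stop("test kernel block has ", ncol(K_test_train),
         " columns; expected ", fit$n_train)
  }
  Ksub <- kernlab::as.kernelMatrix(
    K_test_train[, fit$sv_index, drop = FALSE]
  )
  cls <- kernlab::predict(fit$model, Ksub)
  dec <- as.numeric(kernlab::predict(fit$model, Ksub, type = "decision"))
  pos <- cls == "positive"
  if (any(pos) && any(!pos) &&
      mean(dec[pos]) < mean(dec[!pos])) {
    dec <- -dec
  } else if (all(pos) && mean(dec) < 0) {
    dec <- -dec
  } else if (all(!pos) && mean(dec) > 0) {
    dec <- -dec
  }
  list(class = factor(as.character(cls), levels = c("negative", "positive")),
       score = dec)
}

confusion_counts <- function(truth, pred) {
  c(TP = sum(truth == "positive" & pred == "positive"),
    FP = sum(truth == "negative" & pred == "positive"),
    FN = sum(truth == "positive" & pred == "negative"),
    TN = sum(truth == "negative" & pred == "negative"))
}

#' Precision, recall and F-score from confusion counts
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F = 2PR/(P+R)`. Undefined ratios
#' (zero denominators) are reported as 0 with a warning.
#'
#' @param cc Named vector with `TP`, `FP`, `FN`.
#' @return Named vector `P`, `R`, `F`.
#' @export
prf_metrics <- function(cc) {
  P <- if (cc["TP"] + cc["FP"] > 0) cc["TP"] / (cc["TP"] + cc["FP"]) else {
    warning("precision undefined (no positive predictions); reporting 0",
            call. = FALSE)
    0
  }
  R <- if (cc["TP"] + cc["FN"] > 0) cc["TP"] / (cc["TP"] + cc["FN"]) else {
    warning("recall undefined (no positive instances); reporting 0",
            call. = FALSE)
    0
  }
  F <- if (P + R > 0) 2 * P * R / (P + R) else 0
  c(P = unname(P), R = unname(R), F = unname(F))
}

# Stratified fold assignment: each class is split as evenly as possible.
stratified_folds <- function(y, folds, seed) {
  assign <- integer(length(y))
  with_seed(derive_seed(seed, "folds"), {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      if (length(idx) < folds) {
        stop("class '", cl, "' has ", length(idx),
             " instances; need at least ", folds, " for ", folds, "-fold CV")
      }
      assign[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  assign
}

roc_points <- function(truth, score) {
  r <- pROC::roc(response = truth, predictor = score,
                 levels = c("negative", "positive"), direction = "<",
                 quiet = TRUE)
  data.frame(FPR = rev(1 - r$specificities), TPR = rev(r$sensitivities),
             row.names = NULL)
}

#' Stratified k-fold cross-validation of the three kernels
#'
#' Computes each requested Gram once over the full instance set, then for
#' every fold trains on the complement and predicts the held-out block.
#' Metrics are reported per fold and micro-averaged (pooled confusion
#' counts); the ROC curve is computed from the pooled decision values.
#'
#' @param prep A `ppi_prep` (or a `ppi_corpus`, which is prepared with
#'   `config`).
#' @param config A `kernel_config`.
#' @param folds Number of folds (default 10).
#' @param seed Fold-assignment seed (default 1).
#' @param kernels Kernel tags to evaluate.
#' @return Named list of `eval_report`s: `per_fold` (data frame),
#'   `aggregate` (pooled counts and metrics), `roc`, `auc`.
#' @export
cross_validate <- function(prep, config = kernel_config(), folds = 10L,
                           seed = 1L, kernels = c("fea", "dstk", "ckl")) {
  if (inherits(prep, "ppi_corpus")) {
    prep <- prepare_instances(prep, config,
                              need_trees = any(kernels != "fea"))
  }
  config <- prep$config %||% config
  y <- prep$labels
  fold_of <- stratified_folds(y, folds, seed)
  grams <- list()
  for (tag in unique(kernels)) grams[[tag]] <- gram_matrix(prep, tag, config)
  reports <- list()
  for (tag in unique(kernels)) {
    K <- grams[[tag]]
    per_fold <- NULL
    pooled_truth <- character(0)
    pooled_score <- numeric(0)
    pooled_cc <- c(TP = 0, FP = 0, FN = 0, TN = 0)
    for (f in seq_len(folds)) {
      te <- which(fold_of == f)
      tr <- which(fold_of != f)
      pred <- if (tag == "ckl" && config$ensemble_mode == "score_avg") {
        score_avg_predict(grams, tr, te, y, config)
      } else {
        fit <- train_svm(K[tr, tr, drop = FALSE], y[tr], C = config$C)
        predict_svm(fit, K[te, tr, drop = FALSE])
      }
      cc <- confusion_counts(y[te], pred$class)
      m <- suppressWarnings(prf_metrics(cc))
      per_fold <- rbind(per_fold,
                        data.frame(fold = f, t(cc), t(m)))
      pooled_cc <- pooled_cc + cc
      pooled_truth <- c(pooled_truth, as.character(y[te]))
      pooled_score <- c(pooled_score, pred$score)
    }
    agg <- prf_metrics(pooled_cc)
    roc <- roc_points(factor(pooled_truth,
                             levels = c("negative", "positive")),
                      pooled_score)
    auc <- as.numeric(pROC::auc(pROC::roc(
      response = pooled_truth, predictor = pooled_score,
      levels = c("negative", "positive"), direction = "<", quiet = TRUE
    )))
    reports[[tag]] <- structure(
      list(kernel = tag, per_fold = per_fold,
           aggregate = c(pooled_cc, agg), roc = roc, auc = auc),
      class = "eval_report"
    )
  }
  reports
}

# Score-averaging ensemble variant: one SVM per component kernel, the
# composite decision is the mean of the oriented decision values.
score_avg_predict <- function(grams, tr, te, y, config) {
  stopifnot(!is.null(grams$fea), !is.null(grams$dstk))
  p1 <- predict_svm(train_svm(grams$fea[tr, tr, drop = FALSE], y[tr],
                              C = config$C),
                    grams$fea[te, tr, drop = FALSE])
  p2 <- predict_svm(train_svm(grams$dstk[tr, tr, drop = FALSE], y[tr],
                              C = config$C),
                    grams$dstk[te, tr, drop = FALSE])
  score <- (p1$score + config$w * p2$score) / (1 + config$w)
  list(class = factor(ifelse(score > 0, "positive", "negative"),
                      levels = c("negative", "positive")),
       score = score)
}

#' Tabulate cross-validation reports
#'
#' @param reports Named list from [cross_validate()] (or a named list of
#'   such lists, one per corpus).
#' @param corpus_name Label for the `corpus` column when `reports` is a
#'   single-run list.
#' @return Data frame `corpus,kernel,fold,TP,FP,FN,TN,P,R,F`; the pooled
#'   row has `fold = "all"`.
#' @export
report_table <- function(reports, corpus_name = "corpus") {
  if (length(reports) > 0 && inherits(reports[[1]], "eval_report")) {
    reports <- stats::setNames(list(reports), corpus_name)
  }
  rows <- list()
  for (cname in names(reports)) {
    for (tag in names(reports[[cname]])) {
      rep <- reports[[cname]][[tag]]
      pf <- rep$per_fold
      pf$corpus <- cname; pf$kernel <- tag
      pf$fold <- as.character(pf$fold)
      agg <- as.list(rep$aggregate)
      rows[[length(rows) + 1]] <- rbind(
        pf[, c("corpus", "kernel", "fold", "TP", "FP", "FN", "TN",
               "P", "R", "F")],
        data.frame(corpus = cname, kernel = tag, fold = "all",
                   TP = agg$TP, FP = agg$FP, FN = agg$FN, TN = agg$TN,
                   P = agg$P, R = agg$R, F = agg$F)
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write evaluation results (CSV + JSON) and ROC points (CSV)
#'
#' @param reports As accepted by [report_table()].
#' @param dir Output directory (created if needed).
#' @param corpus_name Passed to [report_table()].
#' @return Invisibly, the paths written.
#' @export
write_results <- function(reports, dir, corpus_name = "corpus") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- report_table(reports, corpus_name)
  csv <- file.path(dir, "results.csv")
  utils::write.csv(tab, csv, row.names = FALSE)
  js <- file.path(dir, "results.json")
  jsonlite::write_json(tab, js, dataframe = "rows", digits = NA)
  if (inherits(reports[[1]], "eval_report")) {
    reports <- stats::setNames(list(reports), corpus_name)
  }
  roc_rows <- list()
  for (cname in names(reports)) {
    for (tag in names(reports[[cname]])) {
      r <- reports[[cname]][[tag]]$roc
      r$corpus <- cname; r$kernel <- tag
      roc_rows[[length(roc_rows) + 1]] <- r
    }
  }
  roc_csv <- file.path(dir, "roc.csv")
  utils::write.csv(do.call(rbind, roc_rows), roc_csv, row.names = FALSE)
  invisible(c(csv, js, roc_csv))
}

#' @export
print.eval_report <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf("eval_report [%s]: P=%.3f R=%.3f F=%.3f (TP=%d FP=%d FN=%d TN=%d), AUC=%.3f\n",
              x$kernel, a["P"], a["R"], a["F"],
              a["TP"], a["FP"], a["FN"], a["TN"], x$auc))
  invisible(x)
}
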