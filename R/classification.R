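# Shared rpart settings: fully grown Gini trees (no pruning, minimum leaf
# size 1), the base learner for both ensembles.
base_tree_control <- function() {
  rpart::rpart.control(minsplit = 2L, minbucket = 1L, cp = 0, maxdepth = 30L,
                       xval = 0L, maxsurrogate = 0L, maxcompete = 0L)
}

fit_base_tree <- function(X, y) {
  if (length(unique(y)) < 2L) {
    # a bootstrap replica can miss the rare class entirely; such a tree is
    # a constant vote for the class it saw
    return(structure(list(const = y[[1L]]), class = "nettop_stump"))
  }
  df <- as.data.frame(X)
  df$.label <- factor(y, levels = c(0L, 1L))
  rpart::rpart(.label ~ ., data = df, method = "class",
               parms = list(split = "gini"), control = base_tree_control())
}

tree_votes <- function(tree, X) {
  if (inherits(tree, "nettop_stump")) {
    return(rep(as.integer(tree$const), nrow(as.data.frame(X))))
  }
  p <- predict(tree, as.data.frame(X), type = "class")
  as.integer(as.character(p))
}

#' Train a Decision Tree Bagger (DTB)
#'
#' Fits `n_trees` fully grown Gini decision trees, each on an independent
#' bootstrap replica of size N (N observations drawn from N with
#' replacement).  The ensemble score of a row is the fraction of trees
#' voting for the positive class.
#'
#' @param data labeled dataset (numeric features plus `label` in \{0, 1\})
#' @param n_trees number of bagged trees
#' @param seed integer seed (bootstrap replicas are deterministic given it)
#' @return a `nettop_model` (family `"dtb"`); use [predict.nettop_model()]
#'   for scores in `[0, 1]`
#' @export
train_dtb <- function(data, n_trees = 100L, seed = 1L) {
  feats <- feature_columns(data)
  y <- data$label
  if (length(unique(y)) < 2L) stop("training data contains a single class")
  if (n_trees < 1L) stop("n_trees must be >= 1")
  X <- as.matrix(data[, feats, drop = FALSE])
  n <- nrow(X)
  set.seed(seed)
  trees <- vector("list", n_trees)
  inbag <- vector("list", n_trees)
  for (t in seq_len(n_trees)) {
    idx <- sample.int(n, n, replace = TRUE)
    inbag[[t]] <- idx
    trees[[t]] <- fit_base_tree(X[idx, , drop = FALSE], y[idx])
  }
  structure(list(family = "dtb", trees = trees, weights = rep(1, n_trees),
                 inbag = inbag, features = feats, n_train = n, seed = seed),
            class = "nettop_model")
}

#' Train a RUSBoost ensemble
#'
#' Boosting for class-imbalanced data: each round trains a Gini tree on all
#' minority rows plus an equal number of majority rows sampled without
#' replacement according to the current boosting weights, then reweights
#' misclassified rows as in discrete AdaBoost.  With balanced input no row
#' is removed and the procedure reduces to plain boosting.
#'
#' @param data labeled dataset (numeric features plus `label` in \{0, 1\})
#' @param n_rounds number of boosting rounds
#' @param seed integer seed
#' @return a `nettop_model` (family `"rusboost"`); scores are the
#'   alpha-weighted fraction of positive votes, in `[0, 1]`
#' @export
train_rusboost <- function(data, n_rounds = 100L, seed = 1L) {
  feats <- feature_columns(data)
  y <- data$label
  if (length(unique(y)) < 2L) stop("training data contains a single class")
  X <- as.matrix(data[, feats, drop = FALSE])
  n <- nrow(X)
  counts <- table(factor(y, levels = c(0L, 1L)))
  minority_label <- as.integer(names(counts)[which.min(counts)])
  min_idx <- which(y == minority_label)
  maj_idx <- which(y != minority_label)
  n_min <- length(min_idx)

  set.seed(seed)
  w <- rep(1 / n, n)
  trees <- list()
  alphas <- numeric(0)
  for (round in seq_len(n_rounds)) {
    maj_take <- if (length(maj_idx) > n_min) {
      sample(maj_idx, n_min, replace = FALSE, prob = w[maj_idx])
    } else {
      maj_idx
    }
    idx <- c(min_idx, maj_take)
    tree <- fit_base_tree(X[idx, , drop = FALSE], y[idx])
    pred <- tree_votes(tree, X)
    wrong <- pred != y
    err <- sum(w[wrong])
    err <- min(max(err, 1e-10), 1 - 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    if (alpha <= 0) {
      # worse than chance under current weights: skip the round
      next
    }
    trees[[length(trees) + 1L]] <- tree
    alphas <- c(alphas, alpha)
    w <- w * exp(ifelse(wrong, alpha, -alpha))
    w <- w / sum(w)
  }
  if (length(trees) == 0L) {
    stop("RUSBoost failed: no round achieved better-than-chance accuracy")
  }
  structure(list(family = "rusboost", trees = trees, weights = alphas,
                 inbag = NULL, features = feats, n_train = n, seed = seed),
            class = "nettop_model")
}

#' Score new rows with a fitted ensemble
#'
#' @param object a `nettop_model` from [train_dtb()] or [train_rusboost()]
#' @param newdata data.frame containing the model's feature columns
#' @param ... unused
#' @return numeric scores in `[0, 1]` (weighted fraction of positive votes)
#' @export
predict.nettop_model <- function(object, newdata, ...) {
  X <- as.matrix(as.data.frame(newdata)[, object$features, drop = FALSE])
  votes <- vapply(object$trees, function(tr) as.numeric(tree_votes(tr, X)),
                  numeric(nrow(X)))
  votes <- matrix(votes, nrow = nrow(X))
  as.vector(votes %*% object$weights) / sum(object$weights)
}

#' @export
print.nettop_model <- function(x, ...) {
  cat(sprintf("<nettop_model> family=%s, %d trees, %d training rows\n",
              x$family, length(x$trees), x$n_train))
  invisible(x)
}

#' Confusion counts at a decision threshold
#'
#' Rows with `score >= threshold` are predicted positive.
#'
#' @param scores numeric scores
#' @param labels binary labels (1 = positive), aligned with `scores`
#' @param threshold decision threshold (default 0.5)
#' @return list of class `nettop_confusion` with `TP`, `FP`, `TN`, `FN`
#' @export
evaluate <- function(scores, labels, threshold = 0.5) {
  if (length(scores) != length(labels)) {
    stop("`scores` and `labels` must have the same length")
  }
  pred <- as.integer(scores >= threshold)
  structure(list(TP = sum(pred == 1L & labels == 1L),
                 FP = sum(pred == 1L & labels == 0L),
                 TN = sum(pred == 0L & labels == 0L),
                 FN = sum(pred == 0L & labels == 1L)),
            class = "nettop_confusion")
}

safe_ratio <- function(num, den) if (den == 0) 0 else num / den

#' Performance metrics from confusion counts
#'
#' ACC = (TP+TN)/N, PPV = TP/(TP+FP), SN = TP/(TP+FN), SP = TN/(TN+FP),
#' F = 2*SN*PPV/(SN+PPV), Gm = sqrt(SN*SP); AUC by trapezoid over the ROC
#' curve when scores are supplied.  Ratios with a zero denominator are
#' reported as 0 and the affected metric names are recorded in the
#' `degenerate` attribute.
#'
#' @param counts a `nettop_confusion` from [evaluate()]
#' @param scores,labels optional; when both are given AUC is added
#' @return named numeric vector of class `nettop_metrics`
#' @export
metrics <- function(counts, scores = NULL, labels = NULL) {
  n <- counts$TP + counts$TN + counts$FP + counts$FN
  if (n == 0L) stop("empty confusion table")
  degenerate <- character(0)
  ratio <- function(num, den, name) {
    if (den == 0) {
      degenerate <<- c(degenerate, name)
      0
    } else num / den
  }
  acc <- (counts$TP + counts$TN) / n
  ppv <- ratio(counts$TP, counts$TP + counts$FP, "PPV")
  sn <- ratio(counts$TP, counts$TP + counts$FN, "SN")
  sp <- ratio(counts$TN, counts$TN + counts$FP, "SP")
  f <- ratio(2 * sn * ppv, sn + ppv, "F")
  gm <- sqrt(sn * sp)
  out <- c(ACC = acc, PPV = ppv, SN = sn, SP = sp, F = f, Gm = gm)
  if (!is.null(scores) && !is.null(labels)) {
    out <- c(out, AUC = roc_auc(scores, labels)$auc)
  }
  structure(out, degenerate = degenerate, class = "nettop_metrics")
}

#' @export
print.nettop_metrics <- function(x, ...) {
  print(round(unclass(x), 4))
  deg <- attr(x, "degenerate")
  if (length(deg) > 0L) {
    cat("degenerate (0/0 reported as 0):", paste(deg, collapse = ", "), "\n")
  }
  invisible(x)
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over the unique scores; each point plots
#' (1 - SP, SN).  The curve runs from (0, 0) to (1, 1) and the trapezoid
#' area equals the Mann-Whitney probability that a random positive outscores
#' a random negative (ties counted half).
#'
#' @param scores numeric scores, higher = more positive
#' @param labels binary labels with both classes present
#' @return list with `curve` (data.frame `fpr`, `tpr`) and `auc`
#' @export
roc_auc <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop("`scores` and `labels` must have the same length")
  }
  pos <- labels == 1L
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC requires both classes present")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- pos[ord]
  is_last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(p)[is_last_of_tie]
  fp <- cumsum(!p)[is_last_of_tie]
  curve <- data.frame(fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos))
  auc <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                                  utils::tail(curve$tpr, -1)) / 2)
  list(curve = curve, auc = auc)
}

#' Stratified k-fold cross-validation of the full pipeline
#'
#' Splits rows into `k_folds` stratified folds (both classes represented in
#' every fold).  Within each fold, feature selection (backward elimination)
#' and SMOTE are applied to the training rows only, so no synthetic sample
#' and no selection decision ever touches a test fold.  RUSBoost performs
#' its own majority undersampling and is refused in combination with SMOTE.
#' Per-metric results are summarized as `M +/- 1.96 * sigma_M` (95%
#' confidence interval on the fold mean, `sigma_M` the standard error).
#'
#' @param table feature table (column `vertex` plus numeric features)
#' @param signature character vector of positive gene identifiers
#' @param model_family `"dtb"` or `"rusboost"`
#' @param k_folds number of folds (default 10)
#' @param use_smote balance each training fold with [smote()]
#' @param select_features run in-fold backward elimination (inner 3-fold CV
#'   on training rows) before fitting
#' @param seed integer seed governing folds, SMOTE, and model fits
#' @param n_trees ensemble size per fold
#' @param smote_k SMOTE neighbourhood size
#' @param threshold decision threshold for the confusion-based metrics
#' @return a `nettop_cv` list: `per_fold` (fold-by-metric data.frame),
#'   `summary` (mean, standard error, 95% CI half-width per metric),
#'   `folds` (fold id per input row), `fold_detail` (per fold: test
#'   vertices, synthetic-row count, selected features)
#' @export
cross_validate <- function(table, signature,
                           model_family = c("dtb", "rusboost"),
                           k_folds = 10L, use_smote = TRUE,
                           select_features = FALSE, seed = 1L,
                           n_trees = 100L, smote_k = 5L, threshold = 0.5) {
  model_family <- match.arg(model_family)
  if (k_folds < 2L) stop("k_folds must be >= 2")
  if (model_family == "rusboost" && use_smote) {
    stop("RUSBoost performs its own majority undersampling, which conflicts ",
         "with SMOTE oversampling; use use_smote = FALSE with rusboost")
  }
  data <- suppressMessages(label_dataset(table, signature))
  n <- nrow(data)
  if (sum(data$label == 1L) < k_folds) {
    stop("too few positive rows for stratified folds")
  }
  set.seed(seed)
  folds <- integer(n)
  for (cls in c(0L, 1L)) {
    idx <- sample(which(data$label == cls))
    folds[idx] <- rep_len(seq_len(k_folds), length(idx))
  }

  per_fold <- NULL
  detail <- vector("list", k_folds)
  for (kf in seq_len(k_folds)) {
    test_idx <- which(folds == kf)
    train <- data[-test_idx, , drop = FALSE]
    test <- data[test_idx, , drop = FALSE]
    if (length(unique(train$label)) < 2L) {
      stop(sprintf("fold %d has single-class training data", kf))
    }
    selected <- feature_columns(train)
    if (select_features) {
      be <- backward_elimination(
        train[, c("vertex", selected), drop = FALSE],
        train$vertex[train$label == 1L],
        model_family = model_family, k_folds = 3L,
        use_smote = use_smote, seed = seed + kf,
        n_trees = max(25L, n_trees %/% 4L), smote_k = smote_k)
      selected <- be$survivors
      train <- train[, c("vertex", selected, "label", "provenance"),
                     drop = FALSE]
    }
    n_synth <- 0L
    if (use_smote) {
      train <- smote(train, k_neighbors = smote_k, seed = seed + kf)
      n_synth <- sum(train$provenance == "synthetic")
    }
    model <- if (model_family == "dtb") {
      train_dtb(train, n_trees = n_trees, seed = seed + kf)
    } else {
      train_rusboost(train, n_rounds = n_trees, seed = seed + kf)
    }
    scores <- predict(model, test[, selected, drop = FALSE])
    cm <- evaluate(scores, test$label, threshold = threshold)
    m <- if (length(unique(test$label)) == 2L) {
      metrics(cm, scores, test$label)
    } else {
      c(metrics(cm), AUC = NA_real_)
    }
    per_fold <- rbind(per_fold, as.data.frame(as.list(unclass(m))))
    detail[[kf]] <- list(test_vertices = test$vertex,
                         train_vertices = train$vertex,
                         n_synthetic = n_synth,
                         selected = selected)
  }
  per_fold <- cbind(fold = seq_len(k_folds), per_fold)
  met_names <- setdiff(names(per_fold), "fold")
  summ <- do.call(rbind, lapply(met_names, function(mn) {
    v <- per_fold[[mn]]
    v <- v[!is.na(v)]
    m <- mean(v)
    se <- stats::sd(v) / sqrt(length(v))
    data.frame(metric = mn, mean = m, se = se, half_width = 1.96 * se)
  }))
  structure(list(per_fold = per_fold, summary = summ, folds = folds,
                 fold_detail = detail, model_family = model_family,
                 use_smote = use_smote, k_folds = k_folds, seed = seed),
            class = "nettop_cv")
}

#' @export
print.nettop_cv <- function(x, ...) {
  cat(sprintf("<nettop_cv> %s, %d-fold%s\n", x$model_family, x$k_folds,
              if (x$use_smote) " + SMOTE" else ""))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-4s %.3f +/- %.3f\n", s$metric[i], s$mean[i],
                s$half_width[i]))
  }
  invisible(x)
}
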