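# Gini impurity of a vector of class counts.
gini_impurity <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  1 - sum((counts / n)^2)
}

#' Gini (impurity-decrease) feature importance
#'
#' For every split in every tree of the ensemble, credits the split feature
#' with the node-size-weighted Gini impurity decrease
#' `n * g(node) - n_left * g(left) - n_right * g(right)`, and sums the
#' credit per feature.  Reported unnormalized (no division by the number of
#' trees), so magnitudes grow with ensemble and training-set size.
#'
#' @param model a fitted `nettop_model`
#' @return named nonnegative vector over the model's features; a feature
#'   never split on scores 0
#' @export
gini_importance <- function(model) {
  if (!inherits(model, "nettop_model") || length(model$trees) == 0L) {
    stop("`model` must be a fitted nettop_model")
  }
  imp <- stats::setNames(numeric(length(model$features)), model$features)
  for (tree in model$trees) {
    if (inherits(tree, "nettop_stump")) next
    fr <- tree$frame
    if (nrow(fr) < 2L) next
    node_id <- as.integer(rownames(fr))
    counts <- fr$yval2[, 2:3, drop = FALSE]
    g <- apply(counts, 1L, gini_impurity)
    n <- fr$n
    splits <- which(fr$var != "<leaf>")
    for (i in splits) {
      left <- match(node_id[i] * 2L, node_id)
      right <- match(node_id[i] * 2L + 1L, node_id)
      drop_val <- n[i] * g[i] - n[left] * g[left] - n[right] * g[right]
      v <- as.character(fr$var[i])
      imp[v] <- imp[v] + drop_val
    }
  }
  imp
}

# Out-of-bag ensemble accuracy at threshold 0.5.  `columns_override` lets a
# caller swap one feature column (used by the permutation importance).
oob_accuracy <- function(model, X, y, columns_override = NULL) {
  Xd <- as.data.frame(X)
  if (!is.null(columns_override)) {
    for (nm in names(columns_override)) Xd[[nm]] <- columns_override[[nm]]
  }
  n <- nrow(Xd)
  votes <- matrix(NA_real_, n, length(model$trees))
  for (t in seq_along(model$trees)) {
    oob <- setdiff(seq_len(n), model$inbag[[t]])
    if (length(oob) == 0L) next
    votes[oob, t] <- tree_votes(model$trees[[t]], Xd[oob, , drop = FALSE])
  }
  score <- rowMeans(votes, na.rm = TRUE)
  valid <- !is.nan(score)
  mean((score[valid] >= 0.5) == (y[valid] == 1L))
}

#' Permutation (accuracy) feature importance
#'
#' Mean decrease in out-of-bag accuracy when a feature's column is randomly
#' permuted, averaged over `n_repeats` permutations.  Requires the bagged
#' ensemble's bootstrap structure; for models without it (RUSBoost) the
#' decrease is measured on the supplied data with full-ensemble
#' predictions, with a warning.
#'
#' @param model a fitted `nettop_model`
#' @param data the model's training data (labeled dataset)
#' @param seed integer seed for the permutations
#' @param n_repeats permutations averaged per feature
#' @return named numeric vector (can be slightly negative for noise
#'   features)
#' @export
accuracy_importance <- function(model, data, seed = 1L, n_repeats = 10L) {
  feats <- model$features
  X <- data[, feats, drop = FALSE]
  y <- data$label
  if (nrow(X) == 0L) stop("`data` is empty")
  has_oob <- !is.null(model$inbag)
  if (!has_oob) {
    warning("model carries no bootstrap structure; ",
            "falling back to held-out permutation on the supplied data")
  }
  n <- nrow(X)
  set.seed(seed)
  perms <- replicate(n_repeats, sample.int(n), simplify = FALSE)
  imp <- stats::setNames(numeric(length(feats)), feats)

  if (has_oob) {
    base <- oob_accuracy(model, X, y)
    oob_rows <- lapply(model$inbag, function(idx) setdiff(seq_len(n), idx))
    for (f in feats) {
      # stack the n_repeats permuted copies and predict each tree once on
      # its out-of-bag rows across all copies (predict-call overhead
      # dominates the cost otherwise)
      Xbig <- X[rep(seq_len(n), n_repeats), , drop = FALSE]
      Xbig[[f]] <- unlist(lapply(perms, function(p) X[[f]][p]),
                          use.names = FALSE)
      votes <- matrix(NA_real_, n * n_repeats, length(model$trees))
      for (t in seq_along(model$trees)) {
        rows <- as.vector(outer(oob_rows[[t]],
                                (seq_len(n_repeats) - 1L) * n, "+"))
        if (length(rows) == 0L) next
        votes[rows, t] <- tree_votes(model$trees[[t]],
                                     Xbig[rows, , drop = FALSE])
      }
      score <- rowMeans(votes, na.rm = TRUE)
      ok <- !is.nan(score)
      correct <- (score >= 0.5) == (rep(y, n_repeats) == 1L)
      acc_per_rep <- vapply(seq_len(n_repeats), function(r) {
        idx <- seq_len(n) + (r - 1L) * n
        mean(correct[idx][ok[idx]])
      }, 0)
      imp[f] <- mean(base - acc_per_rep)
    }
  } else {
    base <- mean((predict(model, X) >= 0.5) == (y == 1L))
    for (f in feats) {
      drops <- vapply(perms, function(p) {
        Xd <- X
        Xd[[f]] <- X[[f]][p]
        base - mean((predict(model, Xd) >= 0.5) == (y == 1L))
      }, 0)
      imp[f] <- mean(drops)
    }
  }
  imp
}

#' Combined importance score
#'
#' Geometric mean of the accuracy-based and Gini-based importance of a
#' feature, `sqrt(a * g)`; puts the two scores, which live on very
#' different scales, on a common footing.  Tabular output conventionally
#' rounds it to 2 decimals.
#'
#' @param accuracy_importance,gini_importance nonnegative numbers
#'   (vectorized)
#' @return `sqrt(accuracy_importance * gini_importance)`
#' @export
combined_score <- function(accuracy_importance, gini_importance) {
  if (any(accuracy_importance < 0) || any(gini_importance < 0)) {
    stop("combined_score requires nonnegative inputs")
  }
  sqrt(accuracy_importance * gini_importance)
}

#' Full importance table for a fitted ensemble
#'
#' Accuracy importance, Gini importance, and the combined score per
#' feature, sorted by combined score descending.  Negative accuracy
#' importances (noise features) are clamped to 0 before combining.
#'
#' @inheritParams accuracy_importance
#' @return data.frame with columns `feature`, `accuracy_importance`,
#'   `gini_importance`, `combined_score`
#' @export
importance_table <- function(model, data, seed = 1L, n_repeats = 10L) {
  acc <- accuracy_importance(model, data, seed = seed, n_repeats = n_repeats)
  gin <- gini_importance(model)
  out <- data.frame(feature = names(acc),
                    accuracy_importance = unname(acc),
                    gini_importance = unname(gin[names(acc)]),
                    stringsAsFactors = FALSE)
  out$combined_score <- combined_score(pmax(out$accuracy_importance, 0),
                                       out$gini_importance)
  out[order(-out$combined_score), , drop = FALSE]
}

#' Feature importance for a labeled network (model-averaged)
#'
#' The user-facing importance analysis: labels the feature table, balances
#' it with SMOTE (for the bagged-tree family), then trains `n_models`
#' independently seeded ensembles and averages their accuracy and Gini
#' importances before combining.  With several near-collinear topological
#' features a single tree ensemble concentrates split credit on an
#' arbitrary member of a correlated group; averaging over independent fits
#' (different bootstrap and SMOTE draws) stabilizes the ranking.
#'
#' @param table feature table (column `vertex` plus numeric features)
#' @param signature character vector of positive gene identifiers
#' @param model_family `"dtb"` or `"rusboost"`
#' @param n_models independently seeded fits to average over
#' @param n_trees ensemble size per fit
#' @param seed integer base seed
#' @param use_smote balance the training data with SMOTE (refused for
#'   rusboost, which undersamples internally)
#' @param n_repeats permutations per feature for the accuracy importance
#' @return data.frame with columns `feature`, `accuracy_importance`,
#'   `gini_importance`, `combined_score`, sorted by combined score
#'   descending
#' @export
feature_importance <- function(table, signature, model_family = "dtb",
                               n_models = 5L, n_trees = 100L, seed = 1L,
                               use_smote = TRUE, n_repeats = 10L) {
  if (model_family == "rusboost" && use_smote) {
    stop("RUSBoost performs its own majority undersampling, which conflicts ",
         "with SMOTE oversampling; use use_smote = FALSE with rusboost")
  }
  labeled <- suppressMessages(label_dataset(table, signature))
  acc <- gin <- NULL
  for (i in seq_len(n_models)) {
    s <- seed + (i - 1L) * 101L
    fit_data <- if (use_smote) smote(labeled, seed = s) else labeled
    model <- if (model_family == "dtb") {
      train_dtb(fit_data, n_trees = n_trees, seed = s)
    } else {
      train_rusboost(fit_data, n_rounds = n_trees, seed = s)
    }
    a <- accuracy_importance(model, fit_data, seed = s,
                             n_repeats = n_repeats)
    g <- gini_importance(model)
    if (is.null(acc)) {
      acc <- a
      gin <- g[names(a)]
    } else {
      acc <- acc + a[names(acc)]
      gin <- gin + g[names(acc)]
    }
  }
  acc <- acc / n_models
  gin <- gin / n_models
  out <- data.frame(feature = names(acc),
                    accuracy_importance = unname(acc),
                    gini_importance = unname(gin),
                    stringsAsFactors = FALSE)
  out$combined_score <- combined_score(pmax(out$accuracy_importance, 0),
                                       out$gini_importance)
  out[order(-out$combined_score), , drop = FALSE]
}

#' Backward feature elimination by cross-validated G-mean
#'
#' Greedy backward search: at each step removes the feature whose removal
#' maximizes the mean cross-validated G-mean, continuing while the score
#' does not decrease (so redundant and constant features are pruned even
#' when they are merely harmless), and stopping as soon as every removal
#' would lower it.  Ties between candidate removals are broken by dropping
#' the feature with the lower combined importance score.  Feature selection
#' that feeds a cross-validated performance claim must run inside the
#' training folds; [cross_validate()] with `select_features = TRUE` does
#' exactly that using this routine.
#'
#' @param table feature table (column `vertex` plus numeric features, >= 2
#'   features)
#' @param signature character vector of positive gene identifiers
#' @param model_family `"dtb"` or `"rusboost"`
#' @param k_folds folds for the internal cross-validation
#' @param use_smote balance internal training folds with SMOTE
#' @param seed integer seed
#' @param n_trees ensemble size per internal fit
#' @param smote_k SMOTE neighbourhood size
#' @return list with `survivors` (character vector of retained features)
#'   and `trace` (data.frame per step: features remaining, feature removed,
#'   mean G-mean)
#' @export
backward_elimination <- function(table, signature,
                                 model_family = c("dtb", "rusboost"),
                                 k_folds = 10L, use_smote = TRUE,
                                 seed = 1L, n_trees = 50L, smote_k = 5L) {
  model_family <- match.arg(model_family)
  features <- setdiff(names(table), NON_FEATURE_COLS)
  if (length(features) < 2L) stop("backward elimination needs >= 2 features")

  gmean_of <- function(feats) {
    cv <- cross_validate(table[, c("vertex", feats), drop = FALSE],
                         signature, model_family = model_family,
                         k_folds = k_folds, use_smote = use_smote,
                         select_features = FALSE, seed = seed,
                         n_trees = n_trees, smote_k = smote_k)
    cv$summary$mean[cv$summary$metric == "Gm"]
  }

  combined <- NULL  # tie-break table, computed lazily
  tie_break_order <- function(cands) {
    if (is.null(combined)) {
      labeled <- suppressMessages(label_dataset(table, signature))
      fit_data <- if (use_smote && model_family == "dtb") {
        smote(labeled, k_neighbors = smote_k, seed = seed)
      } else labeled
      model <- if (model_family == "dtb") {
        train_dtb(fit_data, n_trees = n_trees, seed = seed)
      } else {
        train_rusboost(fit_data, n_rounds = n_trees, seed = seed)
      }
      combined <<- importance_table(model, fit_data, seed = seed,
                                    n_repeats = 3L)
    }
    sc <- combined$combined_score[match(cands, combined$feature)]
    cands[order(sc)]   # lowest combined score removed first
  }

  current <- gmean_of(features)
  trace <- data.frame(step = 0L, n_features = length(features),
                      removed = NA_character_, gmean = current,
                      stringsAsFactors = FALSE)
  step <- 0L
  while (length(features) > 1L) {
    cand <- vapply(features,
                   function(f) gmean_of(setdiff(features, f)), 0)
    best <- max(cand)
    if (best < current) break
    winners <- features[cand == best]
    drop_feat <- if (length(winners) > 1L) {
      tie_break_order(winners)[1L]
    } else winners
    features <- setdiff(features, drop_feat)
    current <- best
    step <- step + 1L
    trace <- rbind(trace,
                   data.frame(step = step, n_features = length(features),
                              removed = drop_feat, gmean = current,
                              stringsAsFactors = FALSE))
  }
  list(survivors = features, trace = trace)
}
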