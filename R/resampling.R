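# Columns of a labeled dataset that are not predictor features.
NON_FEATURE_COLS <- c("vertex", "label", "provenance")

feature_columns <- function(data) {
  setdiff(names(data), NON_FEATURE_COLS)
}

#' Attach signature labels to a feature table
#'
#' Labels a vertex positive (1) when its identifier belongs to the signature
#' gene set (exact, case-sensitive match after whitespace trimming).  The
#' matched-positive count is logged; zero matches is an error because
#' classification is then impossible.
#'
#' @param table feature table from [compute_all()] (column `vertex` plus
#'   numeric features)
#' @param signature character vector of signature gene identifiers
#' @return the table with integer `label` (1 = signature gene) and
#'   `provenance` (`"original"`) columns appended
#' @export
label_dataset <- function(table, signature) {
  if (length(signature) == 0L) stop("signature gene set is empty")
  sig <- unique(trimws(signature))
  lab <- as.integer(trimws(table$vertex) %in% sig)
  n_pos <- sum(lab)
  message(sprintf("matched %d of %d signature genes to network vertices",
                  n_pos, length(sig)))
  if (n_pos == 0L) {
    stop("no signature gene matches any network vertex; cannot label")
  }
  if (n_pos == nrow(table)) {
    warning("every vertex is labeled positive; dataset has a single class")
  }
  out <- table
  out$label <- lab
  out$provenance <- "original"
  out
}

#' SMOTE: synthetic minority oversampling
#'
#' Balances the two classes by creating synthetic minority samples rather
#' than resampling with replacement: each synthetic row is
#' `x + u * (x_nn - x)` where `x` is a minority row, `x_nn` one of its
#' `k_neighbors` nearest minority neighbours under Euclidean distance in
#' feature space, and `u` a single uniform draw on `[0, 1)` shared by all
#' features of that sample (so synthetic points lie on the segment between
#' their two parents).  The minority class is oversampled exactly to the
#' majority count: each minority row spawns `floor(deficit / n_min)`
#' replicates and the remainder is topped up from random minority draws.
#' Original rows are preserved verbatim.
#'
#' @param data labeled dataset from [label_dataset()]
#' @param k_neighbors number of nearest minority neighbours considered
#'   (clamped to `n_min - 1` with a warning when too large)
#' @param seed integer seed making the output deterministic
#' @param standardize scale features to unit variance for the neighbour
#'   search only (interpolation always happens on the raw scale)
#' @return the input rows followed by synthetic rows (`provenance =
#'   "synthetic"`, vertex ids `syn000001...`), classes exactly balanced
#' @export
smote <- function(data, k_neighbors = 5L, seed = 1L, standardize = FALSE) {
  feats <- feature_columns(data)
  if (length(feats) == 0L) stop("no feature columns found")
  if (!"label" %in% names(data)) stop("`data` must carry a `label` column")
  counts <- table(factor(data$label, levels = c(0L, 1L)))
  n_min <- min(counts)
  n_maj <- max(counts)
  if (n_min == n_maj) return(data)
  minority_label <- as.integer(names(counts)[which.min(counts)])
  if (n_min < 2L) {
    stop("SMOTE requires at least 2 minority samples")
  }
  if (k_neighbors < 1L) stop("k_neighbors must be >= 1")
  if (k_neighbors >= n_min) {
    warning(sprintf("k_neighbors = %d >= minority size %d; clamped to %d",
                    k_neighbors, n_min, n_min - 1L))
    k_neighbors <- n_min - 1L
  }

  min_idx <- which(data$label == minority_label)
  X <- as.matrix(data[min_idx, feats, drop = FALSE])
  Xs <- X
  if (standardize) {
    sdev <- apply(X, 2L, stats::sd)
    sdev[sdev == 0] <- 1
    Xs <- sweep(X, 2L, sdev, "/")
  }
  D <- as.matrix(stats::dist(Xs))
  diag(D) <- Inf
  # k nearest minority neighbours of each minority row (ties by row order)
  ord <- apply(D, 1L, function(row) order(row)[seq_len(k_neighbors)])
  nn <- if (k_neighbors == 1L) matrix(ord, ncol = 1L) else t(ord)

  deficit <- n_maj - n_min
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)

  per_row <- rep(floor(deficit / n_min), n_min)
  extra <- deficit - sum(per_row)
  if (extra > 0L) {
    topup <- sample.int(n_min, extra, replace = extra > n_min)
    tab <- tabulate(topup, nbins = n_min)
    per_row <- per_row + tab
  }
  parents <- rep(seq_len(n_min), per_row)
  chosen_nn <- nn[cbind(parents,
                        sample.int(k_neighbors, length(parents),
                                   replace = TRUE))]
  u <- stats::runif(length(parents))
  synth <- X[parents, , drop = FALSE] +
    u * (X[chosen_nn, , drop = FALSE] - X[parents, , drop = FALSE])

  syn_df <- data[rep(min_idx[1L], length(parents)), , drop = FALSE]
  syn_df[, feats] <- synth
  syn_df$vertex <- sprintf("syn%06d", seq_along(parents))
  syn_df$label <- minority_label
  if ("provenance" %in% names(syn_df)) syn_df$provenance <- "synthetic"
  out <- rbind(data, syn_df)
  rownames(out) <- NULL
  out
}
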