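#' Binary confusion counts
#'
#' Tallies T_A (class-A elements classified A), T_B, F_A (class-B elements
#' classified A) and F_B from paired truth/prediction vectors for a binary
#' problem.
#'
#' @param truth,pred Vectors of labels.
#' @param class_a,class_b The two class labels (A first).
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(truth, pred, class_a, class_b) {
  stopifnot(length(truth) == length(pred))
  truth <- as.character(truth); pred <- as.character(pred)
  ok <- truth %in% c(class_a, class_b)
  truth <- truth[ok]; pred <- pred[ok]
  out <- structure(list(
    T_A = sum(truth == class_a & pred == class_a),
    T_B = sum(truth == class_b & pred == class_b),
    F_A = sum(truth == class_b & pred == class_a),
    F_B = sum(truth == class_a & pred == class_b),
    class_a = class_a, class_b = class_b), class = "confusion_counts")
  if (out$T_A + out$T_B + out$F_A + out$F_B == 0) {
    stop("confusion_counts: no elements of either class")
  }
  out
}

#' Recall of a class, in percent
#'
#' `REC_A = 100 * T_A / (T_A + F_B)`: the percentage of class-A elements
#' classified as A. `for_class = "B"` gives the symmetric
#' `100 * T_B / (T_B + F_A)`.
#'
#' @param counts A [confusion_counts()].
#' @param for_class `"A"` or `"B"`.
#' @return Recall in percent.
#' @export
recall <- function(counts, for_class = c("A", "B")) {
  for_class <- match.arg(for_class)
  stopifnot(inherits(counts, "confusion_counts"))
  if (for_class == "A") {
    den <- counts$T_A + counts$F_B
    if (den == 0) stop("recall: class A is empty")
    100 * counts$T_A / den
  } else {
    den <- counts$T_B + counts$F_A
    if (den == 0) stop("recall: class B is empty")
    100 * counts$T_B / den
  }
}

#' Overall accuracy, in percent
#'
#' `ACC = 100 * (T_A + T_B) / (T_A + T_B + F_A + F_B)`.
#'
#' @param counts A [confusion_counts()].
#' @return Accuracy in percent.
#' @export
accuracy <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tot <- counts$T_A + counts$T_B + counts$F_A + counts$F_B
  100 * (counts$T_A + counts$T_B) / tot
}

#' Training/test split plan
#'
#' @param train_cells Named integer vector: number of training cells per
#'   class (default 200 monocytes and 50 per NB line, mirroring a
#'   balanced-frames design in which the monocyte count equals the summed
#'   NB count).
#' @param qpms_per_cell Frames sampled per training cell (default 50).
#' @param seed Integer seed.
#' @return An object of class `split_plan`.
#' @export
split_plan <- function(train_cells = c(THP1 = 200L, CHP212 = 50L,
                                       SKNBE2 = 50L, SHSY5Y = 50L,
                                       SKNSH = 50L),
                       qpms_per_cell = 50L, seed = 1L) {
  stopifnot(!is.null(names(train_cells)), all(train_cells >= 0),
            qpms_per_cell >= 1)
  structure(list(train_cells = train_cells,
                 qpms_per_cell = as.integer(qpms_per_cell),
                 seed = as.integer(seed)), class = "split_plan")
}

#' Build disjoint training and test sets from a manifest
#'
#' Samples the planned number of training cells per class among the cells
#' with at least `qpms_per_cell` frames, then samples exactly
#' `qpms_per_cell` frames from each. The remaining frames of training
#' cells are discarded — they enter neither set — and the test set keeps
#' ALL frames of every non-training cell, so train and test never share a
#' cell.
#'
#' @param manifest Data.frame with `cell_id`, `class`, `frame` columns
#'   (e.g. from [simulate_manifest()] or [make_dataset()]).
#' @param plan A [split_plan()].
#' @return A list with data.frames `train` and `test` (manifest rows) and
#'   `train_cells` (the sampled ids).
#' @export
build_split <- function(manifest, plan) {
  stopifnot(inherits(plan, "split_plan"),
            all(c("cell_id", "class", "frame") %in% names(manifest)))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(plan$seed)
  train_rows <- list()
  train_ids <- character(0)
  for (cls in names(plan$train_cells)) {
    n_want <- plan$train_cells[[cls]]
    if (n_want == 0L) next
    frames_per_cell <- table(manifest$cell_id[manifest$class == cls])
    eligible <- names(frames_per_cell)[frames_per_cell >= plan$qpms_per_cell]
    if (length(eligible) < n_want) {
      stop(sprintf(
        "build_split: class %s has %d cells with >= %d frames, %d requested",
        cls, length(eligible), plan$qpms_per_cell, n_want))
    }
    chosen <- sample(eligible, n_want)
    train_ids <- c(train_ids, chosen)
    for (id in chosen) {
      rows <- manifest[manifest$cell_id == id, , drop = FALSE]
      pick <- sample(nrow(rows), plan$qpms_per_cell)
      train_rows[[id]] <- rows[sort(pick), , drop = FALSE]
    }
  }
  train <- do.call(rbind, c(train_rows, list(make.row.names = FALSE)))
  test <- manifest[!(manifest$cell_id %in% train_ids), , drop = FALSE]
  list(train = train, test = test, train_cells = train_ids)
}

#' First two principal components
#'
#' PCA on z-scored features, returning the two leading score columns and
#' loadings ordered by decreasing explained variance, with a deterministic
#' sign convention (the largest-magnitude loading of each component is
#' positive).
#'
#' @param x Numeric matrix or data.frame (samples x features).
#' @return A list with `scores` (n x 2), `loadings` (d x 2),
#'   `explained` (length-2 fraction of variance).
#' @export
pca_first2 <- function(x) {
  x <- as.matrix(x)
  stopifnot(nrow(x) >= 3, ncol(x) >= 2)
  sds <- apply(x, 2, stats::sd)
  if (sum(sds > 0) < 2) stop("pca_first2: rank below 2")
  xz <- x[, sds > 0, drop = FALSE]
  p <- stats::prcomp(xz, center = TRUE, scale. = TRUE)
  if (length(p$sdev) < 2 || p$sdev[2] == 0) stop("pca_first2: rank below 2")
  flip <- vapply(1:2, function(j) {
    sign(p$rotation[which.max(abs(p$rotation[, j])), j])
  }, numeric(1))
  list(scores = sweep(p$x[, 1:2, drop = FALSE], 2, flip, `*`),
       loadings = sweep(p$rotation[, 1:2, drop = FALSE], 2, flip, `*`),
       explained = (p$sdev[1:2]^2) / sum(p$sdev^2))
}

#' Fisher's separability criterion on 2D scores
#'
#' `J = ||mu_A - mu_B||^2 / (tr(Sigma_A) + tr(Sigma_B))`: squared distance
#' between group means over the total within-group scatter, computed on
#' the first two PCA components. Larger J = better separated groups.
#'
#' @param scores_a,scores_b Numeric matrices of 2D points (rows).
#' @return Scalar J.
#' @export
fisher_criterion <- function(scores_a, scores_b) {
  a <- as.matrix(scores_a); b <- as.matrix(scores_b)
  stopifnot(nrow(a) >= 2, nrow(b) >= 2, ncol(a) == ncol(b))
  num <- sum((colMeans(a) - colMeans(b))^2)
  den <- sum(diag(stats::cov(a))) + sum(diag(stats::cov(b)))
  if (den == 0) stop("fisher_criterion: zero total scatter")
  num / den
}

#' Group-averaged absolute feature correlation
#'
#' Mean absolute Pearson correlation over all feature pairs crossing each
#' pair of feature groups (self-pairs excluded within a group). Constant
#' features are skipped. The result is a symmetric matrix with entries in
#' `[0, 1]`.
#'
#' @param x Feature table (samples x features) whose columns are covered
#'   by `groups`.
#' @param groups Named list of character vectors assigning every feature
#'   to exactly one group (default [feature_groups()]).
#' @return A `length(groups)` square matrix.
#' @export
grouped_correlation <- function(x, groups = feature_groups()) {
  x <- as.data.frame(x)
  feats <- unlist(groups, use.names = FALSE)
  stopifnot(all(feats %in% names(x)))
  keep <- feats[vapply(feats, function(f) stats::sd(x[[f]]) > 0, logical(1))]
  if (length(keep) < length(feats)) {
    message(sprintf("grouped_correlation: skipping %d constant feature(s)",
                    length(feats) - length(keep)))
  }
  cm <- abs(stats::cor(as.matrix(x[keep])))
  g <- length(groups)
  out <- matrix(NA_real_, g, g, dimnames = list(names(groups), names(groups)))
  for (i in seq_len(g)) {
    for (j in i:g) {
      fi <- intersect(groups[[i]], keep)
      fj <- intersect(groups[[j]], keep)
      sub <- cm[fi, fj, drop = FALSE]
      if (i == j) {
        vals <- sub[upper.tri(sub)]
      } else {
        vals <- as.vector(sub)
      }
      out[i, j] <- out[j, i] <- mean(vals)
    }
  }
  out
}

#' Correlation-filtered ReliefF feature ranking
#'
#' First drops, in stable column order, every feature whose absolute
#' Pearson correlation with an earlier kept feature reaches
#' `corr_threshold`; then ranks the survivors with binary ReliefF
#' (k nearest hits/misses, Euclidean distance on z-scored features,
#' feature differences normalised by range).
#'
#' @param x Feature table (samples x features).
#' @param y Binary labels.
#' @param corr_threshold Absolute-correlation cutoff (default 0.9).
#' @param k Number of nearest hits/misses (default 10).
#' @return Data.frame with `feature`, `weight`, sorted by decreasing
#'   weight.
#' @export
relief_rank <- function(x, y, corr_threshold = 0.9, k = 10L) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  stopifnot(nlevels(y) == 2L, all(table(y) >= 2L), nrow(x) == length(y))

  sds <- apply(x, 2, stats::sd)
  x <- x[, sds > 0, drop = FALSE]
  if (!ncol(x)) stop("relief_rank: all features constant")
  cm <- abs(stats::cor(x))
  keep <- logical(ncol(x))
  for (j in seq_len(ncol(x))) {
    keep[j] <- !any(cm[j, which(keep[seq_len(j - 1)])] >= corr_threshold)
    if (j == 1L) keep[1L] <- TRUE
  }
  x <- x[, keep, drop = FALSE]
  if (!ncol(x)) stop("relief_rank: all features dropped by the filter")

  xz <- scale(x)
  rng <- apply(x, 2, function(v) diff(range(v)))
  rng[rng == 0] <- 1
  n <- nrow(x); d <- ncol(x)
  D <- as.matrix(stats::dist(xz))
  diag(D) <- Inf
  w <- numeric(d)
  for (i in seq_len(n)) {
    same <- which(y == y[i]); same <- same[same != i]
    diff_cls <- which(y != y[i])
    kh <- min(k, length(same)); km <- min(k, length(diff_cls))
    hits <- same[order(D[i, same])][seq_len(kh)]
    misses <- diff_cls[order(D[i, diff_cls])][seq_len(km)]
    dh <- abs(sweep(x[hits, , drop = FALSE], 2, x[i, ])) / rep(rng, each = kh)
    dm <- abs(sweep(x[misses, , drop = FALSE], 2, x[i, ])) / rep(rng, each = km)
    w <- w - colSums(dh) / (kh * n) + colSums(dm) / (km * n)
  }
  out <- data.frame(feature = colnames(x), weight = w)
  out[order(-out$weight), , drop = FALSE]
}

#' Evaluate the hierarchical classifier on a test feature table
#'
#' Computes, for every level of the tree, the frame-level (no-voting) and
#' cell-level (max-voting) confusion counts, recalls and accuracy over the
#' test cells belonging to that level's two branches, then composes the
#' global root-to-leaf path probabilities from the voted recalls.
#'
#' @param model A [train_hierarchy()] result.
#' @param features Frame-level test feature table with `cell_id`, `class`
#'   and feature columns.
#' @return A list with `per_level` (one entry per level: recalls and
#'   accuracy, with and without voting) and `global` (named vector of
#'   path probabilities in percent).
#' @export
evaluate_hierarchy <- function(model, features) {
  groups <- model$groups
  per_level <- list()
  voted_recall <- list()
  for (lv in c("L1", "L2", "L3.1", "L3.2")) {
    m <- model$levels[[lv]]
    lab <- .level_label(features$class, groups, lv)
    keep <- !is.na(lab)
    fr <- features[keep, , drop = FALSE]
    truth <- lab[keep]
    cols <- feature_set(model$level_specs[[lv]]$feature_set)
    P <- predict(m, fr[, cols, drop = FALSE], type = "prob")
    pred <- m$levels[max.col(P, ties.method = "first")]
    cc_frame <- confusion_counts(truth, pred, m$levels[1], m$levels[2])

    ids <- unique(fr$cell_id)
    cell_truth <- cell_pred <- character(length(ids))
    for (i in seq_along(ids)) {
      sel <- fr$cell_id == ids[i]
      cell_truth[i] <- truth[sel][1]
      cell_pred[i] <- max_vote(factor(pred[sel], levels = m$levels),
                               probs = P[sel, , drop = FALSE])$winner
    }
    cc_cell <- confusion_counts(cell_truth, cell_pred,
                                m$levels[1], m$levels[2])
    per_level[[lv]] <- list(
      frame = list(counts = cc_frame,
                   recall = c(recall(cc_frame, "A"), recall(cc_frame, "B")),
                   accuracy = accuracy(cc_frame)),
      cell = list(counts = cc_cell,
                  recall = c(recall(cc_cell, "A"), recall(cc_cell, "B")),
                  accuracy = accuracy(cc_cell)))
    rv <- c(recall(cc_cell, "A"), recall(cc_cell, "B")) / 100
    names(rv) <- m$levels
    voted_recall[[lv]] <- rv
  }
  paths <- hierarchy_paths(list(
    L1 = voted_recall$L1, L2 = voted_recall$L2,
    L3.1 = voted_recall$L3.1, L3.2 = voted_recall$L3.2))
  global <- vapply(paths, global_probability, numeric(1))
  list(per_level = per_level, global = global)
}
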