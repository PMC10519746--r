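#' Majority vote over the frame predictions of one cell
#'
#' Implements per-cell max-voting: the cell is assigned to the class
#' predicted for the largest number of its N rotating-view frames. An even
#' split (possible for even N) is broken by the larger mean posterior
#' probability across frames when `probs` is supplied, otherwise by the
#' first class level; the `tie` flag records that a tie occurred.
#'
#' @param frame_predictions Factor or character vector of per-frame labels
#'   (length N >= 1).
#' @param probs Optional N x K matrix of per-frame posterior probabilities
#'   with class names as columns, used only to break ties.
#' @return A list of class `vote_result`: `winner`, `counts` (named),
#'   `n`, `tie`.
#' @export
max_vote <- function(frame_predictions, probs = NULL) {
  if (!length(frame_predictions)) stop("max_vote: empty prediction list")
  f <- as.factor(frame_predictions)
  counts <- table(f)
  top <- names(counts)[counts == max(counts)]
  tie <- length(top) > 1L
  winner <- top[1L]
  if (tie && !is.null(probs)) {
    mp <- colMeans(probs[, top, drop = FALSE])
    winner <- top[which.max(mp)]
  }
  structure(list(winner = winner, counts = c(counts),
                 n = length(frame_predictions), tie = tie),
            class = "vote_result")
}

#' @export
print.vote_result <- function(x, ...) {
  cat(sprintf("<vote_result> winner %s (%s of %d frames%s)\n", x$winner,
              paste(sprintf("%s=%d", names(x$counts), x$counts),
                    collapse = ", "),
              x$n, if (x$tie) ", tie-broken" else ""))
  invisible(x)
}

#' Compose a global path probability
#'
#' Multiplies the per-level recall fractions found along a root-to-leaf
#' path of the hierarchical tree and reports the product as a percentage
#' rounded to one decimal. For example, the probability of correctly
#' identifying a leaf reached through levels with recalls 0.950, 0.983 and
#' 0.954 is `0.950 * 0.983 * 0.954 = 89.1%`.
#'
#' @param recalls Numeric vector of per-level recalls, each in `[0, 1]`.
#' @return The global probability in percent, rounded to one decimal.
#' @export
global_probability <- function(recalls) {
  stopifnot(length(recalls) >= 1, all(recalls >= 0), all(recalls <= 1))
  round(100 * prod(recalls), 1)
}

#' Benchmark per-level max-voting recalls of the holographic NB study
#'
#' Max-voting recall fractions reported for the best per-level feature
#' sets of the three-level monocyte/neuroblastoma hierarchy (hybrid
#' features at L1, L2 and L3.1; fractal features at L3.2). Multiplying
#' them along each root-to-leaf path with [global_probability()] yields
#' the published global per-line probabilities.
#'
#' @return A named list of per-level recall fractions.
#' @export
reference_recalls <- function() {
  list(
    L1 = c(Monocyte = 0.979, NB = 0.950),
    L2 = c(NB1 = 0.983, NB2 = 0.966),
    L3.1 = c(CHP212 = 0.954, SKNBE2 = 0.839),
    L3.2 = c(SHSY5Y = 0.812, SKNSH = 0.802)
  )
}

#' Root-to-leaf recall paths of the reference hierarchy
#'
#' @param recalls Per-level recall list in the layout of
#'   [reference_recalls()].
#' @return Named list mapping each leaf class to its ordered vector of
#'   per-level recall fractions.
#' @export
hierarchy_paths <- function(recalls = reference_recalls()) {
  list(
    Monocyte = unname(recalls$L1["Monocyte"]),
    CHP212 = unname(c(recalls$L1["NB"], recalls$L2["NB1"],
                      recalls$L3.1["CHP212"])),
    SKNBE2 = unname(c(recalls$L1["NB"], recalls$L2["NB1"],
                      recalls$L3.1["SKNBE2"])),
    SHSY5Y = unname(c(recalls$L1["NB"], recalls$L2["NB2"],
                      recalls$L3.2["SHSY5Y"])),
    SKNSH = unname(c(recalls$L1["NB"], recalls$L2["NB2"],
                     recalls$L3.2["SKNSH"]))
  )
}

# map leaf classes to the binary label of a level -----------------------------
.level_label <- function(class, groups, level) {
  switch(level,
    L1 = ifelse(class %in% groups$monocyte, "Monocyte", "NB"),
    L2 = ifelse(class %in% groups$NB1, "NB1",
                ifelse(class %in% groups$NB2, "NB2", NA_character_)),
    L3.1 = ifelse(class %in% groups$NB1, class, NA_character_),
    L3.2 = ifelse(class %in% groups$NB2, class, NA_character_),
    stop("unknown level"))
}

#' Train the three-level hierarchical classifier
#'
#' Trains four binary shallow networks on the frame-level feature table:
#' L1 (monocyte vs NB), L2 (NB1 vs NB2 super-groups), L3.1 and L3.2 (leaf
#' lines within each super-group). Each level consumes its own feature set
#' — by default hybrid features at L1/L2/L3.1 and the sole fractal
#' features at L3.2, the configuration found best for the hardest
#' sub-problem — and standardises features with its own training split
#' only.
#'
#' @param features Data.frame with columns `cell_id`, `class` and the 37
#'   feature columns (frame rows), e.g. from [extract_features_batch()].
#' @param groups Class-group map, see [default_class_groups()].
#' @param level_specs Named list of [shallow_net_spec()] for `L1`, `L2`,
#'   `L3.1`, `L3.2`.
#' @param seed Integer seed.
#' @return An object of class `hierarchy_model`.
#' @export
train_hierarchy <- function(features, groups = default_class_groups(),
                            level_specs = list(
                              L1 = shallow_net_spec(feature_set = "hybrid"),
                              L2 = shallow_net_spec(feature_set = "hybrid"),
                              `L3.1` = shallow_net_spec(feature_set = "hybrid"),
                              `L3.2` = shallow_net_spec(feature_set = "fractal")),
                            seed = 1L) {
  stopifnot(all(c("cell_id", "class") %in% names(features)))
  nb_classes <- c(groups$NB1, groups$NB2)
  models <- list()
  for (lv in c("L1", "L2", "L3.1", "L3.2")) {
    lab <- .level_label(features$class, groups, lv)
    keep <- !is.na(lab)
    if (lv != "L1") keep <- keep & features$class %in% nb_classes
    cols <- feature_set(level_specs[[lv]]$feature_set)
    models[[lv]] <- train_level(features[keep, cols, drop = FALSE],
                                lab[keep], level_specs[[lv]],
                                seed = seed + match(lv, c("L1", "L2", "L3.1",
                                                          "L3.2")))
  }
  structure(list(levels = models, groups = groups,
                 level_specs = level_specs, seed = seed),
            class = "hierarchy_model")
}

#' @export
print.hierarchy_model <- function(x, ...) {
  cat("<hierarchy_model> levels:\n")
  for (lv in names(x$levels)) {
    m <- x$levels[[lv]]
    cat(sprintf("  %-5s %s vs %s  (%s features, CV acc %s)\n", lv,
                m$levels[1], m$levels[2], x$level_specs[[lv]]$feature_set,
                ifelse(is.na(m$cv_accuracy), "-",
                       sprintf("%.3f", m$cv_accuracy))))
  }
  invisible(x)
}

#' Classify cells by traversing the hierarchy with per-level max-voting
#'
#' For every cell, all frames are classified at L1 and max-voted; cells
#' voted NB descend to L2 (same frames), and then to L3.1 or L3.2
#' according to the winning super-group. The returned record keeps the
#' per-level vote results, forming the root-to-leaf path.
#'
#' @param model A [train_hierarchy()] result.
#' @param features Frame-level feature table with `cell_id` (and
#'   optionally `class`) columns.
#' @return A data.frame with one row per cell: `cell_id`, `class` (if
#'   present), `leaf` (predicted class) plus a list-column `path` of
#'   `vote_result`s.
#' @export
classify_cells <- function(model, features) {
  stopifnot(inherits(model, "hierarchy_model"))
  groups <- model$groups
  ids <- unique(features$cell_id)
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    fr <- features[features$cell_id == ids[i], , drop = FALSE]
    path <- list()

    vote_at <- function(lv) {
      m <- model$levels[[lv]]
      cols <- feature_set(model$level_specs[[lv]]$feature_set)
      P <- predict(m, fr[, cols, drop = FALSE], type = "prob")
      pred <- m$levels[max.col(P, ties.method = "first")]
      max_vote(factor(pred, levels = m$levels), probs = P)
    }

    v1 <- vote_at("L1"); path$L1 <- v1
    if (v1$winner == "Monocyte") {
      leaf <- groups$monocyte[1]
    } else {
      v2 <- vote_at("L2"); path$L2 <- v2
      if (v2$winner == "NB1") {
        v3 <- vote_at("L3.1"); path$L3.1 <- v3
      } else {
        v3 <- vote_at("L3.2"); path$L3.2 <- v3
      }
      leaf <- v3$winner
    }
    out[[i]] <- list(cell_id = ids[i],
                     class = if ("class" %in% names(fr)) fr$class[1] else NA,
                     leaf = leaf, path = path)
  }
  res <- data.frame(cell_id = vapply(out, `[[`, character(1), "cell_id"),
                    class = vapply(out, function(o) as.character(o$class),
                                   character(1)),
                    leaf = vapply(out, `[[`, character(1), "leaf"))
  res$path <- lapply(out, `[[`, "path")
  res
}

#' Route single frames through the hierarchy without voting
#'
#' Classifies every frame independently down the tree (L1, then L2, then
#' the matching L3 node), i.e. the per-QPM prediction that max-voting
#' aggregates. Useful to quantify the accuracy gained by voting.
#'
#' @param model A [train_hierarchy()] result.
#' @param features Frame-level feature table.
#' @return Character vector of leaf predictions, one per row of
#'   `features`.
#' @export
classify_frames <- function(model, features) {
  stopifnot(inherits(model, "hierarchy_model"))
  pred_at <- function(lv, rows) {
    m <- model$levels[[lv]]
    cols <- feature_set(model$level_specs[[lv]]$feature_set)
    as.character(predict(m, features[rows, cols, drop = FALSE]))
  }
  n <- nrow(features)
  leaf <- character(n)
  p1 <- pred_at("L1", seq_len(n))
  leaf[p1 == "Monocyte"] <- model$groups$monocyte[1]
  nb <- which(p1 != "Monocyte")
  if (length(nb)) {
    p2 <- pred_at("L2", nb)
    nb1 <- nb[p2 == "NB1"]; nb2 <- nb[p2 == "NB2"]
    if (length(nb1)) leaf[nb1] <- pred_at("L3.1", nb1)
    if (length(nb2)) leaf[nb2] <- pred_at("L3.2", nb2)
  }
  leaf
}

#' Train the flat and two-level baseline models
#'
#' The non-hierarchical baseline is a single five-class shallow network;
#' the two-level baseline first separates monocytes from NB cells and then
#' solves a four-class problem among the NB lines. Both use hybrid
#' features and are evaluated per cell with max-voting.
#'
#' @param features Frame-level feature table (`cell_id`, `class` + feature
#'   columns) covering all five classes.
#' @param spec A [shallow_net_spec()]; the feature set applies to every
#'   node (default hybrid).
#' @param groups Class-group map.
#' @param seed Integer seed.
#' @return A list of class `baseline_models` with elements `flat`
#'   (`shallow_net`) and `two_level` (list of `L1` and `NB4` networks).
#' @export
build_baselines <- function(features, spec = shallow_net_spec(),
                            groups = default_class_groups(), seed = 1L) {
  cols <- feature_set(spec$feature_set)
  all_classes <- c(groups$monocyte, groups$NB1, groups$NB2)
  if (!all(all_classes %in% features$class)) {
    stop("build_baselines: all five classes must be present")
  }
  flat <- train_shallow_net(features[, cols, drop = FALSE],
                            factor(features$class, levels = all_classes),
                            spec, seed = seed + 10L)
  lab1 <- .level_label(features$class, groups, "L1")
  l1 <- train_level(features[, cols, drop = FALSE], lab1, spec,
                    seed = seed + 11L)
  nb <- features$class %in% c(groups$NB1, groups$NB2)
  nb4 <- train_shallow_net(features[nb, cols, drop = FALSE],
                           factor(features$class[nb],
                                  levels = c(groups$NB1, groups$NB2)),
                           spec, seed = seed + 12L)
  structure(list(flat = flat, two_level = list(L1 = l1, NB4 = nb4),
                 groups = groups, feature_cols = cols),
            class = "baseline_models")
}

#' Per-cell max-voted predictions of the baseline models
#'
#' @param baselines A [build_baselines()] result.
#' @param features Frame-level feature table.
#' @param model `"flat"` or `"two_level"`.
#' @return Data.frame with `cell_id`, `class`, `leaf`.
#' @export
classify_cells_baseline <- function(baselines, features,
                                    model = c("flat", "two_level")) {
  model <- match.arg(model)
  cols <- baselines$feature_cols
  ids <- unique(features$cell_id)
  leaf <- character(length(ids))
  truth <- character(length(ids))
  for (i in seq_along(ids)) {
    fr <- features[features$cell_id == ids[i], , drop = FALSE]
    truth[i] <- as.character(fr$class[1])
    if (model == "flat") {
      P <- predict(baselines$flat, fr[, cols, drop = FALSE], type = "prob")
      pred <- baselines$flat$levels[max.col(P, ties.method = "first")]
      leaf[i] <- max_vote(factor(pred, levels = baselines$flat$levels),
                          probs = P)$winner
    } else {
      m1 <- baselines$two_level$L1
      P1 <- predict(m1, fr[, cols, drop = FALSE], type = "prob")
      pred1 <- m1$levels[max.col(P1, ties.method = "first")]
      v1 <- max_vote(factor(pred1, levels = m1$levels), probs = P1)
      if (v1$winner == "Monocyte") {
        leaf[i] <- baselines$groups$monocyte[1]
      } else {
        m4 <- baselines$two_level$NB4
        P4 <- predict(m4, fr[, cols, drop = FALSE], type = "prob")
        pred4 <- m4$levels[max.col(P4, ties.method = "first")]
        leaf[i] <- max_vote(factor(pred4, levels = m4$levels),
                            probs = P4)$winner
      }
    }
  }
  data.frame(cell_id = ids, class = truth, leaf = leaf)
}
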