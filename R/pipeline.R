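#' Pipeline run configuration
#'
#' Bundles every knob of the end-to-end run: synthetic dataset, optional
#' hologram round trip, feature extraction, split, training and
#' evaluation. Defaults give a desk-scale five-class experiment small
#' enough for routine re-runs.
#'
#' @param seed Master seed; every stochastic stage derives its seed from
#'   it.
#' @param specs Named list of [phenotype_spec()] (default
#'   [default_phenotypes()]).
#' @param optics An [optics_config()].
#' @param cells_per_class Cells generated per class.
#' @param n_views Frames per cell.
#' @param noise_sd Phase-noise s.d. in radians.
#' @param train_cells Named vector of training cells per class (classes
#'   absent from the vector are test-only).
#' @param qpms_per_cell Frames sampled per training cell.
#' @param hologram_roundtrip When `TRUE`, every QPM is encoded as an
#'   off-axis hologram and reconstructed numerically before feature
#'   extraction, so features are computed from reconstructed rather than
#'   ground-truth phase maps.
#' @param level_specs Per-level [shallow_net_spec()] list for
#'   [train_hierarchy()] (`NULL` = its defaults).
#' @param baselines Also train the flat and two-level baselines.
#' @param out_dir Optional directory for cached stage outputs (features
#'   table CSV keyed by a config hash).
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       specs = default_phenotypes(),
                       optics = optics_config(hologram_size = 512L),
                       cells_per_class = c(THP1 = 52L, CHP212 = 24L,
                                           SKNBE2 = 24L, SHSY5Y = 24L,
                                           SKNSH = 24L),
                       n_views = 8L,
                       noise_sd = 0.02,
                       train_cells = c(THP1 = 32L, CHP212 = 8L,
                                       SKNBE2 = 8L, SHSY5Y = 8L,
                                       SKNSH = 8L),
                       qpms_per_cell = 6L,
                       hologram_roundtrip = FALSE,
                       level_specs = NULL,
                       baselines = FALSE,
                       out_dir = NULL) {
  stopifnot(length(specs) >= 1, !is.null(names(cells_per_class)))
  structure(list(seed = as.integer(seed), specs = specs, optics = optics,
                 cells_per_class = cells_per_class,
                 n_views = as.integer(n_views), noise_sd = noise_sd,
                 train_cells = train_cells,
                 qpms_per_cell = as.integer(qpms_per_cell),
                 hologram_roundtrip = isTRUE(hologram_roundtrip),
                 level_specs = level_specs,
                 baselines = isTRUE(baselines),
                 out_dir = out_dir),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Reads a YAML file whose top-level keys mirror the [run_config()]
#' arguments; `phenotypes` entries mirror [phenotype_spec()] fields and
#' `optics` the [optics_config()] fields. A `seed` entry is mandatory.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
run_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stop("config must declare a seed")
  args <- list(seed = y$seed)
  if (!is.null(y$phenotypes)) {
    args$specs <- lapply(y$phenotypes, function(p) do.call(phenotype_spec, p))
    names(args$specs) <- vapply(args$specs, `[[`, character(1), "name")
  }
  if (!is.null(y$optics)) args$optics <- do.call(optics_config, y$optics)
  for (nm in c("cells_per_class", "n_views", "noise_sd", "train_cells",
               "qpms_per_cell", "hologram_roundtrip", "baselines",
               "out_dir")) {
    if (!is.null(y[[nm]])) args[[nm]] <- if (nm %in% c("cells_per_class",
                                                       "train_cells")) {
      unlist(y[[nm]])
    } else y[[nm]]
  }
  do.call(run_config, args)
}

.config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config[setdiff(names(config), "out_dir")], f)
  unname(tools::md5sum(f))
}

#' Run the full synthetic phenotyping pipeline
#'
#' Executes simulate -> (optional hologram round trip) -> extract ->
#' split -> train -> evaluate and returns a report. Per-stage wall times
#' are recorded; when `config$out_dir` is set, the extracted feature table
#' is cached on disk keyed by a hash of the configuration and reused on
#' reruns.
#'
#' @param config A [run_config()].
#' @return A list of class `pipeline_report`: `config_hash`, `provenance`
#'   (`"ground_truth"` or `"reconstructed"`), `features` (frame table),
#'   `split`, `hierarchy` (trained model), `evaluation`
#'   (see [evaluate_hierarchy()]), `tree` (full-tree per-cell results with
#'   per-class recall), optional `baselines`, and `timings` (seconds).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  timings <- c()
  tick <- function(label, expr) {
    t0 <- proc.time()[3]
    out <- force(expr)
    timings[[label]] <<- unname(proc.time()[3] - t0)
    message(sprintf("[pipeline] %-10s %.1f s", label, timings[[label]]))
    out
  }
  hash <- .config_hash(config)
  cache <- if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    file.path(config$out_dir, sprintf("features_%s.csv", hash))
  } else NULL

  specs <- config$specs[names(config$cells_per_class)]
  manifest <- tick("simulate", make_dataset(
    specs, config$cells_per_class, config$optics, seed = config$seed,
    n_views = config$n_views, noise_sd = config$noise_sd,
    keep_sequences = TRUE, write_images = FALSE))
  sequences <- attr(manifest, "sequences")

  provenance <- "ground_truth"
  if (config$hologram_roundtrip) {
    cfg <- recon_config()
    sequences <- tick("holo", lapply(sequences, function(sq) {
      sq$frames <- lapply(sq$frames, function(q) {
        h <- encode_hologram(q, config$optics)
        ref <- encode_hologram(qpm_image(matrix(0, nrow(q$phase),
                                                ncol(q$phase)), q$pitch),
                               config$optics)
        reconstruct_qpm(h, cfg, reference = ref)
      })
      sq
    }))
    provenance <- "reconstructed"
  }

  features <- if (!is.null(cache) && file.exists(cache)) {
    message("[pipeline] extract    (cached)")
    utils::read.csv(cache, stringsAsFactors = FALSE)
  } else {
    fe <- tick("extract", extract_features_batch(sequences))
    if (!is.null(cache)) utils::write.csv(fe, cache, row.names = FALSE)
    fe
  }

  plan <- split_plan(config$train_cells, config$qpms_per_cell,
                     seed = config$seed)
  split <- tick("split", build_split(features, plan))
  train_feats <- merge(split$train[, c("cell_id", "frame")], features,
                       by = c("cell_id", "frame"))
  test_feats <- split$test

  model <- tick("train", if (is.null(config$level_specs)) {
    train_hierarchy(train_feats, seed = config$seed)
  } else {
    train_hierarchy(train_feats, level_specs = config$level_specs,
                    seed = config$seed)
  })

  evaluation <- tick("evaluate", evaluate_hierarchy(model, test_feats))
  tree <- classify_cells(model, test_feats)
  classes <- unique(tree$class)
  per_class_recall <- vapply(classes, function(cl) {
    sel <- tree$class == cl
    100 * mean(tree$leaf[sel] == cl)
  }, numeric(1))

  report <- list(config_hash = hash, provenance = provenance,
                 features = features, split = split, hierarchy = model,
                 evaluation = evaluation,
                 tree = list(cells = tree, per_class_recall = per_class_recall),
                 timings = timings)
  if (config$baselines) {
    base <- tick("baselines", build_baselines(train_feats,
                                              seed = config$seed))
    report$baselines <- list(
      models = base,
      flat = classify_cells_baseline(base, test_feats, "flat"),
      two_level = classify_cells_baseline(base, test_feats, "two_level"))
  }
  class(report) <- "pipeline_report"
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> provenance: %s\n", x$provenance))
  cat("  global path probabilities (%):\n")
  print(round(x$evaluation$global, 1))
  cat("  full-tree per-class recall (%):\n")
  print(round(x$tree$per_class_recall, 1))
  invisible(x)
}
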