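#' Simulate a dataset manifest without rendering images
#'
#' Draws, for every cell, a class, a per-cell view count from the
#' phenotype's `n_views_range`, and one manifest row per frame. Useful for
#' testing split construction and voting logic at full dataset scale
#' without the cost of projecting phase maps.
#'
#' @param specs Named list of [phenotype_spec()] objects.
#' @param cells_per_class Integer vector (recycled across `specs`) of cell
#'   counts per class.
#' @param seed Integer seed.
#' @return A data.frame with columns `cell_id`, `class`, `frame`,
#'   `angle_rad`, `path` (paths `NA` for manifest-only simulation).
#' @export
simulate_manifest <- function(specs, cells_per_class, seed = 1L) {
  stopifnot(length(specs) >= 1)
  cells_per_class <- rep_len(as.integer(cells_per_class), length(specs))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  rows <- list()
  cell_no <- 0L
  for (k in seq_along(specs)) {
    sp <- specs[[k]]
    if (cells_per_class[k] == 0L) next
    for (i in seq_len(cells_per_class[k])) {
      cell_no <- cell_no + 1L
      cand <- seq.int(sp$n_views_range[1], sp$n_views_range[2])
      nv <- cand[sample.int(length(cand), 1L)]
      rows[[cell_no]] <- data.frame(
        cell_id = sprintf("cell%04d", cell_no),
        class = sp$name,
        frame = seq_len(nv),
        angle_rad = if (nv == 1L) 0 else seq(0, pi, length.out = nv),
        path = NA_character_)
    }
  }
  if (!length(rows)) stop("no cells requested")
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Generate a synthetic rolling-cell QPM dataset on disk
#'
#' Draws `cells_per_class` phantoms per phenotype, projects each along its
#' rolling-rotation sequence, writes every frame as a 32-bit float TIFF and
#' a manifest CSV with header `cell_id,class,frame,angle_rad,path`. Two
#' runs with the same seed produce identical manifests and images.
#'
#' @param specs Named list of [phenotype_spec()] objects.
#' @param cells_per_class Integer vector (recycled) of cells per class.
#' @param optics An [optics_config()].
#' @param seed Integer seed.
#' @param out_dir Output directory (created if missing).
#' @param n_views Optional fixed view count per cell overriding the
#'   phenotype's `n_views_range`.
#' @param noise_sd Additive Gaussian phase noise s.d. in radians
#'   (default 0.02).
#' @return The manifest data.frame (also written to
#'   `file.path(out_dir, "manifest.csv")`), invisibly carrying the
#'   attribute `sequences` when `keep_sequences = TRUE`.
#' @param keep_sequences Keep the generated `cell_sequence` objects in
#'   memory and attach them to the result (default `FALSE`).
#' @param write_images Write TIFF frames (default `TRUE`); when `FALSE`
#'   only the manifest is produced and `path` is `NA`.
#' @export
make_dataset <- function(specs, cells_per_class, optics = optics_config(),
                         seed = 1L, out_dir = tempfile("qpmset"),
                         n_views = NULL, noise_sd = 0.02,
                         keep_sequences = FALSE, write_images = TRUE) {
  stopifnot(length(specs) >= 1)
  cells_per_class <- rep_len(as.integer(cells_per_class), length(specs))
  if (write_images) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  # pre-draw independent sub-seeds so per-cell generation is reproducible
  total_cells <- sum(cells_per_class)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 2L * total_cells)

  rows <- list()
  seqs <- if (keep_sequences) vector("list", total_cells) else NULL
  cell_no <- 0L
  for (k in seq_along(specs)) {
    sp <- specs[[k]]
    if (cells_per_class[k] == 0L) next
    for (i in seq_len(cells_per_class[k])) {
      cell_no <- cell_no + 1L
      phantom <- make_phantom(sp, seed = sub_seeds[2L * cell_no - 1L])
      nv <- if (!is.null(n_views)) as.integer(n_views) else {
        set.seed(sub_seeds[2L * cell_no])
        cand <- seq.int(sp$n_views_range[1], sp$n_views_range[2])
        cand[sample.int(length(cand), 1L)]
      }
      sq <- roll_sequence(phantom, nv, optics, seed = sub_seeds[2L * cell_no],
                          noise_sd = noise_sd)
      sq$cell_id <- sprintf("cell%04d", cell_no)
      paths <- rep(NA_character_, nv)
      if (write_images) {
        for (f in seq_len(nv)) {
          paths[f] <- file.path(out_dir,
                                sprintf("%s_f%03d.tif", sq$cell_id, f))
          tiff::writeTIFF(.to_unit(sq$frames[[f]]$phase), paths[f],
                          bits.per.sample = 32L)
        }
      }
      rows[[cell_no]] <- data.frame(cell_id = sq$cell_id, class = sp$name,
                                    frame = seq_len(nv), angle_rad = sq$angles,
                                    path = paths)
      if (keep_sequences) seqs[[cell_no]] <- sq
    }
  }
  manifest <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (write_images) {
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  if (keep_sequences) attr(manifest, "sequences") <- seqs[!vapply(seqs, is.null, logical(1))]
  manifest
}

# writeTIFF stores [0,1] floats; encode phase as phi / PHASE_SCALE
.PHASE_SCALE <- 32
.to_unit <- function(phase) {
  pmin(pmax(phase / .PHASE_SCALE + 0.5, 0), 1)
}
.from_unit <- function(unit) {
  (unit - 0.5) * .PHASE_SCALE
}

#' Read a QPM frame written by [make_dataset()]
#'
#' @param path TIFF path from the manifest.
#' @param pitch Object-plane pixel pitch in um.
#' @param id Provenance id.
#' @return A [qpm_image()].
#' @export
read_qpm <- function(path, pitch, id = basename(path)) {
  u <- tiff::readTIFF(path)
  qpm_image(.from_unit(u), pitch, id = id)
}
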