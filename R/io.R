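# Plain-format readers/writers: multi-page TIFF stacks, label volumes,
# dot tables (CSV), count matrices (CSV + MatrixMarket), JSON sidecars.

#' Write a channel volume as a multi-page 32-bit float TIFF
#'
#' Pages are z planes. The TIFF writer stores unit-interval samples, so
#' intensities are written as `value / 65535` (the same convention as the
#' 16-bit label files); [read_volume_tiff()] undoes the scaling. Values
#' must lie in `[0, 65535]`; negative read-noise excursions are clipped
#' at 0. 32-bit float storage keeps ~7 significant digits.
#'
#' @param vol `(z, y, x)` volume.
#' @param path Output file.
#' @export
write_volume_tiff <- function(vol, path) {
  .assert(.is_volume(vol), "vol must be a 3D array")
  .assert(max(vol) <= 65535, "intensities exceed the storage range")
  pages <- lapply(seq_len(dim(vol)[1]),
                  function(z) pmax(vol[z, , ], 0) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 32, compression = "none")
  invisible(path)
}

#' Read a multi-page TIFF back into a `(z, y, x)` volume
#' @param path TIFF file written by [write_volume_tiff()].
#' @return `(z, y, x)` numeric array (on the original intensity scale).
#' @export
read_volume_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  out <- array(0, c(length(pages), d[1], d[2]))
  for (z in seq_along(pages)) out[z, , ] <- pages[[z]] * 65535
  out
}

#' Write / read an integer label volume as 16-bit TIFF
#'
#' Labels are stored as `value / 65535` (the writer's unit-interval
#' convention); [read_labels_tiff()] undoes the scaling exactly for labels
#' up to 65535.
#'
#' @param labels Integer `(z, y, x)` label array (max 65535).
#' @param path File path.
#' @export
write_labels_tiff <- function(labels, path) {
  .assert(max(labels) <= 65535, "labels exceed 16-bit range")
  pages <- lapply(seq_len(dim(labels)[1]), function(z) labels[z, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  invisible(path)
}

#' @rdname write_labels_tiff
#' @export
read_labels_tiff <- function(path) {
  v <- read_volume_tiff(path)
  array(as.integer(round(v)), dim(v))
}

#' Write one FOV's acquisition to disk
#'
#' One multi-page TIFF per round and channel (channel-major pages within a
#' round would lose the channel names, so files are
#' `round<NN>_ch<NN>.tif`), plus a JSON sidecar with the round plan, voxel
#' size and (only when `with_truth`) the true shifts; with `with_truth` the
#' ground truth is written as CSV (cell table, dot truth, true counts) and
#' TIFF (label volume).
#'
#' @param fov An `scmst_fov` from [simulate_fov()].
#' @param dir Output directory (created).
#' @param with_truth Also write the ground truth?
#' @return `dir`, invisibly.
#' @export
write_fov <- function(fov, dir, with_truth = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (r in seq_along(fov$stack))
    for (ch in names(fov$stack[[r]]))
      write_volume_tiff(
        fov$stack[[r]][[ch]],
        file.path(dir, sprintf("round%02d_ch%02d.tif", r, as.integer(ch))))
  sidecar <- list(
    embryo = fov$embryo, fov = fov$fov,
    voxel_size = fov$config$voxel_size,
    round_plan = fov$layout$round_plan,
    nuclei_channel = fov$layout$nuclei_channel,
    membrane_round = fov$layout$membrane_round,
    membrane_channels = fov$layout$membrane_channels,
    repeat_round = fov$layout$repeat_round
  )
  if (with_truth) sidecar$true_shifts <- fov$truth$shifts
  jsonlite::write_json(sidecar, file.path(dir, "acquisition.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (with_truth) {
    write.csv(fov$truth$cell_table, file.path(dir, "cell_table.csv"),
              row.names = FALSE)
    write.csv(fov$truth$dot_truth, file.path(dir, "dot_truth.csv"),
              row.names = FALSE)
    write.csv(as.data.frame(fov$truth$true_counts),
              file.path(dir, "true_counts.csv"))
    write_labels_tiff(fov$truth$labels, file.path(dir, "labels.tif"))
  }
  invisible(dir)
}

#' Write a dot table as CSV
#' @param dots Dot `data.frame`.
#' @param path Output CSV.
#' @export
write_dots <- function(dots, path) {
  write.csv(dots, path, row.names = FALSE)
  invisible(path)
}

#' Write a count matrix as CSV plus MatrixMarket with metadata TSVs
#'
#' `<stem>.csv` holds the dense counts (cells x genes),
#' `<stem>.mtx` the sparse MatrixMarket form, and `<stem>_cells.tsv` /
#' `<stem>_genes.tsv` the metadata.
#'
#' @param counts An `scmst_counts`.
#' @param stem Path stem (no extension).
#' @export
write_counts <- function(counts, stem) {
  write.csv(cbind(counts$cell_meta, as.data.frame(counts$values)),
            paste0(stem, ".csv"), row.names = FALSE)
  Matrix::writeMM(Matrix::Matrix(counts$values, sparse = TRUE),
                  paste0(stem, ".mtx"))
  write.table(counts$cell_meta, paste0(stem, "_cells.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(counts$gene_meta, paste0(stem, "_genes.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(stem)
}

#' Write an RGB array as PNG
#' @param rgb `ny x nx x 3` array in `[0, 1]`.
#' @param path Output PNG.
#' @export
write_rgb_png <- function(rgb, path) {
  png::writePNG(pmin(pmax(rgb, 0), 1), path)
  invisible(path)
}

#' Export a dendrogram as Newick text
#'
#' @param tree An `hclust` object.
#' @param labels Optional leaf labels (default: `tree$labels` or indices).
#' @return Newick string (also written to `path` when given).
#' @param path Optional output file.
#' @export
as_newick <- function(tree, labels = NULL, path = NULL) {
  if (is.null(labels))
    labels <- if (!is.null(tree$labels)) tree$labels
              else as.character(seq_len(nrow(tree$merge) + 1L))
  rec <- function(i) {
    if (i < 0) return(labels[-i])
    h <- tree$height[i]
    l <- tree$merge[i, 1]; r <- tree$merge[i, 2]
    hl <- if (l < 0) 0 else tree$height[l]
    hr <- if (r < 0) 0 else tree$height[r]
    sprintf("(%s:%.6g,%s:%.6g)", rec(l), h - hl, rec(r), h - hr)
  }
  nwk <- paste0(rec(nrow(tree$merge)), ";")
  if (!is.null(path)) writeLines(nwk, path)
  invisible(nwk)
}
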