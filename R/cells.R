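# 3D cell segmentation, dot-to-cell assignment and the count matrix.

#' Relabel a label volume to contiguous 1..N
#' @param labels Integer `(z, y, x)` label array.
#' @return Relabelled array with the same zero set.
#' @export
relabel_contiguous <- function(labels) {
  ids <- sort(unique(labels[labels > 0L]))
  if (length(ids) == 0) return(labels)
  map <- integer(max(ids))
  map[ids] <- seq_along(ids)
  out <- labels
  out[labels > 0L] <- map[labels[labels > 0L]]
  out
}

#' Segment cells in 3D by seeded watershed
#'
#' Seeds are local maxima of the smoothed nuclei volume (minimum separation
#' about one expected cell radius, anisotropy-aware); the elevation surface
#' is the smoothed membrane composite (sum of the membrane channels). The
#' tissue mask is the union of the membrane walls and the nuclei (each
#' thresholded a small fraction above its background level) with enclosed
#' cytoplasm filled in: complement components that do not reach a lateral
#' (y/x) volume border are interior holes. The watershed floods the mask
#' from the nuclei seeds; components below `min_volume` voxels are removed
#' and labels made contiguous.
#'
#' @param membrane_composite `(z, y, x)` sum of the membrane channels.
#' @param nuclei `(z, y, x)` nuclei channel volume.
#' @param cell_radius Expected lateral cell radius in voxels.
#' @param anisotropy z-to-lateral voxel size ratio.
#' @param min_volume Minimum cell volume in voxels.
#' @param wall_frac Fraction of the (background-to-bright) dynamic range
#'   above background at which membrane walls / nuclei are masked in.
#' @return Integer label array; background 0, labels contiguous `1..N`.
#' @export
segment_cells <- function(membrane_composite, nuclei, cell_radius = 9,
                          anisotropy = 2.4, min_volume = 200,
                          wall_frac = 0.05) {
  .assert(.is_volume(nuclei) && .is_volume(membrane_composite),
          "inputs must be 3D arrays")
  .assert(all(dim(nuclei) == dim(membrane_composite)), "shapes must match")
  .assert(any(nuclei > 0) && sd(nuclei) > 0, "empty nuclei channel")
  d <- dim(nuclei)
  nsm <- gauss3d(nuclei, c(cell_radius / anisotropy / 2, cell_radius / 2,
                           cell_radius / 2))
  msm <- gauss3d(membrane_composite, c(0.8, 1.5, 1.5))
  # mask: membrane walls + nuclei, then fill laterally enclosed cytoplasm
  lvl <- function(v, frac) {
    bg <- median(v)
    bg + frac * (as.numeric(quantile(v, 0.999)) - bg)
  }
  mask0 <- msm > lvl(msm, wall_frac) | nsm > lvl(nsm, 2 * wall_frac)
  inv <- .label3d(!mask0)
  border <- unique(c(inv[, 1, ], inv[, d[2], ], inv[, , 1], inv[, , d[3]]))
  border <- border[border > 0L]
  mask <- mask0 | (inv > 0L & !(inv %in% border))
  # nuclei seeds
  rz <- max(1L, as.integer(round(cell_radius / anisotropy)))
  rl <- max(1L, as.integer(round(cell_radius)))
  floor_n <- as.numeric(quantile(nsm, 0.5))
  idx <- .localmax3d_cpp(nsm, rz, rl, rl, floor_n)
  idx <- idx[mask[idx]]
  .assert(length(idx) >= 1, "no nuclei seeds found")
  seeds <- array(0L, d)
  seeds[idx] <- seq_along(idx)
  labels <- .watershed3d_cpp(msm, seeds, array(as.integer(mask), d))
  # drop crumbs, relabel
  sz <- tabulate(labels[labels > 0L])
  small <- which(sz < min_volume)
  if (length(small)) labels[labels %in% small] <- 0L
  relabel_contiguous(labels)
}

#' Remove cells touching the lateral FOV borders
#'
#' Cells cut by the FOV edge carry partial counts; FOVs are analyzed
#' unstitched, so border-touching labels (in y or x) are dropped and the
#' rest relabelled contiguously.
#'
#' @param labels Integer label array.
#' @return `list(labels, edge_ids)`: the filtered, relabelled volume and
#'   the original ids that were removed.
#' @export
drop_edge_cells <- function(labels) {
  d <- dim(labels)
  edge <- unique(c(
    labels[, 1, ], labels[, d[2], ], labels[, , 1], labels[, , d[3]]
  ))
  edge <- edge[edge > 0L]
  out <- labels
  if (length(edge)) out[out %in% edge] <- 0L
  list(labels = relabel_contiguous(out), edge_ids = sort(edge))
}

#' Assign kept dots to segmented cells
#'
#' Each dot's centroid is mapped from its round's native coordinates into
#' the reference frame by subtracting that round's shift, rounded to the
#' nearest voxel, and assigned the label found there; label 0 or an
#' out-of-volume position leaves the dot unassigned.
#'
#' @param dots Dot table with `round`, `z`, `y`, `x` (native coordinates).
#' @param labels Reference-frame label volume.
#' @param shifts Rounds x 3 integer matrix of round shifts (as estimated by
#'   [register_rounds()]; row r is round r's `(z, y, x)` offset).
#' @return `dots` with a `cell` column (`NA` when unassigned) and an
#'   attribute `n_outside` counting out-of-volume dots.
#' @export
assign_dots <- function(dots, labels, shifts) {
  d <- dim(labels)
  n <- nrow(dots)
  cell <- rep(NA_integer_, n)
  outside <- 0L
  if (n > 0) {
    sh <- shifts[dots$round, , drop = FALSE]
    z <- as.integer(round(dots$z - sh[, 1]))
    y <- as.integer(round(dots$y - sh[, 2]))
    x <- as.integer(round(dots$x - sh[, 3]))
    ok <- z >= 1 & z <= d[1] & y >= 1 & y <= d[2] & x >= 1 & x <= d[3]
    outside <- sum(!ok)
    if (outside > 0)
      warning(sprintf("%d dot(s) mapped outside the volume", outside))
    lab <- labels[cbind(z[ok], y[ok], x[ok])]
    lab[lab == 0L] <- NA_integer_
    cell[ok] <- lab
  }
  dots$cell <- cell
  attr(dots, "n_outside") <- outside
  dots
}

#' Build the cells x genes count matrix
#'
#' `values[c, g]` counts the kept dots of gene `g` assigned to cell `c`;
#' cells without any dot are retained (zero rows, flagged in the metadata).
#'
#' @param dots Assigned, triaged dot table (`gene`, `cell`, `kept`).
#' @param panel Gene panel (column order of the matrix).
#' @param cell_meta Per-cell metadata with a `cell` column covering all
#'   labels of the volume.
#' @return An `scmst_counts` object: `list(values, cell_meta, gene_meta)`.
#' @export
build_count_matrix <- function(dots, panel, cell_meta) {
  .assert(all(dots$gene %in% panel), "dot table contains a gene not in panel")
  keep <- dots$kept & !is.na(dots$cell)
  dd <- dots[keep, , drop = FALSE]
  values <- matrix(0L, nrow(cell_meta), length(panel),
                   dimnames = list(cell_meta$cell, panel))
  if (nrow(dd)) {
    tab <- table(factor(dd$cell, levels = cell_meta$cell),
                 factor(dd$gene, levels = panel))
    values[] <- as.integer(tab)
  }
  cell_meta$total_counts <- as.integer(rowSums(values))
  cell_meta$zero_flag <- cell_meta$total_counts == 0L
  structure(list(values = values, cell_meta = cell_meta,
                 gene_meta = data.frame(gene = panel,
                                        stringsAsFactors = FALSE)),
            class = "scmst_counts")
}

#' Concatenate count matrices from several FOVs
#'
#' Cell ids are FOV-scoped; rows are re-indexed globally (column
#' `cell_global`) so no id collides across FOVs.
#'
#' @param ... `scmst_counts` objects (or one list of them).
#' @return A single `scmst_counts`.
#' @export
bind_counts <- function(...) {
  xs <- list(...)
  if (length(xs) == 1 && !inherits(xs[[1]], "scmst_counts")) xs <- xs[[1]]
  .assert(length(xs) >= 1, "nothing to bind")
  panel <- colnames(xs[[1]]$values)
  for (x in xs) .assert(identical(colnames(x$values), panel),
                        "gene panels differ")
  values <- do.call(rbind, lapply(xs, `[[`, "values"))
  meta <- do.call(rbind, lapply(xs, `[[`, "cell_meta"))
  meta$cell_global <- seq_len(nrow(meta))
  rownames(values) <- meta$cell_global
  rownames(meta) <- NULL
  structure(list(values = values, cell_meta = meta,
                 gene_meta = xs[[1]]$gene_meta),
            class = "scmst_counts")
}

#' @export
print.scmst_counts <- function(x, ...) {
  cat(sprintf("<scmst_counts> %d cells x %d genes, %d total transcripts\n",
              nrow(x$values), ncol(x$values), sum(x$values)))
  invisible(x)
}

#' Match segmented labels to ground-truth labels
#'
#' Each recovered label is paired with the truth label of maximal voxel
#' overlap; intersection-over-union is reported. Phantom evaluation helper.
#'
#' @param labels Recovered label volume.
#' @param truth_labels Ground-truth label volume (same shape).
#' @return `data.frame` with `label`, `truth`, `iou` (one row per recovered
#'   label; `truth` 0 when the best overlap is background).
#' @export
match_labels <- function(labels, truth_labels) {
  .assert(all(dim(labels) == dim(truth_labels)), "shapes must match")
  n <- max(labels)
  out <- data.frame(label = seq_len(n), truth = 0L, iou = 0)
  if (n == 0) return(out[0, ])
  sz_t <- tabulate(truth_labels[truth_labels > 0L])
  for (i in seq_len(n)) {
    sel <- labels == i
    tv <- truth_labels[sel]
    tv <- tv[tv > 0L]
    if (length(tv) == 0) next
    tb <- tabulate(tv)
    j <- which.max(tb)
    inter <- tb[j]
    union <- sum(sel) + sz_t[j] - inter
    out$truth[i] <- j
    out$iou[i] <- inter / union
  }
  out
}
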