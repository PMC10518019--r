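# Spatial back-mapping (pseudo-coloring) and display-only stitching.
#
# Visualization never feeds back into the analysis: FOVs are analyzed
# unstitched and mosaics are assembled for display only, after the
# expression analysis is complete.

#' Default qualitative colormap for cell groups
#'
#' @param ids Group identifiers (coerced to character).
#' @return Named vector of hex colors, one per id.
#' @export
group_colormap <- function(ids) {
  pal <- c("#E69F00", "#56B4E9", "#009E73", "#F0E442", "#0072B2",
           "#D55E00", "#CC79A7", "#999999", "#8DD3C7", "#BC80BD")
  ids <- as.character(ids)
  setNames(pal[(seq_along(ids) - 1L) %% length(pal) + 1L], ids)
}

#' Back-map analyzed cells into the tissue image
#'
#' Paints each cell's voxels with its group's pseudo-color; cells present
#' in the label volume but absent from `groups` are drawn gray, background
#' black. The z-projection takes, per (y, x) pixel, the label occupying the
#' most z planes (ties to the smallest label); `projection = "plane"`
#' renders a single z plane instead.
#'
#' @param labels `(z, y, x)` cell label volume.
#' @param groups Named vector or list mapping cell id -> group id; every
#'   mapped id must exist in `labels`.
#' @param colormap Named vector group id -> color (hex or R color name);
#'   defaults to [group_colormap()] over the distinct groups.
#' @param projection `"majority"` (default) or `"plane"`.
#' @param z Plane index when `projection = "plane"`.
#' @param unmapped_color,background_color Colors for unanalyzed cells and
#'   background.
#' @return `ny x nx x 3` RGB array in `[0, 1]`.
#' @export
backmap <- function(labels, groups, colormap = NULL,
                    projection = c("majority", "plane"), z = 1L,
                    unmapped_color = "gray40", background_color = "black") {
  projection <- match.arg(projection)
  ids <- as.integer(names(groups))
  .assert(!anyNA(ids), "groups must be named by integer cell ids")
  present <- unique(labels[labels > 0L])
  .assert(all(ids %in% present), "unknown cell id in group map")
  if (is.null(colormap))
    colormap <- group_colormap(unique(unlist(groups)))
  d <- dim(labels)
  flat <- if (projection == "majority") {
    apply(labels, c(2, 3), function(col) {
      col <- col[col > 0L]
      if (length(col) == 0) return(0L)
      tb <- tabulate(col)
      which.max(tb)
    })
  } else {
    .assert(z >= 1 && z <= d[1], "z plane out of range")
    labels[z, , ]
  }
  n_lab <- max(labels)
  lut <- matrix(rep(grDevices::col2rgb(background_color) / 255, n_lab + 1L),
                nrow = 3)
  lut[, -1] <- grDevices::col2rgb(unmapped_color) / 255
  for (i in seq_along(ids)) {
    g <- as.character(groups[[i]])
    .assert(g %in% names(colormap), paste("no color for group", g))
    lut[, ids[i] + 1L] <- grDevices::col2rgb(colormap[[g]]) / 255
  }
  rgb <- lut[, as.vector(flat) + 1L]
  array(t(rgb), dim = c(nrow(flat), ncol(flat), 3L))
}

#' Stitch FOV images into a display mosaic
#'
#' FOVs are pasted at their acquisition offsets onto a canvas sized to the
#' joint bounding box. Overlapping pixels follow `policy`: `"last_wins"`
#' (later FOVs overwrite) or `"error"` (any overlap aborts with its
#' extent).
#'
#' @param images List of 2D matrices or `ny x nx x 3` RGB arrays (all the
#'   same kind).
#' @param offsets N x 2 integer matrix of `(y, x)` offsets (0-based
#'   canvas positions of each FOV's top-left corner).
#' @param policy `"last_wins"` or `"error"`.
#' @param fill Background fill value.
#' @return `list(canvas, offsets, policy)` of class `scmst_mosaic`.
#' @export
stitch <- function(images, offsets, policy = c("last_wins", "error"),
                   fill = 0) {
  policy <- match.arg(policy)
  .assert(length(images) >= 1, "no images to stitch")
  offsets <- matrix(as.integer(offsets), ncol = 2)
  .assert(nrow(offsets) == length(images),
          "need one (y, x) offset per image")
  .assert(all(offsets >= 0), "offsets must be non-negative")
  rgb <- length(dim(images[[1]])) == 3
  hw <- t(vapply(images, function(im) dim(im)[1:2], integer(2)))
  H <- max(offsets[, 1] + hw[, 1])
  W <- max(offsets[, 2] + hw[, 2])
  canvas <- if (rgb) array(fill, c(H, W, 3L)) else matrix(fill, H, W)
  covered <- matrix(FALSE, H, W)
  for (i in seq_along(images)) {
    ys <- offsets[i, 1] + seq_len(hw[i, 1])
    xs <- offsets[i, 2] + seq_len(hw[i, 2])
    if (policy == "error") {
      ov <- sum(covered[ys, xs])
      .assert(ov == 0,
              sprintf("FOV %d overlaps %d already-covered pixel(s)", i, ov))
    }
    if (rgb) canvas[ys, xs, ] <- images[[i]] else canvas[ys, xs] <- images[[i]]
    covered[ys, xs] <- TRUE
  }
  structure(list(canvas = canvas, offsets = offsets, policy = policy),
            class = "scmst_mosaic")
}

#' @export
print.scmst_mosaic <- function(x, ...) {
  d <- dim(x$canvas)
  cat(sprintf("<scmst_mosaic> %d x %d canvas, %d FOV(s), policy = %s\n",
              d[1], d[2], nrow(x$offsets), x$policy))
  invisible(x)
}
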