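# build a toy two-cell scene: bright membrane walls around/between two
# boxes, nuclei blobs at the centres
two_cell_scene <- function() {
  d <- c(10L, 48L, 48L)
  labels <- array(0L, d)
  labels[2:9, 6:42, 4:23] <- 1L
  labels[2:9, 6:42, 26:45] <- 2L
  mem <- array(0, d)
  # walls: full shell of each box (6-neighbourhood erosion residue)
  for (lab in 1:2) {
    reg <- labels == lab
    inner <- reg
    zi <- 2:(d[1] - 1); yi <- 2:(d[2] - 1); xi <- 2:(d[3] - 1)
    inner[zi, yi, xi] <- reg[zi, yi, xi] &
      reg[zi - 1, yi, xi] & reg[zi + 1, yi, xi] &
      reg[zi, yi - 1, xi] & reg[zi, yi + 1, xi] &
      reg[zi, yi, xi - 1] & reg[zi, yi, xi + 1]
    mem[reg & !inner] <- 250
  }
  nuc <- scmst:::.add_blobs_cpp(array(0, d),
                                matrix(as.integer(rbind(c(5, 24, 13),
                                                        c(5, 24, 35))),
                                       ncol = 3),
                                c(400, 400), scmst:::.psf_kernel(c(1.5, 4, 4)))
  list(labels = labels, mem = mem + 100, nuc = nuc + 100)
}

test_that("watershed segmentation recovers two well-separated cells", {
  sc <- two_cell_scene()
  labs <- segment_cells(sc$mem, sc$nuc, cell_radius = 9, min_volume = 100)
  expect_equal(max(labs), 2L)
  ml <- match_labels(labs, sc$labels)
  expect_true(all(ml$iou >= 0.7))
  expect_equal(sort(ml$truth), 1:2)
  # determinism
  expect_identical(labs, segment_cells(sc$mem, sc$nuc, cell_radius = 9,
                                       min_volume = 100))
  # all-zero membrane with one nucleus: a single label
  nuc1 <- scmst:::.add_blobs_cpp(array(0, c(8L, 32L, 32L)),
                                 matrix(c(4L, 16L, 16L), ncol = 3), 400,
                                 scmst:::.psf_kernel(c(1.5, 4, 4)))
  labs1 <- segment_cells(array(100, c(8L, 32L, 32L)), nuc1 + 100,
                         cell_radius = 8, min_volume = 50)
  expect_equal(max(labs1), 1L)
  expect_error(segment_cells(sc$mem, array(0, dim(sc$mem))), "nuclei")
})

test_that("edge-cell dropping removes exactly the border-touching labels", {
  labels <- array(0L, c(4L, 20L, 20L))
  labels[, 3:8, 3:8] <- 1L      # interior
  labels[, 1:4, 14:19] <- 2L    # touches y border
  labels[, 12:16, 10:14] <- 3L  # interior
  de <- drop_edge_cells(labels)
  expect_equal(de$edge_ids, 2L)
  expect_equal(max(de$labels), 2L)  # relabelled contiguous
  # the interior cells survive with identical voxel sets
  expect_equal(which(de$labels == 1L), which(labels == 1L))
  expect_equal(which(de$labels == 2L), which(labels == 3L))
  # idempotent
  de2 <- drop_edge_cells(de$labels)
  expect_identical(de2$labels, de$labels)
  expect_length(de2$edge_ids, 0)
  # no border cells -> identity
  interior <- array(0L, c(4L, 20L, 20L))
  interior[, 5:10, 5:10] <- 1L
  expect_identical(drop_edge_cells(interior)$labels, interior)
})

test_that("dot assignment maps shifted dots to the owning label", {
  labels <- array(0L, c(6L, 30L, 30L))
  labels[2:5, 5:14, 5:14] <- 1L
  labels[2:5, 18:27, 18:27] <- 2L
  shifts <- rbind(c(0L, 0L, 0L), c(1L, 2L, -3L))
  dots <- data.frame(
    round = c(1L, 2L, 1L, 1L),
    z = c(3L, 4L, 1L, 3L),
    y = c(9L, 12L, 1L, 22L),
    x = c(9L, 7L, 1L, 22L))
  a <- assign_dots(dots, labels, shifts)
  expect_equal(a$cell, c(1L, 1L, NA_integer_, 2L))
  # shifted outside the volume warns and leaves the dot unassigned
  out <- data.frame(round = 2L, z = 1L, y = 2L, x = 29L)
  expect_warning(ao <- assign_dots(out, labels, shifts), "outside")
  expect_true(is.na(ao$cell))
})

test_that("count matrix equals a brute-force tally and conserves totals", {
  cell_meta <- data.frame(cell = 1:7, embryo = 1L, fov = 1L, stage = "HH5")
  panel <- c("gA", "gB", "gC")
  dots <- data.frame(
    gene = c("gA", "gA", "gA", "gB", "gC", "gA", "gB"),
    cell = c(7L, 7L, 7L, NA, 2L, 7L, 2L),
    kept = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE))
  cm <- build_count_matrix(dots, panel, cell_meta)
  expect_equal(cm$values["7", "gA"], 3L)
  expect_equal(cm$values["2", "gB"], 1L)
  expect_equal(sum(cm$values), 4L)  # kept & assigned only
  # brute-force tally oracle
  for (c_ in cell_meta$cell) for (g in panel) {
    expect_equal(cm$values[as.character(c_), g],
                 sum(dots$kept & !is.na(dots$cell) & dots$cell == c_ &
                       dots$gene == g))
  }
  expect_true(cm$cell_meta$zero_flag[1])
  expect_error(build_count_matrix(transform(dots, gene = "nope"), panel,
                                  cell_meta), "not in panel")
  # binding re-indexes cells globally
  cm2 <- cm
  b <- bind_counts(cm, cm2)
  expect_equal(nrow(b$values), 14L)
  expect_false(anyDuplicated(b$cell_meta$cell_global) > 0)
  expect_equal(sum(b$values), 8L)
})
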