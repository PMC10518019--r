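toy_counts <- function(values, embryo, stage = NULL, genes = NULL) {
  if (is.null(genes)) genes <- paste0("g", seq_len(ncol(values)))
  colnames(values) <- genes
  rownames(values) <- seq_len(nrow(values))
  meta <- data.frame(cell = seq_len(nrow(values)), embryo = embryo)
  meta$stage <- if (is.null(stage)) "S1" else stage
  structure(list(values = values, cell_meta = meta,
                 gene_meta = data.frame(gene = genes)),
            class = "scmst_counts")
}

test_that("within-embryo z-scoring matches hand arithmetic and centres columns", {
  m <- matrix(c(0, 1, 2, 3, 5, 5, 5, 5), ncol = 2)
  cnt <- toy_counts(m, embryo = rep(1L, 4))
  z <- zscore_within_embryo(cnt)
  expect_equal(z$values[, 1], (m[, 1] - 1.5) / sd(m[, 1]),
               ignore_attr = TRUE)
  # constant gene degenerates to zeros
  expect_equal(unname(z$values[, 2]), rep(0, 4))
  # per-embryo column means are 0
  m2 <- withr::with_seed(1, matrix(rpois(60, 5), ncol = 3))
  cnt2 <- toy_counts(m2, embryo = rep(1:2, each = 10))
  z2 <- zscore_within_embryo(cnt2)
  for (e in 1:2)
    expect_lt(max(abs(colMeans(z2$values[cnt2$cell_meta$embryo == e, ]))),
              1e-12)
  # single-cell embryo is an error
  expect_error(zscore_within_embryo(toy_counts(m, embryo = c(1, 2, 2, 2))),
               "single cell")
})

test_that("pooled z-scoring re-standardizes and matches the brute two-pass oracle", {
  m <- withr::with_seed(2, matrix(rpois(80, 4), ncol = 4))
  embryo <- rep(1:2, each = 10)
  cnt <- toy_counts(m, embryo = embryo)
  zp <- zscore_pooled(zscore_within_embryo(cnt))
  expect_equal(zp$mode, "pooled_stage")
  expect_lt(max(abs(colMeans(zp$values))), 1e-9)
  expect_lt(max(abs(apply(zp$values, 2, sd) - 1)), 1e-9)
  oracle <- brute_two_pass_z(m, embryo, group = rep("S1", 20))
  expect_equal(unname(zp$values), unname(oracle), tolerance = 1e-12)
  # one embryo only: second pass is a plain re-standardization
  cnt1 <- toy_counts(m[1:10, ], embryo = rep(1L, 10))
  z1 <- zscore_pooled(zscore_within_embryo(cnt1))
  expect_lt(max(abs(colMeans(z1$values))), 1e-9)
})

test_that("cross-stage z-scoring pools all stages and orders stage means", {
  mA <- withr::with_seed(3, matrix(rpois(40, 20), ncol = 2))
  mB <- withr::with_seed(4, matrix(rpois(40, 2), ncol = 2))
  cnt <- toy_counts(rbind(mA, mB), embryo = rep(1:2, each = 20),
                    stage = rep(c("HH5", "7ss"), each = 20))
  zx <- zscore_cross_stage(cnt)
  expect_equal(zx$mode, "cross_stage")
  expect_lt(max(abs(colMeans(zx$values))), 1e-9)
  # symmetric duplicate stages give identical per-stage z distributions
  cnt_dup <- toy_counts(rbind(mA, mA), embryo = rep(1:2, each = 20),
                        stage = rep(c("s1", "s2"), each = 20))
  zd <- zscore_cross_stage(cnt_dup)
  expect_equal(zd$values[1:20, ], zd$values[21:40, ], ignore_attr = TRUE)
  # the high-count stage ends up with positive z for that gene
  expect_gt(mean(zx$values[1:20, 1]), 0)
  expect_error(zscore_cross_stage(toy_counts(mA, embryo = rep(1, 20))),
               "two stages")
})

test_that("cosine distance matches the closed form and its metric properties", {
  m <- withr::with_seed(5, matrix(rnorm(20 * 8), 20, 8))
  d <- as.matrix(cosine_dist(m))
  expect_equal(d, brute_cosine(m), tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(d >= 0 & d <= 2 + 1e-12))
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 20))
  # zero-vector convention
  mz <- rbind(m[1:3, ], 0)
  dz <- as.matrix(cosine_dist(mz))
  expect_equal(unname(dz[4, 1:3]), rep(1, 3))
  expect_equal(unname(dz[4, 4]), 0)
})

test_that("hierarchical clustering agrees with a brute-force agglomeration", {
  m <- withr::with_seed(6, matrix(rnorm(6 * 4), 6, 4))
  res <- hcluster(m, k = 2)
  dmat <- as.matrix(cosine_dist(m))
  parts <- brute_average_linkage(dmat)
  # after each merge, cutree at the matching k gives the same partition
  tree <- res$tree
  for (step in seq_along(parts)) {
    k <- 6 - step
    if (k < 1) break
    lab <- cutree(tree, k = k)
    oracle_lab <- integer(6)
    for (i in seq_along(parts[[step]])) oracle_lab[parts[[step]][[i]]] <- i
    expect_equal(partition_key(lab), partition_key(oracle_lab))
  }
  # duplicated rows merge first (distance zero)
  mdup <- rbind(m[1, ], m[1, ], m[3:6, ])
  resd <- hcluster(mdup, k = 5)
  expect_equal(resd$tree$height[1], 0, tolerance = 1e-12)
  merged_first <- sort(-resd$tree$merge[1, ])
  expect_equal(merged_first, c(1, 2))
  expect_error(hcluster(m, k = 10), "k must be")
  # labels contiguous, leaf order a permutation
  expect_equal(sort(unique(res$labels)), 1:2)
  expect_equal(sort(res$cell_order), 1:6)
})

test_that("co-expression selection equals brute-force filter intersection", {
  zv <- matrix(c(-1, 0, 0.2, 2), ncol = 1)
  colnames(zv) <- "g1"
  z <- scmst:::.new_zmatrix(zv, data.frame(cell = 1:4, stage = "S1"),
                            "pooled_stage", list())
  sel <- select_coexpressing(z, "g1")
  expect_equal(sel$cells, c(3L, 4L))  # strict inequality excludes 0
  # random toys against the oracle
  withr::with_seed(7, for (i in 1:50) {
    m <- matrix(rnorm(10 * 4), 10, 4, dimnames = list(NULL, paste0("g", 1:4)))
    zz <- scmst:::.new_zmatrix(m, data.frame(cell = 1:10, stage = "S1"),
                               "pooled_stage", list())
    genes <- sample(colnames(m), sample(1:3, 1))
    expect_equal(select_coexpressing(zz, genes)$cells,
                 brute_select(m, genes))
  })
  # monotonicity: larger gene sets can only shrink the selection
  m <- withr::with_seed(8, matrix(rnorm(30 * 3), 30, 3,
                                  dimnames = list(NULL, c("a", "b", "c"))))
  zz <- scmst:::.new_zmatrix(m, data.frame(cell = 1:30, stage = "S1"),
                             "pooled_stage", list())
  s1 <- select_coexpressing(zz, c("a"))
  s2 <- select_coexpressing(zz, c("a", "b"))
  expect_true(all(s2$cells %in% s1$cells))
  expect_error(select_coexpressing(zz, character(0)), "empty")
  expect_error(select_coexpressing(zz, "nope"), "unknown")
})

test_that("overlap and stage composition are exact tabulations", {
  mk <- function(cells, n = 10) {
    mask <- rep(FALSE, n); mask[cells] <- TRUE
    structure(list(cells = cells, mask = mask, gene_set = "g",
                   per_stage = NULL), class = "scmst_selection")
  }
  a <- mk(c(1, 2, 3, 4)); b <- mk(c(3, 4, 5))
  ov <- overlap_stats(a, b)
  expect_equal(ov$n_both, 2)
  expect_equal(ov$frac_of_a, 0.5)
  expect_equal(ov$frac_of_b, 2 / 3)
  expect_equal(overlap_stats(a, a)$frac_of_a, 1)
  expect_equal(overlap_stats(a, mk(c(7, 8)))$n_both, 0)
  expect_true(is.na(overlap_stats(a, mk(integer(0)))$frac_of_b))
  # stage composition percentages at one decimal
  zv <- matrix(c(1, 1, -1, -1, -1, -1, -1, -1, -1, -1), ncol = 1,
               dimnames = list(NULL, "g1"))
  z <- scmst:::.new_zmatrix(zv, data.frame(cell = 1:10, stage = "X"),
                            "pooled_stage", list())
  sel <- select_coexpressing(z, "g1")
  expect_equal(sel$per_stage$pct_of_stage, 20.0)
  expect_equal(sum(sel$per_stage$n_selected), length(sel$cells))
})
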