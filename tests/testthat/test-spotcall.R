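psf <- c(0.7, 1, 1)

test_that("detector finds planted isolated dots and suppresses close pairs", {
  g <- expand.grid(z = c(4L, 9L), y = seq(10L, 55L, by = 15L),
                   x = seq(10L, 55L, by = 15L))
  pos <- unname(cbind(g$z, g$y, g$x))
  vol <- planted_volume(positions = pos)
  d <- detect_dots(median3d(vol), psf)
  d <- refine_dots(d, vol)
  expect_equal(nrow(d), nrow(pos))
  # each planted dot has a detection within one voxel per axis
  for (i in seq_len(nrow(pos))) {
    hit <- abs(d$z - pos[i, 1]) <= 1 & abs(d$y - pos[i, 2]) <= 1 &
      abs(d$x - pos[i, 3]) <= 1
    expect_true(any(hit))
  }
  # pure-noise volume yields no detections above the noise ceiling
  empty <- withr::with_seed(8, array(10 + rnorm(12 * 64 * 64, 0, 0.5),
                                     c(12, 64, 64)))
  d0 <- detect_dots(median3d(empty), psf, floor_quantile = 0.999)
  expect_lte(nrow(d0), 3)
  # two dots closer than the suppression distance give one detection
  close2 <- planted_volume(positions = rbind(c(6, 30, 30), c(6, 31, 30)))
  dc <- detect_dots(median3d(close2), psf, min_distance = 2)
  expect_equal(nrow(dc), 1L)
  expect_error(detect_dots(vol, c(0, 1, 1)), "positive")
})

test_that("dot features are the support mean and population sd, order-invariant", {
  # hand-computable: a flat 3-voxel line cannot be built with the ellipsoid
  # support, so engineer a volume constant over the support instead
  vol <- array(20, c(7, 9, 9))
  dots <- data.frame(z = 4L, y = 5L, x = 5L, response = 1)
  f <- dot_features(vol, dots, psf)
  expect_equal(f$mean_intensity, 20)
  expect_equal(f$intensity_variability, 0)
  # arithmetic oracle on a small crafted support
  vol2 <- array(0, c(7, 9, 9))
  off <- scmst:::.support_offsets(psf)
  vals <- seq_len(nrow(off)) * 10
  for (i in seq_len(nrow(off)))
    vol2[4 + off[i, 1], 5 + off[i, 2], 5 + off[i, 3]] <- vals[i]
  f2 <- dot_features(vol2, dots, psf)
  expect_equal(f2$mean_intensity, mean(vals))
  expect_equal(f2$intensity_variability, sqrt(mean((vals - mean(vals))^2)))
  # range variant
  f3 <- dot_features(vol2, dots, psf, variability = "range")
  expect_equal(f3$intensity_variability, max(vals) - min(vals))
  # invariance to dot ordering
  many <- data.frame(z = c(2L, 4L, 6L), y = c(3L, 5L, 7L), x = c(3L, 5L, 7L),
                     response = 1)
  fa <- dot_features(vol2, many, psf)
  fb <- dot_features(vol2, many[3:1, ], psf)
  expect_equal(fa$mean_intensity, rev(fb$mean_intensity))
})

sim_feature_dots <- function(n = c(200, 120, 20),
                             mu = list(c(60, 8), c(250, 45), c(900, 170)),
                             sd = list(c(8, 2), c(20, 8), c(60, 25)),
                             classes = c("nonspecific", "true", "artifact"),
                             seed = 9) {
  withr::with_seed(seed, {
    rows <- do.call(rbind, lapply(which(n > 0), function(i)
      data.frame(
        mean_intensity = rnorm(n[i], mu[[i]][1], sd[[i]][1]),
        intensity_variability = pmax(rnorm(n[i], mu[[i]][2], sd[[i]][2]), 0),
        class = classes[i])))
    rows[sample.int(nrow(rows)), ]
  })
}

test_that("k selection finds well-separated blob counts and degenerates to 1", {
  dots2 <- sim_feature_dots(n = c(150, 150, 0))
  expect_equal(select_k(dots2, seed = 1)$k, 2L)
  dots3 <- sim_feature_dots()
  expect_equal(select_k(dots3, seed = 1)$k, 3L)
  same <- data.frame(mean_intensity = rep(5, 50),
                     intensity_variability = rep(1, 50))
  expect_warning(k1 <- select_k(same), "identical")
  expect_equal(k1$k, 1L)
  expect_equal(select_k(dots3, override = 4L)$k, 4L)
})

test_that("k-means triage separates the three intensity classes", {
  dots <- sim_feature_dots()
  tr <- kmeans_triage(dots, 3, seed = 2)
  kept <- tr$dots[tr$dots$kept, ]
  recall <- sum(kept$class == "true") / sum(dots$class == "true")
  precision <- mean(kept$class == "true")
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)
  # exactness: no kept dot belongs to a rejected cluster
  expect_true(all(tr$dots$cluster[tr$dots$kept] %in% tr$result$retained))
  expect_true(length(tr$result$retained) < tr$result$k)
  # determinism and order independence of the kept mask
  tr2 <- kmeans_triage(dots, 3, seed = 2)
  expect_identical(tr$dots$kept, tr2$dots$kept)
  perm <- withr::with_seed(3, sample.int(nrow(dots)))
  tr3 <- kmeans_triage(dots[perm, ], 3, seed = 2)
  expect_identical(tr3$dots$kept, tr$dots$kept[perm])
  # monotonicity: raising the artifact quantile can only grow the kept set
  lo <- kmeans_triage(dots, 3, artifact_quantile = 0.90, seed = 2)
  hi <- kmeans_triage(dots, 3, artifact_quantile = 0.999, seed = 2)
  expect_true(all(hi$dots$kept | !lo$dots$kept))
  # true-only input at k = 2 rejects the dimmest cluster
  tdots <- sim_feature_dots(n = c(0, 300, 0))
  t2 <- kmeans_triage(tdots, 2, seed = 4)
  # a symmetric single class splits roughly in half, keeping the bright side
  expect_gte(mean(t2$dots$kept), 0.35)
  expect_lte(mean(t2$dots$kept), 0.65)
  kept_mu <- mean(t2$dots$mean_intensity[t2$dots$kept])
  rej_mu <- mean(t2$dots$mean_intensity[!t2$dots$kept])
  expect_gt(kept_mu, rej_mu)
  # k = 1 keeps everything with a warning
  expect_warning(t1 <- kmeans_triage(dots, 1), "k = 1")
  expect_true(all(t1$dots$kept))
})

test_that("recovery rate compares repeat-round yield per gene", {
  base <- data.frame(gene = rep(c("a", "b"), each = 10), kept = TRUE)
  full <- recovery_rate(base, base)
  expect_equal(full$overall, 1)
  expect_true(full$pass)
  half <- base[seq(1, 20, by = 2), ]
  r <- recovery_rate(base, half)
  expect_equal(r$overall, 0.5)
  expect_false(r$pass)
  expect_equal(r$per_gene$recovery, c(0.5, 0.5))
  # a gene with zero initial dots reports NA
  extra <- rbind(base, data.frame(gene = "c", kept = FALSE))
  rr <- recovery_rate(extra, rbind(half, data.frame(gene = "c", kept = TRUE)))
  expect_true(is.na(rr$per_gene$recovery[rr$per_gene$gene == "c"]))
})
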