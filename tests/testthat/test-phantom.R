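test_that("round plan fills rounds in panel order with the right shape", {
  plan <- make_round_plan(default_gene_panel(), 5, 6)
  expect_equal(nrow(plan), 30)
  expect_equal(max(plan$round), 6)
  expect_true(all(table(plan$round) == 5))
  # every gene mapped exactly once, channels distinct within a round
  expect_false(anyDuplicated(plan$gene) > 0)
  for (r in unique(plan$round))
    expect_false(anyDuplicated(plan$channel[plan$round == r]) > 0)

  expect_equal(nrow(make_round_plan("OneGene", 5, 6)), 1)
  sizes <- as.integer(table(make_round_plan(paste0("g", 1:12), 5, 6)$round))
  expect_equal(sizes, c(5L, 5L, 2L))

  expect_error(make_round_plan(character(0)), "non-empty")
  expect_error(make_round_plan(c("a", "a")), "duplicate")
  expect_error(make_round_plan(letters[1:6], 5, 4), "channels")
})

test_that("tissue simulation yields contiguous connected labels, deterministically", {
  cfg <- small_phantom_config()
  tis <- simulate_tissue(cfg, 42)
  labs <- tis$labels
  n <- max(labs)
  expect_equal(n, cfg$n_cells_per_fov)
  # no gaps in 1..N
  expect_equal(sort(unique(as.vector(labs[labs > 0]))), 1:n)
  # each label is one connected component
  for (i in sample(1:n, 5)) {
    comp <- scmst:::.label3d(labs == i)
    expect_equal(max(comp), 1L)
  }
  # determinism
  tis2 <- simulate_tissue(cfg, 42)
  expect_identical(tis$labels, tis2$labels)
  expect_identical(tis$cell_table, tis2$cell_table)
  # infeasible cell count errors
  tiny <- phantom_config(volume_shape = c(4L, 10L, 10L), n_cells_per_fov = 200)
  expect_error(simulate_tissue(tiny, 1), "infeasible")
})

test_that("simulated counts follow the subpopulation means", {
  cfg <- small_phantom_config()
  spec <- cfg$subpop_spec
  ct <- data.frame(cell = 1:1000, subpop = spec[[1]]$name)
  m <- simulate_counts(ct, spec, 7)
  expect_true(is.integer(m))
  # degenerate mean 0 -> all zero counts
  zero_genes <- names(spec[[1]]$means)[spec[[1]]$means == 0]
  if (length(zero_genes)) expect_true(all(m[, zero_genes] == 0))
  # CLT check: sample mean of a marker gene within 3 standard errors
  g <- names(which.max(spec[[1]]$means))
  mu <- max(spec[[1]]$means)
  se <- sqrt(mu / 1000)
  expect_lt(abs(mean(m[, g]) - mu), 3 * se)
  # determinism
  expect_identical(m, simulate_counts(ct, spec, 7))
  # negative mean rejected
  bad <- spec
  bad[[1]]$means[1] <- -1
  expect_error(simulate_counts(ct, bad, 7), "negative")
})

test_that("rendered stacks conserve dot bookkeeping and round structure", {
  cfg <- small_phantom_config()
  fv <- simulate_fov(cfg, 1, 1)
  lay <- fv$layout
  expect_equal(length(fv$stack), lay$rounds)
  dt <- fv$truth$dot_truth
  # conservation: true-class dots in gene rounds equal the count total
  ng <- sum(dt$class == "true" & dt$round <= lay$n_gene_rounds)
  expect_equal(ng, sum(fv$truth$true_counts))
  # every true dot lies inside a nonzero label
  tr <- dt[dt$class == "true", ]
  labs <- fv$truth$labels
  owner <- labs[cbind(tr$z, tr$y, tr$x)]
  expect_true(all(owner > 0))
  expect_equal(owner, tr$cell)
  # reference channel present every round; membrane channels in its round
  for (r in seq_len(lay$rounds))
    expect_true(as.character(lay$nuclei_channel) %in% names(fv$stack[[r]]))
  expect_true(all(as.character(lay$membrane_channels) %in%
                    names(fv$stack[[lay$membrane_round]])))
  # byte-identical regeneration
  fv2 <- simulate_fov(cfg, 1, 1)
  expect_identical(fv$stack, fv2$stack)
  expect_identical(fv$truth, fv2$truth)
})

test_that("a single noiseless transcript renders as one blob at its voxel", {
  cfg <- phantom_config(
    n_embryos = 1, n_fovs_per_embryo = 1,
    volume_shape = c(8L, 48L, 48L), n_cells_per_fov = 2,
    gene_panel = c("gA", "gB"), genes_per_round = 2,
    subpop_spec = list(list(name = "only", fraction = 1,
                            means = c(gA = 0, gB = 0))),
    dot_intensity_model = list(
      true = list(mean = 100, sd = 0),
      nonspecific = list(mean = 30, sd = 0),
      artifact = list(mean = 500, sd = 0),
      nonspecific_rate = 0, artifact_rate = 0),
    illumination_model = list(amplitude = 0, sigma_frac = 0.5),
    shift_model = c(0L, 0L, 0L), noise_sd = 0, background = 0,
    repeat_round = FALSE, stages = "HH5", rng_seed = 2)
  tis <- simulate_tissue(cfg, 3)
  counts <- matrix(c(1L, 0L, 0L, 0L), 2, 2,
                   dimnames = list(1:2, c("gA", "gB")))
  rend <- render_stacks(list(labels = tis$labels,
                             cell_table = tis$cell_table,
                             true_counts = counts), cfg, 4)
  vol <- rend$rounds[[1]][["1"]]
  dt <- rend$dot_truth
  expect_equal(nrow(dt), 1L)
  # the planted voxel is the unique global maximum
  pk <- arrayInd(which.max(vol), dim(vol))
  expect_equal(as.integer(pk), c(dt$z, dt$y, dt$x))
  expect_equal(max(vol), 100, tolerance = 1e-6)
  # flat illumination + zero shift: nuclei template identical across rounds
  expect_identical(rend$rounds[[1]][["6"]], rend$rounds[[2]][["6"]])
})
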