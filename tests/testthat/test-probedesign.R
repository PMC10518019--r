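rand_dna <- function(n, seed = 1, gc = 0.5) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, TRUE,
                                      prob = c((1 - gc) / 2, gc / 2, gc / 2,
                                               (1 - gc) / 2)),
                               collapse = ""))
}

test_that("probe construction yields 60-nt probes that invert correctly", {
  cfg <- probe_config()
  site <- rand_dna(20, seed = 3)
  probe <- construct_probe(site, "B1", cfg)
  expect_equal(nchar(probe), 60L)
  # structure: revcomp(site) + linker + initiator
  expect_equal(substr(probe, 21, 24), cfg$linker)
  expect_equal(substr(probe, 25, 60), unname(cfg$initiators[["B1"]]))
  # stripping linker + initiator reverse-complements back to the site
  binding <- substr(probe, 1, 20)
  expect_equal(scmst:::.revcomp(binding), site)
  # additivity with a zero-length linker
  cfg0 <- probe_config(total_len = 56L, linker_len = 0L, linker = "")
  p0 <- construct_probe(site, "B2", cfg0)
  expect_equal(nchar(p0), 20L + nchar(cfg0$initiators[["B2"]]))
  # errors: wrong site length, invalid characters
  expect_error(construct_probe(substr(site, 1, 10), "B1", cfg), "20 nt")
  expect_error(construct_probe(gsub("A", "N", paste0(site, "A")), "B1", cfg))
})

test_that("tiling caps at 24 probes and warns below the 13-probe minimum", {
  cfg <- probe_config()
  long_cds <- rand_dna(10000, seed = 7, gc = 0.5)
  ps <- tile_gene(long_cds, "B1", cfg, gene = "big")
  expect_equal(nrow(ps$probes), 24L)
  expect_true(all(nchar(ps$probes$probe) == 60L))
  expect_length(ps$warnings, 0)
  # sites non-overlapping and separated by >= min_gap
  gaps <- ps$probes$start[-1] - ps$probes$end[-nrow(ps$probes)] - 1L
  expect_true(all(gaps >= cfg$min_gap))
  # a CDS admitting exactly 12 sites: 12 probes plus an under-coverage warning
  cds12 <- rand_dna(12 * 22 - 2, seed = 11, gc = 0.5)
  expect_warning(ps12 <- tile_gene(cds12, "B3", cfg, gene = "short"),
                 "under-coverage")
  expect_lte(nrow(ps12$probes), 12L)
  expect_gt(length(ps12$warnings), 0)
  # strict mode raises instead
  expect_error(tile_gene(cds12, "B3", probe_config(strict = TRUE)), "under")
  # shorter than one binding site is an error
  expect_error(tile_gene(rand_dna(10), "B1", cfg), "shorter")
  # idempotent / deterministic
  ps2 <- tile_gene(long_cds, "B1", cfg, gene = "big")
  expect_identical(ps$probes, ps2$probes)
})

test_that("initiator assignment is a within-round bijection", {
  plan <- make_round_plan(default_gene_panel(), 5, 6)
  inits <- assign_initiators(plan)
  expect_equal(length(inits), 30L)
  for (r in unique(plan$round)) {
    genes <- plan$gene[plan$round == r]
    expect_false(anyDuplicated(inits[genes]) > 0)
  }
  # pigeonhole: 6 genes in one round with 5 initiators
  plan6 <- make_round_plan(letters[1:6], 6, 6)
  expect_error(assign_initiators(plan6), "initiators")
})

test_that("panel probe design combines tiling and initiator assignment", {
  plan <- make_round_plan(c("gA", "gB", "gC"), 2, 6)
  cds <- c(gA = rand_dna(2000, 21), gB = rand_dna(2000, 22),
           gC = rand_dna(2000, 23))
  res <- design_panel_probes(cds, plan)
  expect_true(all(c("gA", "gB", "gC") %in% res$probes$gene))
  expect_true(all(nchar(res$probes$probe) == 60L))
  # FASTA round trip
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">gA", cds[["gA"]], ">gB", cds[["gB"]], ">gC", cds[["gC"]]), fa)
  res2 <- design_panel_probes(fa, plan)
  expect_identical(res$probes, res2$probes)
})
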