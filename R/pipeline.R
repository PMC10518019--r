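# End-to-end orchestration: phantom acquisition -> preprocess -> register ->
# detect -> triage -> segment -> count -> normalize -> cluster -> select ->
# back-map/stitch, with a JSON manifest for provenance.

.pipeline_defaults <- function() {
  list(
    seed = 1L,
    median_kernel = c(3L, 3L, 3L),
    flatfield_smooth_sigma = 20,
    max_shift = c(2L, 8L, 8L),
    min_distance = 1,
    floor_quantile = 0.95,
    triage_k = 3L,
    triage_k_auto = FALSE,
    artifact_quantile = 0.995,
    recovery_threshold = 0.70,
    drop_edge = TRUE,
    cell_radius = 9,
    min_cell_volume = 150,
    k_clusters = NULL,           # default: number of phantom subpops
    select_genes = c("Nanog", "PouV", "Klf4"),
    stitch_gap = 8L,
    write_images = TRUE
  )
}

#' Build and validate a pipeline configuration
#'
#' @param phantom A [phantom_config()] describing the acquisition.
#' @param ... Stage parameters overriding the defaults (unknown names are
#'   rejected): `seed`, `median_kernel`, `flatfield_smooth_sigma`,
#'   `max_shift`, `min_distance`, `floor_quantile`, `triage_k`,
#'   `triage_k_auto`, `artifact_quantile`, `recovery_threshold`,
#'   `drop_edge`, `cell_radius`, `min_cell_volume`, `k_clusters`,
#'   `select_genes`, `stitch_gap`, `write_images`.
#' @return A validated `scmst_pipeline_config`.
#' @export
pipeline_config <- function(phantom = phantom_config(), ...) {
  .assert(inherits(phantom, "phantom_config"),
          "phantom must be a phantom_config")
  p <- .pipeline_defaults()
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  .assert(length(unknown) == 0,
          paste("unknown config key(s):", paste(unknown, collapse = ", ")))
  p[names(dots)] <- dots
  .assert(p$recovery_threshold >= 0 && p$recovery_threshold <= 1,
          "recovery_threshold must be in [0, 1]")
  .assert(all(p$median_kernel %% 2 == 1), "median kernel dims must be odd")
  if (is.null(p$k_clusters)) p$k_clusters <- length(phantom$subpop_spec)
  .assert(all(p$select_genes %in% phantom$gene_panel),
          "select_genes must be in the gene panel")
  structure(c(list(phantom = phantom), p), class = "scmst_pipeline_config")
}

# anisotropy (z / lateral voxel size) of the acquisition
.aniso <- function(phantom) phantom$voxel_size[1] / phantom$voxel_size[3]

# Process one FOV up to (untriaged) dots + segmentation; returns dot table
# in native coordinates, estimated shifts, labels and cell metadata.
.process_fov <- function(cfg, embryo, fov_idx) {
  ph <- cfg$phantom
  fv <- simulate_fov(ph, embryo, fov_idx)
  lay <- fv$layout
  ani <- .aniso(ph)
  # flat-field per channel, pooled over this FOV's dot-bearing rounds (the
  # membrane round's sheet-like structure would bias the channel 1-2
  # estimates; the field is an optics property, shared by all rounds)
  chan_ids <- sort(unique(unlist(lapply(fv$stack, names))))
  fields <- list()
  for (ch in chan_ids) {
    use <- setdiff(seq_along(fv$stack), lay$membrane_round)
    vols <- lapply(fv$stack[use], function(r) r[[ch]])
    vols <- vols[!vapply(vols, is.null, TRUE)]
    fields[[ch]] <- estimate_flatfield(vols, cfg$flatfield_smooth_sigma)
  }
  corr <- function(r, ch) {
    apply_flatfield(fv$stack[[r]][[as.character(ch)]],
                    fields[[as.character(ch)]])
  }
  prep <- function(r, ch) median3d(corr(r, ch), cfg$median_kernel)
  # registration on the nuclei channel, round 1 = reference
  nuc_ref <- prep(1L, lay$nuclei_channel)
  n_rounds <- length(fv$stack)
  shifts <- matrix(0L, n_rounds, 3, dimnames = list(NULL, c("z", "y", "x")))
  scores <- numeric(n_rounds)
  for (r in seq_len(n_rounds)[-1]) {
    reg <- register_rounds(nuc_ref, prep(r, lay$nuclei_channel),
                           cfg$max_shift)
    shifts[r, ] <- reg$shift
    scores[r] <- reg$score
  }
  # dot detection + features, per gene (native round coordinates)
  plan <- lay$round_plan
  det <- list()
  detect_one <- function(r, ch, gene) {
    volc <- corr(r, ch)
    dots <- detect_dots(median3d(volc, cfg$median_kernel), ph$psf_sigma,
                        cfg$min_distance, cfg$floor_quantile, ani)
    if (nrow(dots) == 0) return(NULL)
    dots <- refine_dots(dots, volc)
    # features on the corrected, unfiltered volume: the median filter
    # flattens the blob profile and would collapse the variability feature
    dots <- dot_features(volc, dots, ph$psf_sigma)
    dots$gene <- gene; dots$round <- r; dots$channel <- ch
    dots$embryo <- embryo; dots$fov <- fov_idx
    dots
  }
  for (i in seq_len(nrow(plan)))
    det[[length(det) + 1L]] <- detect_one(plan$round[i], plan$channel[i],
                                          plan$gene[i])
  if (!is.na(lay$repeat_round)) {
    p1 <- plan[plan$round == 1L, ]
    for (i in seq_len(nrow(p1)))
      det[[length(det) + 1L]] <- detect_one(lay$repeat_round, p1$channel[i],
                                            p1$gene[i])
  }
  dots <- do.call(rbind, det)
  # segmentation in the reference frame
  mr <- lay$membrane_round
  mem <- prep(mr, lay$membrane_channels[1]) +
    prep(mr, lay$membrane_channels[2])
  mem <- apply_shift(mem, -shifts[mr, ], fill = "edge")
  labels <- segment_cells(mem, nuc_ref, cfg$cell_radius, ani,
                          cfg$min_cell_volume)
  edge_ids <- integer(0)
  if (cfg$drop_edge) {
    de <- drop_edge_cells(labels)
    labels <- de$labels
    edge_ids <- de$edge_ids
  }
  occ <- which(labels > 0L)
  d <- dim(labels)
  i0 <- occ - 1L
  lz <- (i0 %% d[1]) + 1L
  ly <- ((i0 %/% d[1]) %% d[2]) + 1L
  lx <- (i0 %/% (d[1] * d[2])) + 1L
  lo <- labels[occ]
  n_cells <- max(labels)
  cell_meta <- data.frame(
    cell = seq_len(n_cells),
    embryo = embryo, fov = fov_idx,
    stage = .embryo_stage(ph, embryo),
    centroid_z = as.numeric(tapply(lz, lo, mean)),
    centroid_y = as.numeric(tapply(ly, lo, mean)),
    centroid_x = as.numeric(tapply(lx, lo, mean)),
    volume_vox = as.integer(tabulate(lo, n_cells)),
    edge_dropped_ids = length(edge_ids),
    stringsAsFactors = FALSE
  )
  list(dots = dots, shifts = shifts, reg_scores = scores, labels = labels,
       cell_meta = cell_meta, layout = lay, truth = fv$truth,
       embryo = as.integer(embryo), fov = as.integer(fov_idx))
}

#' Run the full scMST pipeline on a phantom acquisition
#'
#' Executes the stages in fixed order for every FOV (pre-process, register,
#' detect), triages dots per gene pooled across each embryo's FOVs,
#' segments and counts per FOV, then normalizes, clusters, selects
#' co-expressing cells and renders back-maps and a display mosaic. All
#' artifacts plus a manifest are written under `out_dir`; re-running with
#' the same config reproduces the tabular artifacts byte-identically.
#'
#' @param config An [pipeline_config()].
#' @param out_dir Output directory (created; existing files overwritten).
#' @param keep_truth Attach the phantom ground truth to the return value
#'   (never written unless `write_truth`).
#' @return Invisibly, `list(counts, zscores, zcross, clusters, selection,
#'   recovery, shifts, dots, labels, truth, out_dir)`.
#' @export
run_pipeline <- function(config, out_dir, keep_truth = TRUE) {
  .assert(inherits(config, "scmst_pipeline_config"),
          "config must come from pipeline_config()")
  ph <- config$phantom
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  fovs <- list()
  for (e in seq_len(ph$n_embryos))
    for (f in seq_len(ph$n_fovs_per_embryo))
      fovs[[sprintf("e%d_f%d", e, f)]] <- .process_fov(config, e, f)

  # triage per gene, dots pooled across each embryo's FOVs
  all_dots <- do.call(rbind, lapply(fovs, `[[`, "dots"))
  all_dots$kept <- FALSE
  all_dots$cluster <- NA_integer_
  triage_log <- list()
  for (e in unique(all_dots$embryo)) {
    for (g in unique(all_dots$gene)) {
      sel <- which(all_dots$embryo == e & all_dots$gene == g)
      if (length(sel) < 2) next
      sub <- all_dots[sel, ]
      k <- if (config$triage_k_auto)
        select_k(sub, seed = .subseed(config$seed, 5, e))$k
      else config$triage_k
      tr <- suppressWarnings(
        kmeans_triage(sub, k, artifact_quantile = config$artifact_quantile,
                      seed = .subseed(config$seed, 6, e)))
      all_dots$kept[sel] <- tr$dots$kept
      all_dots$cluster[sel] <- tr$dots$cluster
      triage_log[[sprintf("e%d_%s", e, g)]] <-
        list(k = tr$result$k, retained = tr$result$retained,
             sizes = tr$result$sizes)
    }
  }

  # recovery QC (repeat round vs round 1), per embryo then pooled
  lay1 <- fovs[[1]]$layout
  recovery <- NULL
  if (!is.na(lay1$repeat_round)) {
    ini <- all_dots[all_dots$round == 1L, ]
    rep_ <- all_dots[all_dots$round == lay1$repeat_round, ]
    recovery <- recovery_rate(ini, rep_, config$recovery_threshold)
  }

  # counting per FOV (gene rounds only; repeat round is QC-only)
  counts_list <- list()
  for (nm in names(fovs)) {
    fv <- fovs[[nm]]
    dd <- all_dots[all_dots$embryo == fv$embryo & all_dots$fov == fv$fov &
                     all_dots$round <= lay1$n_gene_rounds, ]
    dd <- assign_dots(dd, fv$labels, fv$shifts)
    counts_list[[nm]] <- build_count_matrix(dd, ph$gene_panel, fv$cell_meta)
  }
  counts <- bind_counts(counts_list)

  # normalization, clustering, selection
  zw <- zscore_within_embryo(counts)
  zp <- zscore_pooled(zw, grouping = "stage")
  zx <- if (length(unique(counts$cell_meta$stage)) >= 2)
    zscore_cross_stage(counts) else zp
  cl <- hcluster(zp, k = config$k_clusters)
  sel <- select_coexpressing(zx, config$select_genes)

  # back-mapping per FOV + one mosaic per embryo (display only)
  if (config$write_images) {
    cmap <- group_colormap(seq_len(config$k_clusters))
    for (e in seq_len(ph$n_embryos)) {
      imgs <- list()
      for (f in seq_len(ph$n_fovs_per_embryo)) {
        nm <- sprintf("e%d_f%d", e, f)
        rows <- which(counts$cell_meta$embryo == e & counts$cell_meta$fov == f)
        groups <- setNames(as.list(cl$labels[rows]),
                           counts$cell_meta$cell[rows])
        img <- backmap(fovs[[nm]]$labels, groups, cmap)
        write_rgb_png(img, file.path(out_dir,
                                     sprintf("backmap_e%d_f%d.png", e, f)))
        imgs[[f]] <- img
      }
      w <- dim(imgs[[1]])[2]
      offs <- cbind(0L, (seq_along(imgs) - 1L) * (w + config$stitch_gap))
      mos <- stitch(imgs, offs)
      write_rgb_png(mos$canvas, file.path(out_dir,
                                          sprintf("mosaic_e%d.png", e)))
    }
  }

  # artifacts
  write_counts(counts, file.path(out_dir, "counts"))
  write_dots(all_dots, file.path(out_dir, "dots.csv"))
  write.csv(cbind(counts$cell_meta[, c("cell", "embryo", "fov", "stage")],
                  cluster = cl$labels),
            file.path(out_dir, "clusters.csv"), row.names = FALSE)
  write.csv(data.frame(cell_global = sel$cells),
            file.path(out_dir, "selection.csv"), row.names = FALSE)
  write.csv(sel$per_stage, file.path(out_dir, "selection_per_stage.csv"),
            row.names = FALSE)
  zdf <- as.data.frame(zp$values)
  write.csv(zdf, file.path(out_dir, "zscores_pooled.csv"), row.names = FALSE)
  if (!is.null(recovery))
    write.csv(recovery$per_gene, file.path(out_dir, "recovery.csv"),
              row.names = FALSE)
  as_newick(cl$tree, path = file.path(out_dir, "dendrogram_cells.nwk"))
  shifts_out <- lapply(fovs, function(fv)
    list(estimated = fv$shifts, scores = round(fv$reg_scores, 4)))
  jsonlite::write_json(shifts_out, file.path(out_dir, "shifts.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("scmst")),
    seed = config$seed,
    phantom_seed = ph$rng_seed,
    n_embryos = ph$n_embryos,
    n_fovs_per_embryo = ph$n_fovs_per_embryo,
    volume_shape = ph$volume_shape,
    gene_panel = ph$gene_panel,
    stages = ph$stages,
    k_clusters = config$k_clusters,
    triage_k = config$triage_k,
    select_genes = config$select_genes,
    recovery_overall = if (is.null(recovery)) NULL else recovery$overall,
    recovery_pass = if (is.null(recovery)) NULL else recovery$pass,
    n_cells = nrow(counts$values),
    n_dots = nrow(all_dots),
    n_dots_kept = sum(all_dots$kept),
    elapsed_s = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 1)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res <- list(counts = counts, zscores = zp, zcross = zx, clusters = cl,
              selection = sel, recovery = recovery,
              shifts = lapply(fovs, `[[`, "shifts"),
              reg_scores = lapply(fovs, `[[`, "reg_scores"),
              dots = all_dots,
              labels = lapply(fovs, `[[`, "labels"),
              triage_log = triage_log,
              truth = if (keep_truth) lapply(fovs, `[[`, "truth") else NULL,
              out_dir = out_dir)
  invisible(res)
}

#' Write a QC report for a completed run directory
#'
#' Summarizes signal recovery, dot triage yield, per-stage cell counts and
#' the clustering, as Markdown. Missing artifacts are noted, not fatal;
#' regeneration is idempotent.
#'
#' @param run_dir Directory produced by [run_pipeline()].
#' @param path Output file (default `qc_report.md` inside `run_dir`).
#' @return `path`, invisibly.
#' @export
qc_report <- function(run_dir, path = file.path(run_dir, "qc_report.md")) {
  lines <- c("# scMST run QC report", "")
  man_f <- file.path(run_dir, "manifest.json")
  if (file.exists(man_f)) {
    man <- jsonlite::read_json(man_f)
    lines <- c(lines, sprintf("- cells: %s", man$n_cells),
               sprintf("- dots detected: %s, kept after triage: %s",
                       man$n_dots, man$n_dots_kept),
               sprintf("- seed: %s (phantom seed %s)", man$seed,
                       man$phantom_seed), "")
  } else {
    lines <- c(lines, "- manifest.json missing", "")
  }
  rec_f <- file.path(run_dir, "recovery.csv")
  lines <- c(lines, "## Signal recovery (repeat of round 1)", "")
  if (file.exists(rec_f)) {
    rec <- read.csv(rec_f)
    overall <- sum(rec$repeat_) / sum(rec$initial)
    lines <- c(lines,
               sprintf("Overall recovery: **%.1f%%** (threshold 70%%): %s",
                       100 * overall,
                       ifelse(overall >= 0.7, "PASS", "FAIL")), "",
               "| gene | initial | repeat | recovery |",
               "|---|---|---|---|",
               sprintf("| %s | %d | %d | %s |", rec$gene, rec$initial,
                       rec$repeat_,
                       ifelse(is.na(rec$recovery), "n/a",
                              sprintf("%.0f%%", 100 * rec$recovery))))
  } else {
    lines <- c(lines, "Not performed (no repeat round).")
  }
  cl_f <- file.path(run_dir, "clusters.csv")
  lines <- c(lines, "", "## Cells per stage and cluster", "")
  if (file.exists(cl_f)) {
    cl <- read.csv(cl_f)
    tab <- table(cl$stage, cl$cluster)
    lines <- c(lines,
               paste("|stage|", paste(colnames(tab), collapse = "|"), "|"),
               paste(rep("|---", ncol(tab) + 1), collapse = ""),
               vapply(rownames(tab), function(s)
                 paste0("|", s, "|", paste(tab[s, ], collapse = "|"), "|"),
                 ""))
  } else {
    lines <- c(lines, "clusters.csv missing")
  }
  sel_f <- file.path(run_dir, "selection_per_stage.csv")
  lines <- c(lines, "", "## Co-expression selection", "")
  if (file.exists(sel_f)) {
    ps <- read.csv(sel_f)
    lines <- c(lines, "| stage | selected | stage total | % of stage |",
               "|---|---|---|---|",
               sprintf("| %s | %d | %d | %.1f |", ps$stage, ps$n_selected,
                       ps$n_stage, ps$pct_of_stage))
  } else {
    lines <- c(lines, "selection_per_stage.csv missing")
  }
  writeLines(lines, path)
  invisible(path)
}
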