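#' Default 30-gene ectoderm panel
#'
#' Gene names follow the chick ectoderm literature: pluripotency factors,
#' neural plate border (NPB), neural crest (NC), central nervous system
#' (CNS), non-neural ectoderm (NNE) and neural progenitor markers, five per
#' block. The panel is only a naming convention for the phantom; any
#' character vector of unique names works.
#'
#' @return Character vector of 30 gene names.
#' @export
default_gene_panel <- function() {
  c(
    "Nanog", "PouV", "Klf4", "Lin28A", "cMyc",          # pluripotency
    "Pax7", "Msx1", "Tfap2A", "Zic1", "Axud1",          # NPB
    "FoxD3", "Snai2", "Sox10", "Sox9", "Ets1",          # NC
    "Sox2", "Sox21", "Otx2", "Six3", "Sox3",            # CNS
    "Dlx5", "Gata2", "Gata3", "Krt19", "Epcam",         # NNE
    "Nestin", "MycN", "Msi1", "Six1", "Eya2"            # neural progenitor
  )
}

#' Default subpopulation expression profiles
#'
#' Four subpopulations mirror the biology the phantom emulates: two committed
#' populations expressing one ectodermal domain programme, a transitioning
#' stem-cell population co-expressing pluripotency genes with domain markers,
#' and an undecided population dominated by the pluripotency programme.
#' Means are expected transcript counts per cell.
#'
#' @param gene_panel Character vector of gene names (blocks of five as in
#'   [default_gene_panel()]).
#' @return A list of subpopulation specs, each `list(name, fraction, means)`
#'   where `means` is a named numeric vector over the panel.
#' @export
default_subpop_spec <- function(gene_panel = default_gene_panel()) {
  g <- gene_panel
  n <- length(g)
  block <- function(i) g[seq((i - 1) * 5 + 1, min(i * 5, n))]
  base <- function(level = 1) setNames(rep(level, n), g)
  pluri <- block(1); npb <- block(2); nc <- block(3)
  cns <- block(4); nne <- block(5); prog <- block(6)
  mk <- function(name, fraction, ...) {
    m <- base()
    for (b in list(...)) m[b$genes] <- b$mean
    list(name = name, fraction = fraction, means = m)
  }
  list(
    mk("committed_NC", 0.30,
       list(genes = nc, mean = 4), list(genes = npb, mean = 1.5),
       list(genes = pluri, mean = 0.25)),
    mk("committed_CNS", 0.30,
       list(genes = cns, mean = 4), list(genes = prog, mean = 2),
       list(genes = pluri, mean = 0.25)),
    mk("transitioning", 0.25,
       list(genes = pluri, mean = 3), list(genes = npb, mean = 3),
       list(genes = nc, mean = 1.2), list(genes = cns, mean = 1.2),
       list(genes = nne, mean = 1.2)),
    mk("undecided", 0.15,
       list(genes = pluri, mean = 4), list(genes = prog, mean = 1.2))
  )
}

#' Phantom acquisition configuration
#'
#' Defines a synthetic multi-round scMST acquisition: 5 genes per round over
#' 6 channels (the last channel carries nuclei in every round for
#' registration), 3 fields of view (FOVs) per embryo section, z planes every
#' 0.5 um, a membrane round after the gene rounds for segmentation, and an
#' optional repeat of the first probe set for RNA-integrity QC.
#'
#' @param n_embryos Number of embryos (default 2; embryos are assigned to
#'   `stages` round-robin).
#' @param n_fovs_per_embryo FOVs per section (default 3).
#' @param volume_shape Integer `(z, y, x)` voxel counts per FOV.
#' @param voxel_size Numeric `(z, y, x)` voxel size in micrometres.
#' @param n_cells_per_fov Target cell count per FOV.
#' @param gene_panel Character vector of gene names.
#' @param genes_per_round Genes imaged per hybridization round (default 5).
#' @param channels_per_round Camera channels per round (default 6; the last
#'   is the nuclei reference channel).
#' @param subpop_spec Subpopulation list as from [default_subpop_spec()].
#' @param dot_intensity_model Per-class dot amplitude model and noise-dot
#'   rates; see Details.
#' @param psf_sigma PSF standard deviation `(z, y, x)` in voxels.
#' @param illumination_model `list(amplitude, sigma_frac)` of the smooth
#'   multiplicative shading field per channel.
#' @param shift_model Integer `(z, y, x)` maximum absolute per-round stage
#'   shift; round 1 is the reference and has zero shift.
#' @param background Camera background level (intensity units).
#' @param noise_sd Additive Gaussian read-noise standard deviation.
#' @param count_model `"poisson"` (default) or `"nb"`; `nb_size` is the
#'   negative-binomial size parameter when `"nb"`.
#' @param nb_size Negative binomial size (dispersion) parameter.
#' @param stages Stage labels cycled over embryos.
#' @param repeat_round Append a repeat of round 1's probe set (QC round)?
#' @param repeat_retention Fraction of true transcripts recovered in the
#'   repeat round (models RNA degradation over the multiplex routine).
#' @param rng_seed Integer master seed; all phantom randomness derives from
#'   it.
#'
#' @details `dot_intensity_model` is a list with elements `true`,
#' `nonspecific`, `artifact` (each `list(mean, sd)` dot amplitudes) and
#' rates `nonspecific_rate`, `artifact_rate` (expected noise dots per
#' gene-channel volume). Defaults separate the classes by far more than 4
#' amplitude standard deviations so that intensity triage is meaningful.
#'
#' @return An object of class `phantom_config` (a validated list).
#' @export
phantom_config <- function(n_embryos = 2,
                           n_fovs_per_embryo = 3,
                           volume_shape = c(12L, 192L, 192L),
                           voxel_size = c(0.5, 0.206, 0.206),
                           n_cells_per_fov = 50,
                           gene_panel = default_gene_panel(),
                           genes_per_round = 5,
                           channels_per_round = 6,
                           subpop_spec = default_subpop_spec(gene_panel),
                           dot_intensity_model = list(
                             true = list(mean = 250, sd = 20),
                             nonspecific = list(mean = 60, sd = 12),
                             artifact = list(mean = 1000, sd = 100),
                             nonspecific_rate = 40,
                             artifact_rate = 8
                           ),
                           psf_sigma = c(0.7, 1.0, 1.0),
                           illumination_model = list(amplitude = 0.25,
                                                     sigma_frac = 0.45),
                           shift_model = c(1L, 8L, 8L),
                           background = 100,
                           noise_sd = 3,
                           count_model = c("poisson", "nb"),
                           nb_size = 10,
                           stages = c("HH5", "7ss"),
                           repeat_round = TRUE,
                           repeat_retention = 0.8,
                           rng_seed = 1L) {
  count_model <- match.arg(count_model)
  .assert(length(gene_panel) >= 1, "gene panel must be non-empty")
  .assert(!anyDuplicated(gene_panel), "gene panel has duplicate names")
  .assert(genes_per_round >= 1 && genes_per_round <= channels_per_round - 1,
          "genes_per_round must leave a free reference channel")
  .assert(all(volume_shape >= 1), "volume_shape must be positive")
  .assert(n_cells_per_fov >= 1, "need at least one cell per FOV")
  fr <- vapply(subpop_spec, function(s) s$fraction, numeric(1))
  .assert(abs(sum(fr) - 1) < 1e-8, "subpop mixing fractions must sum to 1")
  for (s in subpop_spec) {
    .assert(all(s$means >= 0), "subpop means must be non-negative")
    .assert(all(gene_panel %in% names(s$means)),
            "subpop means must cover the gene panel")
  }
  dm <- dot_intensity_model
  .assert(all(c(dm$true$sd, dm$nonspecific$sd, dm$artifact$sd) >= 0) &&
            dm$nonspecific_rate >= 0 && dm$artifact_rate >= 0,
          "intensity sds and rates must be non-negative")
  .assert(all(psf_sigma > 0), "psf_sigma must be positive")
  cfg <- list(
    n_embryos = as.integer(n_embryos),
    n_fovs_per_embryo = as.integer(n_fovs_per_embryo),
    volume_shape = as.integer(volume_shape),
    voxel_size = as.numeric(voxel_size),
    n_cells_per_fov = as.integer(n_cells_per_fov),
    gene_panel = gene_panel,
    genes_per_round = as.integer(genes_per_round),
    channels_per_round = as.integer(channels_per_round),
    subpop_spec = subpop_spec,
    dot_intensity_model = dm,
    psf_sigma = as.numeric(psf_sigma),
    illumination_model = illumination_model,
    shift_model = as.integer(shift_model),
    background = background,
    noise_sd = noise_sd,
    count_model = count_model,
    nb_size = nb_size,
    stages = stages,
    repeat_round = isTRUE(repeat_round),
    repeat_retention = repeat_retention,
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "phantom_config"
  cfg
}

#' Map a gene panel onto hybridization rounds and channels
#'
#' Genes are taken in panel order, `genes_per_round` at a time; within a
#' round they occupy channels `1..genes_per_round`, leaving the remaining
#' channel(s) for the reference stain. The number of rounds is
#' `ceiling(length(gene_panel) / genes_per_round)`.
#'
#' @param gene_panel Character vector of unique gene names.
#' @param genes_per_round Genes per round.
#' @param channels Available channels per round (must be >= genes_per_round).
#' @return A `data.frame` with columns `gene`, `round`, `channel`.
#' @export
make_round_plan <- function(gene_panel, genes_per_round = 5, channels = 6) {
  .assert(length(gene_panel) >= 1, "gene panel must be non-empty")
  .assert(!anyDuplicated(gene_panel), "gene panel has duplicate names")
  .assert(genes_per_round >= 1, "genes_per_round must be >= 1")
  .assert(channels >= genes_per_round,
          "need at least as many channels as genes per round")
  idx <- seq_along(gene_panel) - 1L
  data.frame(
    gene = gene_panel,
    round = idx %/% genes_per_round + 1L,
    channel = idx %% genes_per_round + 1L,
    stringsAsFactors = FALSE
  )
}

#' Stage label for an embryo index
#' @noRd
.embryo_stage <- function(config, embryo) {
  config$stages[(embryo - 1L) %% length(config$stages) + 1L]
}

#' Simulate a tissue section for one FOV
#'
#' Cells are a nearest-seed tessellation (in anisotropy-scaled coordinates)
#' restricted to a smooth tissue band emulating an ectoderm cross-section;
#' stray fragments disconnected from their seed are cleared so each label is
#' one connected region. Each cell is assigned a subpopulation by sampling
#' the configured mixing fractions.
#'
#' @param config A [phantom_config()].
#' @param seed Integer seed for this FOV.
#' @param embryo,fov Metadata recorded in the cell table.
#' @return `list(labels, cell_table)` where `labels` is a `(z, y, x)` integer
#'   array with background 0 and contiguous labels `1..N`, and `cell_table`
#'   has one row per cell (`cell`, `embryo`, `fov`, `stage`, `subpop`,
#'   `centroid_z/y/x`, `volume_vox`).
#' @export
simulate_tissue <- function(config, seed, embryo = 1L, fov = 1L) {
  d <- config$volume_shape
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  n_cells <- config$n_cells_per_fov
  .with_seed(seed, {
    # tissue band: smooth sinusoidal mid-line with ~60% fill
    phase <- runif(1, 0, 2 * pi)
    xs <- seq_len(nx)
    center <- ny / 2 + 0.12 * ny * sin(2 * pi * xs / nx + phase)
    halfw <- ny * (0.30 + 0.03 * cos(4 * pi * xs / nx + phase))
    band <- outer(seq_len(ny), xs, function(y, x) abs(y - center[x]) <= halfw[x])
    mask <- array(rep(band, each = nz), c(nz, ny, nx))
    vox_in <- which(mask)
    .assert(length(vox_in) >= n_cells * 20,
            "cell count infeasible for this volume")
    # anisotropy-scaled coordinates (units of lateral pixels)
    zf <- config$voxel_size[1] / config$voxel_size[3]
    idx2zyx <- function(i) {
      i0 <- i - 1L
      cbind(z = i0 %% nz + 1L,
            y = (i0 %/% nz) %% ny + 1L,
            x = i0 %/% (nz * ny) + 1L)
    }
    target_vol <- length(vox_in) / n_cells * zf  # scaled voxel volume
    dmin <- 0.9 * (3 * target_vol / (4 * pi))^(1 / 3)
    seeds <- NULL
    repeat {
      cand <- sample(vox_in, min(length(vox_in), n_cells * 40))
      pc <- idx2zyx(cand)
      pc_s <- cbind(pc[, 1] * zf, pc[, 2], pc[, 3])
      keep <- integer(0)
      for (i in seq_len(nrow(pc_s))) {
        if (length(keep) == 0) { keep <- i; next }
        dd <- sqrt(colSums((t(pc_s[keep, , drop = FALSE]) - pc_s[i, ])^2))
        if (all(dd >= dmin)) keep <- c(keep, i)
        if (length(keep) == n_cells) break
      }
      if (length(keep) == n_cells) { seeds <- pc[keep, , drop = FALSE]; break }
      dmin <- dmin * 0.8
      .assert(dmin > 0.5, "cell count infeasible for this volume")
    }
    # nearest-seed tessellation over the mask (running argmin over seeds)
    pm <- idx2zyx(vox_in)
    best <- rep(Inf, length(vox_in)); lab_of <- integer(length(vox_in))
    for (i in seq_len(n_cells)) {
      dd <- (zf * (pm[, 1] - seeds[i, 1]))^2 + (pm[, 2] - seeds[i, 2])^2 +
        (pm[, 3] - seeds[i, 3])^2
      upd <- dd < best
      best[upd] <- dd[upd]; lab_of[upd] <- i
    }
    labels <- array(0L, d)
    labels[vox_in] <- lab_of
    # connectivity cleanup: keep only each seed's own component
    # (bounding-box cropped per cell to keep the labelling cheap)
    occ0 <- which(labels > 0L)
    pz <- idx2zyx(occ0)
    lab0 <- labels[occ0]
    for (i in seq_len(n_cells)) {
      sel <- lab0 == i
      rz <- range(pz[sel, 1]); ry <- range(pz[sel, 2]); rx <- range(pz[sel, 3])
      sub <- labels[rz[1]:rz[2], ry[1]:ry[2], rx[1]:rx[2], drop = FALSE]
      comp <- .label3d(sub == i)
      sc <- comp[seeds[i, 1] - rz[1] + 1L, seeds[i, 2] - ry[1] + 1L,
                 seeds[i, 3] - rx[1] + 1L]
      sub[comp != 0L & comp != sc] <- 0L
      labels[rz[1]:rz[2], ry[1]:ry[2], rx[1]:rx[2]] <- sub
    }
    subpops <- vapply(config$subpop_spec, `[[`, "", "name")
    fracs <- vapply(config$subpop_spec, `[[`, 0, "fraction")
    assign <- sample(subpops, n_cells, replace = TRUE, prob = fracs)
    # centroids/volumes from the cleaned label volume
    occ <- which(labels > 0L)
    po <- idx2zyx(occ); lo <- labels[occ]
    cell_table <- data.frame(
      cell = seq_len(n_cells),
      embryo = as.integer(embryo),
      fov = as.integer(fov),
      stage = .embryo_stage(config, embryo),
      subpop = assign,
      centroid_z = as.numeric(tapply(po[, 1], lo, mean)),
      centroid_y = as.numeric(tapply(po[, 2], lo, mean)),
      centroid_x = as.numeric(tapply(po[, 3], lo, mean)),
      volume_vox = as.integer(tabulate(lo, n_cells)),
      stringsAsFactors = FALSE
    )
    list(labels = labels, cell_table = cell_table)
  })
}

#' Draw true per-cell transcript counts
#'
#' Counts are independent Poisson draws per cell and gene with the cell's
#' subpopulation mean (negative binomial when `model = "nb"`).
#'
#' @param cell_table Cell table from [simulate_tissue()] (needs `subpop`).
#' @param subpop_spec Subpopulation list as in [phantom_config()].
#' @param seed Integer seed.
#' @param model `"poisson"` or `"nb"`.
#' @param nb_size Negative binomial size parameter.
#' @return Integer matrix cells x genes (dimnames: cell id, gene).
#' @export
simulate_counts <- function(cell_table, subpop_spec, seed,
                            model = c("poisson", "nb"), nb_size = 10) {
  model <- match.arg(model)
  spec_by <- setNames(subpop_spec, vapply(subpop_spec, `[[`, "", "name"))
  .assert(all(cell_table$subpop %in% names(spec_by)),
          "every cell needs a subpop present in subpop_spec")
  genes <- names(spec_by[[1]]$means)
  mu <- t(vapply(cell_table$subpop,
                 function(s) spec_by[[s]]$means[genes],
                 numeric(length(genes))))
  .assert(all(mu >= 0), "negative subpop mean")
  .with_seed(seed, {
    counts <- if (model == "poisson") {
      rpois(length(mu), as.vector(mu))
    } else {
      rnbinom(length(mu), mu = as.vector(mu), size = nb_size)
    }
    m <- matrix(as.integer(counts), nrow(cell_table), length(genes),
                dimnames = list(cell_table$cell, genes))
    m
  })
}

# Gaussian PSF kernel with unit peak, truncated at 3 sigma.
.psf_kernel <- function(sigma) {
  r <- pmax(1L, ceiling(3 * sigma))
  ax <- lapply(1:3, function(i) seq(-r[i], r[i]))
  k <- outer(
    outer(exp(-ax[[1]]^2 / (2 * sigma[1]^2)),
          exp(-ax[[2]]^2 / (2 * sigma[2]^2))),
    exp(-ax[[3]]^2 / (2 * sigma[3]^2))
  )
  array(k, dim = c(length(ax[[1]]), length(ax[[2]]), length(ax[[3]])))
}

# Smooth multiplicative shading field (ny x nx), mean 1, strictly positive.
.illum_field <- function(ny, nx, amplitude, sigma_frac, seed) {
  .with_seed(seed, {
    cy <- runif(1, 0.25, 0.75) * ny
    cx <- runif(1, 0.25, 0.75) * nx
    sy <- sigma_frac * ny; sx <- sigma_frac * nx
    g <- outer(seq_len(ny), seq_len(nx), function(y, x)
      exp(-((y - cy)^2 / (2 * sy^2) + (x - cx)^2 / (2 * sx^2))))
    f <- 1 + amplitude * (g - mean(g))
    f <- pmax(f, 0.05)
    f / mean(f)
  })
}

#' Round layout of a phantom acquisition
#'
#' Gene rounds first (channels `1..genes_per_round` genes, last channel
#' nuclei), then one membrane round (channels 1-2 membrane antibodies, last
#' channel nuclei), then optionally a repeat of round 1's probe set.
#'
#' @param config A [phantom_config()].
#' @return `list(round_plan, n_gene_rounds, membrane_round, repeat_round,
#'   nuclei_channel, membrane_channels, rounds)` where `rounds` is the total
#'   number of acquisition rounds.
#' @export
phantom_layout <- function(config) {
  plan <- make_round_plan(config$gene_panel, config$genes_per_round,
                          config$channels_per_round - 1L)
  ngr <- max(plan$round)
  list(
    round_plan = plan,
    n_gene_rounds = ngr,
    membrane_round = ngr + 1L,
    repeat_round = if (config$repeat_round) ngr + 2L else NA_integer_,
    nuclei_channel = config$channels_per_round,
    membrane_channels = c(1L, 2L),
    rounds = ngr + 1L + as.integer(config$repeat_round)
  )
}

#' Render multi-round image stacks for one FOV
#'
#' Every true transcript becomes one PSF blob at a uniformly drawn voxel of
#' its cell; non-specific and artifact dots are scattered uniformly over the
#' volume at the configured per-channel rates with their own amplitude
#' models. Each round is multiplied by the per-channel illumination field,
#' translated by its integer stage shift and degraded with Gaussian read
#' noise. The nuclei channel is rendered in every round; the membrane round
#' carries the cell-boundary stain in two channels; the optional repeat
#' round re-renders round 1's genes keeping each original transcript with
#' probability `repeat_retention` (same positions: the same molecules are
#' re-probed).
#'
#' @param truth `list(labels, cell_table, true_counts)` as produced by
#'   [simulate_tissue()] and [simulate_counts()].
#' @param config A [phantom_config()].
#' @param seed Integer seed for rendering randomness.
#' @param fov,embryo Metadata recorded in `dot_truth`.
#' @return `list(rounds, dot_truth, shifts, illum)`: `rounds` is a list (one
#'   per acquisition round) of named lists of `(z, y, x)` channel volumes;
#'   `dot_truth` one row per rendered dot (`round`, `channel`, `gene`,
#'   `class`, `cell`, `z`, `y`, `x`, `amplitude`); `shifts` a rounds x 3
#'   integer matrix of true `(z, y, x)` offsets; `illum` the per-channel
#'   shading fields.
#' @export
render_stacks <- function(truth, config, seed, embryo = 1L, fov = 1L) {
  .assert(all(config$psf_sigma > 0), "PSF sigma must be positive")
  lay <- phantom_layout(config)
  d <- config$volume_shape
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  dm <- config$dot_intensity_model
  kernel <- .psf_kernel(config$psf_sigma)
  labels <- truth$labels
  counts <- truth$true_counts
  # per-channel illumination fields are a property of the optics: derived
  # from the master seed so they are shared across FOVs and rounds
  illum <- lapply(seq_len(config$channels_per_round), function(ch)
    .illum_field(ny, nx, config$illumination_model$amplitude,
                 config$illumination_model$sigma_frac,
                 .subseed(config$rng_seed, 7001, ch)))
  cell_vox <- split(which(labels > 0L), labels[labels > 0L])
  illum_rep <- lapply(illum, function(f) {
    a <- array(rep(f, each = nz), d)
    a
  })
  idx2zyx <- function(i) {
    i0 <- i - 1L
    cbind((i0 %% nz) + 1L, ((i0 %/% nz) %% ny) + 1L, (i0 %/% (nz * ny)) + 1L)
  }
  # nuclei template (no noise); re-used every round
  cen <- round(as.matrix(truth$cell_table[, c("centroid_z", "centroid_y",
                                              "centroid_x")]))
  cen <- pmin(pmax(cen, 1L), matrix(d, nrow(cen), 3, byrow = TRUE))
  nuc <- .add_blobs_cpp(array(0, d), matrix(as.integer(cen), ncol = 3),
                        rep(400, nrow(cen)), .psf_kernel(c(1.5, 4, 4)))
  # membrane template: inter-label boundary voxels, lightly blurred
  shift_ne <- function(a, dz, dy, dx) {
    out <- array(a[1], dim(a)) # edge-replicated shift for boundary test
    zi <- pmin(pmax(seq_len(nz) + dz, 1L), nz)
    yi <- pmin(pmax(seq_len(ny) + dy, 1L), ny)
    xi <- pmin(pmax(seq_len(nx) + dx, 1L), nx)
    a[zi, yi, xi]
  }
  boundary <- array(FALSE, d)
  for (s in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
    nb <- shift_ne(labels, s[1], s[2], s[3])
    boundary <- boundary | (labels != nb & (labels > 0L | nb > 0L))
  }
  mem <- gauss3d(array(250 * boundary, d), c(0.6, 1.0, 1.0))

  .with_seed(seed, {
    shifts <- matrix(0L, lay$rounds, 3,
                     dimnames = list(NULL, c("z", "y", "x")))
    for (r in 2:lay$rounds) {
      shifts[r, ] <- vapply(1:3, function(a)
        sample(seq(-config$shift_model[a], config$shift_model[a]), 1L),
        integer(1))
    }
    dots <- list()
    round1_dots <- NULL # cached for the repeat round
    draw_gene_dots <- function(g, cls_rates = TRUE) {
      # true dots for gene g, one per transcript, uniform within the cell
      cc <- counts[, g]
      own <- rep(seq_along(cc), cc)
      if (length(own)) {
        vox <- unlist(lapply(which(cc > 0), function(ci) {
          v <- cell_vox[[as.character(ci)]]
          v[sample.int(length(v), cc[ci], replace = TRUE)]
        }), use.names = FALSE)
        pos <- idx2zyx(vox)
        amp <- pmax(rnorm(length(own), dm$true$mean, dm$true$sd), 1)
        data.frame(class = "true", cell = as.integer(own),
                   z = pos[, 1], y = pos[, 2], x = pos[, 3], amplitude = amp,
                   stringsAsFactors = FALSE)
      } else {
        data.frame(class = character(0), cell = integer(0), z = integer(0),
                   y = integer(0), x = integer(0), amplitude = numeric(0))
      }
    }
    draw_noise_dots <- function(class, rate, model) {
      n <- rpois(1, rate)
      if (n == 0)
        return(data.frame(class = character(0), cell = integer(0),
                          z = integer(0), y = integer(0), x = integer(0),
                          amplitude = numeric(0)))
      data.frame(class = class, cell = NA_integer_,
                 z = sample.int(nz, n, TRUE), y = sample.int(ny, n, TRUE),
                 x = sample.int(nx, n, TRUE),
                 amplitude = pmax(rnorm(n, model$mean, model$sd), 1),
                 stringsAsFactors = FALSE)
    }
    render_round <- function(r, genes_here, reuse = NULL) {
      chans <- list()
      plan_r <- lay$round_plan[lay$round_plan$gene %in% genes_here, ]
      for (i in seq_len(nrow(plan_r))) {
        g <- plan_r$gene[i]; ch <- plan_r$channel[i]
        dd <- if (is.null(reuse)) {
          rbind(
            draw_gene_dots(g),
            draw_noise_dots("nonspecific", dm$nonspecific_rate, dm$nonspecific),
            draw_noise_dots("artifact", dm$artifact_rate, dm$artifact)
          )
        } else {
          prev <- reuse[reuse$gene == g & reuse$class == "true", ]
          kept <- prev[runif(nrow(prev)) < config$repeat_retention, ]
          kept$amplitude <- pmax(rnorm(nrow(kept), dm$true$mean, dm$true$sd), 1)
          rbind(
            kept[, c("class", "cell", "z", "y", "x", "amplitude")],
            draw_noise_dots("nonspecific", dm$nonspecific_rate, dm$nonspecific),
            draw_noise_dots("artifact", dm$artifact_rate, dm$artifact)
          )
        }
        vol <- .add_blobs_cpp(
          array(0, d),
          matrix(as.integer(c(dd$z, dd$y, dd$x)), ncol = 3),
          dd$amplitude, kernel)
        chans[[as.character(ch)]] <- vol
        if (nrow(dd)) {
          dd$gene <- g; dd$round <- r; dd$channel <- ch
          dd$embryo <- as.integer(embryo); dd$fov <- as.integer(fov)
          # native (as-acquired) coordinates include the round's stage shift
          dd$z_native <- dd$z + shifts[r, 1]
          dd$y_native <- dd$y + shifts[r, 2]
          dd$x_native <- dd$x + shifts[r, 3]
          dd$in_volume <- dd$z_native >= 1 & dd$z_native <= nz &
            dd$y_native >= 1 & dd$y_native <= ny &
            dd$x_native >= 1 & dd$x_native <= nx
          dots[[length(dots) + 1L]] <<- dd
        }
      }
      chans[[as.character(lay$nuclei_channel)]] <- nuc
      if (r == lay$membrane_round) {
        chans[[as.character(lay$membrane_channels[1])]] <- 0.8 * mem
        chans[[as.character(lay$membrane_channels[2])]] <- 0.6 * mem
      }
      # optics: the stage shift moves the tissue signal; background level,
      # shading field and read noise are properties of the camera/optics
      # and cover the full frame in every round
      out <- list()
      for (ch in names(chans)) {
        v <- apply_shift(chans[[ch]], shifts[r, ]) + config$background
        v <- v * illum_rep[[as.integer(ch)]]
        v <- v + rnorm(length(v), 0, config$noise_sd)
        out[[ch]] <- v
      }
      out
    }
    rounds <- vector("list", lay$rounds)
    for (r in seq_len(lay$n_gene_rounds)) {
      genes_here <- lay$round_plan$gene[lay$round_plan$round == r]
      rounds[[r]] <- render_round(r, genes_here)
      if (r == 1L)
        round1_dots <- do.call(rbind, dots)
    }
    rounds[[lay$membrane_round]] <- render_round(lay$membrane_round,
                                                 character(0))
    if (config$repeat_round)
      rounds[[lay$repeat_round]] <- render_round(
        lay$repeat_round, lay$round_plan$gene[lay$round_plan$round == 1L],
        reuse = round1_dots)
    dot_truth <- if (length(dots)) do.call(rbind, dots) else NULL
    cols <- c("embryo", "fov", "round", "channel", "gene", "class", "cell",
              "z", "y", "x", "z_native", "y_native", "x_native",
              "in_volume", "amplitude")
    if (!is.null(dot_truth)) dot_truth <- dot_truth[, cols]
    list(rounds = rounds, dot_truth = dot_truth, shifts = shifts,
         illum = illum)
  })
}

#' Simulate one complete phantom FOV
#'
#' Convenience wrapper chaining [simulate_tissue()], [simulate_counts()] and
#' [render_stacks()] with sub-seeds derived deterministically from the
#' config's master seed, so any FOV can be regenerated independently and
#' byte-identically.
#'
#' @param config A [phantom_config()].
#' @param embryo,fov Indices of the FOV to generate.
#' @return An object of class `scmst_fov`: `list(stack, truth, layout,
#'   config, embryo, fov)` where `truth` bundles `labels`, `cell_table`,
#'   `true_counts`, `dot_truth` and `shifts`.
#' @export
simulate_fov <- function(config, embryo = 1L, fov = 1L) {
  tis <- simulate_tissue(config, .subseed(config$rng_seed, 1, embryo, fov),
                         embryo = embryo, fov = fov)
  counts <- simulate_counts(tis$cell_table, config$subpop_spec,
                            .subseed(config$rng_seed, 2, embryo, fov),
                            model = config$count_model,
                            nb_size = config$nb_size)
  rend <- render_stacks(list(labels = tis$labels, cell_table = tis$cell_table,
                             true_counts = counts),
                        config, .subseed(config$rng_seed, 3, embryo, fov),
                        embryo = embryo, fov = fov)
  structure(list(
    stack = rend$rounds,
    truth = list(labels = tis$labels, cell_table = tis$cell_table,
                 true_counts = counts, dot_truth = rend$dot_truth,
                 shifts = rend$shifts),
    illum = rend$illum,
    layout = phantom_layout(config),
    config = config, embryo = as.integer(embryo), fov = as.integer(fov)
  ), class = "scmst_fov")
}

#' Simulate a full phantom acquisition (all embryos and FOVs)
#'
#' Materializes every FOV in memory; at the default desk scale this is
#' roughly 1 GB, so pipelines that only need one FOV at a time should call
#' [simulate_fov()] inside their own loop instead.
#'
#' @param config A [phantom_config()].
#' @return List of `scmst_fov` objects, ordered by embryo then FOV.
#' @export
simulate_phantom <- function(config) {
  out <- list()
  for (e in seq_len(config$n_embryos))
    for (f in seq_len(config$n_fovs_per_embryo))
      out[[length(out) + 1L]] <- simulate_fov(config, e, f)
  out
}

#' @export
print.scmst_fov <- function(x, ...) {
  cat(sprintf(
    "<scmst_fov> embryo %d FOV %d: %d rounds, %d cells, %d true dots\n",
    x$embryo, x$fov, length(x$stack), nrow(x$truth$cell_table),
    sum(x$truth$dot_truth$class == "true")))
  invisible(x)
}
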