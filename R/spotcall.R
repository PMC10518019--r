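# Dot detection and K-means intensity triage.
#
# Detection is deliberately high-recall: dim non-specific dots are detected
# on purpose and removed downstream by the intensity triage, mirroring QC
# practice where the scatter of (mean intensity, intensity variability) per
# dot is clustered and only the true-signal clusters are retained.

# integer offsets of the 1-sigma support ellipsoid around a dot centroid
.support_offsets <- function(psf_sigma) {
  r <- pmax(1L, ceiling(psf_sigma))
  g <- expand.grid(dz = -r[1]:r[1], dy = -r[2]:r[2], dx = -r[3]:r[3])
  keep <- (g$dz / max(psf_sigma[1], 1))^2 + (g$dy / max(psf_sigma[2], 1))^2 +
    (g$dx / max(psf_sigma[3], 1))^2 <= 1 + 1e-9
  as.matrix(g[keep, ])
}

#' Detect candidate dots in a single-channel volume
#'
#' Difference-of-Gaussians band-pass response, local maxima separated by at
#' least `min_distance` (in anisotropy-scaled voxels, approximated by an
#' axis-wise box), above a permissive response floor. The floor is the
#' larger of the `floor_quantile` response quantile and a robust noise
#' ceiling (`median + noise_k * mad` of the response, which is dominated by
#' background voxels): permissive enough to keep dim non-specific dots for
#' the downstream triage, but above camera noise so pure-noise maxima are
#' not called.
#'
#' @param vol Pre-processed `(z, y, x)` volume.
#' @param psf_sigma PSF sigma `(z, y, x)` in voxels (sets the band-pass
#'   scales and the support ellipsoid).
#' @param min_distance Minimum separation between detections in lateral
#'   voxels (scaled by voxel anisotropy along z via `anisotropy`).
#' @param floor_quantile Response quantile below which maxima are ignored.
#' @param anisotropy z-to-lateral voxel size ratio used to scale distances.
#' @param noise_k Multiplier of the response MAD for the noise ceiling.
#' @return `data.frame` of dots: `z`, `y`, `x` (1-based voxel coordinates),
#'   `response`.
#' @export
detect_dots <- function(vol, psf_sigma, min_distance = 1,
                        floor_quantile = 0.95, anisotropy = 2.4,
                        noise_k = 6) {
  .assert(.is_volume(vol), "vol must be a 3D array")
  .assert(all(psf_sigma > 0), "psf_sigma must be positive")
  band <- gauss3d(vol, psf_sigma) - gauss3d(vol, 2 * psf_sigma)
  rz <- max(1L, as.integer(round(min_distance / anisotropy)))
  rl <- max(1L, as.integer(round(min_distance)))
  thresh <- max(as.numeric(quantile(band, floor_quantile)),
                median(band) + noise_k * mad(band))
  idx <- .localmax3d_cpp(band, rz, rl, rl, thresh)
  d <- dim(vol)
  i0 <- idx - 1L
  data.frame(
    z = (i0 %% d[1]) + 1L,
    y = ((i0 %/% d[1]) %% d[2]) + 1L,
    x = (i0 %/% (d[1] * d[2])) + 1L,
    response = band[idx]
  )
}

#' Refine dot centroids to the local intensity peak
#'
#' The band-pass detector localizes on the median-filtered volume, which can
#' displace a maximum by a voxel (mostly along z, where the PSF is narrow
#' relative to the filter kernel). Each dot is moved to the brightest voxel
#' of the *unfiltered* volume within a small window; duplicates created by
#' two detections converging onto one voxel are dropped.
#'
#' @param dots Dot table from [detect_dots()].
#' @param vol Flat-field corrected, unfiltered volume.
#' @param radius Integer search window half-size `(z, y, x)`.
#' @return Refined (and possibly deduplicated) dot table.
#' @export
refine_dots <- function(dots, vol, radius = c(1L, 1L, 1L)) {
  d <- dim(vol)
  for (i in seq_len(nrow(dots))) {
    zz <- max(1, dots$z[i] - radius[1]):min(d[1], dots$z[i] + radius[1])
    yy <- max(1, dots$y[i] - radius[2]):min(d[2], dots$y[i] + radius[2])
    xx <- max(1, dots$x[i] - radius[3]):min(d[3], dots$x[i] + radius[3])
    w <- vol[zz, yy, xx, drop = FALSE]
    j <- arrayInd(which.max(w), dim(w))
    dots$z[i] <- zz[j[1]]; dots$y[i] <- yy[j[2]]; dots$x[i] <- xx[j[3]]
  }
  dots[!duplicated(dots[, c("z", "y", "x")]), , drop = FALSE]
}

#' Compute per-dot intensity features
#'
#' For each dot, the mean and the variability (population standard
#' deviation, or max - min range) of the raw voxel intensities over its
#' 1-sigma ellipsoid support, border-clipped.
#'
#' @param vol The volume the features are read from. Use the flat-field
#'   corrected but *unfiltered* volume: median filtering flattens the dot
#'   profile, collapsing the variability feature into read noise.
#' @param dots Dot table from [detect_dots()].
#' @param psf_sigma PSF sigma defining the support ellipsoid.
#' @param variability `"sd"` (population standard deviation, default) or
#'   `"range"` (max - min).
#' @return `dots` with columns `mean_intensity` and `intensity_variability`
#'   appended.
#' @export
dot_features <- function(vol, dots, psf_sigma, variability = c("sd", "range")) {
  variability <- match.arg(variability)
  d <- dim(vol)
  off <- .support_offsets(psf_sigma)
  .assert(nrow(off) > 0, "empty dot support")
  n <- nrow(dots)
  mi <- numeric(n); iv <- numeric(n)
  for (i in seq_len(n)) {
    z <- dots$z[i] + off[, 1]; y <- dots$y[i] + off[, 2]
    x <- dots$x[i] + off[, 3]
    ok <- z >= 1 & z <= d[1] & y >= 1 & y <= d[2] & x >= 1 & x <= d[3]
    v <- vol[cbind(z[ok], y[ok], x[ok])]
    mi[i] <- mean(v)
    iv[i] <- if (variability == "sd") {
      sqrt(mean((v - mean(v))^2))
    } else {
      max(v) - min(v)
    }
  }
  dots$mean_intensity <- mi
  dots$intensity_variability <- iv
  dots
}

# standardize the two feature columns (guarding zero spread)
.feature_matrix <- function(dots) {
  f <- cbind(dots$mean_intensity, dots$intensity_variability)
  mu <- colMeans(f)
  s <- apply(f, 2, sd)
  s[s == 0] <- 1
  sweep(sweep(f, 2, mu), 2, s, "/")
}

#' Choose the number of intensity clusters
#'
#' Default criterion: k maximizing the mean silhouette width over
#' standardized features; the elbow statistic (largest second difference of
#' the within-cluster SSE curve) is reported as a diagnostic. Automated
#' criteria do not always reflect dataset complexity, so an explicit
#' `override` always wins.
#'
#' @param dots Dot table with features (from [dot_features()]).
#' @param k_range Candidate cluster counts.
#' @param seed Seed for the K-means restarts.
#' @param override Optional integer: forced k (config/manual inspection).
#' @param max_silhouette_n Subsample cap for the O(n^2) silhouette.
#' @return `list(k, diagnostics)`; diagnostics has per-k `wss` and
#'   `silhouette`, and the elbow k.
#' @export
select_k <- function(dots, k_range = 2:6, seed = 1L, override = NULL,
                     max_silhouette_n = 2000L) {
  if (!is.null(override))
    return(list(k = as.integer(override), diagnostics = list(source = "override")))
  n <- nrow(dots)
  if (n < min(k_range) + 1L) {
    warning("too few dots for clustering; k = 1")
    return(list(k = 1L, diagnostics = list(source = "degenerate")))
  }
  k_range <- k_range[k_range <= n - 1L]
  f <- .feature_matrix(dots)
  if (all(apply(f, 2, sd) == 0) || nrow(unique(f)) == 1L) {
    warning("all dot features identical; k = 1")
    return(list(k = 1L, diagnostics = list(source = "degenerate")))
  }
  k_range <- k_range[k_range <= nrow(unique(f))]
  sub <- if (n > max_silhouette_n) {
    .with_seed(.subseed(seed, 17), sample.int(n, max_silhouette_n))
  } else seq_len(n)
  dmat <- dist(f[sub, , drop = FALSE])
  wss <- sil <- setNames(numeric(length(k_range)), k_range)
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    km <- .with_seed(.subseed(seed, k),
                     kmeans(f, centers = k, nstart = 10, iter.max = 100))
    wss[i] <- km$tot.withinss
    cl <- km$cluster[sub]
    sil[i] <- if (length(unique(cl)) < 2) -1 else
      mean(cluster::silhouette(cl, dmat)[, "sil_width"])
  }
  elbow <- if (length(k_range) >= 3) {
    d2 <- diff(diff(wss))
    k_range[which.max(d2) + 1L]
  } else k_range[which.max(-wss)]
  list(
    k = as.integer(k_range[which.max(sil)]),
    diagnostics = list(source = "silhouette", wss = wss, silhouette = sil,
                       elbow_k = as.integer(elbow))
  )
}

#' K-means triage of dots into kept signal vs rejected noise
#'
#' Dots are clustered on standardized (mean intensity, intensity
#' variability). Under the default `"middle_band"` rule the cluster with the
#' lowest mean-intensity centroid is rejected as non-specific binding, any
#' cluster whose mean-intensity centroid exceeds the `artifact_quantile` of
#' dot intensities is rejected as an imaging artifact, and the cluster with
#' the largest variability centroid is rejected when that centroid exceeds
#' twice the median centroid variability; all remaining clusters are kept.
#' At least one cluster is always rejected when `k >= 2` and at least one is
#' always kept (the brightest-of-the-rejected is restored in the degenerate
#' case where every cluster matched a rejection rule).
#'
#' @param dots Dot table with features.
#' @param k Number of clusters (see [select_k()]); `k = 1` keeps everything
#'   with a warning.
#' @param retain_rule Only `"middle_band"` is implemented.
#' @param artifact_quantile Intensity quantile defining "extremely high".
#' @param seed K-means seed (10 restarts).
#' @return `list(dots, result)`: `dots` gains `cluster` and `kept`;
#'   `result` is an `scmst_triage` with centroids, sizes, retained cluster
#'   ids and the parameters used.
#' @export
kmeans_triage <- function(dots, k, retain_rule = "middle_band",
                          artifact_quantile = 0.995, seed = 1L) {
  .assert(retain_rule == "middle_band", "unknown retain_rule")
  .assert(k >= 1, "k must be >= 1")
  if (k == 1L || nrow(dots) < 2L) {
    warning("k = 1: no triage possible, keeping all dots")
    dots$cluster <- 1L
    dots$kept <- TRUE
    res <- structure(list(k = 1L, centroids = NULL, sizes = nrow(dots),
                          retained = 1L, artifact_quantile = artifact_quantile),
                     class = "scmst_triage")
    return(list(dots = dots, result = res))
  }
  f <- .feature_matrix(dots)
  # order-independent clustering: k-means on the (sorted-unique) feature set
  # would be overkill; instead sort rows, cluster, then map back
  ord <- order(dots$mean_intensity, dots$intensity_variability,
               method = "radix")
  km <- .with_seed(.subseed(seed, 23),
                   kmeans(f[ord, , drop = FALSE], centers = k, nstart = 10,
                          iter.max = 100))
  cl <- integer(nrow(dots))
  cl[ord] <- km$cluster
  # centroids on the original feature scale
  cen_mean <- tapply(dots$mean_intensity, cl, mean)
  cen_var <- tapply(dots$intensity_variability, cl, mean)
  ids <- as.integer(names(cen_mean))
  # relabel clusters by increasing mean intensity so ids are reproducible
  rk <- rank(cen_mean, ties.method = "first")
  relab <- integer(max(ids)); relab[ids] <- rk
  cl <- relab[cl]
  cen <- cbind(mean_intensity = as.numeric(cen_mean[order(rk)]),
               intensity_variability = as.numeric(cen_var[order(rk)]))
  rownames(cen) <- seq_len(k)
  sizes <- tabulate(cl, k)
  reject <- rep(FALSE, k)
  reject[1L] <- TRUE # lowest mean intensity: non-specific binding
  hi <- as.numeric(quantile(dots$mean_intensity, artifact_quantile))
  reject[cen[, 1] > hi] <- TRUE
  vmax <- which.max(cen[, 2])
  if (cen[vmax, 2] > 2 * median(cen[, 2])) reject[vmax] <- TRUE
  if (all(reject)) reject[setdiff(order(-cen[, 1]), 1L)[1]] <- FALSE
  retained <- which(!reject)
  dots$cluster <- cl
  dots$kept <- cl %in% retained
  res <- structure(list(k = as.integer(k), centroids = cen, sizes = sizes,
                        retained = as.integer(retained),
                        artifact_quantile = artifact_quantile),
                   class = "scmst_triage")
  list(dots = dots, result = res)
}

#' @export
print.scmst_triage <- function(x, ...) {
  cat(sprintf("<scmst_triage> k = %d, retained clusters: %s\n", x$k,
              paste(x$retained, collapse = ", ")))
  if (!is.null(x$centroids)) print(round(cbind(x$centroids, size = x$sizes), 2))
  invisible(x)
}

#' Signal recovery rate between the initial and repeated first round
#'
#' RNA-integrity QC: the first hybridization probe set is repeated after the
#' multiplex routine and the kept-dot yield compared per gene; a healthy
#' sample recovers more than the QC threshold (default 70%) of its initial
#' signal.
#'
#' @param dots_initial,dots_repeat Triaged dot tables (with `gene` and
#'   `kept` columns) for the initial round and its repeat.
#' @param qc_threshold Overall pass threshold (fraction).
#' @return `list(per_gene, overall, pass)`: `per_gene` is a `data.frame`
#'   (`gene`, `initial`, `repeat_`, `recovery`; `recovery` `NA` when a gene
#'   had no initial dots), `overall` the pooled ratio.
#' @export
recovery_rate <- function(dots_initial, dots_repeat, qc_threshold = 0.70) {
  ki <- dots_initial[dots_initial$kept, , drop = FALSE]
  kr <- dots_repeat[dots_repeat$kept, , drop = FALSE]
  genes <- sort(unique(c(ki$gene, kr$gene)))
  ni <- vapply(genes, function(g) sum(ki$gene == g), 0)
  nr <- vapply(genes, function(g) sum(kr$gene == g), 0)
  per_gene <- data.frame(
    gene = genes, initial = ni, repeat_ = nr,
    recovery = ifelse(ni > 0, nr / ni, NA_real_),
    row.names = NULL, stringsAsFactors = FALSE
  )
  overall <- if (sum(ni) > 0) sum(nr) / sum(ni) else NA_real_
  list(per_gene = per_gene, overall = overall,
       pass = isTRUE(overall >= qc_threshold))
}

#' Match detected dots to ground-truth dots
#'
#' Greedy nearest-neighbor matching (in anisotropy-scaled voxels) within a
#' radius; each truth dot is matched at most once. Intended for phantom
#' evaluation.
#'
#' @param dots Detected dot table (`z`, `y`, `x`).
#' @param truth Truth dot table (`class`, `cell` and the coordinate columns
#'   named by `coords`; use the native columns for rounds acquired with a
#'   stage shift).
#' @param radius Match radius in lateral voxels.
#' @param anisotropy z-to-lateral voxel size ratio.
#' @param coords Names of the truth coordinate columns.
#' @return `dots` with `truth_idx` (row into `truth` or `NA`) and
#'   `truth_class` (`"none"` for unmatched detections).
#' @export
match_dots <- function(dots, truth, radius = 2.5, anisotropy = 2.4,
                       coords = c("z_native", "y_native", "x_native")) {
  if (!all(coords %in% names(truth))) coords <- c("z", "y", "x")
  n <- nrow(dots)
  dots$truth_idx <- NA_integer_
  dots$truth_class <- "none"
  if (n == 0 || nrow(truth) == 0) return(dots)
  pd <- cbind(dots$z * anisotropy, dots$y, dots$x)
  pt <- cbind(truth[[coords[1]]] * anisotropy, truth[[coords[2]]],
              truth[[coords[3]]])
  used <- rep(FALSE, nrow(truth))
  ord <- order(-dots$response)
  for (i in ord) {
    dd <- sqrt((pt[, 1] - pd[i, 1])^2 + (pt[, 2] - pd[i, 2])^2 +
                 (pt[, 3] - pd[i, 3])^2)
    dd[used] <- Inf
    j <- which.min(dd)
    if (dd[j] <= radius) {
      used[j] <- TRUE
      dots$truth_idx[i] <- j
      dots$truth_class[i] <- truth$class[j]
    }
  }
  dots
}
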