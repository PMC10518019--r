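# Pre-processing and inter-round alignment.
#
# Fixed order of operations for every channel volume: flat-field correction
# first, then the 3x3x3 3D median filter, then downstream detection.

# thin wrappers over the compiled kernels
.label3d <- function(mask) {
  m <- array(as.integer(mask), dim(mask))
  .label3d_cpp(m)
}

#' Separable 3D Gaussian smoothing
#'
#' @param vol `(z, y, x)` numeric array.
#' @param sigma Per-axis standard deviation in voxels (`(z, y, x)`); an axis
#'   with `sigma <= 0` is left untouched. Borders are edge-replicated.
#' @return Smoothed array, same shape.
#' @export
gauss3d <- function(vol, sigma) {
  .assert(.is_volume(vol), "vol must be a 3D array")
  .gauss3d_cpp(vol, sigma[1], sigma[2], sigma[3])
}

#' Estimate a per-channel flat-field (illumination) surface
#'
#' Robust surrogate for retrospective shading correction: the per-pixel
#' median across z planes (and across FOVs when several volumes are given)
#' captures the smooth multiplicative background, which is then heavily
#' smoothed and normalized to mean 1.
#'
#' @param vols A `(z, y, x)` volume, or a list of such volumes (same channel
#'   across FOVs) pooled into one estimate.
#' @param smooth_sigma Lateral smoothing sigma in pixels.
#' @return A `ny x nx` matrix of class `scmst_flatfield`, strictly positive,
#'   mean exactly 1.
#' @export
estimate_flatfield <- function(vols, smooth_sigma = 20) {
  if (.is_volume(vols)) vols <- list(vols)
  .assert(length(vols) >= 1 && all(vapply(vols, .is_volume, TRUE)),
          "vols must be a 3D array or list of 3D arrays")
  .assert(any(vapply(vols, function(v) any(v != 0), TRUE)),
          "all-zero channel: nothing to estimate")
  planes <- lapply(vols, .zmedian_cpp)
  base <- Reduce(`+`, planes) / length(planes)
  d <- dim(base)
  sm <- gauss3d(array(base, c(1L, d)), c(0, smooth_sigma, smooth_sigma))
  field <- matrix(sm, d[1], d[2])
  field <- pmax(field, 1e-6)
  field <- field / mean(field)
  structure(field, class = c("scmst_flatfield", "matrix", "array"))
}

#' Apply a flat-field correction (voxel-wise division)
#'
#' @param vol `(z, y, x)` volume.
#' @param field `ny x nx` strictly positive field, broadcast over z.
#' @return Corrected volume (double).
#' @export
apply_flatfield <- function(vol, field) {
  .assert(.is_volume(vol), "vol must be a 3D array")
  d <- dim(vol)
  .assert(all(dim(field) == d[2:3]), "field shape must match (y, x)")
  .assert(all(field > 0), "flat-field must be strictly positive")
  vol / rep(field, each = d[1])
}

#' 3D median filter
#'
#' Each voxel is replaced by the median of its `kernel` box neighborhood;
#' borders are edge-replicated. The default 3x3x3 kernel is the standard
#' speckle-noise filter applied before spot detection.
#'
#' @param vol `(z, y, x)` volume.
#' @param kernel Odd integer kernel dims `(z, y, x)`.
#' @return Filtered volume.
#' @export
median3d <- function(vol, kernel = c(3L, 3L, 3L)) {
  .assert(.is_volume(vol), "vol must be a 3D array")
  .assert(all(kernel %% 2 == 1), "kernel dims must be odd")
  .median3d_cpp(vol, as.integer(kernel[1]), as.integer(kernel[2]),
                as.integer(kernel[3]))
}

#' Register a hybridization round to the reference round
#'
#' Finds the integer `(z, y, x)` translation maximizing the normalized
#' cross-correlation between the shared reference (nuclei) channel of two
#' rounds, searched over `|shift| <= max_shift` via FFT cross-correlation of
#' the mean-subtracted, zero-padded volumes. The returned shift `s`
#' satisfies `moving approx translate(reference, s)`, i.e.
#' `apply_shift(moving, -s)` aligns the moving round onto the reference.
#' Near-ties (within `1e-8` of the maximum) resolve to the smallest
#' `(|z|, |y|, |x|)` lexicographically.
#'
#' @param reference,moving `(z, y, x)` volumes of the same shape.
#' @param max_shift Integer search radius per axis `(z, y, x)`.
#' @return `list(shift = c(z, y, x), score)` with `score` the normalized
#'   cross-correlation at the chosen shift.
#' @export
register_rounds <- function(reference, moving, max_shift = c(2L, 8L, 8L)) {
  .assert(.is_volume(reference) && .is_volume(moving),
          "volumes must be 3D arrays")
  .assert(all(dim(reference) == dim(moving)), "shapes must match")
  .assert(sd(reference) > 0, "flat (zero-variance) reference channel")
  ms <- as.integer(pmin(max_shift, dim(reference) - 1L))
  d <- dim(reference)
  pd <- d + 2L * ms
  pad <- function(v) {
    out <- array(0, pd)
    out[ms[1] + seq_len(d[1]), ms[2] + seq_len(d[2]), ms[3] + seq_len(d[3])] <-
      v - mean(v)
    out
  }
  fr <- fft(pad(reference))
  fm <- fft(pad(moving))
  cc <- Re(fft(fr * Conj(fm), inverse = TRUE)) / prod(pd)
  # cc at index (i,j,k) (0-based, wrapped) = sum ref[v + s] * mov[v] at
  # shift s = wrap(index); restrict to the search window
  wrap <- function(n, m) {
    i <- 0:(n - 1)
    ifelse(i <= n / 2, i, i - n)
  }
  sz <- wrap(pd[1]); sy <- wrap(pd[2]); sx <- wrap(pd[3])
  best <- NULL; best_v <- -Inf
  iz <- which(abs(sz) <= ms[1]); iy <- which(abs(sy) <= ms[2])
  ix <- which(abs(sx) <= ms[3])
  sub <- cc[iz, iy, ix, drop = FALSE]
  mx <- max(sub)
  cand <- which(sub >= mx - 1e-8 * abs(mx), arr.ind = TRUE)
  sh <- cbind(-sz[iz[cand[, 1]]], -sy[iy[cand[, 2]]], -sx[ix[cand[, 3]]])
  ord <- order(abs(sh[, 1]), abs(sh[, 2]), abs(sh[, 3]),
               sh[, 1], sh[, 2], sh[, 3])
  shift <- as.integer(sh[ord[1], ])
  # normalized cross-correlation on the overlap at the chosen shift
  aligned <- apply_shift(moving, -shift)
  ov <- .overlap_mask(d, shift)
  a <- reference[ov]; b <- aligned[ov]
  score <- if (sd(a) == 0 || sd(b) == 0) 0 else cor(a, b)
  list(shift = setNames(shift, c("z", "y", "x")), score = score)
}

.overlap_mask <- function(d, shift) {
  idx <- function(n, s) {
    lo <- max(1L, 1L + s); hi <- min(n, n + s)
    seq(lo, hi)
  }
  arr <- array(FALSE, d)
  arr[idx(d[1], shift[1]), idx(d[2], shift[2]), idx(d[3], shift[3])] <- TRUE
  arr
}

#' Translate a volume by an integer shift
#'
#' Content at voxel `v` moves to `v + shift`; voxels shifted outside the
#' volume are dropped. Vacated voxels are zero-filled by default;
#' `fill = "edge"` replicates the nearest surviving plane instead (useful
#' when a round aligned back to the reference frame feeds segmentation,
#' where a zero margin would punch holes into the elevation surface).
#'
#' @param vol `(z, y, x)` volume.
#' @param shift Integer `(z, y, x)` offset.
#' @param fill `"zero"` or `"edge"`.
#' @return Shifted volume, same shape.
#' @export
apply_shift <- function(vol, shift, fill = c("zero", "edge")) {
  fill <- match.arg(fill)
  .assert(.is_volume(vol), "vol must be a 3D array")
  d <- dim(vol)
  shift <- as.integer(round(shift))
  .assert(all(abs(shift) < d), "|shift| must be smaller than the volume")
  out <- array(0, d)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    s <- shift[a]
    src[[a]] <- seq(max(1L, 1L - s), min(d[a], d[a] - s))
    dst[[a]] <- src[[a]] + s
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- vol[src[[1]], src[[2]], src[[3]]]
  if (fill == "edge") {
    ix <- lapply(1:3, function(a) {
      i <- seq_len(d[a])
      pmin(pmax(i, min(dst[[a]])), max(dst[[a]]))
    })
    out <- out[ix[[1]], ix[[2]], ix[[3]]]
    dim(out) <- d
  }
  out
}

#' Pre-process one channel volume (fixed two-step order)
#'
#' Flat-field correction followed by the 3D median filter.
#'
#' @param vol Raw `(z, y, x)` volume.
#' @param field Flat-field from [estimate_flatfield()] (or `NULL` to skip).
#' @param kernel Median kernel dims.
#' @return Pre-processed volume.
#' @export
preprocess_volume <- function(vol, field = NULL, kernel = c(3L, 3L, 3L)) {
  if (!is.null(field)) vol <- apply_flatfield(vol, field)
  median3d(vol, kernel)
}
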