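# Independent brute-force oracles used by the equivalence tests. These stay
# deliberately naive (loops, direct formulas) and share no code with the
# package internals they check.

# neighborhood median with edge replication, direct loops
brute_median3d <- function(vol, kernel = c(3, 3, 3)) {
  d <- dim(vol)
  r <- (kernel - 1) / 2
  out <- array(NA_real_, d)
  for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3]) {
    zz <- pmin(pmax((z - r[1]):(z + r[1]), 1), d[1])
    yy <- pmin(pmax((y - r[2]):(y + r[2]), 1), d[2])
    xx <- pmin(pmax((x - r[3]):(x + r[3]), 1), d[3])
    out[z, y, x] <- median(vol[zz, yy, xx])
  }
  out
}

# direct cosine distance formula, element by element
brute_cosine <- function(m) {
  n <- nrow(m)
  out <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    ni <- sqrt(sum(m[i, ]^2)); nj <- sqrt(sum(m[j, ]^2))
    out[i, j] <- if (ni == 0 && nj == 0) 0
      else if (ni == 0 || nj == 0) 1
      else 1 - sum(m[i, ] * m[j, ]) / (ni * nj)
  }
  out
}

# filter-and-intersect selection oracle
brute_select <- function(z, genes) {
  sets <- lapply(genes, function(g) which(z[, g] > 0))
  Reduce(intersect, sets)
}

# naive agglomerative clustering with average linkage on a distance matrix;
# returns the partition (as a list of member sets) after each merge
brute_average_linkage <- function(dmat) {
  n <- nrow(dmat)
  clusters <- as.list(seq_len(n))
  partitions <- list()
  while (length(clusters) > 1) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      dd <- mean(dmat[clusters[[i]], clusters[[j]]])
      if (dd < bestd - 1e-12) { bestd <- dd; best <- c(i, j) }
    }
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
    partitions[[length(partitions) + 1L]] <- lapply(clusters, sort)
  }
  partitions
}

# label vector -> canonical partition string for label-invariant comparison
partition_key <- function(labels) {
  groups <- split(seq_along(labels), labels)
  paste(sort(vapply(groups, function(g) paste(g, collapse = ","), "")),
        collapse = "|")
}

# two-pass z-scoring computed directly (sample sd, zeros for sd = 0)
brute_two_pass_z <- function(m, embryo, group) {
  z <- m
  for (e in unique(embryo)) {
    rows <- embryo == e
    for (g in seq_len(ncol(m))) {
      v <- m[rows, g]
      s <- sd(v)
      z[rows, g] <- if (s > 0) (v - mean(v)) / s else 0
    }
  }
  out <- z
  for (gr in unique(group)) {
    rows <- group == gr
    for (g in seq_len(ncol(m))) {
      v <- z[rows, g]
      s <- sd(v)
      out[rows, g] <- if (s > 0) (v - mean(v)) / s else 0
    }
  }
  out
}
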