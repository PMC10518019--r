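# Two-stage z-score normalization, cosine-distance hierarchical clustering
# and co-expression cell selection.
#
# Normalization conventions: z-scores are computed on raw integer counts
# (set `transform = "log1p"` to standardize log1p counts instead); the
# standard deviation uses the sample (n - 1) denominator; a gene with zero
# spread within a group gets z = 0 for that group (degenerate rule, keeps
# the cells rather than dropping the gene).

.zscore_cols <- function(m) {
  mu <- colMeans(m)
  s <- apply(m, 2, sd)
  z <- sweep(m, 2, mu)
  nz <- s > 0
  z[, nz] <- sweep(z[, nz, drop = FALSE], 2, s[nz], "/")
  z[, !nz] <- 0
  z
}

.new_zmatrix <- function(values, cell_meta, mode, provenance) {
  structure(list(values = values, cell_meta = cell_meta, mode = mode,
                 provenance = provenance),
            class = "scmst_zmatrix")
}

#' @export
print.scmst_zmatrix <- function(x, ...) {
  cat(sprintf("<scmst_zmatrix> %d cells x %d genes, mode = %s\n",
              nrow(x$values), ncol(x$values), x$mode))
  invisible(x)
}

#' First-stage z-scoring: per gene within each embryo
#'
#' For each embryo, each gene is standardized over all of that embryo's
#' cells pooled across its fields of view.
#'
#' @param counts An `scmst_counts` (or a list with `values` and `cell_meta`
#'   carrying an `embryo` column).
#' @param transform `"none"` (raw counts, default) or `"log1p"`.
#' @return An `scmst_zmatrix` with mode `"within_embryo"`.
#' @export
zscore_within_embryo <- function(counts, transform = c("none", "log1p")) {
  transform <- match.arg(transform)
  m <- counts$values
  if (transform == "log1p") m <- log1p(m)
  meta <- counts$cell_meta
  .assert(!is.null(meta$embryo), "cell_meta needs an embryo column")
  z <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
  for (e in unique(meta$embryo)) {
    rows <- which(meta$embryo == e)
    .assert(length(rows) >= 2,
            sprintf("embryo %s has a single cell: sd undefined", e))
    z[rows, ] <- .zscore_cols(m[rows, , drop = FALSE])
  }
  .new_zmatrix(z, meta, "within_embryo",
               list(embryos = sort(unique(meta$embryo)),
                    transform = transform))
}

#' Second-stage z-scoring: pooled across embryos of a group
#'
#' Re-standardizes the within-embryo z-scores per gene over all pooled
#' cells of each group (default grouping: developmental stage), putting
#' "high" and "low" expression on a common scale across embryos.
#'
#' @param zwithin An `scmst_zmatrix` from [zscore_within_embryo()].
#' @param grouping `cell_meta` column to pool by (default `"stage"`), or
#'   `NULL` to pool everything.
#' @return An `scmst_zmatrix` with mode `"pooled_stage"`.
#' @export
zscore_pooled <- function(zwithin, grouping = "stage") {
  .assert(inherits(zwithin, "scmst_zmatrix") &&
            zwithin$mode == "within_embryo",
          "zscore_pooled expects a within-embryo z-matrix")
  m <- zwithin$values
  meta <- zwithin$cell_meta
  groups <- if (is.null(grouping)) rep("all", nrow(m)) else meta[[grouping]]
  .assert(!is.null(groups) && !anyNA(groups), "invalid grouping column")
  z <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
  for (g in unique(groups)) {
    rows <- which(groups == g)
    .assert(length(rows) >= 2, sprintf("empty or singleton group %s", g))
    z[rows, ] <- .zscore_cols(m[rows, , drop = FALSE])
  }
  .new_zmatrix(z, meta, "pooled_stage",
               list(grouping = grouping,
                    groups = sort(unique(as.character(groups))),
                    upstream = zwithin$provenance))
}

#' Cross-stage z-scoring
#'
#' Pools the cells of all stages and standardizes each gene once over the
#' pooled raw counts, putting the stages on a common per-gene scale so that
#' expression levels can be compared between stages. (A per-embryo first
#' pass would zero every embryo's mean and thereby erase exactly the
#' between-stage differences this normalization exists to expose, since
#' each embryo belongs to one stage.)
#'
#' @param counts An `scmst_counts` whose `cell_meta` has a `stage` column
#'   spanning at least two stages.
#' @param transform `"none"` (raw counts, default) or `"log1p"`.
#' @return An `scmst_zmatrix` with mode `"cross_stage"`.
#' @export
zscore_cross_stage <- function(counts, transform = c("none", "log1p")) {
  transform <- match.arg(transform)
  .assert(length(unique(counts$cell_meta$stage)) >= 2,
          "cross-stage normalization needs at least two stages")
  m <- counts$values
  if (transform == "log1p") m <- log1p(m)
  z <- .zscore_cols(m)
  .new_zmatrix(z, counts$cell_meta, "cross_stage",
               list(stages = sort(unique(as.character(counts$cell_meta$stage))),
                    transform = transform))
}

#' Pairwise cosine distances between matrix rows
#'
#' `d(u, v) = 1 - (u . v) / (|u| |v|)`, in `[0, 2]`. A zero row against a
#' non-zero row is assigned distance 1 (undefined angle, documented
#' convention); two zero rows have distance 0.
#'
#' @param m Numeric matrix (rows are objects).
#' @return A `dist` object.
#' @export
cosine_dist <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  zero <- nrm == 0
  nrm[zero] <- 1
  u <- m / nrm
  sim <- tcrossprod(u)
  d <- 1 - sim
  if (any(zero)) {
    d[zero, ] <- 1
    d[, zero] <- 1
    d[zero, zero] <- 0
  }
  d[d < 0] <- 0
  as.dist(d)
}

#' Hierarchical clustering of cells on cosine distance
#'
#' Agglomerative clustering (average linkage by default) of cells on the
#' pairwise cosine distance of their z-scored expression profiles, cut at
#' `k` clusters; genes are clustered the same way to give the
#' two-dimensional (cells x genes) heatmap leaf order.
#'
#' @param z An `scmst_zmatrix` (or plain matrix).
#' @param k Number of cell clusters to cut.
#' @param linkage `stats::hclust` method (default `"average"`).
#' @return An `scmst_clusters`: `list(labels, tree, gene_tree, cell_order,
#'   gene_order, k, metric, linkage)`; `labels` are contiguous integers in
#'   dendrogram order of first appearance.
#' @export
hcluster <- function(z, k, linkage = "average") {
  m <- if (inherits(z, "scmst_zmatrix")) z$values else z
  .assert(is.matrix(m) && nrow(m) >= 2, "need a matrix with >= 2 cells")
  .assert(k >= 1 && k <= nrow(m), "k must be in 1..n cells")
  tree <- hclust(cosine_dist(m), method = linkage)
  gene_tree <- if (ncol(m) >= 2) hclust(cosine_dist(t(m)), method = linkage)
               else NULL
  raw <- cutree(tree, k = k)
  # relabel so cluster ids follow the dendrogram leaf order
  ord <- tree$order
  first <- ord[!duplicated(raw[ord])]
  map <- integer(k)
  map[raw[first]] <- seq_len(k)
  labels <- map[raw]
  structure(list(
    labels = labels,
    tree = tree,
    gene_tree = gene_tree,
    cell_order = tree$order,
    gene_order = if (is.null(gene_tree)) seq_len(ncol(m)) else gene_tree$order,
    k = as.integer(k), metric = "cosine", linkage = linkage
  ), class = "scmst_clusters")
}

#' @export
print.scmst_clusters <- function(x, ...) {
  cat(sprintf("<scmst_clusters> %d cells, k = %d (%s linkage, %s distance)\n",
              length(x$labels), x$k, x$linkage, x$metric))
  print(table(cluster = x$labels))
  invisible(x)
}

#' Select cells co-expressing a gene set
#'
#' A cell is selected when its z-score is strictly above 0 (expression
#' higher than the mean) for every gene of the set; per-gene filters are
#' intersected over cell ids.
#'
#' @param z An `scmst_zmatrix`.
#' @param gene_set Non-empty character vector of panel genes.
#' @return An `scmst_selection`: `list(gene_set, cells, mask, per_stage)`;
#'   `cells` are row indices into the z-matrix, `per_stage` a `data.frame`
#'   with per-stage `n_selected`, `n_stage`, `pct_of_stage`,
#'   `pct_of_selection` (percentages rounded to one decimal).
#' @export
select_coexpressing <- function(z, gene_set) {
  .assert(inherits(z, "scmst_zmatrix"), "z must be an scmst_zmatrix")
  .assert(length(gene_set) >= 1, "empty gene set")
  missing <- setdiff(gene_set, colnames(z$values))
  .assert(length(missing) == 0,
          paste("unknown gene(s):", paste(missing, collapse = ", ")))
  sub <- z$values[, gene_set, drop = FALSE]
  mask <- rowSums(sub > 0) == length(gene_set)
  cells <- which(mask)
  stg <- if (is.null(z$cell_meta$stage)) rep("all", nrow(z$values))
         else as.character(z$cell_meta$stage)
  stages <- sort(unique(stg))
  n_sel <- vapply(stages, function(s) sum(mask & stg == s), 0)
  n_stage <- vapply(stages, function(s) sum(stg == s), 0)
  per_stage <- data.frame(
    stage = stages,
    n_selected = as.integer(n_sel),
    n_stage = as.integer(n_stage),
    pct_of_stage = round(100 * n_sel / pmax(n_stage, 1), 1),
    pct_of_selection = round(100 * n_sel / max(sum(n_sel), 1), 1),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(gene_set = gene_set, cells = cells, mask = mask,
                 per_stage = per_stage),
            class = "scmst_selection")
}

#' @export
print.scmst_selection <- function(x, ...) {
  cat(sprintf("<scmst_selection> %d cells co-expressing {%s} (z > 0)\n",
              length(x$cells), paste(x$gene_set, collapse = ", ")))
  print(x$per_stage)
  invisible(x)
}

#' Overlap between two cell selections
#'
#' @param sel_a,sel_b `scmst_selection` objects over the same cell universe.
#' @return `list(n_a, n_b, n_both, frac_of_a, frac_of_b)`; fractions are
#'   `NA` for an empty side.
#' @export
overlap_stats <- function(sel_a, sel_b) {
  .assert(length(sel_a$mask) == length(sel_b$mask),
          "selections are over different cell universes")
  both <- sum(sel_a$mask & sel_b$mask)
  na <- length(sel_a$cells); nb <- length(sel_b$cells)
  list(n_a = na, n_b = nb, n_both = both,
       frac_of_a = if (na > 0) both / na else NA_real_,
       frac_of_b = if (nb > 0) both / nb else NA_real_)
}

#' Stage composition of a selection
#'
#' @param sel An `scmst_selection`.
#' @return Its `per_stage` table (counts, % of stage total, % of
#'   selection).
#' @export
stage_composition <- function(sel) sel$per_stage
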