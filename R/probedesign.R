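# HCR-style probe construction and tiling.
#
# Each probe is 60 nt: a binding segment antisense to the target CDS, a
# 4 nt linker, and an HCR initiator (B1-B5). With the default 36 nt
# initiator the binding segment is 60 - 4 - 36 = 20 nt; only the total
# length and linker length are fixed by the protocol, the 36/20 split is a
# configurable default of this package.

#' Synthetic HCR initiator sequences (B1-B5)
#'
#' Fixed 36-nt stand-ins for the five commercial HCR amplifier initiators
#' (the real sequences are proprietary); they serve the pipeline's
#' bookkeeping role - distinct initiators multiplex the genes within a
#' round - not hybridization thermodynamics.
#'
#' @return Named character vector `B1..B5` of 36-nt sequences.
#' @export
hcr_initiators <- function() {
  c(
    B1 = "GAGGAGGGCAGCAAACGGGAAGAGTCTTCCTTTACG",
    B2 = "CCTCGTAAATCCTCATCAATCATCCAGTAAACCGCC",
    B3 = "GTCCCTGCCTCTATATCTCCACTCAACTTTAACCCG",
    B4 = "CCTCAACCTACCTCCAACTCTCACCATATTCGCTTC",
    B5 = "CTCACTCCCAATCTCTATCTACCCTACAAATCCAAT"
  )
}

#' Probe design configuration
#'
#' @param total_len Total probe length in nt (default 60).
#' @param linker_len Linker length between binding segment and initiator
#'   (default 4).
#' @param linker Linker sequence (its length must equal `linker_len`).
#' @param initiators Named map initiator name -> sequence.
#' @param min_probes Minimum probes per gene before an under-coverage
#'   warning (default 13).
#' @param max_probes Cap on probes per gene (default 24).
#' @param min_gap Minimum nt between adjacent binding sites (default 2).
#' @param gc_bounds Allowed GC fraction interval for binding sites.
#' @param strict Raise an error instead of warning when a gene yields fewer
#'   than `min_probes` sites.
#' @return A `probe_config` list.
#' @export
probe_config <- function(total_len = 60L, linker_len = 4L, linker = "AAAA",
                         initiators = hcr_initiators(), min_probes = 13L,
                         max_probes = 24L, min_gap = 2L,
                         gc_bounds = c(0.35, 0.70), strict = FALSE) {
  .assert(nchar(linker) == linker_len, "linker length mismatch")
  .assert(min_probes <= max_probes, "min_probes must be <= max_probes")
  .assert(all(total_len > linker_len + nchar(initiators)),
          "total_len must exceed linker + initiator length")
  structure(list(total_len = as.integer(total_len),
                 linker_len = as.integer(linker_len), linker = linker,
                 initiators = initiators,
                 min_probes = as.integer(min_probes),
                 max_probes = as.integer(max_probes),
                 min_gap = as.integer(min_gap), gc_bounds = gc_bounds,
                 strict = isTRUE(strict)),
            class = "probe_config")
}

.binding_len <- function(config, initiator) {
  config$total_len - config$linker_len -
    nchar(config$initiators[[initiator]])
}

.check_dna <- function(s) {
  .assert(nchar(s) > 0, "empty sequence")
  .assert(grepl("^[ACGTacgt]+$", s), "sequence contains non-ACGT characters")
  toupper(s)
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Construct one probe from a target site
#'
#' `probe = reverse_complement(target_site) + linker + initiator`; the
#' result is exactly `total_len` nt (60 by default).
#'
#' @param target_site Sense-strand CDS window the probe will bind
#'   (its length must be `total_len - linker_len - initiator length`).
#' @param initiator Initiator name (must exist in the config map).
#' @param config A [probe_config()].
#' @return The full probe sequence (character scalar).
#' @export
construct_probe <- function(target_site, initiator, config = probe_config()) {
  target_site <- .check_dna(target_site)
  .assert(initiator %in% names(config$initiators),
          paste("unknown initiator", initiator))
  blen <- .binding_len(config, initiator)
  .assert(nchar(target_site) == blen,
          sprintf("target site must be %d nt for initiator %s", blen,
                  initiator))
  probe <- paste0(.revcomp(target_site), config$linker,
                  config$initiators[[initiator]])
  stopifnot(nchar(probe) == config$total_len)
  probe
}

.gc_frac <- function(s) {
  ch <- strsplit(s, "")[[1]]
  mean(ch %in% c("G", "C"))
}

#' Tile probes along a coding sequence
#'
#' Greedy left-to-right placement of non-overlapping binding sites
#' separated by at least `min_gap` nt, each passing the GC filter, stopping
#' at `max_probes`. Fewer than `min_probes` sites yields an under-coverage
#' warning (an error when `config$strict`).
#'
#' @param cds Coding sequence (sense strand).
#' @param initiator Initiator name for every probe of this gene.
#' @param config A [probe_config()].
#' @param gene Gene name recorded in the output.
#' @return An `scmst_probeset`: `list(gene, initiator, probes, warnings)`;
#'   `probes` is a `data.frame` with `start`, `end` (1-based site
#'   coordinates on the CDS), `site`, `binding`, `linker`, `initiator`,
#'   `probe`.
#' @export
tile_gene <- function(cds, initiator, config = probe_config(),
                      gene = "gene") {
  cds <- .check_dna(cds)
  .assert(initiator %in% names(config$initiators),
          paste("unknown initiator", initiator))
  blen <- .binding_len(config, initiator)
  .assert(nchar(cds) >= blen,
          sprintf("CDS shorter than one binding site (%d nt)", blen))
  lo <- config$gc_bounds[1]; hi <- config$gc_bounds[2]
  rows <- list()
  pos <- 1L
  n <- nchar(cds)
  while (pos + blen - 1L <= n && length(rows) < config$max_probes) {
    site <- substr(cds, pos, pos + blen - 1L)
    gc <- .gc_frac(site)
    if (gc >= lo && gc <= hi) {
      rows[[length(rows) + 1L]] <- data.frame(
        start = pos, end = pos + blen - 1L, site = site,
        stringsAsFactors = FALSE)
      pos <- pos + blen + config$min_gap
    } else {
      pos <- pos + 1L
    }
  }
  probes <- if (length(rows)) do.call(rbind, rows) else
    data.frame(start = integer(0), end = integer(0), site = character(0),
               stringsAsFactors = FALSE)
  warnings <- character(0)
  if (nrow(probes) < config$min_probes) {
    msg <- sprintf(
      "%s: only %d probe site(s) found (minimum %d): under-coverage",
      gene, nrow(probes), config$min_probes)
    if (config$strict) stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
    warnings <- msg
  }
  if (nrow(probes)) {
    probes$binding <- vapply(probes$site, .revcomp, "")
    probes$linker <- config$linker
    probes$initiator <- initiator
    probes$probe <- vapply(probes$site, construct_probe, "",
                           initiator = initiator, config = config)
    rownames(probes) <- NULL
  }
  structure(list(gene = gene, initiator = initiator, probes = probes,
                 warnings = warnings),
            class = "scmst_probeset")
}

#' @export
print.scmst_probeset <- function(x, ...) {
  cat(sprintf("<scmst_probeset> %s: %d probe(s), initiator %s%s\n", x$gene,
              nrow(x$probes), x$initiator,
              if (length(x$warnings)) " [under-coverage]" else ""))
  invisible(x)
}

#' Assign HCR initiators to genes round by round
#'
#' Within each hybridization round every gene receives a distinct
#' initiator (cycling `B1..B5` in channel order); the same initiator is
#' reused across rounds, which is safe because earlier signal is stripped
#' between rounds.
#'
#' @param round_plan `data.frame` from [make_round_plan()].
#' @param initiators Named initiator map.
#' @return Named character vector gene -> initiator name.
#' @export
assign_initiators <- function(round_plan, initiators = hcr_initiators()) {
  out <- character(nrow(round_plan))
  names(out) <- round_plan$gene
  for (r in unique(round_plan$round)) {
    sel <- which(round_plan$round == r)
    .assert(length(sel) <= length(initiators),
            sprintf("round %d has %d genes but only %d initiators", r,
                    length(sel), length(initiators)))
    ord <- sel[order(round_plan$channel[sel])]
    out[ord] <- names(initiators)[seq_along(ord)]
  }
  out
}

#' Design probes for all genes of a panel
#'
#' Reads coding sequences from a FASTA file (or a named character vector),
#' assigns initiators per round and tiles every gene.
#'
#' @param cds FASTA path or named character vector of coding sequences
#'   covering the round plan's genes.
#' @param round_plan `data.frame` from [make_round_plan()].
#' @param config A [probe_config()].
#' @return `list(probes, sets)`: `probes` is the combined `data.frame`
#'   (gene, site coordinates, sequences), `sets` the per-gene
#'   `scmst_probeset`s.
#' @export
design_panel_probes <- function(cds, round_plan, config = probe_config()) {
  if (is.character(cds) && length(cds) == 1 && file.exists(cds)) {
    ss <- Biostrings::readDNAStringSet(cds)
    cds <- setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  }
  missing <- setdiff(round_plan$gene, names(cds))
  .assert(length(missing) == 0,
          paste("no CDS for:", paste(missing, collapse = ", ")))
  inits <- assign_initiators(round_plan, config$initiators)
  sets <- lapply(round_plan$gene, function(g)
    tile_gene(cds[[g]], inits[[g]], config, gene = g))
  names(sets) <- round_plan$gene
  probes <- do.call(rbind, lapply(sets, function(s) {
    if (nrow(s$probes) == 0) return(NULL)
    cbind(gene = s$gene, s$probes, stringsAsFactors = FALSE)
  }))
  rownames(probes) <- NULL
  list(probes = probes, sets = sets)
}
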