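# Assigning genes to the X chromosome or autosomes from marker-anchored
# windows on assembly scaffolds. Marker positions are 0-based (BED
# convention); gene spans are 1-based inclusive (GFF3 convention);
# windows are half-open intervals centered on the marker.

#' Detect chimeric scaffolds
#'
#' A scaffold is chimeric when it carries at least one marker tagged
#' X-linked and at least one tagged autosomal, indicating a likely assembly
#' error.
#'
#' @param markers Marker tibble with columns `scaffold` and `chromosome`
#'   (values `X`/`A`).
#' @return Character vector of chimeric scaffold ids (possibly empty).
#' @export
detect_chimeric_scaffolds <- function(markers) {
  if (!all(markers$chromosome %in% c("X", "A"))) {
    abort("marker chromosome tags must be X or A")
  }
  tab <- table(markers$scaffold, markers$chromosome)
  if (!all(c("X", "A") %in% colnames(tab))) return(character(0))
  rownames(tab)[tab[, "X"] > 0 & tab[, "A"] > 0]
}

#' Assign genes to chromosomes from marker windows
#'
#' A gene is tagged by a marker when its annotated span overlaps the
#' half-open window of `window_bp` base pairs centered on the marker
#' (`[pos - window_bp/2, pos + window_bp/2)` in 0-based coordinates,
#' clipped at the scaffold edge) on the same scaffold. Genes tagged by both
#' X and A markers (possible on chimeric scaffolds) are `ambiguous` and are
#' meant to be excluded downstream; genes tagged by no marker are
#' `unassigned`. In whole-scaffold mode (`window_bp = Inf`) a gene is
#' tagged by every marker on its scaffold.
#'
#' @param genes Gene tibble with columns `gene`, `scaffold`, `start`, `end`
#'   (1-based inclusive).
#' @param markers Marker tibble with columns `scaffold`, `pos` (0-based)
#'   and `chromosome` (`X`/`A`).
#' @param window_bp Window width in bp (default 200 kb), or `Inf` for
#'   whole-scaffold mode.
#' @return A tibble of class `"chrom_assignment"`: `gene`, `scaffold`,
#'   `chromosome` (`X`, `A`, `ambiguous`, `unassigned`) and `window`.
#' @examples
#' g <- tibble::tibble(gene = "g1", scaffold = "s", start = 390000, end = 410000)
#' m <- tibble::tibble(marker = "m1", scaffold = "s", pos = 500000,
#'                     chromosome = "X")
#' assign_genes(g, m, 200000)
#' @export
assign_genes <- function(genes, markers, window_bp = 200000) {
  if (!all(markers$chromosome %in% c("X", "A"))) {
    abort("marker chromosome tags must be X or A")
  }
  if (!(is.infinite(window_bp) || window_bp > 0)) {
    abort("`window_bp` must be positive (or Inf for whole-scaffold mode)")
  }
  half <- window_bp / 2
  # windows in 1-based inclusive coordinates: 0-based half-open
  # [pos - half, pos + half) becomes [pos - half + 1, pos + half]
  if (is.infinite(window_bp)) {
    wstart <- rep(1, nrow(markers))
    wend <- rep(.Machine$integer.max, nrow(markers))
  } else {
    wstart <- pmax(markers$pos - half + 1, 1)
    wend <- markers$pos + half
  }
  tagged_x <- tagged_a <- character(0)
  for (chrom in c("X", "A")) {
    sel <- markers$chromosome == chrom
    if (!any(sel)) next
    hits <- overlap_hits(
      genes$scaffold, genes$start, genes$end,
      markers$scaffold[sel], wstart[sel], wend[sel]
    )
    if (chrom == "X") tagged_x <- unique(genes$gene[hits])
    else tagged_a <- unique(genes$gene[hits])
  }
  chromosome <- dplyr::case_when(
    genes$gene %in% tagged_x & genes$gene %in% tagged_a ~ "ambiguous",
    genes$gene %in% tagged_x ~ "X",
    genes$gene %in% tagged_a ~ "A",
    TRUE ~ "unassigned"
  )
  out <- tibble(gene = genes$gene, scaffold = genes$scaffold,
                chromosome = chromosome,
                window = if (is.infinite(window_bp)) "whole_scaffold"
                         else as.character(window_bp))
  class(out) <- c("chrom_assignment", class(out))
  out
}

# indices of query intervals overlapping any subject interval on the same
# sequence (1-based inclusive coordinates)
overlap_hits <- function(q_seq, q_start, q_end, s_seq, s_start, s_end) {
  seqs <- union(unique(q_seq), unique(s_seq))
  q <- IRanges::IRanges(start = q_start, end = q_end)
  s <- IRanges::IRanges(start = s_start, end = pmin(s_end, .Machine$integer.max))
  qr <- split(q, factor(q_seq, levels = seqs))
  sr <- split(s, factor(s_seq, levels = seqs))
  hit <- logical(length(q_seq))
  idx_by_seq <- split(seq_along(q_seq), factor(q_seq, levels = seqs))
  for (sq in seqs) {
    h <- IRanges::findOverlaps(qr[[sq]], sr[[sq]])
    hit[idx_by_seq[[sq]][unique(S4Vectors::queryHits(h))]] <- TRUE
  }
  which(hit)
}

#' Re-run assignment across a set of window sizes
#'
#' Runs [assign_genes()] at each window size (use `Inf` for whole-scaffold
#' mode) and stacks the results, so downstream enrichment can be computed
#' per window and the sensitivity of the X/A contrast to window size
#' inspected.
#'
#' @inheritParams assign_genes
#' @param windows Numeric vector of window sizes in bp (default
#'   `c(1e5, 2e5, 4e5, 8e5, Inf)`).
#' @return A tibble: the union of per-window assignments.
#' @export
window_sweep <- function(genes, markers,
                         windows = c(1e5, 2e5, 4e5, 8e5, Inf)) {
  purrr::map_dfr(windows, function(w) assign_genes(genes, markers, w))
}
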