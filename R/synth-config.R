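#' Configuration of the synthetic expression dataset generator
#'
#' Describes a synthetic stand-in for a morph-stratified aphid RNA-seq
#' study: a fragmented genome assembly of scaffolds (a few of them chimeric
#' between the X and autosomes), microsatellite-like markers tagged X or A,
#' gene models, and a gene-by-library count matrix with negative-binomial
#' noise and planted morph-bias categories whose frequency may depend on
#' the chromosome. Defaults emulate the study scale: 8 libraries (3 male,
#' 2 sexual-female, 3 asexual-female), 402 markers of which 14.4% X-linked,
#' 3712 genes of which 13.4% X-linked, 11 chimeric scaffolds, and 12-22
#' million mapped reads per library.
#'
#' `bias_props` gives, for each of the six morph-bias categories, the
#' probability that a gene of each chromosome type is planted in that
#' category (`prop_A`, `prop_X`); the remainder of genes is unbiased. The
#' default proportions plant a male-biased excess on the X and an
#' asexual-female-biased excess on autosomes, at study-like magnitudes.
#'
#' @param n_scaffolds Number of scaffolds (including chimeric ones).
#' @param scaffold_meanlog,scaffold_sdlog Log-normal parameters of scaffold
#'   length (bp); lengths are floored at `scaffold_min`.
#' @param scaffold_min Minimum scaffold length (bp).
#' @param n_markers,marker_x_fraction Marker count and X-linked fraction.
#' @param n_genes,gene_x_fraction Gene count and X-linked fraction.
#' @param n_chimeric Number of chimeric scaffolds (each carries an X segment
#'   and an autosomal segment, and at least one marker of each tag).
#' @param libraries Named integer vector: libraries per morph, names among
#'   `M`, `F`, `A` (male, sexual female, asexual female).
#' @param depth_range Range of per-library mapped-read totals.
#' @param dispersion Negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`).
#' @param bias_props Tibble with columns `category`, `prop_A`, `prop_X`
#'   (see Details), or `NULL` for the defaults.
#' @param fold_range Planted fold-changes are drawn log-uniformly from this
#'   range.
#' @param baseline_sdlog Log-normal spread of baseline gene abundances.
#' @param length_meanlog,length_sdlog,length_min Gene-length distribution
#'   (bp).
#' @param male_x_factor Multiplier on the expression of X-linked genes in
#'   male libraries: 1 models full dosage compensation of the single male
#'   X, 0.5 models none.
#' @return A list of class `"synth_config"`.
#' @examples
#' synth_config(n_genes = 500, n_markers = 80)
#' @export
synth_config <- function(n_scaffolds = 300,
                         scaffold_meanlog = log(1e6), scaffold_sdlog = 0.5,
                         scaffold_min = 2e5,
                         n_markers = 402, marker_x_fraction = 0.144,
                         n_genes = 3712, gene_x_fraction = 0.134,
                         n_chimeric = 11,
                         libraries = c(M = 3, F = 2, A = 3),
                         depth_range = c(12e6, 22e6),
                         dispersion = 0.05,
                         bias_props = NULL,
                         fold_range = c(2.5, 40),
                         baseline_sdlog = 2,
                         length_meanlog = log(1500), length_sdlog = 0.5,
                         length_min = 200,
                         male_x_factor = 1) {
  if (is.null(bias_props)) bias_props <- default_bias_props()
  stopifnot(all(c("category", "prop_A", "prop_X") %in% names(bias_props)))
  if (!setequal(bias_props$category, bias_categories())) {
    abort("`bias_props$category` must be the six morph-bias categories")
  }
  if (any(bias_props$prop_A < 0) || any(bias_props$prop_X < 0) ||
      sum(bias_props$prop_A) > 1 || sum(bias_props$prop_X) > 1) {
    abort("bias proportions must be non-negative and sum to <= 1 per chromosome")
  }
  frac_ok <- function(x) length(x) == 1 && x >= 0 && x <= 1
  if (!frac_ok(marker_x_fraction) || !frac_ok(gene_x_fraction)) {
    abort("X fractions must be in [0, 1]")
  }
  if (dispersion <= 0) abort("`dispersion` must be > 0")
  if (any(depth_range <= 0)) abort("depths must be > 0")
  if (n_chimeric > n_scaffolds) abort("`n_chimeric` cannot exceed `n_scaffolds`")
  if (is.null(names(libraries)) || !all(names(libraries) %in% c("M", "F", "A"))) {
    abort("`libraries` must be a named vector with names among M, F, A")
  }
  structure(
    list(n_scaffolds = n_scaffolds, scaffold_meanlog = scaffold_meanlog,
         scaffold_sdlog = scaffold_sdlog, scaffold_min = scaffold_min,
         n_markers = n_markers, marker_x_fraction = marker_x_fraction,
         n_genes = n_genes, gene_x_fraction = gene_x_fraction,
         n_chimeric = n_chimeric, libraries = libraries,
         depth_range = depth_range, dispersion = dispersion,
         bias_props = as_tibble(bias_props), fold_range = fold_range,
         baseline_sdlog = baseline_sdlog, length_meanlog = length_meanlog,
         length_sdlog = length_sdlog, length_min = length_min,
         male_x_factor = male_x_factor),
    class = "synth_config"
  )
}

#' The six morph-bias categories
#'
#' Category labels follow the `M±F±A±` convention: over-in-one categories
#' (`M+F-A-`, `M-F+A-`, `M-F-A+`) are at least n-fold overexpressed in the
#' focal morph relative to each of the other two; under-in-one categories
#' (`M-F+A+`, `M+F-A+`, `M+F+A-`) are at least n-fold underexpressed in the
#' focal morph, with the two overexpressing morphs within 2-fold of each
#' other.
#'
#' @return Character vector of the six category labels.
#' @export
bias_categories <- function() {
  c("M+F-A-", "M+F+A-", "M-F-A+", "M-F+A+", "M-F+A-", "M+F-A+")
}

default_bias_props <- function() {
  tibble(
    category = bias_categories(),
    prop_A = c(0.0700, 0.0058, 0.0522, 0.0235, 0.0659, 0.0249),
    prop_X = c(0.1615, 0.0154, 0.0282, 0.0051, 0.0487, 0.0179)
  )
}
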