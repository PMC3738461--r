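# Normalization, morph-effect testing and bias-category classification for
# a gene-by-library count matrix with libraries from three reproductive
# morphs (M = male, F = sexual female, A = asexual female).

#' Median-of-ratios library size factors
#'
#' The classical count-normalization scheme: for each library, the size
#' factor is the median over genes of the ratio of the library's count to
#' the gene's geometric mean across libraries, computed over genes with a
#' non-zero count in every library. Normalized counts are raw counts
#' divided by the library's factor.
#'
#' @param counts Counts tibble (`gene` column plus one column per library)
#'   or matrix.
#' @return Named numeric vector of size factors, one per library.
#' @examples
#' m <- rbind(g1 = c(10, 20), g2 = c(100, 200))
#' size_factors(m)  # ratio 1 : 2
#' @export
size_factors <- function(counts) {
  m <- counts_matrix(counts)
  ok <- rowSums(m > 0) == ncol(m)
  if (!any(ok)) abort("no gene has non-zero counts in all libraries")
  logm <- log(m[ok, , drop = FALSE])
  geo <- rowMeans(logm)
  apply(exp(logm - geo), 2, median)
}

#' Normalize a count matrix by size factors
#'
#' @inheritParams size_factors
#' @param factors Size factors (default: computed by [size_factors()]).
#' @return Matrix of normalized counts.
#' @export
normalize_counts <- function(counts, factors = size_factors(counts)) {
  m <- counts_matrix(counts)
  sweep(m, 2, factors, "/")
}

check_design <- function(counts, design) {
  m <- counts_matrix(counts)
  if (anyDuplicated(design$library)) abort("duplicate library ids in design")
  if (!all(design$morph %in% c("M", "F", "A"))) {
    bad <- which(!design$morph %in% c("M", "F", "A"))[1]
    abort(paste0("unknown morph \"", design$morph[bad], "\" in design row ", bad))
  }
  missing <- setdiff(colnames(m), design$library)
  if (length(missing)) {
    abort(paste0("libraries missing from design: ", paste(missing, collapse = ", ")))
  }
  design$morph[match(colnames(m), design$library)]
}

#' Negative-binomial likelihood-ratio test for a morph effect
#'
#' For each gene, compares a negative-binomial model with one mean per
#' reproductive morph against an intercept-only model, both with
#' library-size offsets, and refers twice the log-likelihood difference to
#' a chi-square distribution with 2 degrees of freedom. The per-gene
#' dispersion is a method-of-moments estimate from within-morph replicate
#' variability of the normalized counts (floored at `1e-8`). This is a
#' deliberately simple test of the morph-effect GLM comparison; externally
#' computed p-values (e.g. from a dedicated differential-expression
#' package) can be supplied to downstream steps instead via the `p_values`
#' argument of [classify_expression()].
#'
#' Genes with all-zero counts get `p = 1`.
#'
#' @param counts Counts tibble or matrix.
#' @param design Design tibble with columns `library` and `morph`.
#' @param factors Library size factors (default median-of-ratios).
#' @return A tibble with columns `gene`, `p_value` and `dispersion`.
#' @export
morph_effect_test <- function(counts, design, factors = size_factors(counts)) {
  m <- counts_matrix(counts)
  morph <- check_design(counts, design)
  morphs <- unique(morph)
  if (length(morphs) < 2) abort("need libraries from at least 2 morphs")
  sf <- factors[colnames(m)]
  y <- sweep(m, 2, sf, "/")
  # method-of-moments dispersion from within-morph replicates
  num <- 0; den <- 0
  for (mo in morphs) {
    sel <- morph == mo
    if (sum(sel) < 2) next
    mu <- rowMeans(y[, sel, drop = FALSE])
    v <- apply(y[, sel, drop = FALSE], 1, stats::var)
    num <- num + (v - mu) * sum(sel)
    den <- den + mu^2 * sum(sel)
  }
  mom <- num / pmax(den, 1e-300)
  # With 2-3 replicates per morph the per-gene moment estimate is far too
  # noisy to plug into a chi-square LRT, so genes share a mean-expression
  # dispersion trend: the average of the per-gene estimates within
  # log-mean bins. This keeps the null distribution of the LRT honest.
  mg <- rowMeans(y)
  if (nrow(m) >= 50) {
    bins <- cut(log(mg + 1), breaks = 10)
    trend <- stats::ave(mom, bins, FUN = mean)
  } else {
    trend <- mean(mom)
  }
  disp <- pmax(trend, 1e-8)
  size <- 1 / disp
  # null model: one abundance; alternative: one abundance per morph
  q0 <- rowSums(m) / sum(sf)
  ll0 <- ll1 <- 0
  for (j in seq_len(ncol(m))) {
    ll0 <- ll0 + dnbinom(m[, j], mu = pmax(q0 * sf[j], 1e-12),
                         size = size, log = TRUE)
  }
  for (mo in morphs) {
    sel <- morph == mo
    qm <- rowSums(m[, sel, drop = FALSE]) / sum(sf[sel])
    for (j in which(sel)) {
      ll1 <- ll1 + dnbinom(m[, j], mu = pmax(qm * sf[j], 1e-12),
                           size = size, log = TRUE)
    }
  }
  stat <- pmax(2 * (ll1 - ll0), 0)
  p <- unname(stats::pchisq(stat, df = length(morphs) - 1, lower.tail = FALSE))
  p[rowSums(m) == 0] <- 1
  tibble(gene = rownames(m), p_value = p, dispersion = disp)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of raw p-values (a thin wrapper
#' over [stats::p.adjust()] with `method = "BH"`).
#'
#' @param p Raw p-values in `[0, 1]`.
#' @return Adjusted p-values, in the input order.
#' @export
adjust_bh <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must be in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Classify genes into morph-bias categories
#'
#' Applies the `M±F±A±` classification at fold threshold `n_fold` to
#' normalized per-morph mean expression. A significant gene is
#' *over-in-one* (`M+F-A-`, `M-F+A-`, `M-F-A+`) when the focal morph's mean
#' is at least `n_fold` times each of the other two, and *under-in-one*
#' (`M-F+A+`, `M+F-A+`, `M+F+A-`) when the focal morph's mean is at least
#' `n_fold`-fold below each of the other two *and* the two overexpressing
#' morphs are within 2-fold of each other (strictly). Non-significant genes
#' and genes matching neither pattern are `unbiased`. A zero mean in a
#' denominator counts as infinitely exceeded only when the numerator is
#' positive; comparisons between two zero means fail.
#'
#' @param mean_M,mean_F,mean_A Normalized mean expression per morph
#'   (vectors, recycled).
#' @param n_fold Fold threshold (the study used 2, 5 and 10).
#' @param significant Logical vector: whether the gene's morph effect is
#'   significant after multiple-testing adjustment.
#' @return Character vector of categories (`"unbiased"` or one of
#'   [bias_categories()]).
#' @examples
#' classify_bias(100, 10, 10, n_fold = 2, significant = TRUE)  # "M+F-A-"
#' @export
classify_bias <- function(mean_M, mean_F, mean_A, n_fold = 2,
                          significant = TRUE) {
  if (!n_fold >= 1) abort("`n_fold` must be >= 1")
  n <- max(length(mean_M), length(mean_F), length(mean_A))
  M <- rep_len(as.numeric(mean_M), n)
  F_ <- rep_len(as.numeric(mean_F), n)
  A <- rep_len(as.numeric(mean_A), n)
  sig <- rep_len(as.logical(significant), n)
  if (any(M < 0 | F_ < 0 | A < 0, na.rm = TRUE)) {
    abort("means must be non-negative")
  }
  # x at least k-fold over y; zero y only exceeded by positive x
  over <- function(x, y, k) (x >= k * y) & (x > 0)
  # the two high morphs within 2-fold of each other (strict), both positive
  close2 <- function(x, y) x > 0 & y > 0 & pmax(x, y) / pmin(x, y) < 2
  out <- rep("unbiased", n)
  out[over(M, F_, n_fold) & over(M, A, n_fold)] <- "M+F-A-"
  out[over(F_, M, n_fold) & over(F_, A, n_fold)] <- "M-F+A-"
  out[over(A, M, n_fold) & over(A, F_, n_fold)] <- "M-F-A+"
  und <- out == "unbiased"  # over-in-one takes precedence; disjoint anyway
  out[und & over(F_, M, n_fold) & over(A, M, n_fold) & close2(F_, A)] <- "M-F+A+"
  out[und & over(M, F_, n_fold) & over(A, F_, n_fold) & close2(M, A)] <- "M+F-A+"
  out[und & over(M, A, n_fold) & over(F_, A, n_fold) & close2(M, F_)] <- "M+F+A-"
  out[!sig] <- "unbiased"
  out
}

#' Flag genes with very low read support
#'
#' A gene is low-support when the sum of its normalized counts over all
#' libraries is strictly below `threshold` reads (default 5).
#'
#' @param normalized Matrix (or counts tibble of already-normalized values)
#'   of normalized counts.
#' @param threshold Support threshold.
#' @return Logical vector, one per gene.
#' @export
low_support_flag <- function(normalized, threshold = 5) {
  m <- counts_matrix(normalized)
  rowSums(m) < threshold
}

#' Full expression classification pipeline
#'
#' Normalizes the libraries (median-of-ratios), tests each gene for a
#' reproductive-morph effect, adjusts p-values by Benjamini-Hochberg, and
#' classifies significant genes (`padj < alpha`) into morph-bias categories
#' at each fold threshold. Low-support genes (normalized total < 5 reads)
#' are flagged.
#'
#' @param counts Counts tibble or matrix.
#' @param design Design tibble (`library`, `morph`).
#' @param alpha Adjusted-p significance level (default 0.05).
#' @param folds Fold thresholds (default `c(2, 5, 10)`).
#' @param p_values Optional externally computed raw p-values (named by gene
#'   or in row order), e.g. from a dedicated differential-expression
#'   package; when supplied the built-in test is skipped.
#' @param factors Optional library size factors.
#' @return A tibble of class `"bias_calls"`: `gene`, `p_value`, `padj`,
#'   `mean_M`, `mean_F`, `mean_A`, `low_support`, and one `category_<n>`
#'   column per fold threshold.
#' @export
classify_expression <- function(counts, design, alpha = 0.05,
                                folds = c(2, 5, 10), p_values = NULL,
                                factors = NULL) {
  m <- counts_matrix(counts)
  morph <- check_design(counts, design)
  if (is.null(factors)) factors <- size_factors(m)
  y <- normalize_counts(m, factors)
  if (is.null(p_values)) {
    p <- morph_effect_test(m, design, factors)$p_value
  } else {
    p <- if (!is.null(names(p_values))) unname(p_values[rownames(m)]) else p_values
    if (length(p) != nrow(m)) abort("`p_values` must cover every gene")
  }
  padj <- adjust_bh(p)
  means <- vapply(c("M", "F", "A"), function(mo) {
    rowMeans(y[, morph == mo, drop = FALSE])
  }, numeric(nrow(m)))
  out <- tibble(
    gene = rownames(m), p_value = p, padj = padj,
    mean_M = means[, "M"], mean_F = means[, "F"], mean_A = means[, "A"],
    low_support = low_support_flag(y)
  )
  sig <- !is.na(padj) & padj < alpha
  for (nf in folds) {
    out[[paste0("category_", nf)]] <-
      classify_bias(out$mean_M, out$mean_F, out$mean_A, nf, sig)
  }
  class(out) <- c("bias_calls", class(out))
  out
}
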