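# X-versus-autosome enrichment of morph-bias categories (chi-square
# goodness of fit against the X-linkage baseline) and dosage-compensation
# comparisons on RPKM.

#' Baseline expected frequency of X-linkage
#'
#' The expected proportion of X-linked genes among assigned,
#' adequately-supported genes: `#X / (#X + #A)` over genes assigned `X` or
#' `A` that are not low-support. Using the supported-gene baseline (rather
#' than all assigned genes) avoids bias from the X being slightly enriched
#' in weakly expressed genes.
#'
#' @param assignment A `"chrom_assignment"` tibble (or any data frame with
#'   a `chromosome` column of `X`/`A`/other tags).
#' @param low_support Optional logical vector (same order) flagging
#'   low-support genes to exclude.
#' @return The baseline proportion `p0` (single numeric).
#' @examples
#' expected_fx(tibble::tibble(chromosome = rep(c("X", "A"), c(390, 2930))))
#' @export
expected_fx <- function(assignment, low_support = NULL) {
  chrom <- assignment$chromosome
  keep <- chrom %in% c("X", "A")
  if (!is.null(low_support)) keep <- keep & !low_support
  nx <- sum(chrom[keep] == "X")
  na <- sum(chrom[keep] == "A")
  if (nx + na == 0) abort("no assigned, supported genes to form a baseline")
  nx / (nx + na)
}

#' Chi-square goodness-of-fit test of X-enrichment
#'
#' Tests observed counts of X-linked versus autosomal genes in a category
#' against the baseline proportion `p0` of X-linkage, with a two-cell
#' goodness-of-fit chi-square (1 df, no continuity correction by default).
#' Also reports the observed X-linkage frequency `f_X = X/(X+A)` and the
#' percent deviation `100 * (f_X / p0 - 1)`.
#'
#' @param obs_X,obs_A Observed gene counts on the X and autosomes.
#' @param p0 Expected proportion of X-linkage (from [expected_fx()]).
#' @param correct Apply the Yates continuity correction (default `FALSE`).
#' @return A one-row tibble: `obs_X`, `obs_A`, `f_X`, `p0`,
#'   `pct_deviation`, `statistic`, `p_value`.
#' @examples
#' chisq_enrichment(63, 205, 390 / 3320)
#' @export
chisq_enrichment <- function(obs_X, obs_A, p0, correct = FALSE) {
  stopifnot(length(obs_X) == 1, length(obs_A) == 1)
  if (obs_X + obs_A < 1) abort("need at least one observed gene")
  if (p0 <= 0 || p0 >= 1) abort("`p0` must be in (0, 1)")
  n <- obs_X + obs_A
  expd <- n * c(p0, 1 - p0)
  obs <- c(obs_X, obs_A)
  if (correct) {
    stat <- sum((abs(obs - expd) - 0.5)^2 / expd)
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  } else {
    ct <- suppressWarnings(chisq.test(obs, p = c(p0, 1 - p0)))
    stat <- unname(ct$statistic)
    p <- ct$p.value
  }
  f_X <- obs_X / n
  tibble(obs_X = obs_X, obs_A = obs_A, f_X = f_X, p0 = p0,
         pct_deviation = 100 * (f_X / p0 - 1),
         statistic = stat, p_value = p)
}

#' Category-wise enrichment table
#'
#' Joins bias calls with chromosome assignments and, for every fold
#' threshold and every morph-bias category, counts X-linked and autosomal
#' genes and tests X-enrichment against the supported-gene baseline.
#' Ambiguous and unassigned genes are excluded; the baseline uses genes
#' supported by at least 5 normalized reads.
#'
#' @param calls A `"bias_calls"` tibble from [classify_expression()].
#' @param assignment A `"chrom_assignment"` tibble from [assign_genes()].
#' @param p0 Baseline proportion; default computed by [expected_fx()] from
#'   the assigned, supported genes.
#' @return A tibble of class `"enrichment_table"`: one row per
#'   (fold, category).
#' @export
enrichment_table <- function(calls, assignment, p0 = NULL) {
  df <- dplyr::inner_join(as_tibble(calls), as_tibble(assignment), by = "gene")
  df <- df[df$chromosome %in% c("X", "A"), ]
  if (is.null(p0)) p0 <- expected_fx(df, df$low_support)
  fold_cols <- grep("^category_", names(df), value = TRUE)
  out <- purrr::map_dfr(fold_cols, function(col) {
    nf <- sub("^category_", "", col)
    purrr::map_dfr(bias_categories(), function(cat) {
      sel <- df[[col]] == cat
      nx <- sum(sel & df$chromosome == "X")
      na <- sum(sel & df$chromosome == "A")
      if (nx + na == 0) {
        return(tibble(fold = as.numeric(nf), category = cat,
                      obs_X = 0L, obs_A = 0L, f_X = NA_real_, p0 = p0,
                      pct_deviation = NA_real_, statistic = NA_real_,
                      p_value = NA_real_))
      }
      res <- chisq_enrichment(nx, na, p0)
      dplyr::bind_cols(tibble(fold = as.numeric(nf), category = cat),
                       res)
    })
  })
  class(out) <- c("enrichment_table", class(out))
  out
}

#' @exportS3Method generics::tidy
tidy.enrichment_table <- function(x, ...) as_tibble(x)

#' @exportS3Method generics::glance
glance.enrichment_table <- function(x, ...) {
  tibble(n_tests = sum(!is.na(x$p_value)),
         n_significant = sum(x$p_value < 0.05, na.rm = TRUE),
         p0 = x$p0[1])
}

#' Plot category-wise X-linkage frequencies
#'
#' Bar chart of the observed X-linkage frequency per morph-bias category
#' and fold threshold, with the baseline expectation as a horizontal line
#' and significance stars from the chi-square tests.
#'
#' @param object An `"enrichment_table"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.enrichment_table <- function(object, ...) {
  df <- as_tibble(object)
  df$stars <- dplyr::case_when(
    is.na(df$p_value) ~ "",
    df$p_value < 0.001 ~ "***",
    df$p_value < 0.01 ~ "**",
    df$p_value < 0.05 ~ "*",
    TRUE ~ ""
  )
  df$fold_lab <- paste0(df$fold, "-fold")
  ggplot2::ggplot(df, ggplot2::aes(.data$category, .data$f_X,
                                   fill = .data$fold_lab)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$p0),
                        linetype = 2, linewidth = 0.4) +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars),
                       position = ggplot2::position_dodge(width = 0.9),
                       vjust = -0.3, size = 3) +
    ggplot2::labs(x = NULL, y = "frequency of X-linkage (f_X)",
                  fill = "threshold") +
    ggplot2::theme_minimal()
}

#' RPKM expression values
#'
#' Reads per kilobase of exon model per million mapped reads:
#' `count / (length/1e3 * total/1e6)`.
#'
#' @param counts Counts tibble or matrix.
#' @param lengths Gene lengths in bp (named by gene, or in row order).
#' @param totals Per-library mapped-read totals; default the column sums.
#' @return Matrix of RPKM values.
#' @examples
#' rpkm(rbind(g1 = 100), lengths = 1000, totals = 1e7)  # 10
#' @export
rpkm <- function(counts, lengths, totals = NULL) {
  m <- counts_matrix(counts)
  if (!is.null(names(lengths))) lengths <- lengths[rownames(m)]
  lengths <- rep_len(as.numeric(lengths), nrow(m))
  if (any(lengths <= 0)) abort("gene lengths must be > 0")
  if (is.null(totals)) totals <- colSums(m)
  if (any(totals <= 0)) abort("mapped totals must be > 0")
  sweep(m / (lengths / 1e3), 2, totals / 1e6, "/")
}

#' Per-morph mean RPKM and its log transform
#'
#' Averages RPKM over each morph's replicate libraries and returns both the
#' morph means and `log2(RPKM + 1)`.
#'
#' @param rpkm_mat RPKM matrix from [rpkm()].
#' @param design Design tibble (`library`, `morph`).
#' @return A tibble: `gene`, `total_rpkm` (sum over libraries), then per
#'   morph `rpkm_<morph>` and `log2_<morph>`.
#' @export
morph_rpkm <- function(rpkm_mat, design) {
  morph <- design$morph[match(colnames(rpkm_mat), design$library)]
  out <- tibble(gene = rownames(rpkm_mat),
                total_rpkm = rowSums(rpkm_mat))
  for (mo in unique(morph)) {
    mm <- rowMeans(rpkm_mat[, morph == mo, drop = FALSE])
    out[[paste0("rpkm_", mo)]] <- mm
    out[[paste0("log2_", mo)]] <- log2(mm + 1)
  }
  out
}

#' Dosage-compensation comparisons of X and autosomal expression
#'
#' For each morph and each minimal-expression threshold (applied to the
#' total RPKM over all libraries), compares `log2(RPKM + 1)` of X-linked
#' versus autosomal genes with a two-sided Wilcoxon rank-sum test. For
#' males, a doubled-X variant multiplies the X-linked RPKM by 2 before the
#' log transform, modelling the two-copy expression the genes would show if
#' the single male X were fully compensated.
#'
#' @param morph_expr Tibble from [morph_rpkm()].
#' @param assignment A `"chrom_assignment"` tibble.
#' @param thresholds Minimal total-RPKM thresholds (default
#'   `c(0, 0.1, 5)`; 0 means no restriction).
#' @param double_x_males Also run the doubled-X male comparison.
#' @return A tibble of class `"dosage_results"`: `morph`, `threshold`,
#'   `doubled_X`, `n_X`, `n_A`, `median_X`, `median_A`, `statistic`,
#'   `p_value`.
#' @export
dosage_tests <- function(morph_expr, assignment, thresholds = c(0, 0.1, 5),
                         double_x_males = TRUE) {
  df <- dplyr::inner_join(morph_expr, as_tibble(assignment), by = "gene")
  df <- df[df$chromosome %in% c("X", "A"), ]
  morphs <- sub("^rpkm_", "", grep("^rpkm_", names(df), value = TRUE))
  grid <- expand.grid(morph = morphs, threshold = thresholds,
                      stringsAsFactors = FALSE)
  one <- function(morph, threshold, doubled) {
    d <- df[df$total_rpkm > threshold | threshold == 0, ]
    x <- d[[paste0("rpkm_", morph)]][d$chromosome == "X"]
    a <- d[[paste0("rpkm_", morph)]][d$chromosome == "A"]
    if (length(x) < 2 || length(a) < 2) {
      abort("need at least 2 genes on each chromosome type")
    }
    if (doubled) x <- 2 * x
    lx <- log2(x + 1); la <- log2(a + 1)
    wt <- wilcox.test(lx, la, exact = FALSE)
    tibble(morph = morph, threshold = threshold, doubled_X = doubled,
           n_X = length(x), n_A = length(a),
           median_X = median(lx), median_A = median(la),
           statistic = unname(wt$statistic), p_value = wt$p.value)
  }
  out <- purrr::pmap_dfr(grid, function(morph, threshold) {
    res <- one(morph, threshold, FALSE)
    if (double_x_males && morph == "M") {
      res <- dplyr::bind_rows(res, one(morph, threshold, TRUE))
    }
    res
  })
  class(out) <- c("dosage_results", class(out))
  out
}

#' Chi-square test of low-expression enrichment on the X
#'
#' Tests whether genes expressed at a very low level (total RPKM below
#' `cutoff` over all libraries) are over-represented on the X, against the
#' X-linkage baseline `p0`.
#'
#' @param morph_expr Tibble from [morph_rpkm()].
#' @param assignment A `"chrom_assignment"` tibble.
#' @param cutoff Total-RPKM cutoff for "low expression" (default 0.1).
#' @param p0 X-linkage baseline; default the assigned-gene fraction.
#' @return A one-row tibble as from [chisq_enrichment()], plus the
#'   per-chromosome low-expression fractions `frac_low_X`, `frac_low_A`.
#' @export
low_expression_test <- function(morph_expr, assignment, cutoff = 0.1,
                                p0 = NULL) {
  df <- dplyr::inner_join(morph_expr, as_tibble(assignment), by = "gene")
  df <- df[df$chromosome %in% c("X", "A"), ]
  if (is.null(p0)) p0 <- expected_fx(df)
  low <- df$total_rpkm < cutoff
  if (!any(low)) {
    res <- tibble(obs_X = 0L, obs_A = 0L, f_X = NA_real_, p0 = p0,
                  pct_deviation = NA_real_, statistic = NA_real_,
                  p_value = NA_real_)
  } else {
    res <- chisq_enrichment(sum(low & df$chromosome == "X"),
                            sum(low & df$chromosome == "A"), p0)
  }
  res$frac_low_X <- mean(low[df$chromosome == "X"])
  res$frac_low_A <- mean(low[df$chromosome == "A"])
  res
}

#' Plot X versus autosome expression by morph
#'
#' Boxplots of `log2(RPKM + 1)` for X-linked and autosomal genes in each
#' morph, with the doubled-X male variant as an extra box.
#'
#' @param morph_expr Tibble from [morph_rpkm()].
#' @param assignment A `"chrom_assignment"` tibble.
#' @param threshold Minimal total-RPKM filter (default 0 = all genes).
#' @return A ggplot object.
#' @export
plot_dosage <- function(morph_expr, assignment, threshold = 0) {
  df <- dplyr::inner_join(morph_expr, as_tibble(assignment), by = "gene")
  df <- df[df$chromosome %in% c("X", "A"), ]
  if (threshold > 0) df <- df[df$total_rpkm > threshold, ]
  long <- tidyr::pivot_longer(df, dplyr::starts_with("rpkm_"),
                              names_to = "morph", names_prefix = "rpkm_",
                              values_to = "rpkm")
  doubled <- long[long$morph == "M" & long$chromosome == "X", ]
  doubled$rpkm <- 2 * doubled$rpkm
  doubled$chromosome <- "X (doubled)"
  long <- dplyr::bind_rows(long, doubled)
  long$log2expr <- log2(long$rpkm + 1)
  ggplot2::ggplot(long, ggplot2::aes(.data$chromosome, .data$log2expr,
                                     fill = .data$chromosome)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::facet_wrap(ggplot2::vars(.data$morph)) +
    ggplot2::labs(x = NULL, y = "log2(RPKM + 1)") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}
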