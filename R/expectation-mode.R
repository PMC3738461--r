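# Deterministic infinite-population recursion: every stochastic draw of the
# life cycle replaced by its expectation, counts replaced by genotype
# frequencies. Used as the independent check of the closed-form invasion
# growth rate, and available for exploring deterministic dynamics.

#' One deterministic annual cycle on genotype frequencies
#'
#' Advances the genotype frequencies of asexual females through one full
#' cycle (t rounds of clonal selection, morph production, gametogenesis
#' under selection, random union of gametes) in an infinite population:
#' every random draw of the stochastic simulator is replaced by its mean.
#' Fecundities cancel out of frequencies, so only fitnesses matter.
#'
#' @param geno Numeric length-3 vector of genotype frequencies
#'   `c(bb, bB, BB)` among asexual females (must sum to 1).
#' @param scheme A one-row fitness-scheme tibble.
#' @param config A [sim_config()]; only `t` is used.
#' @param location `"autosome"` or `"X"`; defaults to the scheme's.
#' @return The genotype-frequency vector after one full cycle.
#' @export
expected_cycle <- function(geno, scheme, config = sim_config(),
                           location = NULL) {
  stopifnot(length(geno) == 3, abs(sum(geno) - 1) < 1e-8)
  validate_scheme(scheme)
  if (nrow(scheme) != 1L) abort("`scheme` must have exactly one row")
  location <- scheme_location(scheme, location)[1]
  w_a <- c(1, 1 + scheme$h_a * scheme$s_a, 1 + scheme$s_a)
  w_f <- c(1, 1 + scheme$h_f * scheme$s_f, 1 + scheme$s_f)
  for (g in seq_len(config$t)) {
    geno <- geno * w_a
    geno <- geno / sum(geno)
  }
  # sexual females are clones; female gametes weighted by female fitness
  wf <- geno * w_f
  p_f <- (wf[2] / 2 + wf[3]) / sum(wf)
  if (location == "X") {
    # sons draw one maternal X; hemizygous selection then acts
    m <- c(geno[1] + geno[2] / 2, geno[3] + geno[2] / 2)
    wm <- m * c(1, 1 + scheme$s_m)
    p_m <- wm[2] / sum(wm)
  } else {
    wm <- geno * c(1, 1 + scheme$h_m * scheme$s_m, 1 + scheme$s_m)
    p_m <- (wm[2] / 2 + wm[3]) / sum(wm)
  }
  c((1 - p_f) * (1 - p_m),
    p_f * (1 - p_m) + (1 - p_f) * p_m,
    p_f * p_m)
}

#' Deterministic per-cycle frequency growth of a rare allele
#'
#' Starts the deterministic recursion of [expected_cycle()] from
#' Hardy-Weinberg frequencies at a tiny allele frequency `p` and returns
#' the ratio of allele frequencies after one full cycle, `p'/p`. To first
#' order in `p` this equals the closed-form growth rate of
#' [invasion_growth_rate()]; the two are computed through entirely
#' different routes (full genotype-frequency recursion versus rare-allele
#' algebra on heterozygote fitnesses).
#'
#' @inheritParams expected_cycle
#' @param p Starting allele frequency (default `1e-6`).
#' @return The one-cycle growth ratio `p'/p`.
#' @examples
#' sc <- fitness_scheme(s_m = 0.2, location = "X")
#' expected_growth_ratio(sc)           # ~ invasion_growth_rate(sc)$lambda_X
#' @export
expected_growth_ratio <- function(scheme, config = sim_config(),
                                  location = NULL, p = 1e-6) {
  geno <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  geno2 <- expected_cycle(geno, scheme, config, location)
  (geno2[2] / 2 + geno2[3]) / p
}
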