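# Control model: a standard XX/XY (or ZZ/ZW, mutatis mutandis) system with
# discrete generations, 500 males + 500 females, fitness-proportional gamete
# production, and the same invasion bookkeeping as the aphid model. Used to
# recover the classical dominance-dependent predictions for comparison.

#' Run replicates of the standard XX/XY control model
#'
#' Each generation, 500 females and 500 males produce gamete pools in
#' proportion to their fitnesses (Poisson counts with mean `f_s * w` per
#' individual); 1000 female gametes and 1000 male gametes (for an X-linked
#' locus, the 500 X-bearing male gametes) are drawn without replacement and
#' paired: daughters receive a maternal X and the paternal X, sons a
#' maternal X and the Y. Female fitnesses use `s_f`/`h_f`; males are
#' hemizygous (`1 + s_m`) at X-linked loci and diploid with `h_m` at
#' autosomal loci. The returned frequency is the overall allele frequency
#' in the adult population after `config$cycles` generations.
#'
#' @inheritParams run_replicates
#' @param scheme Scheme tibble; `s_a`/`h_a` are ignored by this model.
#' @return A tibble with columns `draw`, `rep`, `freq`.
#' @export
run_standard_xy <- function(scheme, config = sim_config(), location = NULL,
                            reps = config$reps, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  location <- scheme_location(scheme, location)[1]
  validate_scheme(scheme)
  idx <- rep(seq_len(nrow(scheme)), each = reps)
  freq <- xy_run_cycles(scheme[idx, , drop = FALSE], config, location)
  tibble(draw = idx, rep = rep(seq_len(reps), times = nrow(scheme)),
         freq = freq)
}

xy_run_cycles <- function(scheme, config, location) {
  Nf <- 500L  # females; same number of males
  R <- nrow(scheme)
  p0 <- config$p0
  f <- config$f_s
  wf_het <- 1 + scheme$h_f * scheme$s_f
  wf_hom <- 1 + scheme$s_f
  wm_het <- 1 + scheme$h_m * scheme$s_m
  wm_hom <- 1 + scheme$s_m
  ff <- rmultinom(R, Nf, c((1 - p0)^2, 2 * p0 * (1 - p0), p0^2))
  f_bb <- ff[1, ]; f_bB <- ff[2, ]; f_BB <- ff[3, ]
  if (location == "X") {
    m_B <- rbinom(R, Nf, p0)           # hemizygous male X alleles
    m_bb <- m_bB <- m_BB <- NULL
  } else {
    mm <- rmultinom(R, Nf, c((1 - p0)^2, 2 * p0 * (1 - p0), p0^2))
    m_bb <- mm[1, ]; m_bB <- mm[2, ]; m_BB <- mm[3, ]
  }
  final <- rep(NA_real_, R)
  act <- seq_len(R)
  n_allele_f <- 2L * Nf
  for (cy in seq_len(config$cycles)) {
    Ra <- length(act)
    # female gamete pool
    g_bb <- rpois(Ra, f_bb * f)
    g_bB <- rpois(Ra, f_bB * f * wf_het[act])
    g_BB <- rpois(Ra, f_BB * f * wf_hom[act])
    B_f <- rbinom(Ra, g_bB, 0.5) + g_BB
    tot_f <- g_bb + g_bB + g_BB
    if (location == "X") {
      g_mb <- rpois(Ra, (Nf - m_B) * f)
      g_mB <- rpois(Ra, m_B * f * wm_hom[act])
      B_m <- g_mB; tot_m <- g_mb + g_mB   # X-bearing male gametes
      short <- tot_f < 2L * Nf | tot_m < Nf
    } else {
      g2_bb <- rpois(Ra, m_bb * f)
      g2_bB <- rpois(Ra, m_bB * f * wm_het[act])
      g2_BB <- rpois(Ra, m_BB * f * wm_hom[act])
      B_m <- rbinom(Ra, g2_bB, 0.5) + g2_BB
      tot_m <- g2_bb + g2_bB + g2_BB
      short <- tot_f < 2L * Nf | tot_m < 2L * Nf
    }
    if (any(short)) {
      tot <- tot_f[short] + tot_m[short]
      final[act[short]] <- ifelse(tot > 0,
                                  (B_f[short] + B_m[short]) / tot, 0)
      keep <- !short
      act <- act[keep]
      if (!length(act)) return(final)
      B_f <- B_f[keep]; tot_f <- tot_f[keep]
      B_m <- B_m[keep]; tot_m <- tot_m[keep]
      f_bb <- f_bb[keep]; f_bB <- f_bB[keep]; f_BB <- f_BB[keep]
      if (location == "X") m_B <- m_B[keep] else {
        m_bb <- m_bb[keep]; m_bB <- m_bB[keep]; m_BB <- m_BB[keep]
      }
      Ra <- length(act)
    }
    # 1000 maternal gametes: 500 to daughters, 500 to sons
    x <- rhyper(Ra, B_f, tot_f - B_f, n_allele_f)
    xd <- rhyper(Ra, x, n_allele_f - x, Nf)
    xs <- x - xd
    if (location == "X") {
      yd <- rhyper(Ra, B_m, tot_m - B_m, Nf)   # paternal X -> daughters
      f_BB <- rhyper(Ra, xd, Nf - xd, yd)
      f_bB <- xd + yd - 2 * f_BB
      f_bb <- Nf - xd - yd + f_BB
      m_B <- xs
      nB <- 2 * f_BB + f_bB + m_B
      lost <- nB == 0
      fixed <- !lost & (f_bb + f_bB == 0 & m_B == Nf)
    } else {
      y <- rhyper(Ra, B_m, tot_m - B_m, n_allele_f)
      yd <- rhyper(Ra, y, n_allele_f - y, Nf)
      ys <- y - yd
      f_BB <- rhyper(Ra, xd, Nf - xd, yd)
      f_bB <- xd + yd - 2 * f_BB
      f_bb <- Nf - xd - yd + f_BB
      m_BB <- rhyper(Ra, xs, Nf - xs, ys)
      m_bB <- xs + ys - 2 * m_BB
      m_bb <- Nf - xs - ys + m_BB
      nB <- 2 * f_BB + f_bB + 2 * m_BB + m_bB
      lost <- nB == 0
      fixed <- !lost & (f_bb + f_bB == 0 & m_bb + m_bB == 0)
    }
    if (any(lost)) final[act[lost]] <- 0
    if (any(fixed)) final[act[fixed]] <- 1
    keep <- !(lost | fixed)
    if (!any(keep)) return(final)
    if (!all(keep)) {
      act <- act[keep]
      f_bb <- f_bb[keep]; f_bB <- f_bB[keep]; f_BB <- f_BB[keep]
      if (location == "X") m_B <- m_B[keep] else {
        m_bb <- m_bb[keep]; m_bB <- m_bB[keep]; m_BB <- m_BB[keep]
      }
    }
  }
  if (length(act)) {
    if (location == "X") {
      final[act] <- (2 * f_BB + f_bB + m_B) / (2 * Nf + Nf)
    } else {
      final[act] <- (2 * f_BB + f_bB + 2 * m_BB + m_bB) / (4 * Nf)
    }
  }
  final
}
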