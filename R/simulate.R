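# Stochastic simulation of one biallelic locus through the annual aphid
# cycle. All operations act on integer genotype *counts* held as columns of
# a population tibble with one row per replicate, so every step is a single
# vectorized draw (sums of i.i.d. Poissons are drawn as one Poisson per
# genotype class). Fitness schemes are recycled row-wise against replicates.

#' Construct a population table of asexual-female genotype counts
#'
#' One row per replicate population; columns `n_bb`, `n_bB`, `n_BB` hold
#' the integer genotype counts and `phase` tags the point in the annual
#' cycle.
#'
#' @param n_bb,n_bB,n_BB Genotype counts (recycled).
#' @param phase `"clonal"` or `"sexual"`.
#' @return A population tibble.
#' @export
pop_tibble <- function(n_bb, n_bB, n_BB, phase = "clonal") {
  tibble(n_bb = as.numeric(n_bb), n_bB = as.numeric(n_bB),
         n_BB = as.numeric(n_BB), phase = phase)
}

# recycle scheme columns to R replicates
scheme_cols <- function(scheme, R) {
  validate_scheme(scheme)
  idx <- rep_len(seq_len(nrow(scheme)), R)
  list(
    wa_het = 1 + scheme$h_a[idx] * scheme$s_a[idx],
    wa_hom = 1 + scheme$s_a[idx],
    wf_het = 1 + scheme$h_f[idx] * scheme$s_f[idx],
    wf_hom = 1 + scheme$s_f[idx],
    wm_het = 1 + scheme$h_m[idx] * scheme$s_m[idx],
    wm_hom = 1 + scheme$s_m[idx],
    wm_B0  = 1 + scheme$s_m[idx]
  )
}

#' Found a cycle's population of asexual females
#'
#' Draws the genotype counts of the `N` asexual females founding a cycle
#' from a multinomial distribution under Hardy-Weinberg proportions at the
#' initial mutant frequency `p0`.
#'
#' @param config A [sim_config()].
#' @param n_reps Number of replicate populations to found (rows of the
#'   returned tibble).
#' @return A population tibble with columns `n_bb`, `n_bB`, `n_BB`, `phase`.
#' @examples
#' init_population(sim_config(), n_reps = 3)
#' @export
init_population <- function(config = sim_config(), n_reps = 1) {
  p0 <- config$p0
  draws <- rmultinom(n_reps, config$N, c((1 - p0)^2, 2 * p0 * (1 - p0), p0^2))
  pop_tibble(draws[1, ], draws[2, ], draws[3, ])
}

#' One clonal (apomictic) generation
#'
#' Each asexual female of genotype `i` leaves a Poisson number of clonal
#' offspring with mean `f_a * w_a(i)`; genotypes breed true. Aggregated in
#' count space, the offspring count of each genotype class is a single
#' Poisson draw with mean `n_i * f_a * w_a(i)`.
#'
#' @param pop A population tibble (one row per replicate).
#' @param scheme A fitness scheme tibble, recycled across replicates.
#' @param config A [sim_config()].
#' @return The next-generation population tibble; replicates whose total
#'   offspring count is zero are extinct (all-zero rows).
#' @export
clonal_generation <- function(pop, scheme, config = sim_config()) {
  R <- nrow(pop)
  w <- scheme_cols(scheme, R)
  pop_tibble(
    rpois(R, pop$n_bb * config$f_a),
    rpois(R, pop$n_bB * config$f_a * w$wa_het),
    rpois(R, pop$n_BB * config$f_a * w$wa_hom)
  )
}

#' Produce the sexual morphs at the end of the clonal phase
#'
#' Each asexual female gives birth parthenogenetically to one sexual female
#' and one male. Sexual females are exact clones. For an autosomal locus
#' males also carry the maternal diploid genotype; for an X-linked locus
#' each male receives one maternal X, so a heterozygous mother's son is
#' `B/0` with probability 1/2 (drawn binomially over mothers).
#'
#' @inheritParams clonal_generation
#' @param location `"autosome"` or `"X"`.
#' @return A list with `females` (diploid genotype counts) and `males`
#'   (diploid counts for autosomal loci; hemizygote counts `n_b0`, `n_B0`
#'   for X-linked loci).
#' @export
produce_sexual_morphs <- function(pop, scheme, location = NULL) {
  location <- scheme_location(scheme, location)
  females <- pop_tibble(pop$n_bb, pop$n_bB, pop$n_BB, phase = "sexual")
  if (location == "X") {
    sons_B <- rbinom(nrow(pop), pop$n_bB, 0.5)
    males <- tibble(n_b0 = pop$n_bb + (pop$n_bB - sons_B),
                    n_B0 = pop$n_BB + sons_B)
  } else {
    males <- pop_tibble(pop$n_bb, pop$n_bB, pop$n_BB, phase = "sexual")
  }
  list(females = females, males = males)
}

#' Gamete pools produced by the sexual generation
#'
#' Each sexual female of genotype `i` contributes a Poisson number of
#' gametes with mean `f_s * w_f(i)`; heterozygote gametes carry `B` with
#' probability 1/2 (binomial split). Males contribute analogously with
#' `f_m` and male fitnesses; at an X-linked locus every male gamete is
#' X-bearing and carries his single X allele.
#'
#' @param morphs The list returned by [produce_sexual_morphs()].
#' @inheritParams produce_sexual_morphs
#' @param config A [sim_config()].
#' @return A tibble with one row per replicate: `B_f`, `tot_f` (mutant and
#'   total counts in the female pool) and `B_m`, `tot_m` (male pool).
#' @export
gamete_pools <- function(morphs, scheme, config = sim_config(), location = NULL) {
  location <- scheme_location(scheme, location)
  f <- morphs$females
  R <- nrow(f)
  w <- scheme_cols(scheme, R)
  g_bb <- rpois(R, f$n_bb * config$f_s)
  g_bB <- rpois(R, f$n_bB * config$f_s * w$wf_het)
  g_BB <- rpois(R, f$n_BB * config$f_s * w$wf_hom)
  B_f <- rbinom(R, g_bB, 0.5) + g_BB
  tot_f <- g_bb + g_bB + g_BB
  m <- morphs$males
  if (location == "X") {
    m_b <- rpois(R, m$n_b0 * config$f_m)
    m_B <- rpois(R, m$n_B0 * config$f_m * w$wm_B0)
    B_m <- m_B
    tot_m <- m_b + m_B
  } else {
    m_bb <- rpois(R, m$n_bb * config$f_m)
    m_bB <- rpois(R, m$n_bB * config$f_m * w$wm_het)
    m_BB <- rpois(R, m$n_BB * config$f_m * w$wm_hom)
    B_m <- rbinom(R, m_bB, 0.5) + m_BB
    tot_m <- m_bb + m_bB + m_BB
  }
  tibble(B_f = B_f, tot_f = tot_f, B_m = B_m, tot_m = tot_m)
}

#' Form the asexual females of the next cycle from the gamete pools
#'
#' `N` gametes are drawn without replacement from each pool (multivariate
#' hypergeometric on allele counts) and paired uniformly at random: with
#' `x` mutant gametes among the `N` female draws and `y` among the `N` male
#' draws, the number of `B/B` offspring is hypergeometric. Replicates whose
#' pools hold fewer than `N` gametes are flagged extinct; their frequency is
#' taken as the pooled allele frequency (0 when both pools are empty).
#'
#' @param pools The tibble returned by [gamete_pools()].
#' @param config A [sim_config()].
#' @return A list with `pop` (next-cycle population tibble), `extinct`
#'   (logical per replicate) and `freq_extinct` (the frequency recorded for
#'   extinct replicates; `NA` elsewhere).
#' @export
form_next_cycle <- function(pools, config = sim_config()) {
  N <- config$N
  R <- nrow(pools)
  short <- pools$tot_f < N | pools$tot_m < N
  freq_extinct <- rep(NA_real_, R)
  if (any(short)) {
    tot <- pools$tot_f[short] + pools$tot_m[short]
    freq_extinct[short] <-
      ifelse(tot > 0, (pools$B_f[short] + pools$B_m[short]) / tot, 0)
  }
  x <- y <- n_BB <- numeric(R)
  ok <- !short
  if (any(ok)) {
    x[ok] <- rhyper(sum(ok), pools$B_f[ok], pools$tot_f[ok] - pools$B_f[ok], N)
    y[ok] <- rhyper(sum(ok), pools$B_m[ok], pools$tot_m[ok] - pools$B_m[ok], N)
    n_BB[ok] <- rhyper(sum(ok), x[ok], N - x[ok], y[ok])
  }
  pop <- pop_tibble(N - x - y + n_BB, x + y - 2 * n_BB, n_BB)
  pop[short, c("n_bb", "n_bB", "n_BB")] <- 0
  list(pop = pop, extinct = short, freq_extinct = freq_extinct)
}

pop_freq <- function(pop) {
  tot <- pop$n_bb + pop$n_bB + pop$n_BB
  ifelse(tot > 0, (pop$n_bB + 2 * pop$n_BB) / (2 * tot), 0)
}

# Vectorized engine: runs many replicates in lockstep, retiring absorbed
# ones (mutant lost -> 0, mutant fixed -> 1, population extinct -> recorded
# pool frequency). `scheme` has one row per replicate.
run_cycles <- function(scheme, config, location) {
  location <- match_location(location)[1]
  R <- nrow(scheme)
  pop <- init_population(config, R)
  final <- rep(NA_real_, R)
  act <- seq_len(R)
  for (cy in seq_len(config$cycles)) {
    lost <- pop$n_bB + pop$n_BB == 0
    fixed <- !lost & pop$n_bb + pop$n_bB == 0
    if (any(lost)) final[act[lost]] <- 0
    if (any(fixed)) final[act[fixed]] <- 1
    keep <- !(lost | fixed)
    if (!any(keep)) return(final)
    if (!all(keep)) {
      act <- act[keep]
      pop <- pop[keep, ]
    }
    sch <- scheme[act, , drop = FALSE]
    for (g in seq_len(config$t)) {
      pop <- clonal_generation(pop, sch, config)
    }
    dead <- pop$n_bb + pop$n_bB + pop$n_BB == 0
    if (any(dead)) {
      final[act[dead]] <- 0
      act <- act[!dead]
      if (!length(act)) return(final)
      pop <- pop[!dead, ]
      sch <- scheme[act, , drop = FALSE]
    }
    morphs <- produce_sexual_morphs(pop, sch, location)
    pools <- gamete_pools(morphs, sch, config, location)
    nxt <- form_next_cycle(pools, config)
    if (any(nxt$extinct)) {
      final[act[nxt$extinct]] <- nxt$freq_extinct[nxt$extinct]
      act <- act[!nxt$extinct]
      if (!length(act)) return(final)
      pop <- nxt$pop[!nxt$extinct, ]
    } else {
      pop <- nxt$pop
    }
  }
  final[act] <- pop_freq(pop)
  final
}

#' Run replicate simulations of the aphid life cycle
#'
#' Simulates `reps` independent replicates per scheme row through
#' `config$cycles` annual cycles and returns the final mutant-allele
#' frequency among asexual females of each replicate. Replicates in which
#' the mutant is lost (or the population goes extinct) score 0; fixed
#' replicates score 1.
#'
#' @param scheme A fitness-scheme tibble; one block of `reps` replicates is
#'   run per row.
#' @param config A [sim_config()].
#' @param location `"autosome"` or `"X"`; defaults to the scheme's own
#'   `location` column.
#' @param reps Replicates per scheme row (default `config$reps`).
#' @param seed Optional integer seed.
#' @return A tibble with columns `draw` (scheme row), `rep` and `freq`.
#' @examples
#' run_replicates(fitness_scheme(s_a = 0.3), sim_config(cycles = 20), reps = 4)
#' @export
run_replicates <- function(scheme, config = sim_config(), location = NULL,
                           reps = config$reps, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  location <- scheme_location(scheme, location)[1]
  validate_scheme(scheme)
  idx <- rep(seq_len(nrow(scheme)), each = reps)
  freq <- run_cycles(scheme[idx, , drop = FALSE], config, location)
  tibble(draw = idx, rep = rep(seq_len(reps), times = nrow(scheme)),
         freq = freq)
}

#' Run a single replicate and return its final frequency
#'
#' Convenience scalar wrapper around [run_replicates()].
#'
#' @inheritParams run_replicates
#' @return The final frequency of the mutant allele (a single number).
#' @export
run_replicate <- function(scheme, config = sim_config(), location = NULL,
                          seed = NULL) {
  run_replicates(scheme, config, location, reps = 1, seed = seed)$freq
}

#' Record a full trajectory of one replicate
#'
#' Runs one replicate, recording the genotype counts of the founding
#' asexual females and the allele frequency at the start of every cycle.
#' Intended for inspection and plotting rather than sweeps.
#'
#' @inheritParams run_replicates
#' @return A tibble with columns `cycle`, `n_bb`, `n_bB`, `n_BB`, `freq`.
#' @export
run_trajectory <- function(scheme, config = sim_config(), location = NULL,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  location <- scheme_location(scheme, location)[1]
  pop <- init_population(config, 1)
  rows <- vector("list", config$cycles + 1)
  rows[[1]] <- tibble(cycle = 0L, n_bb = pop$n_bb, n_bB = pop$n_bB,
                      n_BB = pop$n_BB, freq = pop_freq(pop))
  for (cy in seq_len(config$cycles)) {
    if (pop$n_bB + pop$n_BB == 0 || pop$n_bb + pop$n_bB == 0) {
      pop2 <- pop  # absorbed: frequency constant hereafter
    } else {
      p <- pop
      for (g in seq_len(config$t)) p <- clonal_generation(p, scheme, config)
      if (p$n_bb + p$n_bB + p$n_BB == 0) {
        pop2 <- pop_tibble(0, 0, 0)
      } else {
        morphs <- produce_sexual_morphs(p, scheme, location)
        pools <- gamete_pools(morphs, scheme, config, location)
        nxt <- form_next_cycle(pools, config)
        pop2 <- nxt$pop
      }
    }
    pop <- pop2
    rows[[cy + 1]] <- tibble(cycle = cy, n_bb = pop$n_bb, n_bB = pop$n_bB,
                             n_BB = pop$n_BB, freq = pop_freq(pop))
  }
  dplyr::bind_rows(rows)
}
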