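test_that("founding populations follow Hardy-Weinberg multinomial draws", {
  set.seed(10)
  cfg <- sim_config()
  pop <- init_population(cfg, n_reps = 1e4)
  expect_true(all(pop$n_bb + pop$n_bB + pop$n_BB == cfg$N))
  # expected heterozygote count 2*p0*(1-p0)*N = 9.95
  exp_het <- 2 * cfg$p0 * (1 - cfg$p0) * cfg$N
  se <- sd(pop$n_bB) / sqrt(nrow(pop))
  expect_lt(abs(mean(pop$n_bB) - exp_het), 3 * se)
  exp_hom <- cfg$p0^2 * cfg$N
  expect_lt(abs(mean(pop$n_BB) - exp_hom), 0.02)
})

test_that("clonal reproduction is Poisson in count space", {
  set.seed(11)
  cfg <- sim_config()
  pop <- pop_tibble(rep(1000, 1e4), 0, 0)
  off <- clonal_generation(pop, fitness_scheme(), cfg)
  tot <- off$n_bb + off$n_bB + off$n_BB
  se <- sd(tot) / sqrt(length(tot))
  expect_lt(abs(mean(tot) - 2000), 3 * se)
  expect_true(all(off$n_bB == 0), info = "empty classes stay empty")
  # heterozygote with s_a = 0.5, h_a = 1: mean offspring 2 * 1.5 = 3/female
  het <- clonal_generation(pop_tibble(0, rep(1000, 5e3), 0),
                           fitness_scheme(s_a = 0.5, h_a = 1), cfg)
  se_h <- sd(het$n_bB / 1000) / sqrt(5e3)
  expect_lt(abs(mean(het$n_bB / 1000) - 3), 3 * se_h)
})

test_that("morph production copies mothers and segregates the X in sons", {
  set.seed(12)
  schx <- fitness_scheme(location = "X")
  mor <- produce_sexual_morphs(pop_tibble(0, rep(1000, 2e3), 0), schx)
  expect_equal(mor$females$n_bB, rep(1000, 2e3))
  expect_true(all(mor$males$n_b0 + mor$males$n_B0 == 1000))
  se <- sd(mor$males$n_B0) / sqrt(2e3)
  expect_lt(abs(mean(mor$males$n_B0) - 500), 3 * se)
  # autosomal locus: sons carry the maternal diploid genotype counts
  scha <- fitness_scheme()
  mora <- produce_sexual_morphs(pop_tibble(3, 5, 7), scha)
  expect_equal(mora$males$n_bB, 5)
  expect_equal(mora$males$n_BB, 7)
  # all-ancestral mothers give all-ancestral hemizygous sons
  morb <- produce_sexual_morphs(pop_tibble(100, 0, 0), schx)
  expect_equal(morb$males$n_B0, 0)
  expect_equal(morb$males$n_b0, 100)
})

test_that("gamete pools have the right Poisson/binomial structure", {
  set.seed(13)
  cfg <- sim_config()
  schx <- fitness_scheme(location = "X")
  # 100 heterozygous neutral females: total ~ Poisson(500), half mutant
  morphs <- list(females = pop_tibble(0, rep(100, 1e4), 0),
                 males = tibble::tibble(n_b0 = rep(100, 1e4), n_B0 = 0))
  pools <- gamete_pools(morphs, schx, cfg)
  se <- sd(pools$tot_f) / sqrt(1e4)
  expect_lt(abs(mean(pools$tot_f) - 500), 3 * se)
  expect_lt(abs(mean(pools$B_f / pools$tot_f) - 0.5), 0.005)
  expect_true(all(pools$B_m == 0))
  # selected hemizygous males: 10 B/0 with s_m = 0.5 -> Poisson(75), all B
  schs <- fitness_scheme(s_m = 0.5, location = "X")
  morphs2 <- list(females = pop_tibble(rep(10, 1e4), 0, 0),
                  males = tibble::tibble(n_b0 = 0, n_B0 = rep(10, 1e4)))
  pools2 <- gamete_pools(morphs2, schs, cfg)
  expect_true(all(pools2$B_m == pools2$tot_m))
  se2 <- sd(pools2$B_m) / sqrt(1e4)
  expect_lt(abs(mean(pools2$B_m) - 10 * cfg$f_m * 1.5), 3 * se2)
})

test_that("gamete union is hypergeometric and detects extinction", {
  set.seed(14)
  cfg <- sim_config()
  # forced heterozygosity: ancestral female pool, mutant male pool
  nxt <- form_next_cycle(tibble::tibble(B_f = 0, tot_f = 5000,
                                        B_m = 5000, tot_m = 5000), cfg)
  expect_equal(nxt$pop$n_bB, 1000)
  expect_false(nxt$extinct)
  # saturated pools of exactly N mutants each -> all homozygous mutant
  nxt2 <- form_next_cycle(tibble::tibble(B_f = 1000, tot_f = 1000,
                                         B_m = 1000, tot_m = 1000), cfg)
  expect_equal(nxt2$pop$n_BB, 1000)
  # mean homozygote count with half-mutant pools of size exactly N
  nxt3 <- form_next_cycle(tibble::tibble(B_f = rep(500, 1e4), tot_f = 1000,
                                         B_m = 500, tot_m = 1000), cfg)
  se <- sd(nxt3$pop$n_BB) / sqrt(1e4)
  expect_lt(abs(mean(nxt3$pop$n_BB) - 250), 3 * se)
  # undersized pool: extinct, frequency = pooled allele frequency
  nxt4 <- form_next_cycle(tibble::tibble(B_f = 10, tot_f = 100,
                                         B_m = 0, tot_m = 5000), cfg)
  expect_true(nxt4$extinct)
  expect_equal(nxt4$freq_extinct, 10 / 5100)
})

test_that("a neutral allele's final frequency is a martingale", {
  res <- run_replicates(fitness_scheme(), sim_config(), reps = 500,
                        seed = 15)
  se <- sd(res$freq) / sqrt(nrow(res))
  expect_lt(abs(mean(res$freq) - 0.005), 3 * se)
})

test_that("strong selection in asexual females decides fixation", {
  up <- run_replicates(fitness_scheme(s_a = 0.3), sim_config(), reps = 100,
                       seed = 16)
  expect_gte(mean(up$freq > 0.95), 0.95)
  down <- run_replicates(fitness_scheme(s_a = -0.3), sim_config(), reps = 100,
                         seed = 17)
  expect_gte(mean(down$freq < 0.005), 0.95)
})

test_that("the deterministic recursion preserves frequencies", {
  cfg <- sim_config()
  geno <- c(0.81, 0.18, 0.01)
  out <- expected_cycle(geno, fitness_scheme(), cfg)
  expect_equal(sum(out), 1)
  # neutral scheme: Hardy-Weinberg input is a fixed point
  expect_equal(out, geno, tolerance = 1e-12)
})

test_that("a short clonal phase weakens the dominance of asexual selection", {
  # among male-beneficial, asexual-deleterious mutations, more invade the X
  # when the cycle has a single clonal generation than with ten
  set.seed(18)
  raw <- draw_parameters(4000, "A")
  sch <- raw[raw$s_a < 0 & raw$s_m > 0, ][seq_len(500), ]
  long <- run_sweep(schemes = sch, config = sim_config(), seed = 19)
  short <- run_sweep(schemes = sch, config = sim_config(t = 1), seed = 20)
  expect_gt(mean(short$mean_freq_X >= 0.05), mean(long$mean_freq_X >= 0.05))
})

test_that("trajectories record absorbing states consistently", {
  tr <- run_trajectory(fitness_scheme(s_a = 0.4),
                       sim_config(cycles = 30), seed = 21)
  expect_equal(nrow(tr), 31)
  expect_true(all(tr$freq >= 0 & tr$freq <= 1))
  expect_true(all(tr$n_bb + tr$n_bB + tr$n_BB > 0))
})
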