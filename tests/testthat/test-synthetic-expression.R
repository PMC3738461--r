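test_that("synthetic genomes respect configured marker and gene fractions", {
  cfg <- synth_config(n_markers = 1e4, n_genes = 5000, n_scaffolds = 200,
                      n_chimeric = 0)
  g <- generate_genome(cfg, seed = 60)
  fx <- mean(g$markers$chromosome == "X")
  se <- sqrt(0.144 * (1 - 0.144) / 1e4)
  expect_lt(abs(fx - 0.144), 3 * se)
  fg <- mean(g$genes$chromosome == "X")
  seg <- sqrt(0.134 * (1 - 0.134) / 5000)
  expect_lt(abs(fg - 0.134), 3 * seg)
  # without chimeric scaffolds every scaffold's markers share one tag
  tags <- tapply(g$markers$chromosome, g$markers$scaffold,
                 function(x) length(unique(x)))
  expect_true(all(tags == 1))
  # gene geometry: spans inside their scaffold, end > start
  len <- g$scaffolds$length[match(g$genes$scaffold, g$scaffolds$scaffold)]
  expect_true(all(g$genes$start >= 1))
  expect_true(all(g$genes$end > g$genes$start))
  expect_true(all(g$genes$end <= len))
})

test_that("planted chimeric scaffolds are exactly the detectable ones", {
  cfg <- small_synth_config()
  g <- generate_genome(cfg, seed = 61)
  chim <- detect_chimeric_scaffolds(g$markers)
  truth <- g$scaffolds$scaffold[g$scaffolds$type == "chimeric"]
  expect_setequal(chim, truth)
  expect_length(chim, cfg$n_chimeric)
})

test_that("counts follow the negative-binomial generative model", {
  # tiny dispersion: variance/mean ratio near the Poisson limit;
  # large dispersion: strongly overdispersed
  null_props <- tibble::tibble(category = bias_categories(),
                               prop_A = rep(0, 6), prop_X = rep(0, 6))
  vm_ratio <- function(dispersion, seed) {
    cfg <- synth_config(n_genes = 400, n_markers = 50, n_scaffolds = 30,
                        n_chimeric = 0, depth_range = c(1e6, 1e6),
                        bias_props = null_props, dispersion = dispersion)
    ds <- synth_dataset(cfg, seed = seed)
    m <- counts_matrix(ds$counts)
    keep <- rowMeans(m) > 50
    median(apply(m[keep, ], 1, var) / rowMeans(m[keep, ]))
  }
  expect_lt(vm_ratio(1e-6, 62), 2)
  expect_gt(vm_ratio(0.5, 62), 10)
})

test_that("planted fold-changes are recovered in the raw counts", {
  cfg <- synth_config(n_genes = 2000, n_markers = 100, n_scaffolds = 40,
                      n_chimeric = 0, depth_range = c(1e6, 1e6),
                      fold_range = c(10, 10))
  ds <- synth_dataset(cfg, seed = 63)
  m <- counts_matrix(ds$counts)
  morph <- ds$design$morph[match(colnames(m), ds$design$library)]
  mm <- rowMeans(m[, morph == "M", drop = FALSE])
  mf <- rowMeans(m[, morph == "F", drop = FALSE])
  ma <- rowMeans(m[, morph == "A", drop = FALSE])
  sel <- ds$truth$category == "M+F-A-" & ds$truth$abundance > 1e-4
  expect_gt(sum(sel), 20)
  expect_gte(mean(mm[sel] / pmax(mf[sel], 1) >= 5 &
                    mm[sel] / pmax(ma[sel], 1) >= 5), 0.95)
})

test_that("library depth scales column totals proportionally", {
  cfg1 <- synth_config(n_genes = 1000, n_markers = 50, n_scaffolds = 30,
                       n_chimeric = 0, depth_range = c(1e6, 1e6))
  cfg2 <- synth_config(n_genes = 1000, n_markers = 50, n_scaffolds = 30,
                       n_chimeric = 0, depth_range = c(2e6, 2e6))
  g <- generate_genome(cfg1, seed = 64)
  truth <- plant_truth(g$genes, cfg1, seed = 65)
  c1 <- generate_counts(truth, cfg1, seed = 66)
  c2 <- generate_counts(truth, cfg2, seed = 66)
  ratio <- sum(counts_matrix(c2$counts)) / sum(counts_matrix(c1$counts))
  # 3-SE band from the generative model: heavy-tailed abundances make the
  # grand total noticeably noisy even at 10^6 reads per library
  fac <- as.matrix(truth[c("factor_M", "factor_F", "factor_A")])
  morph_of_lib <- rep(c("M", "F", "A"), c(3, 2, 3))
  cv_of <- function(depth) {
    mu <- truth$abundance * fac[, paste0("factor_", morph_of_lib)] * depth
    sqrt(sum(mu + 0.05 * mu^2)) / sum(mu)
  }
  sd_ratio <- 2 * sqrt(cv_of(1e6)^2 + cv_of(2e6)^2)
  expect_lt(abs(ratio - 2), 3 * sd_ratio)
})

test_that("datasets survive a disk round trip in standard formats", {
  ds <- synth_dataset(small_synth_config(), seed = 67)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  counts <- read_counts_tsv(file.path(dir, "counts.tsv"))
  expect_equal(counts_matrix(counts), counts_matrix(ds$counts))
  design <- read_design_tsv(file.path(dir, "design.tsv"))
  expect_equal(design$morph, ds$design$morph)
  genes <- read_gff3(file.path(dir, "genes.gff3"))
  expect_setequal(genes$gene, ds$genes$gene)
  ord <- match(ds$genes$gene, genes$gene)
  expect_equal(genes$start[ord], ds$genes$start)
  expect_equal(genes$end[ord], ds$genes$end)
  markers <- read_markers(file.path(dir, "markers.bed"))
  ordm <- match(ds$markers$marker, markers$marker)
  expect_equal(markers$pos[ordm], ds$markers$pos)
  expect_equal(markers$chromosome[ordm], ds$markers$chromosome)
  # GFF3 data rows have 9 tab-separated columns; BED starts are 0-based
  gff <- grep("^[^#]", readLines(file.path(dir, "genes.gff3")), value = TRUE)
  expect_true(all(lengths(strsplit(gff, "\t")) == 9))
  bed <- strsplit(readLines(file.path(dir, "markers.bed")), "\t")
  starts <- as.integer(vapply(bed, `[`, "", 2))
  ends <- as.integer(vapply(bed, `[`, "", 3))
  expect_true(all(starts < ends))
  expect_equal(sort(starts), sort(ds$markers$pos))
})
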