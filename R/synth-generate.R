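# Synthetic genome, marker map, gene annotation and count matrix. Counts
# are generated at the gene level: the read-mapping stage of a real study
# is upstream of this package, so the synthetic entry point is the
# post-mapping count matrix.

#' Generate a synthetic genome with markers and gene models
#'
#' Scaffolds carry a latent true chromosome (X or autosome); a configurable
#' number of them are chimeric, carrying an X segment and an autosomal
#' segment separated by a breakpoint (emulating assembly errors). Markers
#' and genes are placed uniformly on scaffolds of their true chromosome
#' (length-weighted), so markers inherit the scaffold's tag except on
#' chimeric scaffolds, which receive at least one marker of each tag.
#'
#' @param config A [synth_config()].
#' @param seed Optional integer seed.
#' @return A list with tibbles `scaffolds` (`scaffold`, `length`, `type`,
#'   `breakpoint`: X segment is `[0, breakpoint)`), `markers` (`marker`,
#'   `scaffold`, `pos` 0-based, `chromosome`), and `genes` (`gene`,
#'   `scaffold`, `start`, `end` 1-based inclusive, `length`, `chromosome`).
#' @export
generate_genome <- function(config = synth_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ns <- config$n_scaffolds
  len <- pmax(round(rlnorm(ns, config$scaffold_meanlog, config$scaffold_sdlog)),
              config$scaffold_min)
  n_chi <- config$n_chimeric
  n_x <- max(round((ns - n_chi) * config$marker_x_fraction), 1)
  type <- c(rep("chimeric", n_chi), rep("X", n_x),
            rep("A", ns - n_chi - n_x))
  scaffolds <- tibble(
    scaffold = sprintf("scaffold_%04d", seq_len(ns)),
    length = len,
    type = type,
    breakpoint = ifelse(type == "chimeric", floor(len / 2),
                        ifelse(type == "X", len, 0))
  )
  # per-scaffold X and A segment lengths: [0, breakpoint) is X
  seg_x <- scaffolds$breakpoint
  seg_a <- scaffolds$length - scaffolds$breakpoint

  place <- function(n, chrom, min_margin = 0) {
    w <- if (chrom == "X") seg_x else seg_a
    avail <- pmax(w - min_margin, 0)
    i <- sample.int(nrow(scaffolds), n, replace = TRUE, prob = avail)
    offset <- floor(runif(n) * (avail[i]))
    base <- if (chrom == "X") 0 else scaffolds$breakpoint[i]
    tibble(scaffold = scaffolds$scaffold[i], pos = base + offset)
  }

  nm <- config$n_markers
  # guarantee each chimeric scaffold carries one marker of each tag
  forced <- if (n_chi > 0) {
    chi <- scaffolds[scaffolds$type == "chimeric", ]
    dplyr::bind_rows(
      tibble(scaffold = chi$scaffold,
             pos = floor(runif(n_chi) * chi$breakpoint), chromosome = "X"),
      tibble(scaffold = chi$scaffold,
             pos = chi$breakpoint + floor(runif(n_chi) *
                                            (chi$length - chi$breakpoint)),
             chromosome = "A")
    )
  } else {
    tibble(scaffold = character(), pos = numeric(), chromosome = character())
  }
  n_free <- max(nm - nrow(forced), 0)
  n_free_x <- rbinom(1, n_free, config$marker_x_fraction)
  free <- dplyr::bind_rows(
    dplyr::mutate(place(n_free_x, "X"), chromosome = "X"),
    dplyr::mutate(place(n_free - n_free_x, "A"), chromosome = "A")
  )
  markers <- dplyr::bind_rows(forced, free)
  markers <- markers[sample.int(nrow(markers)), ]
  markers$marker <- sprintf("ms_%04d", seq_len(nrow(markers)))
  markers <- markers[c("marker", "scaffold", "pos", "chromosome")]

  ng <- config$n_genes
  glen <- pmax(round(rlnorm(ng, config$length_meanlog, config$length_sdlog)),
               config$length_min)
  is_x <- runif(ng) < config$gene_x_fraction
  pos_x <- place(sum(is_x), "X", min_margin = max(glen))
  pos_a <- place(sum(!is_x), "A", min_margin = max(glen))
  pos <- tibble(scaffold = character(ng), p = numeric(ng))
  pos$scaffold[is_x] <- pos_x$scaffold; pos$p[is_x] <- pos_x$pos
  pos$scaffold[!is_x] <- pos_a$scaffold; pos$p[!is_x] <- pos_a$pos
  genes <- tibble(
    gene = sprintf("gene_%05d", seq_len(ng)),
    scaffold = pos$scaffold,
    start = as.integer(pos$p) + 1L,            # 1-based inclusive
    end = as.integer(pos$p) + as.integer(glen),
    length = as.integer(glen),
    chromosome = ifelse(is_x, "X", "A")
  )
  list(scaffolds = scaffolds, markers = markers, genes = genes)
}

#' Plant bias categories and expression parameters on genes
#'
#' Each gene draws a morph-bias category with chromosome-dependent
#' probabilities from `config$bias_props` (the remainder are unbiased), a
#' planted fold-change (log-uniform on `config$fold_range`), a baseline
#' relative abundance, and the implied per-morph expression factors:
#' over-in-one categories set the focal morph's factor to the fold,
#' under-in-one categories set both non-focal morphs to the fold (so they
#' are within 2-fold of each other).
#'
#' @param genes The `genes` tibble of [generate_genome()].
#' @param config A [synth_config()].
#' @param seed Optional integer seed.
#' @return A truth tibble: the gene table plus `category`, `fold`,
#'   `abundance` and factors `factor_M`, `factor_F`, `factor_A`.
#' @export
plant_truth <- function(genes, config = synth_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ng <- nrow(genes)
  bp <- config$bias_props
  cats <- c(bp$category, "unbiased")
  pr_a <- c(bp$prop_A, 1 - sum(bp$prop_A))
  pr_x <- c(bp$prop_X, 1 - sum(bp$prop_X))
  u <- runif(ng)
  pick <- function(u, pr) findInterval(u, cumsum(pr), left.open = TRUE) + 1L
  category <- ifelse(genes$chromosome == "X",
                     cats[pick(u, pr_x)], cats[pick(u, pr_a)])
  lf <- log(config$fold_range)
  fold <- exp(runif(ng, lf[1], lf[2]))
  fold[category == "unbiased"] <- 1
  fac <- matrix(1, ng, 3, dimnames = list(NULL, c("M", "F", "A")))
  up <- list("M+F-A-" = "M", "M-F+A-" = "F", "M-F-A+" = "A")
  down <- list("M-F+A+" = "M", "M+F-A+" = "F", "M+F+A-" = "A")
  for (cat in names(up)) {
    sel <- category == cat
    fac[sel, up[[cat]]] <- fold[sel]
  }
  for (cat in names(down)) {
    sel <- category == cat
    others <- setdiff(colnames(fac), down[[cat]])
    fac[sel, others] <- fold[sel]
  }
  abundance <- rlnorm(ng, 0, config$baseline_sdlog)
  abundance <- abundance / sum(abundance)
  out <- genes
  out$category <- category
  out$fold <- fold
  out$abundance <- abundance
  out$factor_M <- fac[, "M"]
  out$factor_F <- fac[, "F"]
  out$factor_A <- fac[, "A"]
  out
}

#' Generate the gene-by-library count matrix
#'
#' Counts are negative-binomial: the mean of gene `g` in library `l` is
#' `abundance_g * factor_{g, morph(l)} * depth_l` (times the male-X dosage
#' factor for X-linked genes in male libraries), with variance
#' `mu + dispersion * mu^2`. Library depths are drawn uniformly from
#' `config$depth_range`.
#'
#' @param truth A truth tibble from [plant_truth()].
#' @param config A [synth_config()].
#' @param seed Optional integer seed.
#' @return A list with `counts` (tibble: `gene` plus one integer column per
#'   library) and `design` (tibble: `library`, `morph`, `depth`,
#'   `mapped_total`).
#' @export
generate_counts <- function(truth, config = synth_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  libs <- config$libraries
  morph <- rep(names(libs), times = libs)
  lib_id <- paste0(morph, unlist(lapply(libs, seq_len)))
  depth <- runif(length(lib_id), config$depth_range[1], config$depth_range[2])
  fac <- as.matrix(truth[c("factor_M", "factor_F", "factor_A")])
  colnames(fac) <- c("M", "F", "A")
  size <- 1 / config$dispersion
  ng <- nrow(truth)
  counts <- matrix(0L, ng, length(lib_id),
                   dimnames = list(truth$gene, lib_id))
  for (j in seq_along(lib_id)) {
    mu <- truth$abundance * fac[, morph[j]] * depth[j]
    if (morph[j] == "M" && config$male_x_factor != 1) {
      mu <- mu * ifelse(truth$chromosome == "X", config$male_x_factor, 1)
    }
    counts[, j] <- rnbinom(ng, mu = mu, size = size)
  }
  design <- tibble(library = lib_id, morph = morph, depth = depth,
                   mapped_total = colSums(counts))
  list(counts = counts_to_tibble(counts), design = design)
}

counts_to_tibble <- function(m) {
  out <- as_tibble(m, rownames = "gene")
  out
}

#' Convert a counts tibble to an integer matrix
#'
#' @param counts A counts tibble (first column `gene`, one column per
#'   library) or an already-formed matrix.
#' @return A numeric matrix with gene rownames.
#' @export
counts_matrix <- function(counts) {
  if (is.matrix(counts)) return(counts)
  m <- as.matrix(counts[setdiff(names(counts), "gene")])
  rownames(m) <- counts$gene
  storage.mode(m) <- "double"
  m
}

#' Generate a complete synthetic dataset
#'
#' Composes [generate_genome()], [plant_truth()] and [generate_counts()]
#' under one seed.
#'
#' @param config A [synth_config()].
#' @param seed Optional integer seed.
#' @return A list of class `"synth_dataset"` with elements `scaffolds`,
#'   `markers`, `genes`, `truth`, `counts`, `design` and the `config`.
#' @examples
#' ds <- synth_dataset(synth_config(n_genes = 200, n_markers = 60,
#'                                  n_scaffolds = 40, n_chimeric = 2),
#'                     seed = 1)
#' names(ds)
#' @export
synth_dataset <- function(config = synth_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genome <- generate_genome(config)
  truth <- plant_truth(genome$genes, config)
  cnt <- generate_counts(truth, config)
  structure(
    list(scaffolds = genome$scaffolds, markers = genome$markers,
         genes = genome$genes, truth = truth, counts = cnt$counts,
         design = cnt$design, config = config),
    class = "synth_dataset"
  )
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat("<synth_dataset>", nrow(x$genes), "genes on", nrow(x$scaffolds),
      "scaffolds;", nrow(x$markers), "markers;",
      nrow(x$design), "libraries\n")
  cat("  planted bias:", sum(x$truth$category != "unbiased"), "genes;",
      "X-linked genes:", sum(x$genes$chromosome == "X"), "\n")
  invisible(x)
}
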