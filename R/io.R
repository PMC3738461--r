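# Readers and writers for the dataset formats: TSV count matrices and
# design tables, GFF3 gene annotations and BED marker maps (through
# rtracklayer), with strict validation. GFF3 coordinates are 1-based
# inclusive; BED is 0-based half-open; both conventions are preserved on
# round-trip.

#' Read and write a gene-by-library count matrix
#'
#' `counts.tsv` has a `gene` column followed by one integer column per
#' library. Duplicate gene ids, negative counts and missing cells are
#' rejected with the offending location named.
#'
#' @param path File path.
#' @param counts Counts tibble.
#' @return `read_counts_tsv()` returns a counts tibble.
#' @export
read_counts_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  if (names(out)[1] != "gene") abort("first column of counts.tsv must be `gene`")
  dup <- which(duplicated(out$gene))
  if (length(dup)) {
    abort(paste0("duplicate gene id \"", out$gene[dup[1]], "\" at row ", dup[1]))
  }
  m <- as.matrix(out[-1])
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    abort(paste0("missing count at row ", bad[1], ", column ",
                 colnames(m)[bad[2]]))
  }
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    abort(paste0("negative count at row ", bad[1], ", column ",
                 colnames(m)[bad[2]]))
  }
  out
}

#' @rdname read_counts_tsv
#' @export
write_counts_tsv <- function(counts, path) {
  readr::write_tsv(as_tibble(counts), path)
  invisible(path)
}

#' Read and write the library design table
#'
#' `design.tsv` has columns `library` and `morph` (values `M`, `F`, `A`)
#' and optionally depth/mapped-total columns.
#'
#' @param path File path.
#' @param design Design tibble.
#' @return `read_design_tsv()` returns a design tibble.
#' @export
read_design_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("library", "morph") %in% names(out))) {
    abort("design.tsv needs columns `library` and `morph`")
  }
  bad <- which(!out$morph %in% c("M", "F", "A"))
  if (length(bad)) {
    abort(paste0("unknown morph \"", out$morph[bad[1]], "\" at design row ",
                 bad[1]))
  }
  if (anyDuplicated(out$library)) abort("duplicate library ids in design.tsv")
  out
}

#' @rdname read_design_tsv
#' @export
write_design_tsv <- function(design, path) {
  readr::write_tsv(as_tibble(design), path)
  invisible(path)
}

#' Read and write gene annotations as GFF3
#'
#' Genes are stored as `gene` features with `ID` attributes; GFF3
#' coordinates are 1-based inclusive. Reading returns the internal gene
#' tibble (`gene`, `scaffold`, `start`, `end`, `length`).
#'
#' @param path File path.
#' @param genes Gene tibble (`gene`, `scaffold`, `start`, `end`).
#' @return `read_gff3()` returns a gene tibble.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  tibble(
    gene = as.character(gr$ID),
    scaffold = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    length = GenomicRanges::width(gr)
  )
}

#' @rdname read_gff3
#' @export
write_gff3 <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$scaffold,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = "+"
  )
  gr$source <- "aphidsex"
  gr$type <- "gene"
  gr$ID <- genes$gene
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read and write the marker map
#'
#' Markers travel as BED (0-based half-open single-base intervals whose
#' name carries the marker id and X/A tag as `id|X`) or as a plain TSV with
#' columns `marker`, `scaffold`, `pos`, `chromosome`. The format is picked
#' from the file extension.
#'
#' @param path File path (`.bed` or `.tsv`).
#' @param markers Marker tibble (`marker`, `scaffold`, `pos`, `chromosome`).
#' @return `read_markers()` returns a marker tibble with 0-based `pos`.
#' @export
read_markers <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "bed")
    nm <- strsplit(as.character(gr$name), "|", fixed = TRUE)
    tags <- vapply(nm, function(x) x[length(x)], character(1))
    if (!all(tags %in% c("X", "A"))) {
      abort("BED marker names must end in |X or |A")
    }
    tibble(
      marker = vapply(nm, function(x) paste(x[-length(x)], collapse = "|"),
                      character(1)),
      scaffold = as.character(GenomicRanges::seqnames(gr)),
      pos = GenomicRanges::start(gr) - 1L,  # back to 0-based
      chromosome = tags
    )
  } else {
    out <- readr::read_tsv(path, show_col_types = FALSE)
    need <- c("marker", "scaffold", "pos", "chromosome")
    if (!all(need %in% names(out))) {
      abort("marker TSV needs columns marker, scaffold, pos, chromosome")
    }
    if (!all(out$chromosome %in% c("X", "A"))) {
      abort("marker chromosome tags must be X or A")
    }
    out[need]
  }
}

#' @rdname read_markers
#' @export
write_markers_bed <- function(markers, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = markers$scaffold,
    ranges = IRanges::IRanges(start = markers$pos + 1L, width = 1L),
    name = paste0(markers$marker, "|", markers$chromosome)
  )
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Write a synthetic dataset to a directory
#'
#' Emits `counts.tsv`, `design.tsv`, `genes.gff3`, `markers.bed`,
#' `truth.tsv` and `scaffolds.tsv`.
#'
#' @param dataset A `"synth_dataset"` from [synth_dataset()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_counts_tsv(dataset$counts, file.path(dir, "counts.tsv"))
  write_design_tsv(dataset$design, file.path(dir, "design.tsv"))
  write_gff3(dataset$genes, file.path(dir, "genes.gff3"))
  write_markers_bed(dataset$markers, file.path(dir, "markers.bed"))
  readr::write_tsv(dataset$truth, file.path(dir, "truth.tsv"))
  readr::write_tsv(dataset$scaffolds, file.path(dir, "scaffolds.tsv"))
  invisible(dir)
}

#' Run the full expression pipeline end to end
#'
#' Generates (or loads) a dataset, classifies morph-biased expression,
#' assigns genes to chromosomes from marker windows, computes the
#' enrichment table and the dosage-compensation comparisons, and writes
#' all artifacts to `dir` along with a provenance file (seed, package
#' version, configuration).
#'
#' @param dir Output directory.
#' @param config A [synth_config()] used to generate the dataset, or
#'   `NULL` to load a previously written dataset from `dir`.
#' @param window_bp Marker-window size for chromosome assignment.
#' @param alpha,folds Passed to [classify_expression()].
#' @param seed Integer seed for the synthetic generation.
#' @return Invisibly, a list with all intermediate tables.
#' @export
run_pipeline <- function(dir, config = synth_config(), window_bp = 200000,
                         alpha = 0.05, folds = c(2, 5, 10), seed = 1) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(config)) {
    counts <- read_counts_tsv(file.path(dir, "counts.tsv"))
    design <- read_design_tsv(file.path(dir, "design.tsv"))
    genes <- read_gff3(file.path(dir, "genes.gff3"))
    markers <- read_markers(file.path(dir, "markers.bed"))
  } else {
    ds <- synth_dataset(config, seed = seed)
    write_dataset(ds, dir)
    counts <- ds$counts; design <- ds$design
    genes <- ds$genes; markers <- ds$markers
  }
  calls <- classify_expression(counts, design, alpha = alpha, folds = folds)
  assignment <- assign_genes(genes, markers, window_bp)
  enr <- enrichment_table(calls, assignment)
  rp <- rpkm(counts, setNames(genes$length, genes$gene))
  me <- morph_rpkm(rp, design)
  dos <- dosage_tests(me, assignment)
  lowx <- low_expression_test(me, assignment)
  readr::write_tsv(calls, file.path(dir, "calls.tsv"))
  readr::write_tsv(assignment, file.path(dir, "assignment.tsv"))
  readr::write_tsv(enr, file.path(dir, "enrichment.tsv"))
  readr::write_tsv(dos, file.path(dir, "dosage.tsv"))
  readr::write_tsv(lowx, file.path(dir, "low_expression.tsv"))
  prov <- list(
    package = "aphidsex",
    version = as.character(utils::packageVersion("aphidsex")),
    seed = seed,
    window_bp = window_bp, alpha = alpha, folds = folds,
    generated = !is.null(config)
  )
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(counts = counts, design = design, genes = genes,
                 markers = markers, calls = calls, assignment = assignment,
                 enrichment = enr, morph_expr = me, dosage = dos,
                 low_expression = lowx))
}
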