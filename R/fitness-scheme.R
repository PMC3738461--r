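#' Construct a table of fitness schemes for one biallelic locus
#'
#' A fitness scheme describes the effect of a mutant allele `B` (relative to
#' the ancestral allele `b`) on the three aphid reproductive morphs: asexual
#' females, sexual females and males. Each morph has a selection coefficient
#' `s` (homozygous or hemizygous effect) and a dominance coefficient `h`
#' (heterozygous effect scaling), so the relative fitnesses are
#' `w(b/b) = 1`, `w(b/B) = 1 + h*s`, `w(B/B) = 1 + s` for diploid genotypes
#' and `w(b/0) = 1`, `w(B/0) = 1 + s_m` for hemizygous males at an X-linked
#' locus.
#'
#' All arguments are recycled to a common length, so the function builds
#' one-row or many-row scheme tables alike.
#'
#' @param s_a,s_f,s_m Selection coefficients in asexual females, sexual
#'   females and males; each must lie in `[-0.5, 0.5]`.
#' @param h_a,h_f,h_m Dominance coefficients in the three morphs; each must
#'   lie in `[0, 1]`.
#' @param location `"autosome"` or `"X"`: where the locus sits.
#' @return A tibble with columns `s_a`, `s_f`, `s_m`, `h_a`, `h_f`, `h_m`,
#'   `location`.
#' @examples
#' fitness_scheme(s_m = 0.2, s_a = -0.01, location = "X")
#' @export
fitness_scheme <- function(s_a = 0, s_f = 0, s_m = 0,
                           h_a = 0.5, h_f = 0.5, h_m = 0.5,
                           location = "autosome") {
  location <- match_location(location)
  out <- tibble(
    s_a = as.numeric(s_a), s_f = as.numeric(s_f), s_m = as.numeric(s_m),
    h_a = as.numeric(h_a), h_f = as.numeric(h_f), h_m = as.numeric(h_m),
    location = location
  )
  validate_scheme(out)
  out
}

match_location <- function(location) {
  loc <- as.character(location)
  ok <- loc %in% c("autosome", "A", "X")
  if (!all(ok)) {
    abort(paste0("`location` must be \"autosome\" (or \"A\") or \"X\", got: ",
                 paste(unique(loc[!ok]), collapse = ", ")))
  }
  ifelse(loc == "A", "autosome", loc)
}

validate_scheme <- function(scheme) {
  needed <- c("s_a", "s_f", "s_m", "h_a", "h_f", "h_m")
  missing <- setdiff(needed, names(scheme))
  if (length(missing)) {
    abort(paste0("scheme is missing column(s): ", paste(missing, collapse = ", ")))
  }
  s <- as.matrix(scheme[c("s_a", "s_f", "s_m")])
  h <- as.matrix(scheme[c("h_a", "h_f", "h_m")])
  if (any(!is.finite(s)) || any(s < -0.5) || any(s > 0.5)) {
    abort("selection coefficients must be finite and in [-0.5, 0.5]")
  }
  if (any(!is.finite(h)) || any(h < 0) || any(h > 1)) {
    abort("dominance coefficients must be finite and in [0, 1]")
  }
  invisible(scheme)
}

scheme_location <- function(scheme, location = NULL) {
  if (!is.null(location)) return(match_location(location))
  if ("location" %in% names(scheme)) return(match_location(scheme[["location"]]))
  "autosome"
}

#' Relative fitness of a genotype in a given morph
#'
#' Looks up the relative fitness of a genotype under a fitness scheme,
#' with the ancestral homozygote (or hemizygote) as the reference of 1.
#' Diploid genotypes are written `"b/b"`, `"b/B"`, `"B/B"`; hemizygous male
#' genotypes at X-linked loci are `"b/0"` and `"B/0"`.
#'
#' @param scheme A one-row scheme tibble from [fitness_scheme()] (or any
#'   data frame with the six coefficient columns and a `location`).
#' @param morph One of `"asexual"`, `"sexual_female"`, `"male"`.
#' @param genotype Genotype string (see Details). Hemizygous genotypes are
#'   only valid for males at X-linked loci, and conversely males at X-linked
#'   loci only have hemizygous genotypes.
#' @return A single relative fitness (positive numeric).
#' @examples
#' sc <- fitness_scheme(s_m = 0.2, h_m = 0.5)
#' genotype_fitness(sc, "male", "b/B")  # 1.1
#' @export
genotype_fitness <- function(scheme, morph, genotype) {
  validate_scheme(scheme)
  if (nrow(scheme) != 1L) abort("`scheme` must have exactly one row")
  morph <- match.arg(morph, c("asexual", "sexual_female", "male"))
  location <- scheme_location(scheme)
  hemi <- genotype %in% c("b/0", "B/0")
  dip <- genotype %in% c("b/b", "b/B", "B/B")
  if (!hemi && !dip) {
    abort(paste0("unknown genotype \"", genotype, "\""))
  }
  male_x <- morph == "male" && location == "X"
  if (male_x && !hemi) {
    abort("males are hemizygous at X-linked loci: use genotype \"b/0\" or \"B/0\"")
  }
  if (!male_x && hemi) {
    abort(paste0("hemizygous genotype \"", genotype,
                 "\" is only valid for males at X-linked loci"))
  }
  s <- switch(morph, asexual = scheme$s_a, sexual_female = scheme$s_f,
              male = scheme$s_m)
  h <- switch(morph, asexual = scheme$h_a, sexual_female = scheme$h_f,
              male = scheme$h_m)
  switch(genotype,
    "b/b" = 1, "b/0" = 1,
    "b/B" = 1 + h * s,
    "B/B" = 1 + s,
    "B/0" = 1 + s)
}

#' Per-cycle invasion growth rate of a rare allele
#'
#' Computes the multiplicative growth factor \eqn{\lambda} of the frequency
#' of a rare mutant allele over one full annual cycle (t clonal generations
#' followed by one sexual generation), from heterozygote/hemizygote
#' fitnesses only (the rare-allele limit):
#' \deqn{\lambda_A = (1 + h_a s_a)^t \, [(1 + h_f s_f) + (1 + h_m s_m)]/2}
#' \deqn{\lambda_X = (1 + h_a s_a)^t \, [(1 + h_f s_f) + (1 + s_m)]/2}
#' The allele is predicted to invade when \eqn{\lambda > 1}. For a
#' male-beneficial mutation (`s_m > 0`) with `0 < h_m < 1` the X rate always
#' exceeds the autosomal rate, because the whole male effect is exposed in
#' hemizygous males; the inequality reverses for `s_m < 0`.
#'
#' @param scheme A scheme tibble (any number of rows); see [fitness_scheme()].
#' @param t Number of clonal generations per cycle (default 10).
#' @return The input with columns `lambda_A` and `lambda_X` added, plus
#'   `lambda` (the rate at the scheme's own `location`, if present).
#' @examples
#' invasion_growth_rate(fitness_scheme(s_m = 0.2, h_m = 0.5), t = 10)
#' @export
invasion_growth_rate <- function(scheme, t = 10) {
  validate_scheme(scheme)
  if (length(t) != 1L || t < 1 || t != round(t)) {
    abort("`t` must be a single integer >= 1")
  }
  out <- as_tibble(scheme)
  clonal <- (1 + out$h_a * out$s_a)^t
  out$lambda_A <- clonal * ((1 + out$h_f * out$s_f) + (1 + out$h_m * out$s_m)) / 2
  out$lambda_X <- clonal * ((1 + out$h_f * out$s_f) + (1 + out$s_m)) / 2
  if ("location" %in% names(out)) {
    out$lambda <- ifelse(out$location == "X", out$lambda_X, out$lambda_A)
  }
  out
}

#' Predicted genomic location for an antagonistic sign pattern
#'
#' Maps the signs of the three selection coefficients of a sexually
#' antagonistic mutation to its predicted preferred genomic location
#' (X versus autosomes) and the corresponding expression-bias label expected
#' after expression modifiers silence the harmed morphs (e.g. a mutation
#' beneficial in males only, `s_m > 0, s_f < 0, s_a < 0`, is predicted to
#' accumulate on the X and end up expressed as `M+F-A-`).
#'
#' Concordant patterns (all three coefficients of the same sign) are not
#' antagonistic and raise an error.
#'
#' @param scheme A data frame with columns `s_m`, `s_f`, `s_a` (zeros are not
#'   allowed: a sign pattern needs strict signs).
#' @return A tibble with `s_m`, `s_f`, `s_a` signs, the predicted `location`
#'   (`"X"`, `"A"`, `"slight_bias_X"`, `"slight_bias_A"`) and the expression
#'   `label` (e.g. `"M+F-A-"`).
#' @examples
#' predicted_location(tibble::tibble(s_m = 0.3, s_f = -0.2, s_a = -0.1))
#' @export
predicted_location <- function(scheme) {
  need <- c("s_m", "s_f", "s_a")
  if (!all(need %in% names(scheme))) {
    abort("`scheme` needs columns s_m, s_f, s_a")
  }
  sm <- sign(scheme$s_m); sf <- sign(scheme$s_f); sa <- sign(scheme$s_a)
  if (any(sm == 0 | sf == 0 | sa == 0)) {
    abort("sign patterns require non-zero s_m, s_f, s_a")
  }
  if (any(sm == sf & sf == sa)) {
    abort("concordant pattern (all selection coefficients of the same sign) is not antagonistic")
  }
  key <- paste0(ifelse(sm > 0, "+", "-"), ifelse(sf > 0, "+", "-"),
                ifelse(sa > 0, "+", "-"))
  map <- c(
    "+--" = "X",             "++-" = "X",
    "--+" = "A",             "-++" = "A",
    "-+-" = "slight_bias_A", "+-+" = "slight_bias_X"
  )
  tibble(
    s_m = ifelse(sm > 0, "+", "-"),
    s_f = ifelse(sf > 0, "+", "-"),
    s_a = ifelse(sa > 0, "+", "-"),
    location = unname(map[key]),
    label = paste0("M", .data$s_m, "F", .data$s_f, "A", .data$s_a)
  )
}

#' Read or write fitness schemes as TSV
#'
#' Flat serialization of scheme tables: columns
#' `s_a, s_f, s_m, h_a, h_f, h_m, location`.
#'
#' @param scheme A scheme tibble.
#' @param path File path.
#' @return `read_schemes_tsv()` returns a validated scheme tibble;
#'   `write_schemes_tsv()` returns `path` invisibly.
#' @export
write_schemes_tsv <- function(scheme, path) {
  validate_scheme(scheme)
  readr::write_tsv(as_tibble(scheme), path)
  invisible(path)
}

#' @rdname write_schemes_tsv
#' @export
read_schemes_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  if ("location" %in% names(out)) out$location <- match_location(out$location)
  validate_scheme(out)
  out
}
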