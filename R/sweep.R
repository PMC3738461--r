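# Parameter sweeps: sample fitness schemes under the scenarios of the
# supplementary simulation set, run both chromosomal locations per draw,
# classify invasion outcomes, and summarize by the sign of each selection
# coefficient.

SCENARIOS <- c("A", "B", "C", "D", "E", "F", "XY")

#' Sample fitness schemes under a sweep scenario
#'
#' Selection coefficients `s_a`, `s_f`, `s_m` are drawn i.i.d. uniform on
#' `[-0.5, 0.5]`. Dominance depends on the scenario:
#' * **A** (core): one shared `h ~ U[0, 1]` for all morphs.
#' * **B**: three independent dominance coefficients `h_a`, `h_f`, `h_m`.
#' * **C**: dominance tied to the sign of selection, `h_i = 0.75` when
#'   `s_i > 0` and `h_i = 0.25` when `s_i < 0` (beneficial alleles dominant,
#'   deleterious recessive).
#' * **D**: identical selection in the two female morphs (`s_f := s_a`),
#'   shared `h`.
#' * **E**: as A; the run itself shortens the clonal phase to `t = 1`.
#' * **F**: as A; X-linked runs override `h_a = h_f = 0.5`, emulating
#'   random X inactivation in females (a dosage-compensation-like regime).
#' * **XY**: shared `h`, for the standard XX/XY control (`s_a` unused).
#'
#' @param n_draws Number of parameter sets.
#' @param scenario One of `"A"`..`"F"`, `"XY"`.
#' @param seed Optional integer seed.
#' @return A scheme tibble with a `scenario` column.
#' @examples
#' draw_parameters(5, scenario = "C", seed = 1)
#' @export
draw_parameters <- function(n_draws, scenario = "A", seed = NULL) {
  scenario <- match.arg(scenario, SCENARIOS)
  if (n_draws < 0) abort("`n_draws` must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  s_a <- runif(n_draws, -0.5, 0.5)
  s_f <- runif(n_draws, -0.5, 0.5)
  s_m <- runif(n_draws, -0.5, 0.5)
  if (scenario == "B") {
    h_a <- runif(n_draws); h_f <- runif(n_draws); h_m <- runif(n_draws)
  } else if (scenario == "C") {
    h_a <- ifelse(s_a > 0, 0.75, 0.25)
    h_f <- ifelse(s_f > 0, 0.75, 0.25)
    h_m <- ifelse(s_m > 0, 0.75, 0.25)
  } else {
    h <- runif(n_draws)
    h_a <- h; h_f <- h; h_m <- h
  }
  if (scenario == "D") s_f <- s_a
  tibble(s_a = s_a, s_f = s_f, s_m = s_m,
         h_a = h_a, h_f = h_f, h_m = h_m,
         scenario = rep(scenario, n_draws))
}

#' Classify the invasion outcome of a parameter set
#'
#' A mutation is considered to invade a chromosome type when its mean final
#' frequency (over replicates) reaches at least `hi` (default 0.05, a
#' ten-fold rise from the starting 0.005), and to not invade when the mean
#' stays below `lo` (default 0.005). The joint classes are:
#' `X_only` (invades X, not autosomes), `A_only` (the reverse), `both`,
#' `neither`, and `indeterminate` for means falling between the two
#' thresholds on either chromosome.
#'
#' @param mean_freq_X,mean_freq_A Mean final frequencies on X and autosome.
#' @param hi,lo Invasion / non-invasion thresholds.
#' @return A character vector of classes.
#' @examples
#' classify_invasion(c(0.06, 0.004, 0.03), c(0.001, 0.004, 0.02))
#' @export
classify_invasion <- function(mean_freq_X, mean_freq_A,
                              hi = 0.05, lo = 0.005) {
  stopifnot(all(mean_freq_X >= 0 & mean_freq_X <= 1),
            all(mean_freq_A >= 0 & mean_freq_A <= 1))
  dplyr::case_when(
    mean_freq_X >= hi & mean_freq_A >= hi ~ "both",
    mean_freq_X >= hi & mean_freq_A < lo ~ "X_only",
    mean_freq_A >= hi & mean_freq_X < lo ~ "A_only",
    mean_freq_X < lo & mean_freq_A < lo ~ "neither",
    TRUE ~ "indeterminate"
  )
}

#' Run an invasion sweep over sampled parameter sets
#'
#' Draws `n_draws` fitness schemes under `scenario`, runs `config$reps`
#' stochastic replicates per draw with the locus on the X and again on an
#' autosome (identical scheme both times), averages the final frequencies
#' and classifies the invasion outcome. Scenario `E` shortens the clonal
#' phase to a single generation; scenario `F` overrides `h_a = h_f = 0.5`
#' for the X-linked runs only; scenario `"XY"` runs the standard XX/XY
#' control model instead of the aphid cycle.
#'
#' @inheritParams draw_parameters
#' @param config A [sim_config()].
#' @param schemes Optionally, a pre-drawn scheme tibble (overrides
#'   `n_draws`/`scenario` sampling; a `scenario` column is honoured).
#' @return A tibble of class `"sweep_records"`: the scheme parameters plus
#'   `mean_freq_X`, `mean_freq_A` and `class`.
#' @examples
#' \donttest{
#' run_sweep(50, scenario = "A", config = sim_config(cycles = 20), seed = 1)
#' }
#' @export
run_sweep <- function(n_draws, scenario = "A", config = sim_config(),
                      seed = NULL, schemes = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(schemes)) {
    schemes <- draw_parameters(n_draws, scenario)
  } else {
    validate_scheme(schemes)
    if (!"scenario" %in% names(schemes)) schemes$scenario <- scenario
  }
  scenario <- if (nrow(schemes)) schemes$scenario[1] else scenario
  if (nrow(schemes) == 0) {
    out <- tibble(s_a = double(), s_f = double(), s_m = double(),
                  h_a = double(), h_f = double(), h_m = double(),
                  scenario = character(), mean_freq_X = double(),
                  mean_freq_A = double(), class = character())
    class(out) <- c("sweep_records", class(out))
    return(out)
  }
  if (scenario == "E") config <- modify_config(config, t = 1L)
  runner <- if (scenario == "XY") run_standard_xy else run_replicates
  schemes_x <- schemes
  if (scenario == "F") {
    schemes_x$h_a <- 0.5
    schemes_x$h_f <- 0.5
  }
  fx <- runner(schemes_x, config, location = "X")
  fa <- runner(schemes, config, location = "autosome")
  mean_by_draw <- function(res, n) {
    as.numeric(tapply(res$freq, factor(res$draw, levels = seq_len(n)), mean))
  }
  out <- schemes
  out$mean_freq_X <- mean_by_draw(fx, nrow(schemes))
  out$mean_freq_A <- mean_by_draw(fa, nrow(schemes))
  out$class <- classify_invasion(out$mean_freq_X, out$mean_freq_A)
  class(out) <- c("sweep_records", class(out))
  out
}

modify_config <- function(config, ...) {
  new <- utils::modifyList(unclass(config), list(...))
  do.call(sim_config, new)
}

#' Summarize a sweep by the sign of each selection coefficient
#'
#' For each conditioning sign (`s_m > 0`, `s_m < 0`, `s_f > 0`, ...),
#' reports the percentage of conditioning draws whose mean final frequency
#' reached the invasion threshold on the X, on the autosomes, exclusively on
#' the X, and exclusively on the autosomes (the four columns of the
#' supplementary invasion-pattern summary). Invasion on one chromosome is
#' counted irrespective of the outcome on the other; the exclusive columns
#' use the joint `X_only` / `A_only` classes.
#'
#' @param records A `"sweep_records"` tibble from [run_sweep()].
#' @param hi Invasion threshold on the mean final frequency.
#' @return A tibble of class `"sweep_summary"` with one row per sign
#'   condition: `n`, `pct_invade_X`, `pct_invade_A`, `pct_X_only`,
#'   `pct_A_only`.
#' @export
summarize_by_sign <- function(records, hi = 0.05) {
  if (!nrow(records)) abort("`records` is empty")
  conds <- list(
    "s_m>0" = records$s_m > 0, "s_m<0" = records$s_m < 0,
    "s_f>0" = records$s_f > 0, "s_f<0" = records$s_f < 0,
    "s_a>0" = records$s_a > 0, "s_a<0" = records$s_a < 0
  )
  out <- purrr::map2_dfr(conds, names(conds), function(sel, nm) {
    r <- records[sel, ]
    tibble(
      condition = nm,
      n = nrow(r),
      pct_invade_X = 100 * mean(r$mean_freq_X >= hi),
      pct_invade_A = 100 * mean(r$mean_freq_A >= hi),
      pct_X_only = 100 * mean(r$class == "X_only"),
      pct_A_only = 100 * mean(r$class == "A_only")
    )
  })
  class(out) <- c("sweep_summary", class(out))
  out
}

#' Export sweep records as a plotting-ready TSV
#'
#' Writes one row per sampled parameter set with its coefficients and
#' invasion class, suitable for external scatter plots of the invasion
#' regimes.
#'
#' @param records A `"sweep_records"` tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_classification_scatter <- function(records, path) {
  cols <- c("s_m", "s_f", "s_a", "h_a", "h_f", "h_m", "class")
  readr::write_tsv(as_tibble(records)[cols], path)
  invisible(path)
}

#' @exportS3Method generics::tidy
tidy.sweep_records <- function(x, ...) {
  as_tibble(x)
}

#' @exportS3Method generics::glance
glance.sweep_records <- function(x, ...) {
  cls <- factor(x$class,
                levels = c("X_only", "A_only", "both", "neither",
                           "indeterminate"))
  counts <- table(cls)
  tibble(
    n_draws = nrow(x),
    scenario = if (nrow(x)) x$scenario[1] else NA_character_,
    n_X_only = as.integer(counts[["X_only"]]),
    n_A_only = as.integer(counts[["A_only"]]),
    n_both = as.integer(counts[["both"]]),
    n_neither = as.integer(counts[["neither"]]),
    n_indeterminate = as.integer(counts[["indeterminate"]])
  )
}

#' Plot the invasion regimes of a sweep
#'
#' Scatter of male versus asexual-female selection coefficients, coloured
#' by invasion class and faceted by dominance tertile: the graphical
#' summary of which mutations rise on the X but not autosomes and vice
#' versa.
#'
#' @param object A `"sweep_records"` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.sweep_records <- function(object, ...) {
  df <- as_tibble(object)
  df$h_bin <- cut(df$h_m, breaks = c(0, 1 / 3, 2 / 3, 1),
                  labels = c("h < 1/3", "1/3 ≤ h < 2/3", "h ≥ 2/3"),
                  include.lowest = TRUE)
  ggplot2::ggplot(df, ggplot2::aes(.data$s_a, .data$s_m, colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$h_bin)) +
    ggplot2::labs(x = "selection in asexual females (s_a)",
                  y = "selection in males (s_m)", colour = "invasion") +
    ggplot2::theme_minimal()
}
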