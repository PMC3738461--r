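#' Simulation configuration for the annual aphid cycle
#'
#' Bundles the demographic parameters of the stochastic life-cycle
#' simulation. Defaults follow the core simulation protocol: `N = 1000`
#' founding asexual females per cycle, `t = 10` clonal generations, asexual
#' fecundity `f_a = 2`, sexual-female fecundity `f_s = 5`, initial mutant
#' frequency `p0 = 0.005` (about 10 mutant copies at start), 100 annual
#' cycles per replicate and 25 replicates per parameter set. Male fecundity
#' `f_m` is not pinned down by the morph-symmetric gametogenesis model and
#' defaults to `f_s`.
#'
#' @param N Asexual females founding each cycle (integer >= 2).
#' @param t Clonal generations per cycle (integer >= 1).
#' @param f_a,f_s,f_m Fecundities (positive): asexual females, sexual
#'   females, males.
#' @param p0 Initial frequency of the mutant allele, in (0, 1).
#' @param cycles Annual cycles per replicate (>= 1).
#' @param reps Replicates per parameter set (>= 1).
#' @return A list with class `"sim_config"`.
#' @examples
#' sim_config()
#' @export
sim_config <- function(N = 1000, t = 10, f_a = 2, f_s = 5, f_m = f_s,
                       p0 = 0.005, cycles = 100, reps = 25) {
  stopifnot(length(N) == 1, length(t) == 1, length(p0) == 1)
  if (N < 2 || N != round(N)) abort("`N` must be an integer >= 2")
  if (t < 1 || t != round(t)) abort("`t` must be an integer >= 1")
  if (f_a <= 0 || f_s <= 0 || f_m <= 0) abort("fecundities must be > 0")
  if (p0 <= 0 || p0 >= 1) abort("`p0` must be in (0, 1)")
  if (cycles < 1 || cycles != round(cycles)) abort("`cycles` must be an integer >= 1")
  if (reps < 1 || reps != round(reps)) abort("`reps` must be an integer >= 1")
  structure(
    list(N = as.integer(N), t = as.integer(t), f_a = f_a, f_s = f_s,
         f_m = f_m, p0 = p0, cycles = as.integer(cycles),
         reps = as.integer(reps)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> N =", x$N, " t =", x$t, " f_a =", x$f_a,
      " f_s =", x$f_s, " f_m =", x$f_m, "\n  p0 =", x$p0,
      " cycles =", x$cycles, " reps =", x$reps, "\n")
  invisible(x)
}
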