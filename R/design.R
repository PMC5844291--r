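#' Revertant frequency and screening-window verdict
#'
#' Spontaneous-suppressor screens are run at a restrictive temperature
#' chosen so that the revertant frequency (revertant colonies per cell
#' plated) falls between 1e-8 and 1e-6: below the window suppressors tend
#' to be intragenic; above it suppression tends to be weak and the genetic
#' interaction uninformative. Window endpoints are inclusive in
#' `"suitable"`.
#'
#' @param revertants Number of revertant colonies obtained (>= 0).
#' @param cells_plated Number of cells plated (> 0).
#' @param window Two-element frequency window, default `c(1e-8, 1e-6)`.
#' @return A `screen_design` list: `cells_plated`, `revertants_obtained`,
#'   `frequency`, `window`, `window_verdict`, and `nearest_power_of_ten`
#'   (frequencies just outside the window often still round to 1e-6, which
#'   the report makes visible).
#' @examples
#' revertant_frequency(358, 3.8e8)   # ~9.4e-7, suitable
#' revertant_frequency(56, 4.5e7)    # ~1.2e-6, above the strict window
#' @export
revertant_frequency <- function(revertants, cells_plated,
                                window = c(1e-8, 1e-6)) {
  if (cells_plated <= 0) stop("cells_plated must be > 0")
  if (revertants < 0) stop("revertants must be >= 0")
  f <- revertants / cells_plated
  verdict <- if (f < window[1]) "too_low_intragenic_bias"
             else if (f > window[2]) "too_high_weak_suppression"
             else "suitable"
  structure(list(cells_plated = cells_plated,
                 revertants_obtained = revertants, frequency = f,
                 window = window, window_verdict = verdict,
                 nearest_power_of_ten = if (f > 0) 10^round(log10(f))
                                        else NA_real_),
            class = "screen_design")
}

#' @exportS3Method base::print
print.screen_design <- function(x, ...) {
  cat(sprintf("screen_design: %g revertants / %g cells = %.3g (~1e%+d)\n",
              x$revertants_obtained, x$cells_plated, x$frequency,
              if (is.na(x$nearest_power_of_ten)) 0L
              else as.integer(round(log10(x$nearest_power_of_ten)))))
  cat("  verdict:", x$window_verdict, " (window",
      format(x$window[1]), "-", format(x$window[2]), ")\n")
  invisible(x)
}

#' Expected pool allele frequency of a suppressor
#'
#' In an equal-proportion pool of `N` revertant genomes, an allele carried
#' by `k_sharing` of them has expected read-level frequency `k_sharing/N`
#' (10% for the protocol's N = 10 private suppressor; 100% when shared by
#' all, at which point it is indistinguishable from background).
#'
#' @param N Pool size (>= 1).
#' @param k_sharing Number of revertants carrying the allele, `1..N`.
#' @return The expected allele frequency.
#' @export
expected_af <- function(N, k_sharing = 1) {
  if (k_sharing < 1 || k_sharing > N) stop("k_sharing must lie in [1, N]")
  k_sharing / N
}

#' Genomes sequenced per lane under mixture multiplexing
#'
#' Barcoding `n_mixtures` DNA mixtures of `pool_size` revertants each into
#' one sequencing lane covers `n_mixtures * pool_size` genomes while
#' handling only `n_mixtures` libraries.
#'
#' @param n_mixtures Barcoded mixtures per lane (>= 1).
#' @param pool_size Revertant genomes per mixture (>= 1).
#' @return Number of genomes per lane.
#' @examples
#' lane_multiplex(10, 10)  # 100 genomes in one lane
#' @export
lane_multiplex <- function(n_mixtures, pool_size) {
  if (n_mixtures < 1 || pool_size < 1) stop("both arguments must be >= 1")
  n_mixtures * pool_size
}

#' Power parameters for suppressor detection
#'
#' @param N Pool size.
#' @param coverage_per_genome Fold coverage per pooled genome; pooled depth
#'   is Poisson with mean `N * coverage_per_genome`.
#' @param error_rate Aggregate per-base sequencing error rate.
#' @param min_af Reporting floor (default 0.02).
#' @param alpha Family-wise level of the Bonferroni-corrected caller.
#' @param n_tests Number of tests in the Bonferroni family (3 per genome
#'   site; default 3e5 for a 100 kb toy genome).
#' @param k_sharing Revertants carrying the allele (default 1).
#' @return A `power_params` list.
#' @export
power_params <- function(N = 10, coverage_per_genome = 30,
                         error_rate = 0.002, min_af = 0.02, alpha = 0.05,
                         n_tests = 3e5, k_sharing = 1) {
  if (k_sharing < 1 || k_sharing > N) stop("k_sharing must lie in [1, N]")
  if (error_rate >= k_sharing / N)
    stop("error_rate must be below the true allele frequency k_sharing/N")
  structure(list(N = N, coverage_per_genome = coverage_per_genome,
                 error_rate = error_rate, min_af = min_af, alpha = alpha,
                 n_tests = n_tests, k_sharing = k_sharing),
            class = "power_params")
}

#' Analytic probability of calling a true suppressor allele
#'
#' Marginalises the caller's decision over the Poisson depth distribution:
#' at depth `d` a site is called when the alt count reaches both the
#' Bonferroni-corrected binomial critical value and `ceiling(min_af * d)`.
#' Reads carry the allele with effective frequency
#' `f_eff = (k/N)(1 - e) + (1 - k/N) e/3` (a carrier read may be miscalled
#' away from the allele; a non-carrier read may be miscalled into it).
#' The Poisson sum is truncated at six standard deviations. Power is
#' monotone increasing in coverage and in `k_sharing`.
#'
#' @param params A [power_params()].
#' @return The detection probability.
#' @examples
#' detection_power(power_params())  # > 0.999 at protocol defaults
#' @export
detection_power <- function(params = power_params()) {
  stopifnot(inherits(params, "power_params"))
  lambda <- params$N * params$coverage_per_genome
  if (lambda <= 0) return(0)
  f <- params$k_sharing / params$N
  e <- params$error_rate
  f_eff <- f * (1 - e) + (1 - f) * e / 3
  lo <- max(1, floor(lambda - 6 * sqrt(lambda)))
  hi <- ceiling(lambda + 6 * sqrt(lambda))
  d <- lo:hi
  wt <- stats::dpois(d, lambda)
  crit <- critical_count(d, e, params$alpha, params$n_tests)
  m <- pmax(crit, ceiling(params$min_af * d))
  sum(wt * stats::pbinom(m - 1, d, f_eff, lower.tail = FALSE))
}

## smallest alt count whose Bonferroni-corrected upper-tail p-value passes
critical_count <- function(depth, e, alpha, n_tests) {
  a <- alpha / n_tests
  stats::qbinom(a, depth, e / 3, lower.tail = FALSE) + 1L
}

#' Screen conditions of the three published suppressor screens
#'
#' The per-screen conditions table shipped with the package
#' (`inst/extdata/screen_conditions.tsv`): ts mutant, mutation site,
#' restrictive temperature, cells plated, revertants obtained, revertants
#' sequenced and distinct suppressors obtained, for the cdc48, eso1 and
#' htb1 screens. Used by the design calculators' worked examples.
#'
#' @return A data.frame with one row per screen.
#' @export
screen_conditions <- function() {
  path <- system.file("extdata", "screen_conditions.tsv",
                      package = "poolrevert", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
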