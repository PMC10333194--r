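# Dating LTR insertions from terminal-repeat divergence.
#
# The 5' and 3' terminal repeats of a retroelement are identical at
# insertion; the observed proportion of differing sites d between the pair
# is converted into a substitutions-per-site distance with the Jukes-Cantor
# correction K = -(3/4) ln(1 - 4d/3), and the insertion age is T = K / (2 mu)
# with mu the neutral substitution rate per site per year.

#' Proportion of differing sites between an aligned repeat pair
#'
#' Positions containing a non-ACGT symbol in either sequence are excluded
#' from both numerator and denominator. The repeats are assumed pre-aligned
#' and of equal length; no aligner is embedded.
#'
#' @param ltr5_seq,ltr3_seq Equal-length nucleotide strings.
#' @return The mismatch proportion `d` in `[0, 1]`.
#' @export
#' @examples
#' pair_divergence("ACGTACGTAC", "ACGTACGTAT")  # 0.1
pair_divergence <- function(ltr5_seq, ltr3_seq) {
  stopifnot(is.character(ltr5_seq), is.character(ltr3_seq),
            length(ltr5_seq) == 1L, length(ltr3_seq) == 1L)
  if (nchar(ltr5_seq) != nchar(ltr3_seq))
    stop("terminal repeats differ in length (", nchar(ltr5_seq), " vs ",
         nchar(ltr3_seq), "); supply aligned repeats")
  if (nchar(ltr5_seq) == 0L) stop("empty sequences")
  a <- strsplit(toupper(ltr5_seq), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(ltr3_seq), "", fixed = TRUE)[[1]]
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  if (!any(ok)) stop("no comparable (unambiguous) sites")
  mean(a[ok] != b[ok])
}

#' Jukes-Cantor correction of an observed divergence
#'
#' `K = -(3/4) * log(1 - 4 d / 3)`, the expected substitutions per site for
#' non-coding sequence under JC69. Vectorized.
#'
#' @param d Observed mismatch proportion(s), `0 <= d < 0.75`.
#' @return Corrected distance(s) `K >= d`.
#' @export
#' @examples
#' jc69_correct(0.10)  # 0.107326
jc69_correct <- function(d) {
  if (any(!is.finite(d))) stop("d must be finite")
  if (any(d < 0)) stop("d must be >= 0")
  if (any(d >= 0.75))
    stop("d >= 0.75 is saturated: Jukes-Cantor correction undefined")
  -0.75 * log(1 - 4 * d / 3)
}

#' Expected observed divergence at a given JC69 distance
#'
#' Inverse of [jc69_correct()]: `d = (3/4) (1 - exp(-4K/3))`. Used by the
#' synthetic-data generator and the round-trip invariants.
#'
#' @param K Substitutions per site, `K >= 0`.
#' @return Expected mismatch proportion(s).
#' @export
jc69_expected_divergence <- function(K) {
  if (any(!is.finite(K)) || any(K < 0)) stop("K must be finite and >= 0")
  0.75 * (1 - exp(-4 * K / 3))
}

#' Calibrate a synonymous molecular clock
#'
#' `mu = Ks / (2 T)`: given a mean synonymous divergence between orthologs
#' of two species and the species' divergence time, the neutral substitution
#' rate per site per year. The calibration inputs are stored with the clock.
#'
#' @param ks_mean Mean ortholog Ks (> 0).
#' @param divergence_time_years Divergence time in years (> 0).
#' @return A `molecular_clock` object with fields `mu`, `calibration_ks`,
#'   `calibration_time_years`.
#' @export
#' @examples
#' calibrate_mu(0.75, 62e6)  # mu ~ 6.0e-9 /site/year
calibrate_mu <- function(ks_mean, divergence_time_years) {
  stopifnot(length(ks_mean) == 1L, length(divergence_time_years) == 1L)
  if (!is.finite(ks_mean) || ks_mean <= 0) stop("ks_mean must be > 0")
  if (!is.finite(divergence_time_years) || divergence_time_years <= 0)
    stop("divergence_time_years must be > 0")
  structure(list(mu = ks_mean / (2 * divergence_time_years),
                 calibration_ks = ks_mean,
                 calibration_time_years = divergence_time_years),
            class = "molecular_clock")
}

#' Construct a molecular clock from a known rate
#'
#' @param mu Substitutions per site per year (> 0).
#' @return A `molecular_clock` object (calibration fields `NA`).
#' @export
molecular_clock <- function(mu) {
  if (!is.finite(mu) || mu <= 0) stop("mu must be > 0")
  structure(list(mu = mu, calibration_ks = NA_real_,
                 calibration_time_years = NA_real_),
            class = "molecular_clock")
}

#' @export
print.molecular_clock <- function(x, ...) {
  cat(sprintf("Molecular clock: mu = %.4g substitutions/site/year\n", x$mu))
  if (is.finite(x$calibration_ks))
    cat(sprintf("  calibrated from Ks = %.4g at T = %.4g My\n",
                x$calibration_ks, x$calibration_time_years / 1e6))
  invisible(x)
}

.check_clock <- function(clock) {
  if (!inherits(clock, "molecular_clock"))
    stop("clock must be a molecular_clock (see calibrate_mu())")
  if (!is.finite(clock$mu) || clock$mu <= 0) stop("invalid clock: mu <= 0")
  clock
}

#' Insertion time from a corrected repeat-pair distance
#'
#' `T = K / (2 mu)` years: the two repeats have each accumulated
#' substitutions independently since insertion, so the pair distance grows
#' at twice the per-lineage rate.
#'
#' @param K Corrected distance(s), `K >= 0`.
#' @param clock A `molecular_clock`.
#' @return Insertion time(s) in years.
#' @export
#' @examples
#' insertion_time(0.012, molecular_clock(6e-9))  # 1e6 years
insertion_time <- function(K, clock) {
  .check_clock(clock)
  if (any(!is.finite(K)) || any(K < 0)) stop("K must be finite and >= 0")
  K / (2 * clock$mu)
}

#' Date an event from a synonymous-divergence peak
#'
#' Same arithmetic as [insertion_time()] (`T = Ks / (2 mu)`), exposed for
#' dating polyploidy events from the position of a Ks-distribution peak.
#'
#' @param ks_value Ks value(s), `>= 0`.
#' @param clock A `molecular_clock`.
#' @return Age(s) in years.
#' @export
#' @examples
#' clock <- calibrate_mu(0.48, 45e6)
#' clock_age_from_ks(0.73, clock) / 1e6  # ~68.44 Mya
clock_age_from_ks <- function(ks_value, clock) {
  .check_clock(clock)
  if (any(!is.finite(ks_value)) || any(ks_value < 0))
    stop("ks_value must be finite and >= 0")
  ks_value / (2 * clock$mu)
}

#' Date every intact LTR element in a set
#'
#' Computes, per intact element, the terminal-repeat divergence `d`, the
#' JC69-corrected distance `K` and the insertion time under `clock`. A
#' cached `d` value on the element (column `d`) is used when repeat
#' sequences are absent.
#'
#' @param elements Element data frame (see [read_ltr_elements()] or
#'   [simulate_genome()]).
#' @param clock A `molecular_clock`.
#' @return A data frame with columns `element_id`, `d`, `K`, `T_years`,
#'   `T_mya` (one row per intact element).
#' @export
date_ltr_elements <- function(elements, clock) {
  .check_clock(clock)
  intact <- elements[elements$status == "intact", , drop = FALSE]
  if (nrow(intact) == 0L) stop("no intact elements to date")
  d <- vapply(seq_len(nrow(intact)), function(i) {
    if (!is.na(intact$ltr5_seq[i]) && !is.na(intact$ltr3_seq[i]))
      pair_divergence(intact$ltr5_seq[i], intact$ltr3_seq[i])
    else if (!is.na(intact$d[i]))
      intact$d[i]
    else stop("intact element ", intact$id[i],
              " has neither repeat sequences nor a cached d")
  }, numeric(1))
  K <- jc69_correct(d)
  T_years <- insertion_time(K, clock)
  data.frame(element_id = intact$id, d = d, K = K,
             T_years = T_years, T_mya = T_years / 1e6,
             stringsAsFactors = FALSE)
}

#' Insertion-age histogram
#'
#' Bins ages (in Mya) into left-closed right-open bins starting at 0.
#'
#' @param ages_mya Numeric vector of ages in Mya (non-negative, non-empty).
#' @param bin_width_mya Bin width in Mya (> 0).
#' @return A data frame with `bin_start`, `bin_end`, `count`; the mode bin's
#'   start is attached as attribute `mode_bin_start`.
#' @export
#' @examples
#' age_histogram(c(0.2, 0.2, 1.4), 1.0)
age_histogram <- function(ages_mya, bin_width_mya) {
  if (length(ages_mya) == 0L) stop("empty age set")
  if (!is.numeric(bin_width_mya) || length(bin_width_mya) != 1L ||
      !is.finite(bin_width_mya) || bin_width_mya <= 0)
    stop("bin_width_mya must be a positive number")
  if (any(!is.finite(ages_mya)) || any(ages_mya < 0))
    stop("ages must be finite and >= 0")
  idx <- floor(ages_mya / bin_width_mya)
  nbins <- max(idx) + 1L
  counts <- tabulate(idx + 1L, nbins = nbins)
  out <- data.frame(bin_start = (seq_len(nbins) - 1L) * bin_width_mya,
                    bin_end = seq_len(nbins) * bin_width_mya,
                    count = counts)
  attr(out, "mode_bin_start") <- out$bin_start[which.max(out$count)]
  out
}
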