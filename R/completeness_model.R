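#' Theoretical maximum k-mer completeness of a pseudo-haplotype assembly
#'
#' A perfectly purged pseudo-haplotype keeps exactly one allele at every
#' heterozygous locus, so k-mers unique to the discarded haplotype are
#' intentionally absent. With per-base heterozygosity `r` and independent
#' heterozygous sites, a k-mer window is allele-free with probability
#' `(1-r)^k`; the distinct k-mers of the diploid then number about
#' `G*(2-(1-r)^k)` against `G` for one haplotype, giving the ceiling
#' \deqn{C_{max} = 1 / (2 - (1-r)^k).}
#' The ceiling is strictly decreasing in both `r` and `k` and lies in
#' (0.5, 1]: even a maximally heterozygous genome retains the shared half of
#' its k-mers.
#'
#' @param r Heterozygosity rate, fraction in `[0, 1)` (e.g. 0.015 for 1.5%).
#' @param k K-mer size, integer >= 1 (default 21).
#' @return Completeness fraction in (0.5, 1]. Vectorized over `r`.
#' @examples
#' max_pseudohaplotype_completeness(0.0125, 21)  # 0.8116
#' max_pseudohaplotype_completeness(0, 21)       # 1
#' @export
max_pseudohaplotype_completeness <- function(r, k = 21L) {
  check_rate(r, "r", upper_open = TRUE)
  check_k(k)
  1 / (2 - (1 - r)^k)
}

#' Expected k-mer completeness of a purged assembly
#'
#' The pre-purge assembly typically captures only a fraction `s` of the
#' diploid read k-mers (incomplete coverage, consensus errors, collapsed
#' regions). Purging can at best retain the theoretical ceiling of that
#' starting material, so the expectation is the ceiling scaled by the
#' initial capture rate: `expected = s * maximum`.
#'
#' @param s Pre-purge k-mer completeness, fraction in `(0, 1]`.
#' @inheritParams max_pseudohaplotype_completeness
#' @return Expected completeness fraction, `<=` the ceiling.
#' @examples
#' expected_pseudohaplotype_completeness(0.9401, 0.0125, 21)  # 0.7630
#' @export
expected_pseudohaplotype_completeness <- function(s, r, k = 21L) {
  check_rate(s, "s", lower_open = TRUE)
  s * max_pseudohaplotype_completeness(r, k)
}

#' Fraction of k-mer windows overlapping a heterozygous site
#'
#' `1 - (1-r)^k`: the probability that a window of `k` consecutive bases
#' covers at least one heterozygous site, the quantity from which the
#' pseudo-haplotype ceiling is derived.
#'
#' @inheritParams max_pseudohaplotype_completeness
#' @return Fraction in `[0, 1)`. Vectorized over `r`.
#' @export
het_kmer_fraction <- function(r, k = 21L) {
  check_rate(r, "r", upper_open = TRUE)
  check_k(k)
  1 - (1 - r)^k
}

check_rate <- function(x, name, lower_open = FALSE, upper_open = FALSE) {
  lo_ok <- if (lower_open) x > 0 else x >= 0
  hi_ok <- if (upper_open) x < 1 else x <= 1
  if (anyNA(x) || !all(lo_ok & hi_ok)) {
    stop(sprintf("%s must lie in %s0, 1%s", name,
                 if (lower_open) "(" else "[", if (upper_open) ")" else "]"))
  }
  invisible(x)
}

check_k <- function(k) {
  if (length(k) != 1L || is.na(k) || k < 1 || k != floor(k)) {
    stop("k must be a single integer >= 1")
  }
  invisible(k)
}

#' Judge the quality of haplotype purging
#'
#' Compares the observed k-mer completeness of a purged assembly with the
#' expectation `s * 1/(2-(1-r)^k)` and, when sizes are supplied, the
#' assembly-to-haploid size ratio. The deviation statistic
#' `(observed - expected)` in percentage points drives a three-way verdict:
#' \describe{
#'   \item{INCOMPLETE_PURGING}{deviation above `tolerance_pp`: the assembly
#'     retains k-mers that a clean pseudo-haplotype could not hold, i.e. both
#'     haplotypes are partially present. Flagged `size_corroborated` when the
#'     size ratio also exceeds `size_band[2]`.}
#'   \item{OVER_PURGED}{deviation below `-tolerance_pp`, or size ratio below
#'     `size_band[1]`: genuine sequence was discarded.}
#'   \item{CONSISTENT}{otherwise.}
#' }
#' Thresholds default to 5 percentage points and a 0.8-1.25 size band; both
#' are configurable since the boundary between "minor purging inefficiency"
#' and "failure" is a judgment call.
#'
#' @param heterozygosity_r Heterozygosity rate, fraction in `[0, 1)`.
#' @param prepurge_completeness_s Pre-purge completeness, fraction in `(0,1]`.
#' @param observed_completeness Measured completeness of the purged assembly,
#'   fraction in `[0, 1]`.
#' @param k K-mer size (default 21).
#' @param assembly_size_bp,haploid_size_bp Optional sizes in bases; when both
#'   are given the size ratio corroborates the verdict.
#' @param tolerance_pp Verdict tolerance on the deviation, percentage points.
#' @param size_band Length-2 numeric, acceptable `assembly/haploid` ratio.
#' @return An object of class `completeness_report`: inputs plus `maximum`,
#'   `expected`, `deviation_pp`, `size_ratio`, `verdict`, `size_corroborated`.
#' @examples
#' purging_verdict(0.0456, 0.963812, 0.897580,
#'                 assembly_size_bp = 1299.6e6, haploid_size_bp = 659e6)
#' @export
purging_verdict <- function(heterozygosity_r, prepurge_completeness_s,
                            observed_completeness, k = 21L,
                            assembly_size_bp = NA_real_,
                            haploid_size_bp = NA_real_,
                            tolerance_pp = 5, size_band = c(0.8, 1.25)) {
  if (is.na(observed_completeness)) stop("observed_completeness is required")
  check_rate(observed_completeness, "observed_completeness")
  stopifnot(length(size_band) == 2L, size_band[1] < size_band[2])
  maximum <- max_pseudohaplotype_completeness(heterozygosity_r, k)
  expected <- expected_pseudohaplotype_completeness(
    prepurge_completeness_s, heterozygosity_r, k)

  size_ratio <- NA_real_
  if (!is.na(assembly_size_bp) && !is.na(haploid_size_bp)) {
    if (haploid_size_bp <= 0) stop("haploid_size_bp must be positive")
    if (assembly_size_bp <= 0) stop("assembly_size_bp must be positive")
    size_ratio <- assembly_size_bp / haploid_size_bp
  }

  deviation_pp <- (observed_completeness - expected) * 100
  size_high <- !is.na(size_ratio) && size_ratio > size_band[2]
  size_low <- !is.na(size_ratio) && size_ratio < size_band[1]

  if (deviation_pp > tolerance_pp) {
    verdict <- "INCOMPLETE_PURGING"
  } else if (deviation_pp < -tolerance_pp || size_low) {
    verdict <- "OVER_PURGED"
  } else {
    verdict <- "CONSISTENT"
  }

  structure(
    list(heterozygosity_r = heterozygosity_r,
         prepurge_completeness_s = prepurge_completeness_s,
         observed_completeness = observed_completeness, k = as.integer(k),
         assembly_size_bp = assembly_size_bp, haploid_size_bp = haploid_size_bp,
         maximum = maximum, expected = expected, deviation_pp = deviation_pp,
         size_ratio = size_ratio,
         verdict = verdict,
         size_corroborated = verdict == "INCOMPLETE_PURGING" && size_high,
         tolerance_pp = tolerance_pp, size_band = size_band),
    class = "completeness_report"
  )
}

#' @export
print.completeness_report <- function(x, ...) {
  pct <- function(v) sprintf("%.2f%%", 100 * v)
  cat(sprintf("pseudo-haplotype completeness report (k=%d)\n", x$k))
  cat(sprintf("  heterozygosity r     : %s\n", pct(x$heterozygosity_r)))
  cat(sprintf("  pre-purge s          : %s\n", pct(x$prepurge_completeness_s)))
  cat(sprintf("  maximum / expected   : %s / %s\n", pct(x$maximum), pct(x$expected)))
  cat(sprintf("  observed             : %.4f%%\n", 100 * x$observed_completeness))
  cat(sprintf("  deviation            : %+.2f pp\n", x$deviation_pp))
  if (!is.na(x$size_ratio)) {
    cat(sprintf("  assembly/haploid size: %.2f\n", x$size_ratio))
  }
  cat(sprintf("  verdict              : %s%s\n", x$verdict,
              if (isTRUE(x$size_corroborated)) " (size-corroborated)" else ""))
  invisible(x)
}
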