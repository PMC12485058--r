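#' Locate the sequencing-error cutoff in a k-mer spectrum
#'
#' Read k-mers carrying sequencing errors are mostly singletons, forming a
#' sharp peak at multiplicity 1 that decays into a valley before the genomic
#' coverage peak. The cutoff is the multiplicity at the first local minimum
#' scanning upward from m = 1; k-mers at or below it are treated as error
#' artifacts. If the histogram never falls before it rises (no error peak,
#' e.g. error-free simulated reads), the conventional fallback of 2 is
#' returned.
#'
#' @param spectrum A `kmer_spectrum`.
#' @return Integer multiplicity.
#' @examples
#' s <- read_histo(textConnection("1 1000\n2 100\n3 20\n4 50\n5 200"))
#' find_error_cutoff(s)  # 3
#' @export
find_error_cutoff <- function(spectrum) {
  h <- spectrum_dense(spectrum)
  if (length(h) == 0L || all(h == 0)) stop("empty spectrum: no k-mers counted")
  M <- length(h)
  if (M < 3L || h[2L] >= h[1L]) return(2L)
  m <- 2L
  while (m < M) {
    if (h[m] > h[m - 1L]) break           # started rising without a valley
    if (h[m + 1L] > h[m]) return(m)       # valley at m
    m <- m + 1L
  }
  2L
}

#' Estimate genome size and heterozygosity from a read k-mer spectrum
#'
#' A simplified diploid spectrum model in the spirit of GenomeScope: the
#' spectrum of whole-genome reads from a diploid shows a heterozygous
#' (1-copy) peak at the haploid k-mer coverage lambda and a homozygous
#' (2-copy) peak near 2*lambda. Peaks are located by smoothed argmax (moving
#' average, window 3) rather than mixture fitting, which is accurate enough
#' for validation work while staying dependency-light.
#'
#' Estimates:
#' \itemize{
#'   \item haploid genome size `G = sum_(m>cutoff) m*h[m] / hom_coverage`;
#'   \item heterozygosity from distinct-k-mer masses. A k-mer window is free
#'     of heterozygous sites with probability `q = (1-r)^k`; a diploid of
#'     haploid size G then carries about `G*q` distinct homozygous k-mers and
#'     `2*G*(1-q)` distinct heterozygous ones, so their ratio
#'     `rho = D_het/D_hom = 2((1-r)^-k - 1)` inverts to
#'     `r = 1 - (2/(rho+2))^(1/k)`.
#' }
#' `D_het` is summed over multiplicities in `[0.5*lambda, 1.5*lambda)` and
#' `D_hom` over `[1.5*lambda, 1.5*hom_coverage)`; the boundary at
#' `1.5*lambda` splits the inter-peak valley so neither peak's shoulder is
#' double-counted, and k-mers above `1.5*hom_coverage` (repeats) contribute
#' to the size numerator but not to the het/hom ratio. When no heterozygous
#' peak is detectable the sample is treated as effectively haploid and `r`
#' is reported as 0.
#'
#' @param spectrum A `kmer_spectrum` of whole-genome reads, at coverage high
#'   enough that the homozygous peak is resolved.
#' @param k K-mer size (defaults to `spectrum$k`).
#' @return An object of class `genome_profile`: list with `k`,
#'   `haploid_size_G` (bases), `heterozygosity_r` (fraction),
#'   `het_coverage_lambda`, `hom_coverage`, `error_cutoff`, and the distinct
#'   k-mer masses `d_het`, `d_hom`.
#' @export
fit_profile <- function(spectrum, k = spectrum$k) {
  stopifnot(inherits(spectrum, "kmer_spectrum"))
  k <- as.integer(k)
  cutoff <- find_error_cutoff(spectrum)
  h <- spectrum_dense(spectrum)
  M <- length(h)

  sm <- if (M >= 3L) {
    out <- as.numeric(stats::filter(h, rep(1 / 3, 3), sides = 2))
    out[is.na(out)] <- h[is.na(out)]
    out
  } else h
  genomic <- sm
  if (cutoff >= 1L) genomic[seq_len(min(cutoff, M))] <- 0

  if (all(genomic <= 0)) stop("unfittable spectrum: no peak above the error cutoff")
  P <- which.max(genomic)

  is_local_max <- function(m) {
    m >= 1L && m <= M &&
      (m == 1L || sm[m] >= sm[m - 1L]) && (m == M || sm[m] >= sm[m + 1L])
  }
  window_peak <- function(lo, hi, min_height) {
    lo <- max(lo, cutoff + 1L)
    hi <- min(hi, M)
    if (lo > hi) return(NA_integer_)
    w <- lo:hi
    cand <- w[which.max(sm[w])]
    if (is_local_max(cand) && sm[cand] >= min_height) cand else NA_integer_
  }

  lower <- window_peak(round(0.35 * P), round(0.65 * P), 0.10 * sm[P])
  upper <- window_peak(round(1.60 * P), round(2.60 * P), 0.05 * sm[P])

  if (!is.na(lower)) {          # global peak is the homozygous one
    lambda <- lower; hom <- P
  } else if (!is.na(upper)) {   # global peak is the heterozygous one
    lambda <- P; hom <- upper
  } else {                      # single peak: effectively haploid
    lambda <- P / 2; hom <- P
  }
  diploid <- !is.na(lower) || !is.na(upper)

  if (diploid && abs(hom - 2 * lambda) > 0.25 * 2 * lambda) {
    warning(sprintf(
      "homozygous peak at %d is far from twice the heterozygous peak at %s",
      hom, format(lambda)))
  }

  m <- seq_len(M)
  G <- sum(m[m > cutoff] * h[m > cutoff]) / hom

  if (diploid) {
    in_het <- m > cutoff & m >= 0.5 * lambda & m < 1.5 * lambda
    in_hom <- m >= 1.5 * lambda & m < 1.5 * hom
    d_het <- sum(h[in_het])
    d_hom <- sum(h[in_hom])
    if (d_hom <= 0) stop("unfittable spectrum: empty homozygous peak window")
    rho <- d_het / d_hom
    r <- 1 - (2 / (rho + 2))^(1 / k)
  } else {
    in_hom <- m > cutoff & m >= 0.5 * hom & m < 1.5 * hom
    d_het <- 0
    d_hom <- sum(h[in_hom])
    r <- 0
  }

  structure(
    list(k = k, haploid_size_G = G, heterozygosity_r = r,
         het_coverage_lambda = as.numeric(lambda), hom_coverage = as.numeric(hom),
         error_cutoff = as.integer(cutoff), d_het = d_het, d_hom = d_hom),
    class = "genome_profile"
  )
}

#' @export
print.genome_profile <- function(x, ...) {
  cat(sprintf("genome_profile (k=%d)\n", x$k))
  cat(sprintf("  haploid genome size : %s bp\n",
              format(round(x$haploid_size_G), big.mark = ",", scientific = FALSE)))
  cat(sprintf("  heterozygosity      : %.4f%%\n", 100 * x$heterozygosity_r))
  cat(sprintf("  het / hom coverage  : %s / %s\n",
              format(x$het_coverage_lambda), format(x$hom_coverage)))
  cat(sprintf("  error cutoff        : %d\n", x$error_cutoff))
  invisible(x)
}

#' Serialize a genome profile to JSON
#'
#' @param profile A `genome_profile`.
#' @param path Optional output path; if `NULL` the JSON string is returned.
#' @return JSON string, or `path` invisibly when written to file.
#' @export
profile_json <- function(profile, path = NULL) {
  stopifnot(inherits(profile, "genome_profile"))
  js <- jsonlite::toJSON(unclass(profile), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
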