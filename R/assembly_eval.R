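#' Merqury-style assembly k-mer completeness
#'
#' The fraction of reliable distinct read k-mers that are present in the
#' assembly. Reliable means multiplicity at or above `reliable_cutoff`, which
#' defaults to one above the error-peak valley of the read spectrum (see
#' [find_error_cutoff()]), so sequencing-error k-mers do not deflate the
#' denominator.
#'
#' @param assembly_db `kmer_db` of the assembly.
#' @param read_db `kmer_db` of the reads; must use the same `k`.
#' @param reliable_cutoff Minimum read multiplicity for a k-mer to count as
#'   genomic. `NULL` (default) derives it from the read spectrum.
#' @return Completeness fraction in `[0, 1]`.
#' @export
kmer_completeness <- function(assembly_db, read_db, reliable_cutoff = NULL) {
  stopifnot(inherits(assembly_db, "kmer_db"), inherits(read_db, "kmer_db"))
  if (assembly_db$k != read_db$k) {
    stop("assembly and read databases use different k")
  }
  if (is.null(reliable_cutoff)) {
    reliable_cutoff <- find_error_cutoff(kmer_spectrum(read_db)) + 1L
  }
  reliable <- read_db$key[read_db$count >= reliable_cutoff]
  if (length(reliable) == 0L) {
    stop("no reliable read k-mers at cutoff ", reliable_cutoff,
         "; completeness is undefined")
  }
  sum(reliable %in% assembly_db$key) / length(reliable)
}

#' Consensus quality value (QV) from k-mer agreement
#'
#' Merqury-style base-accuracy estimate: assembly k-mer positions (counted
#' with multiplicity) that are absent from the reads are taken as evidence of
#' consensus error. If a fraction `shared/total` of positions is supported,
#' the per-base error rate is `E = 1 - (shared/total)^(1/k)` (an error
#' corrupts up to k overlapping k-mers) and `QV = -10*log10(E)`. When every
#' assembly k-mer is read-supported, `E = 0` and the QV is reported capped.
#'
#' @param assembly_db `kmer_db` of the assembly (positional counts).
#' @param read_db `kmer_db` of the reads; presence means multiplicity >= 1.
#' @param qv_cap QV to report when no assembly-only k-mers exist (default 99).
#' @return An object of class `qv_report`: list with `k`,
#'   `total_assembly_kmers`, `shared_kmers`, `error_rate_E`, `qv`, `capped`.
#' @export
qv_estimate <- function(assembly_db, read_db, qv_cap = 99) {
  stopifnot(inherits(assembly_db, "kmer_db"), inherits(read_db, "kmer_db"))
  if (assembly_db$k != read_db$k) {
    stop("assembly and read databases use different k")
  }
  if (assembly_db$total_positions <= 0) stop("empty assembly k-mer database")
  in_reads <- assembly_db$key %in% read_db$key
  shared <- sum(as.numeric(assembly_db$count[in_reads]))
  qv_from_kmer_tallies(shared, assembly_db$total_positions, assembly_db$k,
                       qv_cap = qv_cap)
}

#' @param shared,total Assembly k-mer positions found in / ingested in total.
#' @param k K-mer size.
#' @rdname qv_estimate
#' @export
qv_from_kmer_tallies <- function(shared, total, k, qv_cap = 99) {
  stopifnot(total > 0, shared >= 0, shared <= total)
  P <- (shared / total)^(1 / k)
  E <- 1 - P
  capped <- E <= 0
  qv <- if (capped) qv_cap else -10 * log10(E)
  structure(
    list(k = as.integer(k), total_assembly_kmers = total,
         shared_kmers = shared, error_rate_E = E, qv = qv, capped = capped),
    class = "qv_report"
  )
}

#' @export
print.qv_report <- function(x, ...) {
  cat(sprintf("qv_report: QV = %.2f%s (k=%d)\n", x$qv,
              if (x$capped) " [capped]" else "", x$k))
  cat(sprintf("  %s of %s assembly k-mer positions read-supported\n",
              format(x$shared_kmers, big.mark = ",", scientific = FALSE),
              format(x$total_assembly_kmers, big.mark = ",", scientific = FALSE)))
  if (!x$capped) {
    conv <- error_rate_from_qv(x$qv)
    cat(sprintf("  ~1 consensus error in %s bases\n",
                format(conv$one_error_in, big.mark = ",", scientific = FALSE)))
  }
  invisible(x)
}

#' Convert a Phred-scaled QV to an error rate
#'
#' @param qv Phred-scaled quality value, `>= 0`.
#' @return List with `error_rate` (`10^(-qv/10)`) and `one_error_in`, the
#'   reciprocal rounded to 3 significant figures ("1 error in N bases").
#' @examples
#' error_rate_from_qv(33.47)$one_error_in  # 2220
#' @export
error_rate_from_qv <- function(qv) {
  stopifnot(all(qv >= 0))
  error_rate <- 10^(-qv / 10)
  list(error_rate = error_rate, one_error_in = signif(1 / error_rate, 3))
}

#' Basic assembly statistics
#'
#' Total length, GC fraction (over unambiguous A/C/G/T bases only), sequence
#' count, and N50/N90. NXX is the length L such that sequences of length
#' `>= L` sum to at least XX% of the assembly (descending sort, first length
#' reaching the threshold).
#'
#' @param sequences Character vector or `DNAStringSet`; at least one
#'   non-empty sequence.
#' @return An object of class `assembly_stats`: list with `total_length_bp`,
#'   `gc_fraction`, `n_sequences`, `n50_bp`, `n90_bp`.
#' @examples
#' assembly_stats(c(a = "GGCC", b = "ATATAT"))
#' @export
assembly_stats <- function(sequences) {
  x <- Biostrings::DNAStringSet(as_sequence_chars(sequences))
  if (length(x) == 0L || sum(Biostrings::width(x)) == 0L) {
    stop("assembly_stats requires at least one non-empty sequence")
  }
  lens <- Biostrings::width(x)
  freq <- Biostrings::letterFrequency(x, c("A", "C", "G", "T"))
  acgt <- sum(freq)
  gc <- if (acgt > 0) sum(freq[, c("C", "G")]) / acgt else NA_real_
  structure(
    list(total_length_bp = sum(as.numeric(lens)), gc_fraction = gc,
         n_sequences = length(x),
         n50_bp = nxx(lens, 0.5), n90_bp = nxx(lens, 0.9)),
    class = "assembly_stats"
  )
}

nxx <- function(lengths, frac) {
  lens <- sort(lengths, decreasing = TRUE)
  lens[which(cumsum(as.numeric(lens)) >= frac * sum(as.numeric(lens)))[1L]]
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat(sprintf("assembly_stats: %s bp in %d sequences\n",
              format(x$total_length_bp, big.mark = ",", scientific = FALSE),
              x$n_sequences))
  cat(sprintf("  N50 %s bp, N90 %s bp, GC %.2f%%\n",
              format(x$n50_bp, big.mark = ",", scientific = FALSE),
              format(x$n90_bp, big.mark = ",", scientific = FALSE),
              100 * x$gc_fraction))
  invisible(x)
}

#' One-stop purging QC from sequences
#'
#' Runs the full validation chain on in-memory sequences: counts read
#' k-mers, fits the genome profile (heterozygosity and haploid size),
#' measures the pre-purge completeness `s` from the unpurged assembly and
#' the observed completeness of the final assembly, and returns the
#' [purging_verdict()] report. The estimated haploid size and the final
#' assembly size feed the size-ratio corroboration.
#'
#' @param assembly Final (purged) assembly sequences.
#' @param prepurge_assembly Assembly before purging, used to measure `s`.
#'   May be `NULL` if `s` is supplied directly.
#' @param reads Read sequences.
#' @param k K-mer size (default 21).
#' @param s Optional pre-purge completeness fraction, overriding measurement.
#' @param ... Passed to [purging_verdict()] (thresholds).
#' @return A `completeness_report` with an extra `profile` element.
#' @export
purging_qc <- function(assembly, prepurge_assembly = NULL, reads, k = 21L,
                       s = NULL, ...) {
  asm <- as_sequence_chars(assembly)
  rds <- as_sequence_chars(reads)
  read_db <- count_kmers(rds, k)
  profile <- fit_profile(kmer_spectrum(read_db), k)
  cutoff <- profile$error_cutoff + 1L
  asm_db <- count_kmers(asm, k)
  observed <- kmer_completeness(asm_db, read_db, cutoff)
  if (is.null(s)) {
    if (is.null(prepurge_assembly)) {
      stop("supply either prepurge_assembly or s")
    }
    pre_db <- count_kmers(as_sequence_chars(prepurge_assembly), k)
    s <- kmer_completeness(pre_db, read_db, cutoff)
  }
  report <- purging_verdict(
    heterozygosity_r = profile$heterozygosity_r,
    prepurge_completeness_s = s, observed_completeness = observed, k = k,
    assembly_size_bp = sum(nchar(asm)),
    haploid_size_bp = profile$haploid_size_G, ...)
  report$profile <- profile
  report
}
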