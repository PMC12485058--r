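#' Simulate a haploid genome sequence
#'
#' I.i.d. bases with a target GC content and no simulated repeats, so that
#' distinct-k-mer arithmetic (the basis of the completeness model) holds
#' essentially exactly. The default GC of 0.37 matches a typical plant
#' nuclear genome.
#'
#' @param length_bp Sequence length in bases.
#' @param gc_target Target GC fraction, strictly between 0 and 1.
#' @param seed Integer seed; the same seed always yields the same sequence.
#' @return A single DNA string.
#' @export
simulate_haploid <- function(length_bp, gc_target = 0.37, seed = 1L) {
  stopifnot(length_bp >= 1)
  if (!is.numeric(gc_target) || gc_target <= 0 || gc_target >= 1) {
    stop("gc_target must lie strictly between 0 and 1")
  }
  with_seed(seed, {
    bases <- sample(c("A", "C", "G", "T"), length_bp, replace = TRUE,
                    prob = c((1 - gc_target) / 2, gc_target / 2,
                             gc_target / 2, (1 - gc_target) / 2))
    paste(bases, collapse = "")
  })
}

# For each base (row), the three possible substitution targets.
.SUB_TARGETS <- matrix(
  c("C", "G", "T",   # A ->
    "A", "G", "T",   # C ->
    "A", "C", "T",   # G ->
    "A", "C", "G"),  # T ->
  nrow = 4, byrow = TRUE,
  dimnames = list(c("A", "C", "G", "T"), NULL))

#' Derive a second haplotype by planting SNPs
#'
#' Substitutes each position independently with probability `r`; a
#' substitution always changes the base (uniform over the three
#' alternatives). This implements the independent per-base heterozygosity
#' assumption under which the pseudo-haplotype completeness ceiling
#' `1/(2-(1-r)^k)` is exact. Indels and structural variants are deliberately
#' not modeled.
#'
#' @param sequence DNA string (haplotype A).
#' @param r Per-base substitution probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return List with `sequence_B` (the mutated haplotype) and
#'   `snp_positions` (0-based positions where the haplotypes differ).
#' @export
mutate_haplotype <- function(sequence, r, seed = 1L) {
  stopifnot(is.character(sequence), length(sequence) == 1L, r >= 0, r <= 1)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  with_seed(seed, {
    hit <- which(runif(length(chars)) < r)
    if (length(hit)) {
      alt_idx <- sample.int(3L, length(hit), replace = TRUE)
      base_idx <- match(chars[hit], c("A", "C", "G", "T"))
      chars[hit] <- .SUB_TARGETS[cbind(base_idx, alt_idx)]
    }
    list(sequence_B = paste(chars, collapse = ""), snp_positions = hit - 1L)
  })
}

#' Simulate shotgun reads from one or two haplotypes
#'
#' Draws reads of fixed length from uniformly random start positions on a
#' randomly chosen haplotype and strand until total read bases reach
#' `coverage` times the summed haplotype length (so `coverage` is the
#' per-haplotype fold coverage). Optional i.i.d. per-base substitution
#' errors. Fully deterministic given the seed.
#'
#' @param haplotypes Character vector of one or two haplotype sequences.
#' @param coverage Per-haplotype fold coverage (> 0).
#' @param read_length Read length; must not exceed any haplotype length.
#' @param error_rate Per-base substitution error probability (default 0).
#' @param seed Integer seed.
#' @return Named character vector of reads.
#' @export
simulate_reads <- function(haplotypes, coverage = 30, read_length = 150L,
                           error_rate = 0, seed = 1L) {
  haps <- as_sequence_chars(haplotypes)
  lens <- nchar(haps)
  stopifnot(coverage > 0, read_length >= 1, all(read_length <= lens),
            error_rate >= 0, error_rate < 1)
  n_reads <- ceiling(coverage * sum(as.numeric(lens)) / read_length)
  with_seed(seed, {
    hap_idx <- sample.int(length(haps), n_reads, replace = TRUE)
    max_start <- lens[hap_idx] - read_length + 1L
    start <- 1L + floor(runif(n_reads) * max_start)
    reads <- substring(haps[hap_idx], start, start + read_length - 1L)
    rev_strand <- runif(n_reads) < 0.5
    if (any(rev_strand)) {
      reads[rev_strand] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(reads[rev_strand])))
    }
    if (error_rate > 0) {
      n_bases <- n_reads * read_length
      n_err <- rbinom(1L, n_bases, error_rate)
      if (n_err > 0) {
        pos <- sample(n_bases, n_err)
        ri <- (pos - 1L) %/% read_length + 1L
        off <- (pos - 1L) %% read_length + 1L
        for (j in seq_len(n_err)) {
          cur <- substr(reads[ri[j]], off[j], off[j])
          bi <- match(cur, c("A", "C", "G", "T"))
          substr(reads[ri[j]], off[j], off[j]) <-
            .SUB_TARGETS[bi, sample.int(3L, 1L)]
        }
      }
    }
    names(reads) <- sprintf("read%07d", seq_len(n_reads))
    reads
  })
}

#' Simulate a diploid genome with known truth
#'
#' Builds haplotype A de novo, plants SNPs at rate `heterozygosity_r` to
#' obtain haplotype B, and records everything needed to regenerate reads and
#' assembly fixtures. Sub-seeds for the mutation and read-simulation steps
#' are derived deterministically from `seed` so the three stages remain
#' independently reproducible.
#'
#' @param length_bp Haploid genome length (default 1 Mb).
#' @param heterozygosity_r Per-base heterozygosity in `[0, 1)` (default
#'   0.015, a typical outcrossing-crop rate).
#' @param gc_target GC fraction (default 0.37).
#' @param read_coverage Per-haplotype fold coverage for reads (default 30).
#' @param read_length Read length (default 150, short-read scale).
#' @param read_error_rate Per-base read error rate (default 0: error-free).
#' @param seed Integer seed.
#' @return An object of class `diploid_truth`: list with the simulation
#'   parameters, `haplotype_A`, `haplotype_B` and 0-based `snp_positions`.
#' @export
simulate_diploid <- function(length_bp = 1e6, heterozygosity_r = 0.015,
                             gc_target = 0.37, read_coverage = 30,
                             read_length = 150L, read_error_rate = 0,
                             seed = 1L) {
  check_rate(heterozygosity_r, "heterozygosity_r", upper_open = TRUE)
  hapA <- simulate_haploid(length_bp, gc_target, seed = derive_seed(seed, 1L))
  mut <- mutate_haplotype(hapA, heterozygosity_r, seed = derive_seed(seed, 2L))
  structure(
    list(seed = as.integer(seed), length_bp = length_bp,
         gc_target = gc_target, heterozygosity_r = heterozygosity_r,
         haplotype_A = hapA, haplotype_B = mut$sequence_B,
         snp_positions = mut$snp_positions,
         read_coverage = read_coverage, read_length = as.integer(read_length),
         read_error_rate = read_error_rate),
    class = "diploid_truth"
  )
}

# Distinct sub-streams per simulation stage; kept below 2^31.
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 7L + stage * 1000003) %% 2147483647)
}

#' @export
print.diploid_truth <- function(x, ...) {
  cat(sprintf("diploid_truth: %s bp, r=%.4f (%d SNPs), GC %.2f, seed %d\n",
              format(x$length_bp, big.mark = ",", scientific = FALSE),
              x$heterozygosity_r, length(x$snp_positions), x$gc_target,
              x$seed))
  invisible(x)
}

#' Reads for a simulated diploid
#'
#' Convenience wrapper generating the read set recorded in a
#' [simulate_diploid()] truth object (both haplotypes, the stored coverage,
#' length and error rate, and a sub-seed derived from the truth seed).
#'
#' @param truth A `diploid_truth`.
#' @return Named character vector of reads.
#' @export
truth_reads <- function(truth) {
  stopifnot(inherits(truth, "diploid_truth"))
  simulate_reads(c(truth$haplotype_A, truth$haplotype_B),
                 coverage = truth$read_coverage,
                 read_length = truth$read_length,
                 error_rate = truth$read_error_rate,
                 seed = derive_seed(truth$seed, 3L))
}

#' Write assembly/read fixtures for a simulated diploid
#'
#' Materializes the two canonical evaluation scenarios: a correctly purged
#' pseudo-haplotype (`purged.fasta` = haplotype A only) and an unpurged,
#' fully diploid assembly (`unpurged.fasta` = both haplotypes), together
#' with the simulated reads (`reads.fastq`) and a JSON truth record
#' (`truth.json`, sequences omitted). On such fixtures the purged assembly
#' should be judged CONSISTENT and the unpurged one INCOMPLETE_PURGING with
#' a size ratio near 2.
#'
#' @param truth A `diploid_truth` from [simulate_diploid()].
#' @param dir Output directory (created if needed).
#' @return List of file paths (`purged_assembly`, `unpurged_assembly`,
#'   `reads`, `truth_record`), invisibly.
#' @export
make_fixtures <- function(truth, dir) {
  stopifnot(inherits(truth, "diploid_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    purged_assembly = file.path(dir, "purged.fasta"),
    unpurged_assembly = file.path(dir, "unpurged.fasta"),
    reads = file.path(dir, "reads.fastq"),
    truth_record = file.path(dir, "truth.json")
  )
  write_fasta(c(hapA = truth$haplotype_A), paths$purged_assembly)
  write_fasta(c(hapA = truth$haplotype_A, hapB = truth$haplotype_B),
              paths$unpurged_assembly)
  write_fastq(truth_reads(truth), paths$reads)
  rec <- unclass(truth)
  rec$haplotype_A <- NULL
  rec$haplotype_B <- NULL
  rec$n_snps <- length(truth$snp_positions)
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA),
             paths$truth_record)
  invisible(paths)
}
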