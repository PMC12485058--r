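# Simulated-diploid fixtures shared between the stochastic validation tests.
# Full-scale fixtures (1 Mb, 30x error-free reads per haplotype) are built
# once per (r, seed) and their summary statistics cached; the bulky k-mer
# databases are not retained.

.fixture_cache <- new.env(parent = emptyenv())

# Summary of one simulated diploid: the fitted read-spectrum profile and the
# observed k-mer completeness of haplotype A against the diploid reads.
diploid_fixture_summary <- function(r, seed, length_bp = 1e6) {
  key <- sprintf("r%g_seed%d_L%g", r, seed, length_bp)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  truth <- simulate_diploid(length_bp = length_bp, heterozygosity_r = r,
                            seed = seed)
  read_db <- count_kmers(truth_reads(truth), 21)
  profile <- fit_profile(kmer_spectrum(read_db))
  hap_db <- count_kmers(truth$haplotype_A, 21)
  observed <- kmer_completeness(hap_db, read_db, profile$error_cutoff + 1L)
  res <- list(r = r, seed = seed, length_bp = length_bp,
              n_snps = length(truth$snp_positions),
              r_hat = profile$heterozygosity_r,
              G_hat = profile$haploid_size_G,
              error_cutoff = profile$error_cutoff,
              observed_completeness = observed)
  .fixture_cache[[key]] <- res
  res
}

# Small diploid (200 kb) reused by unit tests; retains the databases.
small_diploid_fixture <- function() {
  if (!is.null(.fixture_cache[["small"]])) return(.fixture_cache[["small"]])
  truth <- simulate_diploid(length_bp = 2e5, heterozygosity_r = 0.02,
                            read_coverage = 25, seed = 42)
  read_db <- count_kmers(truth_reads(truth), 21)
  profile <- fit_profile(kmer_spectrum(read_db))
  res <- list(truth = truth, read_db = read_db, profile = profile)
  .fixture_cache[["small"]] <- res
  res
}
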