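test_that("haploid simulation is deterministic and honors GC target", {
  a <- simulate_haploid(1000, gc_target = 0.37, seed = 1)
  b <- simulate_haploid(1000, gc_target = 0.37, seed = 1)
  expect_identical(a, b)
  expect_false(identical(a, simulate_haploid(1000, gc_target = 0.37, seed = 2)))

  gc <- assembly_stats(a)$gc_fraction
  expect_lt(abs(gc - 0.37), 0.05)
  expect_error(simulate_haploid(1000, gc_target = 0), "between 0 and 1")
  expect_error(simulate_haploid(1000, gc_target = 1), "between 0 and 1")
})

test_that("mutation plants the expected SNPs and always changes the base", {
  s <- simulate_haploid(5000, seed = 3)
  same <- mutate_haplotype(s, 0, seed = 4)
  expect_identical(same$sequence_B, s)
  expect_length(same$snp_positions, 0L)

  all_diff <- mutate_haplotype(s, 1, seed = 4)
  a <- strsplit(s, "")[[1]]
  b <- strsplit(all_diff$sequence_B, "")[[1]]
  expect_true(all(a != b))

  # binomial 3-sigma bound on the SNP count at r = 0.015 over 100 kb
  s2 <- simulate_haploid(1e5, seed = 6)
  mut <- mutate_haplotype(s2, 0.015, seed = 7)
  expect_lt(abs(length(mut$snp_positions) - 1500),
            3 * sqrt(1e5 * 0.015 * 0.985))
  # recorded positions are exactly where the haplotypes differ (0-based)
  a2 <- strsplit(s2, "")[[1]]
  b2 <- strsplit(mut$sequence_B, "")[[1]]
  expect_identical(which(a2 != b2) - 1L, mut$snp_positions)
})

test_that("read simulation hits the coverage target deterministically", {
  truth <- simulate_diploid(length_bp = 5e4, heterozygosity_r = 0.015, seed = 9)
  reads <- truth_reads(truth)
  total_bases <- sum(nchar(reads))
  expect_lt(abs(total_bases / (2 * truth$length_bp) - truth$read_coverage) /
              truth$read_coverage, 0.02)

  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  write_fastq(truth_reads(truth), f1)
  write_fastq(truth_reads(truth), f2)
  expect_identical(readLines(f1), readLines(f2))  # byte-identical under seed
})

test_that("error-free read k-mers all originate from the two haplotypes", {
  truth <- simulate_diploid(length_bp = 3e4, heterozygosity_r = 0.02, seed = 10)
  reads <- truth_reads(truth)
  read_db <- count_kmers(reads, 21)
  union_db <- count_kmers(c(truth$haplotype_A, truth$haplotype_B), 21)
  expect_true(all(read_db$key %in% union_db$key))
})

test_that("error-bearing reads introduce novel k-mers at the expected scale", {
  genome <- simulate_haploid(3e4, seed = 15)
  clean <- simulate_reads(genome, coverage = 10, error_rate = 0, seed = 16)
  noisy <- simulate_reads(genome, coverage = 10, error_rate = 0.005, seed = 16)
  db_clean <- count_kmers(clean, 21)
  db_noisy <- count_kmers(noisy, 21)
  expect_gt(db_noisy$n_distinct, db_clean$n_distinct)
  # the error peak makes singleton k-mers dominate the low end
  sp <- kmer_spectrum(db_noisy)
  expect_gt(sp$count[sp$multiplicity == 1], 0.1 * db_noisy$n_distinct)
})

test_that("diploid truth object satisfies its own invariants", {
  truth <- simulate_diploid(length_bp = 2e4, heterozygosity_r = 0.03, seed = 21)
  expect_identical(nchar(truth$haplotype_A), nchar(truth$haplotype_B))
  n <- length(truth$snp_positions)
  expect_lt(abs(n - 2e4 * 0.03), 3 * sqrt(2e4 * 0.03 * 0.97))
  expect_error(simulate_diploid(heterozygosity_r = 1), "\\[0, 1\\)")
})

test_that("fixture files support the end-to-end purging scenarios", {
  fx <- small_diploid_fixture()
  dir <- tempfile("fixtures")
  paths <- make_fixtures(fx$truth, dir)
  expect_true(all(file.exists(unlist(paths))))

  truth_rec <- jsonlite::fromJSON(paths$truth_record)
  expect_equal(truth_rec$n_snps, length(fx$truth$snp_positions))
  expect_null(truth_rec$haplotype_A)

  # purged pseudo-haplotype judged consistent; measure s from the
  # unpurged (pre-purge) assembly as in a real pipeline
  purged <- purging_qc(assembly = read_sequences(paths$purged_assembly),
                       prepurge_assembly = read_sequences(paths$unpurged_assembly),
                       reads = read_sequences(paths$reads))
  expect_identical(purged$verdict, "CONSISTENT")
  expect_lt(abs(purged$size_ratio - 1), 0.1)

  # leaving both haplotypes in place is flagged, with a diploid-scale size
  unpurged <- purging_qc(assembly = read_sequences(paths$unpurged_assembly),
                         reads = read_sequences(paths$reads), s = purged$prepurge_completeness_s)
  expect_identical(unpurged$verdict, "INCOMPLETE_PURGING")
  expect_true(unpurged$size_corroborated)
  expect_lt(abs(unpurged$size_ratio - 2), 0.15)
})
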