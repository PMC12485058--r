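test_that("canonical_kmer picks the lexicographic minimum of strand pair", {
  expect_identical(canonical_kmer("ACGT"), "ACGT")  # revcomp palindrome
  expect_identical(canonical_kmer("TTTT"), "AAAA")
  expect_identical(canonical_kmer("AACG"), "AACG")  # revcomp CGTT is larger
  expect_identical(canonical_kmer("acgt"), "ACGT")  # case-insensitive
  expect_error(canonical_kmer("ACNG"), "outside")
})

test_that("canonicalization is idempotent and strand-symmetric", {
  set.seed(101)
  kmers <- vapply(1:50, function(i) random_dna(7), character(1))
  can <- canonical_kmer(kmers)
  expect_identical(canonical_kmer(can), can)
  expect_identical(canonical_kmer(reverse_complement(kmers)), can)
  expect_true(all(can <= reverse_complement(can)))
})

test_that("count_kmers handles homopolymers, strand collapse and skips", {
  expect_identical(kmer_counts(count_kmers("AAAAA", 3)), c(AAA = 3L))
  expect_identical(count_kmers("AAAAA", 3)$total_positions, 3)

  db <- count_kmers("ACGTACGT", 4)
  expect_identical(kmer_counts(db), c(ACGT = 2L, CGTA = 2L, GTAC = 1L))
  expect_identical(db$total_positions, 5)

  db <- count_kmers("ACNGT", 2)  # GT canonicalizes to AC; CN/NG skipped
  expect_identical(kmer_counts(db), c(AC = 2L))
  expect_identical(db$total_positions, 2)
  expect_identical(db$skipped_windows, 2)
})

test_that("count_kmers of degenerate inputs yields empty databases", {
  expect_identical(count_kmers(character(0), 5)$n_distinct, 0L)
  expect_identical(count_kmers("ACG", 5)$n_distinct, 0L)  # k > sequence
  expect_error(count_kmers("ACGT", 0), "between 1 and 26")
  expect_error(count_kmers("ACGT", 27), "between 1 and 26")
})

test_that("counting matches the brute-force enumerator on random sequences", {
  set.seed(7)
  for (k in c(2L, 4L, 7L)) {
    for (rep in 1:4) {
      seqs <- replicate(3, random_dna(sample(50:200, 1),
                                      alphabet = c("A", "C", "G", "T", "N")))
      db <- count_kmers(seqs, k)
      ref <- naive_count_kmers(seqs, k)
      expect_identical(kmer_counts(db), ref$counts,
                       info = sprintf("k=%d rep=%d", k, rep))
      expect_identical(db$total_positions, as.numeric(ref$total))
    }
  }
})

test_that("counting is strand-invariant and conserves window tallies", {
  set.seed(11)
  for (rep in 1:5) {
    seqs <- replicate(4, random_dna(sample(30:150, 1)))
    fwd <- count_kmers(seqs, 5)
    rev <- count_kmers(reverse_complement(seqs), 5)
    expect_identical(fwd$key, rev$key)
    expect_identical(fwd$count, rev$count)
    # conservation: sum of multiplicities equals ingested positions,
    # and the spectrum redistributes the same mass
    expect_identical(sum(as.numeric(fwd$count)), fwd$total_positions)
    sp <- kmer_spectrum(fwd)
    expect_identical(sum(sp$multiplicity * sp$count), fwd$total_positions)
    expect_identical(sum(sp$count), as.numeric(fwd$n_distinct))
  }
})

test_that("kmer_spectrum tallies distinct k-mers per multiplicity", {
  sp <- kmer_spectrum(count_kmers("ACGTACGT", 4))  # counts 2,2,1
  expect_identical(sp$multiplicity, c(1L, 2L))
  expect_identical(sp$count, c(1, 2))

  sp0 <- kmer_spectrum(count_kmers(character(0), 4))
  expect_length(sp0$multiplicity, 0L)

  sp3 <- kmer_spectrum(count_kmers("AAAAA", 3))  # {AAA: 3}
  expect_identical(sp3$multiplicity, 3L)
  expect_identical(sp3$count, 1)
})

test_that("histo files round-trip and malformed input names the line", {
  f <- tempfile(fileext = ".histo")
  writeLines(c("1 10", "2 5"), f)
  sp <- read_histo(f, k = 21)
  expect_identical(sp$multiplicity, c(1L, 2L))
  expect_identical(sp$count, c(10, 5))

  sp2 <- spectrum_from_map(list(`1` = 1, `2` = 2), k = 4)
  write_histo(sp2, f)
  back <- read_histo(f, k = 4)
  expect_identical(back$multiplicity, sp2$multiplicity)
  expect_identical(back$count, sp2$count)

  writeLines(c("1 x"), f)
  expect_error(read_histo(f), "line 1")
  writeLines(c("1 5", "1 7"), f)
  expect_error(read_histo(f), "line 2")
  writeLines(c("1 5", "2"), f)
  expect_error(read_histo(f), "line 2")
})

test_that("kmer_dump writes lexicographically sorted kmer/count pairs", {
  f <- tempfile()
  kmer_dump(count_kmers("ACGTACGT", 4), f)
  lines <- readLines(f)
  expect_identical(lines, c("ACGT\t2", "CGTA\t2", "GTAC\t1"))
})

test_that("FASTA and FASTQ writing round-trips through Biostrings readers", {
  fa <- tempfile(fileext = ".fasta")
  write_fasta(c(chr1 = "ACGTACGTAC", chr2 = "GGGTTTAAAC"), fa)
  seqs <- read_sequences(fa)
  expect_identical(as.character(seqs),
                   c(chr1 = "ACGTACGTAC", chr2 = "GGGTTTAAAC"))

  fq <- tempfile(fileext = ".fastq")
  write_fastq(c(r1 = "ACGTTGCA", r2 = "TTTTACGT"), fq)
  reads <- read_sequences(fq)
  expect_identical(unname(as.character(reads)), c("ACGTTGCA", "TTTTACGT"))
})
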