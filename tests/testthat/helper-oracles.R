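# Independent brute-force reference implementations used to cross-check the
# package's fast paths.

# Naive canonical k-mer counter: enumerate every window in R, reverse
# complement by hand, tally with table().
naive_count_kmers <- function(sequences, k) {
  rc1 <- function(s) {
    chartr("ACGT", "TGCA",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = ""))
  }
  tallies <- list()
  total <- 0
  for (s in toupper(sequences)) {
    n <- nchar(s)
    if (n < k) next
    for (i in seq_len(n - k + 1L)) {
      w <- substr(s, i, i + k - 1L)
      if (grepl("[^ACGT]", w)) next
      rc <- rc1(w)
      can <- if (w <= rc) w else rc
      tallies[[can]] <- (tallies[[can]] %||% 0L) + 1L
      total <- total + 1L
    }
  }
  counts <- unlist(tallies)
  if (is.null(counts)) counts <- integer(0)
  list(counts = counts[order(names(counts))], total = total)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force NXX: largest length L such that sequences of length >= L cover
# at least frac of the assembly, scanning candidate lengths directly.
naive_nxx <- function(lengths, frac) {
  total <- sum(lengths)
  for (L in sort(unique(lengths), decreasing = TRUE)) {
    if (sum(lengths[lengths >= L]) >= frac * total) return(L)
  }
  min(lengths)
}

# Random DNA string for property tests.
random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

reverse_complement <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

# Build a spectrum directly from a multiplicity -> count map (list or
# named vector), for closed-form spectrum tests.
spectrum_from_map <- function(map, k = 21L) {
  m <- as.integer(names(map))
  o <- order(m)
  f <- tempfile(fileext = ".histo")
  writeLines(paste(m[o], unname(unlist(map))[o]), f)
  on.exit(unlink(f))
  read_histo(f, k = k)
}
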