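#' Canonicalize k-mers
#'
#' Returns, for each input k-mer, the lexicographically smaller of the k-mer
#' and its reverse complement (the Jellyfish `-C` convention). Canonical
#' counting makes k-mer tallies independent of which strand was sequenced or
#' assembled.
#'
#' @param kmer Character vector of DNA strings over `A`, `C`, `G`, `T`
#'   (case-insensitive; uppercased on entry).
#' @return Character vector of canonical k-mers, same length as `kmer`.
#' @examples
#' canonical_kmer(c("ACGT", "TTTT", "AACG"))
#' @export
canonical_kmer <- function(kmer) {
  km <- toupper(as.character(kmer))
  bad <- grepl("[^ACGT]", km)
  if (any(bad)) {
    stop("k-mer contains characters outside {A,C,G,T}: ",
         paste(utils::head(km[bad], 3L), collapse = ", "))
  }
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(km)))
  ifelse(km <= rc, km, rc)
}

#' Count canonical k-mers in a sequence collection
#'
#' Slides a window of length `k` over every sequence; each window consisting
#' only of `A`, `C`, `G`, `T` contributes one count to its canonical k-mer.
#' Windows containing any other character (ambiguity codes, gaps) are skipped
#' silently and tallied in `skipped_windows`. Counting is in memory and
#' intended for desk-scale inputs (up to tens of megabases).
#'
#' @param sequences Character vector or `Biostrings::DNAStringSet`.
#' @param k K-mer length, between 1 and 26 (default 21, the conventional size
#'   for genome profiling and Merqury-style evaluation).
#' @return An object of class `kmer_db`: a list with elements `k`, `key`
#'   (sorted numeric 2-bit encodings of the distinct canonical k-mers),
#'   `count` (integer multiplicities, parallel to `key`), `n_distinct`,
#'   `total_positions` (k-mer windows ingested) and `skipped_windows`.
#' @examples
#' db <- count_kmers("ACGTACGT", k = 4)
#' kmer_counts(db)
#' @export
count_kmers <- function(sequences, k = 21L) {
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L || k > 26L) {
    stop("k must be a single integer between 1 and 26")
  }
  seqs <- as_sequence_chars(sequences)
  res <- count_kmers_cpp(seqs, k)
  structure(
    list(k = k, key = res$key, count = res$count,
         n_distinct = length(res$key),
         total_positions = res$total, skipped_windows = res$skipped),
    class = "kmer_db"
  )
}

#' @export
print.kmer_db <- function(x, ...) {
  cat(sprintf(
    "kmer_db: k=%d, %s distinct canonical k-mers, %s positions (%s skipped)\n",
    x$k, format(x$n_distinct, big.mark = ","),
    format(x$total_positions, big.mark = ",", scientific = FALSE),
    format(x$skipped_windows, big.mark = ",", scientific = FALSE)))
  invisible(x)
}

#' Extract k-mer multiplicities as a named vector
#'
#' Decodes the canonical k-mers of a [count_kmers()] database into strings.
#' Intended for small databases (inspection, tests, dumps); a 60 Mbp read set
#' has millions of distinct k-mers and is better handled in encoded form.
#'
#' @param db A `kmer_db`.
#' @return Named integer vector, names sorted lexicographically.
#' @export
kmer_counts <- function(db) {
  stopifnot(inherits(db, "kmer_db"))
  setNames(db$count, decode_kmers_cpp(db$key, db$k))
}

#' Write a k-mer dump
#'
#' Writes tab-separated `kmer<TAB>count` lines, sorted lexicographically by
#' k-mer.
#'
#' @param db A `kmer_db`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
kmer_dump <- function(db, path) {
  stopifnot(inherits(db, "kmer_db"))
  writeLines(paste(decode_kmers_cpp(db$key, db$k), db$count, sep = "\t"), path)
  invisible(path)
}

#' K-mer spectrum (multiplicity histogram) of a database
#'
#' Tallies, for each multiplicity m, how many distinct canonical k-mers occur
#' exactly m times. The spectrum of whole-genome reads carries peaks at the
#' heterozygous (1-copy) and homozygous (2-copy) coverage depths and is the
#' input to [fit_profile()].
#'
#' @param db A `kmer_db` from [count_kmers()].
#' @return An object of class `kmer_spectrum`: list with `k`, `multiplicity`
#'   (increasing integer vector) and `count` (numeric, distinct k-mers at each
#'   multiplicity).
#' @export
kmer_spectrum <- function(db) {
  stopifnot(inherits(db, "kmer_db"))
  if (db$n_distinct == 0L) {
    return(new_spectrum(db$k, integer(0), numeric(0)))
  }
  tab <- tabulate(db$count)
  m <- which(tab > 0L)
  new_spectrum(db$k, m, as.numeric(tab[m]))
}

new_spectrum <- function(k, multiplicity, count) {
  structure(list(k = as.integer(k), multiplicity = as.integer(multiplicity),
                 count = as.numeric(count)),
            class = "kmer_spectrum")
}

#' @export
print.kmer_spectrum <- function(x, ...) {
  cat(sprintf("kmer_spectrum: k=%d, %s distinct k-mers over %d multiplicity classes\n",
              x$k, format(sum(x$count), big.mark = ","), length(x$multiplicity)))
  invisible(x)
}

# Dense counts indexed 1..max(multiplicity); zeros where absent.
spectrum_dense <- function(spectrum) {
  stopifnot(inherits(spectrum, "kmer_spectrum"))
  if (length(spectrum$multiplicity) == 0L) return(numeric(0))
  h <- numeric(max(spectrum$multiplicity))
  h[spectrum$multiplicity] <- spectrum$count
  h
}

#' Read and write Jellyfish-style histogram files
#'
#' The `.histo` format is one `multiplicity count` pair per line, whitespace
#' separated, multiplicities strictly increasing. The format does not record
#' the k-mer size, so `k` is supplied by the caller on read.
#'
#' @param path File path.
#' @param k K-mer size the histogram was computed with (default 21).
#' @return `read_histo()` returns a `kmer_spectrum`; `write_histo()` returns
#'   `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".histo")
#' write_histo(kmer_spectrum(count_kmers("ACGTACGT", k = 4)), f)
#' read_histo(f, k = 4)
#' @export
read_histo <- function(path, k = 21L) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  idx <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "[[:space:]]+")
  m <- integer(length(fields))
  cnt <- numeric(length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) != 2L || anyNA(suppressWarnings(as.numeric(f))) ||
        any(as.numeric(f) != floor(as.numeric(f)))) {
      stop(sprintf("malformed histo line %d: '%s'", idx[i], lines[idx[i]]))
    }
    m[i] <- as.integer(f[1L])
    cnt[i] <- as.numeric(f[2L])
  }
  if (any(m < 1L)) stop(sprintf("non-positive multiplicity at line %d",
                                idx[which(m < 1L)[1L]]))
  if (is.unsorted(m, strictly = TRUE)) {
    bad <- which(diff(m) <= 0L)[1L] + 1L
    stop(sprintf("multiplicities not strictly increasing at line %d", idx[bad]))
  }
  if (any(cnt < 0)) stop("negative count in histo file")
  new_spectrum(k, m, cnt)
}

#' @param spectrum A `kmer_spectrum`.
#' @rdname read_histo
#' @export
write_histo <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "kmer_spectrum"))
  writeLines(paste(spectrum$multiplicity,
                   format(spectrum$count, scientific = FALSE, trim = TRUE)),
             path)
  invisible(path)
}

#' Read sequences from FASTA or FASTQ
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that picks the format
#' from the file extension (`.fastq`/`.fq`, optionally gzipped, are read as
#' FASTQ; everything else as FASTA).
#'
#' @param path Sequence file path.
#' @return A `Biostrings::DNAStringSet`.
#' @export
read_sequences <- function(path) {
  fmt <- if (grepl("\\.(fastq|fq)(\\.gz)?$", path, ignore.case = TRUE))
    "fastq" else "fasta"
  Biostrings::readDNAStringSet(path, format = fmt)
}

#' Write sequences to FASTA or FASTQ
#'
#' `write_fasta()` writes named sequences as FASTA. `write_fastq()` writes
#' reads as FASTQ with a constant quality of `I` (Phred 40), which is how the
#' simulator exports error-free or uniformly error-bearing reads.
#'
#' @param sequences Named character vector or `DNAStringSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(as_sequence_chars(sequences))
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    names(x) <- sprintf("seq%d", seq_along(x))
  }
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
write_fastq <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(as_sequence_chars(sequences))
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    names(x) <- sprintf("read%d", seq_along(x))
  }
  qual <- Biostrings::BStringSet(strrep("I", Biostrings::width(x)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}
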