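#' Read a batch table of genomes for completeness reporting
#'
#' Expects a TSV with columns `genome`, `r_percent`, `s_percent`,
#' `observed_percent` and optionally `assembly_size_mb`, `haploid_size_mb`.
#' Percent columns are percentages (1.5 means 1.5%). Validation errors name
#' the offending row.
#'
#' @param path TSV file path.
#' @return A data.frame; `observed_text` preserves the input formatting of
#'   the observed column so reports can echo it at its original precision.
#' @export
read_genome_batch <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = TRUE)
  required <- c("genome", "r_percent", "s_percent", "observed_percent")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("batch table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  raw <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  df$observed_text <- raw$observed_percent
  if (!"assembly_size_mb" %in% names(df)) df$assembly_size_mb <- NA_real_
  if (!"haploid_size_mb" %in% names(df)) df$haploid_size_mb <- NA_real_
  validate_batch(df)
  df
}

validate_batch <- function(df) {
  for (i in seq_len(nrow(df))) {
    who <- sprintf("row %d (%s)", i, df$genome[i])
    r <- df$r_percent[i]; s <- df$s_percent[i]; obs <- df$observed_percent[i]
    if (is.na(r) || r < 0 || r >= 100) {
      stop(who, ": r_percent must lie in [0, 100)")
    }
    if (is.na(s) || s <= 0 || s > 100) {
      stop(who, ": s_percent must lie in (0, 100]")
    }
    if (is.na(obs) || obs < 0 || obs > 100) {
      stop(who, ": observed_percent must lie in [0, 100]")
    }
  }
  invisible(df)
}

#' Batch completeness report
#'
#' Applies the pseudo-haplotype completeness model and [purging_verdict()]
#' to every row of a batch table, yielding one report row per genome with
#' the theoretical maximum, the scaled expectation, the observed-minus-
#' expected deviation in percentage points, the assembly/haploid size ratio
#' where sizes are given, and the three-way verdict.
#'
#' @param batch Data.frame as returned by [read_genome_batch()] (or built in
#'   code with the same columns).
#' @param k K-mer size (default 21).
#' @param tolerance_pp,size_band Verdict thresholds, see [purging_verdict()].
#' @return Data.frame with columns `genome`, `r_percent`, `s_percent`,
#'   `observed_percent`, `maximum_percent`, `expected_percent`,
#'   `deviation_pp`, `size_ratio`, `verdict`, `size_corroborated`.
#' @examples
#' completeness_batch(cassava_panel())
#' @export
completeness_batch <- function(batch, k = 21L, tolerance_pp = 5,
                               size_band = c(0.8, 1.25)) {
  if (!"assembly_size_mb" %in% names(batch)) batch$assembly_size_mb <- NA_real_
  if (!"haploid_size_mb" %in% names(batch)) batch$haploid_size_mb <- NA_real_
  validate_batch(batch)
  rows <- lapply(seq_len(nrow(batch)), function(i) {
    rep <- purging_verdict(
      heterozygosity_r = batch$r_percent[i] / 100,
      prepurge_completeness_s = batch$s_percent[i] / 100,
      observed_completeness = batch$observed_percent[i] / 100,
      k = k,
      assembly_size_bp = batch$assembly_size_mb[i] * 1e6,
      haploid_size_bp = batch$haploid_size_mb[i] * 1e6,
      tolerance_pp = tolerance_pp, size_band = size_band)
    data.frame(
      genome = batch$genome[i],
      r_percent = batch$r_percent[i],
      s_percent = batch$s_percent[i],
      observed_percent = batch$observed_percent[i],
      maximum_percent = 100 * rep$maximum,
      expected_percent = 100 * rep$expected,
      deviation_pp = rep$deviation_pp,
      size_ratio = rep$size_ratio,
      verdict = rep$verdict,
      size_corroborated = rep$size_corroborated,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if ("observed_text" %in% names(batch)) out$observed_text <- batch$observed_text
  out
}

#' Write a completeness report as TSV or JSON
#'
#' TSV output formats the model columns (`maximum_percent`,
#' `expected_percent`, `deviation_pp`, `size_ratio`) at 2 decimal places and
#' echoes the observed column at its input precision when available; column
#' order and rounding are stable across runs.
#'
#' @param report Data.frame from [completeness_batch()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(report, path) {
  fmt2 <- function(v) ifelse(is.na(v), "NA", sprintf("%.2f", v))
  out <- data.frame(
    genome = report$genome,
    r_percent = fmt2(report$r_percent),
    s_percent = sprintf("%.4f", report$s_percent),
    maximum_percent = fmt2(report$maximum_percent),
    expected_percent = fmt2(report$expected_percent),
    observed_percent = if ("observed_text" %in% names(report))
      report$observed_text else sprintf("%.4f", report$observed_percent),
    deviation_pp = fmt2(report$deviation_pp),
    size_ratio = fmt2(report$size_ratio),
    verdict = report$verdict,
    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_report_tsv
#' @export
write_report_json <- function(report, path) {
  keep <- setdiff(names(report), "observed_text")
  writeLines(jsonlite::toJSON(report[keep], dataframe = "rows",
                              auto_unbox = TRUE, digits = NA, na = "null"),
             path)
  invisible(path)
}

#' Bundled ten-genome Manihot assembly panel
#'
#' The published k-mer completeness parameters for ten pseudo-haplotype
#' *Manihot* (cassava and one wild relative) assemblies evaluated at k = 21:
#' GenomeScope heterozygosity estimates, Merqury 21-mer completeness before
#' purging and of the final assembly, and total assembly sizes. The haploid
#' genome size estimate is included for the wild *M. glaziovii* accession
#' ("WildType"), whose purging is the panel's known failure case.
#'
#' @return Batch data.frame suitable for [completeness_batch()].
#' @export
cassava_panel <- function() {
  read_genome_batch(system.file("extdata", "cassava_panel.tsv",
                                package = "purgecheck", mustWork = TRUE))
}
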