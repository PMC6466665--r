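#' Genome assemblies
#'
#' An `assembly` bundles an ordered collection of nucleotide records (one per
#' contig) with its provenance. Record ids must be unique; every FASTA record
#' is treated as one contig (N runs are not split).
#'
#' @param records List of nucleotide [seq_record()] objects, or a FASTA path.
#' @param source_path Provenance string recorded in reports.
#' @return An object of class `assembly`.
#' @export
assembly <- function(records, source_path = NA_character_) {
  if (is.character(records) && length(records) == 1L) {
    source_path <- records
    records <- read_fasta(records, alphabet = "dna")
  }
  if (length(records) == 0L) stop("empty assembly")
  ids <- vapply(records, function(r) r$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate contig ids")
  total <- sum(vapply(records, function(r) nchar(r$sequence), numeric(1)))
  if (total <= 0) stop("empty assembly")
  names(records) <- ids
  structure(list(records = records, source_path = source_path),
            class = "assembly")
}

#' @export
print.assembly <- function(x, ...) {
  st <- assembly_stats(x)
  cat(sprintf("<assembly: %d contigs, %s bp, N50 %s (L50 %d)>\n",
              st$n_contigs, format(st$total_length, big.mark = ","),
              format(st$n50_length, big.mark = ","), st$l50_count))
  invisible(x)
}

contig_lengths <- function(x) {
  vapply(x$records, function(r) nchar(r$sequence), numeric(1))
}

#' Contiguity statistics from contig lengths
#'
#' N50 is the length of the contig at which the cumulative sum of the
#' descending-sorted lengths first reaches half the assembly size; L50 is that
#' contig's 1-based rank. "First reaches" is inclusive: a cumulative sum equal
#' to exactly half counts as reached. Note that some older tools swap the two
#' names; this package follows the modern convention (N50 a length, L50 a
#' count).
#'
#' @param lengths Positive integer contig lengths, any order.
#' @return A list of class `assembly_stats` with `n_contigs`, `total_length`,
#'   `n50_length`, `l50_count`, `max_length` and (unset here) `n_fraction`.
#' @examples
#' contig_stats(c(10, 8, 6, 4, 2))  # N50 = 8, L50 = 2
#' @export
contig_stats <- function(lengths) {
  lengths <- as.numeric(lengths)
  if (length(lengths) == 0L || any(!is.finite(lengths)) || any(lengths <= 0))
    stop("invalid lengths")
  srt <- sort(lengths, decreasing = TRUE)
  csum <- cumsum(srt)
  half <- sum(srt) / 2
  l50 <- which(csum >= half)[1L]
  structure(list(n_contigs = length(lengths),
                 total_length = sum(srt),
                 n50_length = srt[l50],
                 l50_count = l50,
                 max_length = srt[1L],
                 n_fraction = NA_real_),
            class = "assembly_stats")
}

#' Fraction of N bases in an assembly
#' @param x An [assembly()].
#' @return Proportion of bases that are N, in `[0, 1]`.
#' @export
n_fraction <- function(x) {
  seqs <- vapply(x$records, function(r) r$sequence, character(1))
  n_count <- sum(vapply(seqs, function(s) {
    sum(utf8ToInt(s) == utf8ToInt("N"))
  }, numeric(1)))
  n_count / sum(nchar(seqs))
}

#' Full statistics for an assembly
#' @param x An [assembly()].
#' @return An `assembly_stats` list including `n_fraction`.
#' @export
assembly_stats <- function(x) {
  st <- contig_stats(contig_lengths(x))
  st$n_fraction <- n_fraction(x)
  st
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat(sprintf(paste0("contigs: %d  total: %s bp  N50: %s bp  L50: %d  ",
                     "max: %s bp  N fraction: %s\n"),
              x$n_contigs, format(x$total_length, big.mark = ","),
              format(x$n50_length, big.mark = ","), x$l50_count,
              format(x$max_length, big.mark = ","),
              ifelse(is.na(x$n_fraction), "NA", sprintf("%.4f", x$n_fraction))))
  invisible(x)
}
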