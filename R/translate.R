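#' Six-frame translation with invertible genome coordinates
#'
#' Translates a contig in all six frames under the standard genetic code.
#' Frames `+0,+1,+2` read the forward strand at offsets 0..2; `-0,-1,-2` read
#' the reverse complement likewise. Stop codons are retained as `*`; any codon
#' containing an ambiguous base translates to `X`; trailing 1-2 bases are
#' dropped. Each frame records the mapping between peptide index and
#' forward-strand genome coordinates (0-based, half-open), see
#' [frame_to_genome()].
#'
#' @param record A nucleotide [seq_record()].
#' @return A list of six `frame` objects with fields `contig_id`, `strand`,
#'   `offset`, `peptide`, `contig_length`.
#' @examples
#' fr <- six_frame_translate(seq_record("x", "ATGGCCTAA"))
#' fr[[1]]$peptide  # "MA*"
#' @export
six_frame_translate <- function(record) {
  n <- nchar(record$sequence)
  fwd <- Biostrings::DNAString(record$sequence)
  rev <- Biostrings::reverseComplement(fwd)
  out <- vector("list", 6L)
  idx <- 1L
  for (strand in c("+", "-")) {
    src <- if (strand == "+") fwd else rev
    for (off in 0:2) {
      len <- n - off
      len <- len - (len %% 3L)
      pep <- if (len >= 3L) {
        as.character(Biostrings::translate(
          Biostrings::subseq(src, start = off + 1L, width = len),
          if.fuzzy.codon = "X", no.init.codon = TRUE))
      } else ""
      out[[idx]] <- structure(
        list(contig_id = record$id, strand = strand, offset = off,
             peptide = pep, contig_length = n),
        class = "reading_frame")
      idx <- idx + 1L
    }
  }
  out
}

#' Map a peptide span back to genome coordinates
#'
#' @param frame A frame from [six_frame_translate()].
#' @param ps,pe 0-based half-open peptide span within the frame.
#' @return `c(genome_start, genome_end)`, 0-based half-open, forward strand.
#' @export
frame_to_genome <- function(frame, ps, pe) {
  n <- frame$contig_length
  off <- frame$offset
  if (frame$strand == "+") {
    c(off + 3L * ps, off + 3L * pe)
  } else {
    c(n - off - 3L * pe, n - off - 3L * ps)
  }
}

reverse_complement_string <- function(x) {
  intToUtf8(rev(utf8ToInt(chartr("ACGTN", "TGCAN", x))))
}
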