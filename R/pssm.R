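#' Build a position-specific scoring matrix from a gapped alignment
#'
#' Each retained alignment column becomes a vector of log-odds scores (bits,
#' base 2) against a background frequency vector:
#' `score(a) = log2((count(a) + w * bg(a)) / (n_eff + w) / bg(a))`,
#' where `n_eff` is the number of non-gap residues in the column and `w` the
#' pseudocount weight. Columns with 50% or more gaps are dropped.
#'
#' @param alignment Character vector of equal-length gapped rows (`-` or `.`
#'   as gap).
#' @param pseudocount_weight Positive pseudocount weight `w`.
#' @param background Background frequencies over the alphabet (must sum to 1);
#'   default uniform.
#' @param alphabet `"protein"` (20 letters) or `"dna"` (4 letters).
#' @return An object of class `pssm`: scores matrix (alphabet x columns),
#'   `alphabet`, `background`, `pseudocount_weight`, and `col_index` (the
#'   retained alignment columns).
#' @export
build_profile <- function(alignment, pseudocount_weight = 1.0,
                          background = NULL,
                          alphabet = c("protein", "dna")) {
  alphabet <- match.arg(alphabet)
  letters <- if (alphabet == "protein") AA_ORDER else NT_ORDER
  if (length(alignment) == 0L) stop("empty alignment")
  widths <- nchar(alignment)
  if (length(unique(widths)) != 1L) stop("alignment rows differ in length")
  if (widths[1L] == 0L) stop("empty alignment")
  if (is.null(background)) background <- rep(1 / length(letters), length(letters))
  if (abs(sum(background) - 1) > 1e-9) stop("background must sum to 1")

  rows <- do.call(rbind, strsplit(toupper(alignment), "", fixed = TRUE))
  is_res <- matrix(rows %in% letters, nrow = nrow(rows))
  gap_frac <- 1 - colMeans(is_res)
  keep <- which(gap_frac < 0.5)
  if (length(keep) == 0L) stop("all alignment columns are gappy")

  w <- pseudocount_weight
  scores <- vapply(keep, function(j) {
    col <- rows[, j]
    col <- col[col %in% letters]
    counts <- tabulate(match(col, letters), nbins = length(letters))
    n_eff <- sum(counts)
    log2((counts + w * background) / (n_eff + w) / background)
  }, numeric(length(letters)))
  scores <- matrix(scores, nrow = length(letters),
                   dimnames = list(letters, NULL))
  structure(list(scores = scores, alphabet = alphabet,
                 background = background, pseudocount_weight = w,
                 col_index = keep),
            class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("<pssm: %s, %d columns>\n", x$alphabet, ncol(x$scores)))
  invisible(x)
}

profile_length <- function(profile) ncol(profile$scores)

# Scoring matrix with rows for the full working alphabet: the 20 residues (or
# 4 bases), then X (or N) scoring 0 everywhere, stop codons at -4 bits
# (protein only), and a sentinel row at -1e9 that no extension can cross.
score_matrix <- function(profile) {
  sc <- profile$scores
  L <- ncol(sc)
  if (profile$alphabet == "protein") {
    rbind(sc, X = rep(0, L), `*` = rep(-4, L), `#` = rep(-1e9, L))
  } else {
    rbind(sc, N = rep(0, L), `#` = rep(-1e9, L))
  }
}

#' Best local alignment score of a sequence against a profile
#'
#' Smith-Waterman-style dynamic programme in which aligning a residue to a
#' column adds the column's log-odds score for that residue, and skipping a
#' column or a residue costs a flat penalty per position. `X` (protein) and
#' `N` (nucleotide) score 0 at every column; `*` scores -4 bits. The empty
#' alignment is admissible, so the score is never negative.
#'
#' @param profile A [build_profile()] object.
#' @param sequence Peptide (or nucleotide, for DNA profiles) string.
#' @param skip_penalty Per-position skip penalty, bits.
#' @return The best local alignment score in bits.
#' @export
score_sequence <- function(profile, sequence, skip_penalty = 2) {
  stopifnot(inherits(profile, "pssm"))
  if (!nzchar(sequence)) return(0)
  codes <- if (profile$alphabet == "protein") encode_peptide(sequence)
           else encode_nucleotide(sequence)
  .pssm_local_score(codes, score_matrix(profile), skip_penalty)
}

#' Family detection threshold from member self-scores
#'
#' The threshold is 80% of the weakest member's score against its own family
#' profile, so every member of a well-formed family clears its family's
#' threshold by construction.
#'
#' @param member_scores Non-empty numeric vector of member self-scores, bits.
#' @return The detection threshold in bits.
#' @export
family_threshold <- function(member_scores) {
  if (length(member_scores) == 0L) stop("no member scores")
  0.8 * min(member_scores)
}
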