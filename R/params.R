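#' Scan parameters
#'
#' One container for every tunable numeric parameter of the toolkit. Defaults
#' follow the method's published settings where stated; the rest are the
#' package's documented choices.
#'
#' @param seed_k Exact-match seed length for protein search, residues.
#' @param hde_seed_k Seed length for nucleotide (conserved-element) search.
#' @param xdrop X-drop termination threshold for seed extension, bits.
#' @param min_hsp_score Minimum score for a reported HSP, bits.
#' @param aberrant_factor A gene model at least this multiple of the family's
#'   mean member length is classified aberrant.
#' @param coverage_complete Minimum fraction of profile columns a model must
#'   cover to be complete.
#' @param partial_floor A model scoring at least this fraction of the family
#'   threshold (but failing the complete criteria) is partial; in read mode it
#'   is also the per-HSP detection floor.
#' @param presence_fraction Fraction of reference species a candidate family
#'   must span to be retained when building marker sets.
#' @param paralog_margin A member's self-score must exceed its score against
#'   every other retained family's profile by more than this many bits.
#' @param max_genome_gap Maximum genomic gap (intron allowance) between
#'   chained HSPs, bases.
#' @param max_profile_overlap Maximum profile-column overlap between chained
#'   HSPs.
#' @param skip_penalty Per-position penalty (bits) for skipping a profile
#'   column or a peptide residue in the profile-alignment dynamic programme.
#' @param pseudocount Pseudocount weight used when building profiles.
#' @param block_size Reads per block in read mode.
#' @param n_blocks Number of blocks reservoir-sampled in read mode.
#' @param stop_patience Consecutive blocks without a newly detected marker
#'   after which read-mode scanning stops.
#' @param truncation_fraction Default fraction of sequence removed by the
#'   truncation benchmark generator.
#' @param rng_seed Default seed for stochastic operations.
#' @return A list of class `scan_params`.
#' @export
scan_params <- function(seed_k = 4L,
                        hde_seed_k = 12L,
                        xdrop = 20,
                        min_hsp_score = 15,
                        aberrant_factor = 2.0,
                        coverage_complete = 0.70,
                        partial_floor = 0.30,
                        presence_fraction = 0.99,
                        paralog_margin = 0,
                        max_genome_gap = 10000L,
                        max_profile_overlap = 10L,
                        skip_penalty = 2,
                        pseudocount = 1.0,
                        block_size = 10000L,
                        n_blocks = 1000L,
                        stop_patience = 20L,
                        truncation_fraction = 0.10,
                        rng_seed = 1L) {
  p <- list(seed_k = as.integer(seed_k), hde_seed_k = as.integer(hde_seed_k),
            xdrop = as.numeric(xdrop),
            min_hsp_score = as.numeric(min_hsp_score),
            aberrant_factor = as.numeric(aberrant_factor),
            coverage_complete = as.numeric(coverage_complete),
            partial_floor = as.numeric(partial_floor),
            presence_fraction = as.numeric(presence_fraction),
            paralog_margin = as.numeric(paralog_margin),
            max_genome_gap = as.integer(max_genome_gap),
            max_profile_overlap = as.integer(max_profile_overlap),
            skip_penalty = as.numeric(skip_penalty),
            pseudocount = as.numeric(pseudocount),
            block_size = as.integer(block_size),
            n_blocks = as.integer(n_blocks),
            stop_patience = as.integer(stop_patience),
            truncation_fraction = as.numeric(truncation_fraction),
            rng_seed = as.integer(rng_seed))
  props <- c("coverage_complete", "partial_floor", "presence_fraction",
             "truncation_fraction")
  for (nm in props) {
    if (!is.numeric(p[[nm]]) || p[[nm]] <= 0 || p[[nm]] > 1)
      stop("parameter '", nm, "' must be in (0, 1]")
  }
  counts <- c("seed_k", "hde_seed_k", "block_size", "n_blocks",
              "stop_patience", "max_genome_gap")
  for (nm in counts) {
    if (is.na(p[[nm]]) || p[[nm]] < 1L) stop("parameter '", nm, "' must be positive")
  }
  structure(p, class = "scan_params")
}
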