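#' Group a record stream into blocks
#'
#' @param stream A record stream ([read_fastx()], [stream_from_records()]).
#' @param block_size Reads per block (the final block may be smaller).
#' @return A stream of blocks; each block is `list(id = <1-based block
#'   number>, records = <list of records>)`.
#' @export
block_stream <- function(stream, block_size) {
  block_size <- as.integer(block_size)
  if (is.na(block_size) || block_size < 1L) stop("block_size must be >= 1")
  done <- FALSE
  block_no <- 0L
  function() {
    if (done) return(NULL)
    recs <- vector("list", block_size)
    n <- 0L
    while (n < block_size) {
      r <- stream()
      if (is.null(r)) { done <<- TRUE; break }
      n <- n + 1L
      recs[[n]] <- r
    }
    if (n == 0L) return(NULL)
    block_no <<- block_no + 1L
    list(id = block_no, records = recs[seq_len(n)])
  }
}

#' Uniform single-pass sample of k items from a stream
#'
#' Classic reservoir sampling (Algorithm R): the first `k` items fill the
#' reservoir, item `i > k` replaces a uniformly chosen slot with probability
#' `k/i`; the reservoir is shuffled before being returned. Deterministic
#' given `rng_seed`. A stream shorter than `k` returns every item.
#'
#' @param stream An item stream (e.g. [block_stream()]) or a list.
#' @param k Number of items to keep.
#' @param rng_seed Integer seed.
#' @return List of sampled items, in randomized order.
#' @export
reservoir_sample <- function(stream, k, rng_seed = 1L) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be >= 1")
  if (is.list(stream)) stream <- local({
    items <- stream; pos <- 0L
    function() { pos <<- pos + 1L; if (pos > length(items)) NULL else items[[pos]] }
  })
  with_seed(rng_seed, {
    reservoir <- vector("list", k)
    n_seen <- 0L
    repeat {
      item <- stream()
      if (is.null(item)) break
      n_seen <- n_seen + 1L
      if (n_seen <= k) {
        reservoir[[n_seen]] <- item
      } else {
        j <- sample.int(n_seen, 1L)
        if (j <= k) reservoir[[j]] <- item
      }
    }
    n_kept <- min(n_seen, k)
    reservoir <- reservoir[seq_len(n_kept)]
    if (n_kept > 1L) reservoir <- reservoir[sample.int(n_kept)]
    reservoir
  })
}

# Six-frame translate every read in a block and join all frames into one
# encoded vector, with sentinel separators so no seed or extension crosses a
# read boundary.
.block_codes <- function(records) {
  seqs <- vapply(records, function(r) r$sequence, character(1))
  sets <- Biostrings::DNAStringSet(seqs)
  peps <- character(0)
  for (strand in c("+", "-")) {
    src <- if (strand == "+") sets else Biostrings::reverseComplement(sets)
    w <- Biostrings::width(src)
    for (off in 0:2) {
      wid <- pmax(0L, ((w - off) %/% 3L) * 3L)
      ok <- wid >= 3L
      if (!any(ok)) next
      sub <- Biostrings::subseq(src[ok], start = off + 1L, width = wid[ok])
      peps <- c(peps, as.character(Biostrings::translate(
        sub, if.fuzzy.codon = "X", no.init.codon = TRUE)))
    }
  }
  encode_peptide(paste(peps, collapse = "#"))
}

#' Iteratively scan sampled read blocks for markers
#'
#' One block is scanned per iteration against the families not yet detected;
#' a family is detected when any HSP reaches `partial_floor` of its score
#' threshold (reads cover gene fragments, so the full-length threshold does
#' not apply). A counter of consecutive zero-gain iterations resets on any
#' gain; scanning stops when it reaches `stop_patience`, or when the blocks
#' run out.
#'
#' @param blocks List of blocks (from [reservoir_sample()] over
#'   [block_stream()]), or a list of record lists.
#' @param markerset A [marker_set()].
#' @param params A [scan_params()]; defaults to the marker set's.
#' @return An object of class `rarefaction_curve`: `per_iteration` data frame
#'   (`iteration`, `block_id`, `new_markers`, `cumulative_markers`),
#'   `stopped_at`, `stop_reason` (`"patience_exhausted"` or
#'   `"blocks_exhausted"`), and `detected_ids`.
#' @export
iterative_scan <- function(blocks, markerset, params = NULL) {
  if (length(blocks) == 0L) stop("no blocks to scan")
  if (is.null(params)) params <- markerset$params
  families <- markerset$families
  thr <- vapply(families, function(f) f$score_threshold, numeric(1))
  detected <- logical(length(families))
  names(detected) <- names(families)
  fails <- 0L
  rows <- vector("list", length(blocks))
  it <- 0L
  stop_reason <- "blocks_exhausted"
  for (b in blocks) {
    it <- it + 1L
    recs <- if (!is.null(b$records)) b$records else b
    bid <- if (!is.null(b$id)) b$id else it
    new_count <- 0L
    if (!all(detected)) {
      undet <- which(!detected)
      st <- subset_seed_table(markerset$seed_table, undet)
      if (length(st$fam) > 0L) {
        codes <- .block_codes(recs)
        profs <- lapply(families[undet], function(f) score_matrix(f$profile))
        floor_scores <- params$partial_floor * thr[undet]
        raw <- .seed_extend_multi(codes, profs, st$seeds, st$fam, st$col,
                                  AA_X, params$xdrop,
                                  min(params$min_hsp_score, min(floor_scores)))
        if (nrow(raw) > 0L) {
          hit <- raw$score >= floor_scores[raw$fam]
          newly <- unique(undet[raw$fam[hit]])
          new_count <- length(newly)
          detected[newly] <- TRUE
        }
      }
    }
    rows[[it]] <- data.frame(iteration = it, block_id = bid,
                             new_markers = new_count,
                             cumulative_markers = sum(detected))
    if (new_count == 0L) fails <- fails + 1L else fails <- 0L
    if (fails >= params$stop_patience) { stop_reason <- "patience_exhausted"; break }
  }
  structure(list(per_iteration = do.call(rbind, rows[seq_len(it)]),
                 stopped_at = it, stop_reason = stop_reason,
                 detected_ids = names(detected)[detected]),
            class = "rarefaction_curve")
}

#' @export
print.rarefaction_curve <- function(x, ...) {
  cat(sprintf("<rarefaction: %d markers after %d iterations (%s)>\n",
              length(x$detected_ids), x$stopped_at, x$stop_reason))
  invisible(x)
}

#' Completeness estimate from unassembled reads
#'
#' Splits the reads into blocks, reservoir-samples `n_blocks` of them, and
#' scans them iteratively ([iterative_scan()]) until the marker discovery
#' curve plateaus. Designed for long reads; every block is six-frame
#' translated and searched for marker fragments.
#'
#' @param reads A FASTA/FASTQ path, a record stream, or a list of records.
#' @param markerset A [marker_set()].
#' @param params A [scan_params()]; defaults to the marker set's. `rng_seed`
#'   drives the reservoir sample.
#' @return List with `pct_detected`, `n_detected`, `n_families`, and `curve`
#'   (a `rarefaction_curve`).
#' @export
reads_completeness <- function(reads, markerset, params = NULL) {
  if (is.null(params)) params <- markerset$params
  stream <- if (is.function(reads)) reads
  else if (is.character(reads)) read_fastx(reads)
  else if (is.list(reads)) stream_from_records(reads)
  else stop("cannot interpret 'reads'")
  blocks <- reservoir_sample(block_stream(stream, params$block_size),
                             params$n_blocks, params$rng_seed)
  if (length(blocks) == 0L) stop("empty reads")
  curve <- iterative_scan(blocks, markerset, params)
  n <- length(markerset$families)
  list(pct_detected = 100 * length(curve$detected_ids) / n,
       n_detected = length(curve$detected_ids),
       n_families = n, curve = curve)
}
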