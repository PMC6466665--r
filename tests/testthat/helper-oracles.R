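# Independent brute-force oracles and shared (cached) fixtures.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, fn) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE))
    assign(name, fn(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# N50/L50 by explicit prefix enumeration over the descending-sorted lengths.
bf_contig_stats <- function(lengths) {
  srt <- sort(lengths, decreasing = TRUE)
  total <- sum(srt)
  for (i in seq_along(srt)) {
    if (sum(srt[seq_len(i)]) >= total / 2)
      return(list(n50_length = srt[i], l50_count = i))
  }
}

# Local profile-alignment DP written independently in plain R (full matrix,
# no rolling rows), for cross-checking the compiled scorer.
bf_local_score <- function(profile, peptide, skip_pen = 2) {
  sc <- mycomplete:::score_matrix(profile)
  codes <- if (profile$alphabet == "protein") {
    mycomplete:::encode_peptide(peptide)
  } else mycomplete:::encode_nucleotide(peptide)
  n <- length(codes)
  L <- ncol(sc)
  H <- matrix(0, n + 1L, L + 1L)
  for (i in seq_len(n)) {
    for (j in seq_len(L)) {
      H[i + 1L, j + 1L] <- max(0,
                               H[i, j] + sc[codes[i] + 1L, j],
                               H[i, j + 1L] - skip_pen,
                               H[i + 1L, j] - skip_pen)
    }
  }
  max(H)
}

# Exhaustive chaining oracle: every subset of HSPs, ordered by profile start,
# checked against the pairwise chaining constraints between consecutive
# elements, scored with the overlap-trim rule.
bf_chain_score <- function(hsps, max_gap = 10000, max_ov = 10) {
  n <- nrow(hsps)
  minus <- hsps$strand[1L] == "-"
  ts <- if (minus) -hsps$genome_end else hsps$genome_start
  te <- if (minus) -hsps$genome_start else hsps$genome_end
  percol <- hsps$score / pmax(1, hsps$profile_end - hsps$profile_start)
  best <- 0
  for (mask in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    if (length(idx) == 0L) next
    idx <- idx[order(hsps$profile_start[idx], hsps$profile_end[idx])]
    total <- hsps$score[idx[1L]]
    ok <- TRUE
    if (length(idx) > 1L) {
      for (t in seq_along(idx)[-1L]) {
        i <- idx[t - 1L]; j <- idx[t]
        if (hsps$profile_start[i] >= hsps$profile_start[j] ||
            hsps$profile_end[i] >= hsps$profile_end[j]) { ok <- FALSE; break }
        ov <- max(0, hsps$profile_end[i] - hsps$profile_start[j])
        if (ov > max_ov) { ok <- FALSE; break }
        gap <- ts[j] - te[i]
        if (gap < 0 || gap > max_gap) { ok <- FALSE; break }
        total <- total + hsps$score[j] - ov * min(percol[i], percol[j])
      }
    }
    if (ok && total > best) best <- total
  }
  best
}

random_hsp_set <- function(n) {
  ps <- sort(sample(0:80, n))
  len <- sample(5:30, n, replace = TRUE)
  gs <- sort(sample(seq(0, 20000, by = 3), n))
  data.frame(family_id = "f", contig_id = "c", strand = "+",
             genome_start = gs, genome_end = gs + 3L * len,
             profile_start = ps, profile_end = ps + len,
             score = round(runif(n, 10, 60), 2),
             peptide = strrep("A", len), stringsAsFactors = FALSE)
}

# A record stream that counts how many records it has yielded, for checking
# that consumers pull records one at a time.
counting_stream <- function(records) {
  count <- 0L
  pos <- 0L
  stream <- function() {
    pos <<- pos + 1L
    if (pos > length(records)) return(NULL)
    count <<- count + 1L
    records[[pos]]
  }
  list(stream = stream, yielded = function() count)
}

# Shared mid-size fixtures (built once per test run)
fix_markerset <- function() fixture("ms_small", function() {
  make_marker_set(n_families = 10L, n_members = 5L, mean_length = 200L,
                  divergence = 0.1, n_hde = 3L, rng_seed = 42L)
})

fix_genome <- function() fixture("genome_small", function() {
  make_genome(fix_markerset(), n_contigs = 6L, genome_size = 6e5,
              rng_seed = 42L)
})

fix_report <- function() fixture("report_small", function() {
  full_report(fix_genome()$assembly, fix_markerset())
})

# scripted blocks: a tiny 2-family marker set plus reads that do or do not
# contain family genes, to drive the stopping rule deterministically
scripted_fixture <- function() {
  fixture("scripted_reads", function() {
    ms <- make_marker_set(n_families = 2, n_members = 3, mean_length = 120,
                          rng_seed = 61)
    genes <- with_seed(62, lapply(ms$families, function(f) {
      mycomplete:::.reverse_translate(f$members[[1]])
    }))
    junk <- function(seed) with_seed(seed, list(
      seq_record("j", mycomplete:::.random_dna(400))))
    list(ms = ms, genes = genes, junk = junk)
  })
}
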