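# Synthetic study-condition generators: marker families, genomes with known
# embedded loci, truncated assemblies and simulated long reads. Every
# generator is bit-reproducible given (parameters, seed).

.random_peptide <- function(n) paste(sample(AA_ORDER, n, replace = TRUE),
                                     collapse = "")

.mutate_peptide <- function(x, divergence) {
  chars <- strsplit(x, "")[[1L]]
  hit <- which(runif(length(chars)) < divergence)
  for (i in hit) chars[i] <- sample(setdiff(AA_ORDER, chars[i]), 1L)
  paste(chars, collapse = "")
}

.random_dna <- function(n, gc = 0.5) {
  paste(sample(NT_ORDER, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

.mutate_dna <- function(x, divergence) {
  chars <- strsplit(x, "")[[1L]]
  hit <- which(runif(length(chars)) < divergence)
  for (i in hit) chars[i] <- sample(setdiff(NT_ORDER, chars[i]), 1L)
  paste(chars, collapse = "")
}

# Codon table for reverse translation (uniform choice among synonymous codons)
.codons_by_aa <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), gc)
})

.reverse_translate <- function(peptide) {
  aas <- strsplit(peptide, "")[[1L]]
  paste(vapply(aas, function(a) {
    opts <- .codons_by_aa[[a]]
    opts[sample.int(length(opts), 1L)]
  }, character(1)), collapse = "")
}

#' Generate synthetic protein marker families
#'
#' Each family descends from a random ancestor peptide of roughly
#' `mean_length` residues; members are independent copies with substitutions
#' at rate `divergence` (no indels, so the member alignment is the trivial
#' ungapped one). Profiles and 80%-of-minimum thresholds are built as for
#' real families, so every member clears its own family's threshold by
#' construction.
#'
#' @param n_families Number of families.
#' @param n_members Members per family.
#' @param mean_length Mean ungapped member length, residues.
#' @param divergence Substitutions per site among members, in `[0, 0.5)`.
#' @param rng_seed Integer seed.
#' @param params A [scan_params()] (pseudocount weight is taken from it).
#' @return List of [marker_family()] objects.
#' @export
make_marker_families <- function(n_families, n_members = 6L,
                                 mean_length = 300L, divergence = 0.1,
                                 rng_seed = 1L, params = scan_params()) {
  if (n_families < 1L) stop("n_families must be >= 1")
  if (divergence < 0 || divergence >= 0.5)
    stop("divergence must be in [0, 0.5)")
  with_seed(rng_seed, {
    lapply(seq_len(n_families), function(i) {
      len <- max(50L, round(runif(1L, 0.8, 1.2) * mean_length))
      anc <- .random_peptide(len)
      members <- vapply(seq_len(n_members), function(j) {
        .mutate_peptide(anc, divergence)
      }, character(1))
      id <- sprintf("fam%03d", i)
      names(members) <- sprintf("%s_m%02d", id, seq_len(n_members))
      marker_family(id, members,
                    species = sprintf("sp%02d", seq_len(n_members)),
                    pseudocount_weight = params$pseudocount)
    })
  })
}

#' Generate synthetic conserved non-coding elements
#'
#' @param n_elements Number of elements.
#' @param n_members Members per element.
#' @param length Element length, bases (must be at least `min_length`).
#' @param divergence Substitutions per site among members.
#' @param rng_seed Integer seed.
#' @param min_length Minimum element length, bases.
#' @return List of [hde_element()] objects.
#' @export
make_hde_elements <- function(n_elements, n_members = 6L, length = 300L,
                              divergence = 0.02, rng_seed = 1L,
                              min_length = 200L) {
  if (n_elements < 1L) stop("n_elements must be >= 1")
  with_seed(rng_seed, {
    lapply(seq_len(n_elements), function(i) {
      anc <- .random_dna(length)
      members <- vapply(seq_len(n_members), function(j) {
        .mutate_dna(anc, divergence)
      }, character(1))
      id <- sprintf("hde%02d", i)
      names(members) <- sprintf("%s_m%02d", id, seq_len(n_members))
      hde_element(id, members, min_length = min_length)
    })
  })
}

#' Generate a complete synthetic marker set
#'
#' Convenience wrapper bundling [make_marker_families()] and
#' [make_hde_elements()] into a [marker_set()], with the first `n_multicopy`
#' families given a multi-copy expectation via a synthetic genome survey.
#'
#' @param n_families,n_members,mean_length,divergence See
#'   [make_marker_families()].
#' @param n_multicopy Number of families expected in `copies` copies.
#' @param copies Expected minimum copy number for multi-copy families.
#' @param n_hde,hde_length,hde_divergence See [make_hde_elements()].
#' @param rng_seed Integer seed.
#' @param params A [scan_params()].
#' @return A [marker_set()].
#' @export
make_marker_set <- function(n_families = 20L, n_members = 6L,
                            mean_length = 300L, divergence = 0.1,
                            n_multicopy = 0L, copies = 2L,
                            n_hde = 0L, hde_length = 300L,
                            hde_divergence = 0.02,
                            rng_seed = 1L, params = scan_params()) {
  families <- make_marker_families(n_families, n_members, mean_length,
                                   divergence, rng_seed, params)
  if (n_multicopy > 0L) {
    survey <- setNames(lapply(seq_len(n_families), function(i) {
      if (i <= n_multicopy) rep(as.integer(copies), 3L) else rep(1L, 3L)
    }), vapply(families, function(f) f$id, character(1)))
    families <- set_copy_expectations(families, survey)
  }
  elements <- if (n_hde > 0L) {
    make_hde_elements(n_hde, n_members, hde_length, hde_divergence,
                      rng_seed + 10000L)
  } else list()
  marker_set(families, elements, params)
}

#' Build a genome with known embedded marker and element loci
#'
#' Contigs of random background sequence at the requested GC content, with
#' each family's first member reverse-translated (uniform codon choice) and
#' inserted at recorded loci on random strands; multi-copy families are
#' inserted `expected_min_copies` times, element members verbatim. Optional
#' introns (up to `max_introns` per gene, 50-500 bp of random sequence at
#' codon boundaries) split genes into multiple exons.
#'
#' @param markerset A [marker_set()].
#' @param n_contigs Number of contigs.
#' @param genome_size Total genome size, bases.
#' @param gc GC content of the background, proportion.
#' @param max_introns Maximum introns per protein locus (0 = none).
#' @param rng_seed Integer seed.
#' @return List with `assembly` (an [assembly()]) and `truth` (data frame:
#'   `id`, `contig_id`, `strand`, `genome_start`, `genome_end`, `kind`).
#' @export
make_genome <- function(markerset, n_contigs = 10L, genome_size = 2e6,
                        gc = 0.5, max_introns = 0L, rng_seed = 1L) {
  stopifnot(inherits(markerset, "marker_set"))
  with_seed(rng_seed, {
    contig_len <- rep(floor(genome_size / n_contigs), n_contigs)
    contig_len[1L] <- contig_len[1L] + (genome_size - sum(contig_len))
    contigs <- lapply(contig_len, function(n) {
      strsplit(.random_dna(n, gc), "")[[1L]]
    })
    names(contigs) <- sprintf("ctg%02d", seq_len(n_contigs))

    inserts <- list()
    for (f in markerset$families) {
      nt0 <- NULL
      for (cp in seq_len(f$expected_min_copies)) {
        nt <- .reverse_translate(f$members[[1L]])
        if (max_introns > 0L) {
          n_int <- sample.int(max_introns + 1L, 1L) - 1L
          if (n_int > 0L) {
            n_cod <- nchar(nt) / 3L
            at <- sort(sample(seq_len(n_cod - 1L), n_int)) * 3L
            pieces <- substring(nt, c(1L, at + 1L), c(at, nchar(nt)))
            intr <- vapply(seq_len(n_int), function(i) {
              .random_dna(sample(50:500, 1L), gc)
            }, character(1))
            nt <- paste0(paste0(pieces[seq_len(n_int)], intr, collapse = ""),
                         pieces[n_int + 1L])
          }
        }
        inserts[[length(inserts) + 1L]] <- list(id = f$id, seq = nt,
                                                kind = "protein")
        nt0 <- nt
      }
    }
    for (e in markerset$hde_elements) {
      inserts[[length(inserts) + 1L]] <- list(id = e$id, seq = e$members[[1L]],
                                              kind = "hde")
    }

    placed <- lapply(contigs, function(x) matrix(numeric(), ncol = 2L))
    truth <- vector("list", length(inserts))
    margin <- 100L
    for (ii in seq_along(inserts)) {
      ins <- inserts[[ii]]
      len <- nchar(ins$seq)
      ok <- FALSE
      for (try in seq_len(500L)) {
        ci <- sample.int(n_contigs, 1L, prob = contig_len)
        cl <- contig_len[ci]
        if (cl < len + 2L * margin) next
        start <- sample.int(cl - len - 2L * margin, 1L) + margin  # 0-based
        iv <- placed[[ci]]
        if (nrow(iv) > 0L &&
            any(pmin(iv[, 2L], start + len + margin) >
                pmax(iv[, 1L], start - margin))) next
        ok <- TRUE
        break
      }
      if (!ok) stop("loci cannot fit in requested genome size")
      strand <- sample(c("+", "-"), 1L)
      s <- if (strand == "+") ins$seq else reverse_complement_string(ins$seq)
      contigs[[ci]][(start + 1L):(start + len)] <- strsplit(s, "")[[1L]]
      placed[[ci]] <- rbind(placed[[ci]], c(start, start + len))
      truth[[ii]] <- data.frame(id = ins$id, contig_id = names(contigs)[ci],
                                strand = strand, genome_start = start,
                                genome_end = start + len, kind = ins$kind,
                                stringsAsFactors = FALSE)
    }
    records <- lapply(names(contigs), function(nm) {
      seq_record(nm, paste(contigs[[nm]], collapse = ""))
    })
    list(assembly = assembly(records, source_path = "synthetic"),
         truth = do.call(rbind, truth))
  })
}

#' Randomly truncate an assembly
#'
#' Non-overlapping windows are deleted uniformly at random across contigs
#' until at least fraction `f` of the total sequence is removed (the first
#' crossing of the target stops the process, so the overshoot is at most one
#' window). Each deletion splits its contig into two records, so the result
#' is a valid, more fragmented assembly with no masked runs.
#'
#' @param x An [assembly()].
#' @param f Fraction of total bases to remove, in `[0, 1)`.
#' @param window Deletion window size, bases.
#' @param rng_seed Integer seed.
#' @return List with `assembly` (the truncated [assembly()]) and `deletions`
#'   (data frame: `contig_id`, `start`, `end`, 0-based half-open).
#' @export
truncate_assembly <- function(x, f, window = 1000L, rng_seed = 1L) {
  if (f < 0 || f >= 1) stop("f must be in [0, 1)")
  if (window < 1L) stop("window must be >= 1")
  if (f == 0) return(list(assembly = x,
                          deletions = data.frame(contig_id = character(),
                                                 start = integer(),
                                                 end = integer())))
  lens <- contig_lengths(x)
  total <- sum(lens)
  target <- f * total
  with_seed(rng_seed, {
    dels <- lapply(x$records, function(r) matrix(numeric(), ncol = 2L))
    removed <- 0
    attempts <- 0L
    while (removed < target) {
      attempts <- attempts + 1L
      if (attempts > 10000L) stop("cannot remove requested fraction")
      ci <- sample.int(length(lens), 1L, prob = lens)
      if (lens[ci] <= window) next
      start <- sample.int(lens[ci] - window, 1L) - 1L
      iv <- dels[[ci]]
      if (nrow(iv) > 0L &&
          any(pmin(iv[, 2L], start + window) > pmax(iv[, 1L], start))) next
      dels[[ci]] <- rbind(iv, c(start, start + window))
      removed <- removed + window
    }
    records <- list()
    log_rows <- list()
    for (nm in names(x$records)) {
      s <- x$records[[nm]]$sequence
      iv <- dels[[nm]]
      if (nrow(iv) == 0L) {
        records[[length(records) + 1L]] <- x$records[[nm]]
        next
      }
      iv <- iv[order(iv[, 1L]), , drop = FALSE]
      log_rows[[length(log_rows) + 1L]] <-
        data.frame(contig_id = nm, start = iv[, 1L], end = iv[, 2L])
      keep_start <- c(0, iv[, 2L])
      keep_end <- c(iv[, 1L], nchar(s))
      piece <- 0L
      for (i in seq_along(keep_start)) {
        if (keep_end[i] <= keep_start[i]) next
        piece <- piece + 1L
        records[[length(records) + 1L]] <- seq_record(
          sprintf("%s_%d", nm, piece),
          substr(s, keep_start[i] + 1L, keep_end[i]))
      }
    }
    if (length(records) == 0L) stop("truncation removed the whole assembly")
    list(assembly = assembly(records, source_path = x$source_path),
         deletions = do.call(rbind, log_rows))
  })
}

#' Simulate long reads from an assembly
#'
#' Reads are drawn from uniform random positions and strands; lengths are
#' normal, truncated to `[500, contig length]`; sequencing errors are
#' substitutions only (the homology engine is not frameshift tolerant, so
#' indel errors would probe a declared non-goal, not the method). Qualities
#' are flat.
#'
#' @param x An [assembly()].
#' @param n_reads Number of reads.
#' @param length_mean,length_sd Read length distribution, bases.
#' @param error_rate Per-base substitution rate, in `[0, 0.3)`.
#' @param rng_seed Integer seed.
#' @return List of [seq_record()] objects with flat qualities.
#' @export
simulate_reads <- function(x, n_reads, length_mean = 8000, length_sd = 1000,
                           error_rate = 0, rng_seed = 1L) {
  if (error_rate < 0 || error_rate >= 0.3)
    stop("error_rate must be in [0, 0.3)")
  if (length_mean <= 0) stop("length_mean must be positive")
  lens <- contig_lengths(x)
  if (max(lens) < 500) stop("assembly shorter than minimum read length")
  if (n_reads == 0L) return(list())
  nt_codes <- utf8ToInt("ACGT")
  with_seed(rng_seed, {
    eligible <- which(lens >= 500)
    lapply(seq_len(n_reads), function(i) {
      ci <- if (length(eligible) == 1L) eligible else
        sample(eligible, 1L, prob = lens[eligible])
      cl <- lens[ci]
      len <- min(cl, max(500L, round(rnorm(1L, length_mean, length_sd))))
      start <- sample.int(cl - len + 1L, 1L)
      s <- substr(x$records[[ci]]$sequence, start, start + len - 1L)
      if (runif(1L) < 0.5) s <- reverse_complement_string(s)
      if (error_rate > 0) {
        codes <- utf8ToInt(s)
        hit <- which(runif(nchar(s)) < error_rate)
        if (length(hit) > 0L) {
          # shift each hit base to one of the three other bases, uniformly
          idx <- match(codes[hit], nt_codes)
          shift <- sample.int(3L, length(hit), replace = TRUE)
          codes[hit] <- nt_codes[((idx - 1L + shift) %% 4L) + 1L]
          s <- intToUtf8(codes)
        }
      }
      seq_record(sprintf("read_%06d", i), s, quality = strrep("I", nchar(s)))
    })
  })
}
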