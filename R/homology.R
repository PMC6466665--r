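# Seed tables: every k-mer of every member peptide, anchored at the profile
# column of its first residue. Only k-mers whose residues map to consecutive
# retained profile columns can seed a diagonal extension.
build_seed_table <- function(families, k) {
  seqs <- list(); fam <- integer(); col <- integer()
  for (fi in seq_along(families)) {
    f <- families[[fi]]
    seen <- character()
    for (mi in seq_along(f$members)) {
      codes <- encode_peptide(f$members[[mi]])
      cmap <- f$colmaps[[mi]]
      np <- length(codes)
      if (np < k) next
      for (p in 1:(np - k + 1L)) {
        cols <- cmap[p:(p + k - 1L)]
        if (anyNA(cols) || any(diff(cols) != 1L)) next
        if (any(codes[p:(p + k - 1L)] >= AA_X)) next
        key <- paste0(cols[1L], ":", paste(codes[p:(p + k - 1L)], collapse = ","))
        if (key %in% seen) next
        seen <- c(seen, key)
        seqs[[length(seqs) + 1L]] <- codes[p:(p + k - 1L)]
        fam <- c(fam, fi)
        col <- c(col, cols[1L])
      }
    }
  }
  if (length(seqs) == 0L)
    return(list(seeds = matrix(integer(), nrow = k), fam = integer(),
                col = integer(), k = k))
  list(seeds = matrix(unlist(seqs), nrow = k), fam = fam, col = col, k = k)
}

subset_seed_table <- function(st, fam_idx) {
  keep <- st$fam %in% fam_idx
  list(seeds = st$seeds[, keep, drop = FALSE],
       fam = match(st$fam[keep], fam_idx), col = st$col[keep], k = st$k)
}

# Merge overlapping HSPs on the same (family, diagonal), keeping the higher
# score; the C++ pass suppresses most duplicates, this finishes the job.
.merge_diagonal <- function(df) {
  if (nrow(df) <= 1L) return(df)
  df$diag <- df$fs - df$ps
  df <- df[order(df$fam, df$diag, df$fs), , drop = FALSE]
  keep <- rep(TRUE, nrow(df))
  i <- 1L
  for (j in seq_len(nrow(df))[-1L]) {
    same <- df$fam[j] == df$fam[i] && df$diag[j] == df$diag[i]
    if (same && df$fs[j] < df$fe[i]) {
      if (df$score[j] > df$score[i]) keep[i] <- FALSE else keep[j] <- FALSE
      if (keep[j]) i <- j
    } else i <- j
  }
  df <- df[keep, , drop = FALSE]
  df$diag <- NULL
  df
}

.empty_hsps <- function() {
  data.frame(family_id = character(), contig_id = character(),
             strand = character(), genome_start = integer(),
             genome_end = integer(), profile_start = integer(),
             profile_end = integer(), score = numeric(),
             peptide = character(), stringsAsFactors = FALSE)
}

# Scan one frame's peptide (already encoded) for all families in the seed
# table; returns HSPs in genome coordinates.
.scan_codes <- function(codes, frame, families, st, params) {
  if (length(st$fam) == 0L) return(.empty_hsps())
  profs <- lapply(families, function(f) score_matrix(f$profile))
  raw <- .seed_extend_multi(codes, profs, st$seeds, st$fam, st$col,
                            AA_X, params$xdrop, params$min_hsp_score)
  if (nrow(raw) == 0L) return(.empty_hsps())
  raw <- .merge_diagonal(raw)
  n <- frame$contig_length
  off <- frame$offset
  if (frame$strand == "+") {
    gs <- off + 3L * raw$fs; ge <- off + 3L * raw$fe
  } else {
    gs <- n - off - 3L * raw$fe; ge <- n - off - 3L * raw$fs
  }
  data.frame(family_id = vapply(families[raw$fam], function(f) f$id,
                                character(1)),
             contig_id = frame$contig_id, strand = frame$strand,
             genome_start = gs, genome_end = ge,
             profile_start = raw$ps, profile_end = raw$pe,
             score = raw$score,
             peptide = substring(frame$peptide, raw$fs + 1L, raw$fe),
             stringsAsFactors = FALSE)
}

#' Seeded translated search of one family against six-frame translations
#'
#' Exact `seed_k`-mer matches between any member peptide and a translated
#' frame are extended in both directions along the diagonal by
#' profile-vs-peptide scoring with X-drop termination; overlapping HSPs on
#' one diagonal keep the best score; HSPs under `min_hsp_score` bits are
#' dropped. Genome coordinates are 0-based half-open on the forward strand
#' and always span whole codons.
#'
#' @param family A [marker_family()].
#' @param frames Frames from [six_frame_translate()] (possibly from several
#'   contigs).
#' @param params A [scan_params()].
#' @return A data frame of HSPs: `family_id`, `contig_id`, `strand`,
#'   `genome_start`, `genome_end`, `profile_start`, `profile_end`, `score`,
#'   `peptide`.
#' @export
seed_and_extend <- function(family, frames, params = scan_params()) {
  st <- build_seed_table(list(family), params$seed_k)
  out <- lapply(frames, function(fr) {
    .scan_codes(encode_peptide(fr$peptide), fr, list(family), st, params)
  })
  do.call(rbind, out)
}

#' Assemble colinear HSPs into the best-scoring chain
#'
#' Dynamic programme over HSPs of one family on one contig and strand.
#' Successive HSPs must advance strictly in both genome and profile
#' coordinates (genome order follows the strand), with a genomic gap of at
#' most `max_genome_gap` bases and a profile overlap of at most
#' `max_profile_overlap` columns. Overlapping profile columns are not
#' double-counted: the overlap times the lower-scoring HSP's mean per-column
#' score is subtracted. Score ties are broken toward the smaller genome start,
#' then the lexicographically smaller exon fingerprint.
#'
#' @param hsps Data frame of HSPs sharing family, contig and strand.
#' @param params A [scan_params()].
#' @return List with `exons` (the chained HSP rows, in profile order) and
#'   `total_score`; both empty/zero for empty input.
#' @export
chain_hsps <- function(hsps, params = scan_params()) {
  if (is.null(hsps) || nrow(hsps) == 0L)
    return(list(exons = .empty_hsps(), total_score = 0))
  minus <- hsps$strand[1L] == "-"
  ts <- if (minus) -hsps$genome_end else hsps$genome_start
  te <- if (minus) -hsps$genome_start else hsps$genome_end
  ord <- order(hsps$profile_start, hsps$profile_end, ts)
  hsps <- hsps[ord, , drop = FALSE]
  ts <- ts[ord]; te <- te[ord]
  res <- .chain_dp(as.numeric(hsps$profile_start),
                   as.numeric(hsps$profile_end),
                   as.numeric(ts), as.numeric(te),
                   as.numeric(hsps$score),
                   params$max_genome_gap, params$max_profile_overlap)
  dp <- res$dp
  pred <- res$pred
  trace <- function(j) {
    idx <- integer()
    while (j > 0L) { idx <- c(j, idx); j <- pred[j] }
    idx
  }
  best <- max(dp)
  cands <- which(dp > best - 1e-9)
  chains <- lapply(cands, trace)
  if (length(cands) > 1L) {
    gs <- vapply(chains, function(ix) min(hsps$genome_start[ix]), numeric(1))
    fp <- vapply(chains, function(ix) {
      paste(hsps$genome_start[ix], hsps$genome_end[ix], collapse = ";")
    }, character(1))
    pick <- order(gs, fp)[1L]
  } else pick <- 1L
  idx <- chains[[pick]]
  list(exons = hsps[idx, , drop = FALSE], total_score = dp[cands[pick]])
}

#' Classify a gene model as complete, partial or aberrant
#'
#' A model whose peptide is at least `aberrant_factor` times the family's
#' mean member length is aberrant. Otherwise it is complete when its total
#' score reaches the family threshold and it covers at least
#' `coverage_complete` of the profile columns (both boundaries inclusive);
#' failing that it is partial when the score reaches `partial_floor` of the
#' threshold; anything weaker is discarded (`NA`).
#'
#' @param model A gene model (see [scan_assembly()]).
#' @param family The model's [marker_family()].
#' @param params A [scan_params()].
#' @return `"aberrant"`, `"complete"`, `"partial"`, or `NA_character_`.
#' @export
classify_model <- function(model, family, params = scan_params()) {
  if (nchar(model$model_peptide) >= params$aberrant_factor * family$mean_length)
    return("aberrant")
  thr <- family$score_threshold
  if (model$total_score >= thr && model$coverage >= params$coverage_complete)
    return("complete")
  if (model$total_score >= params$partial_floor * thr) return("partial")
  NA_character_
}

.profile_union <- function(starts, ends) {
  ord <- order(starts)
  starts <- starts[ord]; ends <- ends[ord]
  tot <- 0L; cur_s <- starts[1L]; cur_e <- ends[1L]
  for (i in seq_along(starts)[-1L]) {
    if (starts[i] <= cur_e) cur_e <- max(cur_e, ends[i])
    else { tot <- tot + (cur_e - cur_s); cur_s <- starts[i]; cur_e <- ends[i] }
  }
  tot + (cur_e - cur_s)
}

.make_model <- function(exons, total_score, family, params) {
  pep <- paste(exons$peptide, collapse = "")
  model <- list(family_id = family$id,
                contig_id = exons$contig_id[1L],
                strand = exons$strand[1L],
                exons = exons,
                model_peptide = pep,
                total_score = total_score,
                coverage = .profile_union(exons$profile_start,
                                          exons$profile_end) /
                  profile_length(family$profile),
                genome_start = min(exons$genome_start),
                genome_end = max(exons$genome_end),
                status = NA_character_)
  model$status <- classify_model(model, family, params)
  structure(model, class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model %s @ %s:%d-%d(%s) %s, %.1f bits, %.0f%% coverage>\n",
              x$family_id, x$contig_id, x$genome_start, x$genome_end,
              x$strand, x$status, x$total_score, 100 * x$coverage))
  invisible(x)
}

# Iteratively extract chains for one family/contig/strand group so that
# multiple gene copies (including tandem copies) each yield a model. After a
# chain is accepted its HSPs, and any HSP mostly inside the model's genomic
# span, are removed before re-chaining.
.models_for_group <- function(hsps, family, params, max_copies = 25L) {
  models <- list()
  floor_score <- params$partial_floor * family$score_threshold
  for (rep in seq_len(max_copies)) {
    if (nrow(hsps) == 0L) break
    ch <- chain_hsps(hsps, params)
    if (nrow(ch$exons) == 0L || ch$total_score < floor_score) break
    model <- .make_model(ch$exons, ch$total_score, family, params)
    if (!is.na(model$status)) models[[length(models) + 1L]] <- model
    used <- paste(ch$exons$genome_start, ch$exons$genome_end)
    all_key <- paste(hsps$genome_start, hsps$genome_end)
    ov <- pmin(hsps$genome_end, model$genome_end) -
      pmax(hsps$genome_start, model$genome_start)
    span <- hsps$genome_end - hsps$genome_start
    hsps <- hsps[!(all_key %in% used) & !(ov / span >= 0.5), , drop = FALSE]
  }
  models
}

#' Scan an assembly for all marker families
#'
#' Translates each contig in six frames (cached across families), finds HSPs
#' by seeded X-drop extension, chains them per family/contig/strand, and
#' classifies the resulting gene models. Models are returned in deterministic
#' order (family id, contig id, strand, genome start).
#'
#' @param x An [assembly()].
#' @param markerset A [marker_set()].
#' @param params A [scan_params()]; defaults to the marker set's.
#' @return List of `gene_model` objects.
#' @export
scan_assembly <- function(x, markerset, params = NULL) {
  stopifnot(inherits(x, "assembly"), inherits(markerset, "marker_set"))
  if (is.null(params)) params <- markerset$params
  if (length(x$records) == 0L) stop("empty assembly")
  families <- markerset$families
  st <- markerset$seed_table
  hsp_list <- list()
  for (rec in x$records) {
    frames <- six_frame_translate(rec)
    for (fr in frames) {
      if (!nzchar(fr$peptide)) next
      h <- .scan_codes(encode_peptide(fr$peptide), fr, families, st, params)
      if (nrow(h) > 0L) hsp_list[[length(hsp_list) + 1L]] <- h
    }
  }
  if (length(hsp_list) == 0L) return(list())
  hsps <- do.call(rbind, hsp_list)
  models <- list()
  groups <- split(seq_len(nrow(hsps)),
                  paste(hsps$family_id, hsps$contig_id, hsps$strand,
                        sep = "\r"))
  for (g in groups) {
    fam <- families[[hsps$family_id[g[1L]]]]
    models <- c(models, .models_for_group(hsps[g, , drop = FALSE], fam, params))
  }
  if (length(models) == 0L) return(list())
  ord <- order(vapply(models, function(m) m$family_id, character(1)),
               vapply(models, function(m) m$contig_id, character(1)),
               vapply(models, function(m) m$strand, character(1)),
               vapply(models, function(m) m$genome_start, numeric(1)))
  models[ord]
}
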