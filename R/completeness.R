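#' Pick each family's representative gene model
#'
#' Aberrant models are excluded from representative choice (but tallied);
#' among the rest the longest model peptide wins, ties broken by higher total
#' score, then smaller genome start. A family with only aberrant models is
#' "aberrant"; with no models at all, "missing".
#'
#' @param models List of gene models from [scan_assembly()].
#' @param markerset A [marker_set()].
#' @return Named list per family id: `status`, `best_model` (or `NULL`),
#'   `n_models`, `n_aberrant`.
#' @export
select_final_models <- function(models, markerset) {
  fam_ids <- names(markerset$families)
  by_fam <- split(models, vapply(models, function(m) m$family_id, character(1)))
  out <- lapply(fam_ids, function(fid) {
    ms <- by_fam[[fid]]
    if (is.null(ms) || length(ms) == 0L)
      return(list(status = "missing", best_model = NULL, n_models = 0L,
                  n_aberrant = 0L))
    status <- vapply(ms, function(m) m$status, character(1))
    ok <- ms[status != "aberrant"]
    if (length(ok) == 0L)
      return(list(status = "aberrant", best_model = NULL,
                  n_models = length(ms), n_aberrant = length(ms)))
    len <- vapply(ok, function(m) nchar(m$model_peptide), numeric(1))
    sc <- vapply(ok, function(m) m$total_score, numeric(1))
    gs <- vapply(ok, function(m) m$genome_start, numeric(1))
    pick <- order(-len, -sc, gs)[1L]
    list(status = ok[[pick]]$status, best_model = ok[[pick]],
         n_models = length(ms), n_aberrant = sum(status == "aberrant"))
  })
  names(out) <- fam_ids
  out
}

#' Protein completeness percentages
#'
#' The headline number counts complete families only;
#' `pct_complete_or_partial` is reported alongside since partial models may
#' reflect genuine but fragmented genes.
#'
#' @param selection Output of [select_final_models()].
#' @param markerset A [marker_set()].
#' @return List with `pct_complete`, `pct_complete_or_partial`,
#'   `pct_partial`, `pct_aberrant`, `pct_missing`, `n_families`.
#' @export
protein_completeness <- function(selection, markerset) {
  n <- length(markerset$families)
  status <- vapply(selection, function(s) s$status, character(1))
  list(pct_complete = 100 * sum(status == "complete") / n,
       pct_complete_or_partial =
         100 * sum(status %in% c("complete", "partial")) / n,
       pct_partial = 100 * sum(status == "partial") / n,
       pct_aberrant = 100 * sum(status == "aberrant") / n,
       pct_missing = 100 * sum(status == "missing") / n,
       n_families = n)
}

#' Search an assembly for conserved non-coding elements
#'
#' Each element's nucleotide profile is scanned over both strands, seeded by
#' exact `hde_seed_k`-mers from the element members and extended as in
#' [seed_and_extend()]. An element is detected when its best hit scores at
#' least 80% of the weakest member's self-score.
#'
#' @param x An [assembly()].
#' @param elements List of [hde_element()] objects.
#' @param params A [scan_params()].
#' @return List with `hits` (data frame: `element_id`, `contig_id`, `strand`,
#'   `genome_start`, `genome_end`, `score`, `detected`), `detected`,
#'   `total`, `pct_hde`.
#' @export
hde_search <- function(x, elements, params = scan_params()) {
  if (length(elements) == 0L) stop("no elements to search")
  k <- params$hde_seed_k
  st <- .hde_seed_table(elements, k)
  profs <- lapply(elements, function(e) score_matrix(e$profile))
  hit_rows <- list()
  for (rec in x$records) {
    n <- nchar(rec$sequence)
    for (strand in c("+", "-")) {
      s <- if (strand == "+") rec$sequence
           else reverse_complement_string(rec$sequence)
      codes <- encode_nucleotide(s)
      raw <- .seed_extend_multi(codes, profs, st$seeds, st$fam, st$col,
                                NT_N, params$xdrop, params$min_hsp_score)
      if (nrow(raw) == 0L) next
      raw <- .merge_diagonal(raw)
      gs <- if (strand == "+") raw$fs else n - raw$fe
      ge <- if (strand == "+") raw$fe else n - raw$fs
      hit_rows[[length(hit_rows) + 1L]] <- data.frame(
        element_id = vapply(elements[raw$fam], function(e) e$id, character(1)),
        contig_id = rec$id, strand = strand,
        genome_start = gs, genome_end = ge, score = raw$score,
        stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(hit_rows)) do.call(rbind, hit_rows) else
    data.frame(element_id = character(), contig_id = character(),
               strand = character(), genome_start = integer(),
               genome_end = integer(), score = numeric(),
               stringsAsFactors = FALSE)
  thr <- vapply(elements, function(e) e$score_threshold, numeric(1))
  names(thr) <- vapply(elements, function(e) e$id, character(1))
  hits$detected <- hits$score >= thr[hits$element_id]
  detected_ids <- unique(hits$element_id[hits$detected])
  list(hits = hits, detected = length(detected_ids),
       total = length(elements),
       detected_ids = detected_ids,
       pct_hde = 100 * length(detected_ids) / length(elements))
}

.hde_seed_table <- function(elements, k) {
  seqs <- list(); fam <- integer(); col <- integer()
  for (ei in seq_along(elements)) {
    e <- elements[[ei]]
    aln_cols <- e$profile$col_index
    seen <- character()
    for (mi in seq_along(e$members)) {
      row <- strsplit(e$alignment[[mi]], "")[[1L]]
      res_cols <- which(!row %in% c("-", "."))
      cmap <- match(res_cols, aln_cols) - 1L
      codes <- encode_nucleotide(e$members[[mi]])
      np <- length(codes)
      if (np < k) next
      for (p in 1:(np - k + 1L)) {
        cols <- cmap[p:(p + k - 1L)]
        if (anyNA(cols) || any(diff(cols) != 1L)) next
        kc <- codes[p:(p + k - 1L)]
        if (any(kc >= NT_N)) next
        key <- paste0(cols[1L], ":", paste(kc, collapse = ","))
        if (key %in% seen) next
        seen <- c(seen, key)
        seqs[[length(seqs) + 1L]] <- kc
        fam <- c(fam, ei); col <- c(col, cols[1L])
      }
    }
  }
  if (length(seqs) == 0L)
    return(list(seeds = matrix(integer(), nrow = k), fam = integer(),
                col = integer(), k = k))
  list(seeds = matrix(unlist(seqs), nrow = k), fam = fam, col = col, k = k)
}

#' Audit multi-copy families for collapsed assembly regions
#'
#' For each family expected in more than one copy, counts non-aberrant models
#' scoring at least the family threshold at distinct loci (pairwise genomic
#' overlap below 50% of the smaller model). A family with fewer such copies
#' than expected is flagged as a potentially collapsed region. Note the
#' method cannot distinguish genuinely collapsed repeats from unassembled
#' data.
#'
#' @param models List of gene models from [scan_assembly()].
#' @param markerset A [marker_set()].
#' @return List with `n_copies` (named per family) and `collapse_flags`
#'   (family ids).
#' @export
multicopy_audit <- function(models, markerset) {
  fam_ids <- names(markerset$families)
  by_fam <- split(models, vapply(models, function(m) m$family_id, character(1)))
  n_copies <- setNames(integer(length(fam_ids)), fam_ids)
  for (fid in fam_ids) {
    fam <- markerset$families[[fid]]
    ms <- by_fam[[fid]]
    if (is.null(ms)) next
    ms <- ms[vapply(ms, function(m) {
      m$status != "aberrant" && m$total_score >= fam$score_threshold
    }, logical(1))]
    n_copies[fid] <- .count_distinct_loci(ms)
  }
  expected <- vapply(markerset$families, function(f) f$expected_min_copies,
                     integer(1))
  flags <- fam_ids[expected > 1L & n_copies < expected]
  list(n_copies = n_copies, collapse_flags = flags)
}

.count_distinct_loci <- function(ms) {
  if (length(ms) == 0L) return(0L)
  kept <- list()
  ord <- order(-vapply(ms, function(m) m$total_score, numeric(1)))
  for (m in ms[ord]) {
    distinct <- all(vapply(kept, function(k) {
      if (k$contig_id != m$contig_id) return(TRUE)
      ov <- min(k$genome_end, m$genome_end) - max(k$genome_start, m$genome_start)
      if (ov <= 0) return(TRUE)
      ov / min(k$genome_end - k$genome_start,
               m$genome_end - m$genome_start) < 0.5
    }, logical(1)))
    if (distinct) kept[[length(kept) + 1L]] <- m
  }
  length(kept)
}

#' Full completeness report for an assembly
#'
#' Runs the whole pipeline: marker scan, representative selection, protein
#' completeness, conserved-element search, multi-copy audit, and assembly
#' statistics. Deterministic given its inputs.
#'
#' @param x An [assembly()].
#' @param markerset A [marker_set()].
#' @param params A [scan_params()]; defaults to the marker set's.
#' @return An object of class `completeness_report`.
#' @export
full_report <- function(x, markerset, params = NULL) {
  if (is.null(params)) params <- markerset$params
  models <- scan_assembly(x, markerset, params)
  selection <- select_final_models(models, markerset)
  pct <- protein_completeness(selection, markerset)
  audit <- multicopy_audit(models, markerset)
  hde <- if (length(markerset$hde_elements) > 0L) {
    hde_search(x, markerset$hde_elements, params)
  } else list(hits = NULL, detected = 0L, total = 0L, detected_ids = character(),
              pct_hde = NA_real_)
  fam_ids <- names(markerset$families)
  per_family <- data.frame(
    family_id = fam_ids,
    status = vapply(selection, function(s) s$status, character(1)),
    n_copies = as.integer(audit$n_copies[fam_ids]),
    expected_min_copies = vapply(markerset$families,
                                 function(f) f$expected_min_copies, integer(1)),
    score = vapply(selection, function(s) {
      if (is.null(s$best_model)) NA_real_ else s$best_model$total_score
    }, numeric(1)),
    peptide_length = vapply(selection, function(s) {
      if (is.null(s$best_model)) NA_integer_
      else nchar(s$best_model$model_peptide)
    }, integer(1)),
    collapsed = fam_ids %in% audit$collapse_flags,
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(per_family = per_family,
                 pct_complete = pct$pct_complete,
                 pct_complete_or_partial = pct$pct_complete_or_partial,
                 pct_partial = pct$pct_partial,
                 pct_aberrant = pct$pct_aberrant,
                 pct_missing = pct$pct_missing,
                 hde_detected = hde$detected,
                 hde_total = hde$total,
                 pct_hde = hde$pct_hde,
                 collapse_flags = audit$collapse_flags,
                 assembly_stats = assembly_stats(x),
                 source_path = x$source_path,
                 models = models,
                 note = paste("copy counts cannot distinguish collapsed",
                              "repeats from unassembled data")),
            class = "completeness_report")
}

#' @export
print.completeness_report <- function(x, ...) {
  cat(sprintf("Completeness report (%d protein markers, %d DNA elements)\n",
              nrow(x$per_family), x$hde_total))
  cat(sprintf("  complete: %.1f%%  complete-or-partial: %.1f%%  partial: %.1f%%\n",
              x$pct_complete, x$pct_complete_or_partial, x$pct_partial))
  cat(sprintf("  aberrant: %.1f%%  missing: %.1f%%\n",
              x$pct_aberrant, x$pct_missing))
  if (x$hde_total > 0L)
    cat(sprintf("  conserved elements detected: %d/%d (%.1f%%)\n",
                x$hde_detected, x$hde_total, x$pct_hde))
  cat(sprintf("  multi-copy collapse flags: %s\n",
              if (length(x$collapse_flags)) paste(x$collapse_flags,
                                                  collapse = ", ") else "none"))
  print(x$assembly_stats)
  invisible(x)
}
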