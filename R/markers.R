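#' Protein marker families
#'
#' A marker family is a set of orthologous peptides from reference species,
#' summarised as a profile ([build_profile()]) with a per-family detection
#' threshold equal to 80% of the weakest member's self-score
#' ([family_threshold()]). `mean_length` is the mean ungapped member length
#' and anchors the aberrant-model rule; `expected_min_copies` is the minimum
#' copy number observed across surveyed genomes (1 for single-copy families).
#'
#' @param id Family identifier.
#' @param alignment Character vector of equal-length gapped member rows,
#'   named by member id.
#' @param species Character vector of source species, one per member
#'   (defaults to member names).
#' @param pseudocount_weight,background Passed to [build_profile()].
#' @param skip_penalty Passed to [score_sequence()] for member self-scores.
#' @return An object of class `marker_family`.
#' @export
marker_family <- function(id, alignment, species = NULL,
                          pseudocount_weight = 1.0, background = NULL,
                          skip_penalty = 2) {
  if (is.null(names(alignment)))
    names(alignment) <- paste0(id, "_m", seq_along(alignment))
  if (is.null(species)) species <- names(alignment)
  stopifnot(length(species) == length(alignment))
  profile <- build_profile(alignment, pseudocount_weight, background,
                           alphabet = "protein")
  members <- gsub("[-.]", "", alignment)
  if (any(!nzchar(members))) stop("family '", id, "' has an all-gap member")

  # map each member's ungapped residue index (1-based) to its 0-based profile
  # column, NA where the alignment column was dropped as gappy
  colmaps <- lapply(alignment, function(row) {
    chars <- strsplit(row, "")[[1L]]
    res_cols <- which(!chars %in% c("-", "."))
    m <- match(res_cols, profile$col_index) - 1L
    m
  })
  self_scores <- vapply(members, function(m) {
    score_sequence(profile, m, skip_penalty)
  }, numeric(1))
  fam <- structure(list(
    id = id, members = members, species = species, alignment = alignment,
    profile = profile, colmaps = colmaps, self_scores = self_scores,
    score_threshold = family_threshold(self_scores),
    mean_length = mean(nchar(members)),
    expected_min_copies = 1L, single_copy = TRUE), class = "marker_family")
  fam
}

#' @export
print.marker_family <- function(x, ...) {
  cat(sprintf(
    "<marker_family %s: %d members, %d columns, threshold %.1f bits%s>\n",
    x$id, length(x$members), profile_length(x$profile), x$score_threshold,
    if (x$single_copy) "" else sprintf(", >=%d copies", x$expected_min_copies)))
  invisible(x)
}

#' Highly conserved non-coding DNA elements
#'
#' Elements are nucleotide profiles built from alignments of conserved
#' non-coding loci (at least 200 bp, at least 70% identity among members).
#' Detection reuses the protein rule: an element is present when the best hit
#' scores at least 80% of the weakest member's self-score.
#'
#' @param id Element identifier.
#' @param alignment Gapped nucleotide member rows, named by member.
#' @param min_length Minimum element length, bases.
#' @param pseudocount_weight,background Passed to [build_profile()].
#' @return An object of class `hde_element`.
#' @export
hde_element <- function(id, alignment, min_length = 200L,
                        pseudocount_weight = 1.0, background = NULL) {
  if (is.null(names(alignment)))
    names(alignment) <- paste0(id, "_m", seq_along(alignment))
  profile <- build_profile(alignment, pseudocount_weight, background,
                           alphabet = "dna")
  if (profile_length(profile) < min_length)
    stop("element '", id, "' profile shorter than min_length (",
         profile_length(profile), " < ", min_length, ")")
  members <- gsub("[-.]", "", alignment)
  identity <- .mean_pairwise_identity(alignment)
  if (!is.na(identity) && identity < 0.70)
    stop("element '", id, "' member identity below 70% (",
         sprintf("%.2f", identity), ")")
  self_scores <- vapply(members, function(m) score_sequence(profile, m),
                        numeric(1))
  structure(list(id = id, members = members, alignment = alignment,
                 profile = profile, min_length = as.integer(min_length),
                 source_identity = identity, self_scores = self_scores,
                 score_threshold = family_threshold(self_scores)),
            class = "hde_element")
}

.mean_pairwise_identity <- function(alignment) {
  if (length(alignment) < 2L) return(NA_real_)
  rows <- strsplit(toupper(alignment), "")
  pairs <- utils::combn(length(rows), 2L)
  mean(apply(pairs, 2L, function(p) {
    a <- rows[[p[1L]]]; b <- rows[[p[2L]]]
    ok <- !(a %in% c("-", ".")) & !(b %in% c("-", "."))
    if (!any(ok)) return(0)
    mean(a[ok] == b[ok])
  }))
}

#' Marker sets
#'
#' A marker set bundles the protein families, the non-coding elements and the
#' scan parameters, plus a precomputed seed table used by the homology
#' engine.
#'
#' @param families List of [marker_family()] objects.
#' @param hde_elements List of [hde_element()] objects (may be empty).
#' @param params A [scan_params()] object.
#' @return An object of class `marker_set`.
#' @export
marker_set <- function(families, hde_elements = list(), params = scan_params()) {
  if (length(families) == 0L) stop("empty marker set")
  fids <- vapply(families, function(f) f$id, character(1))
  if (anyDuplicated(fids)) stop("duplicate family ids")
  names(families) <- fids
  if (length(hde_elements) > 0L) {
    eids <- vapply(hde_elements, function(e) e$id, character(1))
    if (anyDuplicated(eids)) stop("duplicate element ids")
    names(hde_elements) <- eids
  }
  ms <- structure(list(families = families, hde_elements = hde_elements,
                       params = params, seed_table = NULL),
                  class = "marker_set")
  ms$seed_table <- build_seed_table(families, params$seed_k)
  ms
}

#' @export
print.marker_set <- function(x, ...) {
  multi <- sum(!vapply(x$families, function(f) f$single_copy, logical(1)))
  cat(sprintf("<marker_set: %d families (%d multi-copy), %d elements>\n",
              length(x$families), multi, length(x$hde_elements)))
  invisible(x)
}

#' Filter candidate families by species presence and ambiguity
#'
#' A candidate family is retained when (i) it spans at least
#' `ceiling(presence_fraction * n_species)` distinct species and (ii) it is
#' unambiguous among the species-passing candidates: every member's self-score
#' must exceed its score against every other candidate's profile by more than
#' `paralog_margin` bits. Cross-family ambiguity is how paralogous families
#' reveal themselves; two identical candidates eliminate each other.
#'
#' @param clusters List of [marker_family()] objects (species tags set).
#' @param n_species Number of species in the reference panel.
#' @param params A [scan_params()].
#' @return The retained families, in input order.
#' @export
filter_families <- function(clusters, n_species, params = scan_params()) {
  if (n_species <= 0L) stop("n_species must be positive")
  need <- ceiling(params$presence_fraction * n_species)
  present <- vapply(clusters, function(f) {
    length(unique(f$species)) >= need
  }, logical(1))
  cand <- clusters[present]
  if (length(cand) <= 1L) return(cand)
  keep <- rep(TRUE, length(cand))
  for (i in seq_along(cand)) {
    for (j in seq_along(cand)) {
      if (i == j) next
      cross <- vapply(cand[[i]]$members, function(m) {
        score_sequence(cand[[j]]$profile, m, params$skip_penalty)
      }, numeric(1))
      if (any(cand[[i]]$self_scores <= cross + params$paralog_margin)) {
        keep[i] <- FALSE
        break
      }
    }
  }
  cand[keep]
}

#' Set multi-copy expectations from a genome survey
#'
#' For each family the expected minimum copy number is the smallest copy
#' count observed across the surveyed genomes, floored at 1 (a survey genome
#' lacking the family triggers a warning rather than a zero expectation).
#'
#' @param families List of [marker_family()] objects.
#' @param survey Named list: per family id, an integer vector of copy counts,
#'   one per surveyed genome.
#' @return The families with `expected_min_copies` and `single_copy` set.
#' @export
set_copy_expectations <- function(families, survey) {
  lapply(families, function(f) {
    counts <- survey[[f$id]]
    if (is.null(counts) || length(counts) == 0L) {
      warning("family '", f$id, "' absent from survey; expecting 1 copy",
              call. = FALSE)
      counts <- 1L
    }
    if (any(counts == 0L))
      warning("family '", f$id, "' missing from some surveyed genomes; ",
              "copy expectation floored at 1", call. = FALSE)
    f$expected_min_copies <- max(1L, min(as.integer(counts)))
    f$single_copy <- f$expected_min_copies == 1L
    f
  })
}

# ---- marker-set bundle (directory of gapped FASTA + JSON manifest) ----------

#' Save or load a marker set bundle
#'
#' The bundle is a plain directory: one gapped FASTA per family under
#' `families/` (headers carry the species tag), one per element under
#' `elements/`, and a JSON manifest recording the parameters, thresholds and
#' copy expectations. Profiles and thresholds are rebuilt deterministically at
#' load, so the round trip is exact.
#'
#' @param ms A [marker_set()].
#' @param path Bundle directory.
#' @return `save_markerset` returns `path` invisibly; `load_markerset`
#'   returns the [marker_set()].
#' @export
save_markerset <- function(ms, path) {
  stopifnot(inherits(ms, "marker_set"))
  dir.create(file.path(path, "families"), recursive = TRUE, showWarnings = FALSE)
  if (length(ms$hde_elements) > 0L)
    dir.create(file.path(path, "elements"), showWarnings = FALSE)
  fam_meta <- lapply(ms$families, function(f) {
    writeLines(unlist(lapply(seq_along(f$alignment), function(i) {
      c(sprintf(">%s %s", names(f$alignment)[i], f$species[i]), f$alignment[i])
    })), file.path(path, "families", paste0(f$id, ".afa")))
    list(id = f$id, score_threshold = f$score_threshold,
         mean_length = f$mean_length,
         expected_min_copies = f$expected_min_copies)
  })
  el_meta <- lapply(ms$hde_elements, function(e) {
    writeLines(unlist(lapply(seq_along(e$alignment), function(i) {
      c(paste0(">", names(e$alignment)[i]), e$alignment[i])
    })), file.path(path, "elements", paste0(e$id, ".afa")))
    list(id = e$id, score_threshold = e$score_threshold,
         min_length = e$min_length)
  })
  manifest <- list(format = "mycomplete-markerset",
                   version = 1L,
                   params = unclass(ms$params),
                   families = unname(fam_meta),
                   elements = unname(el_meta))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_markerset
#' @export
load_markerset <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("corrupt marker set: missing manifest")
  manifest <- jsonlite::read_json(mf)
  for (field in c("params", "families"))
    if (is.null(manifest[[field]])) stop("corrupt marker set: missing ", field)
  if (length(manifest$families) == 0L) stop("corrupt marker set: no families")
  params <- do.call(scan_params, manifest$params[names(manifest$params) %in%
                                                 names(formals(scan_params))])
  families <- lapply(manifest$families, function(meta) {
    for (field in c("id", "score_threshold", "mean_length",
                    "expected_min_copies"))
      if (is.null(meta[[field]])) stop("corrupt marker set: family missing ",
                                       field)
    aln_path <- file.path(path, "families", paste0(meta$id, ".afa"))
    if (!file.exists(aln_path)) stop("corrupt marker set: missing alignment ",
                                     meta$id)
    lines <- readLines(aln_path)
    hdr <- which(startsWith(lines, ">"))
    rows <- setNames(lines[hdr + 1L],
                     vapply(strsplit(sub("^>", "", lines[hdr]), " "),
                            `[`, character(1), 1L))
    species <- vapply(strsplit(sub("^>", "", lines[hdr]), " "), function(x) {
      if (length(x) > 1L) x[2L] else x[1L]
    }, character(1))
    f <- marker_family(meta$id, rows, species = species,
                       pseudocount_weight = params$pseudocount)
    f$expected_min_copies <- as.integer(meta$expected_min_copies)
    f$single_copy <- f$expected_min_copies == 1L
    f
  })
  elements <- lapply(manifest$elements, function(meta) {
    aln_path <- file.path(path, "elements", paste0(meta$id, ".afa"))
    if (!file.exists(aln_path)) stop("corrupt marker set: missing alignment ",
                                     meta$id)
    lines <- readLines(aln_path)
    hdr <- which(startsWith(lines, ">"))
    rows <- setNames(lines[hdr + 1L], sub("^>", "", lines[hdr]))
    hde_element(meta$id, rows, min_length = meta$min_length,
                pseudocount_weight = params$pseudocount)
  })
  marker_set(families, elements, params)
}
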