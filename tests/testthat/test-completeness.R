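# construct a fake classified model without running the scanner
fake_model <- function(family_id, status, score, pep_len, contig = "c1",
                       start = 0L) {
  structure(list(family_id = family_id, contig_id = contig, strand = "+",
                 exons = NULL, model_peptide = strrep("A", pep_len),
                 total_score = score, coverage = 0.9,
                 genome_start = start, genome_end = start + 3L * pep_len,
                 status = status),
            class = "gene_model")
}

test_that("representative choice: aberrant excluded, then longest, then score", {
  ms <- fixture("ms_sel", function() {
    make_marker_set(n_families = 2, n_members = 3, mean_length = 140,
                    rng_seed = 23)
  })
  fid <- names(ms$families)[1]
  fid2 <- names(ms$families)[2]

  # 300 >= 2 x 140: the long model is aberrant, the 120 one represents
  models <- list(fake_model(fid, "aberrant", 500, 300),
                 fake_model(fid, "complete", 90, 120))
  sel <- select_final_models(models, ms)
  expect_equal(sel[[fid]]$status, "complete")
  expect_equal(nchar(sel[[fid]]$best_model$model_peptide), 120)
  expect_equal(sel[[fid2]]$status, "missing")

  # equal lengths: the higher score wins
  models <- list(fake_model(fid, "complete", 80, 200, start = 0L),
                 fake_model(fid, "complete", 90, 200, start = 900L))
  sel <- select_final_models(models, ms)
  expect_equal(sel[[fid]]$best_model$total_score, 90)

  # only aberrant models -> family counted aberrant
  models <- list(fake_model(fid, "aberrant", 500, 300))
  sel <- select_final_models(models, ms)
  expect_equal(sel[[fid]]$status, "aberrant")
})

test_that("completeness percentages are plain family fractions", {
  ms <- fixture("ms_pct", function() {
    make_marker_set(n_families = 10, n_members = 2, mean_length = 60,
                    rng_seed = 29)
  })
  ids <- names(ms$families)
  status <- c(rep("complete", 5), rep("partial", 3), rep("missing", 2))
  sel <- setNames(lapply(status, function(s) list(status = s)), ids)
  pct <- protein_completeness(sel, ms)
  expect_equal(pct$pct_complete, 50)
  expect_equal(pct$pct_complete_or_partial, 80)
  expect_equal(pct$pct_complete + pct$pct_partial + pct$pct_aberrant +
                 pct$pct_missing, 100)

  all_c <- setNames(lapply(ids, function(i) list(status = "complete")), ids)
  expect_equal(protein_completeness(all_c, ms)$pct_complete, 100)
  all_m <- setNames(lapply(ids, function(i) list(status = "missing")), ids)
  expect_equal(protein_completeness(all_m, ms)$pct_complete, 0)
})

test_that("conserved elements are found on both strands, absent when absent", {
  els <- make_hde_elements(2, n_members = 4, length = 260, rng_seed = 37)
  e1 <- els[[1]]
  flank <- with_seed(91, mycomplete:::.random_dna(4000))
  fwd <- assembly(list(seq_record("c", paste0(
    flank, e1$members[[1]], with_seed(92, mycomplete:::.random_dna(4000))))))
  res <- hde_search(fwd, els, scan_params())
  expect_true(e1$id %in% res$detected_ids)
  expect_false(els[[2]]$id %in% res$detected_ids)
  expect_equal(res$pct_hde, 50)

  rc <- assembly(list(seq_record("c", mycomplete:::reverse_complement_string(
    fwd$records[[1]]$sequence))))
  res_rc <- hde_search(rc, els, scan_params())
  expect_true(e1$id %in% res_rc$detected_ids)
  hit <- res_rc$hits[res_rc$hits$element_id == e1$id &
                       res_rc$hits$detected, ][1, ]
  expect_equal(hit$strand, "-")

  for (seed in 1:5) {
    rnd <- assembly(list(seq_record("r", with_seed(
      400 + seed, mycomplete:::.random_dna(50000)))))
    expect_equal(hde_search(rnd, els, scan_params())$detected, 0)
  }
})

test_that("multi-copy audit flags fewer-than-expected distinct loci", {
  ms <- fixture("ms_mc", function() {
    make_marker_set(n_families = 2, n_members = 3, mean_length = 100,
                    n_multicopy = 1, copies = 2, rng_seed = 41)
  })
  mc <- names(ms$families)[1]
  thr <- ms$families[[mc]]$score_threshold

  one <- list(fake_model(mc, "complete", thr + 5, 100, start = 0L))
  audit <- multicopy_audit(one, ms)
  expect_equal(audit$collapse_flags, mc)
  expect_equal(unname(audit$n_copies[mc]), 1L)

  two <- c(one, list(fake_model(mc, "complete", thr + 4, 100, start = 5000L)))
  expect_length(multicopy_audit(two, ms)$collapse_flags, 0)

  # two models at the same locus are one copy
  same <- c(one, list(fake_model(mc, "complete", thr + 4, 100, start = 30L)))
  expect_equal(multicopy_audit(same, ms)$collapse_flags, mc)

  audit0 <- multicopy_audit(list(), ms)
  expect_equal(audit0$collapse_flags, mc)
  expect_equal(unname(audit0$n_copies[mc]), 0L)
})

test_that("full_report recovers a synthetic genome and reacts to deletions", {
  ms <- fix_markerset()
  g <- fix_genome()
  rep <- fix_report()
  expect_equal(rep$pct_complete, 100)
  expect_equal(rep$pct_hde, 100)
  expect_length(rep$collapse_flags, 0)

  # delete one family's locus: that family missing, percentage drops by 1/n
  n <- length(ms$families)
  loc <- g$truth[g$truth$kind == "protein", ][1, ]
  recs <- g$assembly$records
  s <- recs[[loc$contig_id]]$sequence
  recs[[loc$contig_id]] <- seq_record(
    loc$contig_id,
    paste0(substr(s, 1, loc$genome_start),
           substr(s, loc$genome_end + 1, nchar(s))))
  rep2 <- full_report(assembly(recs), ms)
  # residual background HSPs may still chain into a weak partial model, but
  # the family must no longer count as complete
  expect_false(rep2$per_family$status[rep2$per_family$family_id == loc$id] ==
                 "complete")
  expect_equal(rep2$pct_complete, 100 * (n - 1) / n)
})

test_that("every family gets exactly one status", {
  rep <- fix_report()
  expect_true(all(rep$per_family$status %in%
                    c("complete", "partial", "aberrant", "missing")))
  expect_equal(rep$pct_complete + rep$pct_partial + rep$pct_aberrant +
                 rep$pct_missing, 100, tolerance = 1e-9)
})

test_that("nested assemblies never gain completeness or elements", {
  ms <- fix_markerset()
  g <- fix_genome()
  rep_full <- fix_report()
  sub <- assembly(g$assembly$records[-(1:2)])
  rep_sub <- full_report(sub, ms)
  expect_lte(rep_sub$pct_complete, rep_full$pct_complete)
  expect_lte(rep_sub$hde_detected, rep_full$hde_detected)
})

test_that("report serialization: TSV shape, JSON idempotence, round trip", {
  rep <- fix_report()
  tsv <- write_report(rep, "tsv")
  lines <- strsplit(tsv, "\n")[[1]]
  n_fam <- nrow(rep$per_family)
  expect_equal(sum(!startsWith(lines, "#") & nzchar(lines)), n_fam + 1L)
  expect_true(any(grepl("^## pct_complete\t", lines)))

  js <- write_report(rep, "json")
  back <- read_report(js)
  expect_equal(back$pct_complete, rep$pct_complete)
  expect_equal(back$per_family$status, rep$per_family$status)
  expect_equal(back$collapse_flags, rep$collapse_flags)
  # serialize -> parse -> serialize is byte-identical
  expect_identical(write_report(back, "json"), js)
})

test_that("a report over zero markers is rejected", {
  rep <- fix_report()
  rep$per_family <- rep$per_family[0, ]
  expect_error(write_report(rep, "tsv"), "empty marker set")
})
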