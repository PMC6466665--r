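test_that("six-frame translation follows the standard code and frames", {
  fr <- six_frame_translate(seq_record("x", "ATGGCCTAA"))
  expect_equal(fr[[1]]$peptide, "MA*")          # +0
  fr2 <- six_frame_translate(seq_record("x", "CAT"))
  expect_equal(fr2[[4]]$peptide, "M")           # -0: revcomp is ATG
  frN <- six_frame_translate(seq_record("x", "ATNGGC"))
  expect_equal(frN[[1]]$peptide, "XG")          # N codon -> X
})

test_that("frame coordinates invert exactly on both strands", {
  with_seed(17, {
    s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
               collapse = "")
    rec <- seq_record("c", s)
    for (fr in six_frame_translate(rec)) {
      np <- nchar(fr$peptide)
      if (np < 5) next
      ps <- 3L; pe <- np - 1L
      g <- frame_to_genome(fr, ps, pe)
      sub <- substr(s, g[1] + 1L, g[2])
      if (fr$strand == "-") sub <- mycomplete:::reverse_complement_string(sub)
      pep <- as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                                no.init.codon = TRUE))
      expect_equal(pep, substr(fr$peptide, ps + 1L, pe))
    }
  })
})

# one single-member family whose gene is embedded verbatim
embed_family_genome <- function(strand = "+", seed = 101) {
  with_seed(seed, {
    member <- paste(sample(mycomplete:::AA_ORDER, 80, replace = TRUE),
                    collapse = "")
    fam <- marker_family("f1", setNames(member, "m1"))
    gene <- mycomplete:::.reverse_translate(member)
    flank1 <- mycomplete:::.random_dna(1500)
    flank2 <- mycomplete:::.random_dna(1500)
    insert <- if (strand == "+") gene else
      mycomplete:::reverse_complement_string(gene)
    list(family = fam, member = member,
         record = seq_record("ctg", paste0(flank1, insert, flank2)),
         gene_start = nchar(flank1), gene_end = nchar(flank1) + nchar(gene))
  })
}

test_that("an embedded member is recovered as one full-length HSP", {
  fx <- embed_family_genome("+")
  hsps <- seed_and_extend(fx$family, six_frame_translate(fx$record),
                          scan_params())
  hit <- hsps[which.max(hsps$score), ]
  expect_equal(hit$peptide, fx$member)
  self_ungapped <- sum(vapply(seq_len(80), function(j) {
    fx$family$profile$scores[substr(fx$member, j, j), j]
  }, numeric(1)))
  expect_equal(hit$score, self_ungapped, tolerance = 1e-9)
  expect_equal(hit$strand, "+")
  expect_equal(c(hit$genome_start, hit$genome_end),
               c(fx$gene_start, fx$gene_end))
})

test_that("reverse-strand embedding yields forward coordinates, '-' strand", {
  fx <- embed_family_genome("-", seed = 102)
  hsps <- seed_and_extend(fx$family, six_frame_translate(fx$record),
                          scan_params())
  hit <- hsps[which.max(hsps$score), ]
  expect_equal(hit$strand, "-")
  expect_equal(hit$peptide, fx$member)
  expect_equal(c(hit$genome_start, hit$genome_end),
               c(fx$gene_start, fx$gene_end))
  # coordinate round trip through the genome slice
  sub <- substr(fx$record$sequence, hit$genome_start + 1L, hit$genome_end)
  pep <- as.character(Biostrings::translate(Biostrings::DNAString(
    mycomplete:::reverse_complement_string(sub)), no.init.codon = TRUE))
  expect_equal(pep, hit$peptide)
})

test_that("no shared k-mer means no HSPs", {
  fam <- marker_family("pk", setNames(strrep("K", 60), "m1"))
  rec <- seq_record("c", strrep("GCC", 400))  # poly-alanine in frame +0
  hsps <- seed_and_extend(fam, six_frame_translate(rec), scan_params())
  expect_equal(nrow(hsps), 0)
})

test_that("chaining adds colinear HSPs and picks the best alternative", {
  h2 <- data.frame(family_id = "f", contig_id = "c", strand = "+",
                   genome_start = c(0, 600), genome_end = c(300, 900),
                   profile_start = c(0, 110), profile_end = c(100, 210),
                   score = c(30, 40), peptide = "x",
                   stringsAsFactors = FALSE)
  ch <- chain_hsps(h2, scan_params())
  expect_equal(nrow(ch$exons), 2)
  expect_equal(ch$total_score, 70)

  excl <- h2
  excl$profile_start <- c(0, 0); excl$profile_end <- c(100, 100)
  ch <- chain_hsps(excl, scan_params())
  expect_equal(nrow(ch$exons), 1)
  expect_equal(ch$total_score, 40)

  expect_equal(chain_hsps(h2[0, ], scan_params())$total_score, 0)
})

test_that("chaining equals the exhaustive oracle on random instances", {
  p <- scan_params()
  with_seed(55, {
    for (rep in 1:25) {
      hsps <- random_hsp_set(sample(3:8, 1))
      got <- chain_hsps(hsps, p)$total_score
      expect_equal(got, bf_chain_score(hsps), tolerance = 1e-9)
    }
  })
})

test_that("model classification applies aberrant, complete, partial rules", {
  fam <- fix_markerset()$families[[1]]
  thr <- fam$score_threshold
  mk <- function(len, score, cov) {
    list(model_peptide = strrep("A", len), total_score = score,
         coverage = cov)
  }
  p <- scan_params()
  expect_equal(classify_model(mk(ceiling(2 * fam$mean_length), thr * 2, 1),
                              fam, p), "aberrant")
  expect_equal(classify_model(mk(100, thr, 0.70), fam, p), "complete")
  expect_equal(classify_model(mk(100, 0.5 * thr, 0.2), fam, p), "partial")
  expect_true(is.na(classify_model(mk(100, 0.1 * thr, 0.2), fam, p)))
})

test_that("scan_assembly recovers every embedded family as complete", {
  ms <- fix_markerset()
  g <- fix_genome()
  models <- scan_assembly(g$assembly, ms)
  status <- vapply(models, `[[`, character(1), "status")
  fams <- vapply(models, `[[`, character(1), "family_id")
  complete_fams <- unique(fams[status == "complete"])
  expect_setequal(complete_fams, names(ms$families))
})

test_that("pure random sequence yields no complete models", {
  ms <- fixture("ms_tiny", function() {
    make_marker_set(n_families = 10, n_members = 4, mean_length = 150,
                    rng_seed = 8)
  })
  for (seed in 1:5) {
    rec <- with_seed(1000 + seed,
                     seq_record("r", mycomplete:::.random_dna(100000)))
    models <- scan_assembly(assembly(list(rec)), ms)
    status <- vapply(models, `[[`, character(1), "status")
    expect_equal(sum(status == "complete"), 0)
  }
})

test_that("a gene split 50/50 across contigs is at best partial", {
  fx <- embed_family_genome("+", seed = 103)
  ms <- marker_set(list(fx$family))
  s <- fx$record$sequence
  cut <- fx$gene_start + (fx$gene_end - fx$gene_start) %/% 2
  split_asm <- assembly(list(seq_record("c1", substr(s, 1, cut)),
                             seq_record("c2", substr(s, cut + 1, nchar(s)))))
  rep <- full_report(split_asm, ms)
  expect_true(rep$per_family$status[1] %in% c("partial", "missing"))
  expect_false(rep$per_family$status[1] == "complete")
})

test_that("reverse-complementing every contig preserves scan results", {
  ms <- fix_markerset()
  g <- fix_genome()
  rc <- assembly(lapply(g$assembly$records, function(r) {
    seq_record(r$id, mycomplete:::reverse_complement_string(r$sequence))
  }))
  fp <- function(models) {
    x <- sort(vapply(models, function(m) {
      sprintf("%s|%s|%.6f", m$family_id, m$status, m$total_score)
    }, character(1)))
    x
  }
  expect_equal(fp(scan_assembly(rc, ms)), fp(scan_assembly(g$assembly, ms)))
})

test_that("deleting a contig never increases the complete-model count", {
  ms <- fix_markerset()
  g <- fix_genome()
  n_complete <- function(models) {
    sum(vapply(models, `[[`, character(1), "status") == "complete")
  }
  base <- n_complete(scan_assembly(g$assembly, ms))
  drop1 <- assembly(g$assembly$records[-1])
  expect_lte(n_complete(scan_assembly(drop1, ms)), base)
})
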