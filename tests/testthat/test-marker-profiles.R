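test_that("profile scores follow the log-odds closed form", {
  # single row, uniform background, vanishing pseudocount: observed residue
  # scores log2(20) at each column
  p <- build_profile(c(m1 = "MK"), pseudocount_weight = 1e-12)
  expect_equal(unname(p$scores["M", 1]), log2(20), tolerance = 1e-6)
  expect_equal(unname(p$scores["K", 2]), log2(20), tolerance = 1e-6)

  # explicit closed form with a real pseudocount
  p <- build_profile(c(a = "AA", b = "AC"), pseudocount_weight = 1)
  expected_A_col2 <- log2((1 + 1 / 20) / (2 + 1) / (1 / 20))
  expect_equal(unname(p$scores["A", 2]), expected_A_col2)
})

test_that("a unanimous column scores its residue above all others", {
  rows <- setNames(rep("WGH", 10), paste0("m", 1:10))
  p <- build_profile(rows)
  for (j in 1:3) {
    obs <- c("W", "G", "H")[j]
    expect_true(all(p$scores[obs, j] > p$scores[rownames(p$scores) != obs, j]))
  }
})

test_that("columns with >=50% gaps are dropped", {
  rows <- c(a = "MK-A", b = "MK-A", c = "MKWA", d = "MK-A", e = "MKWA")
  p <- build_profile(rows)  # column 3 is 60% gaps
  expect_equal(ncol(p$scores), 3)
  expect_equal(p$col_index, c(1L, 2L, 4L))
  expect_error(build_profile(c(a = "--", b = "--")), "gappy")
  expect_error(build_profile(character()), "empty")
})

test_that("score_sequence agrees with an independent full-matrix DP", {
  with_seed(21, {
    for (rep in 1:10) {
      rows <- vapply(1:3, function(i) {
        paste(sample(mycomplete:::AA_ORDER, 40, replace = TRUE), collapse = "")
      }, character(1))
      p <- build_profile(setNames(rows, paste0("m", 1:3)))
      pep <- paste(sample(mycomplete:::AA_ORDER, 50, replace = TRUE),
                   collapse = "")
      expect_equal(score_sequence(p, pep), bf_local_score(p, pep),
                   tolerance = 1e-9)
    }
  })
})

test_that("self-alignment scores the sum of own column scores, empty is 0", {
  p <- build_profile(c(m = "MKWAHDLV"))
  self <- sum(vapply(1:8, function(j) {
    p$scores[substr("MKWAHDLV", j, j), j]
  }, numeric(1)))
  expect_equal(score_sequence(p, "MKWAHDLV"), self)
  expect_equal(score_sequence(p, ""), 0)
  # X scores zero at every column
  expect_equal(score_sequence(p, "XXXXXXXX"), 0)
})

test_that("family threshold is 80% of the weakest member", {
  expect_equal(family_threshold(c(100, 90, 50)), 40)
  expect_equal(family_threshold(77), 0.8 * 77)
  expect_equal(family_threshold(0), 0)
  expect_error(family_threshold(numeric()), "no member scores")
})

test_that("every member of a built family clears its own threshold", {
  fams <- make_marker_families(10, n_members = 6, mean_length = 120,
                               divergence = 0.15, rng_seed = 31)
  for (f in fams) {
    expect_equal(f$score_threshold, 0.8 * min(f$self_scores))
    expect_true(all(f$self_scores >= f$score_threshold))
  }
})

test_that("species-presence filter uses ceil(presence * n_species)", {
  mk_cluster <- function(id, n_sp) {
    members <- setNames(rep("MKWAHDLVPESTRGNQCIFY", n_sp),
                        paste0(id, "_m", seq_len(n_sp)))
    marker_family(id, members, species = paste0("sp", seq_len(n_sp)))
  }
  kept <- filter_families(list(mk_cluster("a", 99)), n_species = 100)
  expect_equal(length(kept), 1)
  kept <- filter_families(list(mk_cluster("b", 98)), n_species = 100)
  expect_equal(length(kept), 0)
  expect_error(filter_families(list(), 0), "n_species")
})

test_that("ambiguous (identical) clusters drop, disjoint ones survive", {
  seqs <- c("MKWAHDLVPESTRGNQCIFY")
  twin1 <- marker_family("t1", setNames(seqs, "m1"), species = "sp1")
  twin2 <- marker_family("t2", setNames(seqs, "m1"), species = "sp1")
  expect_length(filter_families(list(twin1, twin2), n_species = 1), 0)

  polyk <- marker_family("pk", setNames(strrep("K", 30), "m1"), species = "sp1")
  polyd <- marker_family("pd", setNames(strrep("D", 30), "m1"), species = "sp1")
  kept <- filter_families(list(polyk, polyd), n_species = 1)
  expect_equal(sort(vapply(kept, `[[`, character(1), "id")), c("pd", "pk"))
})

test_that("filter_families is independent of cluster order", {
  fams <- make_marker_families(5, n_members = 3, mean_length = 80,
                               rng_seed = 77)
  a <- filter_families(fams, n_species = 3)
  b <- filter_families(rev(fams), n_species = 3)
  expect_setequal(vapply(a, `[[`, character(1), "id"),
                  vapply(b, `[[`, character(1), "id"))
})

test_that("copy expectations take the survey minimum, floored at one", {
  fams <- make_marker_families(3, n_members = 3, mean_length = 80,
                               rng_seed = 3)
  ids <- vapply(fams, `[[`, character(1), "id")
  survey <- setNames(list(c(2L, 3L, 2L, 5L), c(1L, 1L, 1L)), ids[1:2])
  expect_warning(out <- set_copy_expectations(fams[1:2], survey), NA)
  expect_equal(out[[1]]$expected_min_copies, 2L)
  expect_false(out[[1]]$single_copy)
  expect_equal(out[[2]]$expected_min_copies, 1L)
  expect_true(out[[2]]$single_copy)

  survey3 <- setNames(list(c(0L, 2L)), ids[3])
  expect_warning(out3 <- set_copy_expectations(fams[3], survey3), "floored")
  expect_equal(out3[[1]]$expected_min_copies, 1L)
  expect_warning(set_copy_expectations(fams[3], list()), "absent")
})

test_that("marker-set bundles round-trip exactly", {
  ms <- make_marker_set(n_families = 3, n_members = 3, mean_length = 80,
                        n_multicopy = 1, n_hde = 1, hde_length = 250,
                        rng_seed = 13)
  dir <- withr::local_tempdir()
  save_markerset(ms, dir)
  back <- load_markerset(dir)
  for (fid in names(ms$families)) {
    expect_identical(back$families[[fid]]$score_threshold,
                     ms$families[[fid]]$score_threshold)
    expect_identical(back$families[[fid]]$members, ms$families[[fid]]$members)
    expect_identical(back$families[[fid]]$expected_min_copies,
                     ms$families[[fid]]$expected_min_copies)
  }
  expect_identical(back$hde_elements[[1]]$score_threshold,
                   ms$hde_elements[[1]]$score_threshold)
  expect_identical(unclass(back$params), unclass(ms$params))
})

test_that("corrupt marker-set bundles are rejected", {
  expect_error(load_markerset(withr::local_tempdir()), "corrupt marker set")
  ms <- make_marker_set(n_families = 2, n_members = 2, mean_length = 60,
                        rng_seed = 9)
  dir <- withr::local_tempdir()
  save_markerset(ms, dir)
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"))
  mf$families[[1]]$score_threshold <- NULL
  jsonlite::write_json(mf, file.path(dir, "manifest.json"), auto_unbox = TRUE)
  expect_error(load_markerset(dir), "corrupt marker set")
})
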