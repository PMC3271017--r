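test_that("dyad occurrences are counted with overlaps and order", {
  expect_identical(count_occurrences("HDHD", "HD"), 2L)
  expect_identical(count_occurrences("HHH", "HH"), 2L)
  expect_identical(count_occurrences("DH", "HD"), 0L)
  expect_identical(count_occurrences("H", "HD"), 0L)
  expect_identical(count_occurrences(c("HD", "AA", "HDHD"), "HD"), c(1L, 0L, 2L))
  expect_error(count_occurrences("HD", "H"), "two amino-acid")
  expect_error(count_occurrences("HD", "HX"), "invalid residue")
})

test_that("count_occurrences agrees with a naive position-by-position scan", {
  set.seed(9)
  dyads <- c("HD", "HH", "AA", "WC", "KM")
  for (i in 1:2000) {
    s <- random_aa_string(sample(2:40, 1))
    d <- sample(dyads, 1)
    expect_identical(count_occurrences(s, d), count_naive(s, d))
  }
})

test_that("n_sequences_containing counts sequences, not copies", {
  expect_identical(n_sequences_containing(c(a = "HDA", b = "AAA"), "HD"), 1L)
  expect_identical(n_sequences_containing(c(a = "HDHD"), "HD"), 1L)
  expect_identical(n_sequences_containing(c(a = "AAA", b = "CCC"), "HD"), 0L)
})

test_that("build_null accumulates a conserved histogram over replicates", {
  reps <- list(c(a = "AAA", b = "CCC"),              # 0 containing
               c(a = "HDA", b = "AHD"),              # 2
               c(a = "HDH", b = "HDA"))              # 2
  null <- build_null(reps, "HD")
  expect_identical(sum(null$histogram), 3L)
  expect_identical(unname(null$histogram[c("0", "2")]), c(1L, 2L))
  expect_identical(null$n_leaves, 2L)
  expect_error(build_null(list(c(a = "HD"), c(a = "HD", b = "AA")), "HD"),
               "heterogeneous")
})

test_that("empirical p-values count exceedances and bound zero counts", {
  h <- c(rep(5L, 95), rep(10L, 5))
  null <- build_null(lapply(h, function(k)
    setNames(c(rep("HD", k), rep("AA", 12 - k)), paste0("s", 1:12))), "HD")
  expect_equal(empirical_pvalue(null, 10)$p_value, 0.05)
  expect_false(empirical_pvalue(null, 10)$upper_bound)
  expect_equal(empirical_pvalue(null, 0)$p_value, 1)
  res <- empirical_pvalue(null, 12)
  expect_true(res$upper_bound)
  expect_identical(res$exceedances, 0L)
  expect_equal(res$p_value, 1 / 100)
  expect_error(empirical_pvalue(null, 13), "0\\.\\.12")
  expect_error(empirical_pvalue(null, -1), "0\\.\\.12")
})

test_that("p-values are monotone non-increasing in the observed count", {
  set.seed(21)
  counts <- sample(0:8, 500, replace = TRUE, prob = 9:1)
  null <- build_null(lapply(counts, function(k)
    setNames(c(rep("HD", k), rep("AA", 8 - k)), paste0("s", 1:8))), "HD")
  p <- vapply(0:8, function(o) empirical_pvalue(null, o)$p_value, numeric(1))
  expect_true(all(diff(p) <= 0))
})

test_that("scan_all_dyads matches the per-dyad test and handles edge cases", {
  m <- test_model()
  tr <- star_tree(5, 0.4)
  root <- "MHDSGYEVHHQKLVFFAEDVGSNKGAIIGL"
  reps <- simulate_replicates(tr, root, m, n_reps = 60, seed = 12)
  observed <- reps[[60]]
  scan <- scan_all_dyads(reps[1:59], observed, alpha = 0.05)
  expect_identical(nrow(scan), 400L)
  expect_setequal(scan$dyad, as.vector(outer(aa_alphabet(), aa_alphabet(), paste0)))
  # dual route: every row must equal build_null + empirical_pvalue
  for (d in c("HD", "HH", "KM", "AA", "WW")) {
    ref <- empirical_pvalue(build_null(reps[1:59], d), n_sequences_containing(observed, d))
    row <- scan[scan$dyad == d, ]
    expect_equal(row$p_value, ref$p_value)
    expect_identical(row$exceedances, ref$exceedances)
    expect_identical(row$observed, ref$observed)
  }
  # alpha = 0: nothing can be flagged since every p is positive
  expect_false(any(scan_all_dyads(reps[1:59], observed, alpha = 0)$flagged))
  # observed identical to the only replicate: every dyad has p = 1
  self <- scan_all_dyads(list(observed), observed, alpha = 0.01)
  expect_true(all(self$p_value == 1))
})

test_that("streaming simulate_null equals build_null over materialized replicates", {
  m <- test_model()
  tr <- three_leaf()
  root <- "MHDSGYEVHHQKLVFFAEDV"
  reps <- simulate_replicates(tr, root, m, n_reps = 40, seed = 31)
  streamed <- simulate_null(tr, root, m, "HD", n_reps = 40, seed = 31)
  expect_identical(streamed$histogram, build_null(reps, "HD")$histogram)
  scan_stream <- simulate_scan(tr, root, m, reps[[1]], n_reps = 40, seed = 31)
  expect_equal(scan_stream, scan_all_dyads(reps, reps[[1]]), ignore_attr = TRUE)
})

test_that("multi-copy fraction and mean presence count summarize replicates", {
  reps <- list(c(a = "HDHD", b = "AAAA"), c(a = "HDAA", b = "AHDA"))
  expect_equal(multi_copy_fraction(reps, "HD"), 0.5)
  expect_equal(multi_copy_fraction(list(c(a = "AAAA")), "HD"), 0)
  expect_equal(mean_containing_count(list(
    c(a = "AA", b = "AA", c = "AA", d = "AA"),
    c(a = "HD", b = "HD", c = "AA", d = "AA"),
    c(a = "HD", b = "HD", c = "HD", d = "HD")), "HD"), 2)
})

test_that("a motif-bearing root yields a larger mean presence count than a motif-free root", {
  m <- test_model()
  spec <- synth_spec(n_leaves = 12, seq_length = 40, seed = 61)
  tr <- sample_tree(spec)
  root_free <- gsub("HD", "HA", sample_root(spec, m))
  spec_hd <- synth_spec(n_leaves = 12, seq_length = 40, root_mode = "dyad_seeded", seed = 61)
  root_hd <- sample_root(spec_hd, m)
  stopifnot(count_occurrences(root_free, "HD") == 0, count_occurrences(root_hd, "HD") >= 1)
  mean_free <- mean_containing_count(
    simulate_replicates(tr, root_free, m, n_reps = 400, seed = 62), "HD")
  mean_hd <- mean_containing_count(
    simulate_replicates(tr, root_hd, m, n_reps = 400, seed = 62), "HD")
  expect_lt(mean_free, mean_hd)
})

test_that("dyad test results export as TSV", {
  null <- build_null(list(c(a = "HDA", b = "AHD"), c(a = "AAA", b = "HDA")), "HD")
  res <- empirical_pvalue(null, 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_dyad_tsv(res, f)
  tab <- read.delim(f)
  expect_identical(tab$dyad, "HD")
  expect_identical(tab$exceedances, 1L)
})
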