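test_that("composition counts singles and dyads with the boundary and residue rules", {
  comp <- composition("HD")
  expect_equal(comp$dyad["H", "D"], 1)
  expect_equal(unname(comp$single[c("H", "D")]), c(0.5, 0.5))
  expect_identical(comp$n_dyads, 1L)

  # nonstandard residues void both adjacent pairs
  expect_error(composition("HXD"), "no valid dyads")
  comp2 <- composition(c("AXCD"))
  expect_identical(comp2$n_dyads, 1L)        # only CD survives
  expect_equal(comp2$dyad["C", "D"], 1)
  expect_identical(unname(comp2$single_counts["A"]), 1L)  # singles keep A and skip X

  # dyads never span sequence boundaries
  comp3 <- composition(c("AC", "DE"))
  expect_identical(comp3$n_dyads, 2L)
  expect_equal(comp3$dyad["C", "D"], 0)
  expect_equal(comp3$dyad["A", "C"], 0.5)
  expect_equal(comp3$dyad["D", "E"], 0.5)

  expect_equal(sum(comp3$single), 1, tolerance = 1e-12)
  expect_equal(sum(comp3$dyad), 1, tolerance = 1e-12)
})

test_that("log-odds are zero under independence and NA where undefined", {
  # a collection whose dyad distribution factorizes: all 400 pairs equally often
  pairs <- as.vector(outer(aa_alphabet(), aa_alphabet(), paste0))
  comp <- composition(pairs)
  expect_equal(unname(comp$single), rep(0.05, 20), tolerance = 1e-12)
  lo <- log_odds(comp, base = 2)
  expect_lt(max(abs(lo$s)), 1e-10)

  lo2 <- log_odds(composition(c("ACAC", "CACA")), base = 2)
  expect_true(is.na(lo2$s["H", "D"]))
  expect_false(is.na(lo2$s["A", "C"]))
  expect_false(is.na(lo2$s["C", "A"]))
  expect_error(log_odds(composition("ACAC"), base = 1), "base")
})

test_that("enrichment and depletion of a dyad flip the sign of its log-odds", {
  set.seed(5)
  base_seqs <- replicate(300, random_aa_string(50))
  neutral <- composition(base_seqs)
  lo0 <- log_odds(neutral, base = 2)
  # doubling the HD count over independence drives the cell positive
  n_extra <- ceiling(2 * neutral$single["H"] * neutral$single["D"] * neutral$n_dyads)
  enriched <- composition(c(base_seqs, rep("HD", n_extra)))
  expect_gt(log_odds(enriched, base = 2)$s["H", "D"], 0)
  # removing every HD makes the cell undefined or negative
  depleted <- composition(gsub("HD", "HA", base_seqs))
  lo_dep <- log_odds(depleted, base = 2)
  expect_true(is.na(lo_dep$s["H", "D"]) || lo_dep$s["H", "D"] < 0)
})

test_that("composition of a concatenation equals the count-weighted merge", {
  set.seed(6)
  a <- replicate(20, random_aa_string(30))
  b <- replicate(15, random_aa_string(45))
  merged <- merge_compositions(composition(a, "a"), composition(b, "b"))
  direct <- composition(c(a, b))
  expect_identical(merged$single_counts, direct$single_counts)
  expect_identical(merged$dyad_counts, direct$dyad_counts)
  expect_identical(merged$n_sequences, direct$n_sequences)
})

test_that("composition tables round-trip through TSV exactly", {
  set.seed(7)
  comp <- composition(replicate(10, random_aa_string(25)), label = "rt")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_composition_tsv(comp, f)
  back <- read_composition_tsv(f)
  expect_identical(back$single_counts, comp$single_counts)
  expect_identical(back$dyad_counts, comp$dyad_counts)
  expect_equal(back$dyad, comp$dyad, tolerance = 1e-15)
})

test_that("log-odds tables export in a 20x20 layout with the base recorded", {
  set.seed(8)
  lo <- log_odds(composition(replicate(50, random_aa_string(60))), base = 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_log_odds_tsv(lo, f)
  lines <- readLines(f)
  expect_match(lines[1], "base=2")
  expect_length(lines, 22L)
  expect_identical(strsplit(lines[2], "\t")[[1]][-1], aa_alphabet())
})

test_that("split_by_species applies the strict more-than filter", {
  headers <- c(sprintf("sp|P%05d|X_HUMAN Protein OS=Homo sapiens OX=9606 GN=G%d PE=1 SV=1", 1:1001, 1:1001),
               sprintf("sp|Q%05d|Y_YEAST Protein OS=Saccharomyces cerevisiae OX=559292 PE=1 SV=1", 1:5))
  seqs <- setNames(rep("MHDSGY", 1006), headers)
  cols <- suppressMessages(split_by_species(seqs, min_sequences = 1000))
  expect_identical(names(cols), "Homo sapiens")
  expect_length(cols[["Homo sapiens"]], 1001L)
  expect_identical(as.integer(attr(cols, "dropped")["Saccharomyces cerevisiae"]), 5L)

  # exactly min_sequences records: dropped (strictly "more than")
  at_line <- setNames(rep("MHDSGY", 1000), sprintf("sp|R%04d|Z_MOUSE P OS=Mus musculus PE=1", 1:1000))
  expect_length(suppressMessages(split_by_species(at_line, min_sequences = 1000)), 0L)

  # fallback pattern: NCBI-style bracketed organism
  ncbi <- setNames(rep("MHDSGY", 4), sprintf("XP_%06d.1 amyloid-like protein [Nematostella vectensis]", 1:4))
  cols2 <- suppressMessages(split_by_species(ncbi, min_sequences = 2))
  expect_identical(names(cols2), "Nematostella vectensis")

  expect_error(suppressMessages(split_by_species(setNames("MHDSGY", "no_tag_here"),
                                                 min_sequences = 0)),
               "cannot parse a species")
})
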