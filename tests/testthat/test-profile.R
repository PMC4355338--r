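test_that("hydropathy lookups match the published scale endpoints", {
  expect_equal(hydropathy("I"), 4.5)
  expect_equal(hydropathy("W"), -0.9)
  expect_equal(hydropathy("R"), -4.5)
  expect_error(hydropathy("X"), "unknown or absent")
  expect_error(hydropathy("-"), "unknown or absent")
})

test_that("a scale read from TSV matches the built-in one", {
  sc <- read_hydropathy_scale(system.file("extdata", "kyte_doolittle.tsv",
                                          package = "isopocket"))
  expect_equal(sc, kd_scale())
  f <- tempfile()
  writeLines(c("residue\tvalue", "A\t1.8"), f)
  expect_error(read_hydropathy_scale(f), "incomplete")
})

test_that("cleft totals reproduce the published values where arithmetic agrees", {
  t4 <- table4()
  ii <- pocket_hydrophobicity(t4, "II")
  expect_equal(ii$raw, 26.0)
  expect_equal(ii$rounded, 26L)
  expect_equal(ii$residues, c("I", "V", "V", "L", "V", "L", "P", "L", "W"))
  expect_equal(pocket_hydrophobicity(t4, "IX")$rounded, 23L)
  i <- pocket_hydrophobicity(t4, "I")
  expect_equal(i$raw, 14.4)
  expect_equal(i$rounded, 14L)
  # the .5 case demands rounding half away from zero
  xii <- pocket_hydrophobicity(t4, "XII")
  expect_equal(xii$raw, 8.5)
  expect_equal(xii$rounded, 9L)
})

test_that("computed-vs-printed disagreements are flagged, not matched", {
  rep <- score_report(table4(), reference_totals = table4_printed())
  expect_equal(rep$isoform[rep$flag], c("III", "IV", "VI"))
  expect_equal(rep$rounded_total[rep$flag], c(9, 3, 6))
  expect_equal(rep$reference_total[rep$flag], c(8, 4, 7))
  expect_false(any(rep$flag[!rep$isoform %in% c("III", "IV", "VI")]))
})

test_that("absent residues make the pocket total undefined", {
  tab <- make_table(list(I91 = "I-", W209 = "WW"), c("a", "b"))
  expect_equal(pocket_hydrophobicity(tab, "a")$raw, 3.6)
  expect_error(pocket_hydrophobicity(tab, "b"), "position(s) 91", fixed = TRUE)
  expect_error(pocket_hydrophobicity(tab, "zz"), "not in table")
})

test_that("pocket totals are order-invariant and monotone in hydropathy", {
  # same residue multiset distributed over different positions: same total
  expect_equal(pocket_hydrophobicity(make_table(list(I10 = "I", W20 = "W",
                                                     K30 = "K"), "a"),
                                     "a")$raw,
               pocket_hydrophobicity(make_table(list(K10 = "K", I20 = "I",
                                                     W30 = "W"), "a"),
                                     "a")$raw)
  # replacing any residue by a strictly more hydrophobic one raises the raw sum
  tab <- make_table(list(I91 = "K", V121 = "V"), "a")
  tab2 <- make_table(list(I91 = "L", V121 = "V"), "a")
  expect_gt(pocket_hydrophobicity(tab2, "a")$raw,
            pocket_hydrophobicity(tab, "a")$raw)
})

test_that("distinct counts match hand counts on the published table", {
  t3 <- table3()
  expect_equal(column_distinct(t3, 94), 1L)
  expect_equal(column_distinct(t3, 91), 8L)
  expect_equal(column_distinct(t3, 67), 7L)
  expect_error(column_distinct(t3, 999), "not in table")
})

test_that("column entropy matches direct evaluation", {
  tab <- make_table(list(A10 = "AAAAAAKKKKKK",
                         H94 = "HHHHHHHHHHHH"), sprintf("i%02d", 1:12))
  expect_equal(column_entropy(tab, 94), 0.0)
  expect_equal(column_entropy(tab, 10), 1.0)
  # Q x5, N x2, five singletons over 12 isoforms
  t3 <- table3()
  p <- c(5, 2, 1, 1, 1, 1, 1) / 12
  expect_equal(column_entropy(t3, 67), -sum(p * log2(p)))
  expect_equal(round(column_entropy(t3, 67), 2), 2.45)
})

test_that("entropy respects its bounds and the distinct-count link", {
  set.seed(31)
  for (k in 1:25) {
    n <- sample(2:12, 1)
    res <- paste(sample(c("A", "K", "L", "W"), n, replace = TRUE),
                 collapse = "")
    tab <- make_table(list(A50 = res), sprintf("i%02d", 1:n))
    h <- column_entropy(tab, 50)
    expect_gte(h, 0)
    expect_lte(h, log2(n) + 1e-12)
    expect_equal(h == 0, column_distinct(tab, 50) == 1)
  }
})

test_that("hydropathy range spans max minus min over observed residues", {
  t3 <- table3()
  expect_equal(hydropathy_range(t3, 94), 0.0)
  expect_equal(hydropathy_range(t3, 91), 9.0)  # Ile 4.5 to Arg -4.5
  tab <- make_table(list(V10 = "VL"), c("a", "b"))
  expect_equal(hydropathy_range(tab, 10), 0.4)
})

test_that("classification separates conserved, variable and selective positions", {
  t3 <- table3()
  cls <- classify_positions(position_profiles(t3),
                            entropy_threshold = 1.0,
                            contact_positions = c(67, 91, 131))
  expect_setequal(cls$position[cls$classification == "selective"],
                  c(67, 91, 131))
  expect_setequal(cls$position[cls$classification == "conserved"],
                  c(62, 92, 94, 96, 119, 143, 199, 209))
  expect_equal(cls$position[cls$classification == "variable"], 135)
  # ranking places the hot-spot first
  expect_equal(cls$position[cls$rank == 1], 91)
  expect_true(all(cls$entropy_bits[cls$position == 91] >=
                  cls$entropy_bits))
})

test_that("an empty contact set yields no selective calls", {
  cls <- classify_positions(position_profiles(table3()),
                            contact_positions = integer(0))
  expect_false(any(cls$classification == "selective"))
  expect_setequal(cls$position[cls$classification == "variable"],
                  c(67, 91, 131, 135))
})

test_that("threshold zero on an invariant table leaves everything conserved", {
  tab <- make_table(list(H94 = "HHH", W209 = "WWW"), c("a", "b", "c"))
  cls <- classify_positions(position_profiles(tab), entropy_threshold = 0)
  expect_true(all(cls$classification == "conserved"))
})

test_that("single-observation columns are reported but unclassified", {
  tab <- make_table(list(A10 = "A--", K20 = "KKK"), c("a", "b", "c"))
  cls <- classify_positions(position_profiles(tab))
  expect_equal(cls$classification[cls$position == 10], "unclassified")
})

test_that("conserved position counts cover the published and trivial cases", {
  expect_equal(conserved_position_count(table3()), 8L)
  tab <- make_table(list(A1 = "AAA", K2 = "KKK", L3 = "LLL",
                         W4 = "WWW", V5 = "VVV"), c("a", "b", "c"))
  expect_equal(conserved_position_count(tab), 5L)
  tab2 <- make_table(list(A1 = "AK", K2 = "KA"), c("a", "b"))
  expect_equal(conserved_position_count(tab2), 0L)
  expect_error(conserved_position_count(
    make_table(list(), character(0))), "empty")
})

test_that("cleft membership annotations are attached as metadata", {
  prof <- position_profiles(table3())
  expect_equal(prof$cleft[prof$position == 67], "hydrophilic")
  expect_equal(prof$cleft[prof$position == 121], "hydrophobic")
  expect_equal(prof$cleft[prof$position == 91], "none")
})
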