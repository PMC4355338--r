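test_that("identical sequences align gap-free with identity columns only", {
  aln <- global_align("ACDE", "ACDE")
  expect_equal(aln$aligned_a, "ACDE")
  expect_equal(aln$aligned_b, "ACDE")
  expect_equal(percent_identity(aln), 100.0)
  expect_equal(conserved_count(aln), 4)
})

test_that("a single deletion is placed optimally and scored like the brute force", {
  params <- alignment_params()
  sm <- oracle_submatrix()
  aln <- global_align("ACDE", "ACE", params)
  expect_equal(nchar(aln$aligned_a), 4)
  expect_equal(sum(strsplit(aln$aligned_b, "")[[1]] == "-"), 1)
  expect_equal(aln$score,
               brute_force_score("ACDE", "ACE", sm,
                                 params$gap_open, params$gap_extend))
})

test_that("all-mismatch pairs stay gap-free when opening a gap costs more", {
  aln <- global_align("AAAA", "TTTT")
  expect_false(grepl("-", aln$aligned_a))
  expect_false(grepl("-", aln$aligned_b))
  expect_equal(percent_identity(aln), 0.0)
  expect_equal(conserved_count(aln), 0)
})

test_that("alignment score equals brute-force enumeration on random short pairs", {
  set.seed(42)
  params <- alignment_params()
  sm <- oracle_submatrix()
  for (k in 1:40) {
    a <- random_peptide(sample(1:7, 1))
    b <- random_peptide(sample(1:7, 1))
    aln <- global_align(a, b, params)
    expect_equal(aln$score,
                 brute_force_score(a, b, sm, params$gap_open,
                                   params$gap_extend),
                 info = paste(a, b))
    # de-gapping the alignment recovers the inputs
    expect_equal(gsub("-", "", aln$aligned_a), a)
    expect_equal(gsub("-", "", aln$aligned_b), b)
    # no gap-gap columns
    ca <- strsplit(aln$aligned_a, "")[[1]]
    cb <- strsplit(aln$aligned_b, "")[[1]]
    expect_false(any(ca == "-" & cb == "-"))
  }
})

test_that("scores agree with Biostrings pairwiseAlignment as a cross-check", {
  params <- alignment_params()
  sm <- oracle_submatrix()
  set.seed(7)
  for (k in 1:10) {
    a <- random_peptide(sample(5:40, 1))
    b <- random_peptide(sample(5:40, 1))
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = sm, gapOpening = params$gap_open,
      gapExtension = params$gap_extend, type = "global",
      scoreOnly = TRUE)
    expect_equal(global_align(a, b, params)$score, ref)
  }
})

test_that("percent identity and conserved count are symmetric", {
  set.seed(11)
  for (k in 1:20) {
    a <- random_peptide(sample(3:15, 1))
    b <- random_peptide(sample(3:15, 1))
    ab <- global_align(a, b)
    ba <- global_align(b, a)
    expect_equal(percent_identity(ab), percent_identity(ba))
    expect_equal(conserved_count(ab), conserved_count(ba))
  }
})

test_that("identity uses the both-non-gap denominator", {
  aln <- structure(list(aligned_a = "AC-E", aligned_b = "ACDE",
                        score = 0, ids = c("a", "b")),
                   class = "pairwise_alignment")
  expect_equal(percent_identity(aln), 100.0)  # 3 of 3 co-aligned columns
  expect_equal(conserved_count(aln), 3)
})

test_that("unknown residues are alignment-neutral and never identical", {
  params <- alignment_params()
  expect_equal(global_align("AXA", "AXA", params)$score,
               2 * oracle_submatrix()["A", "A"])
  aln <- global_align("AXA", "AXA", params)
  expect_equal(percent_identity(aln), round(100 * 2 / 3, 1))
  expect_equal(conserved_count(aln), 2)
})

test_that("identity matrix is symmetric with an exact diagonal", {
  fam <- lapply(1:4, function(i)
    isoform_sequence(paste0("s", i), random_peptide(30)))
  im <- identity_matrix(fam)
  expect_equal(im$identity, t(im$identity))
  expect_equal(im$conserved, t(im$conserved))
  expect_equal(unname(diag(im$identity)), rep(100, 4))
  expect_equal(unname(diag(im$conserved)),
               vapply(fam, function(s) nchar(s$residues), 0L))
})

test_that("identity matrix recovers planted family identity and edge cases", {
  fam3 <- lapply(1:3, function(i) isoform_sequence(paste0("s", i), "HWGKY"))
  im <- identity_matrix(fam3)
  expect_true(all(im$identity == 100))

  # disjoint alphabets -> 0 percent identity
  im0 <- identity_matrix(list(isoform_sequence("a", "AAAA"),
                              isoform_sequence("b", "TTTT")))
  expect_equal(im0$identity["a", "b"], 0.0)

  # planted 80% identity to the reference, binomial tolerance
  fam <- generate_family(family_config(
    n_isoforms = 6, length = 150, background_rate = 0.2,
    invariant_positions = integer(0), variable_positions = list(),
    seed = 19))
  ref <- isoform_sequence("ref", fam$truth$reference)
  ids <- vapply(fam$family, function(s)
    percent_identity(global_align(s, ref)), 0)
  expect_true(all(abs(ids - 80) < 10))
  expect_equal(mean(ids), 80, tolerance = 0.05)
})

test_that("identity matrix TSV round-trips through the two-triangle layout", {
  fam <- lapply(1:3, function(i)
    isoform_sequence(paste0("s", i), random_peptide(25)))
  im <- identity_matrix(fam)
  f <- tempfile(fileext = ".tsv")
  write_identity_matrix(im, f)
  back <- read_identity_matrix(f)
  expect_equal(back$identity, im$identity)
  off <- upper.tri(im$conserved)
  expect_equal(back$conserved[off], im$conserved[off])
})

test_that("progressive MSA degenerates to pairwise for two sequences", {
  a <- isoform_sequence("a", "HEAGAWGHEE")
  b <- isoform_sequence("b", "PAWHEAE")
  msa <- progressive_msa(list(a, b))
  aln <- global_align(a, b)
  expect_equal(unname(msa$rows), c(aln$aligned_a, aln$aligned_b))
})

test_that("identical sequences give a gap-free MSA block", {
  fam <- lapply(1:3, function(i) isoform_sequence(paste0("s", i), "HWGKYHW"))
  msa <- progressive_msa(fam)
  expect_true(all(!grepl("-", msa$rows)))
  expect_equal(unname(msa$rows), rep("HWGKYHW", 3))
})

test_that("a planted insertion becomes a gap column in every other row", {
  fam <- generate_family(family_config(
    n_isoforms = 5, length = 80, background_rate = 0.02,
    invariant_positions = integer(0), variable_positions = list(),
    insertion = list(member = 3, position = 40, length = 4), seed = 23))
  msa <- progressive_msa(fam$family)
  cols <- do.call(rbind, lapply(msa$rows, function(r) strsplit(r, "")[[1]]))
  ins_cols <- which(cols[3, ] != "-" & colSums(cols[-3, , drop = FALSE] == "-") == 4)
  expect_equal(length(ins_cols), 4)
  # de-gapping any row reproduces its input
  for (i in seq_along(fam$family))
    expect_equal(gsub("-", "", msa$rows[[i]]), fam$family[[i]]$residues)
})

test_that("alignment parameter validation enforces the gap invariant", {
  expect_error(alignment_params(gap_open = 1, gap_extend = 2), "exceed")
  expect_error(global_align("", "AA"), "non-empty")
})
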