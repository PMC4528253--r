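test_that("records map to columns and aggregate into hotspots", {
  aln <- family_alignment(c(A = "MSKDE-Y", B = "MSKDEQY"), "fam")
  recs <- make_records(
    list("A", 2, "S", "phosphorylation"),
    list("B", 2, "S", "phosphorylation"),
    list("B", 3, "K", "ubiquitination"),
    list("A", 6, "Y", "phosphorylation"))  # residue 6 of A -> column 7
  hs <- build_hotspots(recs, aln)
  expect_equal(hs$column, c(2, 3, 7))
  expect_equal(hs$total_ptms, c(2, 1, 1))
  expect_equal(hs$n_types, c(1, 1, 1))
  expect_equal(sum(hs$total_ptms), nrow(recs))
})

test_that("multi-type hotspots count distinct modification types", {
  aln <- family_alignment(c(A = "MKKK", B = "MKKK"), "fam")
  recs <- make_records(
    list("A", 2, "K", "ubiquitination"),
    list("B", 2, "K", "acetylation", known_function = TRUE),
    list("A", 3, "K", "ubiquitination"))
  hs <- build_hotspots(recs, aln)
  expect_equal(hs$n_types[hs$column == 2], 2)
  expect_equal(hs$per_type_counts[[1]],
               c(acetylation = 1L, ubiquitination = 1L))
  # known_function is inherited from any contributing record
  expect_equal(hs$known_function, c(TRUE, FALSE))
})

test_that("unmapped members, overlong indices and letter mismatches drop", {
  aln <- family_alignment(c(A = "MSKDE"), "fam")
  recs <- make_records(
    list("A", 2, "S", "phosphorylation"),
    list("Z", 2, "S", "phosphorylation"),     # no such member
    list("A", 99, "S", "phosphorylation"),    # beyond length
    list("A", 3, "S", "phosphorylation"))     # letter mismatch (K)
  expect_warning(expect_warning(expect_warning(
    hs <- build_hotspots(recs, aln), "absent"), "beyond"), "disagrees")
  expect_equal(nrow(hs), 1)
  expect_equal(hs$total_ptms, 1)
})

test_that("hotspot counts equal the brute-force grouping oracle", {
  set.seed(7)
  for (rep in 1:100) {
    n_mem <- sample(2:20, 1)
    len <- sample(20:200, 1)
    seqs <- vapply(seq_len(n_mem), function(i) {
      s <- sample(c("A", "S", "K", "T", "-"), len, replace = TRUE,
                  prob = c(0.3, 0.25, 0.25, 0.15, 0.05))
      paste(s, collapse = "")
    }, character(1))
    names(seqs) <- paste0("m", seq_len(n_mem))
    # guard against all-gap members
    seqs[!grepl("[A-Z]", seqs)] <- paste(rep("A", len), collapse = "")
    aln <- family_alignment(seqs, "rand")

    n_rec <- sample(1:300, 1)
    mem <- sample(names(seqs), n_rec, replace = TRUE)
    ridx <- vapply(mem, function(m) {
      sample(nchar(member_sequence(aln, m)), 1)
    }, integer(1))
    res <- vapply(seq_len(n_rec), function(i) {
      substr(member_sequence(aln, mem[i]), ridx[i], ridx[i])
    }, character(1))
    recs <- tibble::tibble(
      protein_id = mem, organism = "x", residue_index = ridx,
      residue = res, mod_type = sample(c("phosphorylation",
                                         "ubiquitination"),
                                       n_rec, replace = TRUE),
      evidence = "r", experimental = TRUE, known_function = FALSE,
      citation = NA_character_) |>
      deduplicate_ptms()

    hs <- build_hotspots(recs, aln)
    oracle <- oracle_hotspot_counts(recs, aln)
    expect_equal(hs$column, as.integer(names(oracle)))
    expect_equal(hs$total_ptms, as.integer(oracle))
    expect_equal(sum(hs$total_ptms), nrow(recs))  # conservation of mass
  }
})

test_that("hotspot features are invariant to member order", {
  aln1 <- family_alignment(c(A = "MSKDE", B = "MSKDQ", C = "MSRDE"), "f")
  aln2 <- family_alignment(c(C = "MSRDE", A = "MSKDE", B = "MSKDQ"), "f")
  recs <- make_records(list("A", 2, "S", "phosphorylation"),
                       list("C", 3, "R", "methylation"))
  h1 <- build_hotspots(recs, aln1)
  h2 <- build_hotspots(recs, aln2)
  expect_equal(h1[c("column", "total_ptms", "CS", "PRC")],
               h2[c("column", "total_ptms", "CS", "PRC")])
})

test_that("column conservation is the modal non-gap frequency", {
  aln <- family_alignment(c(a = "KKA-", b = "KKA-", c = "RKA-",
                            d = "-KA-"), "f")
  expect_equal(column_conservation(aln, 2), 1.0)    # K,K,K,K
  expect_equal(column_conservation(aln, 1), 2 / 3)  # K,K,R,-
  expect_equal(column_conservation(aln, 4), 0.0)    # all gaps
  # optional: gaps count against conservation
  expect_equal(column_conservation(aln, 1, count_gaps = TRUE), 2 / 4)
  # pluggable scorer hook
  expect_equal(column_conservation(aln, 1, scorer = function(r) 0.42), 0.42)
  expect_error(column_conservation(aln, 9), "range")
  # all-gap member does not change CS at other columns
  aln_g <- family_alignment(c(a = "KKA-", b = "KKA-", c = "RKA-",
                              d = "-KA-", e = "----"), "f")
  expect_equal(column_conservation(aln_g, 1), column_conservation(aln, 1))
})

test_that("modifiable-residue conservation follows the PTM-type table", {
  aln <- family_alignment(c(a = "SK", b = "TK", c = "YR", d = "SR"), "f")
  expect_equal(
    modifiable_residue_conservation(aln, 1, "phosphorylation"), 1.0)
  expect_equal(
    modifiable_residue_conservation(aln, 2, "ubiquitination"), 0.5)
  aln2 <- family_alignment(c(a = "S", b = "A", c = "A", d = "A"), "f")
  expect_equal(
    modifiable_residue_conservation(aln2, 1, "phosphorylation"), 0.25)
  # other:<label> falls back to the residues observed modified
  expect_equal(
    modifiable_residue_conservation(aln, 1, "other:weird",
                                    observed = c("S", "T")), 0.75)
})
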