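mk_hotspots <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r) tibble::tibble(
    family_id = r$family_id %||% "fam", column = r$column,
    total_ptms = r$total_ptms, n_types = r$n_types %||% 1L,
    per_type_counts = list(r$types %||% c(phosphorylation = r$total_ptms)),
    contributing = list(NULL),
    known_function = r$known_function %||% FALSE,
    CS = r$CS %||% 1, PRC = r$PRC %||% 1)))
}

mk_info <- function(columns, relative_sasa = 0.5, interface = FALSE,
                    disordered = FALSE) {
  tibble::tibble(
    member_id = "A", residue_index = columns, column = columns,
    resletter = "S", resno = columns, sasa = relative_sasa * 155,
    relative_sasa = relative_sasa, buried = relative_sasa < 0.05,
    interface = interface, disordered_unresolved = disordered)
}

test_that("PTM and interface scores follow their closed forms", {
  expect_equal(ptm_score(c(1, 5)), c(1, 5))
  expect_equal(ptm_score(5, mode = "log"), 1 + log(5))
  expect_equal(interface_score(3, FALSE), 3)
  expect_equal(interface_score(3, TRUE, w_if = 1), 6)
  expect_equal(interface_score(c(3, 4), c(TRUE, TRUE), w_if = 0), c(3, 4))
})

test_that("FP multiplies intensity, accessibility and conservation", {
  hs <- mk_hotspots(list(column = 1, total_ptms = 2L))
  # PS 2, non-interface, rel SASA 0.5, CS 1, PRC 1 -> 2*0.5*1*100 = 100
  out <- score_hotspots(hs, mk_info(1, 0.5))
  expect_equal(out$fp, 100)
  expect_equal(out$branch, "exposed")
  # interface doubles it under the default boost
  expect_equal(score_hotspots(hs, mk_info(1, 0.5, interface = TRUE))$fp, 200)
  # no conserved modifiable residue -> zero
  hs0 <- mk_hotspots(list(column = 1, total_ptms = 2L, PRC = 0))
  expect_equal(score_hotspots(hs0, mk_info(1, 0.5))$fp, 0)
})

test_that("buried residues take the FP_b branch, continuous at threshold", {
  hs <- mk_hotspots(list(column = 1, total_ptms = 3L))
  w <- fp_weights()
  at <- score_hotspots(hs, mk_info(1, w$burial_threshold), weights = w)
  just_below <- score_hotspots(hs, mk_info(1, w$burial_threshold - 1e-9),
                               weights = w)
  expect_equal(at$branch, "exposed")
  expect_equal(just_below$branch, "buried")
  expect_equal(at$fp, just_below$fp, tolerance = 1e-6)
  # disordered unresolved residues are never buried
  dis <- score_hotspots(hs, mk_info(1, 1, disordered = TRUE), weights = w)
  expect_equal(dis$branch, "exposed")
})

test_that("fp is monotone in each factor and in interface residence", {
  base <- list(column = 1, total_ptms = 2L, CS = 0.6, PRC = 0.5)
  fp_of <- function(hs_args, info) {
    score_hotspots(do.call(mk_hotspots, list(hs_args)), info)$fp
  }
  f0 <- fp_of(base, mk_info(1, 0.4))
  expect_gt(fp_of(modifyList(base, list(total_ptms = 5L)), mk_info(1, 0.4)), f0)
  expect_gt(fp_of(modifyList(base, list(CS = 0.9)), mk_info(1, 0.4)), f0)
  expect_gt(fp_of(modifyList(base, list(PRC = 0.9)), mk_info(1, 0.4)), f0)
  expect_gt(fp_of(base, mk_info(1, 0.8)), f0)
  expect_gt(fp_of(base, mk_info(1, 0.4, interface = TRUE)), f0)
})

test_that("hotspots without structural information are skipped", {
  hs <- mk_hotspots(list(column = 1, total_ptms = 1L),
                    list(column = 9, total_ptms = 2L))
  expect_warning(out <- score_hotspots(hs, mk_info(1)), "9")
  expect_equal(out$column, 1)
})

test_that("ranking sorts, breaks ties deterministically, attaches medians", {
  hs <- mk_hotspots(list(column = 1, total_ptms = 1L, CS = 0.1),
                    list(column = 2, total_ptms = 2L, CS = 0.2),
                    list(column = 3, total_ptms = 3L, CS = 0.3))
  scored <- score_hotspots(hs, mk_info(1:3, 1))
  scored$fp <- c(10, 20, 30)  # exact hand values
  r <- rank_hotspots(scored)
  expect_equal(r$fp, c(30, 20, 10))
  expect_equal(r$rank, 1:3)
  expect_equal(unique(r$family_median_fp), 20)
  expect_equal(r$fold_over_median[1], 1.5)

  # all-equal scores: tie-break on counts desc then column asc, fold 1
  scored2 <- scored
  scored2$fp <- 7
  scored2$total_ptms <- c(1L, 5L, 5L)
  r2 <- rank_hotspots(scored2)
  expect_equal(r2$column, c(2, 3, 1))
  expect_equal(unique(r2$fold_over_median), 1)

  # single hotspot
  r1 <- rank_hotspots(scored[1, ])
  expect_equal(r1$rank, 1)
  expect_equal(r1$fold_over_median, 1)
})

test_that("rank order is invariant to a common positive rescaling", {
  set.seed(3)
  hs <- do.call(mk_hotspots, lapply(1:12, function(i)
    list(column = i, total_ptms = sample(1:6, 1),
         CS = runif(1), PRC = runif(1))))
  info <- mk_info(1:12, runif(12, 0.06, 1),
                  interface = sample(c(TRUE, FALSE), 12, replace = TRUE))
  r_a <- rank_hotspots(score_hotspots(hs, info, fp_weights()))
  r_b <- rank_hotspots(score_hotspots(hs, info,
                                      fp_weights(prc_scale = 1000,
                                                 cs_scale = 10)))
  expect_equal(r_a$column, r_b$column)
})

test_that("grouping controls the median: per family versus pooled", {
  hs <- dplyr::bind_rows(
    mk_hotspots(list(family_id = "f1", column = 1, total_ptms = 1L),
                list(family_id = "f1", column = 2, total_ptms = 3L)),
    mk_hotspots(list(family_id = "f2", column = 1, total_ptms = 10L),
                list(family_id = "f2", column = 2, total_ptms = 30L)))
  scored <- score_hotspots(hs, mk_info(c(1, 2, 1, 2), 1))
  fam <- rank_hotspots(scored, group_by = "family")
  pool <- rank_hotspots(scored, group_by = "pooled")
  expect_equal(sort(unique(fam$family_median_fp)), c(200, 2000))
  expect_equal(unique(pool$family_median_fp),
               median(scored$fp))
})
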