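# independent brute-force oracle: enumerate every assignment of the
# pooled values to the two groups; U by direct pair counting
oracle_mw <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  u_of <- function(xs, ys) {
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_of(x, y)
  combs <- combn(n + m, n)
  u_all <- apply(combs, 2, function(ix)
    u_of(pooled[ix], pooled[-ix]))
  p <- mean(abs(u_all - n * m / 2) >= abs(u_obs - n * m / 2) - 1e-9)
  list(U = u_obs, p = p)
}

test_that("exact Mann-Whitney equals permutation enumeration", {
  set.seed(17)
  cases <- c(
    list(list(x = c(3, 4), y = c(1, 2)),
         list(x = c(4, 4), y = c(1, 1, 2)),
         list(x = c(1, 1, 1), y = c(1, 1, 1))),
    lapply(1:10, function(i) {
      list(x = sample(1:6, sample(2:8, 1), replace = TRUE),
           y = sample(1:6, sample(2:8, 1), replace = TRUE))
    }))
  for (cs in cases) {
    got <- mann_whitney_u(cs$x, cs$y)
    ora <- oracle_mw(cs$x, cs$y)
    expect_equal(got$method, "exact")
    expect_equal(got$U, ora$U)
    expect_equal(got$p_value, ora$p)
  }
})

test_that("exact and tie-corrected normal p agree for balanced n=8", {
  set.seed(29)
  for (rep in 1:10) {
    x <- runif(8); y <- runif(8) + runif(1, -0.3, 0.3)  # no ties
    exact <- mann_whitney_u(x, y, exact_max = 8)
    approx <- mann_whitney_u(x, y, exact_max = 0)
    expect_equal(approx$method, "normal")
    expect_lt(abs(exact$p_value - approx$p_value), 0.02)
  }
})

test_that("large-sample branch matches wilcox.test", {
  set.seed(41)
  x <- rnorm(30, 0.5); y <- rnorm(25)
  got <- mann_whitney_u(x, y)
  ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(got$U, unname(ref$statistic))
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("separation report computes fold difference and p-value", {
  d <- tibble::tibble(v = c(4, 4, 1, 1, 2),
                      k = c(TRUE, TRUE, FALSE, FALSE, FALSE))
  rep_ <- separation_report(d, v, k, factor_label = "demo")
  expect_equal(rep_$mean_known, 4)
  expect_equal(rep_$mean_unknown, 4 / 3)
  expect_equal(rep_$fold_difference, 3)
  expect_equal(rep_$normalized_mean_known, 3)
  expect_equal(rep_$n_known, 2)
  expect_equal(rep_$n_unknown, 3)

  # identical distributions: fold 1, p ~ 1
  d2 <- tibble::tibble(v = rep(c(1, 2), 4),
                       k = rep(c(TRUE, FALSE), each = 4))
  rep2 <- separation_report(d2, v, k)
  expect_equal(rep2$fold_difference, 1)
  expect_gt(rep2$p_value, 0.9)

  expect_error(separation_report(d[d$k, ], v, k), "both")

  td <- tidy(rep_)
  expect_equal(td$fold_difference, 3)
  expect_equal(glance(rep_)$n, 5)
})

test_that("ordinal-rank mode is available for sensitivity analysis", {
  d <- tibble::tibble(v = c(1000, 5, 4, 3), k = c(TRUE, FALSE, FALSE, FALSE))
  raw <- separation_report(d, v, k)
  rk <- separation_report(d, v, k, use_ranks = TRUE)
  expect_gt(raw$fold_difference, rk$fold_difference)
  expect_equal(rk$mean_known, 4)  # top rank of 4
})

test_that("threshold curve counts agree with the separation report at t=0", {
  set.seed(53)
  hs <- tibble::tibble(
    family_id = "f", column = 1:40, total_ptms = sample(1:6, 40, TRUE),
    n_types = 1L, per_type_counts = replicate(40, c(phosphorylation = 1L),
                                              simplify = FALSE),
    contributing = replicate(40, NULL, simplify = FALSE),
    known_function = rep(c(TRUE, FALSE), c(8, 32)),
    CS = runif(40), PRC = runif(40))
  info <- tibble::tibble(
    member_id = "A", residue_index = 1:40, column = 1:40, resletter = "S",
    resno = 1:40, sasa = 100, relative_sasa = runif(40, 0.06, 1),
    buried = FALSE, interface = FALSE, disordered_unresolved = FALSE)
  ranking <- rank_hotspots(score_hotspots(hs, info))
  curve <- known_fraction_vs_threshold(ranking, thresholds = c(0, 1, 1e9))
  rep_ <- separation_report(ranking, fp, known_function)
  expect_equal(curve$n_known[1], rep_$n_known)
  expect_equal(curve$n_unknown[1], rep_$n_unknown)
  expect_equal(curve$pct_known[1], 8 / 40)
  # beyond the maximum fp: empty counts, undefined fraction
  expect_equal(curve$n_known[3] + curve$n_unknown[3], 0)
  expect_true(is.na(curve$pct_known[3]))
})

test_that("known concentrated at top gives a non-decreasing curve", {
  hs <- tibble::tibble(
    family_id = "f", fp = 40:1, known_function = rep(c(TRUE, FALSE),
                                                     c(10, 30)),
    family_median_fp = median(40:1))
  curve <- known_fraction_vs_threshold(hs, thresholds = c(0, 0.5, 1, 1.5))
  expect_true(all(diff(curve$pct_known) >= 0))
})

test_that("PTM load divides counts by protein length", {
  recs <- dplyr::bind_rows(lapply(1:10, function(i)
    make_records(list("P1", i, "S", "phosphorylation"))))
  recs <- dplyr::bind_rows(recs,
                           make_records(list("P2", 1, "K", "ubiquitination")))
  load <- ptm_load(recs, c(P1 = 100, P2 = 50))
  expect_equal(load$load[load$protein_id == "P1"], 0.10)
  expect_equal(load$load[load$protein_id == "P2"], 0.02)
  expect_warning(out <- ptm_load(recs, c(P1 = 100)), "P2")
  expect_equal(nrow(out), 1)
})

test_that("region enrichment reports overall and per-type fractions", {
  recs <- dplyr::bind_rows(
    lapply(1:2, function(i) make_records(list("P1", i, "S",
                                              "phosphorylation"))),
    lapply(11:16, function(i) make_records(list("P1", i, "S",
                                                "phosphorylation"))),
    make_records(list("P1", 3, "K", "ubiquitination")))
  enr <- region_enrichment(recs, 1, 10)
  expect_equal(enr$n_region, 3)
  expect_equal(enr$fraction, 3 / 9)
  ph <- enr$per_type[enr$per_type$mod_type == "phosphorylation", ]
  expect_equal(ph$fraction, 2 / 8)
  expect_equal(region_enrichment(recs, 1, 100)$fraction, 1)
})

test_that("multi-type distribution fractions sum to one with pair table", {
  hs <- tibble::tibble(
    n_types = c(1L, 1L, 1L, 2L),
    per_type_counts = list(
      c(phosphorylation = 2L), c(ubiquitination = 1L),
      c(acetylation = 1L),
      c(phosphorylation = 1L, ubiquitination = 2L)))
  mt <- multi_type_distribution(hs)
  expect_equal(unname(mt$fractions), c(0.75, 0.25, 0))
  expect_equal(sum(mt$fractions), 1, tolerance = 1e-12)
  expect_equal(mt$pairs$n, 1)
  expect_equal(mt$pairs$type_a, "phosphorylation")
  expect_equal(mt$pairs$type_b, "ubiquitination")

  hs3 <- tibble::tibble(n_types = 3L,
                        per_type_counts = list(c(a = 1L, b = 1L, c = 1L)))
  expect_equal(unname(multi_type_distribution(hs3)$fractions), c(0, 0, 1))
})
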