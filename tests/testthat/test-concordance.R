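test_that("Cohen's kappa matches hand arithmetic on a printed 2x2 table", {
  a <- c(rep(TRUE, 25), rep(FALSE, 75))
  b <- c(rep(TRUE, 20), rep(FALSE, 5), rep(TRUE, 10), rep(FALSE, 65))
  kt <- cohens_kappa(a, b)
  expect_equal(kt$p_o, 0.85, tolerance = 1e-12)
  expect_equal(kt$p_e, 0.60, tolerance = 1e-12)
  expect_equal(kt$kappa, 0.625, tolerance = 1e-12)
  expect_equal(kt$status, "ok")
  expect_true(kt$p_value < 0.05)
})

test_that("kappa is 1 for identical raters, ~0 under independence, symmetric", {
  x <- c(TRUE, FALSE, TRUE, TRUE, FALSE)
  expect_equal(cohens_kappa(x, x)$kappa, 1)
  set.seed(3)
  a <- runif(1e5) < 0.3
  b <- runif(1e5) < 0.3
  kt <- cohens_kappa(a, b)
  expect_lt(abs(kt$kappa), 3 * kt$se0)
  expect_gt(kt$p_value, 0.001)
  expect_equal(cohens_kappa(a, b)$kappa, cohens_kappa(b, a)$kappa)
  # relabeling both raters leaves kappa unchanged
  expect_equal(cohens_kappa(!a, !b)$kappa, kt$kappa)
  # both raters constant and identical: chance agreement 1, undefined
  expect_equal(cohens_kappa(rep(TRUE, 5), rep(TRUE, 5))$status, "degenerate")
})

test_that("Spearman correlation matches the rank formula and flags constants", {
  expect_equal(rank_correlation(1:10, (1:10)^3)$rho, 1)
  expect_equal(rank_correlation(1:10, -(1:10)^3)$rho, -1)
  # d^2 = (0, 1, 1, 0): rho = 1 - 6*2/(4*15) = 0.8
  expect_equal(rank_correlation(c(1, 2, 3, 4), c(1, 3, 2, 4))$rho, 0.8,
               tolerance = 1e-12)
  expect_equal(rank_correlation(rep(2, 5), 1:5)$status, "degenerate")
})

test_that("signed-rank p-values agree with full sign enumeration", {
  # all-positive differences at n = 6: two-sided exact p = 2/64
  x <- c(1.2, 2.5, 0.7, 3.1, 1.9, 0.4)
  res <- paired_signed_rank(x, rep(0, 6))
  expect_equal(res$p_value, 2 / 64, tolerance = 1e-12)
  expect_equal(res$method, "exact")
  set.seed(14)
  for (n in c(5, 8, 12)) {
    d <- round(rnorm(n, 0.3, 1), 3)
    d <- d[d != 0]
    res <- paired_signed_rank(d, rep(0, length(d)))
    expect_equal(res$p_value, enumerate_signed_rank_p(d), tolerance = 1e-12)
  }
})

test_that("signed-rank handles zeros, symmetry and large-sample fallback", {
  x <- c(1, 2, 3)
  expect_equal(paired_signed_rank(x, x)$status, "degenerate")
  # perfectly symmetric differences: statistic at the null centre
  d <- c(1.5, -1.5, 0.7, -0.7, 2.2, -2.2)
  res <- paired_signed_rank(d, rep(0, 6))
  expect_equal(res$statistic, sum(rank(abs(d))) / 2)
  expect_gt(res$p_value, 0.5)
  set.seed(9)
  big <- rnorm(300, 0.3)
  res_big <- paired_signed_rank(big, rep(0, 300))
  expect_equal(res_big$method, "normal approximation")
  expect_lt(res_big$p_value, 0.05)
})

test_that("venn regions are exhaustive, disjoint and consistent with marginals", {
  # two disjoint criteria of sizes 3 and 4 in n = 10
  a <- c(rep(TRUE, 3), rep(FALSE, 7))
  b <- c(rep(FALSE, 3), rep(TRUE, 4), rep(FALSE, 3))
  vs <- venn_counts(list(A = a, B = b))
  counts <- setNames(vs$regions$count, vs$regions$pattern)
  expect_equal(counts[["10"]], 3)
  expect_equal(counts[["01"]], 4)
  expect_equal(counts[["11"]], 0)
  expect_equal(counts[["00"]], 3)
  expect_equal(vs$union, 7)
  # nested criteria: inner-only region empty
  inner <- c(TRUE, FALSE, FALSE, FALSE)
  outer <- c(TRUE, TRUE, FALSE, FALSE)
  vs2 <- venn_counts(list(inner = inner, outer = outer))
  expect_equal(vs2$regions$count[vs2$regions$pattern == "10"], 0)
  # random flags: regions sum to n, marginals match direct recount
  set.seed(12)
  flags <- list(p = runif(1000) < 0.3, q = runif(1000) < 0.5,
                r = runif(1000) < 0.1)
  vs3 <- venn_counts(flags)
  expect_equal(sum(vs3$regions$count), 1000)
  expect_equal(unname(vs3$marginals), vapply(flags, sum, numeric(1)),
               ignore_attr = TRUE)
  expect_equal(vs3$union, sum(Reduce(`|`, flags)))
})

test_that("incremental age table matches hand enumeration and is monotone", {
  cls <- data.frame(
    fh_high =     c(TRUE,  FALSE, FALSE, FALSE, FALSE, TRUE,  FALSE, FALSE),
    gail_high =   c(FALSE, TRUE,  FALSE, FALSE, TRUE,  TRUE,  FALSE, FALSE),
    prs_high =    c(FALSE, FALSE, TRUE,  FALSE, TRUE,  FALSE, TRUE,  FALSE),
    ptv_carrier = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE,  TRUE))
  ages <- c(32, 33, 31, 34, 52, 53, 51, 54)
  tab <- incremental_by_age(cls, ages)
  r30 <- tab[tab$age_group == "30-34", ]
  r50 <- tab[tab$age_group == "50-54", ]
  # hand enumeration, bin 30-34: FH {1}; +Gail {1,2}; +PRS {1,2,3}; +PTV same
  expect_equal(r30$upto_fh_high, 1 / 4)
  expect_equal(r30$upto_gail_high, 2 / 4)
  expect_equal(r30$upto_prs_high, 3 / 4)
  expect_equal(r30$upto_ptv_carrier, 3 / 4)
  # bin 50-54: FH {6}; +Gail {5,6}; +PRS {5,6,7}; +PTV {5,6,7,8}
  expect_equal(r50$upto_fh_high, 1 / 4)
  expect_equal(r50$upto_gail_high, 2 / 4)
  expect_equal(r50$upto_prs_high, 3 / 4)
  expect_equal(r50$upto_ptv_carrier, 4 / 4)
  # proportions non-decreasing along the sequence in every bin
  props <- as.matrix(tab[, grep("^upto_", names(tab))])
  expect_true(all(apply(props[stats::complete.cases(props), , drop = FALSE],
                        1, function(x) all(diff(x) >= 0))))
  # a single-criterion prefix equals that criterion's per-bin proportion
  tab1 <- incremental_by_age(cls, ages, sequence = "prs_high")
  expect_equal(tab1$upto_prs_high[tab1$age_group == "30-34"], 1 / 4)
  # union is invariant to order within a prefix
  tab_swap <- incremental_by_age(cls, ages,
                                 sequence = c("gail_high", "fh_high",
                                              "prs_high", "ptv_carrier"))
  expect_equal(tab_swap$upto_fh_high, tab$upto_gail_high)
  # out-of-range ages go to an overflow bin with a warning
  expect_warning(tab_o <- incremental_by_age(cls, c(ages[-8], 80)), "outside")
  expect_true("other" %in% tab_o$age_group)
})
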