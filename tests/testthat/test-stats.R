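test_that("Welch t-test matches hand computation", {
  w <- welch_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$t, -3 / sqrt(2 / 3), tolerance = 1e-4)
  expect_equal(w$df, 4, tolerance = 1e-9)
  expect_equal(w$p, 2 * pt(-3 / sqrt(2 / 3), 4), tolerance = 1e-9)
  expect_equal(round(w$p, 4), 0.0213)
  # identical groups
  expect_equal(welch_t(c(1, 2, 3), c(1, 2, 3))$t, 0)
  expect_equal(welch_t(c(5, 5), c(5, 5))$p, 1)
  # antisymmetry
  ws <- welch_t(c(4, 5, 6), c(1, 2, 3))
  expect_equal(ws$t, -w$t)
  expect_equal(ws$p, w$p)
  expect_error(welch_t(1, c(1, 2)), "at least 2")
})

test_that("Welch p agrees with numerical integration of the t density", {
  set.seed(13)
  for (k in 1:10) {
    a <- rnorm(sample(3:8, 1)); b <- rnorm(sample(3:8, 1), 0.5)
    w <- welch_t(a, b)
    dens <- function(x) {
      gamma((w$df + 1) / 2) / (sqrt(w$df * pi) * gamma(w$df / 2)) *
        (1 + x^2 / w$df)^(-(w$df + 1) / 2)
    }
    p_num <- 2 * integrate(dens, abs(w$t), Inf, rel.tol = 1e-10)$value
    expect_equal(w$p, p_num, tolerance = 1e-6)
  }
})

test_that("exact Wilcoxon enumerates sign assignments", {
  r <- wilcoxon_signed_rank(c(0, 0, 0, 0), c(1, 2, 3, 4))
  expect_equal(r$p, 0.125)        # 2/16 assignments as extreme
  expect_equal(r$W, 10)
  expect_warning(r0 <- wilcoxon_signed_rank(c(1, 2), c(1, 2)), "zero")
  expect_equal(r0$p, 1)
  # sign flip symmetry
  d <- c(1.2, -0.5, 2, 0.7, -3)
  rp <- wilcoxon_signed_rank(rep(0, 5), d)
  rn <- wilcoxon_signed_rank(rep(0, 5), -d)
  expect_equal(rp$p, rn$p)
  # zero differences are dropped and reported
  rz <- wilcoxon_signed_rank(c(1, 2, 3), c(1, 4, 5))
  expect_equal(rz$n_zero, 1)
  expect_equal(rz$n_used, 2)
})

test_that("exact path agrees with the classical distribution (no ties)", {
  set.seed(19)
  for (n in c(4, 6, 8, 10)) {
    d <- sample(100, n) * c(-1, 1)[1 + rbinom(n, 1, 0.5)]
    mine <- wilcoxon_signed_rank(rep(0, n), d)
    ref <- suppressWarnings(wilcox.test(d, exact = TRUE))
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("large-sample path uses the tie-corrected normal approximation", {
  set.seed(23)
  d <- rnorm(30, 0.3)
  mine <- wilcoxon_signed_rank(rep(0, 30), d)
  ref <- wilcox.test(d, exact = FALSE, correct = FALSE)
  expect_equal(mine$method, "normal approximation")
  expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
})

test_that("Fisher exact test matches hypergeometric enumeration", {
  expect_equal(fisher_exact(matrix(1, 2, 2)), 1)
  expect_equal(fisher_exact(matrix(c(3, 0, 0, 3), 2)), 0.1)
  set.seed(29)
  for (k in 1:15) {
    m <- matrix(rpois(4, 3), 2)
    if (sum(m) == 0) next
    p_mine <- fisher_exact(m)
    # enumerate all tables with the observed margins
    r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
    a_range <- max(0, c1 - (n - r1)):min(r1, c1)
    probs <- dhyper(a_range, r1, n - r1, c1)
    p_enum <- sum(probs[probs <= dhyper(m[1, 1], r1, n - r1, c1) *
                          (1 + 1e-7)])
    expect_equal(p_mine, p_enum, tolerance = 1e-9)
    expect_equal(fisher_exact(t(m)), p_mine, tolerance = 1e-12)
  }
  expect_error(fisher_exact(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("Bonferroni threshold reproduces the printed level", {
  expect_equal(round(bonferroni_alpha(0.05, 9), 4), 0.0056)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_equal(bonferroni_alpha(0.05, 5), 0.01)
  expect_error(bonferroni_alpha(0.05, 0), "positive integer")
})

test_that("group comparison flags only genuinely different metrics", {
  sds <- data.frame(metric = c("hindered", "restricted", "nonrestricted",
                               "fiber", "adc", "fa", "t1w_gd", "t2w",
                               "flair"),
                    treatment_effect = c(0.001, rep(0.05, 8)),
                    progression = c(0.001, rep(0.05, 8)))
  co <- make_cohort(cohort_spec(metric_sds = sds, seed = 10))
  cmp <- compare_groups(co$metrics)
  expect_equal(attr(cmp, "adjusted_alpha"), 0.05 / 9)
  expect_true(cmp$significant[cmp$metric == "hindered"])
  expect_false(any(cmp$significant[cmp$metric != "hindered"]))
  # permutation invariance of patient rows
  cmp2 <- compare_groups(co$metrics[sample(nrow(co$metrics)), ])
  expect_equal(cmp2$p, cmp$p, tolerance = 1e-12)
  expect_error(compare_groups(co$metrics[1:5, ]), "at least 2")
})

test_that("time-to-diagnosis summary reproduces the published table", {
  tt <- time_to_diagnosis(table1_fixture())
  expect_equal(tt$n_analyzed, 9)
  expect_equal(tt$overall$median, 7.7)
  expect_equal(tt$overall$q1, 0)
  expect_equal(tt$overall$q3, 20.1)
  expect_equal(tt$n_earlier, 6)
  expect_equal(tt$fraction_earlier, 2 / 3, tolerance = 1e-9)
  pg <- tt$by_group$progression
  expect_equal(pg$n, 5)
  expect_equal(pg$median, 7.7)
  expect_equal(pg$q1, 0)
  expect_equal(pg$q3, 15.0)
})

test_that("degenerate and invalid timing inputs are handled", {
  r <- data.frame(Subject = c("a", "b"),
                  Diagnosis = c("progression", "treatment_effect"),
                  SurgeryToDBSI_weeks = c(10, 12),
                  SurgeryToSOC_weeks = c(10, 12))
  tt <- time_to_diagnosis(r)
  expect_equal(tt$overall$median, 0)
  expect_equal(tt$overall$q3, 0)
  expect_equal(tt$n_earlier, 0)
  expect_error(time_to_diagnosis(r[0, ]), "no analyzed")
  r$SurgeryToSOC_weeks[1] <- NA
  expect_error(time_to_diagnosis(r), "both diagnosis times")
})
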