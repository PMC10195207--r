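test_that("phantoms are deterministic and carry valid ground truth", {
  tab <- dbsi_scheme()
  spec <- phantom_spec(shape = c(8, 8, 4),
                       lesions = list(list(center = c(4, 4, 2), radius = 1.5,
                                           params = dbsi_archetype(
                                             "treatment_effect"),
                                           role = "lesion")),
                       snr = 25, seed = 42)
  p1 <- make_phantom(spec, tab)
  p2 <- make_phantom(spec, tab)
  expect_identical(p1$volume$data, p2$volume$data)
  expect_gt(sum(p1$labels$labels == 1), 0)
  tsum <- p1$truth$fiber + p1$truth$restricted + p1$truth$hindered +
    p1$truth$nonrestricted
  expect_true(all(abs(tsum - 1) < 1e-6))
})

test_that("lesion archetypes order the hindered fraction as intended", {
  te <- true_fractions(dbsi_archetype("treatment_effect"))
  bg <- true_fractions(dbsi_archetype("background"))
  pg <- true_fractions(dbsi_archetype("progression"))
  expect_gt(te["hindered"], bg["hindered"])
  expect_lt(pg["hindered"], bg["hindered"])
})

test_that("phantom geometry is validated", {
  expect_error(phantom_spec(shape = c(6, 6, 3),
                            lesions = list(list(center = c(1, 1, 1),
                                                radius = 2,
                                                params = dbsi_archetype(
                                                  "csf")))),
               "inside")
  spec <- phantom_spec(shape = c(10, 10, 5),
                       lesions = list(
                         list(center = c(5, 5, 3), radius = 2,
                              params = dbsi_archetype("progression")),
                         list(center = c(6, 5, 3), radius = 2,
                              params = dbsi_archetype("csf"))),
                       snr = 30, seed = 1)
  expect_error(make_phantom(spec, dbsi_scheme()), "overlap")
})

test_that("random voxel draws are normalized archetype mixtures", {
  set.seed(12)
  for (k in 1:20) {
    p <- random_voxel_params()
    tot <- sum(vapply(p$aniso, `[[`, 0, "fraction")) + sum(p$iso$weights)
    expect_equal(tot, 1, tolerance = 1e-9)
    expect_true(all(p$iso$grid >= 0 & p$iso$grid <= 3))
  }
})

test_that("cohort generation follows the group model", {
  # degenerate draw: zero sds pin every patient at the group mean
  sds <- data.frame(metric = c("hindered", "restricted", "nonrestricted",
                               "fiber", "adc", "fa", "t1w_gd", "t2w",
                               "flair"),
                    treatment_effect = 0, progression = 0)
  spec0 <- cohort_spec(metric_sds = sds, seed = 3)
  co <- make_cohort(spec0)
  expect_equal(unique(co$metrics$hindered[
    co$metrics$Diagnosis == "treatment_effect"]), 0.17)
  expect_equal(unique(co$metrics$hindered[
    co$metrics$Diagnosis == "progression"]), 0.08)
  # determinism
  expect_identical(make_cohort(spec0), make_cohort(cohort_spec(
    metric_sds = sds, seed = 3)))
})

test_that("large cohorts match the generative means (CLT check)", {
  spec <- cohort_spec(n_treatment_effect = 500, n_progression = 500,
                      seed = 8)
  co <- make_cohort(spec)
  a <- co$metrics$hindered[co$metrics$Diagnosis == "treatment_effect"]
  b <- co$metrics$hindered[co$metrics$Diagnosis == "progression"]
  expect_lt(abs(mean(a) - 0.17), 3 * 0.02 / sqrt(500))
  expect_lt(abs(mean(b) - 0.08), 3 * 0.03 / sqrt(500))
  # independence across patients: near-zero correlation of residual pairs
  expect_lt(abs(cor(a[1:499], a[2:500])), 0.15)
})

test_that("timing model honours the zero-delay point mass", {
  spec <- cohort_spec(n_treatment_effect = 30, n_progression = 30,
                      p_zero = 1, seed = 5)
  co <- make_cohort(spec)
  expect_true(all(co$records$SurgeryToSOC_weeks ==
                    co$records$SurgeryToDBSI_weeks))
  expect_error(cohort_spec(n_treatment_effect = 0, n_progression = 0))
})

test_that("the published table fixture is verbatim", {
  t1 <- table1_fixture()
  expect_equal(nrow(t1), 12)
  r4 <- t1[t1$Subject == "C1-004", ]
  expect_equal(r4$Diagnosis, "treatment_effect")
  expect_equal(r4$SurgeryToDBSI_weeks, 23.0)
  expect_equal(r4$SurgeryToSOC_weeks, 75.0)
  r11 <- t1[t1$Subject == "C1-011", ]
  expect_equal(r11$SurgeryToDBSI_weeks, 12.4)
  expect_equal(r11$SurgeryToSOC_weeks, 12.4)
  expect_equal(sum(t1$Diagnosis %in% c("treatment_effect", "progression")),
               9)
})

test_that("patient tables round trip through TSV", {
  td <- withr::local_tempdir()
  p <- file.path(td, "records.tsv")
  write_patient_table(table1_fixture(), p)
  back <- read_patient_table(p)
  expect_equal(back$SurgeryToSOC_weeks, table1_fixture()$SurgeryToSOC_weeks)
  expect_equal(back$Subject, table1_fixture()$Subject)
})
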