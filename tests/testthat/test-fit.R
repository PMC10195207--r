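test_that("band fractions split the spectrum at the published thresholds", {
  fr <- compute_fractions(iso_spectrum(c(0.5, 1.2, 2.0), c(0.5, 0.3, 0.2)))
  expect_equal(unname(fr), c(0, 0.5, 0.3, 0.2))
  # boundaries are inclusive on the right
  expect_equal(unname(compute_fractions(iso_spectrum(1.0, 1))["restricted"]),
               1)
  expect_equal(unname(compute_fractions(iso_spectrum(1.5, 1))["hindered"]),
               1)
  expect_equal(unname(compute_fractions(iso_spectrum(1.5000001, 1))[
    "nonrestricted"]), 1)
  # fiber weight joins the normalization
  fr2 <- compute_fractions(iso_spectrum(0.5, 0.5), fiber_weight = 0.5)
  expect_equal(unname(fr2), c(0.5, 0.5, 0, 0))
  expect_error(compute_fractions(iso_spectrum(1, 0)), "zero")
})

test_that("single-compartment voxels are recovered sharply", {
  tab <- dbsi_scheme()
  v <- fit_voxel(dbsi_signal(tab, dbsi_params(iso = iso_spectrum(1.2, 1))),
                 tab)
  expect_gte(v$hindered_fraction, 0.95)
  expect_lte(v$fiber_fraction, 0.02)
  # zero-diffusivity limit: constant signal
  v0 <- fit_voxel(rep(1, length(tab)), tab)
  expect_equal(v0$restricted_fraction, 1, tolerance = 1e-3)
})

test_that("a 50/50 stick-plus-free voxel splits evenly", {
  tab <- dbsi_scheme()
  p <- dbsi_params(aniso_component(0.5, 1.5, 0.2, c(0, 0, 1)),
                   iso_spectrum(2.5, 0.5))
  v <- fit_voxel(dbsi_signal(tab, p), tab)
  expect_equal(v$fiber_fraction, 0.5, tolerance = 0.05)
  expect_equal(v$nonrestricted_fraction, 0.5, tolerance = 0.05)
})

test_that("fit output always satisfies the fraction invariants", {
  tab <- dbsi_scheme()
  set.seed(31)
  for (k in 1:8) {
    p <- random_voxel_params()
    s <- dbsi_signal(tab, p)
    if (k > 4) s <- add_rician_noise(s, 30, seed = 400 + k)
    for (cfg in list(fit_config(), fit_config_clinical())) {
      v <- fit_voxel(s, tab, cfg)
      fr <- fraction_vector(v)
      expect_equal(sum(fr), 1, tolerance = 1e-6)
      expect_true(all(fr >= 0 & fr <= 1))
      expect_gte(v$residual_rms, 0)
    }
  }
})

test_that("noise-free round trips recover the generating fractions", {
  tab <- dbsi_scheme()
  set.seed(17)
  err <- replicate(15, {
    p <- random_voxel_params()
    v <- fit_voxel(dbsi_signal(tab, p), tab)
    mean(abs(fraction_vector(v) - true_fractions(p)))
  })
  expect_lt(mean(err), 0.03)
})

test_that("fitting is deterministic and rejects degenerate input", {
  tab <- dbsi_scheme()
  s <- add_rician_noise(dbsi_signal(tab, dbsi_archetype("background")),
                        30, seed = 2)
  v1 <- fit_voxel(s, tab)
  v2 <- fit_voxel(s, tab)
  expect_identical(fraction_vector(v1), fraction_vector(v2))
  expect_error(fit_voxel(rep(0, length(tab)), tab), "degenerate")
  expect_error(fit_voxel(s[-1], tab), "length")
})

test_that("fit_map honors the mask and is bit-reproducible", {
  tab <- dbsi_scheme()
  spec <- phantom_spec(shape = c(3, 3, 2), snr = 30, seed = 6)
  ph <- make_phantom(spec, tab)
  mask <- array(FALSE, c(3, 3, 2)); mask[1:2, 1, 1] <- TRUE
  m1 <- fit_map(ph$volume, tab, mask, fit_config_clinical())
  m2 <- fit_map(ph$volume, tab, mask, fit_config_clinical())
  expect_identical(m1$hindered, m2$hindered)
  expect_true(all(m1$fiber[!mask] == 0))
  expect_true(all(abs(m1$fiber[mask] + m1$restricted[mask] +
                        m1$hindered[mask] +
                        m1$nonrestricted[mask] - 1) < 1e-6))
  expect_error(fit_map(ph$volume, tab, array(FALSE, c(3, 3, 2))), "empty")
})

test_that("noise-free phantom maps match ground truth", {
  tab <- dbsi_scheme()
  spec <- phantom_spec(shape = c(4, 4, 2), snr = Inf, seed = 1)
  ph <- make_phantom(spec, tab)
  maps <- fit_map(ph$volume, tab, array(TRUE, c(4, 4, 2)))
  err <- mean(abs(c(maps$fiber - ph$truth$fiber,
                    maps$restricted - ph$truth$restricted,
                    maps$hindered - ph$truth$hindered,
                    maps$nonrestricted - ph$truth$nonrestricted)))
  expect_lt(err, 0.02)
})

test_that("parameter maps write one NIfTI per metric", {
  tab <- dbsi_scheme()
  spec <- phantom_spec(shape = c(3, 3, 2), snr = Inf, seed = 2)
  ph <- make_phantom(spec, tab)
  maps <- fit_map(ph$volume, tab, array(TRUE, c(3, 3, 2)),
                  fit_config_clinical())
  td <- withr::local_tempdir()
  paths <- write_parameter_maps(maps, file.path(td, "phantom"))
  expect_length(paths, 6)
  expect_true(all(file.exists(paths)))
  back <- RNifti::readNifti(paths[["hindered"]])
  expect_equal(array(as.numeric(back), dim = c(3, 3, 2)), maps$hindered,
               tolerance = 1e-6)
})
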