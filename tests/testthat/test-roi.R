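test_that("identity resampling returns the input", {
  set.seed(2)
  vol <- array(runif(5 * 5 * 4), c(5, 5, 4))
  idt <- rigid_transform()
  expect_equal(apply_rigid(vol, idt, dim(vol), method = "nearest"), vol)
  expect_equal(apply_rigid(vol, idt, dim(vol), method = "trilinear"), vol,
               tolerance = 1e-6)
})

test_that("whole-voxel translation shifts the grid exactly", {
  vol <- array(0, c(6, 6, 4)); vol[3, 3, 2] <- 1
  tr <- rigid_transform(translation = c(1, 0, 0))  # move +1 voxel in x
  out <- apply_rigid(vol, tr, dim(vol), method = "nearest")
  expect_equal(unname(which(out == 1, arr.ind = TRUE)[1, ]), c(4, 3, 2))
  out2 <- apply_rigid(vol, tr, dim(vol), method = "trilinear")
  expect_equal(out2[4, 3, 2], 1, tolerance = 1e-9)
})

test_that("rotating a spherical phantom preserves its interior mean", {
  dm <- c(15, 15, 15)
  ctr <- c(8, 8, 8)
  idx <- which(array(TRUE, dm), arr.ind = TRUE)
  r2 <- rowSums(sweep(idx, 2, ctr)^2)
  vol <- array(0, dm); vol[idx[r2 <= 16, ]] <- 1
  th <- 35 * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  aff <- diag(4); aff[1:3, 4] <- -ctr          # rotate about the center
  rot <- rigid_transform(R)
  out <- apply_rigid(vol, rot, dm, ref_affine = aff, mov_affine = aff)
  inside <- array(FALSE, dm); inside[idx[r2 <= 9, ]] <- TRUE
  expect_equal(mean(out[inside]), mean(vol[inside]), tolerance = 0.01)
})

test_that("invalid rigid transforms are rejected", {
  expect_error(rigid_transform(matrix(2 * diag(3), 3, 3)), "orthonormal")
  refl <- diag(c(-1, 1, 1))
  expect_error(rigid_transform(refl), "orthonormal")
})

test_that("rigid transforms round trip as 4x4 text", {
  th <- 0.4
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  tr <- rigid_transform(R, c(1.5, -2, 0.25))
  td <- withr::local_tempdir()
  p <- file.path(td, "xfm.txt")
  write_rigid_transform(tr, p)
  back <- read_rigid_transform(p)
  expect_equal(back$rotation, tr$rotation, tolerance = 1e-10)
  expect_equal(back$translation, tr$translation, tolerance = 1e-10)
})

test_that("new/enlarging enhancement follows the component rule", {
  dm <- c(12, 12, 6)
  sphere <- function(ctr, r) {
    idx <- which(array(TRUE, dm), arr.ind = TRUE)
    m <- array(FALSE, dm)
    m[idx[rowSums(sweep(idx, 2, ctr)^2) <= r^2, ]] <- TRUE
    m
  }
  cur <- sphere(c(6, 6, 3), 5)
  pri <- sphere(c(6, 6, 3), 3)
  out <- new_enhancement_mask(cur, pri)
  expect_equal(out$labels > 0, cur & !pri)          # the shell
  # prior empty: everything is new
  expect_equal(new_enhancement_mask(cur, array(FALSE, dm))$labels > 0, cur)
  # current inside prior: nothing qualifies
  expect_equal(sum(new_enhancement_mask(pri, cur)$labels), 0)
  # two components, only the enlarging one contributes
  cur2 <- sphere(c(3, 3, 3), 2) | sphere(c(9, 9, 3), 2)
  pri2 <- sphere(c(3, 3, 3), 2) | sphere(c(9, 9, 3), 1)
  out2 <- new_enhancement_mask(cur2, pri2)
  expect_true(all(!(out2$labels > 0)[sphere(c(3, 3, 3), 2)]))
  expect_equal(out2$labels > 0, sphere(c(9, 9, 3), 2) & !pri2)
  expect_error(new_enhancement_mask(cur, array(FALSE, c(5, 5, 5))), "grid")
})

test_that("slice sampling keeps every n-th slice from the lowest", {
  dm <- c(4, 4, 20)
  m <- array(FALSE, dm); m[2, 2, 10:16] <- TRUE
  out <- sample_slices(m, 3)
  kept <- which(apply(out$labels > 0, 3, any))
  expect_equal(kept, c(10, 13, 16))
  expect_equal(sample_slices(m, 1)$labels > 0, m)
  single <- array(FALSE, dm); single[, , 7] <- TRUE
  expect_equal(sample_slices(single, 5)$labels > 0, single)
  expect_error(sample_slices(array(FALSE, dm)), "empty")
  # output is always a subset of the input
  expect_true(all(!(out$labels > 0 & !m)))
})

test_that("ROI means average each metric over the ROI", {
  dm <- c(4, 4, 2)
  roi <- array(FALSE, dm); roi[1:2, 1, 1] <- TRUE
  hind <- array(0, dm); hind[1, 1, 1] <- 0.1; hind[2, 1, 1] <- 0.2
  row <- roi_means(list(hindered = hind, t2w = array(7, dm)), roi,
                   subject = "P1")
  expect_equal(row$hindered, 0.15)
  expect_equal(row$t2w, 7)
  expect_equal(row$n_voxels, 2)
  expect_error(roi_means(list(h = hind), array(FALSE, dm)), "empty")
})

test_that("lesion classification compares against the reference mean", {
  dm <- c(8, 8, 4)
  les <- array(FALSE, dm); les[3:4, 3:4, 2] <- TRUE
  ref <- array(FALSE, dm); ref[6:7, 6:7, 2] <- TRUE
  h <- array(0.1, dm)
  h[les] <- 0.3
  up <- classify_lesion(h, les, ref)
  expect_equal(up$label, "treatment_effect")
  expect_equal(up$margin, 0.2, tolerance = 1e-12)
  h[les] <- 0.02
  expect_equal(classify_lesion(h, les, ref)$label, "progression")
  # antisymmetry: swapping masks flips the call
  expect_equal(classify_lesion(h, ref, les)$label, "treatment_effect")
  h[les] <- 0.1
  expect_equal(classify_lesion(h, les, ref)$label, "indeterminate")
  expect_error(classify_lesion(h, les, les), "overlap")
})

test_that("the reference shell rings the lesion and obeys exclusions", {
  dm <- c(14, 14, 7)
  les <- array(FALSE, dm); les[7, 7, 4] <- TRUE
  sh <- reference_shell(les, inner = 2, outer = 3)
  d <- which(sh$labels > 0, arr.ind = TRUE)
  cheb <- pmax(abs(d[, 1] - 7), abs(d[, 2] - 7), abs(d[, 3] - 4))
  expect_true(all(cheb >= 2 & cheb <= 3))
  expect_false(any(sh$labels[les] > 0))
  # CSF-like voxels excluded by the nonrestricted map
  freemap <- array(0, dm); freemap[7, 9, 4] <- 0.95
  sh2 <- reference_shell(les, inner = 2, outer = 3,
                         nonrestricted_map = freemap)
  expect_equal(sh2$labels[7, 9, 4], 0L)
  expect_error(reference_shell(array(FALSE, dm)), "empty")
})
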