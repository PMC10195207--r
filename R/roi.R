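#' Rigid (rotation + translation) world-coordinate transform
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation length-3 numeric (mm).
#' @return Object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3, 3)) ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-6 ||
      abs(det(rotation) - 1) > 1e-6) {
    stop("rotation must be orthonormal with determinant +1")
  }
  if (length(translation) != 3) stop("translation must be a 3-vector")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' Read / write a rigid transform as a 4x4 text matrix
#'
#' Plain-text 4x4 row-major matrix in world (mm) coordinates, the layout
#' ITK-style registration tools exchange.
#'
#' @param path file path.
#' @return a [rigid_transform()].
#' @export
read_rigid_transform <- function(path) {
  m <- unname(as.matrix(read.table(path)))
  if (!all(dim(m) == c(4, 4))) stop("expected a 4x4 matrix")
  rigid_transform(m[1:3, 1:3], m[1:3, 4])
}

#' @rdname read_rigid_transform
#' @param transform a [rigid_transform()] to write.
#' @export
write_rigid_transform <- function(transform, path) {
  stopifnot(inherits(transform, "rigid_transform"))
  m <- rbind(cbind(transform$rotation, transform$translation), c(0, 0, 0, 1))
  write.table(m, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Resample a moving volume onto a reference grid under a rigid transform
#'
#' Each reference voxel center is mapped to world coordinates through
#' `ref_affine`, through the inverse rigid transform, and into the moving
#' volume's voxel space through the inverse of `mov_affine`; the moving
#' volume is then sampled there (trilinear for intensity images,
#' nearest-neighbour for label maps). Voxels falling outside the moving
#' field of view are 0.
#'
#' @param moving 3D array to resample.
#' @param transform a [rigid_transform()] mapping moving world coordinates
#'   to reference world coordinates.
#' @param ref_shape length-3 integer shape of the output grid.
#' @param ref_affine,mov_affine 4x4 voxel-to-world affines (1-based voxel
#'   indices).
#' @param method "trilinear" or "nearest".
#' @return 3D array on the reference grid.
#' @export
apply_rigid <- function(moving, transform, ref_shape,
                        ref_affine = diag(4), mov_affine = ref_affine,
                        method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  stopifnot(inherits(transform, "rigid_transform"))
  moving <- as.array(moving)
  if (length(dim(moving)) != 3) stop("moving must be a 3D array")
  idx <- as.matrix(expand.grid(i = seq_len(ref_shape[1]),
                               j = seq_len(ref_shape[2]),
                               k = seq_len(ref_shape[3])))
  world <- t(ref_affine %*% rbind(t(idx), 1))[, 1:3, drop = FALSE]
  # reference world -> moving world (inverse of the forward rigid map)
  mov_world <- sweep(world, 2, transform$translation) %*% transform$rotation
  vox <- t(solve(mov_affine) %*% rbind(t(mov_world), 1))[, 1:3, drop = FALSE]
  dm <- dim(moving)
  out <- numeric(nrow(vox))
  if (method == "nearest") {
    v <- round(vox)
    ok <- v[, 1] >= 1 & v[, 1] <= dm[1] & v[, 2] >= 1 & v[, 2] <= dm[2] &
      v[, 3] >= 1 & v[, 3] <= dm[3]
    out[ok] <- moving[v[ok, , drop = FALSE]]
  } else {
    f <- floor(vox)
    d <- vox - f
    ok <- f[, 1] >= 1 & f[, 1] + 1 <= dm[1] & f[, 2] >= 1 &
      f[, 2] + 1 <= dm[2] & f[, 3] >= 1 & f[, 3] + 1 <= dm[3]
    # clamp exact upper-edge hits so x+1 stays in range
    edge <- vox[, 1] == dm[1] | vox[, 2] == dm[2] | vox[, 3] == dm[3]
    hit <- which(edge & !ok &
                   vox[, 1] >= 1 & vox[, 1] <= dm[1] &
                   vox[, 2] >= 1 & vox[, 2] <= dm[2] &
                   vox[, 3] >= 1 & vox[, 3] <= dm[3])
    if (length(hit)) {
      f[hit, ] <- pmin(f[hit, , drop = FALSE],
                       matrix(dm - 1L, length(hit), 3, byrow = TRUE))
      d[hit, ] <- vox[hit, , drop = FALSE] - f[hit, , drop = FALSE]
      ok[hit] <- f[hit, 1] >= 1 & f[hit, 2] >= 1 & f[hit, 3] >= 1
    }
    fo <- f[ok, , drop = FALSE]; dd <- d[ok, , drop = FALSE]
    acc <- numeric(sum(ok))
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- (if (dx) dd[, 1] else 1 - dd[, 1]) *
        (if (dy) dd[, 2] else 1 - dd[, 2]) *
        (if (dz) dd[, 3] else 1 - dd[, 3])
      acc <- acc + w * moving[cbind(fo[, 1] + dx, fo[, 2] + dy, fo[, 3] + dz)]
    }
    out[ok] <- acc
  }
  array(out, ref_shape)
}

# 26-connected component labelling by breadth-first search
.label_components <- function(mask) {
  dm <- dim(mask)
  lab <- array(0L, dm)
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  cur <- 0L
  todo <- which(mask & lab == 0L)
  for (s in todo) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    lab[s] <- cur
    frontier <- matrix(arrayInd(s, dm), ncol = 3)
    while (nrow(frontier)) {
      cand <- do.call(rbind, lapply(seq_len(nrow(nb)), function(r) {
        sweep(frontier, 2, -nb[r, ])
      }))
      ok <- cand[, 1] >= 1 & cand[, 1] <= dm[1] &
        cand[, 2] >= 1 & cand[, 2] <= dm[2] &
        cand[, 3] >= 1 & cand[, 3] <= dm[3]
      cand <- unique(cand[ok, , drop = FALSE])
      new <- cand[mask[cand] & lab[cand] == 0L, , drop = FALSE]
      if (nrow(new)) lab[new] <- cur
      frontier <- new
    }
  }
  lab
}

#' New or enlarging enhancement mask
#'
#' Selects the voxels of the current contrast-enhancing lesion that were
#' absent from the most recent prior lesion mask, restricted to lesion
#' components that are actually new (no prior overlap) or enlarging
#' (prior overlap smaller than the component). Components judged per
#' 26-connected 3D component; stable or shrinking components contribute
#' nothing.
#'
#' @param current_lesion,prior_lesion [label_map()]s (or logical arrays)
#'   on the same grid; non-zero voxels are lesion.
#' @return a [label_map()] with 1 on selected voxels.
#' @export
new_enhancement_mask <- function(current_lesion, prior_lesion) {
  cur <- if (inherits(current_lesion, "label_map")) {
    current_lesion$labels > 0
  } else as.array(current_lesion) > 0
  pri <- if (inherits(prior_lesion, "label_map")) {
    prior_lesion$labels > 0
  } else as.array(prior_lesion) > 0
  if (!all(dim(cur) == dim(pri))) stop("current/prior grids differ")
  out <- array(0L, dim(cur))
  comp <- .label_components(cur)
  for (cc in seq_len(max(comp, 0L))) {
    voxels <- comp == cc
    overlap <- sum(voxels & pri)
    if (overlap < sum(voxels)) {       # new (0) or enlarging (< size)
      out[voxels & !pri] <- 1L
    }
  }
  label_map(out, legend = c(background = 0L, new_enhancement = 1L))
}

#' Retain a mask on every n-th axial slice
#'
#' Starting from the lowest axial slice containing mask voxels, keeps the
#' mask only on slices z0, z0 + stride, z0 + 2 * stride, ... (the
#' every-third-slice segmentation rule at the default stride).
#'
#' @param mask a [label_map()] or logical array.
#' @param stride slice stride (>= 1), default 3.
#' @return a [label_map()] of the retained voxels.
#' @export
sample_slices <- function(mask, stride = 3L) {
  if (stride < 1 || stride != round(stride)) stop("stride must be >= 1")
  m <- if (inherits(mask, "label_map")) mask$labels > 0 else as.array(mask) > 0
  zs <- which(apply(m, 3, any))
  if (!length(zs)) stop("empty mask")
  keep_z <- seq(min(zs), dim(m)[3], by = stride)
  out <- array(0L, dim(m))
  out[, , keep_z] <- m[, , keep_z]
  label_map(out, legend = c(background = 0L, sampled = 1L))
}

#' Mean intensity of each metric over an ROI
#'
#' @param maps named list of 3D arrays (e.g. a `parameter_maps` object's
#'   metric maps together with co-registered conventional volumes), all on
#'   the ROI grid.
#' @param roi a [label_map()] or logical array; non-zero voxels form the
#'   ROI.
#' @param subject,timepoint identifiers recorded in the output row.
#' @return one-row data.frame: subject, timepoint, n_voxels, one column
#'   per metric.
#' @export
roi_means <- function(maps, roi, subject = "S001", timepoint = 1L) {
  m <- if (inherits(roi, "label_map")) roi$labels > 0 else as.array(roi) > 0
  if (!any(m)) stop("empty ROI")
  if (inherits(maps, "parameter_maps")) {
    maps <- maps[c("fiber", "restricted", "hindered", "nonrestricted",
                   "adc", "fa")]
  }
  stopifnot(is.list(maps), length(names(maps)) == length(maps))
  vals <- vapply(maps, function(x) {
    x <- as.array(x)
    if (!all(dim(x) == dim(m))) stop("map grid does not match ROI")
    mean(x[m])
  }, 0)
  cbind(data.frame(subject = subject, timepoint = timepoint,
                   n_voxels = sum(m)),
        as.data.frame(as.list(vals)))
}

# Chebyshev distance-from-mask by iterated 26-neighbour dilation
.chebyshev_rings <- function(mask, n) {
  dm <- dim(mask)
  dist <- array(Inf, dm)
  dist[mask] <- 0
  cur <- mask
  for (r in seq_len(n)) {
    grown <- cur
    grown[] <- FALSE
    # dilate by shifting along each axis combination
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      xs <- pmin(pmax(seq_len(dm[1]) + dx, 1), dm[1])
      ys <- pmin(pmax(seq_len(dm[2]) + dy, 1), dm[2])
      zs <- pmin(pmax(seq_len(dm[3]) + dz, 1), dm[3])
      grown <- grown | cur[xs, ys, zs, drop = FALSE]
    }
    newly <- grown & !is.finite(dist)
    dist[newly] <- r
    cur <- grown
  }
  dist
}

#' Surrounding-parenchyma reference shell
#'
#' Builds the default comparison region for lesion classification: voxels
#' 2-6 voxels (Chebyshev distance, 26-connectivity) outside the lesion,
#' excluding any voxel of `exclude` (e.g. prior lesions) and, when a
#' nonrestricted-fraction map is supplied, excluding CSF-like voxels with
#' nonrestricted fraction > `csf_threshold`.
#'
#' @param lesion [label_map()] or logical array.
#' @param inner,outer shell distance bounds in voxels.
#' @param exclude optional mask of voxels never eligible.
#' @param nonrestricted_map optional 3D array for CSF exclusion.
#' @param csf_threshold nonrestricted fraction above which a voxel is
#'   treated as CSF.
#' @return a [label_map()] with role `parenchyma_reference`.
#' @export
reference_shell <- function(lesion, inner = 2L, outer = 6L, exclude = NULL,
                            nonrestricted_map = NULL, csf_threshold = 0.8) {
  m <- if (inherits(lesion, "label_map")) lesion$labels > 0 else
    as.array(lesion) > 0
  if (!any(m)) stop("empty lesion mask")
  stopifnot(inner >= 1, outer >= inner)
  dist <- .chebyshev_rings(m, outer)
  shell <- is.finite(dist) & dist >= inner & dist <= outer
  if (!is.null(exclude)) {
    e <- if (inherits(exclude, "label_map")) exclude$labels > 0 else
      as.array(exclude) > 0
    shell <- shell & !e
  }
  if (!is.null(nonrestricted_map)) {
    shell <- shell & as.array(nonrestricted_map) <= csf_threshold
  }
  if (!any(shell)) stop("reference shell is empty")
  label_map(array(as.integer(shell), dim(m)),
            legend = c(background = 0L, parenchyma_reference = 1L))
}

#' Classify a lesion from the hindered fraction map
#'
#' The qualitative reading rule made explicit: a lesion whose mean
#' hindered fraction exceeds that of the surrounding parenchyma reference
#' is called `treatment_effect` (hyperintense), one below is
#' `progression` (hypointense). Exactly equal means give `indeterminate`
#' rather than an arbitrary side. The margin (lesion mean minus reference
#' mean) is reported alongside the label.
#'
#' @param hindered_map 3D hindered-fraction array.
#' @param lesion,reference disjoint non-empty masks ([label_map()] or
#'   logical arrays).
#' @return list with `label`, `margin`, `lesion_mean`, `reference_mean`.
#' @export
classify_lesion <- function(hindered_map, lesion, reference) {
  les <- if (inherits(lesion, "label_map")) lesion$labels > 0 else
    as.array(lesion) > 0
  ref <- if (inherits(reference, "label_map")) reference$labels > 0 else
    as.array(reference) > 0
  if (!any(les) || !any(ref)) stop("lesion and reference must be non-empty")
  if (any(les & ref)) stop("lesion and reference masks overlap")
  h <- as.array(hindered_map)
  lm <- mean(h[les]); rm <- mean(h[ref])
  label <- if (lm > rm) "treatment_effect" else if (lm < rm) "progression"
  else "indeterminate"
  list(label = label, margin = lm - rm, lesion_mean = lm, reference_mean = rm)
}
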