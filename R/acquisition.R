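#' Diffusion gradient table
#'
#' Container for a diffusion-weighted acquisition scheme: one b-value
#' (s/mm^2) and one gradient direction per acquired volume. Directions of
#' diffusion-weighted entries (b > 0) must be unit vectors; b = 0 entries
#' conventionally carry a zero direction.
#'
#' @param bvals numeric vector of non-negative b-values (s/mm^2).
#' @param bvecs 3 x n matrix of gradient directions, one column per entry.
#' @param normalize if `TRUE`, non-unit b > 0 columns are renormalized with
#'   a warning rather than rejected.
#' @return An object of class `gradient_table` with elements `bvals` and
#'   `bvecs`.
#' @export
gradient_table <- function(bvals, bvecs, normalize = FALSE) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != 3L) stop("bvecs must be a 3 x n matrix")
  if (length(bvals) != ncol(bvecs)) {
    stop("bvals length (", length(bvals), ") does not match bvec count (",
         ncol(bvecs), ")")
  }
  if (length(bvals) < 2L) stop("a gradient table needs at least 2 entries")
  if (length(bvals) < 7L) {
    warning("fewer than 7 entries: too few directions for tensor fitting")
  }
  if (any(!is.finite(bvals)) || any(bvals < 0)) {
    stop("b-values must be finite and non-negative")
  }
  if (!any(bvals == 0)) stop("at least one b = 0 entry is required")
  nrm <- sqrt(colSums(bvecs^2))
  dw <- bvals > 0
  bad <- dw & abs(nrm - 1) > 1e-8
  if (any(bad)) {
    if (!normalize) {
      stop(sum(bad), " diffusion-weighted direction(s) are not unit vectors")
    }
    warning("renormalizing ", sum(bad), " non-unit gradient direction(s)")
    bvecs[, bad] <- sweep(bvecs[, bad, drop = FALSE], 2, nrm[bad], "/")
  }
  structure(list(bvals = bvals, bvecs = unname(bvecs)),
            class = "gradient_table")
}

#' @export
length.gradient_table <- function(x) length(x$bvals)

#' @export
print.gradient_table <- function(x, ...) {
  shells <- sort(unique(round(x$bvals)))
  cat("Gradient table:", length(x$bvals), "entries,",
      sum(x$bvals == 0), "b=0;",
      "b-values (s/mm²):", paste(shells, collapse = ", "), "\n")
  invisible(x)
}

#' Build a DSI-style q-space grid acquisition scheme
#'
#' Enumerates all integer lattice points (qx, qy, qz) with
#' qx^2 + qy^2 + qz^2 <= r^2. The origin contributes the b = 0 entry; every
#' other point q contributes direction q/|q| at b = b_max * |q|^2 / r^2
#' (b scales with |q|^2, the q-space convention). Antipodal pairs measure
#' the same diffusion attenuation and are collapsed to a single direction
#' by default.
#'
#' The published scheme reduces this grid to a fixed vendor direction
#' table; when that table is available, construct the scheme directly with
#' [gradient_table()] instead.
#'
#' @param r positive integer lattice radius (3 for DBSI, 5 for DSI).
#' @param b_max maximum b-value in s/mm^2 (1500 for the DBSI protocol).
#' @param collapse_antipodal collapse q and -q into one entry (default TRUE).
#' @return A [gradient_table()]; the first entry is the b = 0 origin.
#' @export
build_grid_scheme <- function(r, b_max, collapse_antipodal = TRUE) {
  if (!.is_scalar_number(r) || r < 1 || r != round(r)) {
    stop("r must be a positive integer")
  }
  if (!.is_scalar_number(b_max) || b_max <= 0) stop("b_max must be > 0")
  q <- as.matrix(expand.grid(qx = -r:r, qy = -r:r, qz = -r:r))
  q <- q[rowSums(q^2) <= r^2, , drop = FALSE]
  q2 <- rowSums(q^2)
  q <- q[order(q2, q[, 1], q[, 2], q[, 3]), , drop = FALSE]
  q2 <- rowSums(q^2)
  if (collapse_antipodal) {
    # keep the lexicographically larger of each +/-q pair
    keep <- q2 == 0 | q[, 1] > 0 |
      (q[, 1] == 0 & q[, 2] > 0) |
      (q[, 1] == 0 & q[, 2] == 0 & q[, 3] > 0)
    q <- q[keep, , drop = FALSE]
    q2 <- q2[keep]
  }
  bvals <- b_max * q2 / r^2
  bvecs <- t(q)
  nz <- q2 > 0
  bvecs[, nz] <- sweep(bvecs[, nz, drop = FALSE], 2, sqrt(q2[nz]), "/")
  gradient_table(bvals = bvals, bvecs = bvecs)
}

#' Diffusion-weighted image volume
#'
#' A 4D signal array whose 4th axis is indexed by a [gradient_table()],
#' with voxel size (mm) and a 4x4 voxel-to-world affine.
#'
#' @param data 4D numeric array of non-negative signal.
#' @param voxel_size length-3 numeric, mm.
#' @param affine 4x4 voxel-to-world matrix; default diagonal from voxel_size.
#' @return Object of class `dwi_volume`.
#' @export
dwi_volume <- function(data, voxel_size = c(2, 2, 2), affine = NULL) {
  data <- as.array(data)
  if (length(dim(data)) != 4L) stop("data must be a 4D array")
  if (any(!is.finite(data)) || any(data < 0)) {
    stop("signal values must be finite and non-negative")
  }
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0)) {
    stop("voxel_size must be 3 positive numbers (mm)")
  }
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("affine must be 4x4")
  structure(list(data = data, voxel_size = voxel_size, affine = affine),
            class = "dwi_volume")
}

#' Label map on the grid of a reference volume
#'
#' Integer-valued 3D segmentation sharing the spatial grid of its reference
#' DWI volume. The legend maps label values to roles (e.g. `lesion`,
#' `prior_lesion`, `parenchyma_reference`, `background`).
#'
#' @param labels 3D integer array (0 = background by convention).
#' @param legend named integer vector, names are roles.
#' @param reference_shape optional length-3 integer to validate against.
#' @return Object of class `label_map`.
#' @export
label_map <- function(labels, legend = c(background = 0L, lesion = 1L),
                      reference_shape = NULL) {
  labels <- as.array(labels)
  if (length(dim(labels)) != 3L) stop("labels must be a 3D array")
  if (any(labels < 0) || any(labels != round(labels))) {
    stop("labels must be non-negative integers")
  }
  if (!is.null(reference_shape) && !all(dim(labels) == reference_shape)) {
    stop("label map shape ", paste(dim(labels), collapse = "x"),
         " does not match reference ", paste(reference_shape, collapse = "x"))
  }
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, legend = legend), class = "label_map")
}

#' Binary mask of voxels carrying a given role
#' @param map a [label_map()].
#' @param role role name present in the legend.
#' @return logical 3D array.
#' @export
label_mask <- function(map, role) {
  stopifnot(inherits(map, "label_map"))
  if (!role %in% names(map$legend)) stop("role '", role, "' not in legend")
  map$labels == map$legend[[role]]
}

#' Read a DWI volume with its FSL-style gradient files
#'
#' @param path_image NIfTI file (.nii or .nii.gz), 4D.
#' @param path_bval text file with b-values on one line (s/mm^2).
#' @param path_bvec text file with three rows (x, y, z components).
#' @return list with elements `volume` ([dwi_volume()]) and `table`
#'   ([gradient_table()]).
#' @export
read_dwi <- function(path_image, path_bval, path_bvec) {
  img <- RNifti::readNifti(path_image)
  d <- dim(img)
  if (length(d) != 4L) {
    stop("expected a 4D NIfTI image, got ", length(d), " dimensions")
  }
  bvals <- scan(path_bval, quiet = TRUE)
  bvecs <- as.matrix(read.table(path_bvec))
  if (nrow(bvecs) != 3L) stop("bvec file must have exactly three rows")
  if (length(bvals) != d[4] || ncol(bvecs) != d[4]) {
    stop("gradient file count (", length(bvals), "/", ncol(bvecs),
         ") does not match image 4th axis (", d[4], ")")
  }
  vol <- dwi_volume(array(as.numeric(img), dim = d),
                    voxel_size = RNifti::pixdim(img)[seq_len(3)],
                    affine = RNifti::xform(img))
  tab <- gradient_table(bvals, bvecs, normalize = TRUE)
  list(volume = vol, table = tab)
}

#' Write a DWI volume and gradient table as NIfTI + bval/bvec
#'
#' Inverse of [read_dwi()]: bvals on one space-separated line, bvecs as
#' three rows (FSL dialect).
#'
#' @param volume a [dwi_volume()].
#' @param table a [gradient_table()] of matching length.
#' @param path_image,path_bval,path_bvec output paths.
#' @return invisibly, the image path.
#' @export
write_dwi <- function(volume, table, path_image, path_bval, path_bvec) {
  stopifnot(inherits(volume, "dwi_volume"), inherits(table, "gradient_table"))
  if (length(volume$data) == 0) stop("empty volume")
  if (dim(volume$data)[4] != length(table)) {
    stop("volume 4th axis does not match gradient table length")
  }
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- c(volume$voxel_size, 1)
  img <- RNifti::`sform<-`(img, structure(volume$affine, code = 2L))
  RNifti::writeNifti(img, path_image)
  cat(paste(format(table$bvals, trim = TRUE, scientific = FALSE,
                   digits = 15), collapse = " "),
      "\n", sep = "", file = path_bval)
  write.table(format(table$bvecs, trim = TRUE, scientific = FALSE,
                     digits = 15),
              file = path_bvec, row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path_image)
}

#' Read / write a label map as NIfTI
#' @param path NIfTI file.
#' @param legend legend passed on to [label_map()].
#' @return a [label_map()].
#' @export
read_label_map <- function(path, legend = c(background = 0L, lesion = 1L)) {
  img <- RNifti::readNifti(path)
  label_map(array(as.integer(round(img)), dim = dim(img)[seq_len(3)]),
            legend = legend)
}

#' @rdname read_label_map
#' @param map a [label_map()] to write.
#' @param voxel_size voxel size in mm.
#' @export
write_label_map <- function(map, path, voxel_size = c(2, 2, 2)) {
  stopifnot(inherits(map, "label_map"))
  img <- RNifti::asNifti(map$labels)
  RNifti::pixdim(img) <- voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}
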