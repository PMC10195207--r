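#' One phantom lesion-classification replicate
#'
#' Builds a two-lesion phantom (one treatment-effect archetype, one
#' progression archetype, on parenchyma background), fits the hindered
#' fraction map over the lesion and reference-shell voxels on every
#' `stride`-th axial slice, and classifies each lesion against its
#' surrounding-parenchyma shell with [classify_lesion()].
#'
#' @param seed integer seed controlling the phantom noise.
#' @param snr Rician SNR of the phantom (Inf for noise-free).
#' @param config [fit_config()] used for the maps; default the
#'   low-variance clinical preset.
#' @param radius lesion radius in voxels.
#' @param stride axial slice stride for the segmentation rule.
#' @param smooth_radius box-smoothing radius passed to [fit_map()];
#'   default 1 (3x3x3), the usual clinical preprocessing.
#' @param table optional [gradient_table()].
#' @return list with elements `treatment_effect` and `progression`, each
#'   a [classify_lesion()] result.
#' @export
classification_replicate <- function(seed, snr = 30,
                                     config = fit_config_clinical(),
                                     radius = 3.5, stride = 3L,
                                     smooth_radius = 1L, table = NULL) {
  if (is.null(table)) table <- suppressWarnings(build_grid_scheme(3, 1500))
  shape <- c(26, 26, 9)
  spec <- phantom_spec(
    shape = shape,
    lesions = list(
      list(center = c(7, 7, 5), radius = radius,
           params = dbsi_archetype("treatment_effect"),
           role = "lesion_te"),
      list(center = c(20, 20, 5), radius = radius,
           params = dbsi_archetype("progression"),
           role = "lesion_prog")),
    snr = snr, seed = seed)
  ph <- make_phantom(spec, table)
  out <- list()
  for (role in c("lesion_te", "lesion_prog")) {
    les <- label_mask(ph$labels, role)
    other <- ph$labels$labels > 0 & !les
    roi <- sample_slices(les, stride)
    shell <- reference_shell(les, exclude = other)
    shell_s <- sample_slices(shell, stride)
    fit_mask <- roi$labels > 0 | shell_s$labels > 0
    maps <- fit_map(ph$volume, table, fit_mask, config,
                    smooth_radius = smooth_radius, dti = FALSE)
    out[[if (role == "lesion_te") "treatment_effect" else "progression"]] <-
      classify_lesion(maps$hindered, roi, shell_s)
  }
  out
}
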