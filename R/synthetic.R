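#' Random tissue-archetype voxel parameters
#'
#' Draws one voxel as a mixture of 2-3 compartments chosen from the four
#' tissue archetypes the model distinguishes: an anisotropic fiber
#' (lambda_par 1.4-2.0, lambda_perp 0.15-0.4 um^2/ms, random orientation),
#' restricted cellular water (D 0.2-0.5), hindered edema/necrosis water
#' (D 1.15-1.35) and free water (D 2.5-3.0). Mixing weights are uniform on
#' 0.2-1 before normalization. This mirrors validation-phantom practice:
#' compartments sit at canonical diffusivities and the mixing fractions
#' vary.
#'
#' @param n_compartments number of compartments (2 or 3 typical).
#' @return a [dbsi_params()].
#' @export
random_voxel_params <- function(n_compartments = sample(2:3, 1)) {
  k <- n_compartments
  types <- sample(c("fiber", "restricted", "hindered", "free"), k)
  w <- runif(k, 0.2, 1)
  aniso <- list(); iso_D <- c(); iso_w <- c()
  for (j in seq_len(k)) {
    if (types[j] == "fiber") {
      o <- rnorm(3); o <- o / sqrt(sum(o^2))
      aniso <- c(aniso, list(aniso_component(w[j], runif(1, 1.4, 2.0),
                                             runif(1, 0.15, 0.4), o)))
    } else {
      iso_D <- c(iso_D, switch(types[j],
                               restricted = runif(1, 0.2, 0.5),
                               hindered = runif(1, 1.15, 1.35),
                               free = runif(1, 2.5, 3.0)))
      iso_w <- c(iso_w, w[j])
    }
  }
  if (!length(iso_D)) { iso_D <- 3; iso_w <- 0 }
  o <- order(iso_D)
  dbsi_params(aniso, iso_spectrum(iso_D[o], iso_w[o]), normalize = TRUE)
}

#' Ground-truth four-fraction vector of a parameter set
#' @param params a [dbsi_params()].
#' @return named vector (fiber, restricted, hindered, nonrestricted).
#' @export
true_fractions <- function(params) {
  stopifnot(inherits(params, "dbsi_params"))
  compute_fractions(params$iso,
                    sum(vapply(params$aniso, `[[`, 0, "fraction")))
}

#' Canonical tissue archetype parameter sets
#'
#' Fixed voxel compositions used to build phantoms:
#' * `background` - normal-appearing parenchyma: fiber-rich with a modest
#'   hindered pool (hindered fraction 0.12).
#' * `treatment_effect` - edema/necrosis-dominated enhancing lesion:
#'   hindered fraction 0.35, well above parenchyma.
#' * `progression` - hypercellular tumor: restricted-dominated, hindered
#'   fraction 0.04, below parenchyma.
#' * `csf` - nearly pure free water.
#'
#' @param type archetype name.
#' @return a [dbsi_params()].
#' @export
dbsi_archetype <- function(type = c("background", "treatment_effect",
                                    "progression", "csf")) {
  type <- match.arg(type)
  zhat <- c(0, 0, 1)
  switch(type,
    background = dbsi_params(
      aniso_component(0.45, 1.7, 0.25, zhat),
      iso_spectrum(c(0.4, 1.25, 2.6), c(0.20, 0.12, 0.23))),
    treatment_effect = dbsi_params(
      aniso_component(0.10, 1.5, 0.3, zhat),
      iso_spectrum(c(0.4, 1.25, 2.6), c(0.20, 0.35, 0.35))),
    progression = dbsi_params(
      aniso_component(0.10, 1.5, 0.3, zhat),
      iso_spectrum(c(0.35, 1.25, 2.6), c(0.56, 0.04, 0.30))),
    csf = dbsi_params(list(), iso_spectrum(c(0.4, 3.0), c(0.02, 0.98))))
}

#' Phantom specification
#'
#' A rectangular grid filled with a background archetype, plus spherical
#' lesion regions with their own parameters. Lesions must lie inside the
#' grid; overlapping lesions with different parameters are rejected.
#'
#' @param shape length-3 integer grid shape.
#' @param background [dbsi_params()] for non-lesion voxels.
#' @param lesions list of lesions, each a list with `center` (voxel
#'   coordinates, 1-based), `radius` (voxels), `params` ([dbsi_params()])
#'   and optionally `label` (integer, default sequential from 1).
#' @param snr Rician signal-to-noise ratio at S_0; `Inf` for noise-free.
#' @param seed integer seed for the noise draw.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(12, 12, 5),
                         background = dbsi_archetype("background"),
                         lesions = list(), snr = 30, seed = 1L) {
  stopifnot(length(shape) == 3, all(shape >= 1),
            inherits(background, "dbsi_params"), snr > 0)
  for (i in seq_along(lesions)) {
    l <- lesions[[i]]
    stopifnot(length(l$center) == 3, l$radius > 0,
              inherits(l$params, "dbsi_params"))
    if (any(l$center - floor(l$radius) < 1) ||
        any(l$center + floor(l$radius) > shape)) {
      stop("lesion ", i, " does not lie inside the grid")
    }
    if (is.null(l$label)) lesions[[i]]$label <- i
  }
  structure(list(shape = as.integer(shape), background = background,
                 lesions = lesions, snr = snr, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Synthesize a DWI phantom from a specification
#'
#' Every voxel's signal is generated from the forward multi-tensor model
#' with Rician noise at `spec$snr`; the label map marks each lesion with
#' its label and 0 elsewhere; ground-truth fraction maps are returned for
#' validation. Deterministic given `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @param table a [gradient_table()]; default r = 3 grid scheme at
#'   b_max 1500 s/mm^2.
#' @return list with `volume` ([dwi_volume()]), `table`, `labels`
#'   ([label_map()]) and `truth` (list of 3D arrays fiber/restricted/
#'   hindered/nonrestricted).
#' @export
make_phantom <- function(spec, table = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.null(table)) {
    table <- suppressWarnings(build_grid_scheme(3, 1500))
  }
  shape <- spec$shape
  set.seed(spec$seed)
  region <- array(0L, shape)       # 0 background, i = lesion i
  for (i in seq_along(spec$lesions)) {
    l <- spec$lesions[[i]]
    idx <- which(array(TRUE, shape), arr.ind = TRUE)
    d2 <- (idx[, 1] - l$center[1])^2 + (idx[, 2] - l$center[2])^2 +
      (idx[, 3] - l$center[3])^2
    inside <- d2 <= l$radius^2
    clash <- inside & region[idx] != 0L
    if (any(clash)) stop("lesion ", i, " overlaps another lesion")
    region[idx[inside, , drop = FALSE]] <- i
  }
  param_of <- c(list(spec$background), lapply(spec$lesions, `[[`, "params"))
  # one clean signal per distinct region, then per-voxel noise
  clean <- lapply(param_of, function(p) dbsi_signal(table, p))
  truths <- lapply(param_of, true_fractions)
  nvol <- length(table)
  data <- array(0, c(shape, nvol))
  truth <- list(fiber = array(0, shape), restricted = array(0, shape),
                hindered = array(0, shape), nonrestricted = array(0, shape))
  idx <- which(array(TRUE, shape), arr.ind = TRUE)
  for (v in seq_len(nrow(idx))) {
    r <- region[idx[v, 1], idx[v, 2], idx[v, 3]] + 1L
    s <- clean[[r]]
    if (is.finite(spec$snr)) {
      s <- sqrt((s + rnorm(nvol, 0, 1 / spec$snr))^2 +
                  rnorm(nvol, 0, 1 / spec$snr)^2)
    }
    data[idx[v, 1], idx[v, 2], idx[v, 3], ] <- s
    tf <- truths[[r]]
    truth$fiber[idx[v, 1], idx[v, 2], idx[v, 3]] <- tf["fiber"]
    truth$restricted[idx[v, 1], idx[v, 2], idx[v, 3]] <- tf["restricted"]
    truth$hindered[idx[v, 1], idx[v, 2], idx[v, 3]] <- tf["hindered"]
    truth$nonrestricted[idx[v, 1], idx[v, 2], idx[v, 3]] <- tf["nonrestricted"]
  }
  legend <- c(background = 0L,
              setNames(seq_along(spec$lesions),
                       vapply(seq_along(spec$lesions), function(i) {
                         nm <- spec$lesions[[i]]$role
                         if (is.null(nm)) paste0("lesion", i) else nm
                       }, character(1))))
  list(volume = dwi_volume(data), table = table,
       labels = label_map(region, legend = legend),
       truth = truth)
}

#' Cohort specification
#'
#' Generative model for a two-group patient cohort: per-group means and
#' sds for each lesion-ROI metric, and a diagnosis-timing model. The
#' timing model is a mixture: with probability `p_zero` the DBSI-assisted
#' and standard-of-care diagnoses coincide (difference 0 weeks), otherwise
#' the standard-of-care diagnosis lags by a log-normal extra delay.
#'
#' Default metric means give the hindered fraction a genuine group
#' difference (0.17 +/- 0.02 treatment effect vs 0.08 +/- 0.03
#' progression) while every other metric overlaps between groups.
#'
#' @param n_treatment_effect,n_progression group sizes.
#' @param metric_means data.frame with columns `metric`,
#'   `treatment_effect`, `progression` (means) or NULL for defaults.
#' @param metric_sds same layout for sds, or NULL for defaults.
#' @param surgery_to_dbsi_range uniform range (weeks) for surgery-to-DBSI
#'   diagnosis times.
#' @param p_zero probability that the standard-of-care diagnosis has no
#'   extra delay.
#' @param delay_meanlog,delay_sdlog log-normal parameters of the positive
#'   extra delay (weeks).
#' @param seed integer seed.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_treatment_effect = 4, n_progression = 5,
                        metric_means = NULL, metric_sds = NULL,
                        surgery_to_dbsi_range = c(11, 33),
                        p_zero = 1 / 3, delay_meanlog = 2.8,
                        delay_sdlog = 0.9, seed = 1L) {
  stopifnot(n_treatment_effect >= 0, n_progression >= 0,
            n_treatment_effect + n_progression > 0,
            p_zero >= 0, p_zero <= 1, delay_sdlog >= 0)
  metrics <- c("hindered", "restricted", "nonrestricted", "fiber",
               "adc", "fa", "t1w_gd", "t2w", "flair")
  if (is.null(metric_means)) {
    metric_means <- data.frame(
      metric = metrics,
      treatment_effect = c(0.17, 0.25, 0.35, 0.20, 1.2, 0.15, 300, 400, 350),
      progression = c(0.08, 0.25, 0.35, 0.20, 1.2, 0.15, 300, 400, 350))
  }
  if (is.null(metric_sds)) {
    metric_sds <- data.frame(
      metric = metrics,
      treatment_effect = c(0.02, 0.05, 0.08, 0.05, 0.15, 0.04, 40, 50, 45),
      progression = c(0.03, 0.05, 0.08, 0.05, 0.15, 0.04, 40, 50, 45))
  }
  stopifnot(identical(metric_means$metric, metric_sds$metric),
            all(metric_sds$treatment_effect >= 0),
            all(metric_sds$progression >= 0))
  structure(list(n_treatment_effect = as.integer(n_treatment_effect),
                 n_progression = as.integer(n_progression),
                 metric_means = metric_means, metric_sds = metric_sds,
                 surgery_to_dbsi_range = surgery_to_dbsi_range,
                 p_zero = p_zero, delay_meanlog = delay_meanlog,
                 delay_sdlog = delay_sdlog, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic patient cohort
#'
#' Draws per-patient lesion-ROI metric means from the group distributions
#' and diagnosis timelines from the timing model. Patients are
#' independent; deterministic given `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @return list with `records` (data.frame: Subject, Diagnosis,
#'   SurgeryToDBSI_weeks, SurgeryToSOC_weeks) and `metrics` (data.frame:
#'   Subject, Diagnosis, one column per metric).
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_treatment_effect + spec$n_progression
  diag <- c(rep("treatment_effect", spec$n_treatment_effect),
            rep("progression", spec$n_progression))
  subj <- sprintf("S%03d", seq_len(n))
  dbsi_t <- runif(n, spec$surgery_to_dbsi_range[1],
                  spec$surgery_to_dbsi_range[2])
  extra <- ifelse(runif(n) < spec$p_zero, 0,
                  rlnorm(n, spec$delay_meanlog, spec$delay_sdlog))
  records <- data.frame(Subject = subj, Diagnosis = diag,
                        SurgeryToDBSI_weeks = round(dbsi_t, 1),
                        SurgeryToSOC_weeks = round(dbsi_t + extra, 1))
  met <- spec$metric_means$metric
  vals <- sapply(seq_along(met), function(j) {
    mu <- ifelse(diag == "treatment_effect",
                 spec$metric_means$treatment_effect[j],
                 spec$metric_means$progression[j])
    sd <- ifelse(diag == "treatment_effect",
                 spec$metric_sds$treatment_effect[j],
                 spec$metric_sds$progression[j])
    rnorm(n, mu, sd)
  })
  colnames(vals) <- met
  metrics <- cbind(data.frame(Subject = subj, Diagnosis = diag), vals)
  list(records = records, metrics = metrics)
}

#' The published 12-patient time-to-diagnosis table
#'
#' The enrolled cohort's diagnosis labels, weeks from initial surgery to
#' DBSI-assisted and standard-of-care diagnosis, and the published
#' per-patient difference. Two stable and one excluded subject carry
#' missing times. The difference column is kept verbatim because the
#' source computed it from unrounded dates: for one subject it differs
#' in the last digit from subtracting the (rounded) printed times.
#'
#' @return data.frame with columns Subject, Diagnosis,
#'   SurgeryToDBSI_weeks, SurgeryToSOC_weeks, Difference_weeks.
#' @export
table1_fixture <- function() {
  data.frame(
    Subject = sprintf("C1-%03d", 1:12),
    Diagnosis = c("stable", "excluded", "treatment_effect",
                  "treatment_effect", "treatment_effect", "progression",
                  "treatment_effect", "progression", "progression",
                  "progression", "progression", "stable"),
    SurgeryToDBSI_weeks = c(NA, NA, 11.3, 23.0, 12.7, 32.1, 14.9, 16.6,
                            15.7, 19.0, 12.4, NA),
    SurgeryToSOC_weeks = c(NA, NA, 11.3, 75.0, 20.4, 52.3, 65.6, 31.6,
                           23.4, 19.0, 12.4, NA),
    Difference_weeks = c(NA, NA, 0.0, 52.0, 7.7, 20.1, 50.7, 15.0,
                         7.7, 0.0, 0.0, NA),
    stringsAsFactors = FALSE)
}

#' Read / write a patient table as TSV
#' @param path file path.
#' @return data.frame in the [table1_fixture()] layout.
#' @export
read_patient_table <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname read_patient_table
#' @param records data.frame in the [table1_fixture()] layout.
#' @export
write_patient_table <- function(records, path) {
  write.table(records, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
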