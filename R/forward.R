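#' Anisotropic tensor component
#'
#' One cylindrically symmetric anisotropic diffusion tensor: a signal
#' fraction, axial and radial diffusivities (um^2/ms) and a principal
#' direction. Axial diffusivity must dominate radial.
#'
#' @param fraction signal-intensity fraction in [0, 1].
#' @param lambda_par axial diffusivity (um^2/ms).
#' @param lambda_perp radial diffusivity (um^2/ms), <= lambda_par.
#' @param orientation unit 3-vector.
#' @return Object of class `aniso_component`.
#' @export
aniso_component <- function(fraction, lambda_par, lambda_perp, orientation) {
  if (!.is_scalar_number(fraction) || fraction < 0 || fraction > 1) {
    stop("fraction must be in [0, 1]")
  }
  if (!.is_scalar_number(lambda_par) || !.is_scalar_number(lambda_perp) ||
      lambda_perp < 0 || lambda_par < lambda_perp) {
    stop("need lambda_par >= lambda_perp >= 0")
  }
  orientation <- as.numeric(orientation)
  if (length(orientation) != 3L || abs(sqrt(sum(orientation^2)) - 1) > 1e-8) {
    stop("orientation must be a unit 3-vector")
  }
  structure(list(fraction = fraction, lambda_par = lambda_par,
                 lambda_perp = lambda_perp, orientation = orientation),
            class = "aniso_component")
}

#' Isotropic diffusivity spectrum
#'
#' Non-negative weights f(D) on a strictly increasing diffusivity grid
#' spanning the isotropic spectrum limits \[a, b\] (um^2/ms). The weights
#' are the discrete signal fractions of the spectrum; the continuous
#' integral of the model is represented as their sum against
#' exp(-b D) basis functions.
#'
#' @param grid strictly increasing diffusivities (um^2/ms), all >= 0.
#' @param weights non-negative weights, same length.
#' @return Object of class `iso_spectrum`.
#' @export
iso_spectrum <- function(grid, weights) {
  grid <- as.numeric(grid); weights <- as.numeric(weights)
  if (length(grid) != length(weights) || length(grid) == 0) {
    stop("grid and weights must be non-empty and of equal length")
  }
  if (any(grid < 0) || any(diff(grid) <= 0)) {
    stop("grid must be non-negative and strictly increasing")
  }
  if (any(weights < 0)) stop("weights must be non-negative")
  structure(list(grid = grid, weights = weights), class = "iso_spectrum")
}

#' Full DBSI voxel parameter set
#'
#' A normalized voxel: the anisotropic fractions plus the isotropic
#' spectrum weights must sum to 1.
#'
#' @param aniso list of [aniso_component()] (may be empty).
#' @param iso an [iso_spectrum()].
#' @param normalize if TRUE, rescale all fractions to sum to 1.
#' @return Object of class `dbsi_params`.
#' @export
dbsi_params <- function(aniso = list(), iso, normalize = FALSE) {
  if (inherits(aniso, "aniso_component")) aniso <- list(aniso)
  stopifnot(all(vapply(aniso, inherits, TRUE, "aniso_component")),
            inherits(iso, "iso_spectrum"))
  total <- sum(vapply(aniso, `[[`, 0, "fraction")) + sum(iso$weights)
  if (normalize) {
    if (total <= 0) stop("cannot normalize an all-zero parameter set")
    aniso <- lapply(aniso, function(a) { a$fraction <- a$fraction / total; a })
    iso$weights <- iso$weights / total
  } else if (abs(total - 1) > 1e-6) {
    stop("fractions sum to ", format(total),
         "; a voxel must be normalized (or use normalize = TRUE)")
  }
  structure(list(aniso = aniso, iso = iso), class = "dbsi_params")
}

#' Signal of one anisotropic tensor component
#'
#' exp(-b lambda_perp) * exp(-b (lambda_par - lambda_perp) cos^2 phi),
#' where phi is the angle between the diffusion gradient and the
#' component's principal direction. The fraction is not applied here.
#'
#' @param b b-value in s/mm^2 (converted to ms/um^2 internally).
#' @param grad_dir unit gradient direction (ignored at b = 0).
#' @param comp an [aniso_component()].
#' @return attenuation in (0, 1].
#' @export
aniso_signal <- function(b, grad_dir, comp) {
  stopifnot(inherits(comp, "aniso_component"))
  if (any(b < 0)) stop("b must be non-negative")
  grad_dir <- as.numeric(grad_dir)
  if (length(grad_dir) != 3L) stop("grad_dir must be a 3-vector")
  if (any(b > 0) && abs(sqrt(sum(grad_dir^2)) - 1) > 1e-8) {
    stop("grad_dir must be a unit vector")
  }
  bb <- .b_to_ms_um2(b)
  cphi2 <- sum(grad_dir * comp$orientation)^2
  exp(-bb * comp$lambda_perp) *
    exp(-bb * (comp$lambda_par - comp$lambda_perp) * cphi2)
}

#' Signal of one isotropic diffusivity
#'
#' The integrand of the isotropic spectrum term: exp(-b D).
#'
#' @param b b-value in s/mm^2.
#' @param D isotropic diffusivity (um^2/ms).
#' @return attenuation in (0, 1].
#' @export
iso_signal <- function(b, D) {
  if (any(b < 0) || any(D < 0)) stop("b and D must be non-negative")
  drop(exp(-outer(.b_to_ms_um2(b), D)))
}

#' Forward DBSI signal for a full acquisition
#'
#' Evaluates the multi-tensor model S_k/S_0 = sum_i f_i * aniso_i(b_k) +
#' sum_j f(D_j) exp(-b_k D_j) at every gradient-table entry. The isotropic
#' integral is discretized on the spectrum grid, whose weights are the
#' discrete fractions.
#'
#' @param table a [gradient_table()].
#' @param params a [dbsi_params()] (normalized).
#' @param normalize auto-normalize unnormalized params instead of erroring.
#' @return numeric vector of S_k/S_0, one per table entry; exactly 1 at
#'   b = 0 entries.
#' @export
dbsi_signal <- function(table, params, normalize = FALSE) {
  stopifnot(inherits(table, "gradient_table"))
  if (!inherits(params, "dbsi_params")) {
    params <- dbsi_params(params$aniso, params$iso, normalize = normalize)
  } else if (normalize) {
    params <- dbsi_params(params$aniso, params$iso, normalize = TRUE)
  }
  bb <- .b_to_ms_um2(table$bvals)
  s <- numeric(length(table))
  for (comp in params$aniso) {
    cphi2 <- as.numeric(crossprod(comp$orientation, table$bvecs))^2
    s <- s + comp$fraction *
      exp(-bb * (comp$lambda_perp +
                   (comp$lambda_par - comp$lambda_perp) * cphi2))
  }
  if (length(params$iso$grid)) {
    s <- s + as.numeric(exp(-outer(bb, params$iso$grid)) %*%
                          params$iso$weights)
  }
  s
}

#' Add Rician noise to a normalized signal vector
#'
#' Magnitude-MR noise: sqrt((s + n1)^2 + n2^2) with n1, n2 independent
#' zero-mean Gaussians of sd 1/snr (signal normalized so S_0 = 1).
#' Deterministic given a seed.
#'
#' @param signals numeric vector of noise-free signal.
#' @param snr positive scalar signal-to-noise ratio at S_0.
#' @param seed integer seed (optional; uses the current RNG state if NULL).
#' @param model "rician" (default) or "gaussian".
#' @return noisy signal vector, non-negative under the Rician model.
#' @export
add_rician_noise <- function(signals, snr, seed = NULL,
                             model = c("rician", "gaussian")) {
  model <- match.arg(model)
  if (!.is_scalar_number(snr) || snr <= 0) stop("snr must be > 0")
  if (!is.null(seed)) set.seed(seed)
  sigma <- 1 / snr
  n <- length(signals)
  if (model == "rician") {
    sqrt((signals + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
  } else {
    signals + rnorm(n, 0, sigma)
  }
}
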