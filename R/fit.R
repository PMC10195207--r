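#' Non-negative least squares with optional ridge penalty
#'
#' Solves min ||A x - y||^2 + ridge * ||x||^2 subject to x >= 0 by the
#' Lawson-Hanson active-set method (compiled). The ridge penalty is applied
#' by augmenting the system with sqrt(ridge) * I.
#'
#' @param A design matrix (n x p).
#' @param y response vector (length n).
#' @param ridge non-negative ridge weight on the squared-norm of x.
#' @return list with `x` (non-negative coefficients), `rnorm` (residual
#'   norm of the augmented system) and `iterations`.
#' @export
dbsi_nnls <- function(A, y, ridge = 0) {
  A <- as.matrix(A)
  y <- as.numeric(y)
  if (nrow(A) != length(y)) stop("nrow(A) must equal length(y)")
  if (ridge < 0) stop("ridge must be >= 0")
  if (ridge > 0) {
    A <- rbind(A, diag(sqrt(ridge), ncol(A)))
    y <- c(y, numeric(ncol(A)))
  }
  res <- nnls_cpp(A, y)
  res$x <- as.numeric(res$x)
  res
}

#' Near-uniform antipodally symmetric direction set
#'
#' Deterministic Fibonacci-spiral sampling of the upper hemisphere
#' (antipodal symmetry makes the lower hemisphere redundant for diffusion
#' encoding and fiber-orientation candidates).
#'
#' @param n number of directions.
#' @return 3 x n matrix of unit vectors with z >= 0.
#' @export
hemisphere_directions <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  z <- i / n                     # upper hemisphere only
  phi <- pi * (1 + sqrt(5)) * i
  r <- sqrt(pmax(0, 1 - z^2))
  rbind(r * cos(phi), r * sin(phi), z)
}

#' Fitting configuration for the per-voxel DBSI solve
#'
#' @param grid_a,grid_b isotropic spectrum limits (um^2/ms); the default
#'   0--3 spans restricted cellular water up to free water at body
#'   temperature.
#' @param grid_step spectrum grid spacing (um^2/ms).
#' @param n_orientations size of the stage-1 candidate orientation set.
#' @param max_aniso maximum number of anisotropic tensors retained.
#' @param prior_lambda list of nominal (axial, radial) diffusivity pairs
#'   (um^2/ms) building the stage-1 anisotropic dictionary.
#' @param lambda_par_bounds,lambda_perp_bounds bounds for the stage-2
#'   per-component diffusivity refinement (um^2/ms).
#' @param ridge_rel ridge weight for the dense spectrum solve, relative to
#'   the squared largest singular value of its design matrix.
#' @param stage1_threshold orientation retained when its stage-1 weight
#'   exceeds this fraction of the total weight.
#' @param coarse_step spectrum spacing of the stage-1 isotropic basis.
#' @param refine if FALSE, skip the nonlinear diffusivity refinements and
#'   report the dense-grid solve directly (faster, higher variance under
#'   noise).
#' @param merge_gap spectrum peaks closer than this (um^2/ms) are treated
#'   as one compartment during consolidation.
#' @param min_fraction anisotropic components falling below this final
#'   weight are pruned and the voxel re-fit without them.
#' @param iso_anchors optional numeric vector of fixed isotropic
#'   diffusivities (um^2/ms). When set, the spectrum is solved only at
#'   these anchors (no dense grid, no consolidation): a low-variance
#'   estimator for clinical-SNR map work, at the cost of spectral
#'   flexibility. See [fit_config_clinical()].
#' @param seed integer recorded for provenance; the fit itself is
#'   deterministic.
#' @return Object of class `fit_config`.
#' @export
fit_config <- function(grid_a = 0, grid_b = 3, grid_step = 0.1,
                       n_orientations = 60L, max_aniso = 2L,
                       prior_lambda = list(c(1.5, 0.25), c(1.8, 0.4)),
                       lambda_par_bounds = c(0.5, 2.5),
                       lambda_perp_bounds = c(0, 1.0),
                       ridge_rel = 0, stage1_threshold = 0.05,
                       coarse_step = 0.3, refine = TRUE,
                       merge_gap = 0.35, min_fraction = 0.03,
                       iso_anchors = NULL, seed = 1L) {
  if (is.numeric(prior_lambda)) prior_lambda <- list(prior_lambda)
  stopifnot(grid_a >= 0, grid_b > grid_a, grid_step > 0, max_aniso >= 0,
            n_orientations >= 1, ridge_rel >= 0, stage1_threshold >= 0,
            coarse_step > 0, merge_gap >= 0, min_fraction >= 0)
  if (!is.null(iso_anchors)) {
    iso_anchors <- sort(as.numeric(iso_anchors))
    stopifnot(length(iso_anchors) >= 1, all(iso_anchors >= 0),
              !anyDuplicated(iso_anchors))
  }
  structure(list(grid_a = grid_a, grid_b = grid_b, grid_step = grid_step,
                 n_orientations = as.integer(n_orientations),
                 max_aniso = as.integer(max_aniso),
                 prior_lambda = prior_lambda,
                 lambda_par_bounds = lambda_par_bounds,
                 lambda_perp_bounds = lambda_perp_bounds,
                 ridge_rel = ridge_rel, stage1_threshold = stage1_threshold,
                 coarse_step = coarse_step, refine = isTRUE(refine),
                 merge_gap = merge_gap, min_fraction = min_fraction,
                 iso_anchors = iso_anchors,
                 seed = as.integer(seed)),
            class = "fit_config")
}

#' Low-variance fitting preset for clinical-SNR parameter maps
#'
#' A [fit_config()] that solves the isotropic spectrum only at one fixed
#' anchor diffusivity per band (restricted 0.3, hindered 1.25,
#' nonrestricted 2.7 um^2/ms) instead of the dense grid. With b <= 1.5
#' ms/um^2 the mixing fraction of adjacent-band compartments with free
#' diffusivities is barely identifiable per voxel at clinical SNR; fixing
#' one representative diffusivity per band trades that unresolvable
#' spectral freedom for a large variance reduction, which is what
#' lesion-classification maps need — relative contrasts (lesion versus
#' surrounding parenchyma) are preserved while per-voxel scatter drops
#' severalfold. It is also much faster than the full
#' compartment-selection fit. Per-voxel fiber diffusivity refinement
#' stays on (`refine = TRUE`); disable it for a further speed-up at some
#' cost in fiber/spectrum separation.
#'
#' @param ... overrides passed to [fit_config()].
#' @return a [fit_config()].
#' @export
fit_config_clinical <- function(...) {
  fit_config(iso_anchors = c(0.3, 1.25, 2.7), refine = TRUE, ...)
}

# anisotropic basis column for every table entry, given orientation + lambdas
.aniso_column <- function(bb, bvecs, orientation, lpar, lperp) {
  cphi2 <- as.numeric(crossprod(orientation, bvecs))^2
  exp(-bb * (lperp + (lpar - lperp) * cphi2))
}

# per-(table, config) design structures, cached: the stage-1 dictionary and
# the spectrum bases are identical for every voxel of a map
.dbsir_cache <- new.env(parent = emptyenv())

.fit_context <- function(table, config) {
  bb <- .b_to_ms_um2(table$bvals)
  key <- paste(c(signif(table$bvals, 10), signif(table$bvecs, 10),
                 config$n_orientations, unlist(config$prior_lambda),
                 config$grid_a, config$grid_b, config$grid_step,
                 config$coarse_step, config$iso_anchors), collapse = ",")
  hit <- .dbsir_cache[[key]]
  if (!is.null(hit)) return(hit)
  dirs <- hemisphere_directions(config$n_orientations)
  n <- length(bb)
  A1 <- cbind(
    do.call(cbind, lapply(seq_len(ncol(dirs)), function(j) {
      vapply(config$prior_lambda, function(l) {
        .aniso_column(bb, table$bvecs, dirs[, j], l[1], l[2])
      }, numeric(n))
    })),
    exp(-outer(bb, seq(config$grid_a, config$grid_b,
                       by = config$coarse_step)))
  )
  full_D <- if (is.null(config$iso_anchors)) {
    seq(config$grid_a, config$grid_b, by = config$grid_step)
  } else config$iso_anchors
  ctx <- list(bb = bb, dirs = dirs, A1 = A1, full_D = full_D,
              iso_basis = exp(-outer(bb, full_D)))
  if (length(ls(.dbsir_cache)) > 8) {
    rm(list = ls(.dbsir_cache), envir = .dbsir_cache)
  }
  assign(key, ctx, envir = .dbsir_cache)
  ctx
}

#' Band-wise signal fractions from a fitted spectrum
#'
#' Collapses the isotropic spectrum into the three diagnostic bands —
#' restricted (0 <= D <= 1.0 um^2/ms, cellularity), hindered
#' (1.0 < D <= 1.5, edema/necrosis) and nonrestricted (D > 1.5, free
#' water) — and renormalizes together with the anisotropic (fiber) weight
#' so the four fractions sum to 1. Band edges are inclusive on the right:
#' D = 1.0 is restricted, D = 1.5 is hindered.
#'
#' @param iso an [iso_spectrum()] of fitted weights.
#' @param fiber_weight summed anisotropic weight (>= 0).
#' @return named numeric vector (fiber, restricted, hindered,
#'   nonrestricted) summing to 1.
#' @export
compute_fractions <- function(iso, fiber_weight = 0) {
  stopifnot(inherits(iso, "iso_spectrum"), fiber_weight >= 0)
  total <- fiber_weight + sum(iso$weights)
  if (total <= 0) stop("total weight is zero; degenerate voxel")
  restricted <- sum(iso$weights[iso$grid <= 1.0])
  hindered <- sum(iso$weights[iso$grid > 1.0 & iso$grid <= 1.5])
  nonrestricted <- sum(iso$weights[iso$grid > 1.5])
  c(fiber = fiber_weight, restricted = restricted, hindered = hindered,
    nonrestricted = nonrestricted) / total
}

# consolidate a dense spectrum into peak positions: cluster non-zero grid
# weights with single linkage, cutting where the gap exceeds merge_gap;
# returns weight-averaged diffusivity per cluster, heaviest first
.spectrum_peaks <- function(grid, weights, merge_gap) {
  nz <- which(weights > 1e-10)
  if (!length(nz)) return(numeric(0))
  grp <- cumsum(c(1, diff(grid[nz]) > merge_gap))
  D <- as.numeric(tapply(grid[nz] * weights[nz], grp, sum) /
                    tapply(weights[nz], grp, sum))
  w <- as.numeric(tapply(weights[nz], grp, sum))
  D[order(w, decreasing = TRUE)]
}

#' Fit the DBSI model in a single voxel
#'
#' Spectral deconvolution of a normalized signal vector, in three stages.
#'
#' Stage 1 (orientation screening): anisotropic basis functions on a fixed
#' candidate orientation set (at the nominal diffusivity priors) plus a
#' coarse isotropic basis are fit by NNLS; orientations carrying more than
#' `stage1_threshold` of the total weight — de-duplicated when nearly
#' collinear, up to `max_aniso` — are retained.
#'
#' Stage 2 (spectrum solve): each retained component's axial/radial
#' diffusivity is refined by bounded search, then ridge-regularized NNLS is
#' solved over the anisotropic columns plus exp(-b D_j) on the full
#' spectrum grid.
#'
#' Stage 3 (compartment consolidation, skipped when `refine = FALSE`): the
#' dense spectrum is ill-posed — solutions differing by large band
#' re-attributions fit the data almost equally well — so its peaks are
#' consolidated into discrete isotropic compartments, the compartment
#' diffusivities refined by bounded nonlinear search, and the number of
#' compartments chosen by BIC. Anisotropic components whose final weight
#' falls below `min_fraction` are pruned. This collapses the effective
#' degrees of freedom to the few physical compartments actually present
#' and is what makes band fractions stable under measurement noise.
#'
#' @param signals numeric vector of S_k/S_0 (b = 0 entries ~ 1).
#' @param table matching [gradient_table()].
#' @param config a [fit_config()].
#' @return Object of class `dbsi_voxel`: `fiber_fraction`,
#'   `restricted_fraction`, `hindered_fraction`, `nonrestricted_fraction`
#'   (summing to 1), the fitted [aniso_component()] list, the fitted
#'   [iso_spectrum()] (compartment form), and `residual_rms`.
#' @export
fit_voxel <- function(signals, table, config = fit_config()) {
  stopifnot(inherits(table, "gradient_table"), inherits(config, "fit_config"))
  signals <- as.numeric(signals)
  if (length(signals) != length(table)) {
    stop("signal length does not match gradient table")
  }
  if (all(signals <= 0)) stop("all-zero signals; degenerate voxel")
  n_floor <- sum(signals < .Machine$double.eps)
  signals <- pmax(signals, .Machine$double.eps)
  b0 <- table$bvals == 0
  y <- signals / mean(signals[b0])
  ctx <- .fit_context(table, config)
  bb <- ctx$bb
  n <- length(y)

  # ---- stage 1: orientation screening --------------------------------
  dirs <- ctx$dirs
  w1 <- dbsi_nnls(ctx$A1, y)$x
  npri <- length(config$prior_lambda)
  aw <- vapply(seq_len(ncol(dirs)), function(j) {
    sum(w1[((j - 1) * npri + 1):(j * npri)])
  }, 0)
  keep <- which(aw > config$stage1_threshold * sum(w1))
  keep <- keep[order(aw[keep], decreasing = TRUE)]
  sel <- integer(0)
  for (j in keep) {
    if (length(sel) &&
        any(abs(crossprod(dirs[, j], dirs[, sel, drop = FALSE])) > 0.95)) next
    sel <- c(sel, j)
    if (length(sel) >= config$max_aniso) break
  }

  # ---- stage 2: lambda refinement + spectrum solve -------------------
  full_D <- ctx$full_D
  iso_basis <- ctx$iso_basis
  lambdas <- rep(list(c(mean(config$lambda_par_bounds),
                        config$prior_lambda[[1]][2])), length(sel))
  aniso_cols <- function(lams) {
    if (!length(sel)) return(NULL)
    vapply(seq_along(sel), function(i) {
      .aniso_column(bb, table$bvecs, dirs[, sel[i]],
                    lams[[i]][1], min(lams[[i]][2], lams[[i]][1]))
    }, numeric(n))
  }
  ridge_of <- function(A) {
    if (config$ridge_rel <= 0) return(0)
    config$ridge_rel * max(svd(A, nu = 0, nv = 0)$d)^2
  }
  dense_rnorm <- function(lams) {
    A <- cbind(aniso_cols(lams), iso_basis)
    dbsi_nnls(A, y, ridge = ridge_of(A))$rnorm
  }
  if (length(sel) && config$refine) {
    for (i in seq_along(sel)) {
      opt <- optim(lambdas[[i]],
                   function(par) dense_rnorm(`[[<-`(lambdas, i, par)),
                   method = "L-BFGS-B",
                   lower = c(config$lambda_par_bounds[1],
                             config$lambda_perp_bounds[1]),
                   upper = c(config$lambda_par_bounds[2],
                             config$lambda_perp_bounds[2]),
                   control = list(maxit = 20, factr = 1e10))
      lambdas[[i]] <- opt$par
    }
  }
  A2 <- cbind(aniso_cols(lambdas), iso_basis)
  dense <- dbsi_nnls(A2, y, ridge = ridge_of(A2))
  n_a <- length(sel)
  dense_iso_w <- dense$x[(n_a + 1):length(dense$x)]

  finish <- function(aniso_list, iso, w_total, A, w_raw) {
    fr <- compute_fractions(iso, sum(vapply(aniso_list, `[[`, 0, "fraction")))
    structure(list(fiber_fraction = unname(fr["fiber"]),
                   restricted_fraction = unname(fr["restricted"]),
                   hindered_fraction = unname(fr["hindered"]),
                   nonrestricted_fraction = unname(fr["nonrestricted"]),
                   aniso = aniso_list, iso = iso,
                   residual_rms = sqrt(mean((A %*% w_raw - y)^2)),
                   n_floored = n_floor),
              class = "dbsi_voxel")
  }

  if (!config$refine || !is.null(config$iso_anchors)) {
    w <- dense$x
    # prune insignificant anisotropic components, re-solve once
    if (n_a > 0) {
      drop_i <- which(w[seq_len(n_a)] / sum(w) < config$min_fraction)
      if (length(drop_i)) {
        sel <- sel[-drop_i]; lambdas <- lambdas[-drop_i]
        n_a <- length(sel)
        A2 <- cbind(aniso_cols(lambdas), iso_basis)
        dense <- dbsi_nnls(A2, y, ridge = ridge_of(A2))
        w <- dense$x
      }
    }
    total <- sum(w)
    if (total <= 0) stop("fit collapsed to zero weight; degenerate voxel")
    aniso <- lapply(seq_len(n_a), function(i) {
      aniso_component(w[i] / total, lambdas[[i]][1],
                      max(0, min(lambdas[[i]][2], lambdas[[i]][1])),
                      dirs[, sel[i]])
    })
    return(finish(aniso, iso_spectrum(full_D, w[(n_a + 1):length(w)] / total),
                  total, A2, w))
  }

  # ---- stage 3: compartment consolidation + BIC model selection ------
  peaks <- .spectrum_peaks(full_D, dense_iso_w, config$merge_gap)
  if (!length(peaks) && n_a == 0) {
    stop("fit collapsed to zero weight; degenerate voxel")
  }
  sparse_design <- function(Ds, lams, sel_idx) {
    ac <- if (length(sel_idx)) {
      vapply(seq_along(sel_idx), function(i) {
        .aniso_column(bb, table$bvecs, dirs[, sel_idx[i]],
                      lams[[i]][1], max(0, min(lams[[i]][2], lams[[i]][1])))
      }, numeric(n))
    } else NULL
    cbind(ac, exp(-outer(bb, Ds)))
  }
  # jointly refine fiber parameters (diffusivities AND orientation, as
  # spherical angles) together with the compartment diffusivities: a
  # slightly misfit fiber column lets the (non-unique) spectrum compensate
  # with spurious compartments, and the candidate-orientation grid alone
  # leaves a residual floor that would swamp the model comparison
  ang_of <- function(v) c(acos(min(max(v[3], -1), 1)), atan2(v[2], v[1]))
  dir_of <- function(th, ph) c(sin(th) * cos(ph), sin(th) * sin(ph),
                               cos(th))
  fit_model <- function(Ds, fibs, maxit = 20, factr = 1e9) {
    # fibs: list of c(lpar, lperp, theta, phi) per fiber
    if (!length(Ds) && !length(fibs)) return(NULL)
    na <- length(fibs)
    design_of <- function(Ds, fibs) {
      ac <- if (na) vapply(fibs, function(f) {
        .aniso_column(bb, table$bvecs, dir_of(f[3], f[4]),
                      f[1], max(0, min(f[2], f[1])))
      }, numeric(n)) else NULL
      cbind(ac, exp(-outer(bb, Ds)))
    }
    unpack <- function(par) {
      list(fibs = if (na) lapply(seq_len(na), function(i) {
        par[(4 * i - 3):(4 * i)]
      }) else list(),
      Ds = if (length(Ds)) par[(4 * na + 1):length(par)] else numeric(0))
    }
    par0 <- c(unlist(fibs), Ds)
    lower <- c(rep(c(config$lambda_par_bounds[1],
                     config$lambda_perp_bounds[1], 0, -2 * pi), na),
               rep(config$grid_a, length(Ds)))
    upper <- c(rep(c(config$lambda_par_bounds[2],
                     config$lambda_perp_bounds[2], pi, 2 * pi), na),
               rep(config$grid_b, length(Ds)))
    obj <- function(par) {
      u <- unpack(pmin(pmax(par, lower), upper))
      dbsi_nnls(design_of(u$Ds, u$fibs), y)$rnorm
    }
    opt <- if (length(par0) == 1) {
      optim(par0, obj, method = "Brent", lower = lower, upper = upper)
    } else {
      optim(par0, obj, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = maxit, factr = factr))
    }
    u <- unpack(pmin(pmax(opt$par, lower), upper))
    A <- design_of(u$Ds, u$fibs)
    s <- dbsi_nnls(A, y)
    rss <- max(s$rnorm^2, n * 1e-12)    # floor: noise-free exact fits
    k <- 2 * length(u$Ds) + 4 * na
    list(Ds = u$Ds, w = s$x, A = A, rss = rss, fibs = u$fibs,
         bic = n * log(rss / n) + k * log(n))
  }
  # candidate compartment inits per model order: the spectrum peaks plus
  # canonical tissue diffusivities (multi-start against local minima)
  canon <- c(0.3, 1.25, 2.7)
  inits_for <- function(m) {
    out <- list()
    if (length(peaks) >= m) out <- c(out, list(sort(peaks[seq_len(m)])))
    if (m <= length(canon)) {
      cmb <- utils::combn(canon, m)
      out <- c(out, lapply(seq_len(ncol(cmb)), function(j) cmb[, j]))
    }
    unique(out)
  }
  fibs0 <- lapply(seq_len(n_a), function(i) {
    c(lambdas[[i]], ang_of(dirs[, sel[i]]))
  })
  # scan inits coarsely per model class (compartment count x fiber
  # presence), then polish the best of each class before the BIC vote —
  # an under-converged true model must not lose to a converged small one
  m_max <- max(min(max(length(peaks), 2L), 4L), 1L)
  classes <- list()
  note <- function(mod) {
    if (is.null(mod)) return()
    key <- paste0(length(mod$Ds), "_", length(mod$fibs))
    if (is.null(classes[[key]]) || mod$rss < classes[[key]]$rss) {
      classes[[key]] <<- mod
    }
  }
  for (m in seq_len(m_max)) {
    for (ini in inits_for(m)) {
      note(fit_model(ini, fibs0, maxit = 12))
      if (n_a > 0) note(fit_model(ini, list(), maxit = 12))
    }
    # an exact fit cannot be improved by more compartments; BIC only grows
    if (length(classes) &&
        min(vapply(classes, `[[`, 0, "rss")) <= 2 * n * 1e-12) break
  }
  if (n_a > 0 && !length(classes)) note(fit_model(numeric(0), fibs0))
  cand <- lapply(classes, function(mod) {
    if (mod$rss <= 2 * n * 1e-12) return(mod)
    pol <- fit_model(mod$Ds, mod$fibs, maxit = 60, factr = 1e7)
    if (!is.null(pol) && pol$rss < mod$rss) pol else mod
  })
  best <- cand[[which.min(vapply(cand, `[[`, 0, "bic"))]]
  fib_fin <- best$fibs

  # prune insignificant anisotropic components and re-solve once
  if (length(fib_fin)) {
    wa <- best$w[seq_along(fib_fin)] / sum(best$w)
    drop_i <- which(wa < config$min_fraction)
    if (length(drop_i) == length(fib_fin) && !length(best$Ds)) {
      drop_i <- integer(0)   # keep a degenerate all-aniso voxel as is
    }
    if (length(drop_i)) {
      best <- fit_model(best$Ds, fib_fin[-drop_i])
      fib_fin <- best$fibs
    }
  }
  w <- best$w
  total <- sum(w)
  if (total <= 0) stop("fit collapsed to zero weight; degenerate voxel")
  n_af <- length(fib_fin)
  aniso <- lapply(seq_len(n_af), function(i) {
    f <- fib_fin[[i]]
    aniso_component(w[i] / total, f[1], max(0, min(f[2], f[1])),
                    dir_of(f[3], f[4]))
  })
  iso_w <- w[(n_af + 1):length(w)] / total
  if (length(best$Ds)) {
    o <- order(best$Ds)
    Ds <- best$Ds[o]; iso_w <- iso_w[o]
    # merge compartments the refinement drove together (ties broken low)
    dup <- c(FALSE, diff(Ds) < 1e-6)
    if (any(dup)) {
      grp <- cumsum(!dup)
      iso_w <- as.numeric(tapply(iso_w, grp, sum))
      Ds <- Ds[!dup]
    }
    iso <- iso_spectrum(Ds, iso_w)
  } else {
    iso <- iso_spectrum(config$grid_b, 0)
  }
  finish(aniso, iso, total, best$A, w)
}

#' @export
print.dbsi_voxel <- function(x, ...) {
  cat(sprintf(paste0("DBSI voxel: fiber %.3f | restricted %.3f | ",
                     "hindered %.3f | nonrestricted %.3f (rms %.2e)\n"),
              x$fiber_fraction, x$restricted_fraction, x$hindered_fraction,
              x$nonrestricted_fraction, x$residual_rms))
  invisible(x)
}

# edge-truncated 3D box mean over a (2r+1)^3 neighbourhood, per volume
.box_smooth <- function(data, r) {
  dm <- dim(data)
  out <- array(0, dm)
  cnt <- array(0, dm[1:3])
  acc <- array(0, dm)
  for (dx in -r:r) for (dy in -r:r) for (dz in -r:r) {
    xs <- pmin(pmax(seq_len(dm[1]) + dx, 1), dm[1])
    ys <- pmin(pmax(seq_len(dm[2]) + dy, 1), dm[2])
    zs <- pmin(pmax(seq_len(dm[3]) + dz, 1), dm[3])
    ok_x <- seq_len(dm[1]) + dx >= 1 & seq_len(dm[1]) + dx <= dm[1]
    ok_y <- seq_len(dm[2]) + dy >= 1 & seq_len(dm[2]) + dy <= dm[2]
    ok_z <- seq_len(dm[3]) + dz >= 1 & seq_len(dm[3]) + dz <= dm[3]
    w <- outer(outer(as.numeric(ok_x), as.numeric(ok_y)), as.numeric(ok_z))
    acc <- acc + data[xs, ys, zs, , drop = FALSE] *
      as.numeric(array(w, dm))
    cnt <- cnt + w
  }
  acc / as.numeric(array(cnt, dm))
}

#' Voxel-wise DBSI + DTI parameter maps
#'
#' Applies [fit_voxel()] and [dti_fit()] independently to every voxel
#' inside the mask. Voxels outside the mask are 0 in every map. Voxels are
#' statistically independent, so the result does not depend on evaluation
#' order.
#'
#' @param volume a [dwi_volume()] of raw (unnormalized) signal.
#' @param table matching [gradient_table()].
#' @param mask a [label_map()] or logical/integer 3D array; voxels with a
#'   positive value are fit.
#' @param config a [fit_config()].
#' @param smooth_radius if > 0, the signal is box-averaged over a
#'   (2r+1)^3 neighbourhood before fitting — standard clinical DWI
#'   preprocessing that raises per-voxel SNR and with it the stability of
#'   the band fractions, at the cost of spatial resolution.
#' @param dti also fit the conventional tensor (ADC/FA maps); disable to
#'   save time when only the DBSI fractions are needed.
#' @return Object of class `parameter_maps`: 3D arrays `fiber`,
#'   `restricted`, `hindered`, `nonrestricted`, `adc`, `fa`,
#'   `residual_rms`, plus the logical `mask` and the volume's affine.
#' @export
fit_map <- function(volume, table, mask, config = fit_config(),
                    smooth_radius = 0L, dti = TRUE) {
  stopifnot(inherits(volume, "dwi_volume"))
  shape <- dim(volume$data)[1:3]
  m <- if (inherits(mask, "label_map")) mask$labels > 0 else as.array(mask) > 0
  if (!all(dim(m) == shape)) stop("mask shape does not match volume")
  if (!any(m)) stop("empty mask: no voxels to fit")
  data <- if (smooth_radius > 0) {
    .box_smooth(volume$data, as.integer(smooth_radius))
  } else volume$data
  maps <- c("fiber", "restricted", "hindered", "nonrestricted", "adc", "fa",
            "residual_rms")
  out <- setNames(lapply(maps, function(.) array(0, shape)), maps)
  idx <- which(m, arr.ind = TRUE)
  for (v in seq_len(nrow(idx))) {
    i <- idx[v, 1]; j <- idx[v, 2]; k <- idx[v, 3]
    sig <- data[i, j, k, ]
    res <- fit_voxel(sig, table, config)
    out$fiber[i, j, k] <- res$fiber_fraction
    out$restricted[i, j, k] <- res$restricted_fraction
    out$hindered[i, j, k] <- res$hindered_fraction
    out$nonrestricted[i, j, k] <- res$nonrestricted_fraction
    if (dti) {
      dd <- dti_fit(sig, table)
      out$adc[i, j, k] <- dd$adc
      out$fa[i, j, k] <- dd$fa
    }
    out$residual_rms[i, j, k] <- res$residual_rms
  }
  structure(c(out, list(mask = m, affine = volume$affine,
                        voxel_size = volume$voxel_size)),
            class = "parameter_maps")
}

#' Write parameter maps as one NIfTI per metric
#'
#' Files are named `<prefix>_fiber.nii.gz`, `_restricted`, `_hindered`,
#' `_nonrestricted`, `_adc`, `_fa`.
#'
#' @param maps a `parameter_maps` object from [fit_map()].
#' @param prefix output path prefix.
#' @return invisibly, the written paths.
#' @export
write_parameter_maps <- function(maps, prefix) {
  stopifnot(inherits(maps, "parameter_maps"))
  metrics <- c("fiber", "restricted", "hindered", "nonrestricted",
               "adc", "fa")
  paths <- vapply(metrics, function(mt) {
    p <- paste0(prefix, "_", mt, ".nii.gz")
    img <- RNifti::asNifti(maps[[mt]])
    RNifti::pixdim(img) <- maps$voxel_size
    RNifti::writeNifti(img, p)
    p
  }, character(1))
  invisible(paths)
}
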