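#' Conventional diffusion tensor fit (ADC and FA)
#'
#' Log-linear least-squares fit of the single-tensor model
#' log(S_k/S_0) = -b_k g_k' D g_k to the six unique tensor elements.
#' ADC is the mean eigenvalue (um^2/ms); FA is
#' sqrt(3/2) * ||lambda - mean(lambda)|| / ||lambda||. Negative
#' eigenvalues (noise) are clamped at 0 with a warning.
#'
#' @param signals raw or normalized signal vector.
#' @param table matching [gradient_table()]; needs at least 6 non-collinear
#'   b > 0 directions plus b = 0.
#' @return list with `adc`, `fa`, `eigenvalues` (decreasing), and the 3x3
#'   `tensor`.
#' @export
dti_fit <- function(signals, table) {
  stopifnot(inherits(table, "gradient_table"))
  signals <- as.numeric(signals)
  if (length(signals) != length(table)) {
    stop("signal length does not match gradient table")
  }
  b0 <- table$bvals == 0
  dw <- !b0
  if (sum(dw) < 6) stop("under-determined: need >= 6 diffusion-weighted directions")
  s0 <- mean(pmax(signals[b0], .Machine$double.eps))
  y <- log(pmax(signals[dw], .Machine$double.eps) / s0)
  bb <- .b_to_ms_um2(table$bvals[dw])
  g <- table$bvecs[, dw, drop = FALSE]
  X <- -bb * cbind(g[1, ]^2, g[2, ]^2, g[3, ]^2,
                   2 * g[1, ] * g[2, ], 2 * g[1, ] * g[3, ],
                   2 * g[2, ] * g[3, ])
  if (qr(X)$rank < 6) stop("under-determined: directions are collinear")
  d <- qr.coef(qr(X), y)
  D <- matrix(c(d[1], d[4], d[5],
                d[4], d[2], d[6],
                d[5], d[6], d[3]), 3, 3)
  ev <- eigen(D, symmetric = TRUE, only.values = FALSE)$values
  if (any(ev < 0)) {
    warning("clamping ", sum(ev < 0), " negative eigenvalue(s) at 0")
    ev <- pmax(ev, 0)
  }
  adc <- mean(ev)
  fa <- if (sum(ev^2) > 0) {
    sqrt(3 / 2) * sqrt(sum((ev - adc)^2)) / sqrt(sum(ev^2))
  } else 0
  list(adc = adc, fa = fa, eigenvalues = ev, tensor = D)
}
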