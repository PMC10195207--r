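#' Welch's unequal-variances t-test
#'
#' Two-tailed comparison of two independent groups without assuming equal
#' variances (Satterthwaite degrees of freedom). Thin wrapper over
#' [stats::t.test()] returning the pieces the cohort report uses.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @return list with `t`, `df`, `p`, `mean_a`, `mean_b`, `sd_a`, `sd_b`.
#' @export
welch_t <- function(group_a, group_b) {
  group_a <- as.numeric(group_a); group_b <- as.numeric(group_b)
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least 2 observations")
  }
  if (sd(group_a) == 0 && sd(group_b) == 0) {
    # degenerate: no variance anywhere
    eq <- isTRUE(all.equal(mean(group_a), mean(group_b)))
    if (eq) {
      return(list(t = 0, df = length(group_a) + length(group_b) - 2, p = 1,
                  mean_a = mean(group_a), mean_b = mean(group_b),
                  sd_a = 0, sd_b = 0))
    }
    stop("both groups have zero variance with different means")
  }
  ht <- t.test(group_a, group_b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_a = mean(group_a), mean_b = mean(group_b),
       sd_a = sd(group_a), sd_b = sd(group_b))
}

#' Exact two-tailed Wilcoxon signed-rank test
#'
#' Matched-samples comparison. Zero differences are dropped (with their
#' count reported). For n <= `exact_limit` non-zero differences the null
#' distribution is built by full enumeration of all 2^n sign assignments
#' of the ranked absolute differences — valid with ties, where the
#' classical exact tables are not — and above it a normal approximation
#' with tie correction is used.
#'
#' @param before,after equal-length numeric vectors.
#' @param exact force (TRUE)/suppress (FALSE) enumeration; default
#'   enumerates up to `exact_limit`.
#' @param exact_limit largest n for enumeration (2^n statistics).
#' @return list with `W` (signed-rank statistic of positive differences),
#'   `p`, `n_used`, `n_zero`, `method`.
#' @export
wilcoxon_signed_rank <- function(before, after, exact = NULL,
                                 exact_limit = 12L) {
  before <- as.numeric(before); after <- as.numeric(after)
  if (length(before) != length(after) || length(before) < 2) {
    stop("before/after must be equal-length vectors of length >= 2")
  }
  d <- after - before
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all differences are zero; degenerate result")
    return(list(W = 0, p = 1, n_used = 0, n_zero = n_zero,
                method = "degenerate"))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (is.null(exact)) exact <- n <= exact_limit
  if (exact && n > 25) stop("exact enumeration infeasible for n > 25")
  if (exact) {
    # all 2^n sign assignments; two-tailed p by tail symmetry around mean
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Wnull <- as.numeric(signs %*% r)
    mu <- n * (n + 1) / 4
    p <- mean(abs(Wnull - mu) >= abs(W - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    mu <- n * (n + 1) / 4
    tie_sizes <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_sizes^3 - tie_sizes) / 48
    z <- (W - mu) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(W = W, p = min(p, 1), n_used = n, n_zero = n_zero, method = method)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value summing hypergeometric probabilities of tables (with
#' the observed margins) no more likely than the observed one, via
#' [stats::fisher.test()].
#'
#' @param table 2x2 matrix of non-negative counts.
#' @return two-sided p-value.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("need a 2x2 table")
  if (any(table < 0) || any(table != round(table))) {
    stop("cells must be non-negative integers")
  }
  if (sum(table) == 0) stop("table has no observations")
  fisher.test(table)$p.value
}

#' Bonferroni-adjusted significance level
#'
#' @param alpha family-wise level (0 < alpha <= 1).
#' @param m number of comparisons (>= 1).
#' @return alpha / m.
#' @export
bonferroni_alpha <- function(alpha = 0.05, m = 9L) {
  if (!.is_scalar_number(alpha) || alpha <= 0 || alpha > 1) {
    stop("alpha must be in (0, 1]")
  }
  if (!.is_scalar_number(m) || m < 1 || m != round(m)) {
    stop("m must be a positive integer")
  }
  alpha / m
}

#' Metric-wise group comparison with Bonferroni correction
#'
#' Runs [welch_t()] on every metric column between the two diagnosis
#' groups and flags significance at the Bonferroni-adjusted level
#' alpha / (number of metrics).
#'
#' @param metrics data.frame with a `Diagnosis` column
#'   ("treatment_effect" / "progression") and one numeric column per
#'   metric (any other non-numeric columns are ignored).
#' @param alpha family-wise significance level.
#' @return Object of class `group_comparison`: data.frame with one row per
#'   metric (means, sds, t, df, p, significant) plus attributes
#'   `adjusted_alpha` and `m`.
#' @export
compare_groups <- function(metrics, alpha = 0.05) {
  stopifnot(is.data.frame(metrics), "Diagnosis" %in% names(metrics))
  a <- metrics$Diagnosis == "treatment_effect"
  b <- metrics$Diagnosis == "progression"
  if (sum(a) < 2 || sum(b) < 2) {
    stop("each diagnosis group needs at least 2 patients")
  }
  num <- vapply(metrics, is.numeric, TRUE) &
    !(names(metrics) %in% c("Subject", "Diagnosis"))
  cols <- names(metrics)[num]
  if (!length(cols)) stop("no numeric metric columns found")
  m <- length(cols)
  thr <- bonferroni_alpha(alpha, m)
  rows <- lapply(cols, function(cl) {
    w <- welch_t(metrics[[cl]][a], metrics[[cl]][b])
    data.frame(metric = cl,
               mean_treatment_effect = w$mean_a, sd_treatment_effect = w$sd_a,
               mean_progression = w$mean_b, sd_progression = w$sd_b,
               t = w$t, df = w$df, p = w$p, significant = w$p < thr)
  })
  out <- do.call(rbind, rows)
  attr(out, "adjusted_alpha") <- thr
  attr(out, "m") <- m
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Group comparison (%d metrics, Bonferroni alpha %.4f):\n",
              attr(x, "m"), attr(x, "adjusted_alpha")))
  y <- as.data.frame(x)
  y$p <- sprintf("%.4f", y$p)
  print(y, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Time-to-diagnosis summary: assisted versus standard-of-care
#'
#' Per-patient difference = weeks to standard-of-care diagnosis minus
#' weeks to DBSI-assisted diagnosis; positive means the assisted reading
#' was earlier. A `Difference_weeks` column, when present, is used
#' verbatim (published tables compute it from unrounded dates, so it can
#' differ in the last digit from subtracting rounded times); otherwise
#' the difference is computed from the two time columns.
#' Stable/excluded records are dropped. Medians and interquartile ranges
#' use linear interpolation of order statistics at position
#' 1 + (n - 1) p ([stats::quantile()] type 7).
#'
#' @param records data.frame in the [table1_fixture()] layout.
#' @return Object of class `time_to_diagnosis`: list with `n_analyzed`,
#'   `n_earlier`, `fraction_earlier`, `overall` (median, q1, q3) and
#'   per-group summaries under `by_group`.
#' @export
time_to_diagnosis <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("Diagnosis", "SurgeryToDBSI_weeks",
                  "SurgeryToSOC_weeks") %in% names(records)))
  keep <- records$Diagnosis %in% c("treatment_effect", "progression") |
    records$Diagnosis %in% c("Treatment effect", "Progression")
  r <- records[keep, ]
  if (!nrow(r)) stop("no analyzed (treatment effect / progression) records")
  if (any(is.na(r$SurgeryToDBSI_weeks)) || any(is.na(r$SurgeryToSOC_weeks))) {
    stop("analyzed records must have both diagnosis times")
  }
  if (any(r$SurgeryToDBSI_weeks < 0) || any(r$SurgeryToSOC_weeks < 0)) {
    stop("times must be non-negative")
  }
  d <- if ("Difference_weeks" %in% names(r) &&
           !any(is.na(r$Difference_weeks))) {
    r$Difference_weeks
  } else {
    r$SurgeryToSOC_weeks - r$SurgeryToDBSI_weeks
  }
  smry <- function(x) {
    q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    list(n = length(x), median = q[2], q1 = q[1], q3 = q[3])
  }
  grp <- tolower(gsub(" ", "_", r$Diagnosis))
  by_group <- lapply(split(d, grp), smry)
  structure(list(n_analyzed = nrow(r), n_earlier = sum(d > 0),
                 fraction_earlier = mean(d > 0), differences = d,
                 overall = smry(d), by_group = by_group),
            class = "time_to_diagnosis")
}

#' @export
print.time_to_diagnosis <- function(x, ...) {
  cat(sprintf(paste0("Time to diagnosis, assisted vs standard of care ",
                     "(n = %d analyzed):\n"), x$n_analyzed))
  cat(sprintf("  earlier with assistance: %d (%.1f%%)\n", x$n_earlier,
              100 * x$fraction_earlier))
  cat(sprintf("  overall: median %.1f weeks (IQR %.1f-%.1f)\n",
              x$overall$median, x$overall$q1, x$overall$q3))
  for (g in names(x$by_group)) {
    s <- x$by_group[[g]]
    cat(sprintf("  %s: n = %d, median %.1f (IQR %.1f-%.1f)\n", g, s$n,
                s$median, s$q1, s$q3))
  }
  invisible(x)
}
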