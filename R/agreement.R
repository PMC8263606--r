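#' Intraclass correlation from a two-way layout
#'
#' Computes an ICC from the two-way mean squares of a complete-case
#' `targets x raters` matrix (rows: subjects or walks; columns: measurement
#' systems or repeated trials). Three forms are supported:
#' * `"2,k"` — two-way random effects, absolute agreement, average of k
#'   measurements: `(MSR - MSE) / (MSR + (MSC - MSE) / n)`. The
#'   between-systems validity index.
#' * `"2,1"` — same model, single measurement:
#'   `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#' * `"3,1"` — two-way mixed effects, consistency, single measurement:
#'   `(MSR - MSE) / (MSR + (k-1) MSE)`. The test-retest repeatability index.
#'
#' Rows containing missing values are dropped (complete-case). A matrix with
#' (essentially) zero total variance is perfectly degenerate agreement: the
#' value is defined as 1 and flagged.
#'
#' @param m Numeric matrix, targets in rows, raters/repeats in columns.
#' @param form `"2,k"`, `"2,1"` or `"3,1"`.
#' @return An object of class `icc_result`: `form`, `value`, `MSR`, `MSC`,
#'   `MSE`, `n`, `k`, `degenerate`.
#' @examples
#' m <- cbind(a = c(1, 3, 5, 7), b = c(2, 4, 6, 8))
#' icc(m, "2,k")$value
#' @export
icc <- function(m, form = c("2,k", "2,1", "3,1")) {
  form <- match.arg(form)
  m <- as.matrix(m)
  if (any(is.infinite(m))) stop("matrix must not contain infinite values")
  keep <- stats::complete.cases(m)
  m <- m[keep, , drop = FALSE]
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L)
    stop("need at least 2 complete targets and 2 raters (have ", n, " x ", k, ")")
  grand <- mean(m)
  ri <- rowMeans(m); cj <- colMeans(m)
  MSR <- k * sum((ri - grand)^2) / (n - 1)
  MSC <- n * sum((cj - grand)^2) / (k - 1)
  resid <- m - outer(ri, rep(1, k)) - outer(rep(1, n), cj) + grand
  MSE <- sum(resid^2) / ((n - 1) * (k - 1))
  tot <- sum((m - grand)^2)
  degenerate <- tot <= 1e-12 * max(1, grand^2)
  value <- if (degenerate) 1 else switch(form,
    "2,k" = (MSR - MSE) / (MSR + (MSC - MSE) / n),
    "2,1" = (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n),
    "3,1" = (MSR - MSE) / (MSR + (k - 1) * MSE))
  structure(list(form = form, value = value, MSR = MSR, MSC = MSC, MSE = MSE,
                 n = n, k = k, degenerate = degenerate),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(%s) = %.4f  [%s]  (n = %d, k = %d%s)\n", x$form, x$value,
              classify_icc(x$value), x$n, x$k,
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Qualitative classification of an ICC value
#'
#' Standard agreement bins: 0.0-0.5 poor, 0.5-0.75 moderate,
#' 0.75-0.90 good, 0.90-1.0 excellent (half-open on the left edge, so 0.75
#' is "good" and 0.90 is "excellent"). Negative values indicate worse than
#' chance agreement and are classified "poor" with a flag attribute.
#'
#' @param value ICC value, must be <= 1.
#' @return Character label; for negative input the `"flag"` attribute is
#'   `"negative"`.
#' @examples
#' classify_icc(0.982)  # "excellent"
#' @export
classify_icc <- function(value) {
  if (!is.numeric(value) || length(value) != 1L || is.na(value))
    stop("value must be a single number")
  if (value > 1) stop("ICC cannot exceed 1")
  if (value < 0) return(structure("poor", flag = "negative"))
  if (value < 0.5) "poor"
  else if (value < 0.75) "moderate"
  else if (value < 0.90) "good"
  else "excellent"
}

#' Mean difference between paired systems with a bootstrap CI
#'
#' Mean of the paired differences `a - b` with a seeded percentile-bootstrap
#' 95% confidence interval (the distribution of per-walk differences is
#' typically skewed, so no normality is assumed), and the same quantities as
#' a percentage of the reference system's mean.
#'
#' @param a,b Aligned per-trial measurement vectors (system A, reference
#'   system B), length >= 3.
#' @param n_boot Number of bootstrap resamples (>= 1000).
#' @param seed Integer seed (mandatory: results are reproducible).
#' @param percent Also report percent-of-reference-mean forms.
#' @return An object of class `diff_result`: `mean_diff`, `ci95` (lo, hi),
#'   `percent_of_mean`, `percent_ci95`, `n`, `n_boot`, `seed`.
#' @export
mean_diff_ci <- function(a, b, n_boot = 10000L, seed, percent = TRUE) {
  stopifnot(length(a) == length(b), length(a) >= 3L, n_boot >= 1000L)
  if (missing(seed)) stop("an explicit seed is required")
  d <- a - b
  ok <- is.finite(d)
  d <- d[ok]
  if (length(d) < 3L) stop("need at least 3 complete pairs")
  md <- mean(d)
  bm <- with_seed(seed, {
    idx <- matrix(sample.int(length(d), length(d) * n_boot, replace = TRUE),
                  nrow = n_boot)
    rowMeans(matrix(d[idx], nrow = n_boot))
  })
  ci <- unname(stats::quantile(bm, c(0.025, 0.975)))
  refm <- mean(b[ok])
  pct <- pctci <- NULL
  if (percent) {
    if (abs(refm) < 1e-12)
      stop("reference mean is zero; percent-of-mean is undefined")
    pct <- 100 * md / refm
    pctci <- 100 * ci / refm
  }
  structure(list(mean_diff = md, ci95 = ci, percent_of_mean = pct,
                 percent_ci95 = pctci, n = length(d),
                 n_boot = as.integer(n_boot), seed = as.integer(seed)),
            class = "diff_result")
}

#' @export
print.diff_result <- function(x, ...) {
  cat(sprintf("Diff %.4g [%.4g; %.4g]", x$mean_diff, x$ci95[1], x$ci95[2]))
  if (!is.null(x$percent_of_mean))
    cat(sprintf("  = %.2f%% [%.2f; %.2f] of reference mean",
                x$percent_of_mean, x$percent_ci95[1], x$percent_ci95[2]))
  cat(sprintf("  (n = %d, %d resamples)\n", x$n, x$n_boot))
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' Paired differences and means, the mean difference, its sample SD, and
#' the 95% limits of agreement `mean_diff +/- 1.96 sd_diff`, optionally also
#' expressed as percentages of a reference mean.
#'
#' @param a,b Aligned per-trial measurement vectors, length >= 3.
#' @param reference_mean Scale for the percent forms; default `mean(b)`.
#' @param percent Report percent forms (error if `reference_mean` is 0).
#' @return An object of class `ba_result`: `mean_diff`, `sd_diff`, `loa`
#'   (lower, upper), `percent` (list with `mean_diff`, `loa`), `diffs`,
#'   `means`, `n`.
#' @export
bland_altman <- function(a, b, reference_mean = NULL, percent = TRUE) {
  stopifnot(length(a) == length(b), length(a) >= 3L)
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3L) stop("need at least 3 complete pairs")
  if (is.null(reference_mean)) reference_mean <- mean(b)
  d <- a - b
  m <- (a + b) / 2
  md <- mean(d)
  sdd <- stats::sd(d)
  loa <- c(lower = md - 1.96 * sdd, upper = md + 1.96 * sdd)
  pct <- NULL
  if (percent) {
    if (abs(reference_mean) < 1e-12)
      stop("reference mean is zero; percent forms are undefined")
    pct <- list(mean_diff = 100 * md / reference_mean,
                loa = 100 * loa / reference_mean)
  }
  structure(list(mean_diff = md, sd_diff = sdd, loa = loa, percent = pct,
                 diffs = d, means = m, n = length(d)),
            class = "ba_result")
}

#' @export
print.ba_result <- function(x, ...) {
  cat(sprintf("Bland-Altman: mean diff %.4g, SD %.4g, LoA [%.4g; %.4g] (n = %d)\n",
              x$mean_diff, x$sd_diff, x$loa[1], x$loa[2], x$n))
  if (!is.null(x$percent))
    cat(sprintf("  as %% of reference mean: %.2f%%, LoA [%.2f%%; %.2f%%]\n",
                x$percent$mean_diff, x$percent$loa[1], x$percent$loa[2]))
  invisible(x)
}

#' Full method-agreement report for two measurement systems
#'
#' Builds the standard concurrent-validity table comparing a candidate
#' system (A) against a reference system (B) over a `subjects x conditions x
#' trials` study, one row per gait parameter: mean (SD) per system, ICC(2,k)
#' between systems over all complete walks, ICC(3,1) inter-trial
#' repeatability within each system (targets = subject-condition cells,
#' repeats = trials), the mean difference with a seeded percentile-bootstrap
#' 95% CI as a percentage of the reference mean, and the Bland-Altman block.
#'
#' @param system_a,system_b Long data.frames with columns `subject`,
#'   `condition`, `trial`, `parameter`, `value` (per-walk parameter values);
#'   rows are matched on the first four columns. Incomplete cells are
#'   dropped statistic-wise (complete-case); dropped walks are recorded in
#'   the `"footnote"` attribute.
#' @param n_boot,seed Bootstrap control for the difference CIs.
#' @param icc31_by_condition If `TRUE`, report ICC(3,1) per condition
#'   instead of pooling subject-condition cells.
#' @return A data.frame of class `agreement_report`, one row per parameter.
#' @export
validity_report <- function(system_a, system_b, n_boot = 10000L, seed = 1L,
                            icc31_by_condition = FALSE) {
  need <- c("subject", "condition", "trial", "parameter", "value")
  stopifnot(all(need %in% names(system_a)), all(need %in% names(system_b)))
  merged <- merge(system_a, system_b, by = c("subject", "condition", "trial",
                                             "parameter"),
                  suffixes = c("_a", "_b"), all = TRUE)
  dropped <- merged[!is.finite(merged$value_a) | !is.finite(merged$value_b), ,
                    drop = FALSE]
  params <- unique(merged$parameter)
  rows <- lapply(params, function(p) {
    d <- merged[merged$parameter == p & is.finite(merged$value_a) &
                  is.finite(merged$value_b), , drop = FALSE]
    if (nrow(d) < 3L) stop("fewer than 3 complete walks for parameter ", p)
    i2 <- icc(cbind(d$value_a, d$value_b), "2,k")
    icc31_one <- function(values, d) {
      cell <- paste(d$subject, d$condition, sep = "\r")
      mtx <- tapply(values, list(cell, d$trial), mean)
      icc(mtx, "3,1")$value
    }
    if (icc31_by_condition) {
      i31a <- mean(vapply(unique(d$condition), function(cc)
        icc31_one(d$value_a[d$condition == cc], d[d$condition == cc, ]),
        numeric(1)))
      i31b <- mean(vapply(unique(d$condition), function(cc)
        icc31_one(d$value_b[d$condition == cc], d[d$condition == cc, ]),
        numeric(1)))
    } else {
      i31a <- icc31_one(d$value_a, d)
      i31b <- icc31_one(d$value_b, d)
    }
    dc <- mean_diff_ci(d$value_a, d$value_b, n_boot = n_boot,
                       seed = seed + match(p, params))
    ba <- bland_altman(d$value_a, d$value_b)
    data.frame(
      parameter = p, n_walks = nrow(d),
      mean_a = mean(d$value_a), sd_a = stats::sd(d$value_a),
      mean_b = mean(d$value_b), sd_b = stats::sd(d$value_b),
      icc2k = i2$value, icc2k_class = classify_icc(i2$value),
      icc31_a = i31a, icc31_b = i31b,
      diff = dc$mean_diff, diff_lo = dc$ci95[1], diff_hi = dc$ci95[2],
      diff_pct = dc$percent_of_mean,
      diff_pct_lo = dc$percent_ci95[1], diff_pct_hi = dc$percent_ci95[2],
      ba_loa_lo = ba$loa[["lower"]], ba_loa_hi = ba$loa[["upper"]],
      ba_loa_lo_pct = ba$percent$loa[["lower"]],
      ba_loa_hi_pct = ba$percent$loa[["upper"]],
      stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  attr(out, "footnote") <- if (nrow(dropped) > 0L)
    sprintf("%d walk-parameter cells dropped as incomplete", nrow(dropped))
  else "no missing cells"
  class(out) <- c("agreement_report", "data.frame")
  out
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("Method agreement report (system A vs reference B)\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf(
      paste0("  %-18s A %.3f (%.3f) | B %.3f (%.3f) | ICC(2,k) %.3f %s | ",
             "ICC(3,1) A %.3f B %.3f | Diff %.2f%% [%.2f; %.2f] | ",
             "LoA%% [%.1f; %.1f]\n"),
      x$parameter[i], x$mean_a[i], x$sd_a[i], x$mean_b[i], x$sd_b[i],
      x$icc2k[i], x$icc2k_class[i], x$icc31_a[i], x$icc31_b[i],
      x$diff_pct[i], x$diff_pct_lo[i], x$diff_pct_hi[i],
      x$ba_loa_lo_pct[i], x$ba_loa_hi_pct[i]))
  }
  cat(" ", attr(x, "footnote"), "\n")
  invisible(x)
}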