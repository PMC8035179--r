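#' Dice similarity coefficient
#'
#' `DSC = 2|P & T| / (|P| + |T|)`. When both masks are empty the overlap is
#' undefined and `NA` is returned (rather than 1), so resected glands do not
#' inflate averages.
#'
#' @param p,t logical arrays/vectors of identical shape.
#' @return DSC in `[0, 1]`, or `NA` when both masks are empty.
#' @export
dice <- function(p, t) {
  if (!identical(dim(p), dim(t)) || length(p) != length(t))
    stop("masks must have identical shape")
  p <- as.logical(p); t <- as.logical(t)
  s <- sum(p) + sum(t)
  if (s == 0) return(NA_real_)
  2 * sum(p & t) / s
}

#' Mean absolute percentage error
#'
#' Per-pair `100 |test - ref| / ref` with the reference (manual) measurement
#' as denominator.
#'
#' @param reference,test equal-length numeric vectors; `reference > 0`.
#' @return Named vector `c(mean, sd)`; the per-pair values are attached as
#'   attribute `"values"`.
#' @export
mape <- function(reference, test) {
  if (length(reference) != length(test)) stop("length mismatch")
  if (any(reference <= 0)) stop("reference values must be positive")
  v <- 100 * abs(test - reference) / reference
  structure(c(mean = mean(v), sd = sd(v)), values = v)
}

#' Two-way intraclass correlation coefficient
#'
#' ICC of a two-way random-effects model, single measure, absolute agreement
#' (ICC(A,1)): `(MSR - MSE) / (MSR + (k-1) MSE + k/n (MSC - MSE))`, with an
#' F-distribution-based 95% confidence interval (McGraw & Wong). Absolute
#' agreement penalises a systematic rater offset, so a constant bias yields
#' ICC < 1 even with perfect correlation.
#'
#' @param ratings numeric matrix, n subjects x k raters, complete.
#' @param conf_level confidence level for the interval.
#' @return Object of class `sq_icc`: `icc`, `ci`, `model`, `n`, `k` and the
#'   mean squares `ms = c(MSR, MSC, MSE)`.
#' @export
icc_two_way <- function(ratings, conf_level = 0.95) {
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) stop("ratings table must be complete")
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 raters")
  grand <- mean(ratings)
  rm <- rowMeans(ratings); cm <- colMeans(ratings)
  SSR <- k * sum((rm - grand)^2)
  SSC <- n * sum((cm - grand)^2)
  SST <- sum((ratings - grand)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  if (SST < .Machine$double.eps * n * k)
    stop("degenerate input: ratings have zero variance")
  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
  # F-based CI for ICC(A,1), McGraw & Wong (1996)
  alpha <- 1 - conf_level
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * MSC + b * MSE)^2 /
    ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
  Fl <- qf(1 - alpha / 2, n - 1, v)
  Fu <- qf(1 - alpha / 2, v, n - 1)
  lower <- n * (MSR - Fl * MSE) /
    (Fl * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  upper <- n * (Fu * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * Fu * MSR)
  structure(list(icc = icc, ci = c(lower = lower, upper = upper),
                 model = "two-way random, single measure, absolute agreement",
                 n = n, k = k, ms = c(MSR = MSR, MSC = MSC, MSE = MSE),
                 conf_level = conf_level),
            class = "sq_icc")
}

#' @export
print.sq_icc <- function(x, ...) {
  cat(sprintf("ICC = %.4f (%g%% CI %.4f-%.4f)\n  %s; n = %d subjects, k = %d raters\n",
              x$icc, 100 * x$conf_level, x$ci[1], x$ci[2], x$model, x$n, x$k))
  invisible(x)
}

#' Bland-Altman analysis
#'
#' Differences `d = a - b`; bias = mean(d); 95% limits of agreement =
#' bias +/- 1.96 x sample SD of d.
#'
#' @param a,b equal-length numeric vectors (length >= 2).
#' @return List with `bias`, `sd`, and `loa = c(lower, upper)`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  if (length(a) < 2) stop("need at least 2 pairs")
  d <- a - b
  bias <- mean(d); s <- sd(d)
  list(bias = bias, sd = s,
       loa = c(lower = bias - 1.96 * s, upper = bias + 1.96 * s))
}

#' Paired t test
#'
#' Classical paired t on the differences with a two-sided p-value from the t
#' distribution with n-1 degrees of freedom. Zero difference variance is a
#' degenerate input and raises an error.
#'
#' @param a,b equal-length numeric vectors (length >= 2).
#' @return List with `t`, `df`, `p`.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  if (length(a) < 2) stop("need at least 2 pairs")
  if (var(a - b) == 0)
    stop("degenerate input: differences have zero variance")
  tt <- t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Squared Pearson correlation
#'
#' @param a,b equal-length numeric vectors (length >= 3), non-constant.
#' @return R squared.
#' @export
r_squared <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  if (length(a) < 3) stop("need at least 3 pairs")
  if (sd(a) == 0 || sd(b) == 0) stop("constant input")
  cor(a, b)^2
}

resolve_labels <- function(source, study, index) {
  if (is.function(source)) return(source(study))
  if (is.list(source)) return(source[[index]])
  if (identical(source, "truth")) return(study$truth_labels)
  stop("label source must be 'truth', a function(study), or a list of sq_labels")
}

#' Compare two segmentation sources over a cohort
#'
#' Assembles the full agreement report used to validate automated against
#' manual segmentation: per-gland DSC, paired %ID (from the 20-min SPECT) and
#' VOI volumes from both sources, with MAPE, R squared, Bland-Altman limits
#' and a paired t test on the %ID pairs.
#'
#' @param cohort list of `sq_study`.
#' @param labels_a,labels_b label sources: `"truth"`, a `function(study)`
#'   returning `sq_labels`, or a list of `sq_labels` (one per study).
#'   Source a is treated as the reference.
#' @param decay_correct passed to [percent_injected_dose()].
#' @return Object of class `sq_agreement`: `per_gland` data frame (one row
#'   per study x gland present), `dsc` (mean, sd, range), `mape`, `r2`,
#'   `bland_altman`, `paired_t`, `icc_pid`, `icc_vol`, `n`.
#' @export
compare_segmentations <- function(cohort, labels_a = "truth", labels_b,
                                  decay_correct = TRUE) {
  rows <- list()
  for (i in seq_along(cohort)) {
    st <- cohort[[i]]
    la <- resolve_labels(labels_a, st, i)
    lb <- resolve_labels(labels_b, st, i)
    pa <- percent_injected_dose(st$spect20, la, st$injected_MBq,
                                decay_correct = decay_correct)
    pb <- percent_injected_dose(st$spect20, lb, st$injected_MBq,
                                decay_correct = decay_correct)
    va <- voi_volume(la); vb <- voi_volume(lb)
    for (g in 1:4) {
      ma <- la$labels == g; mb <- lb$labels == g
      if (sum(ma) + sum(mb) == 0) next   # gland absent in both sources
      rows[[length(rows) + 1]] <- data.frame(
        study_id = st$study_id, gland = names(GLAND_CODES)[g],
        dsc = dice(mb, ma), pid_a = pa[g], pid_b = pb[g],
        vol_a = va[g], vol_b = vb[g], row.names = NULL)
    }
  }
  per_gland <- do.call(rbind, rows)
  mp <- mape(per_gland$pid_a, per_gland$pid_b)
  icc_safe <- function(m) tryCatch(icc_two_way(m)$icc,
                                   error = function(e) NA_real_)
  structure(list(
    per_gland = per_gland,
    dsc = c(mean = mean(per_gland$dsc, na.rm = TRUE),
            sd = sd(per_gland$dsc, na.rm = TRUE),
            min = min(per_gland$dsc, na.rm = TRUE),
            max = max(per_gland$dsc, na.rm = TRUE)),
    mape = mp,
    r2 = r_squared(per_gland$pid_a, per_gland$pid_b),
    bland_altman = bland_altman(per_gland$pid_a, per_gland$pid_b),
    paired_t = tryCatch(paired_t(per_gland$pid_a, per_gland$pid_b),
                        error = function(e) NULL),
    icc_pid = icc_safe(cbind(per_gland$pid_a, per_gland$pid_b)),
    icc_vol = icc_safe(cbind(per_gland$vol_a, per_gland$vol_b)),
    n = length(cohort)), class = "sq_agreement")
}

#' @export
print.sq_agreement <- function(x, ...) {
  cat(sprintf("<sq_agreement> %d studies, %d gland pairs\n", x$n,
              nrow(x$per_gland)))
  cat(sprintf("  DSC  %.3f +/- %.3f  [%.3f, %.3f]\n", x$dsc["mean"],
              x$dsc["sd"], x$dsc["min"], x$dsc["max"]))
  cat(sprintf("  %%ID  MAPE %.2f +/- %.2f %%, R^2 = %.3f\n",
              x$mape["mean"], x$mape["sd"], x$r2))
  cat(sprintf("  Bland-Altman bias %.4g, LoA [%.4g, %.4g]\n",
              x$bland_altman$bias, x$bland_altman$loa[1],
              x$bland_altman$loa[2]))
  if (!is.null(x$paired_t))
    cat(sprintf("  paired t = %.3f (p = %.4g)\n", x$paired_t$t, x$paired_t$p))
  if (is.finite(x$icc_pid))
    cat(sprintf("  ICC %%ID %.4f, ICC volume %.4f\n", x$icc_pid, x$icc_vol))
  invisible(x)
}
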