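#' AUROC by Mann--Whitney pair counting
#'
#' The area under the ROC curve for separating two groups equals the
#' Mann--Whitney concordance probability: the fraction of cross-group pairs
#' in which the group-1 value exceeds the group-0 value, counting ties as
#' one half. With `values_group0` the zone I ERV values and
#' `values_group1` the zone II values, lower ERV predicting zone I gives an
#' AUROC above 0.5.
#'
#' @param values_group0 numeric, e.g. minimum ERV of zone I eyes.
#' @param values_group1 numeric, e.g. minimum ERV of zone II eyes.
#' @return AUROC in `[0, 1]`.
#' @examples
#' auroc_mann_whitney(c(1, 3), c(2, 4))  # 0.75
#' @export
auroc_mann_whitney <- function(values_group0, values_group1) {
  x0 <- as.numeric(values_group0); x1 <- as.numeric(values_group1)
  if (!length(x0) || !length(x1))
    stop("auroc_mann_whitney(): both groups must be nonempty")
  if (anyNA(x0) || anyNA(x1)) stop("auroc_mann_whitney(): NA values")
  r <- rank(c(x0, x1))                    # midranks handle ties as 0.5
  n0 <- as.numeric(length(x0)); n1 <- as.numeric(length(x1))
  # U for "group0 < group1": sum of group1 ranks minus its minimum
  u <- sum(r[(n0 + 1L):(n0 + n1)]) - n1 * (n1 + 1) / 2
  unname(u / (n0 * n1))
}

new_test_result <- function(statistic, p_value, n, method, estimate = NA_real_,
                            ci = c(NA_real_, NA_real_), adjusted_p = NA_real_) {
  structure(list(statistic = unname(statistic), p_value = unname(p_value),
                 n = n, method = method, estimate = unname(estimate),
                 ci_low = ci[[1L]], ci_high = ci[[2L]],
                 adjusted_p = adjusted_p),
            class = "erv_test_result")
}

#' @export
print.erv_test_result <- function(x, ...) {
  cat(sprintf("<erv_test_result> %s: statistic %.4g, p = %.3g (n = %d)\n",
              x$method, x$statistic, x$p_value, x$n))
  invisible(x)
}

#' Wilcoxon signed-rank test for paired measurements
#'
#' Two-sided paired signed-rank test, used for the nasal--temporal
#' comparison because the paired differences are not normal. Zero
#' differences are dropped before ranking; the exact null distribution is
#' used for 25 or fewer non-zero pairs without ties, otherwise the normal
#' approximation with tie correction.
#'
#' @param paired_a,paired_b equal-length numeric vectors.
#' @return an `erv_test_result` (statistic = V, the positive-rank sum).
#' @export
wilcoxon_signed_rank <- function(paired_a, paired_b) {
  stopifnot(length(paired_a) == length(paired_b), length(paired_a) >= 1L)
  d <- as.numeric(paired_a) - as.numeric(paired_b)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(new_test_result(0, 1, 0L, "Wilcoxon signed-rank"))
  has_ties <- anyDuplicated(abs(d)) > 0L
  wt <- suppressWarnings(
    stats::wilcox.test(d, exact = (n <= 25L && !has_ties), correct = FALSE)
  )
  new_test_result(wt$statistic, wt$p.value, n, "Wilcoxon signed-rank")
}

#' Mann--Whitney U test (Wilcoxon rank-sum) for two independent groups
#'
#' Two-sided comparison of two independent samples, used for zone I versus
#' zone II ERV. Exact distribution when both groups have 25 or fewer
#' observations and no ties, otherwise normal approximation with tie
#' correction. The statistic relates to [auroc_mann_whitney()] by
#' `U = (1 - AUROC) * n0 * n1` (W for group0 over group1).
#'
#' @param group0,group1 numeric vectors.
#' @return an `erv_test_result` (statistic = W = number of (group0 >
#'   group1) pairs, counting ties as half).
#' @export
mann_whitney_test <- function(group0, group1) {
  x0 <- as.numeric(group0); x1 <- as.numeric(group1)
  if (!length(x0) || !length(x1))
    stop("mann_whitney_test(): both groups must be nonempty")
  has_ties <- anyDuplicated(c(x0, x1)) > 0L
  exact <- length(x0) <= 25L && length(x1) <= 25L && !has_ties
  wt <- suppressWarnings(
    stats::wilcox.test(x0, x1, exact = exact, correct = FALSE)
  )
  new_test_result(wt$statistic, wt$p.value,
                  length(x0) + length(x1), "Mann-Whitney U")
}

#' Holm step-down multiple-testing adjustment
#'
#' Sorts the raw p-values ascending, multiplies the i-th smallest by
#' (m - i + 1), enforces monotonicity by running maxima, caps at 1, and
#' returns the adjusted values in the input order.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same order as the input.
#' @examples
#' holm_adjust(c(0.01, 0.04))  # 0.02 0.04
#' @export
holm_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("holm_adjust(): p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "holm")
}

#' Kruskal--Wallis comparison of VSS across stages within ERV bins
#'
#' Bins the cohort's minimum ERV on each side into half-open intervals
#' `[k*w, (k+1)*w)` anchored at zero (default width 75 px) and, within each
#' bin, compares the VSS distribution across ROP stages 1/2/3 with the
#' Kruskal--Wallis test. Bins with fewer than `min_per_stage` eyes in any
#' stage are skipped (reported with `eligible = FALSE`). Holm adjustment is
#' applied jointly across the emitted tests of each side.
#'
#' @param table a per-eye `CohortTable` (see [aggregate_eyes()]) with
#'   `min_nerv`, `min_terv`, `stage`, `vss`.
#' @param bin_width bin width in pixels (default 75).
#' @param min_per_stage minimum eyes per stage per bin (default 5).
#' @return tibble with one row per (side, bin): `side`, `bin` (index k),
#'   `bin_lo`, `bin_hi`, `n`, `eligible`, `statistic`, `p_value`,
#'   `adjusted_p`.
#' @export
kruskal_wallis_by_bin <- function(table, bin_width = 75, min_per_stage = 5L) {
  stopifnot(bin_width > 0)
  need <- c("stage", "vss")
  stopifnot(all(need %in% names(table)))
  one_side <- function(side, col) {
    dat <- table[is.finite(table[[col]]) & !is.na(table$stage) & !is.na(table$vss), ]
    if (!nrow(dat)) return(NULL)
    bin <- floor(dat[[col]] / bin_width)
    rows <- lapply(sort(unique(bin)), function(k) {
      g <- dat[bin == k, ]
      counts <- tabulate(g$stage, nbins = 3L)
      eligible <- all(counts >= min_per_stage)
      if (eligible) {
        if (length(unique(g$vss)) == 1L) {   # constant response: no evidence
          stat <- 0; p <- 1
        } else {
          kw <- stats::kruskal.test(g$vss, factor(g$stage))
          stat <- unname(kw$statistic); p <- kw$p.value
        }
      } else {
        stat <- NA_real_; p <- NA_real_
      }
      tibble::tibble(side = side, bin = k, bin_lo = k * bin_width,
                     bin_hi = (k + 1) * bin_width, n = nrow(g),
                     eligible = eligible, statistic = stat, p_value = p)
    })
    do.call(rbind, rows)
  }
  out <- rbind(one_side("nasal", "min_nerv"), one_side("temporal", "min_terv"))
  if (is.null(out) || !nrow(out) || !any(out$eligible)) {
    warning("kruskal_wallis_by_bin(): no bin has enough eyes in every stage")
    if (is.null(out)) {
      out <- tibble::tibble(side = character(), bin = integer(),
                            bin_lo = numeric(), bin_hi = numeric(),
                            n = integer(), eligible = logical(),
                            statistic = numeric(), p_value = numeric())
    }
  }
  out$adjusted_p <- NA_real_
  for (s in unique(out$side)) {                   # Holm family: per side
    idx <- which(out$side == s & out$eligible)
    if (length(idx)) out$adjusted_p[idx] <- holm_adjust(out$p_value[idx])
  }
  out
}

#' ICC(2,1): two-way random effects, single rater, absolute agreement
#'
#' Decomposes an n-target by k-rater table by two-way ANOVA (mean squares
#' for rows/targets MSR, columns/raters MSC, error MSE) and estimates
#' `ICC(2,1) = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`, with
#' the standard F-based 95% confidence interval for this form
#' (McGraw & Wong's ICC(A,1)).
#'
#' @param ratings numeric matrix, rows = targets (images), columns = raters
#'   (graders); no missing cells. At least 3 targets, exactly 2 or more
#'   raters (the reproducibility design uses 2).
#' @param conf_level confidence level for the interval (default 0.95).
#' @return list with `icc`, `ci_low`, `ci_high`, `n`, `k`, and the mean
#'   squares `msr`, `msc`, `mse`.
#' @examples
#' icc_2_1(cbind(c(1, 3, 5), c(2, 4, 6)))$icc  # 8/9
#' @export
icc_2_1 <- function(ratings, conf_level = 0.95) {
  m <- as.matrix(ratings)
  if (anyNA(m)) stop("icc_2_1(): missing cells are not allowed")
  n <- nrow(m); k <- ncol(m)
  if (n < 3L) stop("icc_2_1(): need at least 3 targets")
  if (k < 2L) stop("icc_2_1(): need at least 2 raters")
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (denom <= .Machine$double.eps)
    stop("icc_2_1(): zero total variance; ICC undefined")
  icc <- (msr - mse) / denom

  # F-based CI for ICC(A,1), McGraw & Wong (1996)
  alpha <- 1 - conf_level
  if (mse <= .Machine$double.eps && msc <= .Machine$double.eps) {
    ci <- c(icc, icc)                 # degenerate: perfect agreement
  } else {
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
    ci <- c(lower, upper)
  }
  list(icc = icc, ci_low = ci[[1L]], ci_high = ci[[2L]], n = n, k = k,
       msr = msr, msc = msc, mse = mse)
}

#' Pearson correlation with two-sided t-test
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @return an `erv_test_result` with `estimate` = r and the 95% CI.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  ct <- stats::cor.test(x, y, method = "pearson")
  new_test_result(ct$statistic, ct$p.value, length(x), "Pearson correlation",
                  estimate = ct$estimate, ci = as.numeric(ct$conf.int))
}

#' Per-zone ERV summary with zone-discrimination statistics
#'
#' For each of the four ERV metrics (minimum/mean NERV/TERV) reports the
#' per-zone mean and SD, the two-sided Mann--Whitney p-value for the
#' zone I versus zone II comparison, and the AUROC for predicting zone I
#' (oriented so that lower ERV predicts zone I). Metrics for which only one
#' zone has data get NA statistics and are flagged.
#'
#' @param table a per-eye `CohortTable` with a `zone` column.
#' @return tibble with columns metric, zone, n, mean, sd, auroc, p_value,
#'   degenerate.
#' @export
zone_summary <- function(table) {
  if (!nrow(table)) stop("zone_summary(): empty table")
  stopifnot("zone" %in% names(table))
  metrics <- intersect(c("min_nerv", "mean_nerv", "min_terv", "mean_terv"),
                       names(table))
  rows <- lapply(metrics, function(mt) {
    v1 <- table[[mt]][table$zone == "I" & is.finite(table[[mt]])]
    v2 <- table[[mt]][table$zone == "II" & is.finite(table[[mt]])]
    degenerate <- !length(v1) || !length(v2)
    if (!degenerate) {
      auroc <- auroc_mann_whitney(v1, v2)
      p <- mann_whitney_test(v1, v2)$p_value
    } else {
      auroc <- NA_real_; p <- NA_real_
    }
    tibble::tibble(
      metric = mt,
      zone = c("I", "II"),
      n = c(length(v1), length(v2)),
      mean = c(mean(v1), mean(v2)),
      sd = c(stats::sd(v1), stats::sd(v2)),
      auroc = auroc, p_value = p, degenerate = degenerate
    )
  })
  do.call(rbind, rows)
}

#' Nasal--temporal asymmetry summary
#'
#' Restricted to eyes with both sides measured: the fraction with minimum
#' NERV strictly below minimum TERV, the mean and SD of the absolute
#' (`min_terv - min_nerv`, px) and proportional
#' (`(min_terv - min_nerv)/min_terv`) differences, and the paired Wilcoxon
#' signed-rank p-value.
#'
#' @param table a per-eye `CohortTable`.
#' @return list with `n`, `n_nerv_lt_terv`, `frac_nerv_lt_terv`,
#'   `mean_abs_diff`, `sd_abs_diff`, `mean_prop_diff`, `sd_prop_diff`,
#'   `wilcoxon_p`.
#' @export
asymmetry_summary <- function(table) {
  both <- table[is.finite(table$min_nerv) & is.finite(table$min_terv), ]
  if (!nrow(both)) stop("asymmetry_summary(): no eyes with both sides measured")
  lt <- both$min_nerv < both$min_terv
  wt <- wilcoxon_signed_rank(both$min_terv, both$min_nerv)
  list(
    n = nrow(both),
    n_nerv_lt_terv = sum(lt),
    frac_nerv_lt_terv = mean(lt),
    mean_abs_diff = mean(both$abs_diff),
    sd_abs_diff = stats::sd(both$abs_diff),
    mean_prop_diff = mean(both$prop_diff),
    sd_prop_diff = stats::sd(both$prop_diff),
    wilcoxon_p = wt$p_value
  )
}
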