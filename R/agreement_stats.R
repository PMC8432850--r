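# Validation protocol for automatic vs manual ISS scoring: paired TOST
# equivalence with bounds +/-3 ISS points, Wilcoxon signed-rank NHST, the
# dual-criterion equivalence verdict, weighted Cohen's kappa on the 6x6
# ISS-group cross-tabulation, per-group absolute-difference summaries,
# Bonferroni correction, and TOST-based sample-size calculation.

#' Cross-tabulate paired ISS scores by group
#'
#' Bins each pair's manual and automatic ISS into the six analysis groups
#' and counts them into a 6x6 table, rows = manual group, columns =
#' automatic group.
#'
#' @param pairs Data frame with columns `manual_iss` and `auto_iss`
#'   (integers 0-75).
#' @return A 6x6 integer matrix with group-range dimnames; total equals
#'   `nrow(pairs)`.
#' @export
crosstab <- function(pairs) {
  if (!all(c("manual_iss", "auto_iss") %in% names(pairs)))
    stop("crosstab(): input needs columns 'manual_iss' and 'auto_iss'")
  if (!nrow(pairs)) stop("crosstab(): empty input")
  m <- factor(iss_group(pairs$manual_iss), levels = 1:6)
  a <- factor(iss_group(pairs$auto_iss), levels = 1:6)
  tab <- unclass(table(manual = m, auto = a))
  dimnames(tab) <- list(manual = ISS_GROUP_LABELS, auto = ISS_GROUP_LABELS)
  tab
}

KAPPA_BANDS <- c(poor = 0.20, fair = 0.40, moderate = 0.60, good = 0.80,
                 excellent = 1.00)

kappa_band <- function(kappa) {
  names(KAPPA_BANDS)[findInterval(kappa, c(-Inf, KAPPA_BANDS[-5]),
                                  left.open = TRUE)]
}

#' Weighted Cohen's kappa for two raters on ordinal categories
#'
#' Chance-corrected agreement with partial credit for near-misses:
#' \deqn{\kappa_w = (P_o - P_e) / (1 - P_e)} with agreement weights
#' \eqn{w_{ij} = 1 - |i-j|/(k-1)} (linear, default) or
#' \eqn{w_{ij} = 1 - (i-j)^2/(k-1)^2} (quadratic), observed agreement
#' \eqn{P_o = \sum w_{ij} p_{ij}} and expected agreement
#' \eqn{P_e = \sum w_{ij} p_{i\cdot} p_{\cdot j}} from the marginals.
#' The interpretation band uses the conventional cutpoints: below or at
#' 0.20 poor, 0.21-0.40 fair, 0.41-0.60 moderate, 0.61-0.80 good,
#' 0.81-1.00 excellent.
#'
#' @param tab Square contingency matrix of non-negative counts (rows =
#'   rater 1, columns = rater 2, categories ordinal in order).
#' @param weighting `"linear"` (default) or `"quadratic"`.
#' @return A `kappa_result`: list with `kappa`, `weighting`, `band`, `po`,
#'   `pe`, `n`.
#' @export
#' @examples
#' weighted_kappa(reference_crosstab())  # 0.47, "moderate"
weighted_kappa <- function(tab, weighting = c("linear", "quadratic")) {
  weighting <- match.arg(weighting)
  tab <- as.matrix(tab)
  if (nrow(tab) != ncol(tab) || nrow(tab) < 2L)
    stop("weighted_kappa(): table must be square with at least 2 categories")
  if (any(tab < 0) || sum(tab) <= 0)
    stop("weighted_kappa(): counts must be non-negative with positive total")
  k <- nrow(tab)
  p <- tab / sum(tab)
  d <- abs(outer(seq_len(k), seq_len(k), "-"))
  w <- if (weighting == "linear") 1 - d / (k - 1) else 1 - d^2 / (k - 1)^2
  po <- sum(w * p)
  pe <- sum(w * outer(rowSums(p), colSums(p)))
  if (isTRUE(all.equal(pe, 1)))
    stop("weighted_kappa(): degenerate table (expected agreement 1); kappa undefined")
  kappa <- (po - pe) / (1 - pe)
  structure(list(kappa = kappa, weighting = weighting,
                 band = kappa_band(kappa), po = po, pe = pe, n = sum(tab)),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Weighted kappa (%s weights): %.3f ('%s' agreement), n = %d\n",
              x$weighting, x$kappa, x$band, x$n))
  invisible(x)
}

#' Paired TOST equivalence test with Wilcoxon NHST
#'
#' Two one-sided one-sample t-tests of the mean paired difference against
#' the equivalence bounds: the lower test rejects when the mean is
#' significantly above `low`, the upper when significantly below `high`;
#' the TOST p-value is the larger of the two, and equivalence on the TOST
#' side requires it at or below `alpha`. The conventional
#' \eqn{(1-2\alpha)} confidence interval on the mean difference (90% at
#' `alpha = 0.05`) is reported. The dual-criterion verdict additionally
#' requires a non-significant Wilcoxon signed-rank test of the same
#' differences (see [equivalence_verdict()]).
#'
#' @param diffs Numeric vector of paired differences (automatic minus
#'   manual by this package's sign convention), `n >= 2`.
#' @param low,high Equivalence bounds, default -3 and +3 ISS points.
#' @param alpha One-sided test level, default 0.05.
#' @return A `tost_result`: list with `n`, `mean_diff`, `sd_diff`,
#'   `p_lower`, `p_upper`, `p_tost`, `ci_low`, `ci_high`, `p_nhst`,
#'   `equivalent`, `flags`. Zero-variance differences give a degenerate
#'   result (`zero_variance` flag, verdict by the mean's position inside
#'   the open interval `(low, high)`).
#' @export
paired_tost <- function(diffs, low = -3, high = 3, alpha = 0.05) {
  diffs <- as.numeric(diffs)
  if (anyNA(diffs)) stop("paired_tost(): differences contain NA")
  n <- length(diffs)
  if (n < 2L) stop("paired_tost(): need at least 2 paired differences")
  if (!(low < high)) stop("paired_tost(): need low < high")
  m <- mean(diffs)
  s <- stats::sd(diffs)
  p_nhst <- nhst_wilcoxon(diffs)
  if (s == 0) {
    res <- list(n = n, mean_diff = m, sd_diff = 0,
                p_lower = NA_real_, p_upper = NA_real_, p_tost = NA_real_,
                ci_low = m, ci_high = m, p_nhst = p_nhst,
                equivalent = (m > low && m < high),
                flags = "zero_variance")
    return(structure(res, class = "tost_result"))
  }
  se <- s / sqrt(n)
  df <- n - 1
  p_lower <- stats::pt((m - low) / se, df, lower.tail = FALSE)
  p_upper <- stats::pt((m - high) / se, df, lower.tail = TRUE)
  p_tost <- max(p_lower, p_upper)
  tcrit <- stats::qt(1 - alpha, df)
  structure(
    list(n = n, mean_diff = m, sd_diff = s,
         p_lower = p_lower, p_upper = p_upper, p_tost = p_tost,
         ci_low = m - tcrit * se, ci_high = m + tcrit * se,
         p_nhst = p_nhst,
         equivalent = equivalence_verdict(p_tost, p_nhst, alpha),
         flags = character()),
    class = "tost_result")
}

#' @export
print.tost_result <- function(x, ...) {
  cat(sprintf(
    "Paired TOST: n = %d, mean diff = %.3f (sd %.3f), 90%%-type CI [%.3f, %.3f]\n  p(TOST) = %.4g, p(NHST, Wilcoxon) = %.4g -> %s\n",
    x$n, x$mean_diff, x$sd_diff, x$ci_low, x$ci_high, x$p_tost, x$p_nhst,
    if (isTRUE(x$equivalent)) "equivalent" else "not equivalent"))
  invisible(x)
}

#' Wilcoxon signed-rank test of paired differences
#'
#' Two-sided signed-rank p-value with zero differences dropped (the
#' original convention); the exact null distribution is used for 25 or
#' fewer non-zero differences without ties, the normal approximation with
#' continuity correction otherwise. When every difference is zero the
#' p-value is 1 by convention, with a warning.
#'
#' @param diffs Numeric vector of paired differences.
#' @return Two-sided p-value.
#' @export
nhst_wilcoxon <- function(diffs) {
  diffs <- as.numeric(diffs)
  if (anyNA(diffs)) stop("nhst_wilcoxon(): differences contain NA")
  if (!length(diffs)) stop("nhst_wilcoxon(): empty input")
  nz <- diffs[diffs != 0]
  if (!length(nz)) {
    warning("nhst_wilcoxon(): all differences are zero; p = 1 by convention",
            call. = FALSE)
    return(1)
  }
  suppressWarnings(
    stats::wilcox.test(nz, exact = length(nz) <= 25L,
                       correct = TRUE)$p.value)
}

#' Dual-criterion equivalence verdict
#'
#' Equivalence is declared when the TOST is significant (the mean
#' difference is demonstrably inside the bounds) and the NHST is not
#' significant (no demonstrable systematic difference).
#'
#' @param p_tost,p_nhst P-values (vectorised).
#' @param alpha Significance level, default 0.05.
#' @return Logical vector.
#' @export
#' @examples
#' equivalence_verdict(0.001, 0.286)  # TRUE
#' equivalence_verdict(0.015, 0.005)  # FALSE: both significant
equivalence_verdict <- function(p_tost, p_nhst, alpha = 0.05) {
  if (anyNA(p_tost) || anyNA(p_nhst) ||
      any(p_tost < 0 | p_tost > 1) || any(p_nhst < 0 | p_nhst > 1))
    stop("equivalence_verdict(): p-values must be in [0, 1]")
  p_tost <= alpha & p_nhst > alpha
}

#' Per-group absolute-difference summaries
#'
#' Groups pairs by the manual ISS group and reports the count, mean and
#' sample standard deviation of the absolute automatic-minus-manual
#' differences, plus an overall row.
#'
#' @param pairs Data frame with columns `manual_iss` and `auto_iss`.
#' @return Data frame with columns `group`, `group_label`, `n`,
#'   `mean_abs_diff`, `sd_abs_diff` (7 rows: groups 1-6 and `overall`).
#' @export
group_abs_diff_summary <- function(pairs) {
  if (!all(c("manual_iss", "auto_iss") %in% names(pairs)))
    stop("group_abs_diff_summary(): input needs columns 'manual_iss' and 'auto_iss'")
  g <- iss_group(pairs$manual_iss)
  ad <- abs(pairs$auto_iss - pairs$manual_iss)
  one <- function(x) {
    if (!length(x)) return(c(n = 0, mean_abs_diff = NA_real_, sd_abs_diff = NA_real_))
    c(n = length(x), mean_abs_diff = mean(x),
      sd_abs_diff = if (length(x) > 1) stats::sd(x) else NA_real_)
  }
  rows <- t(vapply(1:6, function(k) one(ad[g == k]), numeric(3)))
  rows <- rbind(rows, one(ad))
  data.frame(group = c(as.character(1:6), "overall"),
             group_label = c(ISS_GROUP_LABELS, "0-75"),
             rows, row.names = NULL, stringsAsFactors = FALSE)
}

tost_power <- function(n, sd, low, high, alpha, theta = 0) {
  # noncentral-t power of the paired TOST at true mean difference theta
  if (n < 2L) return(0)
  df <- n - 1
  tcrit <- stats::qt(1 - alpha, df)
  se <- sd / sqrt(n)
  max(0, stats::pt(-tcrit, df, ncp = (theta - high) / se) -
         stats::pt(tcrit, df, ncp = (theta - low) / se))
}

#' Sample size for a paired TOST equivalence design
#'
#' Smallest number of pairs whose TOST power at a true mean difference of
#' zero reaches the target, computed by iterating the noncentral-t power
#' formula over n. Asymptotically n grows with the square of the ratio of
#' the difference SD to the bound half-width.
#'
#' @param sd Standard deviation of the paired differences (> 0).
#' @param low,high Equivalence bounds with `low < 0 < high`; default
#'   -3/+3 ISS points.
#' @param alpha One-sided test level, default 0.05.
#' @param power Target power, default 0.8.
#' @return Smallest sufficient n (at least 2); the power achieved at that
#'   n is attached as attribute `"achieved_power"`.
#' @export
#' @examples
#' tost_sample_size(7.73)
tost_sample_size <- function(sd, low = -3, high = 3, alpha = 0.05,
                             power = 0.8) {
  if (!(is.numeric(sd) && sd > 0)) stop("tost_sample_size(): sd must be > 0")
  if (!(low < 0 && 0 < high))
    stop("tost_sample_size(): bounds must satisfy low < 0 < high")
  if (!(alpha > 0 && alpha < power && power < 1))
    stop("tost_sample_size(): need 0 < alpha < power < 1")
  n <- 2L
  repeat {
    p <- tost_power(n, sd, low, high, alpha)
    if (p >= power) break
    n <- n + 1L
    if (n > 1e6L)
      stop("tost_sample_size(): target power unreachable below n = 1e6")
  }
  structure(n, achieved_power = p)
}

#' Bonferroni correction
#'
#' Multiplies each p-value by the family size and clamps at 1.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bonferroni <- function(pvals) {
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
    stop("bonferroni(): p-values must be in [0, 1]")
  stats::p.adjust(pvals, method = "bonferroni")
}

region_pair_cols <- function(pairs) {
  man <- paste0("manual_ais_", REGION_NAMES)
  aut <- paste0("auto_ais_", REGION_NAMES)
  if (all(c(man, aut) %in% names(pairs))) list(manual = man, auto = aut) else NULL
}

#' Full agreement report for paired manual/automatic scores
#'
#' Assembles the complete validation protocol: per-ISS-group and overall
#' paired TOST + Wilcoxon NHST with the dual-criterion verdict and
#' Bonferroni-adjusted p-values (family = the 7 equivalence tests by
#' default), the 6x6 group cross-tabulation with weighted kappa, per-group
#' absolute-difference summaries, and - when the twelve per-region AIS
#' columns (`manual_ais_*`/`auto_ais_*`) are present - the same kappa and
#' equivalence analysis per body region.
#'
#' @param pairs Data frame with columns `patient_id`, `manual_iss`,
#'   `auto_iss` and optionally `manual_ais_<region>`/`auto_ais_<region>`
#'   for the six regions.
#' @param alpha Significance level, default 0.05; verdicts use the raw
#'   p-values (adjusted ones are reported alongside).
#' @param bounds Equivalence bounds, default `c(-3, 3)`.
#' @param kappa_weights `"linear"` (default) or `"quadratic"`.
#' @return A list of class `agreement_report`: `equivalence` (7-row data
#'   frame), `crosstab`, `kappa` (`kappa_result`), `abs_diff`
#'   (per-group summaries), and `regions` (per-region data frame or
#'   `NULL`).
#' @export
compare_report <- function(pairs, alpha = 0.05, bounds = c(-3, 3),
                           kappa_weights = c("linear", "quadratic")) {
  kappa_weights <- match.arg(kappa_weights)
  need <- c("patient_id", "manual_iss", "auto_iss")
  miss <- setdiff(need, names(pairs))
  if (length(miss))
    stop(sprintf("compare_report(): input is missing column(s): %s",
                 paste(miss, collapse = ", ")))
  if (length(bounds) != 2L || !(bounds[1] < bounds[2]))
    stop("compare_report(): bounds must be an increasing pair")
  d <- pairs$auto_iss - pairs$manual_iss
  g <- iss_group(pairs$manual_iss)

  one_row <- function(dd, label) {
    if (length(dd) < 2L || stats::sd(dd) == 0) {
      return(data.frame(group = label, n = length(dd),
                        mean_diff = if (length(dd)) mean(dd) else NA_real_,
                        sd_diff = if (length(dd) > 1) stats::sd(dd) else NA_real_,
                        p_tost = NA_real_, p_nhst = NA_real_,
                        equivalent = NA, stringsAsFactors = FALSE))
    }
    t <- paired_tost(dd, bounds[1], bounds[2], alpha)
    data.frame(group = label, n = t$n, mean_diff = t$mean_diff,
               sd_diff = t$sd_diff, p_tost = t$p_tost, p_nhst = t$p_nhst,
               equivalent = t$equivalent, stringsAsFactors = FALSE)
  }
  eq <- do.call(rbind, c(
    lapply(1:6, function(k) one_row(d[g == k], ISS_GROUP_LABELS[k])),
    list(one_row(d, "0-75"))))
  ok <- !is.na(eq$p_tost)
  eq$p_tost_bonf <- NA_real_; eq$p_nhst_bonf <- NA_real_
  eq$p_tost_bonf[ok] <- bonferroni(eq$p_tost[ok])
  eq$p_nhst_bonf[ok] <- bonferroni(eq$p_nhst[ok])

  tab <- crosstab(pairs)
  kap <- weighted_kappa(tab, kappa_weights)

  regions <- NULL
  rc <- region_pair_cols(pairs)
  if (!is.null(rc)) {
    regions <- do.call(rbind, lapply(seq_along(REGION_NAMES), function(i) {
      m <- pairs[[rc$manual[i]]]; a <- pairs[[rc$auto[i]]]
      rtab <- unclass(table(factor(m, levels = 0:6), factor(a, levels = 0:6)))
      rk <- tryCatch(weighted_kappa(rtab, kappa_weights)$kappa,
                     error = function(e) NA_real_)
      dd <- a - m
      if (length(dd) >= 2L && stats::sd(dd) > 0) {
        t <- paired_tost(dd, bounds[1], bounds[2], alpha)
        data.frame(region = REGION_NAMES[i], n = length(dd),
                   manual_mean = mean(m), auto_mean = mean(a),
                   kappa = rk, band = if (is.na(rk)) NA_character_ else kappa_band(rk),
                   p_tost = t$p_tost, p_nhst = t$p_nhst,
                   equivalent = t$equivalent, stringsAsFactors = FALSE)
      } else {
        data.frame(region = REGION_NAMES[i], n = length(dd),
                   manual_mean = mean(m), auto_mean = mean(a),
                   kappa = rk, band = if (is.na(rk)) NA_character_ else kappa_band(rk),
                   p_tost = NA_real_, p_nhst = NA_real_, equivalent = NA,
                   stringsAsFactors = FALSE)
      }
    }))
  }

  structure(list(equivalence = eq, crosstab = tab, kappa = kap,
                 abs_diff = group_abs_diff_summary(pairs),
                 regions = regions,
                 alpha = alpha, bounds = bounds),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("== Equivalence (paired TOST, bounds",
      sprintf("[%g, %g],", x$bounds[1], x$bounds[2]),
      "alpha", x$alpha, ") ==\n")
  print(x$equivalence, digits = 3)
  cat("\n== ISS-group cross-tabulation (rows manual, cols automatic) ==\n")
  print(x$crosstab)
  cat("\n")
  print(x$kappa)
  cat("\n== Absolute differences by manual ISS group ==\n")
  print(x$abs_diff, digits = 3)
  if (!is.null(x$regions)) {
    cat("\n== Per-region AIS agreement ==\n")
    print(x$regions, digits = 3)
  }
  invisible(x)
}

# flatten an agreement_report for JSON serialisation
report_to_list <- function(report) {
  list(
    alpha = report$alpha,
    bounds = report$bounds,
    equivalence = report$equivalence,
    crosstab = list(labels = ISS_GROUP_LABELS,
                    counts = unname(apply(report$crosstab, 1, as.integer,
                                          simplify = FALSE))),
    kappa = list(kappa = report$kappa$kappa, weighting = report$kappa$weighting,
                 band = report$kappa$band, n = report$kappa$n),
    abs_diff = report$abs_diff,
    regions = report$regions)
}
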