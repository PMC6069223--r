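#' Device-agreement statistics for paired measurements
#'
#' Compares the same (trajectory, parameter) quantity measured on the same
#' subjects by two devices (e.g. a marker-based and a markerless system):
#' Pearson's correlation R with its two-sided p-value, the reproducibility
#' coefficient RCP% = 100 * 1.96 * sd / base and the coefficient of variation
#' CV% = 100 * sd / base. By convention (`basis = "differences"`) the sd is
#' taken over the paired differences A - B and the percentage base is the
#' pooled mean of all values from both devices; `basis = "values"` instead
#' uses the sd of the pooled values.
#'
#' @param a,b numeric vectors of equal length (n >= 3), one value per subject
#'   per device.
#' @param basis `"differences"` (default) or `"values"`; see Details.
#' @return A list of class `agreement_stats`: `r`, `p_value`, `rcp_pct`,
#'   `cv_pct`, `n`, `flag`.
#' @export
agreement_stats <- function(a, b, basis = c("differences", "values")) {
  basis <- match.arg(basis)
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n < 3L) stop("need at least 3 paired observations", call. = FALSE)
  pooled_mean <- mean(c(a, b))
  if (pooled_mean == 0)
    stop("pooled mean is zero: percentages undefined", call. = FALSE)
  flag <- ""
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    r <- NA_real_
    p <- NA_real_
    flag <- "zero_variance"
  } else {
    ct <- stats::cor.test(a, b, method = "pearson")
    r <- unname(ct$estimate)
    p <- ct$p.value
  }
  s <- if (basis == "differences") stats::sd(a - b) else stats::sd(c(a, b))
  structure(list(r = r, p_value = p,
                 rcp_pct = 100 * 1.96 * s / pooled_mean,
                 cv_pct = 100 * s / pooled_mean,
                 n = n, basis = basis, flag = flag),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("agreement (n=%d): R=%.3f (p=%.3g), RCP=%.1f%%, CV=%.1f%%\n",
              x$n, x$r, x$p_value, x$rcp_pct, x$cv_pct))
  invisible(x)
}

#' One-way ANOVA with Bonferroni post hoc comparisons
#'
#' Compares one parameter's per-subject means across groups (e.g. healthy
#' adults / elderly / stroke): one-way ANOVA F and p, then all pairwise
#' two-sample t tests (pooled variance) with Bonferroni-multiplied p-values
#' capped at 1, and significance flags at `alpha`. p-values are invariant
#' under group relabelling, and Bonferroni p >= raw p always.
#'
#' @param values numeric vector of per-subject values.
#' @param groups group labels (character or factor), >= 2 groups with n >= 2
#'   each.
#' @param alpha significance level for the flags (default 0.05).
#' @return A list of class `group_comparison`: `f`, `p_value`, `pairwise`
#'   (`data.frame` with `group1,group2,t,p_raw,p_bonferroni,significant,flag`),
#'   `group_means` (`data.frame` with `group,n,mean,sd`), `alpha`.
#' @export
group_comparison <- function(values, groups, alpha = 0.05) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  gl <- sort(unique(groups))
  if (length(gl) < 2L) stop("need at least 2 groups", call. = FALSE)
  ns <- table(groups)
  if (any(ns < 2L)) stop("each group needs n >= 2", call. = FALSE)
  fit <- stats::anova(stats::lm(values ~ factor(groups)))
  pairs <- utils::combn(gl, 2L)
  m <- ncol(pairs)
  pw <- do.call(rbind, lapply(seq_len(m), function(k) {
    x <- values[groups == pairs[1L, k]]
    y <- values[groups == pairs[2L, k]]
    flag <- ""
    if ((stats::sd(x) == 0 && length(x) == 2L) ||
        (stats::sd(y) == 0 && length(y) == 2L))
      flag <- "degenerate_variance"
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      tt <- list(statistic = if (mean(x) == mean(y)) 0 else Inf,
                 p.value = if (mean(x) == mean(y)) 1 else 0)
      flag <- "degenerate_variance"
    } else {
      tt <- stats::t.test(x, y, var.equal = TRUE)
    }
    data.frame(group1 = pairs[1L, k], group2 = pairs[2L, k],
               t = unname(tt$statistic), p_raw = tt$p.value,
               p_bonferroni = min(1, m * tt$p.value),
               significant = min(1, m * tt$p.value) < alpha,
               flag = flag, stringsAsFactors = FALSE)
  }))
  gm <- do.call(rbind, lapply(gl, function(g) data.frame(
    group = g, n = sum(groups == g), mean = mean(values[groups == g]),
    sd = stats::sd(values[groups == g]))))
  structure(list(f = fit$`F value`[1L], p_value = fit$`Pr(>F)`[1L],
                 pairwise = pw, group_means = gm, alpha = alpha),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F=%.3f, p=%.3g\n", x$f, x$p_value))
  print(x$pairwise[, c("group1", "group2", "p_raw", "p_bonferroni",
                       "significant")])
  invisible(x)
}

#' Shapiro-Wilk normality check
#'
#' Thin, validated wrapper around [stats::shapiro.test()] returning the W
#' statistic and p-value; constant vectors are rejected with an informative
#' error rather than an opaque one.
#'
#' @param x numeric vector, 3 <= n <= 5000.
#' @return A list with `w`, `p_value`, `n`.
#' @export
normality_check <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L || n > 5000L)
    stop("Shapiro-Wilk requires 3 <= n <= 5000 (n=", n, ")", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("constant vector: normality test undefined", call. = FALSE)
  st <- stats::shapiro.test(x)
  list(w = unname(st$statistic), p_value = st$p.value, n = n)
}
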