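# Method-comparison statistics. x is always the candidate method
# (prediction equation), y the reference (DXA-style criterion); paired
# differences are x - y throughout, so a positive bias means the
# candidate overestimates the reference.

check_paired <- function(x, y, min_n = 3L) {
  if (!is.numeric(x) || !is.numeric(y)) {
    stop_input("paired series must be numeric")
  }
  if (length(x) != length(y)) {
    stop_input("paired series must have equal length (got %d and %d)",
               length(x), length(y))
  }
  if (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y))) {
    stop_input("paired series must not contain missing values")
  }
  if (length(x) < min_n) {
    stop_input("need at least %d paired observations, got %d",
               min_n, length(x))
  }
  length(x)
}

#' Bland-Altman bias and limits of agreement
#'
#' Mean bias of the paired differences `d = x - y` and the 95% limits of
#' agreement `bias +/- 1.96 SD(d)` (sample SD, n - 1 denominator).
#'
#' @param x candidate-method values (e.g. equation fat mass, kg).
#' @param y reference-method values, same length and units.
#' @return list with `bias`, `sd_diff`, `loa_lower`, `loa_upper`, `n`.
#' @seealso [bland_altman_coords()] for the per-subject scatter
#'   coordinates.
#' @examples
#' bland_altman(c(1, 2, 3), c(2, 4, 6))
#' @export
bland_altman <- function(x, y) {
  n <- check_paired(x, y)
  d <- x - y
  bias <- mean(d)
  sdd <- sd(d)
  list(bias = bias, sd_diff = sdd,
       loa_lower = bias - 1.96 * sdd,
       loa_upper = bias + 1.96 * sdd,
       n = n)
}

#' @rdname bland_altman
#' @param ids optional subject identifiers.
#' @return `bland_altman_coords()`: data.frame with one row per subject
#'   and columns `id`, `mean` (pair mean, the x axis of a Bland-Altman
#'   plot) and `diff` (x - y).
#' @export
bland_altman_coords <- function(x, y, ids = NULL) {
  n <- check_paired(x, y)
  if (is.null(ids)) ids <- seq_len(n)
  data.frame(id = ids, mean = (x + y) / 2, diff = x - y)
}

#' Typical-error coefficient of variation
#'
#' Treats each subject's two method values as a pair, computes the
#' within-pair SD `|x - y| / sqrt(2)` as a percentage of the pair mean,
#' and summarises the per-subject CVs as mean and SD across subjects
#' (the "CV% +/- SD" convention of method-comparison tables). Invariant
#' under common positive rescaling of both methods.
#'
#' @inheritParams bland_altman
#' @return list with `cv_mean`, `cv_sd` (percent) and the per-subject
#'   vector `cv`.
#' @export
typical_error_cv <- function(x, y) {
  check_paired(x, y, min_n = 1L)
  pair_mean <- (x + y) / 2
  if (any(pair_mean <= 0)) {
    stop_domain("typical-error CV is undefined for pair means <= 0")
  }
  cv <- 100 * (abs(x - y) / sqrt(2)) / pair_mean
  list(cv_mean = mean(cv),
       cv_sd = if (length(cv) > 1L) sd(cv) else NA_real_,
       cv = cv)
}

#' Technical error of measurement
#'
#' Intra-rater TEM over replicate measurements:
#' `TEM = sqrt(sum(d^2) / (2n))` with `d` the replicate differences,
#' expressed also relative to the grand mean of all measurements
#' (`%TEM`), with a pass flag against the conventional 5% threshold.
#'
#' @param first,second replicate measurements of the same quantities by
#'   the same rater (equal length, any unit).
#' @param threshold acceptability threshold for `%TEM`, default 5.
#' @return list with `tem_abs` (unit of input), `tem_percent`, `pass`,
#'   `n`.
#' @examples
#' tem(c(10, 20), c(11, 21))
#' @export
tem <- function(first, second, threshold = 5) {
  n <- check_paired(first, second, min_n = 2L)
  gm <- mean(c(first, second))
  if (gm <= 0) stop_domain("%%TEM is undefined for grand mean <= 0")
  tem_abs <- sqrt(sum((first - second)^2) / (2 * n))
  tem_percent <- 100 * tem_abs / gm
  list(tem_abs = tem_abs, tem_percent = tem_percent,
       pass = tem_percent <= threshold, n = n)
}

#' Intraclass correlation, two-way absolute agreement, single measures
#'
#' ICC(A,1) in the McGraw-Wong nomenclature, computed from the two-way
#' ANOVA mean squares (subjects crossed with methods/raters):
#'
#' `ICC = (MSR - MSE) / (MSR + (k - 1) MSE + (k/n) (MSC - MSE))`
#'
#' with `MSR` the between-subjects, `MSC` the between-methods and `MSE`
#' the residual mean square. This is the "two-way mixed, absolute
#' agreement" coefficient: it penalises systematic offsets between
#' methods as well as random disagreement.
#'
#' @param ratings numeric matrix or data.frame, one row per subject
#'   (n >= 3), one column per method/rater (k >= 2), no missing values.
#' @return the ICC, a number in (-1, 1]. A table with zero total
#'   variance (all entries equal) returns 1 by convention, with a
#'   message.
#' @examples
#' icc_a1(cbind(c(1, 2, 3, 4), c(2, 3, 4, 5)))   # 10/13
#' @export
icc_a1 <- function(ratings) {
  m <- as.matrix(ratings)
  if (!is.numeric(m) || anyNA(m) || any(!is.finite(m))) {
    stop_input("ratings must be a numeric table without missing values")
  }
  n <- nrow(m)
  k <- ncol(m)
  if (n < 3L || k < 2L) {
    stop_input("need at least 3 subjects and 2 methods, got %d x %d", n, k)
  }
  if (all(m == m[[1L]])) {
    message("icc_a1: zero total variance; returning 1 by convention")
    return(1)
  }
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  resid <- m - outer(row_m, rep(1, k)) -
    matrix(col_m, n, k, byrow = TRUE) + grand
  mse <- sum(resid^2) / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

#' Absolute percentage difference from the reference
#'
#' Per subject `100 |x - y| / y` with the reference in the denominator,
#' summarised as mean and SD across subjects. The absolute value makes
#' the statistic a magnitude of disagreement regardless of direction.
#'
#' @inheritParams bland_altman
#' @return list with `mean`, `sd` (percent) and per-subject `pct_diff`.
#' @export
percent_diff <- function(x, y) {
  check_paired(x, y, min_n = 1L)
  if (any(y <= 0)) {
    stop_domain("percent difference is undefined for reference values <= 0")
  }
  pd <- 100 * abs(x - y) / y
  list(mean = mean(pd), sd = if (length(pd) > 1L) sd(pd) else 0,
       pct_diff = pd)
}

#' Cohen's d for a method comparison
#'
#' Standardised mean difference `|mean(x) - mean(y)| / s_p` with `s_p`
#' the SD pooled over the two method columns, banded on the conventional
#' cut-points (boundaries resolved upward: d = 0.2 is "small", 0.5
#' "medium", 0.8 "large").
#'
#' @inheritParams bland_altman
#' @return list with `d`, `band` (trivial/small/medium/large) and
#'   `infinite` flag (pooled SD zero with unequal means).
#' @export
cohens_d <- function(x, y) {
  n <- check_paired(x, y)
  sp <- sqrt(((n - 1) * var(x) + (n - 1) * var(y)) / (2 * n - 2))
  delta <- abs(mean(x) - mean(y))
  if (sp == 0) {
    if (delta == 0) {
      return(list(d = 0, band = "trivial", infinite = FALSE))
    }
    return(list(d = Inf, band = "large", infinite = TRUE))
  }
  d <- delta / sp
  list(d = d, band = es_band(d), infinite = FALSE)
}

#' @rdname cohens_d
#' @param d an effect-size magnitude.
#' @export
es_band <- function(d) {
  check_number(d, "d", lower = 0)
  cut(d, breaks = c(-Inf, 0.2, 0.5, 0.8, Inf), right = FALSE,
      labels = c("trivial", "small", "medium", "large")) |>
    as.character()
}

# SPSS-style Wilcoxon signed-rank Z: zero differences dropped, ranks of
# |d| with midranks for ties, normal approximation with tie correction,
# no continuity correction. Sign of Z follows W+ relative to its null
# mean, so systematic underestimation gives a negative Z.
wilcoxon_signed_rank_z <- function(d) {
  d <- d[d != 0]
  m <- length(d)
  if (m == 0L) return(list(statistic = 0, p = 1))
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  mu <- m * (m + 1) / 4
  tie_tab <- table(r)
  sigma2 <- m * (m + 1) * (2 * m + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  if (sigma2 <= 0) return(list(statistic = 0, p = 1))
  z <- (w_pos - mu) / sqrt(sigma2)
  list(statistic = z, p = 2 * pnorm(-abs(z)))
}

#' Normality-gated paired location test
#'
#' Tests whether the candidate and reference differ in location:
#' Shapiro-Wilk on the paired differences decides the route. Differences
#' compatible with normality (p >= alpha) get a paired t-test;
#' non-normal differences get the Wilcoxon signed-rank test reported as
#' a normal-approximation Z (ties corrected, zeros dropped). All
#' differences exactly zero is a degenerate case returning p = 1.
#'
#' @inheritParams bland_altman
#' @param alpha significance level of the Shapiro-Wilk gate (and of the
#'   study), default 0.05.
#' @return list with `test` (`"paired_t"`, `"wilcoxon"` or
#'   `"degenerate"`), `statistic` (t or Z), `p`, and `shapiro_p`.
#' @export
paired_location_test <- function(x, y, alpha = 0.05) {
  n <- check_paired(x, y)
  d <- x - y
  if (all(d == 0)) {
    return(list(test = "degenerate", statistic = 0, p = 1,
                shapiro_p = NA_real_))
  }
  if (sd(d) == 0) {
    # constant non-zero shift: t statistic diverges
    return(list(test = "paired_t",
                statistic = sign(mean(d)) * Inf, p = 0,
                shapiro_p = NA_real_))
  }
  # shapiro.test accepts 3..5000 observations
  sw <- shapiro.test(if (n > 5000L) d[seq_len(5000L)] else d)
  if (sw$p.value >= alpha) {
    tt <- t.test(x, y, paired = TRUE)
    list(test = "paired_t", statistic = unname(tt$statistic),
         p = tt$p.value, shapiro_p = sw$p.value)
  } else {
    w <- wilcoxon_signed_rank_z(d)
    list(test = "wilcoxon", statistic = w$statistic, p = w$p,
         shapiro_p = sw$p.value)
  }
}

#' Acceptability verdict for a method comparison
#'
#' A candidate method is deemed to agree acceptably with the reference
#' when the typical-error CV is at most `cv_threshold` percent and the
#' absolute-agreement ICC is at least `icc_threshold` — both boundaries
#' inclusive.
#'
#' @param icc intraclass correlation coefficient.
#' @param cv_mean mean typical-error CV in percent.
#' @param icc_threshold,cv_threshold verdict thresholds, defaults 0.8
#'   and 10.
#' @return `"acceptable"` or `"unacceptable"`.
#' @examples
#' verdict(0.858, 8.8)    # acceptable
#' verdict(0.793, 12.6)   # unacceptable
#' @export
verdict <- function(icc, cv_mean, icc_threshold = 0.8, cv_threshold = 10) {
  check_number(icc, "icc")
  check_number(cv_mean, "cv_mean")
  ifelse(icc >= icc_threshold & cv_mean <= cv_threshold,
         "acceptable", "unacceptable")
}

#' Regression of predicted lean mass on maturity offset
#'
#' Ordinary least squares of lean mass (kg) on the continuous maturity
#' offset (years post-PHV), quantifying how much somatic maturity alone
#' explains of an equation's lean-mass prediction.
#'
#' @param lm_kg predicted lean mass, kg, one value per subject.
#' @param offset maturity offset in years, same length.
#' @return list with `slope` (kg per year post-PHV), `intercept`, `r2`,
#'   `r2_adj`, `f` with `df1`/`df2` (1, n - 2), `p`, `n`.
#' @export
lm_maturity_regression <- function(lm_kg, offset) {
  n <- check_paired(lm_kg, offset)
  if (var(offset) == 0) {
    stop_input("maturity offsets are all equal; regression is undefined")
  }
  fit <- lm(lm_kg ~ offset)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  list(slope = unname(coef(fit)[2L]),
       intercept = unname(coef(fit)[1L]),
       r2 = sm$r.squared,
       r2_adj = sm$adj.r.squared,
       f = unname(fstat[1L]),
       df1 = unname(fstat[2L]),
       df2 = unname(fstat[3L]),
       p = unname(pf(fstat[1L], fstat[2L], fstat[3L],
                     lower.tail = FALSE)),
       n = n)
}

#' Post hoc power of a two-tailed paired t-test
#'
#' Exact noncentral-t power for a paired design: the differences have
#' standardised effect `d`, the test statistic is noncentral t with
#' `n - 1` degrees of freedom and noncentrality `d * sqrt(n)`.
#'
#' @param d standardised effect size (mean difference over SD of
#'   differences), positive.
#' @param n number of pairs, at least 2.
#' @param alpha two-tailed significance level, default 0.05.
#' @return power in (0, 1).
#' @examples
#' power_paired_t(0.78, 25)
#' @export
power_paired_t <- function(d, n, alpha = 0.05) {
  check_number(d, "d", lower = 0, strict_lower = TRUE)
  check_number(n, "n", lower = 2)
  check_number(alpha, "alpha", lower = 0, upper = 1,
               strict_lower = TRUE)
  if (alpha >= 1) stop_input("alpha must lie in (0, 1)")
  df <- n - 1
  ncp <- d * sqrt(n)
  tcrit <- qt(1 - alpha / 2, df)
  pt(-tcrit, df, ncp = ncp) + pt(tcrit, df, ncp = ncp,
                                 lower.tail = FALSE)
}

#' Full agreement report for one method comparison
#'
#' Bundles every validity statistic for one candidate-vs-reference
#' comparison into a single row: ICC, typical-error CV, Bland-Altman
#' bias and limits of agreement, absolute percent difference, Cohen's d
#' with band, the normality-gated location test, and the acceptability
#' verdict.
#'
#' @inheritParams bland_altman
#' @param equation,outcome labels for the comparison (e.g. `"oliver"`,
#'   `"fm"`).
#' @param alpha significance level for the location test gate.
#' @param icc_threshold,cv_threshold verdict thresholds.
#' @return one-row data.frame with columns `equation`, `outcome`, `n`,
#'   `icc`, `cv_mean`, `cv_sd`, `bias`, `sd_diff`, `loa_lower`,
#'   `loa_upper`, `pct_diff_mean`, `pct_diff_sd`, `effect_size`,
#'   `es_band`, `test`, `statistic`, `p`, `verdict`.
#' @export
agreement_report <- function(x, y, equation = "candidate",
                             outcome = "value", alpha = 0.05,
                             icc_threshold = 0.8, cv_threshold = 10) {
  n <- check_paired(x, y)
  ba <- bland_altman(x, y)
  cv <- typical_error_cv(x, y)
  icc <- icc_a1(cbind(x, y))
  pd <- percent_diff(x, y)
  es <- cohens_d(x, y)
  lt <- paired_location_test(x, y, alpha = alpha)
  data.frame(
    equation = equation, outcome = outcome, n = n,
    icc = icc, cv_mean = cv$cv_mean, cv_sd = cv$cv_sd,
    bias = ba$bias, sd_diff = ba$sd_diff,
    loa_lower = ba$loa_lower, loa_upper = ba$loa_upper,
    pct_diff_mean = pd$mean, pct_diff_sd = pd$sd,
    effect_size = es$d, es_band = es$band,
    test = lt$test, statistic = lt$statistic, p = lt$p,
    verdict = verdict(icc, cv$cv_mean, icc_threshold, cv_threshold),
    stringsAsFactors = FALSE
  )
}
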