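# Method-agreement battery: test-retest ICC with F-based CI, paired t,
# Shapiro-Wilk, Pearson + linear regression, Bland-Altman limits of
# agreement. Significance level defaults to 0.05 throughout.

as_session_matrix <- function(data) {
  if (is.data.frame(data) && all(c("subject", "session", "value") %in% names(data))) {
    wide <- tidyr::pivot_wider(data[c("subject", "session", "value")],
                               names_from = "session", values_from = "value")
    m <- as.matrix(wide[-1])
  } else {
    m <- as.matrix(data)
  }
  storage.mode(m) <- "double"
  if (anyNA(m)) abort("missing cells: the ICC design must be complete")
  m
}

#' Test-retest intraclass correlation coefficient
#'
#' ICC for an n-subjects by k-sessions complete table from the two-way ANOVA
#' mean squares. The default model is ICC(2,1) — two-way random effects,
#' absolute agreement, single measurement — the standard test-retest form;
#' ICC(3,1) (two-way mixed, consistency) is available. The 95% confidence
#' interval uses the F-distribution bounds of Shrout & Fleiss (1979) /
#' McGraw & Wong (1996).
#'
#' @param data n x k numeric matrix/data frame (subjects x sessions), or a
#'   long data frame with columns `subject`, `session`, `value`. n >= 3,
#'   no missing cells.
#' @param model `"ICC2"` (absolute agreement, default) or `"ICC3"`
#'   (consistency).
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble: `icc`, `conf_low`, `conf_high`, `model`
#'   (spelled-out name so the choice is auditable), `n`, `k`, and the mean
#'   squares `MSR`, `MSC`, `MSE`.
#' @examples
#' set.seed(1)
#' subj <- rnorm(10, 50, 10)
#' icc_test_retest(cbind(subj + rnorm(10), subj + rnorm(10)))
#' @export
icc_test_retest <- function(data, model = c("ICC2", "ICC3"), conf_level = 0.95) {
  model <- match.arg(model)
  m <- as_session_matrix(data)
  n <- nrow(m); k <- ncol(m)
  if (n < 3) abort("ICC needs at least 3 subjects")
  if (k < 2) abort("ICC needs at least 2 sessions")
  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  SSR <- k * sum((row_means - grand)^2)       # between subjects
  SSC <- n * sum((col_means - grand)^2)       # between sessions
  SST <- sum((m - grand)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  if (SST < 1e-24) abort("zero total variance: ICC is undefined")
  alpha <- 1 - conf_level
  if (model == "ICC2") {
    icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
    Fj <- MSC / MSE
    vn <- (k - 1) * (n - 1) *
      (k * icc * Fj + n * (1 + (k - 1) * icc) - k * icc)^2
    vd <- (n - 1) * k^2 * icc^2 * Fj^2 + (n * (1 + (k - 1) * icc) - k * icc)^2
    v <- vn / vd
    f_u <- stats::qf(1 - alpha / 2, n - 1, v)
    f_l <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (MSR - f_u * MSE) / (f_u * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
    hi <- n * (f_l * MSR - MSE) / (k * MSC + (k * n - k - n) * MSE + n * f_l * MSR)
    label <- "ICC(2,1): two-way random effects, absolute agreement, single measurement"
  } else {
    icc <- (MSR - MSE) / (MSR + (k - 1) * MSE)
    F0 <- MSR / MSE
    f_u <- stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    f_l <- stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    lo <- (F0 / f_u - 1) / (F0 / f_u + k - 1)
    hi <- (F0 * f_l - 1) / (F0 * f_l + k - 1)
    label <- "ICC(3,1): two-way mixed effects, consistency, single measurement"
  }
  tibble(icc = icc, conf_low = lo, conf_high = hi, model = label,
         n = n, k = k, MSR = MSR, MSC = MSC, MSE = MSE)
}

#' Paired t-test between two measurement methods
#'
#' Two-sided paired t-test (wrapper over the standard routine with explicit
#' preconditions: equal lengths >= 2, nonzero difference variance).
#'
#' @param a,b Equal-length numeric vectors of paired measurements.
#' @return One-row tibble: `t_stat`, `df`, `p_value`, `mean_diff`.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) abort("paired vectors must have equal length")
  if (length(a) < 2) abort("paired t-test needs at least 2 pairs")
  d <- a - b
  if (stats::var(d) == 0) abort("zero difference variance: paired t is undefined")
  tt <- stats::t.test(a, b, paired = TRUE)
  tibble(t_stat = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, mean_diff = unname(tt$estimate))
}

#' Bland-Altman limits of agreement
#'
#' Differences `d = a - b`; bias is `mean(d)`; the 95% limits of agreement
#' are `bias +/- 1.96 * sd(d)`; `outside_count` counts differences outside
#' the limits.
#'
#' @param a,b Equal-length numeric vectors (>= 2).
#' @param loa_multiplier Limits-of-agreement multiplier (conventional 1.96).
#' @return An object of class `bland_altman`: one-row `summary` tibble
#'   (`bias`, `loa_low`, `loa_high`, `sd_diff`, `outside_count`, `n`) and
#'   per-pair `data` (`mean`, `diff`) for plotting.
#' @export
bland_altman <- function(a, b, loa_multiplier = 1.96) {
  if (length(a) != length(b)) abort("paired vectors must have equal length")
  if (length(a) < 2) abort("Bland-Altman needs at least 2 pairs")
  d <- a - b
  bias <- mean(d)
  s <- stats::sd(d)
  lo <- bias - loa_multiplier * s
  hi <- bias + loa_multiplier * s
  structure(
    list(summary = tibble(bias = bias, loa_low = lo, loa_high = hi, sd_diff = s,
                          outside_count = sum(d < lo | d > hi), n = length(d)),
         data = tibble(mean = (a + b) / 2, diff = d)),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<bland_altman> bias %.4g, LoA [%.4g, %.4g], %d/%d outside\n",
              s$bias, s$loa_low, s$loa_high, s$outside_count, s$n))
  invisible(x)
}

#' Pearson correlation and linear regression between two methods
#'
#' @param a,b Equal-length numeric vectors (>= 3) with nonzero variance.
#' @return One-row tibble: `pearson_r`, `p_value`, `slope`, `intercept`,
#'   `r_squared` (= r^2; regression of `b` on `a`).
#' @export
pearson_and_regression <- function(a, b) {
  if (length(a) != length(b)) abort("vectors must have equal length")
  if (length(a) < 3) abort("correlation needs at least 3 pairs")
  if (stats::var(a) == 0 || stats::var(b) == 0) abort("zero variance: correlation is undefined")
  ct <- stats::cor.test(a, b, method = "pearson")
  fit <- stats::lm(b ~ a)
  r <- unname(ct$estimate)
  tibble(pearson_r = r, p_value = ct$p.value,
         slope = unname(stats::coef(fit)[2]), intercept = unname(stats::coef(fit)[1]),
         r_squared = r^2)
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper over the standard Shapiro-Wilk routine with explicit range
#' checks (3 <= n <= 5000) and a clear error for constant input.
#'
#' @param x Numeric vector.
#' @return One-row tibble: `W`, `p_value`, `n`.
#' @export
shapiro_wilk <- function(x) {
  n <- length(x)
  if (n < 3 || n > 5000) abort("Shapiro-Wilk needs 3 <= n <= 5000")
  if (stats::var(x) == 0) abort("constant input: Shapiro-Wilk is undefined")
  sw <- stats::shapiro.test(x)
  tibble(W = unname(sw$statistic), p_value = sw$p.value, n = n)
}

#' Full method-agreement battery between two measurement methods
#'
#' Runs the validity battery comparing paired per-subject measurements from
#' two methods: Shapiro-Wilk normality of the paired differences, two-sided
#' paired t, Pearson correlation with linear regression, and Bland-Altman
#' limits of agreement.
#'
#' @param a,b Equal-length numeric vectors (one value per subject and
#'   method).
#' @param alpha Significance level (default 0.05).
#' @return An object of class `agreement_result` with elements `shapiro`,
#'   `paired_t`, `pearson`, `bland_altman`, `alpha`, `n`. Use
#'   [generics::tidy()] / [generics::glance()] for tabular views and
#'   [ggplot2::autoplot()] for the Bland-Altman plot.
#' @export
method_agreement <- function(a, b, alpha = 0.05) {
  structure(
    list(shapiro = shapiro_wilk(a - b),
         paired_t = paired_t(a, b),
         pearson = pearson_and_regression(a, b),
         bland_altman = bland_altman(a, b),
         alpha = alpha, n = length(a)),
    class = "agreement_result"
  )
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("<agreement_result> n = %d, alpha = %g\n", x$n, x$alpha))
  print(glance(x))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an agreement battery
#'
#' @param x An `agreement_result`.
#' @param ... Unused.
#' @return `tidy()`: long tibble `statistic`, `value`. `glance()`: one-row
#'   tibble with the headline quantities.
#' @export
tidy.agreement_result <- function(x, ...) {
  s <- glance(x)
  tibble(statistic = names(s), value = as.numeric(s[1, ]))
}

#' @rdname tidy.agreement_result
#' @export
glance.agreement_result <- function(x, ...) {
  ba <- x$bland_altman$summary
  tibble(
    shapiro_W = x$shapiro$W, shapiro_p = x$shapiro$p_value,
    t_stat = x$paired_t$t_stat, t_p = x$paired_t$p_value,
    pearson_r = x$pearson$pearson_r, pearson_p = x$pearson$p_value,
    slope = x$pearson$slope, intercept = x$pearson$intercept,
    r_squared = x$pearson$r_squared,
    bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high,
    outside_count = ba$outside_count
  )
}
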