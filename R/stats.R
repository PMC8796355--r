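#' Pearson correlation with simple linear regression
#'
#' The cohort analysis pairs every Pearson coefficient with an ordinary
#' least-squares fit of `y` on `x`; for simple regression the coefficient of
#' determination equals the squared correlation identically, which the
#' returned object preserves exactly.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A list of class `cc_stats`: `pearson_r`, `p_value`, `r_squared`,
#'   `slope`, `intercept`, `n`.
#' @export
pearson_regression <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  if (length(x) < 3) stop("need at least 3 paired observations",
                          call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  fit <- lm(y ~ x)
  r <- unname(ct$estimate)
  structure(list(pearson_r = r,
                 p_value = ct$p.value,
                 r_squared = r^2,
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 n = length(x)),
            class = "cc_stats")
}

#' One-sample Kolmogorov-Smirnov normality screen
#'
#' Tests the sample against a normal distribution with the sample mean and
#' SD.  Note the classical caveat: with estimated parameters the K-S
#' p-value is conservative (the Lilliefors correction is deliberately NOT
#' applied, since the analysis protocol names the plain K-S test); treat
#' small p as strong evidence of non-normality, large p as weak evidence
#' only.
#'
#' @param x Numeric vector, n >= 5.
#' @return List with `statistic` (between 0 and 1) and `p_value`.
#' @export
ks_normality <- function(x) {
  if (length(x) < 5) stop("need at least 5 observations", call. = FALSE)
  if (sd(x) == 0) stop("zero variance: distribution test undefined",
                       call. = FALSE)
  kt <- suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x)))
  list(statistic = unname(kt$statistic), p_value = kt$p.value)
}

#' Welch two-sample comparison
#'
#' Welch's unequal-variance t test (two-sided).  Two degenerate samples with
#' equal means return `p = 1` by convention rather than erroring.
#'
#' @param x,y Numeric vectors, each n >= 2.
#' @return List with `t`, `df`, `p_value`, group means.
#' @export
welch_two_sample <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  if (sd(x) == 0 && sd(y) == 0) {
    if (mean(x) == mean(y)) {
      return(list(t = 0, df = length(x) + length(y) - 2, p_value = 1,
                  mean_x = mean(x), mean_y = mean(y)))
    }
    stop("both groups are constant with different means: t undefined",
         call. = FALSE)
  }
  tt <- t.test(x, y, var.equal = FALSE, alternative = "two.sided")
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_x = mean(x), mean_y = mean(y))
}

#' Cohort summary table and correlation matrix
#'
#' Reproduces the cohort analysis stage: per-variable mean, SD, observed
#' range and the mean +- 1.96 SD/sqrt(n) interval (all three interval types
#' are reported and labelled rather than conflated); all pairwise Pearson /
#' R-squared cells among the five uncoverage ratios, acetabular height, A-P
#' diameter and volume proxy, with p-value flags at 0.05 and 0.01; and a
#' two-group split of the cohort at a TUCR threshold (default 0.3) with a
#' Welch comparison of height and A-P diameter between the groups.  No
#' multiple-testing adjustment is applied (flagged in the footer), matching
#' the protocol being emulated.  Pairs with zero variance are reported as
#' not applicable rather than erroring.
#'
#' @param records Data frame with columns `asucr`, `aiucr`, `psucr`,
#'   `piucr`, `tucr`, `height_mm`, `ap_diameter_mm`, `volume_proxy_mm3`
#'   (one row per hip, e.g. from [run_pipeline()]).
#' @param group_split_tucr TUCR threshold for the two-group comparison.
#' @param alpha Significance level (two-tailed), default 0.05.
#' @return A list of class `cc_summary`: `variables` (moments table),
#'   `correlations` (long-format pairwise table), `groups` (split counts
#'   and Welch results), `footer`.
#' @export
cohort_summary <- function(records, group_split_tucr = 0.3, alpha = 0.05) {
  vars <- c("asucr", "aiucr", "psucr", "piucr", "tucr",
            "height_mm", "ap_diameter_mm", "volume_proxy_mm3")
  missing <- setdiff(vars, names(records))
  if (length(missing) > 0) {
    stop("records lack columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(records) < 1) stop("empty cohort", call. = FALSE)
  n <- nrow(records)

  variables <- do.call(rbind, lapply(vars, function(v) {
    x <- records[[v]]
    data.frame(variable = v, n = n, mean = mean(x), sd = sd(x),
               min = min(x), max = max(x),
               sem_lo = mean(x) - 1.96 * sd(x) / sqrt(n),
               sem_hi = mean(x) + 1.96 * sd(x) / sqrt(n),
               spread_lo = mean(x) - 1.96 * sd(x),
               spread_hi = mean(x) + 1.96 * sd(x))
  }))

  pairs <- t(combn(vars, 2))
  correlations <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(k) {
    vx <- pairs[k, 1]; vy <- pairs[k, 2]
    x <- records[[vx]]; y <- records[[vy]]
    if (n < 3 || sd(x) == 0 || sd(y) == 0) {
      return(data.frame(var_x = vx, var_y = vy, pearson_r = NA_real_,
                        r_squared = NA_real_, p_value = NA_real_,
                        slope = NA_real_, intercept = NA_real_,
                        flag = "n/a"))
    }
    st <- pearson_regression(x, y)
    flag <- if (st$p_value < 0.01) "**" else if (st$p_value < alpha) "*"
            else ""
    data.frame(var_x = vx, var_y = vy, pearson_r = st$pearson_r,
               r_squared = st$r_squared, p_value = st$p_value,
               slope = st$slope, intercept = st$intercept, flag = flag)
  }))

  hi <- records$tucr > group_split_tucr
  groups <- list(threshold = group_split_tucr,
                 n_above = sum(hi), n_below = sum(!hi))
  if (sum(hi) >= 2 && sum(!hi) >= 2) {
    groups$height_welch <- welch_two_sample(records$height_mm[hi],
                                            records$height_mm[!hi])
    groups$ap_welch <- welch_two_sample(records$ap_diameter_mm[hi],
                                        records$ap_diameter_mm[!hi])
  } else {
    groups$height_welch <- groups$ap_welch <- NULL
  }

  structure(list(variables = variables, correlations = correlations,
                 groups = groups, alpha = alpha,
                 footer = paste("two-tailed tests at alpha =", alpha,
                                "- no multiple-testing adjustment applied")),
            class = "cc_summary")
}

#' @importFrom utils combn
NULL
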