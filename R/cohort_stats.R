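stat_result <- function(method, estimate, p_value, n, adjusted_for = character()) {
  list(method = method, estimate = estimate, p_value = p_value,
       p_fdr = NA_real_, n = as.integer(n), adjusted_for = adjusted_for)
}

midrank <- function(x) rank(x, ties.method = "average")

#' Spearman rank correlation
#'
#' Rho computed on midranks; two-sided p-value from the t approximation with
#' n - 2 degrees of freedom.
#'
#' @param x,y Paired numeric vectors; incomplete pairs are dropped.
#' @return A stat-result list (`method`, `estimate`, `p_value`, `n`, ...).
#'   `estimate` is `NA` when either vector is constant.
#' @export
spearman <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4) stop("spearman: need at least 4 complete pairs", call. = FALSE)
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    return(stat_result("spearman", NA_real_, NA_real_, n))
  }
  rho <- cor(midrank(x), midrank(y))
  p <- p_from_r(rho, df = n - 2)
  stat_result("spearman", rho, p, n)
}

p_from_r <- function(r, df) {
  if (!is.finite(r) || df < 1) return(NA_real_)
  if (abs(r) >= 1) return(0)
  tval <- r * sqrt(df / (1 - r^2))
  2 * pt(-abs(tval), df)
}

#' Partial Spearman correlation adjusting for one covariate
#'
#' All three variables are midrank-transformed; the ranks of x and y are
#' residualised on the ranks of z by ordinary least squares and the Pearson
#' correlation of the residuals is returned, with a two-sided p from the t
#' distribution on n - 3 degrees of freedom. This is the rank partial
#' correlation used throughout the gestational-age-adjusted analyses.
#'
#' @param x,y Paired numeric vectors.
#' @param z Covariate vector (gestational age in the cohort analyses).
#' @return A stat-result list with `adjusted_for = "z"`. When z is constant
#'   the plain [spearman()] result is returned with a warning.
#' @export
partial_spearman <- function(x, y, z) {
  keep <- is.finite(x) & is.finite(y) & is.finite(z)
  x <- x[keep]; y <- y[keep]; z <- z[keep]
  n <- length(x)
  if (n < 5) {
    stop("partial_spearman: need at least 5 complete triples", call. = FALSE)
  }
  if (length(unique(z)) < 2) {
    warning("partial_spearman: covariate is constant; falling back to spearman",
            call. = FALSE)
    return(spearman(x, y))
  }
  rx <- midrank(x); ry <- midrank(y); rz <- midrank(z)
  ex <- stats::lm.fit(cbind(1, rz), rx)$residuals
  ey <- stats::lm.fit(cbind(1, rz), ry)$residuals
  if (sd(ex) == 0 || sd(ey) == 0) {
    return(stat_result("partial_spearman", NA_real_, NA_real_, n, "z"))
  }
  rho <- cor(ex, ey)
  p <- p_from_r(rho, df = n - 3)
  stat_result("partial_spearman", rho, p, n, adjusted_for = "z")
}

#' ANCOVA group comparison with estimated marginal means
#'
#' Fits metric = b0 + b1 * group + b2 * covariate by ordinary least squares
#' and tests the group coefficient (two-sided t test, equivalent to the
#' 1-df F test). Estimated marginal means are the model predictions for each
#' group at the pooled covariate mean, with standard errors from the
#' coefficient covariance.
#'
#' @param table Cohort data.frame with a `group` column (control/CHD).
#' @param metric Name of the response column.
#' @param covariate Name of the covariate column (default `"ga_weeks"`).
#' @return List with `stat` (a stat-result; `estimate` is the CHD - control
#'   adjusted difference) and `emm` (per-group adjusted means, SEs, and the
#'   covariate value used).
#' @export
ancova_group <- function(table, metric, covariate = "ga_weeks") {
  df <- data.frame(y = table[[metric]],
                   group = factor(table$group, levels = c("control", "CHD")),
                   cov = table[[covariate]])
  df <- df[complete.cases(df), ]
  if (nlevels(droplevels(df$group)) < 2) {
    stop("ancova_group: both groups must be present", call. = FALSE)
  }
  fit <- lm(y ~ group + cov, data = df)
  if (any(is.na(coef(fit)))) {
    stop("ancova_group: singular design", call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  b1 <- sm["groupCHD", ]
  cov_at <- mean(df$cov)
  V <- vcov(fit)
  # EMMs: prediction at the shared covariate mean for each group
  x_control <- c(1, 0, cov_at)
  x_chd <- c(1, 1, cov_at)
  means <- c(control = sum(x_control * coef(fit)),
             CHD = sum(x_chd * coef(fit)))
  ses <- c(control = sqrt(drop(t(x_control) %*% V %*% x_control)),
           CHD = sqrt(drop(t(x_chd) %*% V %*% x_chd)))
  list(
    stat = stat_result("ancova", unname(b1["Estimate"]),
                       unname(b1["Pr(>|t|)"]), nrow(df),
                       adjusted_for = covariate),
    emm = list(group_means = means, se = ses, covariate_at = cov_at,
               diff_se = unname(b1["Std. Error"]))
  )
}

#' One-way ANOVA group comparison (no covariate)
#'
#' @param table Cohort data.frame.
#' @param metric Response column name.
#' @return Stat-result; `estimate` is the CHD - control mean difference and
#'   `p_value` the two-group F/t test p.
#' @export
anova_group <- function(table, metric) {
  df <- data.frame(y = table[[metric]],
                   group = factor(table$group, levels = c("control", "CHD")))
  df <- df[complete.cases(df), ]
  if (nlevels(droplevels(df$group)) < 2) {
    stop("anova_group: both groups must be present", call. = FALSE)
  }
  fit <- lm(y ~ group, data = df)
  sm <- summary(fit)$coefficients
  stat_result("anova", unname(sm["groupCHD", "Estimate"]),
              unname(sm["groupCHD", "Pr(>|t|)"]), nrow(df))
}

#' Group-by-predictor interaction test
#'
#' Fits y = b0 + b1 x + b2 group + b3 (x * group) and reports the
#' interaction coefficient b3 (raw, on the scale of y per unit x) with its
#' two-sided p-value; used to ask whether the slope of one organ metric on
#' another differs between groups.
#'
#' @param table Cohort data.frame.
#' @param y,x Response and predictor column names.
#' @return Stat-result for the interaction coefficient.
#' @export
interaction_test <- function(table, y, x) {
  df <- data.frame(y = table[[y]], x = table[[x]],
                   group = factor(table$group, levels = c("control", "CHD")))
  df <- df[complete.cases(df), ]
  if (nlevels(droplevels(df$group)) < 2) {
    stop("interaction_test: group indicator is constant", call. = FALSE)
  }
  fit <- lm(y ~ x * group, data = df)
  if (any(is.na(coef(fit)))) {
    stop("interaction_test: singular design", call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  stat_result("interaction", unname(sm["x:groupCHD", "Estimate"]),
              unname(sm["x:groupCHD", "Pr(>|t|)"]), nrow(df))
}

#' Mann-Whitney U test
#'
#' Two-sided; exact enumeration of the rank-sum distribution when the
#' combined sample size is at most 12 and there are no ties, otherwise the
#' normal approximation with tie correction.
#'
#' @param x,y Numeric samples.
#' @return Stat-result; `estimate` is the U statistic for `x`.
#' @export
mann_whitney <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (!length(x) || !length(y)) {
    stop("mann_whitney: both samples must be non-empty", call. = FALSE)
  }
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- (length(x) + length(y)) <= 12 && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = use_exact, correct = !use_exact)
  )
  stat_result("mann_whitney", unname(wt$statistic), wt$p.value,
              length(x) + length(y))
}

#' Shapiro-Wilk reporting gate
#'
#' Decides between parametric (mean +/- SD) and nonparametric (median, IQR)
#' reporting at alpha = 0.05. Degenerate samples (n < 3 or constant) default
#' to nonparametric.
#'
#' @param x Numeric sample.
#' @param alpha Significance level for the normality test.
#' @return `"parametric"` or `"nonparametric"`.
#' @export
shapiro_gate <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  if (length(x) < 3 || length(unique(x)) < 2) return("nonparametric")
  p <- shapiro.test(x)$p.value
  if (p < alpha) "nonparametric" else "parametric"
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone, clipped at 1, returned in input
#' order).
#'
#' @param p Vector of p-values in [0, 1]; NA entries are passed through.
#' @return Adjusted p-values.
#' @export
bh_fdr <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    stop("bh_fdr: p-values must lie in [0, 1]", call. = FALSE)
  }
  out <- rep(NA_real_, length(p))
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}
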