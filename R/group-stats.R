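#' Container for one statistical test result
#'
#' @param test_name Label of the test.
#' @param statistic Test statistic.
#' @param df Degrees of freedom (scalar or length-2).
#' @param p_value Uncorrected p-value.
#' @param effect_size Cohen's d, partial eta squared, or rho; `NA` if not
#'   defined.
#' @param n Number of observations.
#' @param correction `"none"` or `"bonferroni"`.
#' @param m Bonferroni family size (number of tests), if corrected.
#' @param tails 1 or 2.
#' @return A list with class `"stat_result"`; `p_corrected` is
#'   `min(1, m * p)` when corrected, else equal to `p_value`.
#' @export
stat_result <- function(test_name, statistic, df, p_value,
                        effect_size = NA_real_, n = NA_integer_,
                        correction = c("none", "bonferroni"), m = 1L,
                        tails = 2L) {
  correction <- match.arg(correction)
  if (!is.na(p_value) && (p_value < 0 || p_value > 1)) {
    stop_param("p_value out of [0, 1]")
  }
  p_corr <- if (correction == "bonferroni") min(1, m * p_value) else p_value
  structure(list(test_name = test_name, statistic = statistic, df = df,
                 p_value = p_value, p_corrected = p_corr,
                 effect_size = effect_size, n = n,
                 correction = correction, m = as.integer(m),
                 tails = as.integer(tails)),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  df <- paste(format(x$df, digits = 4), collapse = ",")
  cat(sprintf("%s: stat = %.4g, df = %s, p = %.4g", x$test_name,
              x$statistic, df, x$p_value))
  if (x$correction != "none") {
    cat(sprintf(" (%s m=%d: p = %.4g)", x$correction, x$m, x$p_corrected))
  }
  if (!is.na(x$effect_size)) cat(sprintf(", effect = %.4g", x$effect_size))
  cat("\n")
  invisible(x)
}

#' t-test (one-sample, paired, or pooled two-sample)
#'
#' Two-sample tests use the pooled-variance (equal variance) form with
#' `df = n1 + n2 - 2`, the convention matching a 20 + 20 design's df of 38.
#' Effect size is Cohen's d (mean difference over pooled SD; over the SD of
#' differences when paired; over the sample SD for one-sample tests).
#'
#' @param x Numeric sample.
#' @param y Second sample (two-sample/paired) or `NULL`.
#' @param mu Null value for the one-sample test.
#' @param paired Treat `x`, `y` as paired.
#' @param test_name Label for the result.
#' @return A [stat_result()].
#' @export
t_test_stat <- function(x, y = NULL, mu = 0, paired = FALSE,
                        test_name = "t-test") {
  if (paired) {
    if (is.null(y) || length(y) != length(x)) {
      stop_param("paired test needs samples of equal length")
    }
    return(t_test_stat(x - y, mu = 0, test_name = test_name))
  }
  if (is.null(y)) {
    n <- length(x)
    if (n < 2L) stop_param("need >= 2 observations")
    s <- sd(x)
    if (s == 0) {
      if (mean(x) == mu) stop_param("zero variance with mean equal to null")
      s <- .Machine$double.eps
    }
    tval <- (mean(x) - mu) / (s / sqrt(n))
    df <- n - 1
    d <- (mean(x) - mu) / s
    ntot <- n
  } else {
    n1 <- length(x); n2 <- length(y)
    if (n1 < 2L || n2 < 2L) stop_param("need >= 2 observations per sample")
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / df
    if (sp2 == 0) {
      if (mean(x) == mean(y)) stop_param("zero variance with equal means")
      sp2 <- .Machine$double.eps
    }
    tval <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    d <- (mean(x) - mean(y)) / sqrt(sp2)
    ntot <- n1 + n2
  }
  p <- 2 * pt(-abs(tval), df)
  stat_result(test_name, tval, df, p, effect_size = d, n = ntot)
}

#' Exact two-sided sign test
#'
#' Binomial test of `k` successes in `n` trials against p = 0.5, two-sided
#' by tail doubling: `p = min(1, 2 * min(P(X <= k), P(X >= k)))`, both tails
#' computed by exact enumeration of binomial probabilities.
#'
#' @param k Number of successes, `0 <= k <= n`.
#' @param n Number of trials, >= 1.
#' @return A [stat_result()] with `statistic = k` and
#'   `effect_size = k / n`.
#' @examples
#' sign_test_exact(29, 40)  # p = 0.006 to 3 d.p.
#' @export
sign_test_exact <- function(k, n) {
  if (n < 1 || k < 0 || k > n) stop_param("need 0 <= k <= n, n >= 1")
  lower <- sum(dbinom(0:k, n, 0.5))
  upper <- sum(dbinom(k:n, n, 0.5))
  p <- min(1, 2 * min(lower, upper))
  stat_result("exact sign test", k, NA_real_, p, effect_size = k / n, n = n)
}

#' Spearman rank correlation
#'
#' rho is the Pearson correlation of mid-ranks (average ranks for ties);
#' the p-value uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` df (exact permutation
#' p-values are not implemented). At `|rho| = 1` the statistic is infinite
#' and p is reported as 0.
#'
#' @param x,y Numeric vectors, `n >= 4`, neither constant.
#' @param test_name Label for the result.
#' @return A [stat_result()] with `statistic = rho` and `effect_size = rho`.
#' @export
spearman_test <- function(x, y, test_name = "Spearman correlation") {
  n <- length(x)
  if (n < 4L || length(y) != n) {
    stop_param("need paired vectors with n >= 4")
  }
  if (var(x) == 0 || var(y) == 0) stop_param("constant vector")
  rho <- cor(rank(x), rank(y))
  df <- n - 2
  if (abs(rho) >= 1 - 1e-15) {
    p <- 0
  } else {
    tval <- rho * sqrt(df / (1 - rho^2))
    p <- 2 * pt(-abs(tval), df)
  }
  stat_result(test_name, rho, df, p, effect_size = rho, n = n)
}

#' Partial Spearman correlation
#'
#' Rank-transforms `x`, `y` and each covariate, residualizes the ranks of
#' `x` and `y` on the covariate ranks by least squares (with intercept), and
#' correlates the residuals (Pearson). Degrees of freedom are reduced by the
#' number of covariates: `df = n - k - 2`.
#'
#' @param x,y Numeric vectors.
#' @param covariates Numeric vector, matrix, or data frame of covariates.
#' @param test_name Label for the result.
#' @return A [stat_result()].
#' @export
partial_spearman <- function(x, y, covariates,
                             test_name = "partial Spearman") {
  z <- as.matrix(as.data.frame(covariates))
  n <- length(x)
  k <- ncol(z)
  if (length(y) != n || nrow(z) != n) stop_param("length mismatch")
  if (n <= k + 3) stop_param("need n > #covariates + 3")
  zr <- apply(z, 2, rank)
  design <- cbind(1, zr)
  if (qr(design)$rank < ncol(design)) stop_param("collinear covariates")
  rx <- lm.fit(design, rank(x))$residuals
  ry <- lm.fit(design, rank(y))$residuals
  # residuals of an exactly-explained variable are rounding noise, not 0
  if (var(rx) <= 1e-16 * var(rank(x)) || var(ry) <= 1e-16 * var(rank(y))) {
    stop_param("a variable is fully explained by the covariates")
  }
  rho <- cor(rx, ry)
  df <- n - k - 2
  if (abs(rho) >= 1 - 1e-15) {
    p <- 0
  } else {
    tval <- rho * sqrt(df / (1 - rho^2))
    p <- 2 * pt(-abs(tval), df)
  }
  stat_result(test_name, rho, df, p, effect_size = rho, n = n)
}

#' Two-group ANCOVA with type-III sums of squares
#'
#' Fits `value ~ group + covariate + group:covariate` with effects coding
#' (+1/-1) on group. Each effect's type-III sum of squares is the RSS
#' increase from deleting its column from the full design; F is tested on
#' (1, n - 4) df and the effect size is partial eta squared
#' `SS_effect / (SS_effect + SS_error)`.
#'
#' The covariate is mean-centred by default so that the group main effect is
#' evaluated at the average covariate value (the conventional ANCOVA
#' reading); centring does not change the interaction test.
#'
#' @param values Numeric response.
#' @param group Two-level grouping vector, each level with >= 3 cases.
#' @param covariate Numeric nuisance covariate.
#' @param center_covariate Mean-centre the covariate (default `TRUE`).
#' @return A named list of three [stat_result()]s: `group`, `covariate`,
#'   `interaction`.
#' @export
ancova_type3 <- function(values, group, covariate, center_covariate = TRUE) {
  group <- as.factor(group)
  n <- length(values)
  if (nlevels(group) != 2L) stop_param("exactly two groups required")
  if (any(table(group) < 3L)) stop_param("each group needs >= 3 cases")
  if (length(covariate) != n || length(group) != n) {
    stop_param("length mismatch")
  }
  g <- ifelse(group == levels(group)[1], 1, -1)
  cv <- if (center_covariate) covariate - mean(covariate) else covariate
  X <- cbind(intercept = 1, group = g, covariate = cv, interaction = g * cv)
  if (qr(X)$rank < 4L) stop_param("rank-deficient design")
  full <- lm.fit(X, values)
  rss_full <- sum(full$residuals^2)
  df_err <- n - 4
  ss_tot_effects <- function(col) {
    red <- lm.fit(X[, -col, drop = FALSE], values)
    sum(red$residuals^2) - rss_full
  }
  effects <- c(group = 2L, covariate = 3L, interaction = 4L)
  out <- lapply(names(effects), function(nm) {
    ss <- ss_tot_effects(effects[[nm]])
    f <- (ss / 1) / (rss_full / df_err)
    stat_result(paste0("ANCOVA ", nm), f, c(1, df_err),
                pf(f, 1, df_err, lower.tail = FALSE),
                effect_size = ss / (ss + rss_full), n = n)
  })
  names(out) <- names(effects)
  out
}

#' Bonferroni correction
#'
#' @param p_values Numeric vector of uncorrected p-values.
#' @param m Family size; must be at least the number of tests.
#' @return `pmin(1, m * p_values)`, order-preserving.
#' @export
bonferroni <- function(p_values, m) {
  if (m < length(p_values)) stop_param("family size m < number of tests")
  pmin(1, m * p_values)
}

#' Per-group demographic summary
#'
#' Column means (also rounded to the integer convention of clinical
#' demographic tables), sample SDs and ranges for a subject covariate table.
#'
#' @param covariates Data frame with (at least) the columns in `columns`.
#' @param columns Character vector of required numeric columns.
#' @return A data frame, one row per column: `mean`, `mean_rounded`, `sd`
#'   (`NA` for a single row), `min`, `max`, `n`.
#' @export
table1_summary <- function(covariates,
                           columns = c("age", "duration", "stage",
                                       "updrs_iii", "mmse", "ace_r",
                                       "lde")) {
  missing_cols <- setdiff(columns, names(covariates))
  if (length(missing_cols)) {
    stop_param("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  rows <- lapply(columns, function(cl) {
    x <- covariates[[cl]]
    x <- x[!is.na(x)]
    data.frame(column = cl, n = length(x), mean = mean(x),
               mean_rounded = round(mean(x)),
               sd = if (length(x) >= 2) sd(x) else NA_real_,
               min = min(x), max = max(x), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Packaged patient demographics fixture
#'
#' Loads the demographic table of the 20 Parkinson's disease patients
#' shipped with the package (gender, age, disease duration and stage,
#' UPDRS-III, MMSE, ACE-R, levodopa dose equivalent).
#'
#' @return A data frame with 20 rows.
#' @export
load_table1 <- function() {
  path <- system.file("extdata", "table1_pd_patients.csv",
                      package = "selfprior", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}
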