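#' Bland-Altman agreement analysis
#'
#' Bias and limits of agreement between two paired measurement series.
#' Differences are `first - second`; bias is their mean, the limits of
#' agreement are bias +/- 1.96 SD, the 95% CI of the bias uses SE = SD/sqrt(n)
#' and each limit's CI uses the classical approximation SE = sqrt(3) SD/sqrt(n),
#' both with t quantiles on n - 1 df.
#'
#' @param first,second paired numeric vectors (equal length >= 2).
#' @param conf confidence level (default 0.95).
#' @return object of class `bland_altman`: `n`, `bias`, `sd_diff`,
#'   `loa_lower`, `loa_upper`, `bias_ci`, `loa_lower_ci`, `loa_upper_ci`,
#'   plus `means`/`diffs` for plotting.
#' @export
#' @examples
#' ba <- bland_altman(c(10, 12, 11), c(9, 11, 10))
#' ba$bias  # 1
bland_altman <- function(first, second, conf = 0.95) {
  if (length(first) != length(second)) abort("Paired vectors differ in length.")
  keep <- complete.cases(first, second)
  first <- first[keep]; second <- second[keep]
  n <- length(first)
  if (n < 2) abort("Bland-Altman needs at least 2 complete pairs.")
  d <- first - second
  bias <- mean(d)
  s <- sd(d)
  tq <- qt(1 - (1 - conf) / 2, n - 1)
  loa <- bias + c(-1, 1) * 1.96 * s
  se_bias <- s / sqrt(n)
  se_loa <- sqrt(3) * s / sqrt(n)
  structure(list(
    n = n, bias = bias, sd_diff = s,
    loa_lower = loa[1], loa_upper = loa[2],
    bias_ci = bias + c(-1, 1) * tq * se_bias,
    loa_lower_ci = loa[1] + c(-1, 1) * tq * se_loa,
    loa_upper_ci = loa[2] + c(-1, 1) * tq * se_loa,
    means = (first + second) / 2, diffs = d, conf = conf
  ), class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> n = %d, bias = %.4g [%.4g, %.4g], LoA = [%.4g, %.4g]\n",
              x$n, x$bias, x$bias_ci[1], x$bias_ci[2], x$loa_lower, x$loa_upper))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Rank-sum test with midranks for ties. The reported statistic is
#' U = min(U1, U2). The two-tailed p-value uses exact enumeration of all
#' group assignments (valid under ties) when both groups have <= 8
#' observations, and the tie-corrected normal approximation (no continuity
#' correction) otherwise; `method` can force either.
#'
#' @param a,b numeric vectors (nonempty).
#' @param method `"auto"`, `"exact"`, or `"normal"`.
#' @return object of class `mw_test`: `U`, `p`, `method`, `n1`, `n2`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))$U  # 0
mann_whitney_u <- function(a, b, method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 < 1 || n2 < 1) abort("Both groups must be nonempty.")
  pooled <- c(a, b)
  r <- rank(pooled)  # midranks
  U1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  U2 <- n1 * n2 - U1
  U <- min(U1, U2)
  if (method == "auto") method <- if (max(n1, n2) <= 8) "exact" else "normal"
  if (method == "exact") {
    combos <- utils::combn(n1 + n2, n1)
    u1p <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    minu <- pmin(u1p, n1 * n2 - u1p)
    p <- mean(minu <= U + 1e-9)
  } else {
    N <- n1 + n2
    ties <- table(pooled)
    tiecorr <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tiecorr)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U1 - n1 * n2 / 2) / sqrt(sigma2)
      p <- 2 * pnorm(-abs(z))
    }
  }
  structure(list(U = U, p = min(p, 1), method = method, n1 = n1, n2 = n2),
            class = "mw_test")
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("<mw_test> U = %g, p = %.4g (%s; n = %d vs %d)\n",
              x$U, x$p, x$method, x$n1, x$n2))
  invisible(x)
}

#' Two-tailed t tests
#'
#' Classical Student statistics: `unpaired_t()` pools variances
#' (df = n1 + n2 - 2); `paired_t()` tests the mean pairwise difference
#' (df = n - 1). Degenerate inputs with zero variance are handled by
#' convention: zero mean difference gives t = 0, p = 1 with a flag; a
#' nonzero difference with zero variance gives p = 0 with a flag.
#'
#' @param a,b numeric vectors (equal length for `paired_t`).
#' @return object of class `t_test`: `t`, `df`, `p`, `flag`.
#' @export
unpaired_t <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) abort("Each group needs >= 2 observations.")
  if (var(a) == 0 && var(b) == 0) {
    return(degenerate_t(mean(a) - mean(b), length(a) + length(b) - 2))
  }
  ht <- stats::t.test(a, b, var.equal = TRUE)
  structure(list(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, flag = NA_character_), class = "t_test")
}

#' @rdname unpaired_t
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) abort("Paired vectors differ in length.")
  keep <- complete.cases(a, b)
  d <- (a - b)[keep]
  if (length(d) < 2) abort("Paired t needs >= 2 complete pairs.")
  if (var(d) == 0) return(degenerate_t(mean(d), length(d) - 1))
  ht <- stats::t.test(d)
  structure(list(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, flag = NA_character_), class = "t_test")
}

degenerate_t <- function(mdiff, df) {
  if (mdiff == 0) {
    structure(list(t = 0, df = df, p = 1, flag = "zero_variance_zero_diff"),
              class = "t_test")
  } else {
    structure(list(t = sign(mdiff) * Inf, df = df, p = 0,
                   flag = "zero_variance_nonzero_diff"), class = "t_test")
  }
}

#' @export
print.t_test <- function(x, ...) {
  cat(sprintf("<t_test> t = %.4g, df = %g, p = %.4g%s\n", x$t, x$df, x$p,
              if (!is.na(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' Yates-corrected chi-square test on a 2x2 table
#'
#' @param table 2x2 matrix of nonnegative counts; all margins must be > 0.
#' @return object of class `chisq_2x2`: `statistic`, `df`, `p`.
#' @export
#' @examples
#' chi_square_2x2(matrix(c(12, 13, 14, 16), 2, byrow = TRUE))$p  # > 0.99
chi_square_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) abort("`table` must be 2x2.")
  if (any(table < 0)) abort("Counts must be nonnegative.")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("All table margins must be > 0.")
  }
  ht <- suppressWarnings(stats::chisq.test(table, correct = TRUE))
  structure(list(statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value), class = "chisq_2x2")
}

#' @export
print.chisq_2x2 <- function(x, ...) {
  cat(sprintf("<chisq_2x2> X2 = %.4g, df = %g, p = %.4g\n",
              x$statistic, x$df, x$p))
  invisible(x)
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the transformed sample skewness (D'Agostino's Z_g1) and kurtosis
#' (Anscombe-Glynn's Z_g2) into K^2 = Z_g1^2 + Z_g2^2, referred to a
#' chi-square distribution with 2 df. p > 0.05 is read as "consistent with
#' normality" in the test gate. Requires n >= 8; constant input has
#' undefined standardized moments and errors.
#'
#' @param x numeric vector, n >= 8.
#' @return object of class `dp_test`: `K2`, `p`, `z_skew`, `z_kurt`, `n`.
#' @export
dagostino_pearson <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 8) abort("D'Agostino-Pearson requires n >= 8.")
  m <- x - mean(x)
  m2 <- mean(m^2)
  if (m2 == 0) abort("Constant input: standardized moments are undefined.")
  g1 <- mean(m^3) / m2^1.5
  g2 <- mean(m^4) / m2^2
  # skewness: D'Agostino (1970) transformation
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  z1 <- delta * log(Y / alpha + sqrt((Y / alpha)^2 + 1))
  # kurtosis: Anscombe & Glynn (1983) transformation
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 - Eb2) / sqrt(Vb2)
  sb <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sb * (2 / sb + sqrt(1 + 4 / sb^2))
  z2 <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) *
    sqrt(9 * A / 2)
  K2 <- z1^2 + z2^2
  structure(list(K2 = K2, p = pchisq(K2, 2, lower.tail = FALSE),
                 z_skew = z1, z_kurt = z2, n = n), class = "dp_test")
}

#' @export
print.dp_test <- function(x, ...) {
  cat(sprintf("<dp_test> K2 = %.4g, p = %.4g (n = %d)\n", x$K2, x$p, x$n))
  invisible(x)
}

#' Normality-gated two-group comparison
#'
#' Implements the study's decision rule: each group is checked for
#' normality with [dagostino_pearson()] (p > 0.05 = normal) and the group
#' variances are compared with an F test at alpha = 0.05. If both groups are
#' normal and variances are not significantly different, a pooled two-tailed
#' unpaired t test is used; otherwise the Mann-Whitney U test. Groups
#' smaller than 8 cannot be normality-tested and fall back to Mann-Whitney
#' with a flag. The gate record makes the chosen path auditable.
#'
#' @param a,b numeric vectors.
#' @param alpha significance threshold used downstream (recorded only).
#' @param normality_alpha gate threshold for the normality p-values.
#' @return object of class `group_comparison`: `test` ("t" or
#'   "mann_whitney"), `statistic`, `df` (t only), `U` (MW only), `p`, and a
#'   `gate` tibble (normality p per group, variance-test p, reason).
#' @export
compare_groups <- function(a, b, alpha = 0.05, normality_alpha = 0.05) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) abort("Each group needs >= 2 observations.")
  norm_a <- norm_b <- NA_real_
  var_p <- NA_real_
  if (length(a) < 8 || length(b) < 8) {
    reason <- "group_too_small_for_normality_test"
    use_t <- FALSE
  } else if (var(a) == 0 || var(b) == 0) {
    reason <- "zero_variance_group"
    use_t <- FALSE
  } else {
    norm_a <- dagostino_pearson(a)$p
    norm_b <- dagostino_pearson(b)$p
    if (norm_a > normality_alpha && norm_b > normality_alpha) {
      var_p <- stats::var.test(a, b)$p.value
      use_t <- var_p > 0.05
      reason <- if (use_t) "normal_equal_variance" else "unequal_variance"
    } else {
      use_t <- FALSE
      reason <- "non_normal"
    }
  }
  gate <- tibble(normality_p_a = norm_a, normality_p_b = norm_b,
                 variance_p = var_p, reason = reason)
  if (use_t) {
    tt <- unpaired_t(a, b)
    res <- list(test = "t", statistic = tt$t, df = tt$df, U = NA_real_,
                p = tt$p, gate = gate, alpha = alpha)
  } else {
    mw <- mann_whitney_u(a, b)
    res <- list(test = "mann_whitney", statistic = mw$U, df = NA_real_,
                U = mw$U, p = mw$p, gate = gate, alpha = alpha)
  }
  structure(res, class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: statistic = %.4g, p = %.4g (gate: %s)\n",
              x$test, x$statistic, x$p, x$gate$reason))
  invisible(x)
}

#' Seeded random eye selection
#'
#' For group comparisons each participant contributes one eye: participants
#' with both eyes available have one chosen uniformly at random
#' (seed-deterministic); single-eye participants keep that eye.
#'
#' @param cohort tibble with `participant`, `has_od`, `has_os` columns.
#' @param seed RNG seed (required).
#' @return `cohort` with an added `eye` column ("OD"/"OS").
#' @export
select_random_eye <- function(cohort, seed) {
  if (missing(seed)) abort("`seed` is required for eye selection.")
  if (!all(c("has_od", "has_os") %in% names(cohort))) {
    abort("`cohort` needs logical columns `has_od` and `has_os`.")
  }
  if (any(!cohort$has_od & !cohort$has_os)) {
    abort("Every participant must have at least one eye available.")
  }
  with_seed(seed, {
    pick <- ifelse(runif(nrow(cohort)) < 0.5, "OD", "OS")
    cohort$eye <- ifelse(cohort$has_od & cohort$has_os, pick,
                         ifelse(cohort$has_od, "OD", "OS"))
    cohort
  })
}
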