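#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a Bland-Altman result
#'
#' @param x a [bland_altman()] object.
#' @param ... unused.
#' @return one row per quantity (`bias`, `loa_lower`, `loa_upper`) with
#'   `estimate`, `conf.low`, `conf.high`.
#' @export
tidy.bland_altman <- function(x, ...) {
  tibble(
    term = c("bias", "loa_lower", "loa_upper"),
    estimate = c(x$bias, x$loa_lower, x$loa_upper),
    conf.low = c(x$bias_ci[1], x$loa_lower_ci[1], x$loa_upper_ci[1]),
    conf.high = c(x$bias_ci[2], x$loa_lower_ci[2], x$loa_upper_ci[2])
  )
}

#' @rdname tidy.bland_altman
#' @export
glance.bland_altman <- function(x, ...) {
  tibble(n = x$n, bias = x$bias, sd_diff = x$sd_diff,
         loa_lower = x$loa_lower, loa_upper = x$loa_upper)
}

#' Tidy a difference-of-Gaussians foveal fit
#'
#' @param x a [fit_dog_center()] / [observer_center()] object.
#' @param ... unused.
#' @return `tidy()`: one row per fitted parameter (empty for observer/raw
#'   centers); `glance()`: one row with `center_mm`, `method`, `rss`,
#'   `converged`.
#' @export
tidy.dog_fit <- function(x, ...) {
  if (is.null(x$params)) return(tibble(term = character(), estimate = numeric()))
  tibble(term = names(x$params), estimate = unlist(x$params))
}

#' @rdname tidy.dog_fit
#' @export
glance.dog_fit <- function(x, ...) {
  tibble(center_mm = x$center_mm, method = x$method, rss = x$rss,
         converged = x$converged)
}

#' Tidy hypothesis-test results
#'
#' @param x an `mw_test`, `t_test`, `chisq_2x2`, or `group_comparison`.
#' @param ... unused.
#' @return a one-row tibble in broom's `statistic`/`p.value` vocabulary.
#' @export
tidy.mw_test <- function(x, ...) {
  tibble(statistic = x$U, p.value = x$p, method = paste0("Mann-Whitney U (", x$method, ")"),
         n1 = x$n1, n2 = x$n2)
}

#' @rdname tidy.mw_test
#' @export
tidy.t_test <- function(x, ...) {
  tibble(statistic = x$t, parameter = x$df, p.value = x$p, method = "t test",
         flag = x$flag)
}

#' @rdname tidy.mw_test
#' @export
tidy.chisq_2x2 <- function(x, ...) {
  tibble(statistic = x$statistic, parameter = x$df, p.value = x$p,
         method = "chi-square (Yates)")
}

#' @rdname tidy.mw_test
#' @export
tidy.group_comparison <- function(x, ...) {
  bind_cols(
    tibble(test = x$test, statistic = x$statistic, df = x$df, U = x$U,
           p.value = x$p),
    x$gate
  )
}

#' @rdname tidy.mw_test
#' @export
tidy.dp_test <- function(x, ...) {
  tibble(statistic = x$K2, p.value = x$p, z_skew = x$z_skew,
         z_kurt = x$z_kurt, n = x$n, method = "D'Agostino-Pearson K2")
}

#' Glance at a pipeline run
#'
#' @param x a `fovtopo_run`.
#' @param ... unused.
#' @return one row: participant counts, scans analysed/excluded, and the
#'   GCL N:T group-test p-value.
#' @export
glance.fovtopo_run <- function(x, ...) {
  nt <- x$stats[x$stats$layer == "GCL" & x$stats$metric == "ratio_NT", ]
  tibble(
    n_control = sum(x$cohort$group == "control"),
    n_albinism = sum(x$cohort$group == "albinism"),
    scans_included = sum(x$log$included),
    scans_excluded = sum(!x$log$included),
    gcl_nt_p = if (nrow(nt)) nt$p else NA_real_
  )
}
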