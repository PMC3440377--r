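#' Design-based estimation for stratified multistage samples
#'
#' Variance estimation follows the standard with-replacement first-stage
#' approximation: per-record contributions are summed to primary sampling
#' unit (PSU) totals \eqn{t_{hj}}, and the variance of the estimated
#' total is
#' \deqn{\widehat{V} = \sum_h \frac{n_h}{n_h - 1}
#'   \sum_j (t_{hj} - \bar t_h)^2}
#' over strata \eqn{h} with \eqn{n_h} PSUs each. Nonlinear estimators
#' (domain proportions, mean paired differences) are linearized first and
#' the same formula applied to their score contributions, keeping every
#' record in the computation with zeroed scores outside the domain — as
#' complex-survey software does, and as correct subdomain standard errors
#' require. 95% confidence intervals are Wald intervals with the normal
#' quantile 1.959964 by default.
#'
#' @name survey_estimation
NULL

z95 <- stats::qnorm(0.975)

# Between-PSU variance of a total of per-record contributions u.
# Strategies for single-PSU strata: "error" (refuse), "centre" (deviation
# from the grand mean PSU total), "certainty" (contributes zero).
taylor_variance <- function(u, stratum, psu, lonely = "error") {
  stopifnot(length(u) == length(stratum), length(u) == length(psu))
  psu_key <- paste(stratum, psu, sep = "\r")
  t_hj <- tapply(u, psu_key, sum)
  psu_stratum <- vapply(strsplit(names(t_hj), "\r", fixed = TRUE),
                        `[[`, character(1), 1L)
  grand_mean <- mean(t_hj)
  v <- 0
  for (h in unique(psu_stratum)) {
    th <- t_hj[psu_stratum == h]
    nh <- length(th)
    if (nh == 1L) {
      if (lonely == "error")
        stop("lonely PSU: stratum '", h, "' has a single PSU; choose a ",
             "lonely-PSU strategy ('centre' or 'certainty')")
      if (lonely == "centre") v <- v + (th - grand_mean)^2
      # "certainty": zero contribution
    } else {
      v <- v + nh / (nh - 1) * sum((th - mean(th))^2)
    }
  }
  as.numeric(v)
}

design_df <- function(stratum, psu) {
  length(unique(paste(stratum, psu, sep = "\r"))) - length(unique(stratum))
}

resolve_design <- function(data, strata_q, psu_q, weight_q) {
  st <- eval_tidy(strata_q, data)
  ps <- eval_tidy(psu_q, data)
  w <- eval_tidy(weight_q, data)
  if (is.null(st) || is.null(ps) || is.null(w))
    stop("survey design requires stratum, psu and weight for every record")
  stopifnot(length(st) == nrow(data), length(ps) == nrow(data),
            length(w) == nrow(data))
  if (anyNA(st) || anyNA(ps) || anyNA(w))
    stop("survey design fields must be non-missing")
  if (any(w < 0)) stop("survey weights must be >= 0")
  list(stratum = as.character(st), psu = as.character(ps), w = as.numeric(w))
}

estimate_row <- function(estimate, var, n, df) {
  se <- sqrt(max(var, 0))
  tibble(estimate = estimate, se = se,
         ci_low = estimate - z95 * se, ci_high = estimate + z95 * se,
         n_records = n, design_df = df)
}

#' Survey-weighted population total
#'
#' Horvitz-Thompson style total \eqn{\sum_i w_i y_i} with the stratified
#' between-PSU variance described in [survey_estimation].
#'
#' @param data Participant tibble.
#' @param value Per-record numeric value (column or vector).
#' @param strata,psu,weight Design columns; default `stratum`, `psu`,
#'   `weight`.
#' @param lonely Single-PSU-stratum strategy: `"error"` (default),
#'   `"centre"` (deviation from the grand PSU-total mean) or
#'   `"certainty"` (zero variance contribution).
#' @return One-row tibble: `estimate`, `se`, `ci_low`, `ci_high`,
#'   `n_records`, `design_df`.
#' @export
#' @examples
#' d <- tibble::tibble(stratum = c(1, 1, 2, 2), psu = c(1, 2, 1, 2),
#'                     weight = c(10, 20, 30, 40), y = c(1, 0, 1, 1))
#' svy_total(d, y)
svy_total <- function(data, value, strata = stratum, psu = psu,
                      weight = weight,
                      lonely = c("error", "centre", "certainty")) {
  data <- as_tibble(data)
  lonely <- match.arg(lonely)
  y <- eval_tidy(enquo(value), data)
  des <- resolve_design(data, enquo(strata), enquo(psu), enquo(weight))
  stopifnot(length(y) == nrow(data))
  u <- des$w * as.numeric(y)
  estimate_row(sum(u), taylor_variance(u, des$stratum, des$psu, lonely),
               nrow(data), design_df(des$stratum, des$psu))
}

#' Survey-weighted domain proportion
#'
#' Ratio estimator \eqn{\hat p = \sum_d w_i y_i / \sum_d w_i} over the
#' records in the domain, with the linearized score
#' \eqn{z_i = d_i w_i (y_i - \hat p) / \sum_d w_i} fed through the
#' stratified between-PSU variance. All records stay in the variance
#' computation (zero score outside the domain). Invariant under rescaling
#' of all weights.
#'
#' @param indicator Per-record 0/1 (or logical) outcome.
#' @param domain Per-record 0/1 domain membership; `NULL` means all
#'   records.
#' @inheritParams svy_total
#' @return One-row tibble as for [svy_total()]. CI bounds are not
#'   truncated here; truncation to `[0, 1]` is a report-time rule.
#' @export
svy_proportion <- function(data, indicator, domain = NULL, strata = stratum,
                           psu = psu, weight = weight,
                           lonely = c("error", "centre", "certainty")) {
  data <- as_tibble(data)
  lonely <- match.arg(lonely)
  y <- as.numeric(eval_tidy(enquo(indicator), data))
  dmn <- eval_tidy(enquo(domain), data)
  dmn <- if (is.null(dmn)) rep(1, nrow(data)) else as.numeric(dmn)
  des <- resolve_design(data, enquo(strata), enquo(psu), enquo(weight))
  stopifnot(length(y) == nrow(data), length(dmn) == nrow(data))
  if (anyNA(y[dmn > 0])) stop("indicator missing inside the domain")
  w_d <- sum(des$w * dmn)
  if (w_d <= 0) stop("undefined estimate: domain has no positive weight")
  p <- sum(des$w * dmn * y, na.rm = TRUE) / w_d
  z <- dmn * des$w * (ifelse(is.na(y), 0, y) - p) / w_d
  estimate_row(p, taylor_variance(z, des$stratum, des$psu, lonely),
               sum(dmn > 0), design_df(des$stratum, des$psu))
}

#' Wald test of marginal homogeneity for paired ordinal ratings
#'
#' Tests whether two risk scores distribute the population identically
#' across the ordered categories, via the survey-weighted mean of the
#' paired ordinal difference \eqn{d_i = \mathrm{rrs}_i - \mathrm{frs}_i}
#' (a ratio estimator, so weight-scale invariant), its Taylor-linearized
#' standard error, and a normal-reference two-sided p-value.
#'
#' @param frs_scores,rrs_scores Per-record ordinal ratings 1-4 (columns
#'   or vectors), paired within record.
#' @inheritParams svy_total
#' @return One-row tibble: `estimate` (weighted mean difference), `se`,
#'   `statistic` (z), `p_value`, `n_records`, `design_df`. A degenerate
#'   zero variance yields p = 1 when the mean difference is zero and
#'   p = 0 (with a warning) otherwise.
#' @export
svy_marginal_homogeneity <- function(data, frs_scores, rrs_scores,
                                     strata = stratum, psu = psu,
                                     weight = weight,
                                     lonely = c("error", "centre", "certainty")) {
  data <- as_tibble(data)
  lonely <- match.arg(lonely)
  f <- as.numeric(eval_tidy(enquo(frs_scores), data))
  r <- as.numeric(eval_tidy(enquo(rrs_scores), data))
  if (anyNA(f) || anyNA(r)) stop("paired scores required for every record")
  d <- r - f
  est <- svy_proportion(data, d, strata = {{ strata }}, psu = {{ psu }},
                        weight = {{ weight }}, lonely = lonely)
  if (est$se == 0) {
    if (est$estimate == 0) {
      z <- 0; p <- 1
    } else {
      warning("degenerate variance: SE = 0 with nonzero mean difference")
      z <- sign(est$estimate) * Inf; p <- 0
    }
  } else {
    z <- est$estimate / est$se
    p <- 2 * pnorm(-abs(z))
  }
  structure(
    tibble(estimate = est$estimate, se = est$se, statistic = z,
           p_value = p, n_records = est$n_records,
           design_df = est$design_df),
    class = c("cvr_mh_test", class(tibble())))
}

#' @export
print.cvr_mh_test <- function(x, ...) {
  cat("Wald test of marginal homogeneity (paired ordinal ratings)\n")
  cat(sprintf("  weighted mean difference = %.4f (SE %.4f), z = %.3f, p = %.4g\n",
              x$estimate, x$se, x$statistic, x$p_value))
  invisible(x)
}

#' @export
tidy.cvr_mh_test <- function(x, ...) {
  tibble(term = "rrs_minus_frs", estimate = x$estimate, std.error = x$se,
         statistic = x$statistic, p.value = x$p_value)
}

#' @export
glance.cvr_mh_test <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p_value, nobs = x$n_records,
         df = x$design_df)
}
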