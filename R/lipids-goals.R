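#' Friedewald LDL-C calculation
#'
#' LDL-C = TC - HDL - TG/5 (mg/dL), valid only below a triglyceride
#' level of 400 mg/dL; at or above 400 the estimate is invalid and the
#' non-HDL-C fallback applies, signalled here by `NA`.
#'
#' @param tc,hdl,tg Total cholesterol, HDL-C, triglycerides (mg/dL,
#'   strictly positive).
#' @return LDL-C in mg/dL, `NA` where `tg >= 400`.
#' @export
#' @examples
#' friedewald_ldl(190, 46, 140) # 116
friedewald_ldl <- function(tc, hdl, tg) {
  ok <- !is.na(tc) & !is.na(hdl) & !is.na(tg)
  if (any(c(tc[!is.na(tc)], hdl[!is.na(hdl)], tg[!is.na(tg)]) <= 0))
    stop("domain error: lipid inputs must be strictly positive")
  out <- ifelse(ok & tg < 400, tc - hdl - tg / 5, NA_real_)
  out
}

#' ATP III risk categories and LDL-C goals
#'
#' Four ordered categories cut on the unrounded ten-year risk with
#' half-open intervals closed on the left: low `[0, 6%)`, moderate
#' `[6%, 10%)`, moderate-high `[10%, 20%)`, high `[20%, 100%]`. Each
#' category carries an LDL-C goal; the `"aggressive"` policy (default)
#' uses the optional intensified goals 160/130/100/70 mg/dL, the
#' `"standard"` policy the non-optional set 160/130/130/100 mg/dL.
#' Non-HDL-C goals are the LDL-C goal + 30 mg/dL.
#'
#' @param goal_policy `"aggressive"` or `"standard"`.
#' @return Tibble with `label`, `ordinal`, `ldl_goal`, `nonhdl_goal`.
#' @export
risk_categories <- function(goal_policy = c("aggressive", "standard")) {
  goal_policy <- match.arg(goal_policy)
  ldl <- if (goal_policy == "aggressive") c(160, 130, 100, 70)
         else c(160, 130, 130, 100)
  tibble(label = factor(c("low", "moderate", "moderate_high", "high"),
                        levels = category_levels),
         ordinal = 1:4, ldl_goal = ldl, nonhdl_goal = ldl + 30)
}

category_levels <- c("low", "moderate", "moderate_high", "high")

#' @rdname risk_categories
#' @param risk Risk fractions in `[0, 1]` (unrounded).
#' @return `categorize_risk()`: ordered factor of category labels.
#' @export
#' @examples
#' categorize_risk(c(0.051, 0.06, 0.125, 0.20))
categorize_risk <- function(risk) {
  risk <- as.numeric(risk)
  if (any(!is.na(risk) & (risk < 0 | risk > 1)))
    stop("domain error: risk must lie in [0, 1]")
  cut(risk, breaks = c(-Inf, 0.06, 0.10, 0.20, Inf), right = FALSE,
      labels = category_levels, ordered_result = TRUE)
}

#' Derive the lipid value used for goal assessment
#'
#' Uses Friedewald LDL-C when triglycerides are present, below
#' 400 mg/dL, and the fast was at least 8 hours; otherwise falls back to
#' non-HDL-C (TC - HDL), per the ATP III fallback rule. A missing
#' fasting time is treated as an unverified fast and routed to the
#' fallback.
#'
#' @param data Participant tibble with `total_cholesterol`,
#'   `hdl_cholesterol` and optionally `triglycerides`, `fasting_hours`.
#' @return Input with `ldl_used`, `nonhdl_used`, `fallback_used`
#'   appended; exactly one of the two lipid values is non-`NA` per row.
#' @export
derive_lipids <- function(data) {
  data <- as_tibble(data)
  n <- nrow(data)
  tg <- if ("triglycerides" %in% names(data)) as.numeric(data$triglycerides)
        else rep(NA_real_, n)
  fast <- if ("fasting_hours" %in% names(data)) as.numeric(data$fasting_hours)
          else rep(NA_real_, n)
  if (anyNA(data$total_cholesterol) || anyNA(data$hdl_cholesterol))
    stop("missing lipids: records lacking TC or HDL should have been ",
         "excluded upstream")
  fallback <- is.na(tg) | tg >= 400 | is.na(fast) | fast < 8
  ldl <- friedewald_ldl(data$total_cholesterol, data$hdl_cholesterol, tg)
  data$ldl_used <- ifelse(fallback, NA_real_, ldl)
  data$nonhdl_used <- ifelse(fallback,
                             data$total_cholesterol - data$hdl_cholesterol,
                             NA_real_)
  data$fallback_used <- fallback
  data
}

#' LDL-C (or non-HDL-C) goal attainment
#'
#' Strict inequality against the category's goal: on the LDL path,
#' attained iff LDL-C < goal; on the fallback path, attained iff
#' non-HDL-C < goal + 30. An LDL-C exactly at goal is not attained.
#'
#' @param ldl,nonhdl Lipid value used (exactly one non-`NA` per record).
#' @param fallback Logical, `TRUE` where the non-HDL path applies.
#' @param category Category labels (as from [categorize_risk()]).
#' @param goal_policy Passed to [risk_categories()].
#' @return Logical vector.
#' @export
goal_attained <- function(ldl, nonhdl, fallback, category,
                          goal_policy = c("aggressive", "standard")) {
  cats <- risk_categories(goal_policy)
  idx <- match(as.character(category), as.character(cats$label))
  if (anyNA(idx)) stop("unknown risk category")
  value <- ifelse(fallback, nonhdl, ldl)
  goal <- ifelse(fallback, cats$nonhdl_goal[idx], cats$ldl_goal[idx])
  if (anyNA(value))
    stop("missing lipids: no usable LDL-C or non-HDL-C value")
  value < goal
}

#' Reclassification direction and clinical significance
#'
#' Direction compares the ordinal categories (RRS vs FRS). A
#' reclassification is clinically significant only when the subject's
#' lipid value lies between the two goals, i.e. goal attainment differs
#' between scores: `rrs_gt_frs` (met the FRS goal, fails the RRS goal —
#' intensification indicated only under RRS) requires attainment
#' (TRUE, FALSE); `rrs_lt_frs` the reverse. Identical attainment is
#' never clinically significant, even when the category changed.
#'
#' @param frs_cat,rrs_cat Category labels.
#' @param attained_frs,attained_rrs Goal attainment under each score.
#' @return Tibble with factor columns `direction` (`up`/`down`/`same`)
#'   and `clinically_significant` (`none`/`rrs_gt_frs`/`rrs_lt_frs`).
#' @export
classify_reclassification <- function(frs_cat, rrs_cat, attained_frs,
                                      attained_rrs) {
  f <- match(as.character(frs_cat), category_levels)
  r <- match(as.character(rrs_cat), category_levels)
  if (anyNA(f) || anyNA(r)) stop("unknown risk category")
  direction <- factor(ifelse(r > f, "up", ifelse(r < f, "down", "same")),
                      levels = c("up", "down", "same"))
  cs <- ifelse(attained_frs & !attained_rrs, "rrs_gt_frs",
               ifelse(!attained_frs & attained_rrs, "rrs_lt_frs", "none"))
  # lipid between two goals requires the goals to differ, hence a moved
  # category; enforce the coupling explicitly
  cs[direction == "same"] <- "none"
  tibble(direction = direction,
         clinically_significant = factor(cs, levels = c("none", "rrs_gt_frs",
                                                        "rrs_lt_frs")))
}

#' Full per-subject goal and reclassification assessment
#'
#' Chains [derive_lipids()], [categorize_risk()] on both scores,
#' [goal_attained()] under each score's category, and
#' [classify_reclassification()]. Expects a scored cohort (see
#' [add_risk_scores()]).
#'
#' @param data Tibble with `frs_risk`, `rrs_risk` and lipid columns.
#' @param goal_policy `"aggressive"` (default) or `"standard"`.
#' @return Input with `ldl_used`, `nonhdl_used`, `fallback_used`,
#'   `frs_category`, `rrs_category`, `attained_frs`, `attained_rrs`,
#'   `direction`, `clinically_significant` appended.
#' @export
assess_goals <- function(data, goal_policy = c("aggressive", "standard")) {
  goal_policy <- match.arg(goal_policy)
  data <- derive_lipids(as_tibble(data))
  if (!all(c("frs_risk", "rrs_risk") %in% names(data)))
    stop("scores missing: run add_risk_scores() first")
  data$frs_category <- categorize_risk(data$frs_risk)
  data$rrs_category <- categorize_risk(data$rrs_risk)
  data$attained_frs <- goal_attained(data$ldl_used, data$nonhdl_used,
                                     data$fallback_used, data$frs_category,
                                     goal_policy)
  data$attained_rrs <- goal_attained(data$ldl_used, data$nonhdl_used,
                                     data$fallback_used, data$rrs_category,
                                     goal_policy)
  cls <- classify_reclassification(data$frs_category, data$rrs_category,
                                   data$attained_frs, data$attained_rrs)
  data$direction <- cls$direction
  data$clinically_significant <- cls$clinically_significant
  data
}
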