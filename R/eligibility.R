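#' Operational diabetes definition
#'
#' A participant is diabetic if any clause holds: physician diagnosis,
#' use of oral hypoglycemics or insulin, an 8-hour fasting glucose
#' >= 126 mg/dL, or a random glucose >= 200 mg/dL (applied regardless of
#' fasting time). Missing inputs never qualify for a clause, so the
#' function is total.
#'
#' @param data Participant tibble with (any of) `diabetes_dx`,
#'   `hypoglycemic_or_insulin`, `glucose`, `fasting_hours`.
#' @return Logical vector, one flag per record.
#' @export
is_diabetic <- function(data) {
  data <- as_tibble(data)
  n <- nrow(data)
  col <- function(nm, default) {
    if (nm %in% names(data)) data[[nm]] else rep(default, n)
  }
  dx <- isTRUE_vec(col("diabetes_dx", FALSE))
  meds <- isTRUE_vec(col("hypoglycemic_or_insulin", FALSE))
  glu <- as.numeric(col("glucose", NA_real_))
  fast <- as.numeric(col("fasting_hours", NA_real_))
  fasting_high <- !is.na(glu) & !is.na(fast) & fast >= 8 & glu >= 126
  random_high <- !is.na(glu) & glu >= 200
  dx | meds | fasting_high | random_high
}

# NA-safe TRUE test, elementwise
isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' ATP III risk-equivalent screen
#'
#' True for self-reported coronary heart disease (MI, CHD or angina),
#' self-reported stroke, or an ankle-brachial index below 0.9 in either
#' leg. Missing ABI values never qualify.
#'
#' @param data Participant tibble with (any of) `self_report_chd`,
#'   `self_report_stroke`, `abi_left`, `abi_right`.
#' @return Logical vector.
#' @export
has_risk_equivalent <- function(data) {
  data <- as_tibble(data)
  n <- nrow(data)
  col <- function(nm, default) {
    if (nm %in% names(data)) data[[nm]] else rep(default, n)
  }
  chd <- isTRUE_vec(col("self_report_chd", FALSE))
  stroke <- isTRUE_vec(col("self_report_stroke", FALSE))
  abi_l <- as.numeric(col("abi_left", NA_real_))
  abi_r <- as.numeric(col("abi_right", NA_real_))
  low_abi <- (!is.na(abi_l) & abi_l < 0.9) | (!is.na(abi_r) & abi_r < 0.9)
  chd | stroke | low_abi
}

exclusion_reasons <- c("age_sex_window", "age_over_79", "pregnant",
                       "missing_bp", "missing_lipids", "diabetes",
                       "risk_equivalent", "chemotherapy", "none")

#' Inclusion/exclusion waterfall
#'
#' Applies the study's eligibility rules in fixed waterfall order so each
#' record receives exactly one exclusion reason: age/sex window (women
#' 45-79, men 50-79, boundaries inclusive; over-79 recorded separately),
#' pregnancy, missing blood pressure, missing lipids (no total or HDL
#' cholesterol; missing triglycerides alone is not exclusion — it routes
#' to the non-HDL-C goal fallback), diabetes ([is_diabetic()]), ATP III
#' risk equivalents ([has_risk_equivalent()]), chemotherapy. The order
#' matters: a pregnant diabetic is counted once, under pregnancy.
#'
#' @param data Participant tibble; `sex` and `age` must be present and
#'   non-missing.
#' @return The input with logical `included` and factor `exclusion_reason`
#'   (level `"none"` for included records) appended.
#' @export
#' @examples
#' apply_inclusion(tibble::tibble(
#'   sex = c("female", "female"), age = c(44, 60), pregnant = FALSE,
#'   systolic_bp = 120, total_cholesterol = 200, hdl_cholesterol = 50))
apply_inclusion <- function(data) {
  data <- as_tibble(data)
  if (!all(c("sex", "age") %in% names(data)) ||
      anyNA(data$sex) || anyNA(data$age))
    stop("malformed record: 'sex' and 'age' must be present and non-missing")
  n <- nrow(data)
  col <- function(nm, default) {
    if (nm %in% names(data)) data[[nm]] else rep(default, n)
  }
  age <- as.numeric(data$age)
  over79 <- age > 79
  in_window <- ifelse(data$sex == "female", age >= 45, age >= 50) & !over79

  sbp <- as.numeric(col("systolic_bp", NA_real_))
  tc <- as.numeric(col("total_cholesterol", NA_real_))
  hdl <- as.numeric(col("hdl_cholesterol", NA_real_))

  checks <- list(
    age_over_79 = over79,
    age_sex_window = !in_window & !over79,
    pregnant = isTRUE_vec(col("pregnant", FALSE)),
    missing_bp = is.na(sbp),
    missing_lipids = is.na(tc) | is.na(hdl),
    diabetes = is_diabetic(data),
    risk_equivalent = has_risk_equivalent(data),
    chemotherapy = isTRUE_vec(col("chemotherapy", FALSE))
  )
  # Table-2 row order decides which reason a multiply-excluded record gets
  order_reasons <- c("age_sex_window", "age_over_79", "pregnant",
                     "missing_bp", "missing_lipids", "diabetes",
                     "risk_equivalent", "chemotherapy")
  reason <- rep("none", n)
  for (r in rev(order_reasons)) reason[checks[[r]]] <- r
  data$included <- reason == "none"
  data$exclusion_reason <- factor(reason, levels = exclusion_reasons)
  data
}

#' Exclusion-waterfall summary
#'
#' Per-reason record counts and survey-weighted population totals (with
#' Taylor-linearized standard errors when design columns are present),
#' in waterfall order with the included rows last — the shape of the
#' study's inclusion/exclusion table.
#'
#' @param data Output of [apply_inclusion()]; design columns `stratum`,
#'   `psu`, `weight` enable SEs.
#' @param lonely Lonely-PSU strategy passed to [svy_total()].
#' @return Tibble with `reason`, `n`, `weighted_total`, and (given a
#'   design) `se`.
#' @export
waterfall_summary <- function(data, lonely = c("error", "centre", "certainty")) {
  data <- as_tibble(data)
  if (!"exclusion_reason" %in% names(data)) data <- apply_inclusion(data)
  lonely <- match.arg(lonely)
  has_design <- all(c("stratum", "psu", "weight") %in% names(data))
  w <- if ("weight" %in% names(data)) as.numeric(data$weight) else rep(1, nrow(data))
  levels_order <- c(setdiff(exclusion_reasons, "none"), "none")
  rows <- lapply(levels_order, function(r) {
    ind <- as.integer(data$exclusion_reason == r)
    if (has_design) {
      est <- svy_total(data, ind, lonely = lonely)
      tibble(reason = r, n = sum(ind), weighted_total = est$estimate,
             se = est$se)
    } else {
      tibble(reason = r, n = sum(ind), weighted_total = sum(w * ind),
             se = NA_real_)
    }
  })
  out <- bind_rows(rows)
  out$reason[out$reason == "none"] <- "included"
  out
}
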