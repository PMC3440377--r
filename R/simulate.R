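#' Configuration for the synthetic NHANES-like cohort generator
#'
#' Defaults encode the study conditions: per-sex covariate distributions
#' matched to the reported subject characteristics (weighted medians and
#' IQRs for total cholesterol, HDL-C, systolic BP, hs-CRP; prevalences
#' for smoking 17.2%/17.3%, premature family history 15.4%/7.7%, BP
#' medication 26.2%/21.8%, lipid medication 10.3%/13.2% in women/men),
#' target weighted totals of 33.5 M women and 20.1 M men, and exclusion
#' prevalences in the proportions of the published inclusion waterfall.
#' Positive skewed covariates are log-normal, moment-matched to the
#' median and IQR; ages follow a right-skewed scaled Beta on the
#' eligible window matched to the reported median.
#'
#' @param n_women,n_men Records per sex.
#' @param n_strata,psus_per_stratum Survey design structure (PSU labels
#'   are nested within strata).
#' @param weight_dispersion Gamma shape for the weight distribution
#'   (weights scale so the expected weighted total per sex hits
#'   `weighted_total`).
#' @param women,men Per-sex parameter lists; any element supplied
#'   overrides the default of the same name (see Details in the
#'   package vignette).
#' @param exclusions Named prevalences for planted exclusion conditions
#'   (`pregnant` applies to women only).
#' @param tg_tail_400 Extra probability mass of triglycerides >= 400
#'   mg/dL.
#' @param tg_missing_rate,fasting_under8_rate Missing-triglyceride and
#'   short-fast rates (both route goal assessment to the non-HDL-C
#'   fallback, not to exclusion).
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_women = 1500, n_men = 1200, n_strata = 15,
                          psus_per_stratum = 2, weight_dispersion = 4,
                          women = list(), men = list(),
                          exclusions = list(), tg_tail_400 = 0.015,
                          tg_missing_rate = 0.05,
                          fasting_under8_rate = 0.12) {
  default_women <- list(
    age_range = c(45, 79), age_median = 54.2,
    tc = c(median = 214.1, iqr = 46.7), hdl = c(median = 57.2, iqr = 20.3),
    sbp = c(median = 126.2, iqr = 26.1), hscrp = c(median = 2.8, iqr = 4.7),
    tg = c(median = 110, iqr = 80),
    smoking = 0.172, family_history = 0.154, bp_meds = 0.262,
    lipid_meds = 0.103, weighted_total = 33.5e6)
  default_men <- list(
    age_range = c(50, 79), age_median = 57.9,
    tc = c(median = 209, iqr = 45.3), hdl = c(median = 44.5, iqr = 15.2),
    sbp = c(median = 126.8, iqr = 20.6), hscrp = c(median = 1.9, iqr = 2.9),
    tg = c(median = 130, iqr = 100),
    smoking = 0.173, family_history = 0.077, bp_meds = 0.218,
    lipid_meds = 0.132, weighted_total = 20.1e6)
  default_excl <- list(pregnant = 0.001, missing_bp = 0.019,
                       missing_lipids = 0.063, diabetes = 0.172,
                       risk_equivalent = 0.130, chemotherapy = 0.006)
  cfg <- list(
    n_women = n_women, n_men = n_men, n_strata = n_strata,
    psus_per_stratum = psus_per_stratum,
    weight_dispersion = weight_dispersion,
    women = modifyList(default_women, women),
    men = modifyList(default_men, men),
    exclusions = modifyList(default_excl, exclusions),
    tg_tail_400 = tg_tail_400, tg_missing_rate = tg_missing_rate,
    fasting_under8_rate = fasting_under8_rate)
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  bad <- character(0)
  chk <- function(ok, nm) if (!all(ok)) bad <<- c(bad, nm)
  chk(cfg$n_women >= 0 && cfg$n_men >= 0 &&
        cfg$n_women + cfg$n_men > 0, "n_women/n_men")
  chk(cfg$n_strata >= 1, "n_strata")
  chk(cfg$psus_per_stratum >= 1, "psus_per_stratum")
  chk(cfg$weight_dispersion > 0, "weight_dispersion")
  probs <- c(unlist(cfg$exclusions), cfg$tg_tail_400, cfg$tg_missing_rate,
             cfg$fasting_under8_rate)
  chk(probs >= 0 & probs <= 1, "prevalences/rates")
  chk(sum(unlist(cfg$exclusions)) <= 1, "exclusion prevalences sum")
  for (s in c("women", "men")) {
    p <- cfg[[s]]
    chk(all(c(p$tc, p$hdl, p$sbp, p$hscrp, p$tg) > 0),
        paste0(s, " distribution scales"))
    chk(p$age_median > p$age_range[1] && p$age_median < p$age_range[2],
        paste0(s, " age_median"))
    chk(all(c(p$smoking, p$family_history, p$bp_meds, p$lipid_meds) >= 0 &
              c(p$smoking, p$family_history, p$bp_meds, p$lipid_meds) <= 1),
        paste0(s, " prevalences"))
    chk(p$weighted_total > 0, paste0(s, " weighted_total"))
  }
  if (length(bad))
    stop("invalid generator config: ", paste(unique(bad), collapse = "; "))
  invisible(cfg)
}

# log-normal moment-matched to (median, IQR):
# mu = ln(median); IQR = 2 * median * sinh(z75 * sigma)
lognormal_params <- function(spec) {
  m <- spec[["median"]]; iqr <- spec[["iqr"]]
  list(meanlog = log(m), sdlog = asinh(iqr / (2 * m)) / qnorm(0.75))
}

rskewed <- function(n, spec) {
  p <- lognormal_params(spec)
  rlnorm(n, p$meanlog, p$sdlog)
}

# right-skewed age on [a, b] with the requested median: Beta(1, b_shape)
rage <- function(n, range, med) {
  q <- (med - range[1]) / (range[2] - range[1])
  shape2 <- log(0.5) / log(1 - q)
  range[1] + (range[2] - range[1]) * rbeta(n, 1, shape2)
}

generate_sex <- function(cfg, sex, seed) {
  n <- if (sex == "female") cfg$n_women else cfg$n_men
  p <- if (sex == "female") cfg$women else cfg$men
  if (n == 0L) return(NULL)
  id_prefix <- if (sex == "female") "W" else "M"

  set.seed(stream_seed(seed, paste0(sex, "/design")))
  stratum <- sprintf("S%02d", sample.int(cfg$n_strata, n, replace = TRUE))
  psu <- paste0(stratum, "-P",
                sample.int(cfg$psus_per_stratum, n, replace = TRUE))
  mean_w <- p$weighted_total / n
  k <- cfg$weight_dispersion
  weight <- rgamma(n, shape = k, scale = mean_w / k)

  set.seed(stream_seed(seed, paste0(sex, "/covariates")))
  age <- rage(n, p$age_range, p$age_median)
  tc <- rskewed(n, p$tc)
  hdl <- pmin(rskewed(n, p$hdl), tc * 0.9)  # HDL cannot exceed TC
  sbp <- rskewed(n, p$sbp)
  hscrp <- rskewed(n, p$hscrp)
  tg <- rskewed(n, p$tg)
  tail400 <- runif(n) < cfg$tg_tail_400
  tg[tail400] <- runif(sum(tail400), 400, 800)
  tg[runif(n) < cfg$tg_missing_rate] <- NA_real_
  short_fast <- runif(n) < cfg$fasting_under8_rate
  fasting_hours <- ifelse(short_fast, runif(n, 2, 8), runif(n, 8, 16))
  glucose <- pmin(rnorm(n, 95, 8), 120)     # non-diabetic baseline
  hba1c <- pmax(rnorm(n, 5.4, 0.4), 4)
  abi_left <- pmax(rnorm(n, 1.10, 0.08), 0.95)
  abi_right <- pmax(rnorm(n, 1.10, 0.08), 0.95)

  set.seed(stream_seed(seed, paste0(sex, "/flags")))
  current_smoker <- runif(n) < p$smoking
  family_history <- runif(n) < p$family_history
  bp_medication <- runif(n) < p$bp_meds
  lipid_medication <- runif(n) < p$lipid_meds

  rec <- tibble(
    participant_id = sprintf("%s%06d", id_prefix, seq_len(n)),
    stratum = stratum, psu = psu, weight = weight, sex = sex, age = age,
    pregnant = FALSE, systolic_bp = sbp, bp_medication = bp_medication,
    lipid_medication = lipid_medication, total_cholesterol = tc,
    hdl_cholesterol = hdl, triglycerides = tg,
    fasting_hours = fasting_hours, glucose = glucose, hba1c = hba1c,
    hscrp = hscrp, current_smoker = current_smoker,
    family_history = family_history, self_report_chd = FALSE,
    self_report_stroke = FALSE, diabetes_dx = FALSE,
    hypoglycemic_or_insulin = FALSE, chemotherapy = FALSE,
    abi_left = abi_left, abi_right = abi_right)

  set.seed(stream_seed(seed, paste0(sex, "/exclusions")))
  ex <- cfg$exclusions
  reasons <- c("pregnant", "missing_bp", "missing_lipids", "diabetes",
               "risk_equivalent", "chemotherapy")
  probs <- unlist(ex[reasons])
  if (sex == "male") probs["pregnant"] <- 0
  planted <- sample(c(reasons, "none"), n, replace = TRUE,
                    prob = c(probs, 1 - sum(probs)))
  mech <- runif(n)  # drawn for all records so plants stay stream-stable
  rec <- plant_exclusions(rec, planted, mech)
  list(records = rec,
       truth = tibble(participant_id = rec$participant_id,
                      planted_reason = planted))
}

# Realise each planted exclusion by exactly one mechanism, chosen by the
# per-record uniform draw u; vectorised over the cohort.
plant_exclusions <- function(rec, planted, u) {
  rec$pregnant[planted == "pregnant"] <- TRUE
  rec$systolic_bp[planted == "missing_bp"] <- NA_real_
  ml <- planted == "missing_lipids"
  rec$total_cholesterol[ml & u < 0.5] <- NA_real_
  rec$hdl_cholesterol[ml & u >= 0.5] <- NA_real_
  dm <- planted == "diabetes"
  rec$diabetes_dx[dm & u < 0.25] <- TRUE
  rec$hypoglycemic_or_insulin[dm & u >= 0.25 & u < 0.5] <- TRUE
  fg <- dm & u >= 0.5 & u < 0.75
  rec$glucose[fg] <- 126 + 60 * u[fg]
  rec$fasting_hours[fg] <- 8 + 8 * u[fg]
  rg <- dm & u >= 0.75
  rec$glucose[rg] <- 200 + 100 * u[rg]
  re <- planted == "risk_equivalent"
  rec$self_report_chd[re & u < 1 / 3] <- TRUE
  rec$self_report_stroke[re & u >= 1 / 3 & u < 2 / 3] <- TRUE
  la <- re & u >= 2 / 3 & u < 5 / 6
  rec$abi_left[la] <- 0.6 + 0.29 * u[la]
  ra <- re & u >= 5 / 6
  rec$abi_right[ra] <- 0.6 + 0.29 * u[ra]
  rec$chemotherapy[planted == "chemotherapy"] <- TRUE
  rec
}

#' Generate a synthetic NHANES-like cohort with known ground truth
#'
#' Deterministic given `(config, seed)`. Random draws use named
#' substreams (design, covariates, flags, exclusions) derived from the
#' master seed, so adding a covariate to one stream never perturbs the
#' others. Exclusion conditions are planted: baseline records satisfy no
#' exclusion predicate, and each planted record realises exactly its
#' assigned condition, so with planted missingness the eligibility
#' waterfall must recover the plant exactly.
#'
#' @param config A [cohort_config()].
#' @param seed Integer master seed.
#' @return List of class `cvr_cohort`: `records` (participant tibble in
#'   the layout [apply_inclusion()] consumes), `truth` (per-record
#'   planted exclusion reason), `config`, `seed`.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_women = 50, n_men = 50), seed = 1)
#' table(cohort$truth$planted_reason)
simulate_cohort <- function(config = cohort_config(), seed = 1L) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  validate_cohort_config(config)
  parts <- list(generate_sex(config, "female", seed),
                generate_sex(config, "male", seed))
  parts <- parts[!vapply(parts, is.null, logical(1))]
  structure(list(
    records = bind_rows(lapply(parts, `[[`, "records")),
    truth = bind_rows(lapply(parts, `[[`, "truth")),
    config = config, seed = as.integer(seed)), class = "cvr_cohort")
}

#' @export
print.cvr_cohort <- function(x, ...) {
  cat("<cvr_cohort> ", nrow(x$records), " records (",
      sum(x$records$sex == "female"), " women, ",
      sum(x$records$sex == "male"), " men), seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Weighted subject-characteristics summary
#'
#' Per-sex weighted medians and IQRs (lower interpolation on the
#' weighted empirical distribution) for age, LDL-C, systolic BP, hs-CRP,
#' HDL-C and total cholesterol, and weighted prevalences with
#' design-based 95% CIs for smoking, family history, and BP/lipid
#' medication use — the subject-characteristics table layout.
#'
#' @param records Participant tibble (design columns required for
#'   prevalence CIs).
#' @param lonely Lonely-PSU strategy for the prevalence CIs.
#' @return Tibble with `sex`, `measure`, `statistic`
#'   (`median`/`iqr`/`proportion`), `estimate`, `ci_low`, `ci_high`.
#' @export
summarize_cohort <- function(records,
                             lonely = c("error", "centre", "certainty")) {
  records <- as_tibble(records)
  lonely <- match.arg(lonely)
  if (nrow(records) == 0L) stop("empty cohort")
  records <- derive_lipids_permissive(records)
  out <- lapply(intersect(c("female", "male"), unique(records$sex)),
                function(s) {
    d <- records[records$sex == s, ]
    w <- d$weight
    med_iqr <- function(measure, x) {
      q <- weighted_quantile(x, w, c(0.25, 0.5, 0.75))
      tibble(sex = s, measure = measure,
             statistic = c("median", "iqr"),
             estimate = c(q[2], q[3] - q[1]),
             ci_low = NA_real_, ci_high = NA_real_)
    }
    prev <- function(measure, flag) {
      est <- svy_proportion(d, flag, lonely = lonely)
      tibble(sex = s, measure = measure, statistic = "proportion",
             estimate = est$estimate, ci_low = est$ci_low,
             ci_high = est$ci_high)
    }
    bind_rows(
      med_iqr("age", d$age),
      med_iqr("ldl_cholesterol", d$ldl_any),
      med_iqr("systolic_bp", d$systolic_bp),
      med_iqr("hscrp", d$hscrp),
      med_iqr("hdl_cholesterol", d$hdl_cholesterol),
      med_iqr("total_cholesterol", d$total_cholesterol),
      prev("current_smoker", as.integer(d$current_smoker)),
      prev("family_history", as.integer(d$family_history)),
      prev("bp_medication", as.integer(d$bp_medication)),
      prev("lipid_medication", as.integer(d$lipid_medication)))
  })
  bind_rows(out)
}

# Friedewald LDL wherever computable, regardless of fast length; only for
# descriptive summaries, never for goal logic.
derive_lipids_permissive <- function(records) {
  tg <- if ("triglycerides" %in% names(records))
    as.numeric(records$triglycerides) else rep(NA_real_, nrow(records))
  records$ldl_any <- friedewald_ldl(records$total_cholesterol,
                                    records$hdl_cholesterol, tg)
  records
}

#' Read and write cohorts as delimited text
#'
#' `write_cohort()` writes `records.csv` and (when present)
#' `truth.csv` into a directory; `read_cohort()` reads a records file
#' written in that layout (the same layout [apply_inclusion()]
#' consumes).
#'
#' @param cohort A `cvr_cohort` or a participant tibble.
#' @param dir Output directory (created if needed).
#' @return `write_cohort()` the directory, invisibly; `read_cohort()` a
#'   participant tibble.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  records <- if (inherits(cohort, "cvr_cohort")) cohort$records else cohort
  readr::write_csv(records, file.path(dir, "records.csv"), na = "")
  if (inherits(cohort, "cvr_cohort"))
    readr::write_csv(cohort$truth, file.path(dir, "truth.csv"), na = "")
  invisible(dir)
}

#' @rdname write_cohort
#' @param path Path to a records CSV file.
#' @export
read_cohort <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
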